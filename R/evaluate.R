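# Supervised benchmark: four classifier families (MLP, ridge logistic
# regression, random forest, RBF SVM), 10-repeat stratified 4-fold
# cross-validation, AUC-ROC per held-out fold.
#
# The positive class is "PwMS" throughout; all families emit continuous
# scores (probabilities or decision values), never hard labels.

POSITIVE_CLASS <- "PwMS"

#' Classifier specification
#'
#' Families and fixed hyperparameters: `NN` is a fully connected network
#' with hidden layers (200, 100, 10) and rectified-linear activations,
#' trained with Adam and early stopping; `LR` is logistic regression with a
#' quadratic (ridge) penalty; `RF` is a random forest of 100 fully grown
#' trees; `SVM` uses an RBF kernel with the scale heuristic for the kernel
#' width and regularization `C = 1`.
#'
#' @param family One of `"NN"`, `"LR"`, `"RF"`, `"SVM"`.
#' @param ... Overrides of the family's default hyperparameters.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("NN", "LR", "RF", "SVM"), ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    NN = list(hidden = c(200, 100, 10), activation = "relu", lr = 1e-3,
              max_epochs = 300, patience = 20, val_fraction = 0.2,
              scale = TRUE),
    LR = list(lambda = NULL, scale = TRUE), # NULL -> 1 / n_train
    RF = list(n_trees = 100, scale = FALSE),
    SVM = list(cost = 1, gamma = "scale", scale = TRUE))
  over <- list(...)
  defaults[names(over)] <- over
  structure(list(family = family, hyperparameters = defaults),
            class = "classifier_spec")
}

#' Default benchmark model set
#'
#' @return List of the four [classifier_spec()]s.
#' @export
default_classifiers <- function() {
  lapply(c("NN", "LR", "RF", "SVM"), classifier_spec)
}

# column-wise z-scoring fitted on training rows; constant columns pass through
fit_scaler <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s == 0 | !is.finite(s)] <- 1
  list(mu = mu, s = s)
}
apply_scaler <- function(sc, X) sweep(sweep(X, 2, sc$mu), 2, sc$s, "/")

## ---- multilayer perceptron (Adam, early stopping) ----------------------

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

mlp_init <- function(sizes, rng) {
  lapply(seq_len(length(sizes) - 1), function(i) {
    fan_in <- sizes[i]
    list(W = matrix(rng(sizes[i] * sizes[i + 1]) * sqrt(2 / fan_in),
                    sizes[i], sizes[i + 1]),
         b = rep(0, sizes[i + 1]))
  })
}

mlp_forward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1)
  acts[[1]] <- X
  for (i in seq_along(layers)) {
    z <- sweep(acts[[i]] %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    acts[[i + 1]] <- if (i < length(layers)) relu(z) else sigmoid(z)
  }
  acts
}

# full-batch Adam on binary cross-entropy
mlp_fit <- function(X, y, hidden, lr = 1e-3, max_epochs = 300, patience = 20,
                    val_fraction = 0.2, seed = 1) {
  set.seed(seed)
  rng <- function(n) rnorm(n)
  n <- nrow(X)
  # stratified validation split for early stopping
  idx_pos <- which(y == 1); idx_neg <- which(y == 0)
  nv_pos <- max(1, round(val_fraction * length(idx_pos)))
  nv_neg <- max(1, round(val_fraction * length(idx_neg)))
  val <- c(sample(idx_pos, nv_pos), sample(idx_neg, nv_neg))
  tr <- setdiff(seq_len(n), val)
  Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
  Xv <- X[val, , drop = FALSE]; yv <- y[val]
  sizes <- c(ncol(X), hidden, 1)
  layers <- mlp_init(sizes, rng)
  m <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  v <- m
  best <- list(loss = Inf, layers = layers, epoch = 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (epoch in seq_len(max_epochs)) {
    acts <- mlp_forward(layers, Xtr)
    p <- acts[[length(acts)]]
    delta <- (p - ytr) / length(ytr)          # d(BCE)/dz at sigmoid output
    for (i in rev(seq_along(layers))) {
      gW <- crossprod(acts[[i]], delta)
      gb <- colSums(delta)
      if (i > 1)
        delta <- (delta %*% t(layers[[i]]$W)) * (acts[[i]] > 0)
      m[[i]]$W <- b1 * m[[i]]$W + (1 - b1) * gW
      m[[i]]$b <- b1 * m[[i]]$b + (1 - b1) * gb
      v[[i]]$W <- b2 * v[[i]]$W + (1 - b2) * gW^2
      v[[i]]$b <- b2 * v[[i]]$b + (1 - b2) * gb^2
      mhatW <- m[[i]]$W / (1 - b1^epoch); vhatW <- v[[i]]$W / (1 - b2^epoch)
      mhatb <- m[[i]]$b / (1 - b1^epoch); vhatb <- v[[i]]$b / (1 - b2^epoch)
      layers[[i]]$W <- layers[[i]]$W - lr * mhatW / (sqrt(vhatW) + eps)
      layers[[i]]$b <- layers[[i]]$b - lr * mhatb / (sqrt(vhatb) + eps)
    }
    pv <- mlp_forward(layers, Xv)[[length(layers) + 1]]
    pv <- pmin(1 - 1e-12, pmax(1e-12, pv))
    vloss <- -mean(yv * log(pv) + (1 - yv) * log(1 - pv))
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, layers = layers, epoch = epoch)
    } else if (epoch - best$epoch >= patience) break
  }
  best$layers
}

mlp_predict <- function(layers, X) {
  as.vector(mlp_forward(layers, X)[[length(layers) + 1]])
}

## ---- family fit/predict -------------------------------------------------

fit_and_score <- function(spec, Xtr, ytr, Xte, seed) {
  hp <- spec$hyperparameters
  if (isTRUE(hp$scale)) {
    sc <- fit_scaler(Xtr)
    Xtr <- apply_scaler(sc, Xtr)
    Xte <- apply_scaler(sc, Xte)
  }
  ybin <- as.numeric(ytr == POSITIVE_CLASS)
  switch(spec$family,
    NN = {
      layers <- mlp_fit(Xtr, ybin, hidden = hp$hidden, lr = hp$lr,
                        max_epochs = hp$max_epochs, patience = hp$patience,
                        val_fraction = hp$val_fraction, seed = seed)
      mlp_predict(layers, Xte)
    },
    LR = {
      lam <- if (is.null(hp$lambda)) 1 / length(ytr) else hp$lambda
      # glmnet advises against classes below 8 observations; small folds are
      # routine in this benchmark, so that advisory is muffled
      fit <- withCallingHandlers(
        glmnet::glmnet(Xtr, factor(ytr, levels = c("HV", "PwMS")),
                       family = "binomial", alpha = 0,
                       lambda = sort(c(lam, lam * 10, lam * 100),
                                     decreasing = TRUE),
                       standardize = FALSE),
        warning = function(w) {
          if (grepl("fewer than 8", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      as.vector(predict(fit, Xte, s = lam, type = "response"))
    },
    RF = {
      fit <- ranger::ranger(x = data.frame(Xtr, check.names = FALSE),
                            y = factor(ytr, levels = c("HV", "PwMS")),
                            num.trees = hp$n_trees, probability = TRUE,
                            min.node.size = 1, seed = seed, num.threads = 1)
      predict(fit, data.frame(Xte, check.names = FALSE),
              num.threads = 1)$predictions[, POSITIVE_CLASS]
    },
    SVM = {
      gamma <- if (identical(hp$gamma, "scale")) {
        vx <- stats::var(as.vector(Xtr))
        if (vx <= 0) 1 / ncol(Xtr) else 1 / (ncol(Xtr) * vx)
      } else hp$gamma
      yf <- factor(ytr, levels = c("HV", "PwMS"))
      fit <- e1071::svm(Xtr, yf, kernel = "radial", gamma = gamma,
                        cost = hp$cost, scale = FALSE)
      dv <- predict(fit, Xte, decision.values = TRUE)
      dv <- attr(dv, "decision.values")
      # orient decision values so larger means more PwMS-like
      if (grepl("^PwMS", colnames(dv)[1])) as.vector(dv[, 1])
      else -as.vector(dv[, 1])
    })
}

## ---- ROC / AUC ----------------------------------------------------------

#' ROC curve points
#'
#' Standard threshold sweep over the unique score values, from the most
#' permissive to the strictest threshold, returning one (FPR, TPR) point per
#' threshold step. The trapezoidal area under these points equals
#' [auc_score()] exactly (ties produce diagonal segments).
#'
#' @param scores Continuous classifier outputs (higher = more positive).
#' @param labels Vector with both classes present; the positive class is
#'   `"PwMS"` (or `1`/`TRUE` for numeric/logical labels).
#' @return Data frame with columns `fpr`, `tpr`, starting at (0, 0) and
#'   ending at (1, 1).
#' @export
roc_points <- function(scores, labels) {
  pos <- labels_to_binary(labels)
  if (all(pos) || all(!pos))
    stop("both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # step through unique thresholds; ties move diagonally in one step
  brk <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(p)[brk]
  fp <- cumsum(!p)[brk]
  data.frame(fpr = c(0, fp / sum(!pos)), tpr = c(0, tp / sum(pos)))
}

labels_to_binary <- function(labels) {
  if (is.character(labels) || is.factor(labels))
    as.character(labels) == POSITIVE_CLASS
  else as.logical(labels)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_points()]; identical to the rank-statistic
#' (Mann-Whitney) formulation with ties counted half.
#'
#' @inheritParams roc_points
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  r <- roc_points(scores, labels)
  sum(diff(r$fpr) * (r$tpr[-1] + r$tpr[-nrow(r)]) / 2)
}

## ---- repeated stratified cross-validation -------------------------------

stratified_folds <- function(labels, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- sample(which(labels == g))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Repeated stratified cross-validation AUC benchmark
#'
#' Fold assignment is stratified by group and re-randomized on every repeat
#' from the master seed. For each fold, any supplied transform pipeline is
#' fitted on the training folds only, each classifier family is fitted on
#' the (transformed) training rows, continuous scores are produced for the
#' held-out fold, and the fold AUC is recorded. All
#' `n_repeats * n_folds` records per family are returned.
#'
#' @param features A [feature_matrix()].
#' @param specs List of [classifier_spec()]s (default all four families).
#' @param n_folds,n_repeats Cross-validation shape (default 4 x 10).
#' @param seed Master seed controlling folds and model initializations.
#' @param transform `NULL`, or a function `(train_fm, test_fm, seed)`
#'   returning `list(train =, test =)` feature matrices (e.g. wrapping
#'   [pca_reduce()] or [rf_importance_select()]); it must not look at test
#'   labels.
#' @return An object of class `cv_result`: data frame with columns
#'   `repeat_index`, `fold`, `family`, `configuration`, `auc`, `n_test`.
#' @export
repeated_cv <- function(features, specs = default_classifiers(),
                        n_folds = 4, n_repeats = 10, seed = 1,
                        transform = NULL) {
  labels <- features$labels
  if (min(table(labels)) < n_folds)
    stop("need at least n_folds subjects per class for stratified folds",
         call. = FALSE)
  records <- list()
  for (r in seq_len(n_repeats)) {
    fold <- stratified_folds(labels, n_folds, seed = seed * 1000L + r)
    for (f in seq_len(n_folds)) {
      te <- which(fold == f)
      tr <- which(fold != f)
      sub_fm <- function(idx) feature_matrix(
        features$X[idx, , drop = FALSE], features$subject_ids[idx],
        labels[idx], features$config_tag)
      fm_tr <- sub_fm(tr); fm_te <- sub_fm(te)
      if (!is.null(transform)) {
        tt <- transform(fm_tr, fm_te, seed * 1000L + r * 10L + f)
        fm_tr <- tt$train; fm_te <- tt$test
      }
      for (spec in specs) {
        sc <- fit_and_score(spec, fm_tr$X, fm_tr$labels, fm_te$X,
                            seed = seed * 1000L + r * 10L + f)
        records[[length(records) + 1]] <- data.frame(
          repeat_index = r, fold = f, family = spec$family,
          configuration = features$config_tag,
          auc = auc_score(sc, labels[te]), n_test = length(te))
      }
    }
  }
  out <- do.call(rbind, records)
  class(out) <- c("cv_result", "data.frame")
  attr(out, "seed") <- seed
  out
}

#' Summarize a cross-validation result
#'
#' Per (configuration, family): the mean and standard deviation over the
#' repeat-level means (each repeat's mean averages its folds), plus the
#' cross-family average and a flag for average `>= 0.70`.
#'
#' @param results A [repeated_cv()] result (several may be `rbind`ed).
#' @return Data frame with columns `configuration`, `architecture` (parsed
#'   from the configuration tag), `family`, `mean_auc`, `sd_auc`,
#'   `family_average`, `flag_ge_0.70`.
#' @export
summarize_cv <- function(results) {
  if (is.null(results) || nrow(results) == 0)
    stop("empty cross-validation result", call. = FALSE)
  keys <- unique(results[, c("configuration", "family")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- results[results$configuration == keys$configuration[i] &
                   results$family == keys$family[i], ]
    rep_means <- tapply(sub$auc, sub$repeat_index, mean)
    data.frame(configuration = keys$configuration[i],
               architecture = strsplit(keys$configuration[i], "/")[[1]][1],
               family = keys$family[i],
               mean_auc = mean(rep_means),
               sd_auc = if (length(rep_means) > 1) sd(rep_means) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  avg <- tapply(out$mean_auc, out$configuration, mean)
  out$family_average <- as.numeric(avg[out$configuration])
  out$flag_ge_0.70 <- out$family_average >= 0.70
  out[order(out$configuration, out$family), ]
}
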