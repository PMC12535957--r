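#' @useDynLib topoconnectome, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor prcomp predict qnorm runif rbinom rbeta rnorm sd var
#' @importFrom utils combn read.csv write.csv
NULL

MODALITIES <- c("GM", "DTI", "FMRI", "SUPRA")
SPACES <- c("raw", "inverted")
ASYMMETRY_TOL <- 1e-9

#' Weighted brain network over a labeled parcellation
#'
#' A single modality's symmetric adjacency matrix with entries in `[0, 1]`
#' (entries in `[-1, 1]` are admitted only for raw functional correlation
#' networks, pending the absolute-value transform) and a zero diagonal.
#' The `space` flag records whether edge weights are connectivity scores
#' (`"raw"`) or dissimilarities obtained by the inversion `1 - e` applied
#' before persistent homology (`"inverted"`).
#'
#' @param weights Square symmetric numeric matrix, zero diagonal.
#' @param region_labels Character vector of region identifiers, one per row.
#' @param modality One of `"GM"`, `"DTI"`, `"FMRI"`, `"SUPRA"`.
#' @param space One of `"raw"`, `"inverted"`.
#' @return An object of class `weighted_network`.
#' @export
weighted_network <- function(weights, region_labels = NULL,
                             modality = c("GM", "DTI", "FMRI", "SUPRA"),
                             space = c("raw", "inverted")) {
  modality <- match.arg(modality)
  space <- match.arg(space)
  weights <- as.matrix(weights)
  if (is.null(region_labels)) {
    region_labels <- if (!is.null(rownames(weights))) rownames(weights)
                     else sprintf("r%03d", seq_len(nrow(weights)))
  }
  net <- structure(
    list(weights = unname(weights), region_labels = as.character(region_labels),
         modality = modality, space = space),
    class = "weighted_network")
  validate_network(net)
  net
}

#' Validate a weighted network's invariants
#'
#' Checks squareness, label count, symmetry (to tolerance 1e-9), value range
#' and zero diagonal. Negative entries are only admitted for raw FMRI
#' networks (signed correlations awaiting [absolute_correlations()]).
#'
#' @param net A `weighted_network`.
#' @return The network, invisibly. Errors on any violation.
#' @export
validate_network <- function(net) {
  w <- net$weights
  if (!is.matrix(w) || nrow(w) != ncol(w))
    stop("network weights must form a square matrix", call. = FALSE)
  if (length(net$region_labels) != nrow(w))
    stop("number of region labels (", length(net$region_labels),
         ") does not match matrix order (", nrow(w), ")", call. = FALSE)
  if (anyNA(w) || any(!is.finite(w)))
    stop("network weights must be finite and non-missing", call. = FALSE)
  asym <- max(abs(w - t(w)))
  if (asym > ASYMMETRY_TOL)
    stop(sprintf("matrix asymmetry %.3g exceeds tolerance %.0e", asym,
                 ASYMMETRY_TOL), call. = FALSE)
  if (any(diag(w) != 0))
    stop("network diagonal must be zero", call. = FALSE)
  lo <- if (net$modality == "FMRI" && net$space == "raw") -1 else 0
  if (min(w) < lo || max(w) > 1)
    stop(sprintf("edge weights must lie in [%d, 1] for %s %s networks",
                 lo, net$space, net$modality), call. = FALSE)
  invisible(net)
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network> %s (%s space), %d regions, mean off-diag %.3f\n",
              x$modality, x$space, length(x$region_labels),
              mean(x$weights[upper.tri(x$weights)])))
  invisible(x)
}

#' Number of regions of a network
#' @param net A `weighted_network`.
#' @return Integer parcellation size.
#' @export
n_regions <- function(net) length(net$region_labels)

#' One subject: three modality networks plus covariates
#'
#' @param subject_id Character identifier.
#' @param group `"HV"` or `"PwMS"`.
#' @param age Age in years.
#' @param sex `"F"` or `"M"`.
#' @param networks Named list with elements `GM`, `DTI`, `FMRI`, each a
#'   [weighted_network()] sharing the same region labels in the same order.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, group = c("HV", "PwMS"), age,
                           sex = c("F", "M"), networks) {
  group <- match.arg(group)
  sex <- match.arg(sex)
  need <- c("GM", "DTI", "FMRI")
  if (!all(need %in% names(networks)))
    stop("subject ", subject_id, ": networks must contain GM, DTI and FMRI",
         call. = FALSE)
  labs <- networks$GM$region_labels
  for (m in need) {
    if (!identical(networks[[m]]$region_labels, labs))
      stop("subject ", subject_id, ": region labels of ", m,
           " differ from GM (order matters)", call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id), group = group,
                 age = as.numeric(age), sex = sex,
                 networks = networks[need]),
            class = "subject_record")
}

#' A cohort of subjects sharing one parcellation
#'
#' @param subjects List of [subject_record()] objects.
#' @param provenance Free-text description of where the data came from
#'   (generator seed for synthetic cohorts).
#' @return An object of class `cohort`.
#' @export
cohort <- function(subjects, provenance = "") {
  if (length(subjects) == 0) stop("cohort needs at least one subject", call. = FALSE)
  labs <- subjects[[1]]$networks$GM$region_labels
  for (s in subjects) {
    if (!identical(s$networks$GM$region_labels, labs))
      stop("subject ", s$subject_id,
           ": parcellation differs from the rest of the cohort", call. = FALSE)
  }
  structure(list(subjects = subjects, parcellation_size = length(labs),
                 region_labels = labs, provenance = provenance),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  g <- cohort_groups(x)
  cat(sprintf("<cohort> %d subjects (%d HV, %d PwMS), %d regions\n",
              length(x$subjects), sum(g == "HV"), sum(g == "PwMS"),
              x$parcellation_size))
  invisible(x)
}

#' Group labels of a cohort
#' @param ch A [cohort()].
#' @return Character vector of `"HV"` / `"PwMS"`, one per subject.
#' @export
cohort_groups <- function(ch) vapply(ch$subjects, function(s) s$group, "")

#' Read a dense square matrix file as a weighted network
#'
#' The file must be a headerless delimited numeric table with as many rows as
#' columns. Asymmetry up to 1e-9 is repaired by averaging; larger asymmetry is
#' treated as corruption and rejected. A nonzero diagonal is forced to zero
#' with a warning. Negative entries are only accepted for `modality = "FMRI"`
#' with `space = "raw"` (signed correlations).
#'
#' @param path File path.
#' @param delimiter Field delimiter (default `","`).
#' @param modality,space Passed to [weighted_network()].
#' @param region_labels Optional label vector; defaults to `r001...`.
#' @return A [weighted_network()].
#' @export
read_square_matrix <- function(path, delimiter = ",",
                               modality = c("GM", "DTI", "FMRI", "SUPRA"),
                               space = c("raw", "inverted"),
                               region_labels = NULL) {
  modality <- match.arg(modality)
  space <- match.arg(space)
  w <- as.matrix(read.csv(path, header = FALSE, sep = delimiter))
  storage.mode(w) <- "double"
  if (nrow(w) != ncol(w))
    stop("file ", path, " is not square: ", nrow(w), " x ", ncol(w),
         call. = FALSE)
  if (anyNA(w)) stop("file ", path, " contains non-numeric entries", call. = FALSE)
  lo <- if (modality == "FMRI" && space == "raw") -1 else 0
  if (min(w) < lo || max(w) > 1)
    stop("file ", path, ": entries outside [", lo, ", 1]", call. = FALSE)
  asym <- max(abs(w - t(w)))
  if (asym > ASYMMETRY_TOL)
    stop("file ", path, sprintf(": asymmetry %.3g above tolerance; refusing to symmetrize",
                                asym), call. = FALSE)
  w <- (w + t(w)) / 2
  if (any(diag(w) != 0)) {
    warning("file ", path, ": nonzero diagonal forced to zero", call. = FALSE)
    diag(w) <- 0
  }
  weighted_network(w, region_labels = region_labels, modality = modality,
                   space = space)
}

#' Write a weighted network to a delimited file
#'
#' @param net A [weighted_network()].
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @export
write_square_matrix <- function(net, path, delimiter = ",") {
  utils::write.table(net$weights, path, sep = delimiter, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a cohort from a JSON manifest
#'
#' The manifest is a JSON object with fields `region_labels` (optional) and
#' `subjects`, a list of records with `subject_id`, `group`, `age`, `sex` and
#' `paths` naming the `gm`, `dti` and `fmri` matrix files (relative paths are
#' resolved against the manifest's directory). All subjects must share the
#' same region labels in the same order.
#'
#' FMRI matrices are read as raw correlations and may carry signed entries
#' in `[-1, 1]`, pending [absolute_correlations()].
#'
#' @param manifest_path Path to the JSON manifest.
#' @return A [cohort()].
#' @export
read_cohort <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  if (is.null(man$subjects) || length(man$subjects) == 0)
    stop("manifest has no subjects", call. = FALSE)
  base <- dirname(normalizePath(manifest_path))
  labs <- if (!is.null(man$region_labels)) unlist(man$region_labels) else NULL
  subjects <- lapply(man$subjects, function(rec) {
    sid <- rec$subject_id
    for (m in c("gm", "dti", "fmri")) {
      if (is.null(rec$paths[[m]]))
        stop("subject ", sid, ": manifest is missing the ", toupper(m),
             " matrix path", call. = FALSE)
    }
    resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
    nets <- list(
      GM = read_square_matrix(resolve(rec$paths$gm), modality = "GM",
                              region_labels = labs),
      DTI = read_square_matrix(resolve(rec$paths$dti), modality = "DTI",
                               region_labels = labs),
      FMRI = read_square_matrix(resolve(rec$paths$fmri), modality = "FMRI",
                                region_labels = labs))
    subject_record(sid, rec$group, rec$age, rec$sex, nets)
  })
  ch <- cohort(subjects, provenance = paste0("manifest:", manifest_path))
  ch
}

#' Write a cohort to disk as matrices plus a JSON manifest
#'
#' @param ch A [cohort()].
#' @param dir Output directory (created if missing).
#' @return Path to the written manifest, invisibly.
#' @export
write_cohort <- function(ch, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- lapply(ch$subjects, function(s) {
    paths <- list()
    for (m in c("GM", "DTI", "FMRI")) {
      fn <- sprintf("%s_%s.csv", s$subject_id, tolower(m))
      write_square_matrix(s$networks[[m]], file.path(dir, fn))
      paths[[tolower(m)]] <- fn
    }
    list(subject_id = s$subject_id, group = s$group, age = s$age,
         sex = s$sex, paths = paths)
  })
  man <- list(region_labels = ch$region_labels, provenance = ch$provenance,
              subjects = recs)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mp)
}

#' Write a cross-validation summary as a results table
#'
#' One row per (configuration, architecture); one `mean±std` column per model
#' family plus the cross-family average, mirroring the usual benchmark table
#' layout. Values are printed to three decimals.
#'
#' @param summary A summary data frame from [summarize_cv()].
#' @param path Output CSV path.
#' @export
write_results_table <- function(summary, path) {
  if (is.null(summary) || nrow(summary) == 0)
    stop("empty summary: nothing to write", call. = FALSE)
  fams <- sort(unique(summary$family))
  keys <- unique(summary[, c("configuration", "architecture"), drop = FALSE])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- summary[summary$configuration == keys$configuration[i] &
                   summary$architecture == keys$architecture[i], ]
    cells <- vapply(fams, function(f) {
      r <- sub[sub$family == f, ]
      if (nrow(r) == 0) NA_character_
      else sprintf("%.3f±%.3f", r$mean_auc, r$sd_auc)
    }, "")
    avg <- mean(sub$mean_auc)
    c(configuration = keys$configuration[i],
      architecture = keys$architecture[i], cells,
      average = sprintf("%.3f", avg),
      flag_ge_0.70 = as.character(avg >= 0.70))
  })
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Re-read a results table written by [write_results_table()]
#'
#' Parses the `mean±std` cells back into numeric columns.
#'
#' @param path CSV path.
#' @return Long-format data frame with columns `configuration`,
#'   `architecture`, `family`, `mean_auc`, `sd_auc`.
#' @export
read_results_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  fams <- setdiff(names(tab), c("configuration", "architecture", "average",
                                "flag_ge_0.70"))
  out <- do.call(rbind, lapply(fams, function(f) {
    parts <- strsplit(tab[[f]], "±")
    data.frame(configuration = tab$configuration,
               architecture = tab$architecture, family = f,
               mean_auc = as.numeric(vapply(parts, `[`, "", 1)),
               sd_auc = as.numeric(vapply(parts, `[`, "", 2)),
               stringsAsFactors = FALSE)
  }))
  out[order(out$configuration, out$architecture, out$family), ]
}

#' Export a persistence diagram as CSV
#'
#' Columns `dim`, `birth`, `death`; infinite deaths are written as `"inf"`.
#'
#' @param diagram A persistence diagram from [compute_persistence()].
#' @param path Output path.
#' @export
write_diagram <- function(diagram, path) {
  d <- data.frame(dim = diagram$dimension, birth = diagram$birth,
                  death = ifelse(is.infinite(diagram$death), "inf",
                                 as.character(diagram$death)))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

# dimension-preserving clamp (pmin/pmax with a leading scalar drops dims)
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
clamp_range <- function(x, lo) {
  x[x < lo] <- lo
  x[x > 1] <- 1
  x
}
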