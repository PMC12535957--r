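# Exhaustive shortest-path oracles for small graphs (N <= 7): every simple
# path between each pair is enumerated, with edge length 1/weight.

exhaustive_paths <- function(w) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  best <- matrix(Inf, n, n); diag(best) <- 0
  npaths <- matrix(0, n, n)
  through <- array(0, c(n, n, n)) # shortest paths s->t passing through v
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    inner <- setdiff(1:n, c(s, t))
    paths <- list(c(s, t))
    for (k in seq_along(inner)) {
      if (k > length(inner)) break
      mids <- combn(inner, k)
      for (j in seq_len(ncol(mids)))
        for (perm in combinat_perms(mids[, j]))
          paths[[length(paths) + 1]] <- c(s, perm, t)
    }
    lens <- vapply(paths, function(p)
      sum(len[cbind(p[-length(p)], p[-1])]), 0)
    d <- min(lens)
    best[s, t] <- best[t, s] <- d
    if (is.finite(d)) {
      sel <- which(abs(lens - d) < 1e-9)
      npaths[s, t] <- npaths[t, s] <- length(sel)
      for (i in sel) {
        mid <- setdiff(paths[[i]], c(s, t))
        for (v in mid) {
          through[s, t, v] <- through[s, t, v] + 1
          through[t, s, v] <- through[t, s, v] + 1
        }
      }
    }
  }
  list(dist = best, npaths = npaths, through = through)
}

combinat_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in combinat_perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

oracle_betweenness <- function(w) {
  n <- nrow(w)
  ep <- exhaustive_paths(w)
  b <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (ep$npaths[s, t] == 0) next
    for (v in setdiff(1:n, c(s, t)))
      b[v] <- b[v] + ep$through[s, t, v] / ep$npaths[s, t]
  }
  b / ((n - 1) * (n - 2) / 2)
}

oracle_closeness <- function(w) {
  n <- nrow(w)
  d <- exhaustive_paths(w)$dist
  vapply(1:n, function(v) {
    dv <- d[v, -v]; dv <- dv[is.finite(dv)]
    if (length(dv) == 0 || sum(dv) == 0) return(0)
    (length(dv) / (n - 1)) * (length(dv) / sum(dv))
  }, 0)
}

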