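# Independent reference implementations used as oracles. These deliberately
# mirror the mathematical definitions with naive code and stay independent of
# the package's optimized paths.

# Greedy L2 boosting, plain R: recomputes training/validation errors from the
# raw matrices at every step.
r_boost_reference <- function(Xtr, ytr, Xv, yv, delta, patience, max_steps = 10000L) {
  p <- ncol(Xtr)
  beta <- best_beta <- numeric(p)
  best_verr <- sum(yv^2)
  since <- 0L
  train_errs <- sum(ytr^2)
  for (step in seq_len(max_steps)) {
    base_err <- sum((ytr - Xtr %*% beta)^2)
    cand <- matrix(NA_real_, p, 2L)
    for (j in seq_len(p)) for (si in 1:2) {
      s <- c(1, -1)[si]
      bj <- beta; bj[j] <- bj[j] + s * delta
      cand[j, si] <- sum((ytr - Xtr %*% bj)^2)
    }
    best <- which(cand == min(cand), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
    if (!(cand[best[1L], best[2L]] < base_err)) break
    beta[best[1L]] <- beta[best[1L]] + c(1, -1)[best[2L]] * delta
    train_errs <- c(train_errs, cand[best[1L], best[2L]])
    verr <- sum((yv - Xv %*% beta)^2)
    if (verr < best_verr) {
      best_verr <- verr; best_beta <- beta; since <- 0L
    } else if ((since <- since + 1L) >= patience) break
  }
  list(beta = best_beta, train_errors = train_errs)
}

# TFCE by explicit threshold summation, clusters via igraph components.
tfce_reference <- function(tmap, adjacency, E = 0.5, H = 2, step = 0.1) {
  n <- length(tmap)
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- adjacency[[i]]
    if (length(nb)) cbind(i, nb) else NULL
  }))
  out <- numeric(n)
  for (sgn in c(1, -1)) {
    m <- sgn * tmap
    if (max(m) <= 0) next
    for (h in seq(step, max(m) + step / 2, by = step)) {
      if (h > max(m)) break
      active <- which(m >= h)
      if (!length(active)) break
      g <- igraph::graph_from_data_frame(
        d = as.data.frame(edges[edges[, 1L] %in% active & edges[, 2L] %in% active, , drop = FALSE]),
        directed = FALSE,
        vertices = data.frame(name = as.character(active)))
      comp <- igraph::components(g)
      for (ci in seq_len(comp$no)) {
        mem <- as.integer(names(comp$membership)[comp$membership == ci])
        out[mem] <- out[mem] + sgn * length(mem)^E * h^H * step
      }
    }
  }
  out
}

# Exact two-sided Wilcoxon signed-rank p by enumeration of all sign patterns,
# following the convention of doubling the smaller tail.
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_null <- as.numeric(signs %*% rk)
  if (v_obs > n * (n + 1) / 4)
    p <- 2 * mean(v_null >= v_obs)
  else
    p <- 2 * mean(v_null <= v_obs)
  min(p, 1)
}

# Tiny deterministic feature set for design/boosting tests.
toy_features <- function(n = 900, n_bands = 2, seed = 1) {
  set.seed(seed)
  m <- matrix(0, n_bands, n)
  for (b in seq_len(n_bands))
    m[b, ] <- abs(stats::filter(rnorm(n + 20), rep(1 / 5, 5), sides = 1))[21:(n + 20)]
  feature_set(list(spectrogram = m))
}
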