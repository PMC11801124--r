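#' Adjacency structures for cluster statistics
#'
#' `chain_adjacency()` connects nearest temporal neighbors of a 1-D axis;
#' `coord_adjacency()` connects channels closer than a distance threshold
#' (e.g. 1.5 x the source-grid spacing). Both return the list-of-neighbors
#' representation used by [tfce_transform()].
#'
#' @param n number of elements (time points).
#' @return list of integer vectors: neighbors of each element (1-based).
#' @export
chain_adjacency <- function(n) {
  lapply(seq_len(n), function(i)
    c(if (i > 1L) i - 1L, if (i < n) i + 1L))
}

#' @rdname chain_adjacency
#' @param coords channels x 3 coordinate matrix (mm).
#' @param max_dist_mm connection threshold in mm.
#' @export
coord_adjacency <- function(coords, max_dist_mm) {
  d <- as.matrix(stats::dist(coords))
  lapply(seq_len(nrow(d)), function(i)
    which(d[i, ] > 0 & d[i, ] <= max_dist_mm))
}

#' Threshold-free cluster enhancement
#'
#' Replaces a fixed cluster-forming threshold by integrating cluster support
#' over all thresholds: for each element, `sum_h extent(h)^E * h^H * step`
#' where `extent(h)` is the size of the supra-threshold cluster containing
#' the element at height `h` on the adjacency graph. Both signs are
#' enhanced; the result carries the sign of the input statistic.
#'
#' @param stat_map numeric statistic map (e.g. a t map).
#' @param adjacency list of integer neighbor vectors (see
#'   [chain_adjacency()]).
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param step threshold increment (default 0.1).
#' @return numeric vector of signed TFCE values.
#' @export
tfce_transform <- function(stat_map, adjacency, E = 0.5, H = 2, step = 0.1) {
  if (length(adjacency) != length(stat_map))
    stop("adjacency must have one entry per element")
  adjacency <- lapply(adjacency, as.integer)
  tfce_transform_cpp(as.numeric(stat_map), adjacency, E, H, step)
}

#' TFCE cluster permutation test for paired designs
#'
#' Dependent-sample t test at every element (time point or channel), enhanced
#' with TFCE, with family-wise error control via the permutation distribution
#' of the maximum |TFCE| under random within-subject sign flips of the
#' condition difference. Element-wise p values are the rank of the observed
#' |TFCE| against that null maximum distribution. Contiguous significant
#' elements are summarized as clusters with their extreme t value and the
#' Cohen's d of the subject-wise data averaged over the cluster's extent.
#'
#' @param condition_a,condition_b subjects x elements matrices (paired rows).
#' @param adjacency element adjacency (list of neighbor vectors).
#' @param n_perm number of sign-flip randomizations (default 10000; < 100
#'   triggers a warning).
#' @param E,H,step TFCE parameters (see [tfce_transform()]).
#' @param alpha significance level for cluster reporting.
#' @param seed integer seed for the sign flips (logged in the result).
#' @return an object of class `tfce_test`: element-wise `t_map`, `tfce_obs`,
#'   `p_map`, a `clusters` data frame (extent indices, extreme t, Cohen's d,
#'   p), the null maxima and the seed.
#' @export
tfce_permutation_test <- function(condition_a, condition_b, adjacency,
                                  n_perm = 10000L, E = 0.5, H = 2, step = 0.1,
                                  alpha = 0.05, seed = 1L) {
  a <- as.matrix(condition_a); b <- as.matrix(condition_b)
  if (!all(dim(a) == dim(b))) stop("conditions must be paired (equal dimensions)")
  ns <- nrow(a); ne <- ncol(a)
  if (length(adjacency) != ne) stop("adjacency must have one entry per element")
  if (n_perm < 100L) warning("fewer than 100 randomizations: p values are coarse")

  d <- a - b
  t_of <- function(m) {
    mu <- colMeans(m)
    s <- sqrt((colSums(m^2) - ns * mu^2) / (ns - 1))
    tt <- mu / (s / sqrt(ns))
    tt[!is.finite(tt)] <- 0
    tt
  }
  t_obs <- t_of(d)
  tfce_obs <- tfce_transform(t_obs, adjacency, E, H, step)

  set.seed(as.integer(seed))
  signs <- matrix(sample(c(-1, 1), n_perm * ns, replace = TRUE), n_perm, ns)
  mu_perm <- signs %*% d / ns                       # n_perm x ne
  ssq <- matrix(colSums(d^2), n_perm, ne, byrow = TRUE)
  s_perm <- sqrt((ssq - ns * mu_perm^2) / (ns - 1))
  t_perm <- mu_perm / (s_perm / sqrt(ns))
  t_perm[!is.finite(t_perm)] <- 0
  null_max <- vapply(seq_len(n_perm), function(i)
    max(abs(tfce_transform(t_perm[i, ], adjacency, E, H, step)), 0), 1)

  p_map <- vapply(abs(tfce_obs), function(v)
    (1 + sum(null_max >= v)) / (n_perm + 1), 1)

  sig <- which(p_map < alpha)
  clusters <- data.frame(elements = character(0), extent = integer(0),
                         t_extreme = numeric(0), cohens_d = numeric(0),
                         p = numeric(0))
  if (length(sig)) {
    lab <- integer(ne); cur <- 0L
    for (i in sig) {
      if (lab[i]) next
      cur <- cur + 1L
      stack <- i; lab[i] <- cur
      while (length(stack)) {
        u <- stack[length(stack)]; stack <- stack[-length(stack)]
        for (w in adjacency[[u]])
          if (w %in% sig && !lab[w]) { lab[w] <- cur; stack <- c(stack, w) }
      }
    }
    rows <- lapply(seq_len(cur), function(cl) {
      idx <- which(lab == cl)
      tt <- t_obs[idx]
      dm <- rowMeans(d[, idx, drop = FALSE])
      data.frame(elements = paste(idx, collapse = ","),
                 extent = length(idx),
                 t_extreme = tt[which.max(abs(tt))],
                 cohens_d = mean(dm) / sd(dm),
                 p = min(p_map[idx]))
    })
    clusters <- do.call(rbind, rows)
  }

  structure(list(t_map = t_obs, tfce_obs = tfce_obs, p_map = p_map,
                 clusters = clusters, null_max = null_max,
                 n_perm = n_perm, E = E, H = H, step = step,
                 alpha = alpha, seed = seed),
            class = "tfce_test")
}

#' @export
print.tfce_test <- function(x, ...) {
  cat("<tfce_test> ", length(x$t_map), " element(s), ", x$n_perm,
      " sign-flip randomizations (seed ", x$seed, ")\n", sep = "")
  cat("  min p =", format(min(x$p_map), digits = 3), "|",
      nrow(x$clusters), "significant cluster(s) at alpha =", x$alpha, "\n")
  invisible(x)
}

#' Paired condition comparison with normality-dependent test choice
#'
#' Tests paired per-subject scalars: if the differences pass a Shapiro-Wilk
#' normality test (alpha = 0.05), a dependent-sample t test is used with
#' Cohen's d = mean(diff)/sd(diff); otherwise a Wilcoxon signed-rank test
#' with the matched-pairs rank-biserial correlation
#' `r_C = (R+ - R-) / (R+ + R-)` over the signed ranks.
#'
#' @param a,b paired numeric vectors, n >= 5.
#' @param shapiro_alpha normality test level.
#' @return an object of class `paired_test`: `method`, `statistic`, `p.value`,
#'   `effect_size`, `effect_type` ("cohens_d" or "rank_biserial"),
#'   `shapiro_p`.
#' @export
paired_test <- function(a, b, shapiro_alpha = 0.05) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (length(a) < 5L) stop("need at least 5 pairs")
  d <- a - b
  if (all(d == 0) || sd(d) == 0)
    stop("degenerate paired comparison: differences have zero variance")
  sw <- shapiro.test(d)$p.value
  if (sw >= shapiro_alpha) {
    tt <- t.test(a, b, paired = TRUE)
    out <- list(method = "paired t", statistic = unname(tt$statistic),
                p.value = tt$p.value, effect_size = mean(d) / sd(d),
                effect_type = "cohens_d", shapiro_p = sw)
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = TRUE))
    dd <- d[d != 0]
    rk <- rank(abs(dd))
    rpos <- sum(rk[dd > 0]); rneg <- sum(rk[dd < 0])
    out <- list(method = "wilcoxon signed-rank", statistic = unname(wt$statistic),
                p.value = wt$p.value, effect_size = (rpos - rneg) / (rpos + rneg),
                effect_type = "rank_biserial", shapiro_p = sw)
  }
  structure(out, class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat("<paired_test> ", x$method, ": statistic = ",
      format(x$statistic, digits = 4), ", p = ", format(x$p.value, digits = 3),
      ", ", x$effect_type, " = ", format(x$effect_size, digits = 3),
      " (Shapiro p = ", format(x$shapiro_p, digits = 3), ")\n", sep = "")
  invisible(x)
}
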