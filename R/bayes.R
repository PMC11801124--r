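jags_student_t_model <- "
model {
  for (i in 1:N) {
    y[i] ~ dt(mu[i], tau, nu)
    mu[i] <- a + u[subj[i]] + b * x[i]
  }
  # non-centered random intercepts for better Gibbs mixing of sigma_u
  for (s in 1:S) {
    u_raw[s] ~ dnorm(0, 1)
    u[s] <- sigma_u * u_raw[s]
  }
  a ~ dnorm(0, 1e-4)
  b ~ dnorm(0, 1e-4)
  # lower bound keeps the likelihood finite for (near-)perfectly collinear
  # inputs; negligible on z-scored data
  sigma ~ dt(0, 1, 3) T(0.001,)
  tau <- pow(sigma, -2)
  sigma_u ~ dt(0, 1, 3) T(0,)
  nu ~ dgamma(2, 0.1)
}"

# Split-Rhat: each chain is halved and the potential scale reduction factor
# is computed over the 2*m half-chains (rank-agnostic classic formula).
split_rhat <- function(draws_by_chain) {
  halves <- unlist(lapply(draws_by_chain, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1L]])
  means <- vapply(halves, mean, 1)
  vars <- vapply(halves, var, 1)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bayesian multilevel regression of behavior on neural tracking
#'
#' Fits `outcome ~ 1 + predictor + (1 | subject)` with Student-t observation
#' noise by MCMC (JAGS). Both variables are z-scored before fitting, so the
#' slope `b` is standardized. Weakly informative priors are used: wide
#' normals on the intercept and slope, half-Student-t(3) on the residual and
#' intercept scales, and Gamma(2, 0.1) on the Student-t degrees of freedom.
#' Reported are the posterior of `b` with an 89\% equal-tailed credible
#' interval, the posterior probability that `b > 0` (in \%), split-R-hat and
#' effective sample size diagnostics, and the joint significance flag of the
#' decision rule: significant iff 0 lies outside the 89\% CI *and*
#' `PP(b > 0)` is below 5.5\% or above 94.5\%.
#'
#' @param outcome numeric outcome, one value per subject-condition cell.
#' @param predictor numeric predictor (e.g. fROI-averaged tracking).
#' @param subject_ids subject identifier per observation (>= 2 observations
#'   per subject: repeated measures).
#' @param n_draws post-warmup draws per chain (default 1500).
#' @param n_warmup adaptation + burn-in draws per chain (default 1000).
#' @param n_chains number of chains (default 4).
#' @param seed integer seed (also seeds each chain's RNG).
#' @return an object of class `bayes_fit` with elements `b_draws`, `b_mean`,
#'   `ci_89`, `pp_gt0`, `nu_mean`, `subject_intercepts`, `diagnostics`
#'   (per-parameter R-hat and ESS), `significant`, `reliable`, `seed`.
#' @export
fit_multilevel <- function(outcome, predictor, subject_ids, n_draws = 1500L,
                           n_warmup = 1000L, n_chains = 4L, seed = 1L) {
  if (length(outcome) != length(predictor) ||
      length(outcome) != length(subject_ids))
    stop("outcome, predictor and subject_ids must have equal length")
  keep <- is.finite(outcome) & is.finite(predictor)
  outcome <- outcome[keep]; predictor <- predictor[keep]
  subject_ids <- subject_ids[keep]
  if (any(table(subject_ids) < 2L))
    stop("each subject needs >= 2 observations (repeated measures)")
  subj <- match(subject_ids, unique(subject_ids))
  y <- as.numeric(scale(outcome))
  x <- as.numeric(scale(predictor))
  if (anyNA(y) || anyNA(x)) stop("zero-variance outcome or predictor")

  inits <- lapply(seq_len(n_chains), function(i)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + i))
  jm <- rjags::jags.model(textConnection(jags_student_t_model),
                          data = list(y = y, x = x, subj = subj,
                                      N = length(y), S = max(subj)),
                          inits = inits, n.chains = n_chains,
                          n.adapt = max(100L, n_warmup %/% 2L), quiet = TRUE)
  update(jm, n.iter = max(100L, n_warmup %/% 2L), progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("a", "b", "sigma", "sigma_u", "nu", "u"),
                              n.iter = n_draws, progress.bar = "none")

  pars <- c("a", "b", "sigma", "sigma_u", "nu")
  diag <- data.frame(parameter = pars,
                     rhat = vapply(pars, function(p)
                       split_rhat(lapply(samp, function(ch) as.numeric(ch[, p]))), 1),
                     ess = vapply(pars, function(p)
                       as.numeric(coda::effectiveSize(samp[, p])), 1))
  b_draws <- as.numeric(unlist(lapply(samp, function(ch) ch[, "b"])))
  ci <- unname(quantile(b_draws, c(0.055, 0.945)))
  pp <- 100 * mean(b_draws > 0)
  u_cols <- grep("^u\\[", colnames(samp[[1L]]), value = TRUE)
  u_means <- vapply(u_cols, function(cn)
    mean(unlist(lapply(samp, function(ch) as.numeric(ch[, cn])))), 1)

  structure(list(
    b_draws = b_draws, b_mean = mean(b_draws), ci_89 = ci, pp_gt0 = pp,
    nu_mean = mean(unlist(lapply(samp, function(ch) as.numeric(ch[, "nu"])))),
    intercept_mean = mean(unlist(lapply(samp, function(ch) as.numeric(ch[, "a"])))),
    subject_intercepts = unname(u_means),
    diagnostics = diag,
    significant = (ci[1L] > 0 || ci[2L] < 0) && (pp < 5.5 || pp > 94.5),
    reliable = all(diag$rhat < 1.01) && all(diag$ess > 400),
    n_obs = length(y), n_subjects = max(subj),
    n_chains = n_chains, n_draws = n_draws, seed = as.integer(seed)),
    class = "bayes_fit")
}

#' @export
print.bayes_fit <- function(x, ...) {
  cat("<bayes_fit> outcome ~ 1 + predictor + (1 | subject), Student-t errors\n")
  cat(sprintf("  b = %.3f, 89%% CI [%.3f, %.3f], PP(b>0) = %.2f%%%s\n",
              x$b_mean, x$ci_89[1L], x$ci_89[2L], x$pp_gt0,
              if (x$significant) "  *" else ""))
  if (!x$reliable)
    cat("  WARNING: convergence diagnostics failed (R-hat >= 1.01 or ESS <= 400); unreliable\n")
  invisible(x)
}
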