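#' Estimated marginal means per period
#'
#' With cell-means coding the marginal mean of a period on the response
#' scale is exactly the exponentiated fixed-effect coefficient (random
#' effects at zero); confidence limits are Wald intervals on the log scale,
#' exponentiated.
#'
#' @param fit an [fit_nb_glmm()] object.
#' @param level confidence level.
#' @return tibble with `period`, `emm` (mean detections per hour),
#'   `se_log`, `lcl`, `ucl`.
#' @export
emm_periods <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "nb_glmm"))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  L <- fit$emm_l
  est <- as.numeric(L %*% fit$beta)
  se <- unname(sqrt(diag(L %*% fit$vcov %*% t(L))))
  tibble::tibble(period = rownames(L),
                 emm = exp(est),
                 se_log = se,
                 lcl = exp(est - zq * se),
                 ucl = exp(est + zq * se))
}

#' Tukey-adjusted pairwise period contrasts
#'
#' All pairwise log-rate differences between periods with Wald z statistics.
#' The multiplicity adjustment follows the single-step max-|z| rule: the
#' adjusted p-value of a contrast is the probability that the maximum
#' absolute component of a multivariate normal vector with the contrasts'
#' estimated correlation exceeds the observed |z|, evaluated by Monte Carlo
#' with a pinned seed (exact studentized-range theory does not apply to
#' GLMM contrasts). Adjusted p-values are never below the unadjusted ones.
#'
#' @param fit an [fit_nb_glmm()] object with at least two periods.
#' @param adjust `"tukey"` (max-|z| single-step) or `"none"`.
#' @param nsim Monte Carlo draws for the adjustment.
#' @param seed internal seed for the adjustment draws.
#' @return tibble with `contrast`, `log_ratio`, `ratio`, `se`, `z`,
#'   `p_unadj`, `p_adj`.
#' @export
pairwise_contrasts <- function(fit, adjust = c("tukey", "none"),
                               nsim = 20000, seed = 421L) {
  stopifnot(inherits(fit, "nb_glmm"))
  adjust <- match.arg(adjust)
  L <- fit$emm_l
  p <- nrow(L)
  if (p < 2) stop("need at least two periods for contrasts")
  pairs <- utils::combn(p, 2)
  C <- L[pairs[1, ], , drop = FALSE] - L[pairs[2, ], , drop = FALSE]
  est <- as.numeric(C %*% fit$beta)
  V <- C %*% fit$vcov %*% t(C)
  se <- sqrt(diag(V))
  z <- est / se
  p_unadj <- 2 * stats::pnorm(-abs(z))
  if (adjust == "tukey") {
    R <- V / tcrossprod(se)
    chol_r <- t(chol(R + diag(1e-10, nrow(R))))
    maxabs <- with_seed(seed, {
      draws <- matrix(stats::rnorm(nsim * nrow(R)), nrow(R), nsim)
      apply(abs(chol_r %*% draws), 2, max)
    })
    p_adj <- vapply(abs(z), function(zz) mean(maxabs >= zz), numeric(1))
    p_adj <- pmax(p_adj, p_unadj)
  } else p_adj <- p_unadj
  nm <- rownames(L)
  tibble::tibble(
    contrast = paste(nm[pairs[1, ]], "-", nm[pairs[2, ]]),
    log_ratio = est, ratio = exp(est), se = se, z = z,
    p_unadj = p_unadj, p_adj = p_adj)
}

#' Simulation-based residual and dispersion diagnostics
#'
#' Randomized-quantile (PIT) residuals against replicate datasets simulated
#' from the fitted conditional model (estimated random-effect modes held
#' fixed), with a Kolmogorov-Smirnov uniformity test, a Pearson dispersion
#' ratio with a simulation-based two-sided p-value, and an
#' observed-vs-expected zero-count test.
#'
#' @param fit an [fit_nb_glmm()] object.
#' @param nsim number of simulated replicates.
#' @param seed seed pinning the simulations and residual randomization.
#' @return list with `residuals` (PIT values), `ks_p`, `dispersion_ratio`,
#'   `dispersion_p`, `zero_obs`, `zero_sim_mean`, `zero_p`.
#' @export
nb_glmm_diagnostics <- function(fit, nsim = 250, seed = 7L) {
  stopifnot(inherits(fit, "nb_glmm"))
  y <- fit$frame$y
  mu <- fit$fitted_mu
  with_seed(seed, {
    sims <- simulate_nb_glmm(fit, nsim = nsim, conditional = TRUE)
    n_less <- rowSums(sims < y)
    n_eq <- rowSums(sims == y)
    resid <- (n_less + stats::runif(length(y)) * (n_eq + 1)) / (nsim + 1)
    ks_p <- suppressWarnings(stats::ks.test(resid, "punif")$p.value)

    vfun <- mu + mu^2 / fit$theta
    disp_stat <- function(v) mean((v - mu)^2 / vfun)
    d_obs <- disp_stat(y)
    d_sim <- apply(sims, 2, disp_stat)
    dispersion_ratio <- d_obs / mean(d_sim)
    r <- mean(d_sim <= d_obs)
    dispersion_p <- min(1, 2 * min(r, 1 - r) + 1 / nsim)

    zero_obs <- sum(y == 0)
    zero_sim <- colSums(sims == 0)
    rz <- mean(zero_sim <= zero_obs)
    zero_p <- min(1, 2 * min(rz, 1 - rz) + 1 / nsim)
    list(residuals = resid, ks_p = ks_p,
         dispersion_ratio = dispersion_ratio, dispersion_p = dispersion_p,
         zero_obs = zero_obs, zero_sim_mean = mean(zero_sim),
         zero_p = zero_p)
  })
}
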