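#' Fit the negative-binomial mixed model for hourly counts
#'
#' Maximum-likelihood fit (Laplace approximation over the random effects)
#' of the period-contrast model: hourly count `y ~ NB2(mu, theta)` with
#' `log mu = beta[period] + b_instrument + b_instrument_day`,
#' `b_instrument ~ N(0, sigma_instrument^2)`,
#' `b_instrument_day ~ N(0, sigma_day^2)`, variance `mu + mu^2/theta`.
#'
#' Fixed effects use treatment coding by default (intercept = log mean of
#' the reference period, remaining coefficients = log rate ratios against
#' it), matching how the period contrast is usually specified;
#' `coding = "cellmeans"` fits one coefficient per period instead. Either
#' way [emm_periods()] recovers the per-period marginal means exactly.
#' The fixed effects are profiled at the
#' joint penalized mode; the outer optimization runs over
#' `(log sigma_instrument, log sigma_day, log theta)` with the inner
#' penalized-Newton solve exploiting the sparse nested random-effect
#' structure. Wald covariance for the fixed effects is the inverse Schur
#' complement of the joint Hessian at the optimum.
#'
#' @param data hourly count table with (at least) the four named columns;
#'   rows with `valid == FALSE` or missing counts are dropped.
#' @param response,period,instrument,day column names.
#' @param coding `"treatment"` (default) or `"cellmeans"`.
#' @param reference reference period level for treatment coding (default:
#'   first level in order of appearance).
#' @param control optional list: `reltol` (outer relative tolerance,
#'   default 1e-8), `newton_tol` (inner gradient tolerance, default 1e-8),
#'   `max_newton` (default 50).
#' @return an object of class `nb_glmm` with elements `beta` (named log
#'   means), `se`, `z`, `vcov`, `sigma_instrument`, `sigma_day`, `theta`,
#'   `loglik`, `convergence` (0 = converged, with message), `ranef`
#'   (lists of instrument and instrument-day modes), and the model frame.
#' @export
fit_nb_glmm <- function(data, response = "count", period = "period",
                        instrument = "instrument", day = "jd",
                        coding = c("treatment", "cellmeans"),
                        reference = NULL, control = list()) {
  coding <- match.arg(coding)
  ctrl <- utils::modifyList(list(reltol = 1e-8, newton_tol = 1e-8,
                                 max_newton = 50L), control)
  d <- as.data.frame(data)
  if ("valid" %in% names(d)) d <- d[d$valid, , drop = FALSE]
  d <- d[!is.na(d[[response]]), , drop = FALSE]
  y <- d[[response]]
  if (any(y < 0) || any(y != round(y))) stop("counts must be non-negative integers")
  f_per <- factor(d[[period]], levels = unique(d[[period]]))
  if (!is.null(reference)) f_per <- stats::relevel(f_per, ref = reference)
  if (nlevels(f_per) < 1) stop("no period levels present")
  f_inst <- factor(d[[instrument]])
  f_day <- factor(paste(d[[instrument]], d[[day]], sep = ":"))
  p <- nlevels(f_per); q1 <- nlevels(f_inst); q2 <- nlevels(f_day)
  indicator <- function(f, prefix = "") {
    m <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                              dims = c(length(f), nlevels(f)))
    colnames(m) <- paste0(prefix, levels(f))
    m
  }
  X <- if (p == 1) {
    m <- Matrix::Matrix(1, length(y), 1, sparse = TRUE)
    colnames(m) <- "(Intercept)"
    m
  } else if (coding == "cellmeans") indicator(f_per, "f_per")
  else Matrix::sparse.model.matrix(~ f_per)
  # rows of emm_l map fixed effects to per-period log marginal means
  emm_l <- if (coding == "cellmeans" || p == 1) diag(p) else
    cbind(1, rbind(0, diag(p - 1)))
  rownames(emm_l) <- levels(f_per)
  Z1 <- indicator(f_inst)
  Z2 <- indicator(f_day)
  A <- cbind(X, Z1, Z2)
  if (Matrix::rankMatrix(X) < p) stop("rank-deficient fixed-effect design")
  n <- length(y)
  b_idx <- (p + 1):(p + q1 + q2)

  # penalized joint log-likelihood pieces, log link with overflow guard
  eta_of <- function(u) pmin(as.numeric(A %*% u), 35)
  nb_ll <- function(eta, theta)
    sum(stats::dnbinom(y, size = theta, mu = exp(eta), log = TRUE))

  u_warm <- if (coding == "cellmeans" || p == 1)
    c(rep(log(mean(y) + 0.5), p), numeric(q1 + q2))
  else c(log(mean(y) + 0.5), numeric(p - 1 + q1 + q2))

  inner_solve <- function(par) {
    s1 <- exp(par[1]); s2 <- exp(par[2]); theta <- exp(par[3])
    dinv <- c(rep(0, p), rep(1 / s1^2, q1), rep(1 / s2^2, q2))
    u <- u_warm
    eta <- eta_of(u)
    pll <- nb_ll(eta, theta) - 0.5 * sum(dinv * u^2)
    conv <- FALSE
    for (it in seq_len(ctrl$max_newton)) {
      mu <- exp(eta)
      g <- y - mu * (y + theta) / (mu + theta)
      grad <- as.numeric(Matrix::crossprod(A, g)) - dinv * u
      if (max(abs(grad)) < ctrl$newton_tol) { conv <- TRUE; break }
      w <- mu * theta * (y + theta) / (mu + theta)^2
      H <- Matrix::crossprod(Matrix::Diagonal(x = sqrt(w)) %*% A) +
        Matrix::Diagonal(x = dinv)
      step <- as.numeric(Matrix::solve(H, grad))
      alpha <- 1
      repeat {
        u_new <- u + alpha * step
        eta_new <- eta_of(u_new)
        pll_new <- nb_ll(eta_new, theta) - 0.5 * sum(dinv * u_new^2)
        if (is.finite(pll_new) && pll_new >= pll - 1e-10) break
        alpha <- alpha / 2
        if (alpha < 1e-10) { u_new <- u; eta_new <- eta; pll_new <- pll; break }
      }
      if (abs(pll_new - pll) < 1e-12 * (abs(pll) + 1)) {
        u <- u_new; eta <- eta_new; pll <- pll_new; conv <- TRUE; break
      }
      u <- u_new; eta <- eta_new; pll <- pll_new
    }
    mu <- exp(eta)
    w <- mu * theta * (y + theta) / (mu + theta)^2
    H <- Matrix::crossprod(Matrix::Diagonal(x = sqrt(w)) %*% A) +
      Matrix::Diagonal(x = dinv)
    u_warm <<- u
    list(u = u, H = H, pll = pll, theta = theta, dinv = dinv,
         converged = conv)
  }

  laplace_nll <- function(par) {
    fit <- inner_solve(par)
    logdet_d <- 2 * q1 * par[1] + 2 * q2 * par[2]
    Hbb <- fit$H[b_idx, b_idx]
    logdet_h <- as.numeric(Matrix::determinant(Hbb, logarithm = TRUE)$modulus)
    -(fit$pll - 0.5 * logdet_d - 0.5 * logdet_h)
  }

  opt <- stats::nlminb(c(log(0.3), log(0.3), 0), laplace_nll,
                       lower = c(log(1e-4), log(1e-4), log(1e-3)),
                       upper = c(log(10), log(10), log(1e4)),
                       control = list(rel.tol = ctrl$reltol,
                                      iter.max = 500L, eval.max = 1000L))
  final <- inner_solve(opt$par)
  if (!final$converged || opt$convergence != 0)
    warning("NB GLMM fit did not fully converge: ", opt$message,
            call. = FALSE)
  cov_full <- Matrix::solve(final$H)
  vcov_beta <- as.matrix(cov_full[seq_len(p), seq_len(p)])
  coef_names <- colnames(X)
  beta <- stats::setNames(final$u[seq_len(p)], coef_names)
  se <- sqrt(diag(vcov_beta))
  dimnames(vcov_beta) <- list(coef_names, coef_names)
  structure(list(
    beta = beta, se = stats::setNames(se, coef_names),
    z = stats::setNames(beta / se, coef_names),
    vcov = vcov_beta, coding = coding, emm_l = emm_l,
    sigma_instrument = exp(opt$par[1]), sigma_day = exp(opt$par[2]),
    theta = exp(opt$par[3]),
    loglik = -opt$objective,
    convergence = opt$convergence, message = opt$message,
    ranef = list(
      instrument = stats::setNames(final$u[p + seq_len(q1)], levels(f_inst)),
      instrument_day = stats::setNames(final$u[p + q1 + seq_len(q2)],
                                       levels(f_day))),
    frame = list(y = y, period = f_per, instrument = f_inst, day = f_day),
    fitted_mu = exp(eta_of(final$u))
  ), class = "nb_glmm")
}

#' @export
print.nb_glmm <- function(x, ...) {
  cat("Negative binomial mixed model (Laplace)\n")
  cat(sprintf("  theta = %.3f, sigma_instrument = %.3f, sigma_day = %.3f\n",
              x$theta, x$sigma_instrument, x$sigma_day))
  cat(sprintf("  log-likelihood = %.2f\n", x$loglik))
  print(data.frame(estimate = x$beta, se = x$se, z = x$z))
  invisible(x)
}

# simulate replicate response vectors from a fit; conditional = TRUE keeps
# the estimated random-effect modes, FALSE redraws random effects
simulate_nb_glmm <- function(fit, nsim = 250, conditional = TRUE) {
  n <- length(fit$frame$y)
  if (conditional) {
    mu <- fit$fitted_mu
    matrix(stats::rnbinom(n * nsim, size = fit$theta, mu = mu), n, nsim)
  } else {
    per_mean <- as.numeric(fit$emm_l %*% fit$beta)
    eta_fix <- per_mean[as.integer(fit$frame$period)]
    i_inst <- as.integer(fit$frame$instrument)
    i_day <- as.integer(fit$frame$day)
    q1 <- nlevels(fit$frame$instrument); q2 <- nlevels(fit$frame$day)
    sapply(seq_len(nsim), function(s) {
      b1 <- stats::rnorm(q1, 0, fit$sigma_instrument)
      b2 <- stats::rnorm(q2, 0, fit$sigma_day)
      stats::rnbinom(n, size = fit$theta,
                     mu = exp(eta_fix + b1[i_inst] + b2[i_day]))
    })
  }
}
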