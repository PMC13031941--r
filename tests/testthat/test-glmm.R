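# smaller-than-study datasets keep module tests fast; the full study
# configuration is exercised by the acceptance suite
small_sim <- function(seed, ...) {
  simulate_counts(count_sim_config(seed = seed, n_instruments = 2,
                                   hours_per_day = 6, ...))
}

test_that("an intercept-only fit recovers the sample mean", {
  per <- tibble::tibble(name = "P", jd_start = 1L, jd_end = 40L,
                        shooting = FALSE)
  d <- simulate_counts(count_sim_config(periods = per, beta = c(P = log(20)),
                                        sigma_instrument = 0, sigma_day = 0,
                                        n_instruments = 1, seed = 14))
  fit <- fit_nb_glmm(d)
  expect_equal(exp(fit$beta[["(Intercept)"]]), mean(d$count),
               tolerance = 1e-3)
})

test_that("with zero random-effect variance the fit reduces to plain NB", {
  skip_if_not_installed("MASS")
  d <- simulate_counts(count_sim_config(seed = 8, sigma_instrument = 0,
                                        sigma_day = 0, n_instruments = 2))
  fit <- fit_nb_glmm(d)
  gnb <- MASS::glm.nb(count ~ period, data = d)
  lev <- rownames(fit$emm_l)
  own <- as.numeric(fit$emm_l %*% fit$beta)
  ref <- unname(stats::predict(gnb, newdata = data.frame(period = lev)))
  expect_lt(max(abs(own - ref)), 1e-3)
  expect_lt(fit$sigma_instrument, 0.02)
  expect_lt(fit$sigma_day, 0.02)
})

test_that("the Laplace fit agrees with an independent mixed-model fitter", {
  skip_if_not_installed("glmmTMB")
  d <- simulate_counts(count_sim_config(seed = 11))
  fit <- fit_nb_glmm(d)
  d$period <- factor(d$period, levels = unique(d$period))  # align reference
  g <- glmmTMB::glmmTMB(
    count ~ period + (1 | instrument) + (1 | instrument:jd),
    family = glmmTMB::nbinom2, data = d)
  expect_equal(fit$theta, glmmTMB::sigma(g), tolerance = 1e-3)
  vc <- glmmTMB::VarCorr(g)$cond
  sds <- sqrt(c(vc$instrument[1, 1], vc$`instrument:jd`[1, 1]))
  expect_equal(fit$sigma_instrument, sds[1], tolerance = 1e-2)
  expect_equal(fit$sigma_day, sds[2], tolerance = 1e-2)
  # fixed effects and Wald SEs (joint-mode profiling differs only slightly)
  b_ref <- glmmTMB::fixef(g)$cond
  expect_equal(unname(fit$beta), unname(b_ref), tolerance = 5e-3)
  expect_equal(unname(fit$se), unname(sqrt(diag(stats::vcov(g)$cond))),
               tolerance = 1e-3)

  skip_if_not_installed("emmeans")
  em_ref <- summary(emmeans::emmeans(g, ~period, type = "response"))
  em <- emm_periods(fit)
  ord <- match(em$period, em_ref$period)
  expect_equal(unname(log(em$emm)), log(em_ref$response[ord]),
               tolerance = 5e-3)
  expect_equal(unname(em$se_log), em_ref$SE[ord] / em_ref$response[ord],
               tolerance = 0.02)
})

test_that("marginal means are the exponentiated linear predictor exactly", {
  d <- small_sim(4)
  fit <- fit_nb_glmm(d)
  em <- emm_periods(fit)
  expect_equal(em$emm, unname(exp(as.numeric(fit$emm_l %*% fit$beta))))
  expect_true(all(em$lcl > 0 & em$ucl > em$lcl))
  # coding invariance and EMM/coefficient order agreement
  fit_cm <- fit_nb_glmm(d, coding = "cellmeans")
  em_cm <- emm_periods(fit_cm)
  expect_equal(em$emm, em_cm$emm, tolerance = 1e-6)
  expect_equal(order(em_cm$emm), order(fit_cm$beta))
})

test_that("marginal means track per-period sample means without REs", {
  d <- simulate_counts(count_sim_config(seed = 19, sigma_instrument = 0,
                                        sigma_day = 0, n_instruments = 2))
  fit <- fit_nb_glmm(d)
  em <- emm_periods(fit)
  obs <- as.numeric(tapply(d$count, d$period, mean)[em$period])
  expect_equal(em$emm, obs, tolerance = 0.03)
})

test_that("Tukey adjustment behaves as a single-step max-|z| correction", {
  d <- small_sim(6)
  fit <- fit_nb_glmm(d)
  ct <- pairwise_contrasts(fit)
  expect_equal(nrow(ct), 6)
  expect_true(all(ct$p_adj >= ct$p_unadj - 1e-12))
  expect_true(all(ct$p_adj <= 1))
  # deterministic under the pinned internal seed
  expect_identical(ct, pairwise_contrasts(fit))

  qs <- (grepl("Quiet", ct$contrast) & grepl("Shooting", ct$contrast))
  expect_true(all(ct$p_adj[qs] < 0.05))
  expect_gt(ct$p_adj[ct$contrast == "Quiet 1 - Quiet 2"], 0.05)
})

test_that("equal period means give near-unit adjusted p-values", {
  beta0 <- log(c("Shooting 1" = 30, "Quiet 1" = 30,
                 "Shooting 2" = 30, "Quiet 2" = 30))
  d <- simulate_counts(count_sim_config(beta = beta0, sigma_day = 0.05,
                                        sigma_instrument = 0, seed = 23))
  ct <- pairwise_contrasts(fit_nb_glmm(d))
  expect_true(all(ct$p_adj > 0.2))
})

test_that("likelihood optimum is stable across starting values", {
  d <- small_sim(9)
  f1 <- fit_nb_glmm(d)
  f2 <- fit_nb_glmm(d, control = list(reltol = 1e-10))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-5)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-4)
})

test_that("estimates concentrate with more data", {
  truth <- count_sim_config()$beta
  err_at <- function(hours, seeds) {
    mean(vapply(seeds, function(s) {
      d <- simulate_counts(count_sim_config(seed = s, hours_per_day = hours))
      fit <- fit_nb_glmm(d)
      lev <- rownames(fit$emm_l)
      tr <- c(truth[lev[1]], truth[lev[-1]] - truth[lev[1]])
      mean(abs(fit$beta - tr)[-1])  # contrasts; intercept shares 3 REs
    }, numeric(1)))
  }
  expect_lt(err_at(24, 300 + 1:8), err_at(2, 300 + 1:8) + 0.02)
})

test_that("conditional simulation diagnostics are self-consistent", {
  ok <- 0
  for (s in 1:6) {
    d <- small_sim(40 + s)
    fit <- fit_nb_glmm(d)
    dg <- nb_glmm_diagnostics(fit, nsim = 120, seed = s)
    if (dg$ks_p > 0.01) ok <- ok + 1
    expect_true(all(dg$residuals >= 0 & dg$residuals <= 1))
  }
  expect_gte(ok, 5)
})

test_that("dispersion and zero diagnostics flag the right alternatives", {
  # Poisson data fitted as NB: dispersion ratio ~ 1
  per <- tibble::tibble(name = "P", jd_start = 1L, jd_end = 60L,
                        shooting = FALSE)
  d <- simulate_counts(count_sim_config(periods = per, beta = c(P = log(5)),
                                        sigma_instrument = 0, sigma_day = 0,
                                        theta = 1e6, n_instruments = 1,
                                        seed = 3))
  fit <- fit_nb_glmm(d)
  dg <- nb_glmm_diagnostics(fit, nsim = 150)
  expect_equal(dg$dispersion_ratio, 1, tolerance = 0.1)
  expect_gt(dg$dispersion_p, 0.01)

  # zero-inflated alternative: excess zeros are flagged
  d2 <- d
  set.seed(99)
  d2$count[sample(nrow(d2), nrow(d2) %/% 3)] <- 0L
  fit2 <- fit_nb_glmm(d2)
  dg2 <- nb_glmm_diagnostics(fit2, nsim = 150)
  expect_gt(dg2$zero_obs, dg2$zero_sim_mean)
  expect_lt(dg2$zero_p, 0.05)
})

test_that("invalid model inputs are rejected", {
  d <- small_sim(2)
  d$count[1] <- -1L
  expect_error(fit_nb_glmm(d), "non-negative")
  d2 <- small_sim(2)
  d2$count[2] <- 1.5
  expect_error(fit_nb_glmm(d2), "integers")
})
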