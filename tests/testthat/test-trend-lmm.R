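test_that("noise-free linear data are interpolated with zero variances", {
  wk <- simulate_weekly_observations(3, 3, beta = c(10, 1, 5, 0.5),
                                     varcomp = c(patient = 0, anchor = 0,
                                                 residual = 0), seed = 1)
  fit <- fit_nested_lmm(wk)
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), c(10, 1, 5, 0.5))
  expect_equal(unname(fit$varcomp), c(0, 0, 0))
})

test_that("an all-identical response is rejected as degenerate", {
  wk <- simulate_weekly_observations(3, 3, beta = c(10, 0, 0, 0),
                                     varcomp = c(patient = 0, anchor = 0,
                                                 residual = 0), seed = 1)
  expect_error(fit_nested_lmm(wk), "degenerate")
})

test_that("optimized likelihood matches the dense oracle on tiny instances", {
  for (seed in 1:3) {
    wk <- simulate_weekly_observations(
      2, 2, beta = c(20, 0.5, 8, 0.6),
      varcomp = c(patient = 4, anchor = 2, residual = 3),
      anchors_per_event_patient = 2, weeks = -12:-5, seed = seed)
    expect_lte(nrow(wk), 50)
    fit <- fit_nested_lmm(wk)
    tt <- wk$week + 12
    g <- as.numeric(wk$group == "event")
    X <- cbind(intercept = 1, time = tt, group = g, time_group = tt * g)
    dense <- lmm_loglik_dense(wk$mean_score, X, wk$patient_id, wk$anchor_id,
                              fit$varcomp)
    expect_equal(fit$loglik, dense$loglik, tolerance = 1e-6)
    expect_equal(unname(fit$beta), dense$beta, tolerance = 1e-6)
    # no +/-1e-3 perturbation of the variance components does better
    for (k in 1:3) {
      for (dlt in c(-1e-3, 1e-3)) {
        vc <- fit$varcomp
        vc[k] <- vc[k] + dlt
        if (any(vc < 0) || vc["residual"] <= 0) next
        ll <- lmm_loglik_dense(wk$mean_score, X, wk$patient_id,
                               wk$anchor_id, vc)$loglik
        expect_lte(ll, fit$loglik + 1e-7)
      }
    }
  }
})

test_that("REML matches the closed-form estimators in a balanced design", {
  set.seed(5)
  p <- 8; a <- 3; nrep <- 4
  pat <- rep(sprintf("p%02d", 1:p), each = a * nrep)
  anc <- rep(sprintf("a%02d", 1:(p * a)), each = nrep)
  y <- rep(rnorm(p, 0, 2), each = a * nrep) +
    rep(rnorm(p * a, 0, 1.5), each = nrep) + rnorm(p * a * nrep, 10, 1)
  fit <- lmm_fit(y, cbind(intercept = rep(1, length(y))), pat, anc)
  pm <- tapply(y, pat, mean)
  am <- tapply(y, anc, mean)
  pat_of_anc <- tapply(pat, anc, function(z) z[1])
  MSP <- a * nrep * sum((pm - mean(y))^2) / (p - 1)
  MSA <- nrep * sum((am - pm[pat_of_anc])^2) / (p * (a - 1))
  MSE <- sum((y - am[anc])^2) / (p * a * (nrep - 1))
  expect_equal(unname(fit$varcomp),
               c((MSP - MSA) / (a * nrep), (MSA - MSE) / nrep, MSE),
               tolerance = 1e-5)
})

test_that("fixed effects reduce to OLS when the variance ratios are zero", {
  wk <- simulate_weekly_observations(10, 10, seed = 3)
  tt <- wk$week + 12
  g <- as.numeric(wk$group == "event")
  X <- cbind(intercept = 1, time = tt, group = g, time_group = tt * g)
  pf <- lmm_profiled_fit(wk$mean_score, X, wk$patient_id, wk$anchor_id,
                         gamma_p = 0, gamma_a = 0)
  ols <- lm.fit(X, wk$mean_score)
  expect_equal(unname(pf$beta), unname(ols$coefficients))
})

test_that("the fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  wk <- simulate_weekly_observations(40, 50,
                                     beta = c(30, -0.1, 12, 0.75),
                                     varcomp = c(patient = 15, anchor = 8,
                                                 residual = 6),
                                     anchors_per_event_patient = c(1, 2, 3),
                                     seed = 7)
  fit <- fit_nested_lmm(wk)
  wk$t <- wk$week + 12
  wk$g <- as.numeric(wk$group == "event")
  lf <- lme4::lmer(mean_score ~ t * g + (1 | patient_id) + (1 | anchor_id),
                   data = wk, REML = TRUE)
  expect_equal(unname(fit$beta), unname(lme4::fixef(lf)), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(lf)), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(unname(fit$varcomp["patient"]),
               vc$vcov[vc$grp == "patient_id"], tolerance = 1e-3)
  expect_equal(unname(fit$varcomp["anchor"]),
               vc$vcov[vc$grp == "anchor_id"], tolerance = 1e-3)
  expect_equal(unname(fit$se), unname(sqrt(diag(as.matrix(vcov(lf))))),
               tolerance = 1e-4)
})

test_that("relabelling the groups flips contrasts but not p-values", {
  wk <- simulate_weekly_observations(15, 15, seed = 9)
  f1 <- fit_nested_lmm(wk)
  wk2 <- wk
  wk2$group <- ifelse(wk$group == "event", "control", "event")
  f2 <- fit_nested_lmm(wk2)
  c1 <- wald_contrasts(f1)
  c2 <- wald_contrasts(f2)
  expect_equal(c1$estimate, -c2$estimate, tolerance = 1e-6)
  expect_equal(c1$p_value, c2$p_value, tolerance = 1e-6)
})

test_that("shifting the response moves only the intercept; scaling scales", {
  wk <- simulate_weekly_observations(12, 12, seed = 11)
  f0 <- fit_nested_lmm(wk)
  wk_s <- wk; wk_s$mean_score <- wk$mean_score + 100
  fs <- fit_nested_lmm(wk_s)
  expect_equal(unname(fs$beta["intercept"]),
               unname(f0$beta["intercept"]) + 100, tolerance = 1e-5)
  expect_equal(unname(fs$beta[-1]), unname(f0$beta[-1]), tolerance = 1e-5)
  wk_c <- wk; wk_c$mean_score <- 3 * wk$mean_score
  fc <- fit_nested_lmm(wk_c)
  expect_equal(unname(fc$beta), 3 * unname(f0$beta), tolerance = 1e-5)
  expect_equal(unname(fc$varcomp), 9 * unname(f0$varcomp), tolerance = 1e-4)
})

test_that("group-mean prediction is the fixed-effect linear predictor", {
  wk <- simulate_weekly_observations(3, 3, beta = c(10, 1, 5, 0.5),
                                     varcomp = c(patient = 0, anchor = 0,
                                                 residual = 0), seed = 1)
  fit <- fit_nested_lmm(wk)
  expect_equal(predict_group_mean(fit, 0, "event"), 10 + 12 + 5 + 6)
  expect_equal(predict_group_mean(fit, -12, "control"),
               unname(fit$beta["intercept"]))
  expect_error(predict_group_mean(fit, 1, "event"), "week")
})

test_that("estimates are unbiased across replicated simulations", {
  beta <- c(30, 1, 12, 0.75)
  n_rep <- 200
  est <- matrix(NA_real_, n_rep, 4)
  for (r in seq_len(n_rep)) {
    wk <- simulate_weekly_observations(
      60, 150, beta = beta,
      varcomp = c(patient = 15, anchor = 8, residual = 6),
      anchors_per_event_patient = c(1, 2), seed = 1000 + r)
    est[r, ] <- fit_nested_lmm(wk)$beta
  }
  bias <- colMeans(est) - beta
  expect_true(all(abs(bias / beta) < 0.02))
})
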