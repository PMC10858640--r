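# Two-level nested random-intercept linear mixed model, fitted by (RE)ML
# with the two variance ratios profiled out. The covariance of a patient's
# observations is
#   V = sigma_e^2 I + sigma_a^2 (block 1 per anchor) + sigma_p^2 (block 1),
# and both the inverse and the determinant are available in closed form
# through two nested rank-one (Woodbury) updates, so each likelihood
# evaluation is a handful of grouped sums. The optimizer works on
# log variance ratios gamma = sigma^2 / sigma_e^2; the residual variance and
# the fixed effects are profiled out exactly.

# Grouped-sum machinery shared by the likelihood evaluations.
lmm_index <- function(patient, anchor) {
  af <- factor(paste(patient, anchor, sep = "\r"))
  pf <- factor(patient)
  ai <- as.integer(af)
  pi <- as.integer(pf)
  n_a <- tabulate(ai)
  pat_of_anchor <- pi[match(seq_along(levels(af)), ai)]
  list(ai = ai, pi = pi, n_a = n_a, pat_of_anchor = pat_of_anchor,
       n_anchor = nlevels(af), n_patient = nlevels(pf))
}

#' Profiled GLS fit at fixed variance ratios
#'
#' Computes the generalized-least-squares fixed effects, the profiled
#' residual variance and the (restricted) log-likelihood of the nested
#' random-intercept model at given variance ratios
#' `gamma_p = sigma_p^2 / sigma_e^2` and `gamma_a = sigma_a^2 / sigma_e^2`.
#' At `gamma_p = gamma_a = 0` the fixed effects are exactly ordinary least
#' squares.
#'
#' @param y Response vector.
#' @param X Fixed-effects design matrix.
#' @param patient,anchor Cluster identifiers per observation (anchors are
#'   nested within patients).
#' @param gamma_p,gamma_a Non-negative variance ratios.
#' @param reml Use the restricted likelihood (default) or full ML.
#' @return List with `beta`, `sigma2_e`, `vcov` (of beta), `loglik`,
#'   `varcomp` (named variances: patient, anchor, residual).
#' @export
lmm_profiled_fit <- function(y, X, patient, anchor, gamma_p, gamma_a,
                             reml = TRUE) {
  idx <- lmm_index(patient, anchor)
  n <- length(y)
  p <- ncol(X)
  d_a <- 1 + gamma_a * idx$n_a
  s_p <- as.numeric(rowsum(idx$n_a / d_a, idx$pat_of_anchor))
  e_p <- 1 + gamma_p * s_p
  winv <- function(M) {
    M <- as.matrix(M)
    Sa <- rowsum(M, idx$ai)                  # anchor sums
    t1 <- M - gamma_a * Sa[idx$ai, , drop = FALSE] / d_a[idx$ai]
    Cp <- rowsum(Sa / d_a, idx$pat_of_anchor)  # patient sums of A^{-1} M
    t1 - gamma_p * (Cp[idx$pi, , drop = FALSE] / e_p[idx$pi]) / d_a[idx$ai]
  }
  WiX <- winv(X)
  Wiy <- winv(y)
  XtWiX <- crossprod(X, WiX)
  beta <- solve(XtWiX, crossprod(X, Wiy))
  r <- y - X %*% beta
  quad <- sum(r * (Wiy - WiX %*% beta))
  logdetW <- sum(log(d_a)) + sum(log(e_p))
  dof <- if (reml) n - p else n
  sigma2 <- max(quad, 0) / dof
  if (sigma2 <= 0) {
    loglik <- Inf                            # interpolating fit
  } else if (reml) {
    loglik <- -0.5 * (dof * log(2 * pi * sigma2) + dof + logdetW +
                        determinant(XtWiX, logarithm = TRUE)$modulus)
  } else {
    loglik <- -0.5 * (dof * log(2 * pi * sigma2) + dof + logdetW)
  }
  list(beta = stats::setNames(as.numeric(beta), colnames(X)),
       sigma2_e = sigma2,
       vcov = sigma2 * solve(XtWiX),
       loglik = as.numeric(loglik),
       varcomp = c(patient = gamma_p * sigma2, anchor = gamma_a * sigma2,
                   residual = sigma2))
}

#' Optimize the nested random-intercept model for an arbitrary design
#'
#' Maximizes the (restricted) likelihood over the two variance ratios by
#' L-BFGS-B on the log scale from several starting points around a
#' moment-based initializer, then recovers the profiled fixed effects and
#' variance components. Ties between starts are broken by the smaller
#' variance-component norm. Ratios ending below 1e-7 are treated as exact
#' zeros (boundary estimates).
#'
#' @inheritParams lmm_profiled_fit
#' @return List as [lmm_profiled_fit()] plus `gamma`, `converged`.
#' @export
lmm_fit <- function(y, X, patient, anchor, reml = TRUE) {
  idx <- lmm_index(patient, anchor)
  ols <- stats::lm.fit(X, y)
  r <- ols$residuals
  am <- as.numeric(rowsum(r, idx$ai)) / idx$n_a
  within <- r - am[idx$ai]
  s2e0 <- sum(within^2) / max(length(y) - idx$n_anchor, 1)
  between <- max(stats::var(am) - s2e0 / mean(idx$n_a), s2e0 * 0.05)
  g0 <- max(between / s2e0, 1e-3)
  init <- c(g0 / 2, g0 / 2)
  obj <- function(lg) {
    -lmm_profiled_fit(y, X, patient, anchor, exp(lg[1]), exp(lg[2]),
                      reml = reml)$loglik
  }
  starts <- list(log(init), log(init * 0.1), log(init * 10),
                 c(log(init[1]), log(1e-6)), c(log(1e-6), log(init[2])))
  best <- NULL
  conv <- FALSE
  for (st in starts) {
    op <- tryCatch(
      stats::optim(st, obj, method = "L-BFGS-B",
                   lower = log(1e-8), upper = log(1e6),
                   control = list(maxit = 500, factr = 1e5,
                                  pgtol = 1e-10)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$value - 1e-9 ||
        (abs(op$value - best$value) <= 1e-9 &&
         sum(exp(op$par)^2) < sum(exp(best$par)^2))) {
      best <- op
      conv <- op$convergence == 0
    }
  }
  if (is.null(best)) stop("variance-component optimization failed")
  polish <- tryCatch(
    stats::optim(best$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) best <- polish
  gam <- exp(best$par)
  gam[gam < 1e-7] <- 0               # boundary estimate: variance is zero
  pf <- lmm_profiled_fit(y, X, patient, anchor, gam[1], gam[2], reml = reml)
  c(pf, list(gamma = gam, converged = conv))
}

#' Fit the nested random-intercept trend model
#'
#' Fits, by restricted maximum likelihood (default) or maximum likelihood,
#' the linear mixed model used to compare 12-week score trends between
#' groups: fixed effects are an intercept, time in weeks since Week -12
#' (`t = week + 12`, so the intercept is the Week -12 prediction of the
#' reference group), a group indicator and the time-by-group interaction;
#' random intercepts enter at the patient level and at the anchor (event)
#' level nested within patient. Control patients typically contribute a
#' singleton anchor each, so the anchor variance is identified by
#' multi-anchor patients. Optimization runs over log variance ratios from
#' several starting points around a moment-based initializer; variance
#' components are bounded below by zero.
#'
#' @param observations Data frame of weekly observations with columns
#'   `patient_id`, `anchor_id`, `week` (in -12..0), the response, and the
#'   grouping column.
#' @param response Name of the response column (default `"mean_score"`).
#' @param group_var Name of the two-level grouping column (default
#'   `"group"`).
#' @param event_level Level of `group_var` coded 1 (default `"event"` when
#'   present, otherwise the second sorted level).
#' @param reml Logical; restricted likelihood (default `TRUE`).
#' @return An object of class `hf_lmm`: fixed effects `beta` (named
#'   `intercept`, `time`, `group`, `time_group`), `se`, `vcov`, `varcomp`
#'   (patient, anchor, residual variances), `loglik`, `reml`, `converged`,
#'   `n_obs`, `n_patients`, `n_anchors`, `event_level`.
#' @export
fit_nested_lmm <- function(observations, response = "mean_score",
                           group_var = "group", event_level = NULL,
                           reml = TRUE) {
  obs <- observations
  for (col in c("patient_id", "anchor_id", "week", response, group_var)) {
    if (!col %in% names(obs)) stop("observations lack column '", col, "'")
  }
  if (any(obs$week < -12 | obs$week > 0)) stop("weeks must lie in [-12, 0]")
  y <- obs[[response]]
  if (stats::var(y) == 0) stop("response is constant; model is degenerate")
  gv <- obs[[group_var]]
  levs <- sort(unique(as.character(gv)))
  if (length(levs) != 2) stop("'", group_var, "' must have exactly 2 levels")
  if (is.null(event_level)) {
    event_level <- if ("event" %in% levs) "event" else levs[2]
  }
  for (lv in levs) {
    if (length(unique(obs$patient_id[gv == lv])) < 2) {
      stop("level '", lv, "' has fewer than 2 patients")
    }
  }
  tt <- obs$week + 12
  g <- as.numeric(as.character(gv) == event_level)
  X <- cbind(intercept = 1, time = tt, group = g, time_group = tt * g)

  # interpolation limit: an exact linear fit needs no variance components
  ols <- stats::lm.fit(X, y)
  if (sum(ols$residuals^2) < 1e-10 * max(1, sum(y^2))) {
    fit <- list(beta = stats::setNames(ols$coefficients, colnames(X)),
                se = stats::setNames(rep(0, 4), colnames(X)),
                vcov = matrix(0, 4, 4, dimnames = list(colnames(X),
                                                       colnames(X))),
                varcomp = c(patient = 0, anchor = 0, residual = 0),
                loglik = NA_real_, reml = reml, converged = TRUE,
                degenerate = TRUE, n_obs = length(y),
                n_patients = length(unique(obs$patient_id)),
                n_anchors = length(unique(paste(obs$patient_id,
                                                obs$anchor_id))),
                event_level = event_level, response = response)
    class(fit) <- "hf_lmm"
    return(fit)
  }

  pf <- lmm_fit(y, X, obs$patient_id, obs$anchor_id, reml = reml)
  idx <- lmm_index(obs$patient_id, obs$anchor_id)
  fit <- list(beta = pf$beta,
              se = sqrt(diag(pf$vcov)),
              vcov = pf$vcov,
              varcomp = pf$varcomp,
              loglik = pf$loglik,
              reml = reml,
              converged = pf$converged,
              degenerate = FALSE,
              n_obs = length(y),
              n_patients = idx$n_patient,
              n_anchors = idx$n_anchor,
              event_level = event_level,
              response = response)
  class(fit) <- "hf_lmm"
  fit
}

#' @export
print.hf_lmm <- function(x, ...) {
  cat("Nested random-intercept linear mixed model",
      if (x$reml) "(REML)" else "(ML)", "\n")
  cat(sprintf("  response: %s | %d obs, %d patients, %d anchors\n",
              x$response, x$n_obs, x$n_patients, x$n_anchors))
  tab <- cbind(estimate = x$beta, se = x$se)
  print(round(tab, 4))
  cat("Variance components (patient / anchor / residual):",
      paste(signif(x$varcomp, 4), collapse = " / "), "\n")
  if (!is.na(x$loglik)) {
    cat(sprintf("log-likelihood: %.4f\n", x$loglik))
  }
  invisible(x)
}

#' Wald contrasts of the trend model
#'
#' The Week -12 (intercept) contrast between groups is the `group`
#' coefficient and the weekly-slope contrast is the `time_group`
#' interaction; both are reported with standard errors, Wald z statistics
#' and two-sided normal-approximation p-values.
#'
#' @param fit An [fit_nested_lmm()] result.
#' @return Data frame with rows `intercept_diff` and `slope_diff`.
#' @export
wald_contrasts <- function(fit) {
  stopifnot(inherits(fit, "hf_lmm"))
  if (!fit$converged) stop("fit did not converge; contrasts unavailable")
  est <- fit$beta[c("group", "time_group")]
  se <- fit$se[c("group", "time_group")]
  z <- ifelse(se > 0, est / se, NA_real_)
  data.frame(contrast = c("intercept_diff", "slope_diff"),
             estimate = unname(est), se = unname(se), z = unname(z),
             p_value = unname(2 * stats::pnorm(-abs(z))),
             row.names = NULL)
}

#' Fixed-effect group-mean prediction
#'
#' Evaluates the fixed-effect linear predictor
#' `beta0 + beta1 t + beta2 g + beta3 t g` with `t = week + 12`, i.e. the
#' model-predicted population mean of the response for a group at a given
#' week of the 13-week window.
#'
#' @param fit An [fit_nested_lmm()] result.
#' @param week Week index in -12..0.
#' @param group Group label (matched against the fit's `event_level`).
#' @return Predicted mean in response units.
#' @export
predict_group_mean <- function(fit, week, group) {
  stopifnot(inherits(fit, "hf_lmm"))
  if (!fit$converged) stop("fit did not converge")
  if (any(week < -12 | week > 0)) stop("week must lie in [-12, 0]")
  tt <- week + 12
  g <- as.numeric(group == fit$event_level)
  as.numeric(fit$beta["intercept"] + fit$beta["time"] * tt +
               fit$beta["group"] * g + fit$beta["time_group"] * tt * g)
}

#' Dense multivariate-normal likelihood oracle
#'
#' Brute-force evaluation of the (restricted) Gaussian log-likelihood of the
#' nested random-intercept model at given variance components: builds the
#' full n x n covariance matrix explicitly, solves the generalized
#' least-squares problem densely and applies the textbook (RE)ML formula.
#' Intended for validating the profiled blockwise implementation on small
#' instances; cost is cubic in n.
#'
#' @param y,X,patient,anchor As in [lmm_profiled_fit()].
#' @param varcomp Named variances `c(patient, anchor, residual)`.
#' @param reml Restricted likelihood (default `TRUE`).
#' @return List with `loglik` and the GLS `beta`.
#' @export
lmm_loglik_dense <- function(y, X, patient, anchor, varcomp, reml = TRUE) {
  n <- length(y)
  p <- ncol(X)
  af <- paste(patient, anchor, sep = "\r")
  Zp <- outer(patient, unique(patient), "==") * 1
  Za <- outer(af, unique(af), "==") * 1
  V <- varcomp[["residual"]] * diag(n) +
    varcomp[["patient"]] * tcrossprod(Zp) +
    varcomp[["anchor"]] * tcrossprod(Za)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  quad <- as.numeric(t(r) %*% Vi %*% r)
  ld <- determinant(V, logarithm = TRUE)$modulus
  if (reml) {
    ll <- -0.5 * ((n - p) * log(2 * pi) + ld +
                    determinant(XtViX, logarithm = TRUE)$modulus + quad)
  } else {
    ll <- -0.5 * (n * log(2 * pi) + ld + quad)
  }
  list(loglik = as.numeric(ll), beta = as.numeric(beta))
}
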