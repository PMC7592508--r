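# Design-based estimation for a stratified multistage sample: weighted
# ratio means with between-PSU Taylor-linearized variance, design-based
# weighted least squares for quintile trend tests, and paired Wald tests.

check_design <- function(n, weights, strata, psus) {
  if (length(weights) != n || length(strata) != n || length(psus) != n) {
    abort("values, weights, strata and psus must have equal length")
  }
  if (any(weights <= 0)) abort("all weights must be positive")
  psu_key <- paste(strata, psus, sep = ".")
  psus_per_stratum <- tapply(psu_key, strata, function(k) length(unique(k)))
  single <- names(psus_per_stratum)[psus_per_stratum < 2]
  if (length(single)) {
    abort(sprintf(
      "stratum %s has a single PSU; design-based variance needs >= 2 PSUs per stratum",
      paste(single, collapse = ", ")))
  }
  list(psu_key = psu_key,
       n_psus = sum(psus_per_stratum),
       n_strata = length(psus_per_stratum))
}

# Between-PSU covariance of linearized score contributions `u` (matrix,
# one row per observation): sum over strata of n_h/(n_h-1) * centred
# PSU-total cross-products.
psu_covariance <- function(u, strata, psu_key) {
  u <- as.matrix(u)
  psu_tot <- rowsum(u, psu_key, reorder = FALSE)
  psu_stratum <- strata[!duplicated(psu_key)]
  names(psu_stratum) <- psu_key[!duplicated(psu_key)]
  psu_stratum <- psu_stratum[rownames(psu_tot)]
  G <- matrix(0, ncol(u), ncol(u))
  for (h in unique(psu_stratum)) {
    th <- psu_tot[psu_stratum == h, , drop = FALSE]
    nh <- nrow(th)
    centred <- sweep(th, 2, colMeans(th))
    G <- G + nh / (nh - 1) * crossprod(centred)
  }
  G
}

#' Survey-weighted mean with Taylor-linearized variance
#'
#' Point estimate is the ratio `sum(w * x) / sum(w)`. Its variance is
#' obtained by linearizing the ratio (score contributions
#' `w * (x - mean) / sum(w)`), totalling the scores within PSUs, and
#' accumulating between-PSU variation within strata. The 95% confidence
#' interval uses a t reference with (PSUs − strata) degrees of freedom,
#' the convention of standard survey software.
#'
#' @param x Outcome values.
#' @param weights Survey weights (all positive).
#' @param strata,psus Design stratum and PSU identifiers (PSU ids need only
#'   be unique within stratum). Every stratum must hold at least two PSUs.
#' @return One-row tibble: `estimate`, `se`, `lower`, `upper`, `df`, `n`.
#' @export
svy_mean <- function(x, weights, strata, psus) {
  d <- check_design(length(x), weights, strata, psus)
  est <- sum(weights * x) / sum(weights)
  z <- weights * (x - est) / sum(weights)
  v <- psu_covariance(matrix(z, ncol = 1), strata, d$psu_key)[1, 1]
  df <- d$n_psus - d$n_strata
  se <- sqrt(v)
  tcrit <- qt(0.975, df)
  tibble::tibble(estimate = est, se = se,
                 lower = est - tcrit * se, upper = est + tcrit * se,
                 df = df, n = length(x))
}

# Design-based weighted least squares with PSU-aggregated sandwich variance.
svy_wls <- function(y, X, weights, strata, psus) {
  d <- check_design(length(y), weights, strata, psus)
  X <- as.matrix(X)
  A <- crossprod(X, weights * X)
  qrA <- qr(A)
  if (qrA$rank < ncol(X)) abort("collinear design matrix in survey regression")
  beta <- drop(solve(qrA, crossprod(X, weights * y)))
  resid <- drop(y - X %*% beta)
  U <- X * (weights * resid)
  G <- psu_covariance(U, strata, d$psu_key)
  Ainv <- solve(qrA, diag(ncol(X)))
  V <- Ainv %*% G %*% t(Ainv)
  df <- d$n_psus - d$n_strata
  list(coef = setNames(beta, colnames(X)), vcov = V, df = df,
       n = length(y), resid = resid)
}

#' Linear trend test across diet-quality quintiles
#'
#' Regresses the outcome on the quintile index (1–5, treated as a
#' continuous score) by survey-weighted least squares, with the
#' design-based (Taylor-linearized, PSU-aggregated) sandwich standard
#' error. Optional covariates (e.g. age, sex) are appended to the model.
#' Two-sided p-values use a t reference with (PSUs − strata) df.
#'
#' @param outcome Outcome values (e.g. per-capita Total Food Demand, g/d).
#' @param quintile Integer quintile labels in 1..5.
#' @param weights,strata,psus Design variables as in [svy_mean()].
#' @param covariates Optional data frame of adjustment covariates; factors
#'   and characters are expanded to dummies.
#' @return One-row tibble: `slope` (per quintile increment), `se`,
#'   `statistic`, `p`, `df`, `adjusted`, `covariates`.
#' @export
trend_test <- function(outcome, quintile, weights, strata, psus,
                       covariates = NULL) {
  if (!all(quintile %in% 1:5)) abort("`quintile` must contain labels in 1..5")
  X <- cbind(`(Intercept)` = 1, quintile = as.numeric(quintile))
  cov_names <- character()
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    mm <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
    X <- cbind(X, mm)
    cov_names <- names(covariates)
  }
  fit <- svy_wls(outcome, X, weights, strata, psus)
  slope <- fit$coef[["quintile"]]
  se <- sqrt(fit$vcov[2, 2])
  stat <- slope / se
  tibble::tibble(
    slope = slope, se = se, statistic = stat,
    p = 2 * pt(-abs(stat), fit$df), df = fit$df,
    adjusted = length(cov_names) > 0,
    covariates = paste(cov_names, collapse = ",")
  )
}

#' Paired Wald test of two score vectors
#'
#' Tests whether two scorings of the same individuals (e.g. modified vs
#' original AHEI-2010) differ on average: the individual-level differences
#' are analysed with [svy_mean()] and the Wald statistic is the estimated
#' difference over its linearized standard error. A zero standard error
#' (e.g. a deterministic constant shift) is handled as degenerate with a
#' warning.
#'
#' @param score_a,score_b Aligned score vectors for the same individuals.
#' @param weights,strata,psus Design variables as in [svy_mean()].
#' @return One-row tibble: `difference`, `se`, `statistic`, `p`, `df`, `n`.
#' @export
wald_difference_test <- function(score_a, score_b, weights, strata, psus) {
  if (length(score_a) != length(score_b)) {
    abort("score vectors must come from the same individuals (equal length)")
  }
  est <- svy_mean(score_a - score_b, weights, strata, psus)
  if (est$se == 0) {
    warn("zero linearized SE (deterministic difference); Wald test is degenerate")
    p <- if (est$estimate == 0) 1 else 0
    stat <- if (est$estimate == 0) 0 else Inf * sign(est$estimate)
  } else {
    stat <- est$estimate / est$se
    p <- 2 * pt(-abs(stat), est$df)
  }
  tibble::tibble(difference = est$estimate, se = est$se, statistic = stat,
                 p = p, df = est$df, n = est$n)
}
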