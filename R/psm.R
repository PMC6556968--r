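#' Fit a propensity model for TERT group membership
#'
#' Fits a maximum-likelihood logistic regression of the binary group label
#' (Z = 1 for TERT-high) on the supplied covariates and returns the fitted
#' propensity scores e_i = P(Z_i = 1 | covariates), clipped away from 0 and 1
#' so that matching weights are always defined.
#'
#' @param covariates data.frame or matrix of per-sample covariates (samples in
#'   rows). Factors/characters are expanded via `model.matrix`. No missing
#'   values are allowed.
#' @param z integer/numeric vector of 0/1 group labels (1 = TERT-high).
#' @param clip scores are clipped into `[clip, 1 - clip]`.
#' @return object of class `propensity_model`: list with `coefficients`,
#'   `scores` (in sample order), `converged`, `separation` (logical flag for
#'   quasi-complete separation).
#' @export
fit_propensity <- function(covariates, z, clip = 1e-6) {
  z <- check_binary_z(z)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(z)) {
    stop("covariates and z must have the same number of samples")
  }
  if (anyNA(covariates)) {
    stop("missing covariate values are not allowed; impute or drop upstream")
  }
  if (sum(z == 1L) < 2L || sum(z == 0L) < 2L) {
    stop("need at least 2 samples per group to fit a propensity model")
  }
  constant <- vapply(covariates, function(col) length(unique(col)) <= 1L,
                     logical(1))
  if (any(constant)) {
    message("dropping constant covariate(s): ",
            paste(names(covariates)[constant], collapse = ", "))
    covariates <- covariates[, !constant, drop = FALSE]
  }
  mm <- if (ncol(covariates) == 0) {
    matrix(1, nrow = length(z), dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ ., data = covariates)
  }
  # flag exactly collinear columns before glm silently aliases them
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    keep <- qr_mm$pivot[seq_len(qr_mm$rank)]
    bad <- colnames(mm)[setdiff(seq_len(ncol(mm)), keep)]
    stop("singular covariate design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- suppressWarnings(
    stats::glm.fit(mm, z, family = stats::binomial(),
                   control = list(epsilon = 1e-8, maxit = 100L))
  )
  scores <- as.numeric(fit$fitted.values)
  separation <- any(scores > 1 - 1e-8) || any(scores < 1e-8)
  if (separation) {
    warning("quasi-complete separation detected; propensity scores clipped")
  }
  scores <- pmin(pmax(scores, clip), 1 - clip)
  structure(
    list(coefficients = stats::setNames(fit$coefficients, colnames(mm)),
         scores = scores, converged = fit$converged,
         separation = separation),
    class = "propensity_model"
  )
}

#' Matching weights from propensity scores
#'
#' w_i = min(e_i, 1 - e_i) / (Z_i e_i + (1 - Z_i)(1 - e_i)). Samples near the
#' region of covariate overlap get weight close to 1; samples whose propensity
#' is extreme for their own group are down-weighted.
#'
#' @param scores propensity scores strictly inside (0, 1).
#' @param z 0/1 group labels.
#' @return numeric vector of weights in (0, 1].
#' @export
matching_weights <- function(scores, z) {
  z <- check_binary_z(z)
  if (length(scores) != length(z)) stop("scores and z lengths differ")
  if (any(scores <= 0 | scores >= 1)) {
    stop("propensity scores must lie strictly inside (0, 1); clip upstream")
  }
  pmin(scores, 1 - scores) / ifelse(z == 1L, scores, 1 - scores)
}

#' Standardized difference of a covariate between groups
#'
#' 100 * |m1 - m0| / sqrt((s1^2 + s0^2) / 2), with group means and variances
#' optionally computed under sample weights. Binary covariates are treated as
#' 0/1 numerics. The weighted variance uses the frequency-weight unbiased
#' form s^2 = sum(w (x - m)^2) / (sum(w) - sum(w^2)/sum(w)), which reduces to
#' the ordinary sample variance at unit weights.
#'
#' @param x numeric (or logical/factor with 2 levels) covariate values.
#' @param z 0/1 group labels.
#' @param weights optional non-negative sample weights; `NULL` for unweighted.
#' @return standardized difference in percent; `Inf` if the pooled variance is
#'   zero while the means differ; 0 if both are zero.
#' @export
standardized_difference <- function(x, z, weights = NULL) {
  z <- check_binary_z(z)
  x <- as_numeric_covariate(x)
  if (is.null(weights)) weights <- rep(1, length(z))
  if (length(x) != length(z) || length(weights) != length(z)) {
    stop("x, z and weights must have equal length")
  }
  if (!any(z == 1L) || !any(z == 0L)) stop("both groups must be non-empty")
  m <- v <- numeric(2)
  for (g in 0:1) {
    idx <- z == g
    w <- weights[idx]
    m[g + 1] <- sum(w * x[idx]) / sum(w)
    denom <- sum(w) - sum(w^2) / sum(w)
    v[g + 1] <- if (denom > 0) sum(w * (x[idx] - m[g + 1])^2) / denom else 0
  }
  pooled <- sqrt((v[1] + v[2]) / 2)
  num <- abs(m[2] - m[1])
  if (pooled == 0) return(if (num == 0) 0 else Inf)
  100 * num / pooled
}

#' Covariate balance before and after matching weighting
#'
#' @param covariates data.frame of covariates.
#' @param z 0/1 group labels.
#' @param weights matching weights.
#' @return data.frame with columns `covariate`, `std_diff_before`,
#'   `std_diff_after`, `balanced` (after < 10 percent).
#' @export
balance_report <- function(covariates, z, weights) {
  covariates <- as.data.frame(covariates)
  before <- vapply(covariates, standardized_difference, numeric(1), z = z)
  after <- vapply(covariates, standardized_difference, numeric(1),
                  z = z, weights = weights)
  data.frame(covariate = names(covariates),
             std_diff_before = unname(before),
             std_diff_after = unname(after),
             balanced = unname(after) < 10,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Matching-weight effect estimator (Delta MW)
#'
#' Weighted mean outcome in the Z = 1 group minus weighted mean outcome in the
#' Z = 0 group, each normalized by its group weight sum.
#'
#' @param y outcome per sample (one feature), or a features x samples matrix
#'   for vectorised evaluation.
#' @param z 0/1 group labels.
#' @param weights matching weights.
#' @return scalar Delta MW, or a named vector (one per feature row) when `y`
#'   is a matrix.
#' @export
mw_estimator <- function(y, z, weights) {
  z <- check_binary_z(z)
  wz1 <- weights * (z == 1L)
  wz0 <- weights * (z == 0L)
  s1 <- sum(wz1)
  s0 <- sum(wz0)
  if (s1 <= 0 || s0 <= 0) stop("zero weight sum in a group")
  if (is.matrix(y)) {
    if (ncol(y) != length(z)) stop("matrix columns must align with z")
    return(drop(y %*% wz1) / s1 - drop(y %*% wz0) / s0)
  }
  if (length(y) != length(z)) stop("y and z lengths differ")
  if (!all(is.finite(y))) stop("outcome must be finite")
  sum(wz1 * y) / s1 - sum(wz0 * y) / s0
}

#' Per-feature weighted regression test of the group effect
#'
#' For each feature (row), fits the weighted least-squares regression of the
#' outcome on intercept + Z; with a binary regressor the Z coefficient is
#' the weighted group-mean difference. The standard error uses the
#' effective-sample-size-corrected pooled form: per group,
#' ESS_g = (sum w)^2 / sum(w^2) and the frequency-weight unbiased variance
#' s_g^2; the pooled variance carries ESS_g - 1 degrees of freedom. With
#' uniform weights this reduces exactly to the classical pooled two-sample
#' t-test, and under matching weights it accounts for the reduced effective
#' sample size that the naive model-based weighted-OLS standard error
#' ignores. Constant features get p = 1 and a degenerate flag rather than
#' being dropped, so row indices stay aligned.
#'
#' @param layer features x samples numeric matrix.
#' @param z 0/1 group labels.
#' @param weights sample weights.
#' @return data.frame with `feature`, `estimate` (weighted group-mean
#'   difference = WLS Z coefficient), `wls_p`, `degenerate`.
#' @export
weighted_feature_test <- function(layer, z, weights) {
  z <- check_binary_z(z)
  layer <- as.matrix(layer)
  if (ncol(layer) != length(z)) stop("matrix columns must align with z")
  w <- weights
  if (sum(w[z == 1L]) <= 0 || sum(w[z == 0L]) <= 0) {
    stop("design degenerate: a group has zero total weight")
  }
  grp_mom <- function(g) {
    wg <- w * (z == g)
    sw <- sum(wg); sw2 <- sum(wg^2)
    m <- drop(layer %*% wg) / sw
    denom <- sw - sw2 / sw
    s2 <- (drop((layer^2) %*% wg) - m^2 * sw) / denom
    list(m = m, s2 = pmax(s2, 0), ess = sw^2 / sw2)
  }
  g1 <- grp_mom(1L); g0 <- grp_mom(0L)
  b1 <- g1$m - g0$m
  df <- g1$ess + g0$ess - 2
  s2_pool <- ((g1$ess - 1) * g1$s2 + (g0$ess - 1) * g0$s2) / df
  se <- sqrt(s2_pool * (1 / g1$ess + 1 / g0$ess))
  tstat <- b1 / se
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  degenerate <- apply(layer, 1, function(r) max(r) == min(r))
  p[degenerate | !is.finite(p)] <- 1
  feats <- rownames(layer)
  if (is.null(feats)) feats <- as.character(seq_len(nrow(layer)))
  data.frame(feature = feats, estimate = b1, wls_p = p,
             degenerate = degenerate | !is.finite(tstat),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment (monotone, capped at 1), delegated to
#' [stats::p.adjust()].
#'
#' @param pvals p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Permutation test for the matching-weight estimator
#'
#' Randomizes the TERT-high/low label, holding the fitted propensity scores
#' fixed as part of the study design and recomputing matching weights and
#' Delta MW for every feature under each shuffle; the add-one permutation
#' p-value per feature is
#' p = (1 + #\{|Delta_perm| >= |Delta_obs|\}) / (n_perm + 1).
#'
#' Labels are shuffled within propensity-score strata (quantile bins of the
#' fitted scores, `n_strata` of them). This randomization-inference
#' construction preserves the confounding structure under the null: features
#' that depend on the confounders keep their dependence relative to the
#' assignment probabilities, so the test stays calibrated for confounded and
#' clean features alike. With `n_strata = 1` (or constant covariates) it
#' reduces to simple label permutation.
#'
#' @param layer features x samples matrix.
#' @param z 0/1 labels.
#' @param covariates covariate data.frame for the propensity fit.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param n_strata propensity-score strata for the shuffles (default 5;
#'   reduced automatically when strata would be degenerate).
#' @return list with `perm_p` (named per feature), `delta_obs`, `n_perm`.
#' @export
permutation_test <- function(layer, z, covariates, n_perm = 1000L, seed,
                             n_strata = 5L) {
  if (missing(seed)) stop("seed is mandatory")
  z <- check_binary_z(z)
  layer <- as.matrix(layer)
  if (n_perm < 1) stop("n_perm must be >= 1")
  ps <- fit_propensity(covariates, z)
  w_obs <- matching_weights(ps$scores, z)
  obs <- mw_estimator(layer, z, w_obs)
  abs_obs <- abs(obs)
  strata <- score_strata(ps$scores, n_strata)
  stratum_idx <- split(seq_along(z), strata)
  exceed <- integer(nrow(layer))
  set.seed(seed)
  resampled <- 0L
  for (b in seq_len(n_perm)) {
    repeat {
      zp <- z
      for (idx in stratum_idx) zp[idx] <- sample(z[idx])
      if (any(zp == 1L) && any(zp == 0L)) break
      resampled <- resampled + 1L
    }
    wp <- matching_weights(ps$scores, zp)
    dp <- mw_estimator(layer, zp, wp)
    exceed <- exceed + (abs(dp) >= abs_obs)
  }
  if (resampled > 0L) {
    message(resampled, " degenerate single-group permutations resampled")
  }
  perm_p <- (1 + exceed) / (n_perm + 1)
  names(perm_p) <- rownames(layer)
  list(perm_p = perm_p, delta_obs = obs, n_perm = n_perm)
}

# quantile bins of propensity scores; collapses to fewer strata when scores
# are (nearly) constant
score_strata <- function(scores, n_strata) {
  if (n_strata <= 1L) return(rep(1L, length(scores)))
  brk <- unique(stats::quantile(scores, seq(0, 1, length.out =
                                              n_strata + 1L)))
  if (length(brk) < 3L) return(rep(1L, length(scores)))
  cut(scores, breaks = brk, include.lowest = TRUE, labels = FALSE)
}

# fit propensity + weights + DeltaMW in one pass (used by permutations and
# resampling so every route estimates the weights the same way)
psm_delta <- function(layer, z, covariates) {
  ps <- fit_propensity(covariates, z)
  w <- matching_weights(ps$scores, z)
  mw_estimator(layer, z, w)
}

#' Select significant features at joint FDR and permutation thresholds
#'
#' Keeps features with BH q strictly below `fdr_alpha` AND permutation p
#' strictly below `perm_alpha`; direction is high-specific when Delta MW > 0
#' (higher weighted mean in the TERT-high group), low-specific otherwise.
#'
#' @param results data.frame with columns `feature`, `delta_mw`, `fdr_q`,
#'   `perm_p` (as produced by [psm_differential()]).
#' @param fdr_alpha,perm_alpha strict significance thresholds.
#' @return the input rows that pass, with a `direction` column.
#' @export
significant_features <- function(results, fdr_alpha = 0.05,
                                 perm_alpha = 0.05) {
  stopifnot(all(c("feature", "delta_mw", "fdr_q", "perm_p") %in%
                  names(results)))
  keep <- results$fdr_q < fdr_alpha & results$perm_p < perm_alpha
  out <- results[keep, , drop = FALSE]
  out$direction <- ifelse(out$delta_mw > 0, "high-specific", "low-specific")
  rownames(out) <- NULL
  out
}

#' Confounder-balanced differential analysis of one omics layer
#'
#' End-to-end wrapper: propensity fit, matching weights, balance report,
#' per-feature weighted regression p, BH q, permutation p, and the joint
#' significance call.
#'
#' @inheritParams permutation_test
#' @param fdr_alpha,perm_alpha strict thresholds for the significance flag.
#' @return list of class `psm_result`: `propensity`, `weights`, `balance`,
#'   `results` (per-feature data.frame with `feature`, `delta_mw`, `wls_p`,
#'   `fdr_q`, `perm_p`, `significant`, `direction`), `n_perm`.
#' @export
psm_differential <- function(layer, z, covariates, n_perm = 1000L, seed,
                             fdr_alpha = 0.05, perm_alpha = 0.05) {
  z <- check_binary_z(z)
  layer <- as.matrix(layer)
  ps <- fit_propensity(covariates, z)
  w <- matching_weights(ps$scores, z)
  bal <- balance_report(covariates, z, w)
  wls <- weighted_feature_test(layer, z, w)
  delta <- mw_estimator(layer, z, w)
  q <- bh_fdr(wls$wls_p)
  perm <- permutation_test(layer, z, covariates, n_perm = n_perm, seed = seed)
  res <- data.frame(feature = wls$feature,
                    delta_mw = unname(delta),
                    wls_p = wls$wls_p,
                    fdr_q = q,
                    perm_p = unname(perm$perm_p),
                    degenerate = wls$degenerate,
                    stringsAsFactors = FALSE)
  res$significant <- res$fdr_q < fdr_alpha & res$perm_p < perm_alpha
  res$direction <- ifelse(res$delta_mw > 0, "high-specific", "low-specific")
  structure(list(propensity = ps, weights = w, balance = bal, results = res,
                 n_perm = n_perm),
            class = "psm_result")
}

#' Resampling robustness of the matching-weight estimator
#'
#' Repeatedly draws subsamples with more than `min_per_group` samples in each
#' group, re-runs the full propensity/weighting/Delta-MW pipeline on each
#' subsample, and reports the Pearson correlation of the resampled Delta MW
#' vector with the full-data vector.
#'
#' @param layer features x samples matrix.
#' @param z 0/1 labels.
#' @param covariates covariate data.frame.
#' @param n_resamples number of resamples.
#' @param min_per_group each resample keeps strictly more than this many
#'   samples per group (default 30).
#' @param seed RNG seed.
#' @return numeric vector of per-resample correlations (NA, flagged via
#'   attribute `degenerate`, if the full-data Delta MW vector is constant).
#' @export
resampling_robustness <- function(layer, z, covariates, n_resamples = 20L,
                                  min_per_group = 30L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  z <- check_binary_z(z)
  layer <- as.matrix(layer)
  n1 <- sum(z == 1L); n0 <- sum(z == 0L)
  if (n1 <= min_per_group || n0 <= min_per_group) {
    stop("each group must have more than ", min_per_group, " samples")
  }
  full <- psm_delta(layer, z, covariates)
  degenerate <- stats::sd(full) == 0
  set.seed(seed)
  r <- vapply(seq_len(n_resamples), function(b) {
    k1 <- sample((min_per_group + 1L):n1, 1L)
    k0 <- sample((min_per_group + 1L):n0, 1L)
    idx <- c(sample(which(z == 1L), k1), sample(which(z == 0L), k0))
    sub <- psm_delta(layer[, idx, drop = FALSE], z[idx],
                     covariates[idx, , drop = FALSE])
    if (degenerate || stats::sd(sub) == 0) return(NA_real_)
    stats::cor(full, sub)
  }, numeric(1))
  attr(r, "degenerate") <- degenerate
  r
}
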