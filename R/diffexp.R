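#' Per-feature two-group linear fits
#'
#' Fits the two-group (sex) model feature by feature on log2 data with
#' complete-case handling: each feature uses its observed values only,
#' and features with fewer than `min_per_group` observed values in
#' either group are excluded (and logged). Effect is
#' `mean(group1) - mean(group2)` with the pooled residual variance.
#'
#' @param x an `ExpressionMatrix` on log2 scale.
#' @param groups factor/character of length `ncol(x)` with exactly two
#'   levels; the first level is group 1 (numerator of the fold change).
#' @param min_per_group minimum observed samples per group (default 2).
#' @return data.frame with `feature_id`, `lfc`, `s2` (pooled residual
#'   variance), `df` (residual df), `n1`, `n2`, `stdev_unscaled`
#'   (`sqrt(1/n1 + 1/n2)`).
#' @export
fit_group_model <- function(x, groups, min_per_group = 2) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "log2") stop("matrix must be on log2 scale", call. = FALSE)
  groups <- as.factor(groups)
  if (length(groups) != ncol(x$values)) {
    stop("groups must have one label per sample", call. = FALSE)
  }
  if (nlevels(droplevels(groups)) != 2) {
    stop("exactly two groups required; got levels: ",
         paste(levels(droplevels(groups)), collapse = ", "), call. = FALSE)
  }
  groups <- droplevels(groups)
  g1 <- groups == levels(groups)[1]
  g2 <- groups == levels(groups)[2]
  if (!any(g1) || !any(g2)) stop("a group is entirely absent", call. = FALSE)

  m <- x$mask
  v <- x$values
  v[!m] <- 0
  n1 <- rowSums(m[, g1, drop = FALSE])
  n2 <- rowSums(m[, g2, drop = FALSE])
  sum1 <- rowSums(v[, g1, drop = FALSE])
  sum2 <- rowSums(v[, g2, drop = FALSE])
  mean1 <- sum1 / n1
  mean2 <- sum2 / n2
  ss1 <- rowSums((v[, g1, drop = FALSE] - outer(ifelse(n1 > 0, mean1, 0), rep(1, sum(g1))))^2 *
                   m[, g1, drop = FALSE])
  ss2 <- rowSums((v[, g2, drop = FALSE] - outer(ifelse(n2 > 0, mean2, 0), rep(1, sum(g2))))^2 *
                   m[, g2, drop = FALSE])
  keep <- n1 >= min_per_group & n2 >= min_per_group
  if (!any(keep)) stop("no feature has enough observed values in both groups", call. = FALSE)
  run_log("fit_group_model", n_in = nrow(v), n_kept = sum(keep),
          excluded = x$feature_ids[!keep])
  df <- (n1 + n2 - 2)[keep]
  out <- data.frame(
    feature_id = x$feature_ids[keep],
    lfc = (mean1 - mean2)[keep],
    s2 = ((ss1 + ss2)[keep]) / df,
    df = df,
    n1 = n1[keep], n2 = n2[keep],
    stdev_unscaled = sqrt(1 / n1[keep] + 1 / n2[keep]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Empirical-Bayes moderated t-statistics
#'
#' Shrinks per-feature variances toward a common prior using the
#' standard hierarchical model for gene-wise variances: the prior df
#' `d0` and prior variance `s0^2` are estimated by method of moments on
#' log variances (digamma/trigamma closed forms), the posterior
#' variance is `s2_post = (d0*s0^2 + df*s2) / (d0 + df)`, and
#' `t_mod = lfc / (sqrt(s2_post) * stdev_unscaled)` is referred to a t
#' distribution on `df + d0` degrees of freedom. `d0` is capped at 1e6
#' (numerically "infinite" prior df).
#'
#' @param fits output of [fit_group_model()].
#' @param d0_override force the prior df (e.g. `0` gives the ordinary
#'   two-sample t-test; mainly a validation aid).
#' @return data.frame with `feature_id`, `lfc`, `t_mod`, `p`, `q` (BH),
#'   `df_total`, `s2_post`, plus attributes `d0` and `s0_2`.
#' @export
ebayes_moderate <- function(fits, d0_override = NULL) {
  req <- c("feature_id", "lfc", "s2", "df", "stdev_unscaled")
  if (!all(req %in% names(fits))) {
    stop("fits must come from fit_group_model()", call. = FALSE)
  }
  if (nrow(fits) < 2) stop("need >= 2 features to estimate hyperparameters", call. = FALSE)
  s2 <- fits$s2
  df <- fits$df
  if (all(s2 == 0)) stop("all residual variances are zero (degenerate input)", call. = FALSE)

  if (is.null(d0_override)) {
    # method of moments on z = log(s2): z ~ log s0^2 + log chi2 terms
    ok <- s2 > 0
    z <- log(s2[ok])
    dfo <- df[ok]
    e <- z - digamma(dfo / 2) + log(dfo / 2)
    n <- length(e)
    evar <- mean((e - mean(e))^2 * n / (n - 1)) - mean(trigamma(dfo / 2))
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      d0 <- min(d0, 1e6)
      s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- 1e6                      # variances essentially exchangeable
      s0_2 <- exp(mean(e))
    }
  } else {
    d0 <- d0_override
    s0_2 <- if (d0 > 0) mean(s2) else 0
  }
  s2_post <- if (d0 > 0) (d0 * s0_2 + df * s2) / (d0 + df) else s2
  df_total <- df + d0
  t_mod <- fits$lfc / (sqrt(s2_post) * fits$stdev_unscaled)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- data.frame(
    feature_id = fits$feature_id,
    lfc = fits$lfc,
    t_mod = t_mod,
    p = p,
    q = bh_adjust(p),
    df_total = df_total,
    s2_post = s2_post,
    stringsAsFactors = FALSE
  )
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  run_log("ebayes_moderate", n_features = nrow(out), d0 = d0, s0_2 = s0_2)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`q_i = min over p_j >= p_i of m*p_j/rank_j`,
#' capped at 1).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Vector of BH-adjusted values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed proteins/features
#'
#' Thresholds are strict, as printed: `|lfc| > lfc_min` and
#' `q < q_max`. A feature at exactly the boundary is not called.
#'
#' @param results output of [ebayes_moderate()].
#' @param lfc_min minimum |log2 fold change| (default 1).
#' @param q_max maximum BH-adjusted p (default 0.05).
#' @return Character vector of feature IDs called differential.
#' @export
call_deps <- function(results, lfc_min = 1, q_max = 0.05) {
  stopifnot(all(c("feature_id", "lfc", "q") %in% names(results)))
  hits <- results$feature_id[abs(results$lfc) > lfc_min & results$q < q_max]
  run_log("call_deps", lfc_min = lfc_min, q_max = q_max, n_deps = length(hits))
  hits
}

#' Power of the two-sample t-test
#'
#' Exact noncentral-t power for a balanced two-sample t-test with
#' standardized effect size `d` (difference in means over the common
#' SD): `df = 2n - 2`, noncentrality `d * sqrt(n/2)`.
#'
#' @param n_per_group samples per group (>= 2).
#' @param effect_d standardized effect size.
#' @param alpha significance level, in (0, 1).
#' @param sides 1 or 2.
#' @return Power as a fraction in [0, 1].
#' @export
t_test_power <- function(n_per_group, effect_d, alpha = 0.05, sides = 2) {
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  if (!sides %in% c(1, 2)) stop("sides must be 1 or 2", call. = FALSE)
  df <- 2 * n_per_group - 2
  ncp <- effect_d * sqrt(n_per_group / 2)
  # central branch keeps power(d = 0) = alpha exact (the ncp algorithm
  # is itself only accurate to ~1e-8)
  if (sides == 2) {
    tcrit <- stats::qt(1 - alpha / 2, df)
    if (ncp == 0) return(alpha)
    stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tcrit, df, ncp = ncp)
  } else {
    tcrit <- stats::qt(1 - alpha, df)
    if (ncp == 0) return(alpha)
    stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE)
  }
}
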