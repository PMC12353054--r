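#' Background-referenced phospho-array quantification
#'
#' Quantifies each phosphorylation-site ROI against the PBS negative
#' control of its own membrane:
#' `signal = mean(PBS pixel intensity) - mean(ROI pixel intensity)`.
#' On chemiluminescent membranes stronger phosphorylation darkens the
#' spot, so a site darker than the PBS background yields a positive
#' signal and a lighter one a negative signal. PBS rows are consumed,
#' not emitted.
#'
#' @param table data.frame with columns `membrane_id`, `roi_id`, `sex`,
#'   `replicate`, `mean_pixel_intensity`; exactly one `roi_id == "PBS"`
#'   row per membrane.
#' @return data.frame with `membrane_id`, `site`, `sex`, `replicate`,
#'   `signal`.
#' @export
quantify_spots <- function(table) {
  need <- c("membrane_id", "roi_id", "sex", "replicate", "mean_pixel_intensity")
  if (!all(need %in% names(table))) {
    stop("table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (mem in unique(table$membrane_id)) {
    sub <- table[table$membrane_id == mem, , drop = FALSE]
    pbs <- sub[sub$roi_id == "PBS", , drop = FALSE]
    if (nrow(pbs) == 0) {
      stop("membrane '", mem, "' has no PBS control ROI", call. = FALSE)
    }
    if (nrow(pbs) > 1) {
      stop("membrane '", mem, "' has ", nrow(pbs), " PBS control ROIs; expected exactly one",
           call. = FALSE)
    }
    sites <- sub[sub$roi_id != "PBS", , drop = FALSE]
    if (nrow(sites) == 0) next
    out[[mem]] <- data.frame(
      membrane_id = mem,
      site = sites$roi_id,
      sex = sites$sex,
      replicate = sites$replicate,
      signal = pbs$mean_pixel_intensity - sites$mean_pixel_intensity,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  run_log("quantify_spots", n_membranes = length(out), n_sites = nrow(res))
  res
}

#' Sex-by-site two-way ANOVA with Tukey HSD
#'
#' Fixed-effects ANOVA of the quantified signals on `sex * site` with
#' type-II sums of squares (robust to the unbalanced membranes that
#' arise in practice), followed by Tukey HSD restricted to
#' sex-within-site comparisons.
#'
#' @param signals output of [quantify_spots()] (long table with `sex`,
#'   `site`, `signal`).
#' @return list with `anova` (type-II table), `interaction_p`, `sex_p`,
#'   and `tukey` (data.frame: site, estimate M-F, adjusted p).
#' @export
phospho_anova <- function(signals) {
  need <- c("sex", "site", "signal")
  if (!all(need %in% names(signals))) {
    stop("signals must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  signals$sex <- factor(signals$sex)
  signals$site <- factor(signals$site)
  if (nlevels(signals$sex) < 2) stop("need >= 2 sexes", call. = FALSE)
  if (nlevels(signals$site) < 2) stop("need >= 2 sites", call. = FALSE)
  cells <- table(signals$sex, signals$site)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(sprintf("%s:%s", rownames(cells)[empty[, 1]],
                       colnames(cells)[empty[, 2]]), collapse = ", "), call. = FALSE)
  }
  if (any(cells < 2)) {
    run_log("phospho_anova", note = "cells with < 2 replicates; unbalanced design")
  }
  fit <- stats::lm(signal ~ sex * site, data = signals)
  a2 <- car::Anova(fit, type = 2)
  av <- stats::aov(signal ~ sex:site, data = signals)
  tk <- stats::TukeyHSD(av)[["sex:site"]]
  cmp <- rownames(tk)
  # keep only comparisons between sexes at the same site
  parts <- strsplit(cmp, "-", fixed = TRUE)
  site_of <- function(lbl) sub("^[^:]+:", "", lbl)
  sex_of <- function(lbl) sub(":.*$", "", lbl)
  keep <- vapply(parts, function(pr) {
    site_of(pr[1]) == site_of(pr[2]) && sex_of(pr[1]) != sex_of(pr[2])
  }, logical(1))
  tk_keep <- tk[keep, , drop = FALSE]
  parts_keep <- parts[keep]
  est <- vapply(seq_along(parts_keep), function(i) {
    # orient as M - F
    if (sex_of(parts_keep[[i]][1]) == "M") tk_keep[i, "diff"] else -tk_keep[i, "diff"]
  }, numeric(1))
  tukey <- data.frame(
    site = vapply(parts_keep, function(pr) site_of(pr[1]), character(1)),
    estimate = est,
    p_adj = unname(tk_keep[, "p adj"]),
    stringsAsFactors = FALSE
  )
  run_log("phospho_anova", interaction_p = a2["sex:site", "Pr(>F)"])
  list(
    anova = a2,
    sex_p = a2["sex", "Pr(>F)"],
    interaction_p = a2["sex:site", "Pr(>F)"],
    tukey = tukey
  )
}
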