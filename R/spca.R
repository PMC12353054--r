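#' Supervised PCA on an externally defined feature list
#'
#' Restricts the matrix to the supplied feature list (e.g. sexually
#' dimorphic chromatin regions or differentially expressed genes mapped
#' to symbols), drops listed features with any missing value
#' (complete-case, logged), and runs an ordinary PCA (SVD, via
#' `prcomp`) on the samples-by-features subset. "Eigengenes" are the
#' per-sample PC scores and "eigenvectors" the per-feature loadings.
#' The PC1 sign is fixed so that the group-1 mean score is >= the
#' group-2 mean score (PCA signs are arbitrary; a deterministic
#' convention keeps results stable). Group separation on PC1 is tested
#' with a two-sided Welch t-test.
#'
#' @param x an `ExpressionMatrix`.
#' @param features a [feature_list()] (or character vector) defining the
#'   supervised subset.
#' @param groups factor/character with two levels, one per sample; the
#'   first level is group 1.
#' @param center,scale. passed to [stats::prcomp()] (defaults TRUE /
#'   FALSE, the cited implementation's defaults).
#' @return An `SpcaResult`: list with `pc_scores` (samples x
#'   components), `loadings` (features x components),
#'   `variance_explained`, `welch_p`, `pc1_sign_flipped`,
#'   `features_used`.
#' @export
spca_fit <- function(x, features, groups, center = TRUE, scale. = FALSE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (inherits(features, "FeatureList")) features <- features$features
  features <- as.character(features)
  present <- intersect(features, x$feature_ids)
  sub <- em_subset(x, features = present)
  complete <- rowSums(!sub$mask) == 0
  run_log("spca_fit", n_listed = length(features), n_present = length(present),
          n_complete = sum(complete))
  if (sum(complete) < 2) {
    stop(sprintf("need >= 2 complete listed features, have %d (listed %d, present %d)",
                 sum(complete), length(features), length(present)), call. = FALSE)
  }
  sub <- em_subset(sub, features = which(complete))
  if (ncol(sub$values) < 3) stop("need >= 3 samples", call. = FALSE)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2 || length(groups) != ncol(sub$values)) {
    stop("groups must give exactly two levels, one label per sample", call. = FALSE)
  }
  pca <- stats::prcomp(t(sub$values), center = center, scale. = scale.)
  scores <- pca$x
  loadings <- pca$rotation
  g1 <- groups == levels(groups)[1]
  flipped <- FALSE
  if (mean(scores[g1, 1]) < mean(scores[!g1, 1])) {
    scores[, 1] <- -scores[, 1]
    loadings[, 1] <- -loadings[, 1]
    flipped <- TRUE
  }
  welch <- stats::t.test(scores[g1, 1], scores[!g1, 1], var.equal = FALSE)
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  structure(
    list(pc_scores = scores, loadings = loadings, variance_explained = ve,
         welch_p = unname(welch$p.value), pc1_sign_flipped = flipped,
         features_used = sub$feature_ids, groups = groups,
         center = center, scale = scale.),
    class = "SpcaResult"
  )
}

#' @export
print.SpcaResult <- function(x, ...) {
  cat(sprintf("SpcaResult: %d features, %d samples; PC1 %.1f%% variance; Welch p = %.3g\n",
              nrow(x$loadings), nrow(x$pc_scores),
              100 * x$variance_explained[1], x$welch_p))
  invisible(x)
}

#' Top PC1 loadings of a supervised PCA
#'
#' Features sorted by |PC1 loading| descending (ties by feature ID);
#' signed loadings retained. The full signed vector can be fed to
#' [rank_features()] for loading-ranked GSEA.
#'
#' @param result an `SpcaResult`.
#' @param k number of features to return (<= feature count).
#' @return data.frame with `feature_id` and `loading` (PC1, signed).
#' @export
top_loadings <- function(result, k = nrow(result$loadings)) {
  stopifnot(inherits(result, "SpcaResult"))
  if (k > nrow(result$loadings)) stop("k exceeds feature count", call. = FALSE)
  l1 <- result$loadings[, 1]
  ord <- order(-abs(l1), names(l1), method = "radix")[seq_len(k)]
  data.frame(feature_id = names(l1)[ord], loading = unname(l1[ord]),
             stringsAsFactors = FALSE)
}
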