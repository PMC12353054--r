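#' Parse compound gene-group identifiers
#'
#' DIA search engines emit protein groups as delimited lists of gene
#' symbols sharing peptide evidence (e.g. `"TRPV1;TRPV2"` or
#' `"TRPV1, TRPV2, TRPA1"`). IDs are split on commas and semicolons,
#' whitespace-trimmed; the first token is the primary symbol.
#'
#' @param ids character vector of raw gene-group IDs.
#' @return A data.frame with `raw_id`, `first_term`, and a list column
#'   `members`.
#' @export
parse_gene_groups <- function(ids) {
  members <- strsplit(as.character(ids), "[,;]")
  members <- lapply(members, function(m) {
    m <- trimws(m)
    m[nzchar(m)]
  })
  if (any(lengths(members) == 0)) {
    stop("gene-group ID parses to zero symbols: ",
         ids[which(lengths(members) == 0)[1]], call. = FALSE)
  }
  out <- data.frame(raw_id = as.character(ids),
                    first_term = vapply(members, `[[`, character(1), 1),
                    stringsAsFactors = FALSE)
  out$members <- members
  out
}

#' Deduplicate gene groups by primary symbol
#'
#' Where two gene groups share a first term (e.g. `"TRPV1"` and
#' `"TRPV1, TRPV2, TRPA1"`), the first term is used as the feature ID
#' and the row with the higher mean observed abundance is retained.
#' Ties keep the earliest input row (deterministic). Output row order is
#' the order of first appearance of each primary symbol.
#'
#' @param x an `ExpressionMatrix` whose feature IDs are (possibly
#'   compound) gene-group identifiers.
#' @return An `ExpressionMatrix` with one row per primary symbol,
#'   feature IDs set to the primary symbols.
#' @export
dedup_gene_groups <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (nrow(x$values) == 0) return(x)
  gg <- parse_gene_groups(x$feature_ids)
  mean_ab <- masked_row_means(x)
  mean_ab[is.na(mean_ab)] <- -Inf   # all-missing rows lose every tie
  idx <- seq_len(nrow(x$values))
  # stable pick: highest mean abundance, earliest row on ties
  ord <- order(gg$first_term, -mean_ab, idx, method = "radix")
  keep_of <- ord[!duplicated(gg$first_term[ord])]
  names(keep_of) <- gg$first_term[keep_of]
  # restore input order of first appearance
  first_appear <- idx[!duplicated(gg$first_term)]
  keep <- keep_of[gg$first_term[first_appear]]
  out <- expression_matrix(
    x$values[keep, , drop = FALSE],
    feature_ids = gg$first_term[keep],
    sample_ids = x$sample_ids,
    scale = x$scale,
    mask = x$mask[keep, , drop = FALSE]
  )
  run_log("dedup_gene_groups", n_in = nrow(x$values), n_out = nrow(out$values),
          kept_raw_ids = unname(gg$raw_id[keep]))
  out
}

#' Filter features by completeness
#'
#' Retains features observed in at least `threshold` of samples.
#' The boundary is inclusive: features present in exactly 80% of
#' samples survive a 0.8 threshold (those present in *less than* 80%
#' are removed).
#'
#' @param x an `ExpressionMatrix`.
#' @param threshold minimum observed fraction, in (0, 1].
#' @return The filtered `ExpressionMatrix` (feature order preserved).
#' @export
completeness_filter <- function(x, threshold = 0.8) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  frac <- rowMeans(x$mask)
  keep <- which(frac >= threshold)
  out <- em_subset(x, features = keep)
  run_log("completeness_filter", threshold = threshold,
          n_in = nrow(x$values), n_out = length(keep))
  out
}

#' Merge technical replicates by mean
#'
#' Collapses technical replicate columns to one column per
#' (donor, tissue) group, averaging observed values; a merged entry is
#' missing only when all replicates are missing. Merged sample IDs are
#' `donor_tissue`.
#'
#' @param x an `ExpressionMatrix`.
#' @param meta a [sample_meta()] table covering every sample of `x`.
#' @return list with `matrix` (merged `ExpressionMatrix`) and `meta`
#'   (one row per merged sample, `replicate = 1`).
#' @export
merge_replicates <- function(x, meta) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  meta <- check_meta(x, meta)
  grp <- paste(meta$donor, meta$tissue, sep = "_")
  groups <- split(seq_along(grp), factor(grp, levels = unique(grp)))
  for (g in names(groups)) {
    d <- unique(meta$donor[groups[[g]]])
    if (length(d) != 1) {
      stop("replicate group '", g, "' spans donors: ",
           paste(d, collapse = ", "), call. = FALSE)
    }
    sx <- unique(as.character(meta$sex[groups[[g]]]))
    if (length(sx) != 1) {
      stop("replicate group '", g, "' has inconsistent sex labels", call. = FALSE)
    }
  }
  vals <- x$values
  vals[!x$mask] <- 0
  merged <- vapply(groups, function(cols) {
    n_obs <- rowSums(x$mask[, cols, drop = FALSE])
    v <- rowSums(vals[, cols, drop = FALSE]) / n_obs
    v[n_obs == 0] <- NA_real_
    v
  }, numeric(nrow(vals)))
  if (is.null(dim(merged))) merged <- matrix(merged, nrow = nrow(vals))
  out <- expression_matrix(merged, feature_ids = x$feature_ids,
                           sample_ids = names(groups), scale = x$scale)
  first_of <- vapply(groups, `[`, integer(1), 1)
  new_meta <- sample_meta(
    sample_id = names(groups),
    donor = meta$donor[first_of],
    sex = as.character(meta$sex[first_of]),
    tissue = meta$tissue[first_of],
    replicate = 1L
  )
  run_log("merge_replicates", n_samples_in = ncol(x$values),
          n_samples_out = ncol(out$values))
  list(matrix = out, meta = new_meta)
}

#' Log2-transform a linear-scale matrix
#'
#' @param x an `ExpressionMatrix` with `scale = "linear"`; all observed
#'   values must be strictly positive.
#' @return The `ExpressionMatrix` on log2 scale.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "linear") {
    stop("matrix is already on log2 scale", call. = FALSE)
  }
  bad <- which(x$mask & x$values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    cells <- apply(utils::head(bad, 5), 1, function(rc) {
      sprintf("(%s, %s)", x$feature_ids[rc[1]], x$sample_ids[rc[2]])
    })
    stop("nonpositive observed value(s) at ", paste(cells, collapse = ", "),
         if (nrow(bad) > 5) sprintf(" and %d more", nrow(bad) - 5) else "",
         call. = FALSE)
  }
  v <- x$values
  v[x$mask] <- log2(v[x$mask])
  expression_matrix(v, feature_ids = x$feature_ids, sample_ids = x$sample_ids,
                    scale = "log2", mask = x$mask)
}

#' Align studies onto a common, complete feature set
#'
#' Restricts each matrix to the features shared by all studies (and by
#' `restrict_to`, if given), optionally removes X/Y-chromosome features
#' (supplied as a list — no genome annotation is consulted), then drops
#' any feature with a missing entry in any study, yielding complete
#' matrices in identical feature order.
#'
#' @param matrices list of >= 2 `ExpressionMatrix` objects.
#' @param restrict_to optional [feature_list()] to intersect with.
#' @param drop_sex_chromosomes logical; requires `sex_chrom_features`.
#' @param sex_chrom_features [feature_list()] of X/Y features to remove.
#' @return List of aligned, complete `ExpressionMatrix` objects.
#' @export
align_studies <- function(matrices, restrict_to = NULL,
                          drop_sex_chromosomes = FALSE,
                          sex_chrom_features = NULL) {
  if (length(matrices) < 2) stop("need at least two studies", call. = FALSE)
  lapply(matrices, function(m) stopifnot(inherits(m, "ExpressionMatrix")))
  counts <- list()
  common <- Reduce(intersect, lapply(matrices, `[[`, "feature_ids"))
  counts$shared_across_studies <- length(common)
  if (!is.null(restrict_to)) {
    # keep restrict_to's ordering: it is the externally defined list
    common <- restrict_to$features[restrict_to$features %in% common]
    counts$after_restrict_to <- length(common)
  }
  if (isTRUE(drop_sex_chromosomes)) {
    if (is.null(sex_chrom_features)) {
      stop("drop_sex_chromosomes = TRUE requires `sex_chrom_features`", call. = FALSE)
    }
    common <- setdiff(common, sex_chrom_features$features)
    counts$after_sex_chrom_removal <- length(common)
  }
  if (length(common)) {
    complete_in <- vapply(matrices, function(m) {
      rowSums(!m$mask[match(common, m$feature_ids), , drop = FALSE]) == 0
    }, logical(length(common)))
    if (is.null(dim(complete_in))) complete_in <- matrix(complete_in, nrow = length(common))
    common <- common[rowSums(complete_in) == length(matrices)]
  }
  counts$after_missingness_removal <- length(common)
  run_log("align_studies", survivor_counts = counts)
  if (!length(common)) {
    stop("no features survive alignment; survivor counts per step: ",
         paste(names(counts), unlist(counts), sep = "=", collapse = ", "),
         call. = FALSE)
  }
  lapply(matrices, em_subset, features = common)
}
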