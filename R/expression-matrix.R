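#' Feature-by-sample expression matrix with explicit missingness
#'
#' `ExpressionMatrix` is the common currency of the package: a numeric
#' feature-by-sample matrix plus an observation mask and a scale flag.
#' Unobserved entries are stored as `NA` (the storage-layer sentinel) and
#' every arithmetic operation in the package consults `mask` rather than
#' relying on `NA` propagation.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   `NA` entries are treated as unobserved.
#' @param feature_ids character vector of unique feature identifiers;
#'   defaults to `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers;
#'   defaults to `colnames(values)`.
#' @param scale `"log2"` or `"linear"` — the scale the observed values
#'   are on.
#' @param mask logical matrix of the same shape as `values`; `TRUE` marks
#'   an observed entry. Defaults to `!is.na(values)`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `mask`, `feature_ids`, `sample_ids`, `scale`.
#' @export
expression_matrix <- function(values,
                              feature_ids = rownames(values),
                              sample_ids = colnames(values),
                              scale = c("log2", "linear"),
                              mask = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(feature_ids)) feature_ids <- paste0("feature_", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(values)))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values)) {
    stop("length(feature_ids) != nrow(values)", call. = FALSE)
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length(sample_ids) != ncol(values)", call. = FALSE)
  }
  dup_f <- feature_ids[duplicated(feature_ids)]
  if (length(dup_f)) {
    stop("duplicate feature IDs: ", paste(unique(dup_f), collapse = ", "),
         call. = FALSE)
  }
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s)) {
    stop("duplicate sample IDs: ", paste(unique(dup_s), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(mask)) mask <- !is.na(values)
  if (!is.logical(mask) || !identical(dim(mask), dim(values))) {
    stop("`mask` must be a logical matrix with the same shape as `values`",
         call. = FALSE)
  }
  if (any(is.na(values) & mask)) {
    stop("entries flagged observed in `mask` must be non-missing in `values`",
         call. = FALSE)
  }
  if (any(!is.finite(values[mask]))) {
    stop("observed values must be finite", call. = FALSE)
  }
  values[!mask] <- NA_real_
  dimnames(values) <- list(feature_ids, sample_ids)
  dimnames(mask) <- dimnames(values)
  structure(
    list(values = values, mask = mask, feature_ids = feature_ids,
         sample_ids = sample_ids, scale = scale),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  n_miss <- sum(!x$mask)
  cat(sprintf("  missing entries: %d (%.1f%%)\n", n_miss,
              100 * n_miss / length(x$mask)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix by features and/or samples
#'
#' @param x an `ExpressionMatrix`.
#' @param features character vector of feature IDs (order respected) or
#'   integer/logical index; `NULL` keeps all.
#' @param samples character vector of sample IDs or index; `NULL` keeps all.
#' @return An `ExpressionMatrix`.
#' @export
em_subset <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  fi <- if (is.null(features)) seq_along(x$feature_ids) else {
    if (is.character(features)) {
      missing_f <- setdiff(features, x$feature_ids)
      if (length(missing_f)) {
        stop("unknown feature IDs: ", paste(utils::head(missing_f, 5), collapse = ", "),
             call. = FALSE)
      }
      match(features, x$feature_ids)
    } else features
  }
  si <- if (is.null(samples)) seq_along(x$sample_ids) else {
    if (is.character(samples)) {
      missing_s <- setdiff(samples, x$sample_ids)
      if (length(missing_s)) {
        stop("unknown sample IDs: ", paste(utils::head(missing_s, 5), collapse = ", "),
             call. = FALSE)
      }
      match(samples, x$sample_ids)
    } else samples
  }
  expression_matrix(
    x$values[fi, si, drop = FALSE],
    feature_ids = x$feature_ids[fi],
    sample_ids = x$sample_ids[si],
    scale = x$scale,
    mask = x$mask[fi, si, drop = FALSE]
  )
}

#' Sample metadata table
#'
#' Validates a sample metadata data frame against the package contract:
#' one row per sample with donor, sex, tissue and technical replicate
#' information.
#'
#' @param sample_id,donor character vectors.
#' @param sex factor or character, levels `M`/`F`.
#' @param tissue character; conventionally `ganglia`, `nerve_root` or
#'   `other`.
#' @param replicate integer >= 1, the technical replicate index within a
#'   (donor, tissue) pair.
#' @return A `data.frame` with class `SampleMeta` prepended.
#' @export
sample_meta <- function(sample_id, donor, sex, tissue = "other", replicate = 1L) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  sex <- as.character(sex)
  if (!all(sex %in% c("M", "F"))) {
    stop("sex must be 'M' or 'F'", call. = FALSE)
  }
  replicate <- as.integer(replicate)
  if (any(replicate < 1L)) stop("replicate must be >= 1", call. = FALSE)
  out <- data.frame(
    sample_id = sample_id,
    donor = as.character(donor),
    sex = factor(sex, levels = c("M", "F")),
    tissue = as.character(tissue),
    replicate = replicate,
    stringsAsFactors = FALSE
  )
  class(out) <- c("SampleMeta", class(out))
  out
}

# internal: check every sample of an ExpressionMatrix has exactly one meta row
check_meta <- function(x, meta) {
  missing_s <- setdiff(x$sample_ids, meta$sample_id)
  if (length(missing_s)) {
    stop("samples without metadata: ", paste(utils::head(missing_s, 5), collapse = ", "),
         call. = FALSE)
  }
  meta[match(x$sample_ids, meta$sample_id), , drop = FALSE]
}

#' Ordered feature list
#'
#' @param features character vector of feature IDs (duplicates removed,
#'   first occurrence kept).
#' @param name list name.
#' @param provenance one of `DAR`, `DEG`, `marker`, `custom`.
#' @param exclude_sex_chromosomes_applied logical flag recording whether
#'   X/Y features were already removed upstream.
#' @return A `FeatureList` object.
#' @export
feature_list <- function(features, name = "feature_list",
                         provenance = c("custom", "DAR", "DEG", "marker"),
                         exclude_sex_chromosomes_applied = FALSE) {
  provenance <- match.arg(provenance)
  features <- as.character(features)
  features <- features[!duplicated(features)]
  structure(
    list(name = name, features = features, provenance = provenance,
         exclude_sex_chromosomes_applied = isTRUE(exclude_sex_chromosomes_applied)),
    class = "FeatureList"
  )
}

#' @export
print.FeatureList <- function(x, ...) {
  cat(sprintf("FeatureList '%s' (%s): %d features\n", x$name, x$provenance,
              length(x$features)))
  invisible(x)
}

#' Gene-set collection (GMT-style)
#'
#' @param sets named list of character vectors (set members); names must
#'   be unique, sets non-empty.
#' @param description optional character vector parallel to `sets`.
#' @return A `GeneSetCollection` object.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (length(sets) == 0) {
    return(structure(list(sets = list(), description = character(0)),
                     class = "GeneSetCollection"))
  }
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("set names must be present and unique", call. = FALSE)
  }
  if (any(lengths(sets) == 0)) {
    stop("gene sets must be non-empty", call. = FALSE)
  }
  sets <- lapply(sets, function(s) {
    s <- as.character(s); s[!duplicated(s)]
  })
  if (is.null(description)) description <- rep("", length(sets))
  names(description) <- names(sets)
  structure(list(sets = sets, description = description),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets (sizes %s)\n", length(x$sets),
              if (length(x$sets)) paste(range(lengths(x$sets)), collapse = "-") else "-"))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)
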