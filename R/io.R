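#' Read a feature-by-sample matrix from TSV/CSV
#'
#' Expects one header row of sample IDs and a first column of feature
#' IDs. Empty cells or `NA` denote missing values. The delimiter is
#' taken from the file extension (`.csv` is comma, anything else tab).
#'
#' @param path file path.
#' @param orientation `"features_in_rows"` (default) or
#'   `"samples_in_rows"`; the latter transposes after reading.
#' @param scale scale flag recorded on the result (`"log2"`/`"linear"`).
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path,
                        orientation = c("features_in_rows", "samples_in_rows"),
                        scale = "log2") {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("matrix file needs a feature-ID column plus >=1 sample column",
                          call. = FALSE)
  ids <- raw[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate feature ID(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  samp <- colnames(raw)[-1]
  dup_s <- samp[duplicated(samp)]
  if (length(dup_s)) {
    stop("duplicate sample ID(s) in ", path, ": ",
         paste(unique(dup_s), collapse = ", "), call. = FALSE)
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  cells[cells == ""] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & !is.na(cells) & cells != "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at row %d (feature '%s'), column %d (sample '%s'): '%s'",
                 bad[1, 1], ids[bad[1, 1]], bad[1, 2], samp[bad[1, 2]],
                 cells[bad[1, , drop = FALSE]]), call. = FALSE)
  }
  em <- expression_matrix(num, feature_ids = ids, sample_ids = samp, scale = scale)
  if (orientation == "samples_in_rows") {
    em <- expression_matrix(t(em$values), feature_ids = em$sample_ids,
                            sample_ids = em$feature_ids, scale = scale)
  }
  run_log("read_matrix", path = path, n_features = nrow(em$values),
          n_samples = ncol(em$values), n_missing = sum(!em$mask))
  em
}

#' Write an ExpressionMatrix to TSV/CSV
#'
#' Inverse of [read_matrix()]: missing entries are written as `NA`.
#' Values are written at full precision so that a write/read round trip
#' reproduces the matrix bit-exactly.
#'
#' @param x an `ExpressionMatrix`.
#' @param path output path; `.csv` writes comma-separated, else tab.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  vals <- x$values
  chr <- matrix(vapply(vals, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1)), nrow = nrow(vals))
  df <- data.frame(feature_id = x$feature_ids, chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", x$sample_ids)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate members within a line are collapsed (first occurrence
#' kept); line order is preserved.
#'
#' @param path GMT file path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(gene_set_collection(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short)) {
    stop(sprintf("GMT parse error at line %d: expected >=3 tab-separated fields, got %d",
                 short[1], lengths(parts)[short[1]]), call. = FALSE)
  }
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  desc <- vapply(parts, `[[`, character(1), 2)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  gene_set_collection(sets, description = desc)
}

#' Write a GeneSetCollection to GMT
#' @param x a `GeneSetCollection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "GeneSetCollection"))
  lines <- vapply(names(x$sets), function(nm) {
    paste(c(nm, x$description[[nm]], x$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text feature list (one ID per line)
#' @inheritParams feature_list
#' @param path file path; blank lines and lines starting with `#` are
#'   skipped.
#' @return A [feature_list()].
#' @export
read_feature_list <- function(path, name = basename(path),
                              provenance = "custom") {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  feature_list(lines, name = name, provenance = provenance)
}

# default run configuration: values as used throughout the analyses
default_config <- function() {
  list(
    fdr = 0.05,                 # DEP q-value threshold (strict <)
    lfc_min = 1,                # DEP |log2 fold change| threshold (strict >)
    completeness = 0.8,         # minimum observed fraction per feature (>=)
    completeness_after_merge = TRUE,
    n_perm = 10000L,            # GSEA permutations
    gsea_min_size = 25L,        # minimum gene-set size, ranked-LFC GSEA
    gsea_max_size = Inf,
    gsea_weight = 1,            # running-sum weight exponent
    msfa_gsea_min_size = 5L,    # minimum set size for loading GSEA
    kmo_min = 0.5,              # per-study sampling-adequacy gate
    anova_q = 0.1,              # factor-contrast significance threshold
    k_shared = 3L,              # shared factors
    ecm_max_iter = 10000L,
    ecm_tol = 1e-6,
    d0_override = NULL,         # force prior df in moderated t (testing aid)
    spca_center = TRUE,
    spca_scale = FALSE,
    seed = 1L,
    normalize_feature_ids = FALSE  # opt-in upper-casing hook
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON key/value file, applies package defaults for
#' absent keys, rejects unknown keys, and range-checks thresholds.
#' With `path = NULL` the full default set is returned.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file, or `NULL`.
#' @param overrides named list applied on top of the file (same
#'   validation).
#' @return Named list of configuration values.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  user <- list()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(user)) user <- list()
  }
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(user)) cfg[[k]] <- user[[k]]
  validate_config(cfg)
  run_log("load_config", config = cfg[!vapply(cfg, is.null, logical(1))])
  cfg
}

validate_config <- function(cfg) {
  in_01 <- function(x) is.numeric(x) && length(x) == 1 && x > 0 && x < 1
  if (!in_01(cfg$fdr)) stop("fdr must be in (0,1)", call. = FALSE)
  if (!is.numeric(cfg$completeness) || cfg$completeness <= 0 || cfg$completeness > 1) {
    stop("completeness must be in (0,1]", call. = FALSE)
  }
  if (!in_01(cfg$anova_q)) stop("anova_q must be in (0,1)", call. = FALSE)
  if (!is.numeric(cfg$kmo_min) || cfg$kmo_min < 0 || cfg$kmo_min > 1) {
    stop("kmo_min must be in [0,1]", call. = FALSE)
  }
  if (!is.numeric(cfg$lfc_min) || cfg$lfc_min < 0) stop("lfc_min must be >= 0", call. = FALSE)
  if (!is.numeric(cfg$n_perm) || cfg$n_perm < 100) {
    stop("n_perm must be >= 100", call. = FALSE)
  }
  if (!is.numeric(cfg$ecm_max_iter) || cfg$ecm_max_iter < 1) {
    stop("ecm_max_iter must be >= 1", call. = FALSE)
  }
  if (!is.numeric(cfg$k_shared) || cfg$k_shared < 1) {
    stop("k_shared must be >= 1", call. = FALSE)
  }
  invisible(cfg)
}

#' Direct the machine-readable run log to a file
#'
#' Every pipeline stage logs its input dimensions, filter survivor
#' counts and effective parameters as JSON lines. By default entries go
#' to `stderr` only (as messages); `set_run_log(path)` additionally
#' appends them to `path`.
#'
#' @param path file path, or `NULL` to disable file logging.
#' @return Previous path, invisibly.
#' @export
set_run_log <- function(path = NULL) {
  old <- getOption("dimorphomics.run_log")
  options(dimorphomics.run_log = path)
  invisible(old)
}

# internal JSON-lines logger
run_log <- function(stage, ...) {
  entry <- list(stage = stage, ...)
  json <- jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA, null = "null")
  if (isTRUE(getOption("dimorphomics.verbose", FALSE))) message(json)
  path <- getOption("dimorphomics.run_log")
  if (!is.null(path)) cat(json, "\n", sep = "", file = path, append = TRUE)
  invisible(NULL)
}
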