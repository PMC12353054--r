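#' Build a ranked list from per-feature statistics
#'
#' Stable descending sort; ties are broken by feature ID in
#' C-locale lexicographic order so rankings are reproducible across
#' platforms and input orderings.
#'
#' @param stats named numeric vector (feature -> statistic); must be
#'   finite, names unique.
#' @param descending sort direction (default `TRUE`).
#' @return A `RankedList`: list with `feature_id`, `stat` (parallel,
#'   sorted) and `tie_rule`.
#' @export
rank_features <- function(stats, descending = TRUE) {
  if (is.null(names(stats)) || anyDuplicated(names(stats))) {
    stop("stats must be named with unique feature IDs", call. = FALSE)
  }
  if (any(!is.finite(stats))) {
    stop("non-finite statistic for: ",
         paste(utils::head(names(stats)[!is.finite(stats)], 5), collapse = ", "),
         call. = FALSE)
  }
  ord <- if (descending) {
    order(-stats, names(stats), method = "radix")
  } else {
    order(stats, names(stats), method = "radix")
  }
  structure(
    list(feature_id = names(stats)[ord], stat = unname(stats[ord]),
         tie_rule = "feature_id lexicographic (C locale)"),
    class = "RankedList"
  )
}

#' @export
print.RankedList <- function(x, ...) {
  cat(sprintf("RankedList: %d features, stat range [%.3g, %.3g]\n",
              length(x$feature_id), min(x$stat), max(x$stat)))
  invisible(x)
}

# core weighted Kolmogorov-Smirnov running statistic given hit
# positions in the ranked list; returns the signed maximum deviation.
# Candidate extrema: the running sum peaks at hit positions and dips
# just before each hit, so only 2m points need inspection.
es_from_positions <- function(absw, pos, N) {
  m <- length(pos)
  if (m == 0) return(0)
  if (m == N) return(0)   # degenerate: every feature is a hit
  pos <- sort.int(pos)
  w <- absw[pos]
  W <- sum(w)
  chit <- if (W > 0) cumsum(w) / W else seq_len(m) / m  # all-zero stats: unweighted
  miss_step <- 1 / (N - m)
  at_hit <- chit - (pos - seq_len(m)) * miss_step
  before_hit <- c(0, chit[-m]) - (pos - seq_len(m)) * miss_step
  hi <- max(at_hit)
  lo <- min(before_hit, 0)
  if (hi >= -lo) hi else lo
}

#' GSEA enrichment score for one set
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic: walking down the
#' ranked list, hits increment by `|stat|^weight / sum(|stat|^weight)`
#' over the set and misses decrement by `1/(N - set size)`; the ES is
#' the signed maximum deviation from zero. The leading edge is the hit
#' subset at or before the extremum (after it, for negative ES).
#'
#' @param ranked a [rank_features()] result.
#' @param set character vector of feature IDs.
#' @param weight weight exponent (0 = classic KS, 1 = weighted;
#'   default 1).
#' @return list with `es`, `running` (length-N running sum),
#'   `leading_edge`.
#' @export
gsea_es <- function(ranked, set, weight = 1) {
  stopifnot(inherits(ranked, "RankedList"))
  N <- length(ranked$feature_id)
  hit <- ranked$feature_id %in% set
  m <- sum(hit)
  if (m == 0) stop("set has no overlap with the ranked list", call. = FALSE)
  if (m == N) {
    return(list(es = 0, running = rep(0, N), leading_edge = character(0)))
  }
  absw <- abs(ranked$stat)^weight
  wh <- absw * hit
  W <- sum(wh)
  inc <- if (W > 0) wh / W else hit / m
  running <- cumsum(inc - (!hit) / (N - m))
  i_ext <- which.max(abs(running))
  es <- running[i_ext]
  leading_edge <- if (es >= 0) {
    ranked$feature_id[seq_len(i_ext)][hit[seq_len(i_ext)]]
  } else {
    ranked$feature_id[i_ext:N][hit[i_ext:N]]
  }
  list(es = es, running = running, leading_edge = leading_edge)
}

#' Permutation GSEA over a gene-set collection
#'
#' Sets are intersected with the ranked features and filtered by size.
#' The null is gene-label permutation: for each permutation, set
#' membership is reassigned uniformly at random at the same size (the
#' appropriate null when the ranking is a precomputed statistic such as
#' a fold change or a factor loading, where sample permutation is not
#' available). `NES = ES / mean(|null ES| of matching sign)` and
#' `p = (1 + #{same-sign null at least as extreme}) / (1 + #same-sign
#' null)`, one-sided by ES sign; q is BH across retained sets.
#'
#' @param ranked a [rank_features()] result.
#' @param sets a [gene_set_collection()].
#' @param n_perm number of permutations (>= 100; default 10000).
#' @param min_size,max_size set-size bounds applied after intersection
#'   (defaults 25 and unbounded; loading-mode analyses use
#'   `min_size = 5`).
#' @param weight running-sum weight exponent (default 1).
#' @param seed integer seed for the permutation stream.
#' @return data.frame: `set`, `size`, `es`, `nes`, `p_perm`, `q`,
#'   `leading_edge` (comma-joined feature IDs), sorted by `p_perm`
#'   then `-|nes|`.
#' @export
gsea_permutation_test <- function(ranked, sets, n_perm = 10000,
                                  min_size = 25, max_size = Inf,
                                  weight = 1, seed = NULL) {
  stopifnot(inherits(ranked, "RankedList"), inherits(sets, "GeneSetCollection"))
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  N <- length(ranked$feature_id)
  inter <- lapply(sets$sets, function(s) intersect(s, ranked$feature_id))
  sizes <- lengths(inter)
  keep <- sizes >= min_size & sizes <= max_size & sizes < N
  run_log("gsea_permutation_test", n_sets_in = length(sets$sets),
          n_sets_retained = sum(keep), min_size = min_size,
          n_perm = n_perm, weight = weight)
  if (!any(keep)) {
    return(data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p_perm = numeric(0), q = numeric(0),
                      leading_edge = character(0), stringsAsFactors = FALSE))
  }
  inter <- inter[keep]
  sizes <- sizes[keep]
  absw <- abs(ranked$stat)^weight
  obs <- lapply(inter, function(s) gsea_es(ranked, s, weight = weight))
  # observed ES through the same routine as the null draws, so that
  # "at least as extreme" comparisons are float-exact at the boundary
  es <- vapply(inter, function(s) {
    es_from_positions(absw, which(ranked$feature_id %in% s), N)
  }, numeric(1))

  local_seed(seed, {
    null_by_size <- lapply(unique(sizes), function(m) {
      vapply(seq_len(n_perm), function(b) {
        es_from_positions(absw, sample.int(N, m), N)
      }, numeric(1))
    })
    names(null_by_size) <- as.character(unique(sizes))
    p_perm <- numeric(length(es))
    nes <- numeric(length(es))
    for (i in seq_along(es)) {
      null_es <- null_by_size[[as.character(sizes[i])]]
      same <- if (es[i] >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
      # inclusive comparison with a float guard so a null draw identical
      # to the observed configuration always counts as "as extreme"
      p_perm[i] <- (1 + sum(abs(same) >= abs(es[i]) - 1e-12)) / (1 + length(same))
      denom <- mean(abs(same))
      nes[i] <- if (length(same) && is.finite(denom) && denom > 0) es[i] / denom else 0
    }
    out <- data.frame(
      set = names(inter), size = as.integer(sizes), es = es, nes = nes,
      p_perm = p_perm, q = bh_adjust(p_perm),
      leading_edge = vapply(obs, function(o) paste(o$leading_edge, collapse = ","),
                            character(1)),
      stringsAsFactors = FALSE
    )
    out <- out[order(out$p_perm, -abs(out$nes), out$set, method = "radix"), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Hypergeometric overrepresentation analysis
#'
#' Upper-tail hypergeometric test of a query set (e.g. the DEPs)
#' against each gene set, relative to a stated background (the features
#' that entered the differential test): `p = P(X >= k)` with `N`
#' background features, `K` set members in background, `n` query
#' features.
#'
#' @param query character vector of feature IDs; must be a subset of
#'   `background`.
#' @param background character vector of feature IDs.
#' @param sets a [gene_set_collection()].
#' @return data.frame: `set`, `overlap`, `set_size_bg`, `query_size`,
#'   `background_size`, `p_hyper`, `q` (BH), sorted by p.
#' @export
ora_hypergeometric <- function(query, background, sets) {
  stopifnot(inherits(sets, "GeneSetCollection"))
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  extra <- setdiff(query, background)
  if (length(extra)) {
    stop("query features outside background: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(sets$sets), function(nm) {
    K <- length(intersect(sets$sets[[nm]], background))
    k <- length(intersect(sets$sets[[nm]], query))
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size_bg = K, query_size = n,
               background_size = N, p_hyper = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p_hyper)
  out <- out[order(out$p_hyper, out$set, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Marker gene sets from per-group quantile cut-offs
#'
#' For each group (e.g. a neuronal subpopulation), features with a mean
#' statistic strictly above the group's `q`-quantile (empirical, linear
#' interpolation) form that group's marker set.
#'
#' @param expr_by_group named list: group -> named numeric vector of
#'   per-feature mean statistics.
#' @param q quantile cut-off (default 0.95).
#' @return A [gene_set_collection()] with one (possibly empty-pruned)
#'   set per group; groups whose set is empty are dropped with a log
#'   entry.
#' @export
quantile_marker_sets <- function(expr_by_group, q = 0.95) {
  stopifnot(is.list(expr_by_group), !is.null(names(expr_by_group)))
  sets <- list()
  for (g in names(expr_by_group)) {
    v <- expr_by_group[[g]]
    if (length(v) < 20) {
      run_log("quantile_marker_sets", group = g, n_features = length(v),
              note = "fewer than 20 features; quantile cut-off unstable")
    }
    thr <- stats::quantile(v, probs = q, type = 7, names = FALSE)
    members <- names(v)[v > thr]
    if (length(members)) {
      sets[[g]] <- members
    } else {
      run_log("quantile_marker_sets", group = g, note = "empty set dropped")
    }
  }
  gene_set_collection(sets)
}

#' Ranking by mean expression over selected samples
#'
#' Per-feature mean over observed entries of the selected samples
#' (e.g. all ganglia samples), passed through [rank_features()].
#' Intended for matrices already deduplicated and completeness-filtered.
#'
#' @param x an `ExpressionMatrix`.
#' @param samples character vector of sample IDs or logical/integer
#'   selector; `NULL` uses all samples.
#' @return A `RankedList`.
#' @export
mean_expression_ranking <- function(x, samples = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  cols <- if (is.null(samples)) {
    seq_along(x$sample_ids)
  } else if (is.character(samples)) {
    idx <- match(samples, x$sample_ids)
    if (anyNA(idx)) stop("unknown sample IDs in selection", call. = FALSE)
    idx
  } else {
    seq_along(x$sample_ids)[samples]
  }
  if (length(cols) == 0) stop("empty sample selection", call. = FALSE)
  mu <- masked_row_means(x, cols)
  if (anyNA(mu)) {
    stop("feature(s) with no observed value in the selection: ",
         paste(utils::head(names(mu)[is.na(mu)], 5), collapse = ", "), call. = FALSE)
  }
  rank_features(mu)
}
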