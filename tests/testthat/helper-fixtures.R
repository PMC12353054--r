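# shared fixture builders and small numeric helpers

make_em <- function(values, feature_ids = NULL, sample_ids = NULL,
                    scale = "log2") {
  if (is.null(feature_ids)) feature_ids <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_len(ncol(values)))
  expression_matrix(values, feature_ids = feature_ids, sample_ids = sample_ids,
                    scale = scale)
}

# centre features (rows) without unit-scaling, keeping the container
center_em <- function(m) {
  expression_matrix(t(scale(t(m$values), center = TRUE, scale = FALSE)),
                    feature_ids = m$feature_ids, sample_ids = m$sample_ids,
                    scale = m$scale)
}

relerr <- function(A, B) norm(A - B, "F") / norm(B, "F")

# brute-force BH step-up: q_i = min over {j: p_j >= p_i} of m * p_j / rank_j
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i) {
    min(1, min(m * p[p >= p[i]] / r[p >= p[i]]))
  }, numeric(1))
}
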