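# Generators producing every pipeline input with known ground truth.
# Default dimensions mirror the study conditions: two studies sharing
# latent factors, proteomics-like [402 features x 16 samples] and
# RNA-like [402 x 50].

# evaluate expr under a temporary RNG state seeded with `seed`;
# seed = NULL uses (and advances) the caller's RNG
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Simulate two (or more) studies sharing latent factors
#'
#' Draws from the multi-study factor model
#' `X_s = Phi f_s + Lambda_s l_s + e_s` with standard-normal factor
#' scores, study-specific factors, and heteroscedastic Gaussian noise
#' `e_s ~ N(0, Psi_s)`. A per-factor sex effect `delta_k` is added to
#' the shared factor scores of male samples, so sexual dimorphism lives
#' in the scores (the quantity the downstream ANOVA reads out), not in
#' the loadings. Loadings are drawn i.i.d. N(0,1) and then rotated to
#' the block-lower-triangular identifiability convention so that
#' recovery tests compare like with like.
#'
#' @param p number of features (default 402).
#' @param n_s integer vector of per-study sample counts (default
#'   `c(16, 50)`).
#' @param K number of shared factors (default 3).
#' @param J_s integer vector of per-study specific factor counts.
#' @param sex_effect numeric length-K vector: mean score shift added to
#'   males on each shared factor (in factor-score SD units).
#' @param noise_scale multiplier on the specific-variance scale;
#'   `Psi_s = noise_scale^2 * Unif(0.5, 1.5)` per feature.
#' @param planted_set_size size of the per-factor "truly loaded" gene
#'   sets recorded in the truth object (top |loading| features).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with `matrices` (list of complete `ExpressionMatrix`),
#'   `meta` (sample metadata with a `study` column), and `truth`
#'   (`phi_true`, `lambda_true`, `psi_true`, `scores_true`,
#'   `sex_assign`, `sex_effect`, `planted_sets`).
#' @export
gen_multistudy <- function(p = 402, n_s = c(16, 50), K = 3,
                           J_s = rep(1L, length(n_s)),
                           sex_effect = rep(0, K),
                           noise_scale = 1,
                           planted_set_size = 25,
                           seed = NULL) {
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (length(J_s) != length(n_s)) stop("J_s must match n_s in length", call. = FALSE)
  if (any(n_s < 2)) stop("each study needs >= 2 samples", call. = FALSE)
  if (p < K + max(J_s)) {
    stop(sprintf("p = %d too small for K = %d shared + max J_s = %d specific factors",
                 p, K, max(J_s)), call. = FALSE)
  }
  if (length(sex_effect) != K) stop("sex_effect must have length K", call. = FALSE)
  local_seed(seed, {
    feature_ids <- sprintf("G%04d", seq_len(p))
    phi <- impose_blt(matrix(stats::rnorm(p * K), p, K))
    S <- length(n_s)
    lambda <- vector("list", S)
    psi <- vector("list", S)
    scores <- vector("list", S)
    mats <- vector("list", S)
    meta_list <- vector("list", S)
    sex_assign <- character(0)
    for (s in seq_len(S)) {
      n <- n_s[s]
      J <- J_s[s]
      lambda[[s]] <- if (J > 0) {
        impose_blt(matrix(stats::rnorm(p * J), p, J))
      } else matrix(0, p, 0)
      psi[[s]] <- noise_scale^2 * stats::runif(p, 0.5, 1.5)
      sex <- rep(c("M", "F"), length.out = n)
      f <- matrix(stats::rnorm(K * n), K, n)
      f <- f + outer(sex_effect, as.numeric(sex == "M"))
      l <- matrix(stats::rnorm(J * n), J, n)
      e <- matrix(stats::rnorm(p * n, sd = sqrt(psi[[s]])), p, n)
      X <- phi %*% f + lambda[[s]] %*% l + e
      ids <- sprintf("study%d_S%02d", s, seq_len(n))
      mats[[s]] <- expression_matrix(X, feature_ids = feature_ids,
                                     sample_ids = ids, scale = "log2")
      scores[[s]] <- f
      m <- sample_meta(sample_id = ids, donor = ids, sex = sex,
                       tissue = if (s == 1) "ganglia" else "other",
                       replicate = 1L)
      m$study <- paste0("study", s)
      meta_list[[s]] <- m
      sa <- sex
      names(sa) <- ids
      sex_assign <- c(sex_assign, sa)
    }
    planted <- lapply(seq_len(K), function(k) {
      ord <- order(-abs(phi[, k]), feature_ids, method = "radix")
      feature_ids[ord[seq_len(min(planted_set_size, p))]]
    })
    names(planted) <- paste0("factor", seq_len(K))
    meta <- do.call(rbind, meta_list)
    truth <- list(phi_true = phi, lambda_true = lambda, psi_true = psi,
                  scores_true = scores, sex_assign = sex_assign,
                  sex_effect = sex_effect, planted_sets = planted)
    list(matrices = mats, meta = meta, truth = truth)
  })
}

#' Simulate a raw DIA-proteomics wide table
#'
#' Emulates the upstream search-engine export: compound gene-group IDs
#' for a stated fraction of features (a partner row sharing the first
#' term), technical replicate columns per (donor, tissue) sample with
#' within-sample correlated noise, and intensity-dependent dropout
#' (probability of missingness logistic in log2 abundance with slope
#' `mnar_strength`; strength 0 recovers missing-completely-at-random).
#' Values are emitted on linear scale, as intensities.
#'
#' @param p number of base features.
#' @param donors number of donors (sex alternates M/F across donors).
#' @param tissues tissue labels; each donor contributes one sample per
#'   tissue.
#' @param replicates_per_sample technical replicates per sample (>= 1).
#' @param missing_rate marginal missingness probability at average
#'   abundance, in [0, 1).
#' @param mnar_strength logistic slope of dropout vs. standardized log2
#'   abundance (0 = MCAR).
#' @param grouped_fraction fraction of features that get a compound
#'   partner row sharing their primary symbol.
#' @param seed integer seed.
#' @return list with `table` (wide data.frame, first column
#'   `gene_group`), `meta` (a [sample_meta()]), and `truth` (true log2
#'   sample-level abundances and the grouped-partner map).
#' @export
gen_proteomics_raw <- function(p = 200, donors = 8,
                               tissues = c("ganglia", "nerve_root"),
                               replicates_per_sample = 2,
                               missing_rate = 0.1, mnar_strength = 1,
                               grouped_fraction = 0.1, seed = NULL) {
  if (replicates_per_sample < 1) stop("replicates_per_sample must be >= 1", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)", call. = FALSE)
  local_seed(seed, {
    donor_ids <- sprintf("D%02d", seq_len(donors))
    donor_sex <- rep(c("M", "F"), length.out = donors)
    samp <- expand.grid(tissue = tissues, donor = donor_ids,
                        stringsAsFactors = FALSE)[, c("donor", "tissue")]
    n_samp <- nrow(samp)
    base_ids <- sprintf("P%04d", seq_len(p))
    mu <- stats::rnorm(p, mean = 20, sd = 3)          # log2 intensity scale
    donor_eff <- matrix(stats::rnorm(p * donors, sd = 0.2), p, donors,
                        dimnames = list(NULL, donor_ids))
    samp_eff <- matrix(stats::rnorm(p * n_samp, sd = 0.4), p, n_samp)
    true_log2 <- mu + donor_eff[, samp$donor] + samp_eff
    # compound partner rows: same first term, systematically lower abundance
    n_grouped <- round(grouped_fraction * p)
    grouped_idx <- if (n_grouped > 0) sort(sample.int(p, n_grouped)) else integer(0)
    partner_ids <- if (n_grouped > 0) {
      sprintf("%s, X%04d, X%04d", base_ids[grouped_idx], grouped_idx, grouped_idx + p)
    } else character(0)
    partner_log2 <- true_log2[grouped_idx, , drop = FALSE] - 1 +
      matrix(stats::rnorm(n_grouped * n_samp, sd = 0.3), n_grouped, n_samp)
    all_ids <- c(base_ids, partner_ids)
    all_log2 <- rbind(true_log2, partner_log2)
    # replicate columns with shared sample-level signal + replicate noise
    rep_cols <- list()
    meta_rows <- list()
    for (i in seq_len(n_samp)) {
      for (r in seq_len(replicates_per_sample)) {
        cn <- sprintf("%s_%s_r%d", samp$donor[i], samp$tissue[i], r)
        rep_cols[[cn]] <- all_log2[, i] + stats::rnorm(nrow(all_log2), sd = 0.15)
        meta_rows[[cn]] <- data.frame(sample_id = cn, donor = samp$donor[i],
                                      sex = donor_sex[match(samp$donor[i], donor_ids)],
                                      tissue = samp$tissue[i], replicate = r,
                                      stringsAsFactors = FALSE)
      }
    }
    obs <- do.call(cbind, rep_cols)
    z <- (obs - mean(mu)) / stats::sd(mu)
    p_miss <- stats::plogis(stats::qlogis(max(missing_rate, 1e-12)) - mnar_strength * z)
    if (missing_rate == 0) p_miss[] <- 0
    drop <- matrix(stats::runif(length(obs)) < p_miss, nrow(obs))
    linear <- 2^obs
    linear[drop] <- NA_real_
    tab <- data.frame(gene_group = all_ids, linear, check.names = FALSE,
                      stringsAsFactors = FALSE)
    mr <- do.call(rbind, meta_rows)
    meta <- sample_meta(mr$sample_id, mr$donor, mr$sex, mr$tissue, mr$replicate)
    truth <- list(true_log2 = true_log2, feature_ids = base_ids,
                  grouped_partners = stats::setNames(partner_ids, base_ids[grouped_idx]),
                  missing_rate = missing_rate, mnar_strength = mnar_strength)
    list(table = tab, meta = meta, truth = truth)
  })
}

#' Simulate a ranked list with planted enriched gene sets
#'
#' Null feature statistics are i.i.d. standard normal; members of the
#' planted set(s) are shifted by `planted_shift`. Decoy sets are drawn
#' uniformly at random.
#'
#' @param n_features number of features.
#' @param n_sets number of gene sets (the first `n_planted` are
#'   planted).
#' @param planted_set_size size of every set (>= 2, <= n_features).
#' @param planted_shift additive shift applied to planted-set member
#'   statistics (0 = all sets null).
#' @param n_planted number of planted sets.
#' @param seed integer seed.
#' @return list with `ranked` (a [rank_features()] result), `sets`
#'   (a [gene_set_collection()]), and `truth` (named logical: planted?).
#' @export
gen_ranked_with_sets <- function(n_features = 1000, n_sets = 10,
                                 planted_set_size = 25, planted_shift = 0,
                                 n_planted = 1, seed = NULL) {
  if (planted_set_size < 2) stop("planted_set_size must be >= 2", call. = FALSE)
  if (planted_set_size > n_features) {
    stop("planted_set_size exceeds n_features", call. = FALSE)
  }
  local_seed(seed, {
    ids <- sprintf("F%05d", seq_len(n_features))
    stats_v <- stats::setNames(stats::rnorm(n_features), ids)
    sets <- lapply(seq_len(n_sets), function(i) {
      ids[sample.int(n_features, planted_set_size)]
    })
    names(sets) <- sprintf("set%02d", seq_len(n_sets))
    planted <- stats::setNames(seq_len(n_sets) <= n_planted, names(sets))
    for (nm in names(sets)[planted]) {
      stats_v[sets[[nm]]] <- stats_v[sets[[nm]]] + planted_shift
    }
    list(ranked = rank_features(stats_v),
         sets = gene_set_collection(sets),
         truth = planted)
  })
}

#' Simulate a phospho-array ROI intensity grid
#'
#' One membrane per (sex, replicate) sample; every membrane carries a
#' PBS negative-control ROI plus one ROI per phosphorylation site.
#' A membrane-level random offset is shared by all ROIs on the same
#' membrane (so background subtraction must remove it). Phosphorylation
#' darkens a spot: site ROIs sit *below* the PBS background by the true
#' signal. `effect_sites` get an extra `effect_size` of signal in males
#' only, planting a Sex:Site interaction.
#'
#' @param sites character vector of site names (must not contain
#'   `"PBS"`).
#' @param n_per_group membranes (samples) per sex.
#' @param effect_sites subset of `sites` carrying the sex effect.
#' @param effect_size intensity shift added for males at
#'   `effect_sites`.
#' @param base_background mean PBS pixel intensity.
#' @param signal_range range of true per-site signals (uniform draw).
#' @param membrane_sd SD of the membrane-level offset.
#' @param pixel_sd SD of per-ROI measurement noise.
#' @param seed integer seed.
#' @return list with `table` (data.frame: `membrane_id`, `roi_id`,
#'   `sex`, `replicate`, `mean_pixel_intensity`) and `truth` (true
#'   signal per site and sex).
#' @export
gen_phospho_grid <- function(sites = sprintf("site%02d", 1:12),
                             n_per_group = 4,
                             effect_sites = character(0), effect_size = 0,
                             base_background = 200, signal_range = c(20, 60),
                             membrane_sd = 10, pixel_sd = 5, seed = NULL) {
  if ("PBS" %in% sites) stop("'PBS' is reserved for the control ROI", call. = FALSE)
  if (!all(effect_sites %in% sites)) stop("effect_sites must be a subset of sites", call. = FALSE)
  local_seed(seed, {
    site_signal <- stats::setNames(
      stats::runif(length(sites), signal_range[1], signal_range[2]), sites)
    rows <- list()
    truth_sig <- rbind(M = site_signal + effect_size * (sites %in% effect_sites),
                       F = site_signal)
    colnames(truth_sig) <- sites
    for (sex in c("M", "F")) {
      for (r in seq_len(n_per_group)) {
        mem <- sprintf("mem_%s%d", sex, r)
        offset <- stats::rnorm(1, sd = membrane_sd)
        pbs <- base_background + offset + stats::rnorm(1, sd = pixel_sd)
        rows[[length(rows) + 1]] <- data.frame(
          membrane_id = mem, roi_id = "PBS", sex = sex, replicate = r,
          mean_pixel_intensity = pbs, stringsAsFactors = FALSE)
        roi <- base_background + offset - truth_sig[sex, ] +
          stats::rnorm(length(sites), sd = pixel_sd)
        rows[[length(rows) + 1]] <- data.frame(
          membrane_id = mem, roi_id = sites, sex = sex, replicate = r,
          mean_pixel_intensity = unname(roi), stringsAsFactors = FALSE)
      }
    }
    list(table = do.call(rbind, rows), truth = list(signal = truth_sig))
  })
}
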