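#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Compares squared correlations to squared partial correlations over
#' all off-diagonal variable pairs: `KMO = sum(r^2) / (sum(r^2) +
#' sum(q^2))`, where partial correlations `q` are the negated, scaled
#' off-diagonal entries of the inverse correlation matrix. Variables
#' are the features (rows); observations the samples. When the
#' correlation matrix is singular (p >= n) the Moore-Penrose
#' pseudo-inverse is used, with a log warning.
#'
#' @param x an `ExpressionMatrix` (complete) or numeric matrix,
#'   features in rows.
#' @return list with `kmo` (overall index) and `msa` (per-feature
#'   measure of sampling adequacy).
#' @export
kmo <- function(x) {
  v <- if (inherits(x, "ExpressionMatrix")) {
    if (any(!x$mask)) stop("KMO requires a complete matrix", call. = FALSE)
    x$values
  } else x
  if (nrow(v) < 3) stop("need >= 3 features", call. = FALSE)
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature(s): ",
         paste(utils::head(rownames(v)[sds == 0], 5), collapse = ", "), call. = FALSE)
  }
  R <- stats::cor(t(v))
  Rinv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(Rinv) || nrow(v) >= ncol(v)) {
    Rinv <- MASS::ginv(R)
    run_log("kmo", note = "singular correlation matrix; pseudo-inverse used")
  }
  d <- sqrt(diag(Rinv))
  Q <- -Rinv / outer(d, d)
  diag(Q) <- 0
  diag(R) <- 0
  r2 <- R^2
  q2 <- Q^2
  overall <- sum(r2) / (sum(r2) + sum(q2))
  msa <- rowSums(r2) / (rowSums(r2) + rowSums(q2))
  names(msa) <- rownames(v)
  list(kmo = overall, msa = msa)
}

#' Within-study factor count by the Kaiser rule
#'
#' Automates the scree-plot choice: counts eigenvalues of the feature
#' correlation matrix exceeding 1. The full spectrum is returned for
#' plotting; a manual `override` short-circuits the rule (scree
#' judgement is ultimately the analyst's).
#'
#' @param x an `ExpressionMatrix` (complete).
#' @param override integer; if given, returned as `J` unchanged.
#' @return list with `J` and `eigenvalues`.
#' @export
choose_study_factors <- function(x, override = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (any(!x$mask)) stop("requires a complete matrix", call. = FALSE)
  R <- stats::cor(t(x$values))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  J <- if (!is.null(override)) as.integer(override) else sum(ev > 1)
  run_log("choose_study_factors", J = J, overridden = !is.null(override))
  list(J = J, eigenvalues = ev)
}

# internal constructor / validator for the fitted-model container
new_msfa_model <- function(phi, lambda, psi, feature_ids,
                           loglik_trace = numeric(0), converged = FALSE,
                           n_iter = 0L) {
  stopifnot(is.matrix(phi), is.list(lambda), is.list(psi))
  for (ps in psi) {
    if (any(ps <= 0)) stop("specific variances must be positive", call. = FALSE)
  }
  rownames(phi) <- feature_ids
  structure(
    list(phi = phi, lambda = lambda, psi = psi, feature_ids = feature_ids,
         loglik_trace = loglik_trace, converged = converged, n_iter = n_iter),
    class = "MsfaModel"
  )
}

#' @export
print.MsfaModel <- function(x, ...) {
  cat(sprintf("MsfaModel: p = %d, K = %d shared, J_s = (%s); %s after %d iterations\n",
              nrow(x$phi), ncol(x$phi),
              paste(vapply(x$lambda, ncol, integer(1)), collapse = ", "),
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

# marginal Gaussian log-likelihood of centred data under the model,
# via the Woodbury identity / determinant lemma (never forms p x p
# inverses)
msfa_loglik <- function(X_list, phi, lambda, psi) {
  ll <- 0
  p <- nrow(phi)
  for (s in seq_along(X_list)) {
    X <- X_list[[s]]
    n <- ncol(X)
    A <- cbind(phi, lambda[[s]])
    ps <- psi[[s]]
    AtPi <- t(A / ps)                       # q x p
    M <- diag(ncol(A)) + AtPi %*% A          # I + A' Psi^-1 A
    cM <- chol(M)
    logdet <- sum(log(ps)) + 2 * sum(log(diag(cM)))
    T_ <- AtPi %*% X                         # q x n
    tr1 <- sum(X^2 / ps) / n
    W <- backsolve(cM, forwardsolve(t(cM), T_))
    tr2 <- sum(W * T_) / n
    ll <- ll - n / 2 * (p * log(2 * pi) + logdet + tr1 - tr2)
  }
  ll
}

#' Starting values for the multi-study factor model
#'
#' Per-study principal-component factor solutions are stacked and the
#' shared loadings initialized from their left singular vectors; the
#' study-specific loadings come from the residual covariance, and the
#' specific variances from the residual diagonal. The
#' block-lower-triangular identifiability constraint (top K x K block
#' lower triangular with positive diagonal, and analogously per study)
#' is imposed on all loading blocks.
#'
#' @param matrices list of aligned, complete `ExpressionMatrix` objects
#'   (features in identical order), already centred (and optionally
#'   scaled) per study.
#' @param K number of shared factors (>= 1).
#' @param J_s integer vector of per-study specific factor counts.
#' @param seed accepted for interface uniformity; initialization is
#'   deterministic.
#' @return An `MsfaModel` holding the starting values.
#' @export
msfa_start <- function(matrices, K, J_s = rep(1L, length(matrices)), seed = NULL) {
  if (K < 1) stop("K must be >= 1: the shared factors are the object of study",
                  call. = FALSE)
  X_list <- lapply(matrices, function(m) {
    stopifnot(inherits(m, "ExpressionMatrix"))
    if (any(!m$mask)) stop("matrices must be complete (align first)", call. = FALSE)
    m$values
  })
  fids <- matrices[[1]]$feature_ids
  for (m in matrices) {
    if (!identical(m$feature_ids, fids)) {
      stop("feature order differs across studies; run align_studies()", call. = FALSE)
    }
  }
  p <- nrow(X_list[[1]])
  n_s <- vapply(X_list, ncol, integer(1))
  if (p < K + max(J_s)) stop("K + J_s exceeds the feature count", call. = FALSE)
  if (K + max(J_s) >= min(n_s)) {
    run_log("msfa_start", note = sprintf(
      "K + J_s (%d) not below the smallest study size (%d); estimates will be unstable",
      K + max(J_s), min(n_s)))
  }
  S_list <- lapply(X_list, function(X) tcrossprod(X) / ncol(X))
  pc_load <- mapply(function(S, J) {
    q <- K + J
    e <- eigen(S, symmetric = TRUE)
    v <- pmax(e$values[seq_len(q)], 0)
    e$vectors[, seq_len(q), drop = FALSE] %*% diag(sqrt(v), q)
  }, S_list, J_s, SIMPLIFY = FALSE)
  sv <- svd(do.call(cbind, pc_load), nu = K, nv = 0)
  phi <- sv$u %*% diag(sv$d[seq_len(K)] / sqrt(length(X_list)), K)
  phi <- impose_blt(phi)
  lambda <- vector("list", length(X_list))
  psi <- vector("list", length(X_list))
  for (s in seq_along(X_list)) {
    R <- S_list[[s]] - tcrossprod(phi)
    J <- J_s[s]
    if (J > 0) {
      e <- eigen(R, symmetric = TRUE)
      v <- pmax(e$values[seq_len(J)], 0)
      lambda[[s]] <- impose_blt(e$vectors[, seq_len(J), drop = FALSE] %*%
                                  diag(sqrt(v), J))
    } else {
      lambda[[s]] <- matrix(0, p, 0)
    }
    psi[[s]] <- pmax(diag(S_list[[s]]) - rowSums(phi^2) - rowSums(lambda[[s]]^2),
                     0.05)
  }
  new_msfa_model(phi, lambda, psi, fids)
}

#' ECM estimation of the multi-study factor model
#'
#' Maximizes the Gaussian marginal likelihood of
#' `Sigma_s = Phi Phi' + Lambda_s Lambda_s' + Psi_s` by
#' expectation/conditional-maximization: one E-step per iteration
#' (posterior moments of the shared and specific factors given the
#' data), then conditional maximization over `Phi` (rows solved jointly
#' across studies), each `Lambda_s`, and each `Psi_s`. The
#' log-likelihood is non-decreasing by construction and is recorded per
#' iteration. The identifiability constraint is re-imposed after
#' convergence (an orthogonal rotation: the likelihood and
#' `Phi Phi'` are unchanged).
#'
#' @param matrices list of aligned, complete, centred
#'   `ExpressionMatrix` objects.
#' @param init an `MsfaModel` of starting values (from
#'   [msfa_start()]).
#' @param max_iter iteration cap (default 10000).
#' @param tol relative log-likelihood change for convergence (default
#'   1e-6).
#' @return A converged (or capped) `MsfaModel`.
#' @export
msfa_ecm <- function(matrices, init, max_iter = 10000, tol = 1e-6) {
  stopifnot(inherits(init, "MsfaModel"))
  X_list <- lapply(matrices, function(m) m$values)
  p <- nrow(X_list[[1]])
  S <- length(X_list)
  n_s <- vapply(X_list, ncol, integer(1))
  K <- ncol(init$phi)
  J_s <- vapply(init$lambda, ncol, integer(1))
  phi <- init$phi
  lambda <- init$lambda
  psi <- init$psi
  Sxx_diag <- lapply(X_list, function(X) rowSums(X^2))
  psi_floor_hit <- FALSE
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    # E-step
    Szz <- vector("list", S)
    Cxz <- vector("list", S)
    for (s in seq_len(S)) {
      A <- cbind(phi, lambda[[s]])
      q <- ncol(A)
      AtPi <- t(A / psi[[s]])
      M <- diag(q) + AtPi %*% A
      B <- solve(M, AtPi)                 # q x p posterior weights
      V <- diag(q) - B %*% A              # posterior covariance
      Ez <- B %*% X_list[[s]]             # q x n
      Szz[[s]] <- n_s[s] * V + tcrossprod(Ez)
      Cxz[[s]] <- tcrossprod(X_list[[s]], Ez)   # p x q
    }
    idx_f <- seq_len(K)
    # CM 1: shared loadings, feature-wise across studies
    lhs <- array(0, dim = c(K, K, p))
    rhs <- matrix(0, p, K)
    for (s in seq_len(S)) {
      w <- 1 / psi[[s]]
      Sff <- Szz[[s]][idx_f, idx_f, drop = FALSE]
      resid <- Cxz[[s]][, idx_f, drop = FALSE]
      if (J_s[s] > 0) {
        idx_l <- K + seq_len(J_s[s])
        Slf <- Szz[[s]][idx_l, idx_f, drop = FALSE]
        resid <- resid - lambda[[s]] %*% Slf
      }
      rhs <- rhs + resid * w
      for (a in idx_f) for (b in idx_f) {
        lhs[a, b, ] <- lhs[a, b, ] + w * Sff[a, b]
      }
    }
    for (j in seq_len(p)) {
      phi[j, ] <- solve(lhs[, , j], rhs[j, ])
    }
    # CM 2: study-specific loadings
    for (s in seq_len(S)) {
      if (J_s[s] == 0) next
      idx_l <- K + seq_len(J_s[s])
      Sll <- Szz[[s]][idx_l, idx_l, drop = FALSE]
      Sfl <- Szz[[s]][idx_f, idx_l, drop = FALSE]
      lambda[[s]] <- t(solve(Sll, t(Cxz[[s]][, idx_l, drop = FALSE] - phi %*% Sfl)))
    }
    # CM 3: specific variances
    for (s in seq_len(S)) {
      A <- cbind(phi, lambda[[s]])
      new_psi <- (Sxx_diag[[s]] - 2 * rowSums(A * Cxz[[s]]) +
                    rowSums((A %*% Szz[[s]]) * A)) / n_s[s]
      if (any(new_psi < 1e-8)) psi_floor_hit <- TRUE
      psi[[s]] <- pmax(new_psi, 1e-8)
    }
    ll <- msfa_loglik(X_list, phi, lambda, psi)
    if (!is.finite(ll)) {
      stop("non-finite log-likelihood at iteration ", iter, call. = FALSE)
    }
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) / (abs(ll_old) + 1e-10) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (psi_floor_hit) {
    warning("specific-variance floor (1e-8) activated during ECM", call. = FALSE)
  }
  phi <- impose_blt(phi)
  lambda <- lapply(lambda, function(L) if (ncol(L) > 0) impose_blt(L) else L)
  run_log("msfa_ecm", n_iter = iter, converged = converged,
          loglik = trace[length(trace)])
  new_msfa_model(phi, lambda, psi, init$feature_ids,
                 loglik_trace = trace, converged = converged, n_iter = iter)
}

#' Bartlett (weighted least squares) factor scores
#'
#' Per-sample generalized-least-squares estimate of the shared factor
#' scores, `f_hat = (Phi' Psi_s^-1 Phi)^-1 Phi' Psi_s^-1 x_tilde`,
#' using the study's own specific variances. The data are centred (and
#' by default unit-variance scaled) per feature within the study before
#' projection; pass `center = FALSE, scale = FALSE` if the matrix is
#' already standardized.
#'
#' @param model an `MsfaModel`.
#' @param x an `ExpressionMatrix` (complete), features aligned to the
#'   model.
#' @param study index into `model$psi` for the study's specific
#'   variances.
#' @param meta optional [sample_meta()] supplying a `sex` column.
#' @param center,scale standardize features before projection
#'   (defaults `TRUE`).
#' @return Long-format data.frame (`FactorScoreTable`): `study`,
#'   `sample_id`, `factor`, `score`, and `sex` when metadata is given.
#' @export
bartlett_scores <- function(model, x, study = 1, meta = NULL,
                            center = TRUE, scale = TRUE) {
  stopifnot(inherits(model, "MsfaModel"), inherits(x, "ExpressionMatrix"))
  if (any(!x$mask)) stop("matrix must be complete", call. = FALSE)
  if (!identical(x$feature_ids, model$feature_ids)) {
    stop("features not aligned to the model", call. = FALSE)
  }
  v <- x$values
  if (center || scale) {
    v <- t(base::scale(t(v), center = center, scale = scale))
    if (any(!is.finite(v))) {
      stop("constant feature(s) cannot be unit-scaled", call. = FALSE)
    }
  }
  phi <- model$phi
  ps <- model$psi[[study]]
  PtPi <- t(phi / ps)                    # K x p
  G <- PtPi %*% phi                      # K x K
  if (!is.finite(rcond(G)) || rcond(G) < 1e-12) {
    stop("Phi' Psi^-1 Phi is (near-)singular; scores are not identified",
         call. = FALSE)
  }
  f_hat <- solve(G, PtPi %*% v)          # K x n
  K <- ncol(phi)
  out <- data.frame(
    study = rep(study, K * ncol(v)),
    sample_id = rep(x$sample_ids, each = K),
    factor = rep(paste0("factor", seq_len(K)), times = ncol(v)),
    score = as.vector(f_hat),
    stringsAsFactors = FALSE
  )
  if (!is.null(meta)) {
    out$sex <- as.character(meta$sex[match(out$sample_id, meta$sample_id)])
  }
  out
}

#' Align factor signs to the male direction
#'
#' Factor loading signs are arbitrary; for interpretability each shared
#' factor is flipped so its pooled scores correlate non-negatively with
#' the male indicator (zero or undefined correlation leaves the factor
#' untouched).
#'
#' @param model an `MsfaModel`.
#' @param scores a [bartlett_scores()] table (pooled across studies)
#'   with a `sex` column.
#' @return list with the sign-aligned `model` and `scores` and the
#'   logical `flipped` vector per factor.
#' @export
align_signs <- function(model, scores) {
  stopifnot(inherits(model, "MsfaModel"))
  if (is.null(scores$sex)) stop("scores need a sex column", call. = FALSE)
  male <- as.numeric(scores$sex == "M")
  K <- ncol(model$phi)
  flipped <- logical(K)
  for (k in seq_len(K)) {
    sel <- scores$factor == paste0("factor", k)
    r <- suppressWarnings(stats::cor(scores$score[sel], male[sel]))
    if (!is.na(r) && r < 0) {
      model$phi[, k] <- -model$phi[, k]
      scores$score[sel] <- -scores$score[sel]
      flipped[k] <- TRUE
    }
  }
  run_log("align_signs", flipped = flipped)
  list(model = model, scores = scores, flipped = flipped)
}

#' Factor-by-sex ANOVA with per-factor contrasts
#'
#' Two-way fixed-effects ANOVA of the pooled factor scores on
#' `sex * factor` (type-II sums of squares, so unbalanced pooling is
#' handled), followed by per-factor male-minus-female contrasts on the
#' cell-means model with single-step (max-t) multiplicity adjustment
#' across the K contrasts. Factors with adjusted p (`q`) below `q_max`
#' form the significant set.
#'
#' @param scores a [bartlett_scores()] table with `sex`.
#' @param q_max contrast significance threshold (default 0.1).
#' @return `FactorAnovaResult`: list with `interaction_p`, `anova`
#'   (type-II table), `contrasts` (factor, estimate male-female, q),
#'   `significant_factors`.
#' @export
factor_sex_anova <- function(scores, q_max = 0.1) {
  need <- c("sample_id", "factor", "score", "sex")
  if (!all(need %in% names(scores))) {
    stop("scores must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  scores$sex <- factor(scores$sex, levels = c("M", "F"))
  if (any(table(scores$sex) == 0)) stop("both sexes must be present", call. = FALSE)
  k_levels <- unique(scores$factor)
  scores$factor <- factor(scores$factor, levels = k_levels)
  if (length(k_levels) > 1) {
    fit <- stats::lm(score ~ sex * factor, data = scores)
    a2 <- car::Anova(fit, type = 2)
    interaction_p <- a2["sex:factor", "Pr(>F)"]
  } else {
    # a single factor leaves no factor main effect or interaction
    fit <- stats::lm(score ~ sex, data = scores)
    a2 <- car::Anova(fit, type = 2)
    interaction_p <- NA_real_
  }
  # cell-means model for the Male.Fk - Female.Fk contrasts
  scores$cell <- factor(paste(scores$sex, scores$factor, sep = "."))
  cm <- stats::lm(score ~ 0 + cell, data = scores)
  cn <- levels(scores$cell)
  Kmat <- t(vapply(k_levels, function(k) {
    row <- numeric(length(cn))
    row[cn == paste0("M.", k)] <- 1
    row[cn == paste0("F.", k)] <- -1
    row
  }, numeric(length(cn))))
  rownames(Kmat) <- paste0("M.", k_levels, " - F.", k_levels)
  colnames(Kmat) <- paste0("cell", cn)
  gl <- multcomp::glht(cm, linfct = Kmat)
  sm <- summary(gl)   # single-step max-t adjustment
  contrasts <- data.frame(
    factor = as.character(k_levels),
    estimate = as.vector(sm$test$coefficients),
    q = as.vector(sm$test$pvalues),
    stringsAsFactors = FALSE
  )
  sig <- contrasts$factor[contrasts$q < q_max]
  run_log("factor_sex_anova", interaction_p = interaction_p,
          significant_factors = sig)
  structure(
    list(interaction_p = interaction_p, anova = a2, contrasts = contrasts,
         significant_factors = sig),
    class = "FactorAnovaResult"
  )
}

#' @export
print.FactorAnovaResult <- function(x, ...) {
  cat(sprintf("Factor x Sex ANOVA: interaction p = %.3g\n", x$interaction_p))
  print(x$contrasts)
  cat("significant (q < threshold):",
      if (length(x$significant_factors)) paste(x$significant_factors, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Ranked shared loadings of one factor
#'
#' Extracts the shared loadings (phi) of a chosen factor as a ranked
#' list for loading-mode GSEA (typically with `min_size = 5` when the
#' aligned feature universe is small, e.g. 402 genes).
#'
#' @param model an `MsfaModel`.
#' @param factor factor index (1..K).
#' @return A `RankedList` over all model features.
#' @export
shared_loading_ranking <- function(model, factor = 1) {
  stopifnot(inherits(model, "MsfaModel"))
  K <- ncol(model$phi)
  if (factor < 1 || factor > K) {
    stop("factor index out of range 1..", K, call. = FALSE)
  }
  rank_features(stats::setNames(model$phi[, factor], model$feature_ids))
}

#' Full multi-study factor pipeline
#'
#' Gates each study on sampling adequacy (KMO >= `kmo_min`), centres
#' and (optionally) unit-scales features per study, fits the shared +
#' specific factor model by ECM, computes pooled Bartlett scores,
#' aligns factor signs to the male direction, and runs the
#' factor-by-sex ANOVA.
#'
#' @param matrices list of aligned complete `ExpressionMatrix` objects.
#' @param meta combined [sample_meta()] covering all samples.
#' @param K shared factors (default 3).
#' @param J_s per-study specific factor counts (default 1 each).
#' @param kmo_min sampling-adequacy gate (default 0.5); set
#'   `enforce_kmo = FALSE` to log instead of refuse.
#' @param scale unit-variance scaling per feature within study
#'   (default TRUE).
#' @param q_max contrast threshold (default 0.1).
#' @param max_iter,tol ECM controls.
#' @param enforce_kmo refuse studies below the gate (default TRUE).
#' @param seed passed to [msfa_start()].
#' @return list with `model`, `scores`, `anova`, `kmo`, `flipped`.
#' @export
msfa_fit <- function(matrices, meta, K = 3, J_s = rep(1L, length(matrices)),
                     kmo_min = 0.5, scale = TRUE, q_max = 0.1,
                     max_iter = 10000, tol = 1e-6, enforce_kmo = TRUE,
                     seed = NULL) {
  kmo_s <- vapply(matrices, function(m) kmo(m)$kmo, numeric(1))
  low <- which(kmo_s < kmo_min)
  if (length(low)) {
    msg <- sprintf("study %s below the KMO sampling-adequacy gate (%.3f < %.2f)",
                   paste(low, collapse = ", "), min(kmo_s[low]), kmo_min)
    if (enforce_kmo) stop(msg, call. = FALSE)
    run_log("msfa_fit", note = msg)
  }
  std <- lapply(matrices, function(m) {
    v <- t(base::scale(t(m$values), center = TRUE, scale = scale))
    expression_matrix(v, feature_ids = m$feature_ids, sample_ids = m$sample_ids,
                      scale = m$scale)
  })
  init <- msfa_start(std, K = K, J_s = J_s, seed = seed)
  model <- msfa_ecm(std, init, max_iter = max_iter, tol = tol)
  scores <- do.call(rbind, lapply(seq_along(std), function(s) {
    bartlett_scores(model, std[[s]], study = s, meta = meta,
                    center = FALSE, scale = FALSE)
  }))
  al <- align_signs(model, scores)
  anova <- factor_sex_anova(al$scores, q_max = q_max)
  list(model = al$model, scores = al$scores, anova = anova,
       kmo = kmo_s, flipped = al$flipped)
}
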