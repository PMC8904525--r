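# Penalized logistic regression family: the plr thresholding operator
# (soft / firm / hard / elastic-net in one display), coordinate-descent
# fitting on sd-standardized dosages, two-stage sliding-window selection,
# and the cross-validated (lambda, kappa) grid.

#' Penalty specification for the plr family
#'
#' `lam` is the threshold on the standardized (per-SE, i.e. z-score)
#' effect scale; `kap` selects the family member: `0` = lasso (soft
#' threshold), `0 < kap < 1` = MCP (firm threshold), `1` = hard threshold
#' (subset/p-value selection), `kap < 0` = elastic net with ridge weight
#' `-kap`.
#'
#' @param lam Positive tuning parameter.
#' @param kap Threshold-shape parameter in `[-3, 1]`.
#' @return A `penalty_spec` list.
#' @export
penalty_spec <- function(lam, kap) {
  stopifnot(lam > 0, kap <= 1)
  structure(list(lam = lam, kap = kap), class = "penalty_spec")
}

#' The plr thresholding operator
#'
#' Odd, piecewise-linear operator applied to a standardized effect `x`:
#' zero below `lam`; identity when `kap > 0` and `|x| >= lam/kap`;
#' otherwise `(x - lam * sign(x)) / (1 - kap)`.  `kap = 1` is the hard
#' threshold limit (0 below `lam`, else `x`).
#'
#' @param x Numeric vector of standardized effects.
#' @param spec A [penalty_spec()].
#' @return Thresholded values, same length as `x`.
#' @export
plr_threshold <- function(x, spec) {
  plr_threshold_cpp(as.numeric(x), spec$lam, spec$kap)
}

#' Sliding-window configuration for stage-1 selection
#'
#' @param block_span Window span in base pairs (default 5.5 Mb).
#' @param overlap Overlap between consecutive windows (default 500 kb).
#' @return A `window_config` list.
#' @export
window_config <- function(block_span = 5.5e6, overlap = 5e5) {
  stopifnot(overlap > 0, overlap < block_span)
  structure(list(block_span = block_span, overlap = overlap),
            class = "window_config")
}

#' Two-stage (lambda, kappa) grid configuration
#'
#' Defaults: stage 1 fits at `lam = 3.0` with
#' `kap in {0, 0.2, 0.4, 0.6, 0.8, 1.0}`; stage 2 sweeps `lam` from 3.0
#' to 5.5 in steps of 0.1 crossed with `kap` from -3.0 to 1.0 in steps of
#' 0.1; five stratified cross-validation folds.
#'
#' @param stage1_lam,stage1_kap Stage-1 grid vectors.
#' @param stage2_lam,stage2_kap Stage-2 grid vectors.
#' @param folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed controlling the fold split.
#' @return A `grid_config` list.
#' @export
grid_config <- function(stage1_lam = 3.0,
                        stage1_kap = seq(0, 1, by = 0.2),
                        stage2_lam = seq(3.0, 5.5, by = 0.1),
                        stage2_kap = seq(-3.0, 1.0, by = 0.1),
                        folds = 5L, seed = 1L) {
  stopifnot(length(stage1_lam) > 0, length(stage2_lam) > 0, folds >= 2)
  structure(list(stage1_lam = stage1_lam, stage1_kap = stage1_kap,
                 stage2_lam = stage2_lam, stage2_kap = stage2_kap,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "grid_config")
}

# Standardized design: NA imputed to 2*freq, columns centered and scaled
# by the population sd (denominator n).  Zero-variance columns flagged.
standardize_dosages <- function(panel) {
  X <- panel$dosages
  n <- nrow(X)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- 2 * panel$freq[j]
  }
  mu <- colMeans(X)
  sdn <- sqrt(colMeans(X^2) - mu^2)
  ok <- sdn > 0
  Xs <- sweep(X, 2, mu, "-")
  Xs[, ok] <- sweep(Xs[, ok, drop = FALSE], 2, sdn[ok], "/")
  Xs[, !ok] <- 0
  list(Xs = Xs, mu = mu, sdn = sdn, ok = ok)
}

#' Fit one penalized logistic regression model
#'
#' Cyclic coordinate descent on a quadratic majorization of the logistic
#' log-likelihood (curvature bound 1/4).  Dosages are standardized to
#' unit variance before fitting, so `lam` acts on the per-SE scale and
#' rarer variants are penalized more heavily on the raw-dosage scale.
#' The intercept is unpenalized; the returned `beta` is on the raw-dosage
#' scale.
#'
#' @param panel A `dosage_panel`.
#' @param phenotype Binary 0/1 vector.
#' @param spec A [penalty_spec()].
#' @param warm Optional previous `fit_state` used as a warm start.
#' @param tol Convergence tolerance on the maximum standardized
#'   coefficient change per sweep.
#' @param max_iter Maximum number of coordinate sweeps.
#' @return A `fit_state` list: `beta` (raw scale), `beta_std`,
#'   `intercept`, `active_set`, `converged`, `n_iter`, `spec`.
#' @export
fit_penalized_logistic <- function(panel, phenotype, spec, warm = NULL,
                                   tol = 1e-7, max_iter = 1000L) {
  y <- as.numeric(phenotype)
  stopifnot(length(y) == nrow(panel$dosages))
  if (length(unique(y)) < 2) stop("phenotype must contain both classes")
  sdz <- standardize_dosages(panel)
  m <- ncol(sdz$Xs)
  beta0 <- if (!is.null(warm)) warm$beta_std else rep(0, m)
  int0 <- if (!is.null(warm)) warm$intercept_std else qlogis(mean(y))
  fit <- cd_fit_cpp(sdz$Xs, y, spec$lam, spec$kap, beta0, int0,
                    tol, as.integer(max_iter))
  beta_std <- fit$beta
  beta_std[!sdz$ok] <- 0
  beta_raw <- ifelse(sdz$ok, beta_std / sdz$sdn, 0)
  intercept_raw <- fit$intercept - sum(beta_raw * sdz$mu)
  structure(list(beta = beta_raw, beta_std = beta_std,
                 intercept = intercept_raw, intercept_std = fit$intercept,
                 active_set = which(beta_std != 0),
                 converged = fit$converged, n_iter = fit$n_iter,
                 spec = spec), class = "fit_state")
}

# Window tiling: starts step by (span - overlap) from the first variant
# position; a chromosome shorter than one window gets a single window.
tile_windows <- function(pos, span, overlap) {
  lo <- min(pos); hi <- max(pos)
  step <- span - overlap
  starts <- seq(lo, by = step, length.out = max(1, ceiling(
    max(0, hi - lo - span) / step) + 1))
  # ensure coverage of the tail
  while (starts[length(starts)] + span <= hi)
    starts <- c(starts, starts[length(starts)] + step)
  lapply(starts, function(s) c(s, s + span))
}

#' Stage-1 sliding-window variant selection
#'
#' Windows tile each chromosome (span / overlap from `wcfg`) starting at
#' the chromosome's first variant position.  Within each window, after
#' the chi-square prefilter, a penalized model is fit for every stage-1
#' `(lam, kap)` combination; the output is the deduplicated union of
#' variants with a nonzero coefficient in any window at any grid point.
#'
#' @param panel A `dosage_panel`.
#' @param phenotype Binary 0/1 vector.
#' @param wcfg A [window_config()].
#' @param gcfg A [grid_config()].
#' @param ss Optional precomputed `summary_set` from
#'   [single_variant_assoc()] (computed if `NULL`).
#' @param chi2_min Prefilter threshold.
#' @return Sorted integer vector of selected panel column indices.
#' @export
stage1_window_select <- function(panel, phenotype, wcfg = window_config(),
                                 gcfg = grid_config(), ss = NULL,
                                 chi2_min = 2.25) {
  if (is.null(ss)) ss <- single_variant_assoc(panel, phenotype)
  keep <- which(ss$z^2 >= chi2_min & ss$flag %in% c("", "separated_firth"))
  if (length(keep) == 0) return(integer(0))
  selected <- integer(0)
  v <- panel$variants
  for (chr in unique(v$chrom[keep])) {
    on_chr <- keep[v$chrom[keep] == chr]
    wins <- tile_windows(v$pos[on_chr], wcfg$block_span, wcfg$overlap)
    for (w in wins) {
      jj <- on_chr[v$pos[on_chr] >= w[1] & v$pos[on_chr] < w[2]]
      if (length(jj) == 0) next
      sub <- subset_panel(panel, variants = jj)
      for (lam in gcfg$stage1_lam) {
        warm <- NULL
        for (kap in sort(gcfg$stage1_kap)) {
          fit <- fit_penalized_logistic(sub, phenotype,
                                        penalty_spec(lam, kap),
                                        warm = warm)
          if (kap < 1) warm <- fit
          selected <- c(selected, jj[fit$active_set])
        }
      }
    }
  }
  sort(unique(selected))
}

#' Stage-2 regularization-path fits over the (lambda, kappa) grid
#'
#' For each `lam`, the lasso member (`kap = 0`) is fit first (cold, or
#' warm from the previous `lam`); from that fit the `kap` value is moved
#' stepwise outward toward +1 and toward -3, each fit warm-started from
#' its neighbor.
#'
#' @param panel A `dosage_panel` already restricted to the stage-1 set.
#' @param phenotype Binary 0/1 vector.
#' @param gcfg A [grid_config()].
#' @return A list with `fits` (list indexed `[[lam]][[kap]]` as character
#'   keys), and the grid vectors `lam`, `kap`.
#' @export
stage2_path_fit <- function(panel, phenotype, gcfg = grid_config()) {
  lams <- gcfg$stage2_lam
  kaps <- sort(gcfg$stage2_kap)
  kkey <- function(x) sprintf("%.6g", x)
  kap_up <- kaps[kaps > 0]                    # toward +1
  kap_dn <- rev(kaps[kaps < 0])               # toward -3
  has0 <- any(abs(kaps) < 1e-12)
  fits <- list()
  prev_lasso <- NULL
  for (lam in lams) {
    lk <- kkey(lam)
    fits[[lk]] <- list()
    f0 <- fit_penalized_logistic(panel, phenotype, penalty_spec(lam, 0),
                                 warm = prev_lasso)
    prev_lasso <- f0
    if (has0) fits[[lk]][[kkey(0)]] <- f0
    warm <- f0
    for (kap in kap_up) {
      warm <- fit_penalized_logistic(panel, phenotype,
                                     penalty_spec(lam, kap), warm = warm)
      fits[[lk]][[kkey(kap)]] <- warm
    }
    warm <- f0
    for (kap in kap_dn) {
      warm <- fit_penalized_logistic(panel, phenotype,
                                     penalty_spec(lam, kap), warm = warm)
      fits[[lk]][[kkey(kap)]] <- warm
    }
  }
  list(fits = fits, lam = lams, kap = kaps)
}

fit_to_weight_set <- function(fit, panel, metadata = list()) {
  act <- fit$active_set
  weight_set(panel$variants[act, , drop = FALSE], fit$beta[act],
             metadata = c(metadata,
                          list(lam = fit$spec$lam, kap = fit$spec$kap,
                               intercept = fit$intercept,
                               scale = "raw-dosage")))
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

penalty_family <- function(kap) {
  ifelse(abs(kap) < 1e-12, "lasso",
         ifelse(kap < 0, "enet",
                ifelse(kap >= 1, "hard", "mcp")))
}

#' Cross-validated grid search over the penalized family
#'
#' Stratified `folds`-fold split; per fold, stage-1 selection and the
#' stage-2 path are run on the training part and each grid point's model
#' is scored on the held-out part by AUC.  Best specs are reported per
#' family (lasso `kap = 0`; MCP `0 < kap < 1`; elastic net `kap < 0`;
#' hard `kap = 1`) and globally, breaking mean-AUC ties by sparsity then
#' by smaller `lam`; the final model is refit on all data at the global
#' best spec.
#'
#' @param panel A `dosage_panel`.
#' @param phenotype Binary 0/1 vector.
#' @param wcfg A [window_config()].
#' @param gcfg A [grid_config()].
#' @param chi2_min Prefilter threshold used in stage 1.
#' @return A list: `auc_grid` (lam x kap matrix of mean CV AUCs),
#'   `size_grid` (mean active-set sizes), `best` (global
#'   [penalty_spec()]), `best_by_family`, `weights` (final `weight_set`),
#'   `final_fit`, `folds` (fold assignment).
#' @export
cross_validate_grid <- function(panel, phenotype, wcfg = window_config(),
                                gcfg = grid_config(), chi2_min = 2.25) {
  y <- as.numeric(phenotype)
  fold <- stratified_folds(y, gcfg$folds, gcfg$seed)
  if (any(tapply(y, fold, function(v) length(unique(v))) < 2))
    stop("a fold contains a single class; increase n or reduce folds")
  lams <- gcfg$stage2_lam; kaps <- sort(gcfg$stage2_kap)
  kkey <- function(x) sprintf("%.6g", x)
  aucsum <- sizesum <- matrix(0, length(lams), length(kaps),
                              dimnames = list(kkey(lams), kkey(kaps)))
  for (f in seq_len(gcfg$folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    ptr <- subset_panel(panel, samples = tr)
    s1 <- stage1_window_select(ptr, y[tr], wcfg, gcfg, chi2_min = chi2_min)
    if (length(s1) == 0) { aucsum <- aucsum + 0.5; next }
    ptr1 <- subset_panel(ptr, variants = s1)
    pte1 <- subset_panel(panel, samples = te)$dosages[, s1, drop = FALSE]
    for (j in seq_len(ncol(pte1))) {
      nas <- is.na(pte1[, j])
      if (any(nas)) pte1[nas, j] <- 2 * panel$freq[s1[j]]
    }
    path <- stage2_path_fit(ptr1, y[tr], gcfg)
    for (li in seq_along(lams)) for (ki in seq_along(kaps)) {
      fit <- path$fits[[kkey(lams[li])]][[kkey(kaps[ki])]]
      sc <- drop(pte1 %*% fit$beta)
      a <- if (length(fit$active_set) == 0 || stats::sd(sc) == 0) 0.5 else
        auc_value(sc, y[te])
      aucsum[li, ki] <- aucsum[li, ki] + a
      sizesum[li, ki] <- sizesum[li, ki] + length(fit$active_set)
    }
  }
  auc_grid <- aucsum / gcfg$folds
  size_grid <- sizesum / gcfg$folds
  pick <- function(mask) {
    cand <- which(mask, arr.ind = TRUE)
    if (nrow(cand) == 0) return(NULL)
    a <- auc_grid[cand]
    best <- cand[a == max(a), , drop = FALSE]
    if (nrow(best) > 1) {                     # sparsest, then smallest lam
      sz <- size_grid[best]
      best <- best[sz == min(sz), , drop = FALSE]
      best <- best[order(lams[best[, 1]]), , drop = FALSE]
    }
    penalty_spec(lams[best[1, 1]], kaps[best[1, 2]])
  }
  fam <- matrix(penalty_family(rep(kaps, each = length(lams))),
                length(lams), length(kaps))
  best_by_family <- list(lasso = pick(fam == "lasso"),
                         mcp = pick(fam == "mcp"),
                         enet = pick(fam == "enet"),
                         hard = pick(fam == "hard"))
  best <- pick(matrix(TRUE, length(lams), length(kaps)))
  s1_all <- stage1_window_select(panel, y, wcfg, gcfg, chi2_min = chi2_min)
  final_fit <- NULL
  weights <- NULL
  if (length(s1_all) > 0) {
    pall <- subset_panel(panel, variants = s1_all)
    final_fit <- fit_penalized_logistic(pall, y, best)
    weights <- fit_to_weight_set(final_fit, pall,
                                 metadata = list(method = "penalized"))
  }
  list(auc_grid = auc_grid, size_grid = size_grid, best = best,
       best_by_family = best_by_family, weights = weights,
       final_fit = final_fit, folds = fold)
}
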