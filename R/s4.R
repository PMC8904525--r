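# "Select and shrink" from summary statistics: a continuous-shrinkage
# (global-local, gamma-gamma) Gibbs sampler over LD blocks that turns a
# marginal summary set into a sparse weight set.  Effects are sampled on
# the sd-standardized scale and de-standardized on output, so rarer
# variants are penalized more heavily on the raw-dosage scale.

#' S4 sampler parameters
#'
#' @param a Local shrinkage shape near zero (> 0).  Smaller `a` shrinks
#'   small effects harder.
#' @param b Tail shrinkage shape (> 0), controlling shrinkage of larger
#'   effects.
#' @param phi Global shrinkage scale (> 0).
#' @param n_iter Total Gibbs iterations (default 5000).
#' @param burnin Burn-in iterations discarded (default 1000).
#' @param thin Keep every `thin`-th post-burn-in draw (default 5).
#' @param seed Integer RNG seed.
#' @param sparsify_tol Variants whose posterior-mean standardized effect
#'   is below this magnitude are dropped from the output (the "select"
#'   step); default 1e-5.
#' @return An `s4_params` list.
#' @export
s4_params <- function(a = 2.75, b = 2, phi = 3e-6, n_iter = 5000L,
                      burnin = 1000L, thin = 5L, seed = 1L,
                      sparsify_tol = 1e-5) {
  stopifnot(a > 0, b > 0, phi > 0, n_iter > burnin, burnin >= 0,
            thin >= 1, sparsify_tol >= 0)
  structure(list(a = a, b = b, phi = phi, n_iter = as.integer(n_iter),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed), sparsify_tol = sparsify_tol),
            class = "s4_params")
}

#' Build a block LD reference from a genotype panel
#'
#' Positions are binned into non-overlapping blocks of `block_span` base
#' pairs per chromosome (anchored at the chromosome's first variant);
#' block correlation matrices are estimated from standardized dosages
#' with a ridge jitter of 1e-6 on the diagonal.
#'
#' @param panel A `dosage_panel` (the reference panel).
#' @param block_span Block span in base pairs (default 1 Mb).
#' @return An `ld_reference`: list of `blocks` (each with `idx` into the
#'   panel's variants, `keys`, correlation matrix `R`), `variants`,
#'   `sd` per variant, and `n_ref`.
#' @export
build_ld_reference <- function(panel, block_span = 1e6) {
  v <- panel$variants
  sdz <- standardize_dosages(panel)
  blocks <- list()
  for (chr in unique(v$chrom)) {
    on_chr <- which(v$chrom == chr)
    o <- on_chr[order(v$pos[on_chr])]
    bin <- floor((v$pos[o] - min(v$pos[o])) / block_span)
    for (bb in unique(bin)) {
      idx <- o[bin == bb]
      if (length(idx) == 1) {
        R <- matrix(1, 1, 1)
      } else {
        R <- cor(sdz$Xs[, idx, drop = FALSE])
        R[!is.finite(R)] <- 0
        diag(R) <- 1 + 1e-6
      }
      blocks[[length(blocks) + 1]] <-
        list(idx = idx,
             keys = paste(v$chrom[idx], v$pos[idx], sep = ":"), R = R)
    }
  }
  structure(list(blocks = blocks, variants = v, sd = panel$sd,
                 n_ref = nrow(panel$dosages)),
            class = "ld_reference")
}

# Conditional posterior mean of the standardized effects in one block
# given fixed local scales psi: solves (R + Diag(1/(phi psi))) mu = bhat.
# Exposed internally so the single-site conjugate closed form can be
# checked independently of the sampler.
s4_conditional_mean <- function(R, bhat_std, psi, phi) {
  M <- R + diag(1 / (phi * psi), nrow = length(psi))
  solve(M, bhat_std)
}

#' Select-and-shrink Gibbs sampler on summary statistics
#'
#' Runs, per LD block, the Gibbs updates of a continuous-shrinkage
#' (gamma-gamma global-local) prior on standardized effect sizes:
#' beta given psi and sigma^2 is multivariate normal with precision
#' `(N / sigma^2) (R + Diag(1 / (phi psi_j)))` and mean solving
#' `(R + Diag(1 / (phi psi_j))) beta = bhat_std`; `psi_j` is generalized
#' inverse Gaussian `GIG(a - 1/2, 2 delta_j, N beta_j^2 / sigma^2)`;
#' `delta_j ~ Gamma(a + b, rate = psi_j + phi)`; `sigma^2` follows its
#' inverse-gamma conditional.  `bhat_std = beta_marginal * sd_j` is the
#' marginal effect on the standardized scale (the standard-deviation
#' correction).  The output weight is the posterior mean standardized
#' effect divided by `sd_j`; variants whose posterior-mean standardized
#' effect is smaller in magnitude than `sparsify_tol` are dropped.
#'
#' @param ss A `summary_set`, harmonized to the LD reference.
#' @param ld An `ld_reference` from [build_ld_reference()].
#' @param params An [s4_params()].
#' @param prefilter Apply the chi-square >= 2.25 prefilter before
#'   sampling (default `TRUE`)?
#' @param chi2_min Prefilter threshold.
#' @return A `weight_set`; attribute `posterior` carries the per-variant
#'   posterior summaries (mean, MC standard error, standardized scale).
#' @export
s4_gibbs <- function(ss, ld, params = s4_params(), prefilter = TRUE,
                     chi2_min = 2.25) {
  stopifnot(inherits(ld, "ld_reference"))
  if (prefilter) ss <- chi2_prefilter(ss, assoc_config(chi2_min))
  if (nrow(ss) == 0) stop("no variants left after prefilter")
  sskey <- paste(ss$chrom, ss$pos, sep = ":")
  ldkey <- paste(ld$variants$chrom, ld$variants$pos, sep = ":")
  pos_in_ld <- match(sskey, ldkey)
  if (anyNA(pos_in_ld))
    stop("summary set contains variants absent from the LD reference")
  m <- nrow(ss)
  sdj <- ld$sd[pos_in_ld]
  if (any(sdj <= 0)) stop("zero-variance variants in the LD reference")
  N <- stats::median(ss$n)
  bhat <- ss$beta * sdj                       # standardized marginal effect
  # restrict blocks to sampled variants
  blocks <- list()
  for (bl in ld$blocks) {
    sel <- match(bl$keys, sskey)
    here <- which(!is.na(sel))
    if (length(here) == 0) next
    blocks[[length(blocks) + 1]] <-
      list(j = sel[here], R = bl$R[here, here, drop = FALSE])
  }
  for (bl in blocks) {
    ev <- eigen(bl$R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop(sprintf("non-PSD LD block (min eigenvalue %.3g)", min(ev)))
  }
  set.seed(params$seed)
  beta <- rep(0, m); psi <- rep(1, m); delta <- rep(params$b, m)
  sigma2 <- 1
  keep_iters <- seq(params$burnin + params$thin, params$n_iter,
                    by = params$thin)
  bsum <- rep(0, m); bsq <- rep(0, m); nkeep <- 0L
  for (it in seq_len(params$n_iter)) {
    quad <- 0
    for (bl in blocks) {
      j <- bl$j
      M <- bl$R + diag(1 / (params$phi * psi[j]), nrow = length(j))
      U <- chol(M)
      mu <- backsolve(U, forwardsolve(t(U), bhat[j]))
      z <- rnorm(length(j))
      beta[j] <- mu + sqrt(sigma2 / N) * backsolve(U, z)
      quad <- quad + sum(beta[j] * (M %*% beta[j]))
    }
    psi <- rgig_cpp(params$a - 0.5, 2 * delta, N * beta^2 / sigma2)
    psi <- pmax(psi, 1e-12)
    delta <- rgamma(m, shape = params$a + params$b, rate = psi + params$phi)
    delta <- pmax(delta, 1e-12)
    rate <- (N / 2) * max(1 - 2 * sum(beta * bhat) + quad, 1e-8)
    sigma2 <- 1 / rgamma(1, shape = (N + m) / 2, rate = rate)
    stopifnot(all(psi > 0), all(delta > 0), sigma2 > 0)
    if (it %in% keep_iters) {
      bsum <- bsum + beta; bsq <- bsq + beta^2; nkeep <- nkeep + 1L
    }
  }
  pm <- bsum / nkeep
  pvar <- pmax(bsq / nkeep - pm^2, 0)
  mcse <- sqrt(pvar / nkeep)                  # ignores autocorrelation
  keep <- abs(pm) >= params$sparsify_tol
  vk <- ss[keep, c("chrom", "pos", "allele_effect", "allele_other", "id"),
           drop = FALSE]
  ws <- weight_set(vk, pm[keep] / sdj[keep],
                   metadata = list(method = "s4", a = params$a,
                                   b = params$b, phi = params$phi,
                                   n_kept_draws = nkeep,
                                   scale = "raw-dosage"))
  attr(ws, "posterior") <- data.frame(
    id = ss$id, post_mean_std = pm, mcse_std = mcse, sd = sdj,
    retained = keep, stringsAsFactors = FALSE)
  ws
}

#' Tune S4 shrinkage parameters by cross-validation
#'
#' Runs the sampler at every grid point on each fold's training summary
#' statistics, scores the fold's held-out panel, and returns the
#' parameters with the best mean held-out AUC; optionally a final run on
#' full-data summaries.  The default grid includes the combination
#' `a = 2.75, b = 2, phi = 3e-6`.
#'
#' @param fold_data A list of folds, each a list with `train_ss`
#'   (a `summary_set`), `test_panel` (a `dosage_panel`) and `test_pheno`
#'   (binary vector).
#' @param ld An `ld_reference`.
#' @param grid A data.frame of candidate `(a, b, phi)` rows.
#' @param params_base An [s4_params()] supplying chain-length settings.
#' @param full_ss Optional full-data `summary_set` for the final run.
#' @return A list: `best` (an `s4_params`), `grid_auc` (grid with mean
#'   AUC per point), `weights` (final `weight_set` when `full_ss` given).
#' @export
s4_tune <- function(fold_data, ld,
                    grid = expand.grid(a = c(1.5, 2.75), b = c(1, 2),
                                       phi = c(3e-6, 1e-4, 1e-2, 1, 100)),
                    params_base = s4_params(), full_ss = NULL) {
  stopifnot(nrow(grid) >= 1)
  grid$mean_auc <- NA_real_
  for (g in seq_len(nrow(grid))) {
    aucs <- numeric(length(fold_data))
    for (f in seq_along(fold_data)) {
      pars <- s4_params(a = grid$a[g], b = grid$b[g], phi = grid$phi[g],
                        n_iter = params_base$n_iter,
                        burnin = params_base$burnin,
                        thin = params_base$thin,
                        seed = params_base$seed + f,
                        sparsify_tol = params_base$sparsify_tol)
      ws <- s4_gibbs(fold_data[[f]]$train_ss, ld, pars)
      aucs[f] <- if (nrow(ws) == 0) 0.5 else
        auc_value(score_panel(fold_data[[f]]$test_panel, ws)$raw_score,
                  fold_data[[f]]$test_pheno)
    }
    grid$mean_auc[g] <- mean(aucs)
  }
  bi <- which.max(grid$mean_auc)
  best <- s4_params(a = grid$a[bi], b = grid$b[bi], phi = grid$phi[bi],
                    n_iter = params_base$n_iter,
                    burnin = params_base$burnin, thin = params_base$thin,
                    seed = params_base$seed,
                    sparsify_tol = params_base$sparsify_tol)
  weights <- if (!is.null(full_ss)) s4_gibbs(full_ss, ld, best) else NULL
  list(best = best, grid_auc = grid, weights = weights)
}
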