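# Single-variant logistic association, the chi-square prefilter, and
# fixed-effects inverse-variance meta-analysis.

#' Association-scan configuration
#'
#' @param chi2_min Chi-square prefilter threshold; variants with a Wald
#'   test statistic strictly below this value are excluded by
#'   [chi2_prefilter()].  Default 2.25.
#' @param covariates Optional numeric matrix of per-sample covariates.
#' @param firth_fallback Refit flagged (separated) variants with Firth's
#'   bias-reduced logistic regression?
#' @return An `assoc_config` list.
#' @export
assoc_config <- function(chi2_min = 2.25, covariates = NULL,
                         firth_fallback = TRUE) {
  stopifnot(chi2_min >= 0)
  structure(list(chi2_min = chi2_min, covariates = covariates,
                 firth_fallback = firth_fallback),
            class = "assoc_config")
}

# Joint Newton iterations for all univariate logistic fits
# (intercept + dosage) in a block of variants; G is n x k, NA-free.
newton_block <- function(G, y, max_iter = 40, tol = 1e-10) {
  n <- nrow(G); k <- ncol(G)
  a <- rep(qlogis(mean(y)), k); b <- rep(0, k)
  for (it in seq_len(max_iter)) {
    eta <- sweep(G * rep(b, each = n), 2, a, "+")
    p <- plogis(eta)
    w <- p * (1 - p)
    r <- y - p
    sa <- colSums(r); sb <- colSums(G * r)
    iaa <- colSums(w); iab <- colSums(G * w); ibb <- colSums(G * G * w)
    det <- iaa * ibb - iab * iab
    det[det < 1e-300] <- NA
    da <- (ibb * sa - iab * sb) / det
    db <- (iaa * sb - iab * sa) / det
    da[!is.finite(da)] <- 0; db[!is.finite(db)] <- 0
    # damp huge steps (separation)
    da <- pmin(pmax(da, -5), 5); db <- pmin(pmax(db, -5), 5)
    a <- a + da; b <- b + db
    if (max(abs(da), abs(db)) < tol) break
  }
  eta <- sweep(G * rep(b, each = n), 2, a, "+")
  p <- plogis(eta); w <- p * (1 - p)
  iaa <- colSums(w); iab <- colSums(G * w); ibb <- colSums(G * G * w)
  det <- iaa * ibb - iab * iab
  se <- sqrt(ifelse(det > 0, iaa / det, Inf))
  list(beta = b, se = se,
       converged = max(abs(b)) < 15 & is.finite(se))
}

# Firth bias-reduced fit for a single variant (intercept + dosage).
firth_fit <- function(g, y, max_iter = 100, tol = 1e-8) {
  X <- cbind(1, g)
  th <- c(qlogis(mean(y)), 0)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% th); p <- plogis(eta); w <- p * (1 - p)
    XtW <- t(X * w)
    I <- XtW %*% X
    Iinv <- tryCatch(solve(I), error = function(e) NULL)
    if (is.null(Iinv)) break
    h <- rowSums((X %*% Iinv) * (X * w))
    U <- t(X) %*% (y - p + h * (0.5 - p))
    step <- drop(Iinv %*% U)
    step <- pmin(pmax(step, -5), 5)
    th <- th + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% th); p <- plogis(eta); w <- p * (1 - p)
  I <- t(X * w) %*% X
  se <- sqrt(diag(solve(I)))[2]
  list(beta = th[2], se = se)
}

#' Single-variant logistic association scan
#'
#' Fits, per variant, a logistic regression of the binary phenotype on the
#' dosage (plus covariates, if configured) and reports the Wald beta, SE,
#' z and two-sided normal p-value.  Missing dosages are mean-imputed
#' (2 x effect-allele frequency).  Monomorphic variants get `beta = 0`,
#' `se = Inf` and the flag `"monomorphic"`; apparently separated fits are
#' flagged and optionally refit with Firth's correction.
#'
#' @param panel A `dosage_panel`.
#' @param phenotype Binary 0/1 vector, one entry per panel sample.
#' @param config An [assoc_config()].
#' @param block_size Number of variants fit simultaneously in the
#'   vectorized Newton solver.
#' @return A `summary_set` with one row per variant and a `flag` column.
#' @export
single_variant_assoc <- function(panel, phenotype, config = assoc_config(),
                                 block_size = 256L) {
  y <- as.numeric(phenotype)
  stopifnot(length(y) == nrow(panel$dosages), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("phenotype must contain both classes")
  m <- ncol(panel$dosages)
  beta <- se <- numeric(m)
  flag <- character(m)
  mono <- panel$sd == 0 | !is.finite(panel$sd)
  use_cov <- !is.null(config$covariates)
  poly <- which(!mono)
  if (use_cov) {
    Z <- as.matrix(config$covariates)
    for (j in poly) {
      g <- panel$dosages[, j]
      g[is.na(g)] <- 2 * panel$freq[j]
      fit <- glm(y ~ g + Z, family = binomial())
      beta[j] <- coef(fit)["g"]
      se[j] <- sqrt(vcov(fit)["g", "g"])
      flag[j] <- if (abs(beta[j]) > 15) "separated" else ""
    }
  } else {
    for (start in seq(1, length(poly), by = block_size)) {
      jj <- poly[start:min(start + block_size - 1L, length(poly))]
      G <- panel$dosages[, jj, drop = FALSE]
      if (anyNA(G)) {
        for (k in seq_along(jj)) {
          nas <- is.na(G[, k])
          if (any(nas)) G[nas, k] <- 2 * panel$freq[jj[k]]
        }
      }
      fit <- newton_block(G, y)
      beta[jj] <- fit$beta; se[jj] <- fit$se
      flag[jj] <- ifelse(abs(fit$beta) > 15 | !is.finite(fit$se),
                         "separated", "")
    }
  }
  if (config$firth_fallback && any(flag == "separated")) {
    for (j in which(flag == "separated")) {
      g <- panel$dosages[, j]
      g[is.na(g)] <- 2 * panel$freq[j]
      ff <- firth_fit(g, y)
      beta[j] <- ff$beta; se[j] <- ff$se
      flag[j] <- "separated_firth"
    }
  }
  beta[mono] <- 0; se[mono] <- Inf; flag[mono] <- "monomorphic"
  z <- ifelse(is.finite(se) & se > 0, beta / se, 0)
  df <- cbind(panel$variants,
              data.frame(beta = beta, se = se, z = z,
                         p = 2 * pnorm(-abs(z)),
                         freq = panel$freq, n = length(y),
                         n_cases = sum(y == 1), n_controls = sum(y == 0),
                         flag = flag, stringsAsFactors = FALSE))
  new_summary_set(df)
}

#' Chi-square prefilter on a summary set
#'
#' Retains variants whose Wald chi-square statistic (`z^2`) is at least
#' `chi2_min`; the strict "less than" side is excluded.  Order preserved.
#'
#' @param ss A `summary_set`.
#' @param config An [assoc_config()] (only `chi2_min` is used).
#' @return The filtered `summary_set`.
#' @export
chi2_prefilter <- function(ss, config = assoc_config()) {
  keep <- ss$z^2 >= config$chi2_min
  keep[is.na(keep)] <- FALSE
  out <- ss[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Fixed-effects inverse-variance meta-analysis of summary sets
#'
#' Variants are matched on (chrom, pos) and aligned to the first set's
#' effect allele (sign-flipping swapped rows; unresolvable allele
#' conflicts are dropped).  For shared variants,
#' `beta = sum(b_k / se_k^2) / sum(1 / se_k^2)` and
#' `se = sqrt(1 / sum(1 / se_k^2))`.  Variants present in a single set
#' are carried through unchanged with `n_sets = 1`.
#'
#' @param sets A list of `summary_set` objects (at least `min_sets`).
#' @param min_sets Minimum number of input sets.
#' @return A `summary_set` with an `n_sets` provenance column.
#' @export
inverse_variance_meta <- function(sets, min_sets = 2L) {
  stopifnot(length(sets) >= min_sets)
  keyed <- lapply(sets, function(s) {
    s$.key <- paste(s$chrom, s$pos, sep = ":"); s
  })
  all_keys <- unique(unlist(lapply(keyed, `[[`, ".key")))
  ref <- keyed[[1]][match(all_keys, keyed[[1]]$.key), , drop = FALSE]
  # reference orientation: first set in which each key appears
  for (k in seq_along(keyed)[-1]) {
    missing_ref <- is.na(ref$.key)
    if (!any(missing_ref)) break
    hit <- match(all_keys[missing_ref], keyed[[k]]$.key)
    fill <- which(missing_ref)[!is.na(hit)]
    ref[fill, ] <- keyed[[k]][hit[!is.na(hit)], , drop = FALSE]
  }
  nk <- length(all_keys)
  wsum <- bwsum <- nsum <- matrix(0, nk, 1)
  count <- integer(nk)
  fsum <- numeric(nk)
  dropped <- character(0)
  for (k in seq_along(keyed)) {
    s <- keyed[[k]]
    i <- match(s$.key, all_keys)
    same <- s$allele_effect == ref$allele_effect[i] &
      s$allele_other == ref$allele_other[i]
    swap <- s$allele_effect == ref$allele_other[i] &
      s$allele_other == ref$allele_effect[i]
    bad <- !(same | swap)
    if (any(bad)) dropped <- c(dropped, s$.key[bad])
    b <- ifelse(swap, -s$beta, s$beta)
    f <- ifelse(swap, 1 - s$freq, s$freq)
    wgt <- 1 / s$se^2
    ok <- !bad & is.finite(wgt)
    wsum[i[ok]] <- wsum[i[ok]] + wgt[ok]
    bwsum[i[ok]] <- bwsum[i[ok]] + b[ok] * wgt[ok]
    nsum[i[ok]] <- nsum[i[ok]] + s$n[ok]
    fsum[i[ok]] <- fsum[i[ok]] + f[ok] * s$n[ok]
    count[i[ok]] <- count[i[ok]] + 1L
  }
  keep <- count >= 1L & !(all_keys %in% dropped)
  beta <- drop(bwsum / wsum)
  se <- sqrt(1 / drop(wsum))
  z <- beta / se
  out <- data.frame(chrom = ref$chrom, pos = ref$pos,
                    allele_effect = ref$allele_effect,
                    allele_other = ref$allele_other,
                    id = ref$id,
                    beta = beta, se = se, z = z,
                    p = 2 * pnorm(-abs(z)),
                    freq = fsum / drop(nsum), n = drop(nsum),
                    n_cases = NA_real_, n_controls = NA_real_,
                    n_sets = count, stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  attr(out, "scheme") <- "fixed-effects inverse-variance"
  attr(out, "n_dropped_allele_conflict") <- length(unique(dropped))
  new_summary_set(out)
}
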