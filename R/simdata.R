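# Synthetic LD-structured case-control genotype data with known truth.
# Haplotypes follow a first-order Markov chain within blocks (geometric
# LD decay), dosages are sums of two haplotypes, and disease follows a
# logistic model whose standardized-PRS effect equals the requested
# per-SD odds ratio.

#' Simulation configuration
#'
#' Defaults emulate a consortium-style case-control study of a common
#' disease: a case fraction of 0.37 (cases oversampled relative to a 1%
#' population prevalence), a per-SD odds ratio of 1.38 for the true
#' polygenic score, a sparse architecture (5% causal), and moderate
#' adjacent-variant LD (r = 0.5) in blocks of 20 variants.
#'
#' @param n_samples Number of samples.
#' @param n_variants Number of variants.
#' @param block_size Variants per LD block.
#' @param r_adjacent Target adjacent-allele (haplotype) correlation,
#'   in `[0, 1)`.
#' @param maf_range Range the per-site effect-allele frequencies are
#'   drawn from, within (0, 0.5].
#' @param frac_causal Fraction of variants that are causal.
#' @param target_or_per_sd Odds ratio per SD of the true standardized
#'   polygenic score.
#' @param prevalence Population disease prevalence (used by
#'   [simulate_case_control()]).
#' @param case_fraction Fraction of cases in the assembled sample.
#' @param seed Integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 2000L, n_variants = 500L,
                       block_size = 20L, r_adjacent = 0.5,
                       maf_range = c(0.05, 0.5), frac_causal = 0.05,
                       target_or_per_sd = 1.38, prevalence = 0.01,
                       case_fraction = 0.37, seed = 1L) {
  stopifnot(r_adjacent >= 0, r_adjacent < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            frac_causal >= 0, frac_causal <= 1,
            target_or_per_sd > 0, prevalence > 0, prevalence < 1,
            case_fraction > 0, case_fraction < 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_variants = as.integer(n_variants),
                 block_size = as.integer(block_size),
                 r_adjacent = r_adjacent, maf_range = maf_range,
                 frac_causal = frac_causal,
                 target_or_per_sd = target_or_per_sd,
                 prevalence = prevalence, case_fraction = case_fraction,
                 seed = as.integer(seed)), class = "sim_config")
}

# Markov-chain haplotypes for one block: n_hap x k matrix of 0/1 alleles
# with site frequencies f and adjacent correlation r.
markov_haplotypes <- function(n_hap, f, r) {
  k <- length(f)
  H <- matrix(0L, n_hap, k)
  H[, 1] <- rbinom(n_hap, 1, f[1])
  if (k > 1) for (j in 2:k) {
    fp <- f[j - 1]; fj <- f[j]
    covr <- r * sqrt(fp * (1 - fp) * fj * (1 - fj))
    p11 <- fp * fj + covr
    p1g1 <- p11 / fp
    p1g0 <- (fj - p11) / (1 - fp)
    if (p1g1 < -1e-12 || p1g1 > 1 + 1e-12 ||
        p1g0 < -1e-12 || p1g0 > 1 + 1e-12)
      stop(sprintf(
        "infeasible (maf, r) combination: f=%.3f -> f=%.3f at r=%.2f",
        fp, fj, r))
    pr <- ifelse(H[, j - 1] == 1, min(max(p1g1, 0), 1),
                 min(max(p1g0, 0), 1))
    H[, j] <- rbinom(n_hap, 1, pr)
  }
  H
}

sim_positions <- function(n_variants, block_size) {
  nb <- ceiling(n_variants / block_size)
  spacing <- max(1L, as.integer(floor(9e5 / block_size)))
  pos <- integer(0)
  for (b in seq_len(nb)) {
    k <- min(block_size, n_variants - (b - 1L) * block_size)
    pos <- c(pos, as.integer((b - 1) * 1e6 + seq_len(k) * spacing))
  }
  pos
}

# Per-site effect-allele frequencies: one base frequency per LD block
# drawn from maf_range with +-10% relative within-block jitter.  Tightly
# linked sites share allele-frequency histories, and near-equal adjacent
# frequencies keep the Markov transition probabilities feasible for any
# r_adjacent < 1.
sim_freqs <- function(cfg) {
  m <- cfg$n_variants
  freqs <- numeric(m)
  start <- 1L
  while (start <= m) {
    k <- min(cfg$block_size, m - start + 1L)
    base <- runif(1, cfg$maf_range[1], cfg$maf_range[2])
    f <- base * runif(k, 0.9, 1.1)
    freqs[start:(start + k - 1L)] <- pmin(pmax(f, cfg$maf_range[1]),
                                          cfg$maf_range[2])
    start <- start + k
  }
  freqs
}

sim_dosage_matrix <- function(cfg, n, freqs) {
  m <- cfg$n_variants
  dos <- matrix(0, n, m)
  start <- 1L
  while (start <= m) {
    k <- min(cfg$block_size, m - start + 1L)
    jj <- start:(start + k - 1L)
    h1 <- markov_haplotypes(n, freqs[jj], cfg$r_adjacent)
    h2 <- markov_haplotypes(n, freqs[jj], cfg$r_adjacent)
    dos[, jj] <- h1 + h2
    start <- start + k
  }
  dos
}

#' Simulate an LD-structured dosage panel with known truth
#'
#' @param cfg A [sim_config()].
#' @return A list: `panel` (a `dosage_panel`), `truth` (list with
#'   `causal` indices, `u` raw causal effect draws, `beta_sd`
#'   = log(target_or_per_sd), site frequencies `freq`).
#' @export
simulate_panel <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  m <- cfg$n_variants
  freqs <- sim_freqs(cfg)
  dos <- sim_dosage_matrix(cfg, cfg$n_samples, freqs)
  v <- variant_key(rep("1", m), sim_positions(m, cfg$block_size),
                   rep("A", m), rep("G", m),
                   sprintf("snp%05d", seq_len(m)))
  panel <- dosage_panel(dos, sprintf("s%05d", seq_len(cfg$n_samples)), v)
  n_causal <- round(cfg$frac_causal * m)
  causal <- if (n_causal > 0) sort(sample.int(m, n_causal)) else integer(0)
  u <- if (n_causal > 0) rnorm(n_causal) else numeric(0)
  list(panel = panel,
       truth = list(causal = causal, u = u,
                    beta_sd = log(cfg$target_or_per_sd), freq = freqs))
}

# liability (standardized true polygenic score) for a dosage matrix
sim_liability <- function(dos, truth) {
  if (length(truth$causal) == 0) return(rep(0, nrow(dos)))
  G <- dos[, truth$causal, drop = FALSE]
  l <- drop(scale(G) %*% truth$u)
  sdl <- stats::sd(l)
  if (!is.finite(sdl) || sdl == 0) rep(0, nrow(dos)) else
    (l - mean(l)) / sdl
}

solve_intercept <- function(lin, target) {
  uniroot(function(a) mean(plogis(a + lin)) - target,
          lower = -30, upper = 30)$root
}

#' Simulate a binary phenotype for an existing panel
#'
#' Disease probability is `plogis(alpha + beta_sd * s)` where `s` is the
#' standardized true polygenic score and `beta_sd = log(target OR per
#' SD)`.  The intercept `alpha` is tilted so the expected in-sample case
#' fraction equals `cfg$case_fraction`: under a logistic model,
#' case-control ascertainment shifts only the intercept and preserves
#' all odds ratios, so this tilt reproduces a case-control design on a
#' fixed panel.
#'
#' @param panel A `dosage_panel` from [simulate_panel()].
#' @param truth The matching truth record.
#' @param cfg The [sim_config()] used to generate the panel.
#' @return A list: `phenotype` (0/1 vector), `alpha`, `oracle_auc`
#'   (empirical AUC of the true score), `liability`.
#' @export
simulate_phenotype <- function(panel, truth, cfg) {
  set.seed(cfg$seed + 1L)
  s <- sim_liability(panel$dosages, truth)
  alpha <- solve_intercept(truth$beta_sd * s, cfg$case_fraction)
  y <- rbinom(length(s), 1, plogis(alpha + truth$beta_sd * s))
  # guarantee both classes for downstream model fitting
  if (sum(y) == 0) y[which.max(s)] <- 1L
  if (sum(y) == length(y)) y[which.min(s)] <- 0L
  list(phenotype = y, alpha = alpha,
       oracle_auc = if (stats::sd(s) > 0) auc_value(s, y) else 0.5,
       liability = s)
}

#' Simulate a case-control study by rejection sampling
#'
#' Draws population batches (genotypes and disease status under the
#' prevalence-calibrated logistic model) and keeps cases and controls
#' until the target counts `n_samples * case_fraction` and the
#' complement are filled; errors if the quota is not met within
#' `max_batches` batches.
#'
#' @param cfg A [sim_config()].
#' @param batch_size Population batch size (default `2 * n_samples`).
#' @param max_batches Attempt cap.
#' @return A list: `panel`, `phenotype`, `truth`.
#' @export
simulate_case_control <- function(cfg = sim_config(),
                                  batch_size = NULL, max_batches = 200L) {
  set.seed(cfg$seed)
  m <- cfg$n_variants
  if (is.null(batch_size)) batch_size <- 2L * cfg$n_samples
  freqs <- sim_freqs(cfg)
  n_causal <- round(cfg$frac_causal * m)
  causal <- if (n_causal > 0) sort(sample.int(m, n_causal)) else integer(0)
  u <- if (n_causal > 0) rnorm(n_causal) else numeric(0)
  truth <- list(causal = causal, u = u,
                beta_sd = log(cfg$target_or_per_sd), freq = freqs)
  need_cases <- round(cfg$n_samples * cfg$case_fraction)
  need_controls <- cfg$n_samples - need_cases
  if (need_cases > max_batches * batch_size * cfg$prevalence * 3)
    stop("prevalence incompatible with requested case count; ",
         "raise max_batches or batch_size")
  got_cases <- got_controls <- 0L
  case_rows <- control_rows <- list()
  # population intercept from prevalence via quadrature over N(0,1) score
  gh <- gauss_hermite_normal(32)
  alpha <- uniroot(function(a)
    sum(gh$w * plogis(a + truth$beta_sd * gh$z)) - cfg$prevalence,
    lower = -30, upper = 30)$root
  for (b in seq_len(max_batches)) {
    dos <- sim_dosage_matrix(cfg, batch_size, freqs)
    s <- sim_liability(dos, truth)
    y <- rbinom(batch_size, 1, plogis(alpha + truth$beta_sd * s))
    if (got_cases < need_cases && any(y == 1)) {
      take <- head(which(y == 1), need_cases - got_cases)
      case_rows[[length(case_rows) + 1]] <- dos[take, , drop = FALSE]
      got_cases <- got_cases + length(take)
    }
    if (got_controls < need_controls && any(y == 0)) {
      take <- head(which(y == 0), need_controls - got_controls)
      control_rows[[length(control_rows) + 1]] <- dos[take, , drop = FALSE]
      got_controls <- got_controls + length(take)
    }
    if (got_cases >= need_cases && got_controls >= need_controls) break
  }
  if (got_cases < need_cases || got_controls < need_controls)
    stop("case/control quota not reached within max_batches")
  dos <- rbind(do.call(rbind, case_rows), do.call(rbind, control_rows))
  y <- c(rep(1L, need_cases), rep(0L, need_controls))
  o <- sample.int(length(y))                  # shuffle rows
  v <- variant_key(rep("1", m), sim_positions(m, cfg$block_size),
                   rep("A", m), rep("G", m),
                   sprintf("snp%05d", seq_len(m)))
  panel <- dosage_panel(dos[o, , drop = FALSE],
                        sprintf("s%05d", seq_len(length(y))), v)
  list(panel = panel, phenotype = y[o], truth = truth)
}

#' Summary statistics from a simulated panel
#'
#' Convenience wrapper running the single-variant association scan, so
#' summary-statistic methods can be exercised end-to-end on synthetic
#' data.
#'
#' @param panel A `dosage_panel`.
#' @param phenotype Binary 0/1 vector.
#' @param config An [assoc_config()].
#' @return A `summary_set`.
#' @export
simulate_summary <- function(panel, phenotype, config = assoc_config()) {
  single_variant_assoc(panel, phenotype, config)
}

#' Draw marginal summary statistics directly from the LD model
#'
#' Given true standardized joint effects `beta_std`, marginal
#' standardized estimates are drawn per block as
#' `bhat ~ N(R beta_std, R / n)` — the large-sample distribution of
#' marginal GWAS estimates — and converted to the raw-dosage scale using
#' the reference SDs.  Useful for fast summary-level experiments at
#' large nominal n without simulating individual-level data.
#'
#' @param ld An `ld_reference`.
#' @param beta_std Numeric vector of true standardized effects, one per
#'   LD-reference variant.
#' @param n Nominal GWAS sample size.
#' @param seed Integer seed.
#' @return A `summary_set` (with an attribute `beta_std_hat` of the
#'   standardized marginal estimates).
#' @export
simulate_marginal_stats <- function(ld, beta_std, n, seed = 1L) {
  stopifnot(length(beta_std) == nrow(ld$variants))
  set.seed(seed)
  m <- length(beta_std)
  bhat <- numeric(m)
  for (bl in ld$blocks) {
    R <- bl$R
    U <- chol(R)
    mu <- drop(R %*% beta_std[bl$idx])
    bhat[bl$idx] <- mu +
      drop(t(U) %*% rnorm(length(bl$idx))) / sqrt(n)
  }
  sdj <- ld$sd
  beta <- bhat / sdj
  se <- 1 / (sqrt(n) * sdj)
  z <- bhat * sqrt(n)
  # HWE-implied effect-allele frequency from the dosage sd
  disc <- pmax(1 - 2 * sdj^2, 0)
  freq <- (1 - sqrt(disc)) / 2
  df <- cbind(ld$variants,
              data.frame(beta = beta, se = se, z = z,
                         p = 2 * pnorm(-abs(z)), freq = freq, n = n,
                         n_cases = NA_real_, n_controls = NA_real_,
                         flag = "", stringsAsFactors = FALSE))
  out <- new_summary_set(df)
  attr(out, "beta_std_hat") <- bhat
  out
}

#' Write the small plain-text fixture suite used by the unit tests
#'
#' Produces, under `out_dir`: a PLINK triplet, a VCF, a summary-statistic
#' TSV, a weight TSV, a synthetic age-specific rates CSV, and the
#' percentile-band count table fixture.  Deterministic under `seed`.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed.
#' @return Invisibly, the list of files written.
#' @export
make_fixture_suite <- function(out_dir, seed = 42L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim_config(n_samples = 30L, n_variants = 10L, block_size = 5L,
                    seed = seed)
  sim <- simulate_panel(cfg)
  panel <- sim$panel
  write_plink(panel, file.path(out_dir, "toy"))
  # VCF with GT from the same hard calls
  vcf <- file.path(out_dir, "toy.vcf")
  gtmap <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", panel$sample_ids),
                   collapse = "\t"))
  for (j in seq_len(ncol(panel$dosages))) {
    v <- panel$variants[j, ]
    gt <- gtmap[as.character(round(panel$dosages[, j]))]
    gt[is.na(gt)] <- "./."
    lines <- c(lines, paste(c(v$chrom, v$pos, v$id, v$allele_other,
                              v$allele_effect, ".", "PASS", ".", "GT",
                              gt), collapse = "\t"))
  }
  writeLines(lines, vcf)
  ph <- simulate_phenotype(panel, sim$truth, cfg)
  ss <- simulate_summary(panel, ph$phenotype)
  data.table::fwrite(as.data.frame(ss)[, c("chrom", "pos",
                                           "allele_effect",
                                           "allele_other", "id", "beta",
                                           "se", "p", "freq", "n")],
                     file.path(out_dir, "toy_summary.tsv"), sep = "\t")
  ws <- weight_set(panel$variants, round(rnorm(ncol(panel$dosages)), 4))
  write_weights(ws, file.path(out_dir, "toy_weights.tsv"))
  for (f in c("synthetic_rates.csv", "tab3_band_counts.tsv"))
    file.copy(system.file("extdata", f, package = "penprs"),
              file.path(out_dir, f), overwrite = TRUE)
  invisible(list.files(out_dir, full.names = TRUE))
}
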