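# PRS scoring, standardization and evaluation: AUC, OR per SD,
# percentile-band ORs against the middle quintile, and theoretical band
# ORs under the multiplicative model.

#' Score a dosage panel with a weight set
#'
#' Computes `PRS_i = sum_j x_ij beta_j` after harmonizing the weight set
#' to the panel (allele-swap sign flips; strand-ambiguous variants kept
#' by default since scoring is within a single dataset).  Missing dosages
#' are imputed as twice the effect-allele frequency.  Unmatched weights
#' are reported in the attached report, never silently dropped.
#'
#' @param panel A `dosage_panel`.
#' @param ws A `weight_set`.
#' @param drop_ambiguous Drop strand-ambiguous variants during
#'   harmonization (default `FALSE` within one dataset)?
#' @return A `score_set`: data.frame with `sample_id`, `raw_score`, and
#'   attributes `report` and `n_variants_used`.
#' @export
score_panel <- function(panel, ws, drop_ambiguous = FALSE) {
  h <- harmonize(ws, panel, drop_ambiguous = drop_ambiguous)
  if (nrow(h$target) == 0) stop("no weight-set variants overlap the panel")
  X <- panel$dosages[, h$panel_index, drop = FALSE]
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- 2 * panel$freq[h$panel_index[j]]
  }
  raw <- drop(X %*% h$target$weight)
  out <- data.frame(sample_id = panel$sample_ids, raw_score = raw,
                    stringsAsFactors = FALSE)
  class(out) <- c("score_set", "data.frame")
  attr(out, "report") <- h$report
  attr(out, "n_variants_used") <- nrow(h$target)
  out
}

#' Standardize PRS values against a reference group
#'
#' Mean and SD are computed on the reference group (conventionally the
#' controls of the same population) and applied to all samples; an
#' external `(center, scale)` pair may be supplied instead, e.g. to put
#' one cohort on another cohort's SD scale.
#'
#' @param scores A `score_set` (or numeric vector).
#' @param reference_ids Sample ids forming the reference group; `NULL`
#'   uses all samples.
#' @param center,scale Optional external mean and SD, used verbatim.
#' @return The `score_set` with a `std_score` column (or, for a numeric
#'   input, the standardized vector) and a `standardization` attribute.
#' @export
standardize_scores <- function(scores, reference_ids = NULL,
                               center = NULL, scale = NULL) {
  vec <- if (is.data.frame(scores)) scores$raw_score else as.numeric(scores)
  if (is.null(center) || is.null(scale)) {
    ref <- if (is.null(reference_ids)) seq_along(vec) else {
      stopifnot(is.data.frame(scores))
      which(scores$sample_id %in% reference_ids)
    }
    if (length(ref) < 2) stop("reference group needs >= 2 samples")
    center <- mean(vec[ref])
    scale <- stats::sd(vec[ref])
    descr <- if (is.null(reference_ids)) "all samples" else "reference ids"
  } else descr <- "external"
  if (!is.finite(scale) || scale <= 0)
    stop("reference group has zero score variance")
  std <- (vec - center) / scale
  if (!is.data.frame(scores)) return(std)
  scores$std_score <- std
  attr(scores, "standardization") <- list(mean = center, sd = scale,
                                          reference = descr)
  scores
}

# Mann-Whitney AUC; ties count 1/2. Internal fast path.
auc_value <- function(score, labels) {
  y <- as.numeric(labels)
  n1 <- as.numeric(sum(y == 1)); n0 <- as.numeric(sum(y == 0))
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the ROC curve with a DeLong-style confidence interval
#'
#' Mann-Whitney estimator (ties count one half), with the DeLong
#' placement-based variance for the confidence interval.
#'
#' @param score Numeric score vector (or `score_set`; uses `std_score`
#'   when present, else `raw_score`).
#' @param labels Binary 0/1 outcome vector.
#' @param conf_level Confidence level (default 0.95).
#' @return A list: `auc`, `se`, `ci` (length-2 vector).
#' @export
prs_auc <- function(score, labels, conf_level = 0.95) {
  if (is.data.frame(score))
    score <- if ("std_score" %in% names(score)) score$std_score else
      score$raw_score
  y <- as.numeric(labels)
  a <- auc_value(score, y)
  cases <- score[y == 1]; controls <- score[y == 0]
  n1 <- length(cases); n0 <- length(controls)
  # DeLong placements
  rall <- rank(c(cases, controls))
  r1 <- rank(cases); r0 <- rank(controls)
  v10 <- (rall[seq_len(n1)] - r1) / n0          # P(control < case_i)
  v01 <- 1 - (rall[n1 + seq_len(n0)] - r0) / n1 # P(case > control_j)
  s2 <- var(v10) / n1 + var(v01) / n0
  se <- sqrt(s2)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  list(auc = a, se = se,
       ci = c(max(0, a - zq * se), min(1, a + zq * se)))
}

#' Odds ratio per standard deviation of PRS
#'
#' Univariate logistic regression of the outcome on the standardized
#' score; returns `exp(beta)` with a Wald confidence interval.
#'
#' @param scores A `score_set` with `std_score` (or a numeric vector of
#'   standardized scores).
#' @param labels Binary 0/1 outcome vector.
#' @param conf_level Confidence level.
#' @return A list: `or`, `log_or`, `se`, `ci`.
#' @export
or_per_sd <- function(scores, labels, conf_level = 0.95) {
  s <- if (is.data.frame(scores)) {
    if (!"std_score" %in% names(scores))
      stop("standardize scores first (see standardize_scores)")
    scores$std_score
  } else as.numeric(scores)
  y <- as.numeric(labels)
  fit <- glm(y ~ s, family = binomial())
  if (!fit$converged) stop("logistic regression did not converge")
  b <- coef(fit)["s"]; se <- sqrt(vcov(fit)["s", "s"])
  zq <- qnorm(1 - (1 - conf_level) / 2)
  list(or = unname(exp(b)), log_or = unname(b), se = unname(se),
       ci = unname(exp(c(b - zq * se, b + zq * se))))
}

#' Percentile band definitions
#'
#' Default bands follow the conventional risk-stratification layout
#' 0-5, 5-10, 10-20, 20-40, 40-60 (reference middle quintile), 60-80,
#' 80-90, 90-95, 95-100.
#'
#' @param breaks Increasing percentile cut points from 0 to 100.
#' @param reference Label of the reference band.
#' @return A `percentile_bands` data.frame with `low`, `high`, `label`.
#' @export
percentile_bands <- function(breaks = c(0, 5, 10, 20, 40, 60, 80, 90,
                                        95, 100),
                             reference = "40-60") {
  stopifnot(breaks[1] == 0, breaks[length(breaks)] == 100,
            all(diff(breaks) > 0))
  lab <- paste(head(breaks, -1), tail(breaks, -1), sep = "-")
  if (!reference %in% lab) stop("reference band not among bands")
  structure(data.frame(low = head(breaks, -1), high = tail(breaks, -1),
                       label = lab, stringsAsFactors = FALSE),
            class = c("percentile_bands", "data.frame"),
            reference = reference)
}

woolf_ci <- function(or, a, b, c, d, conf_level) {
  zq <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  exp(log(or) + c(-zq, zq) * se)
}

#' Per-band odds ratios relative to the reference band
#'
#' Accepts either scores plus labels (percentile cuts computed on the
#' combined sample's scores) or a precomputed per-band count table with
#' columns `label`, `cases`, `controls`.  The crude OR for band b is
#' `(cases_b / controls_b) / (cases_ref / controls_ref)` with a Woolf
#' log-scale confidence interval; zero cells trigger a 0.5 continuity
#' correction and a flag.
#'
#' @param scores Numeric scores or `score_set` (ignored when `counts`
#'   given).
#' @param labels Binary 0/1 outcome vector (ignored when `counts` given).
#' @param bands A [percentile_bands()].
#' @param counts Optional data.frame of per-band counts.
#' @param conf_level Confidence level.
#' @return A data.frame with `label`, `controls`, `cases`, `or`,
#'   `ci_low`, `ci_high`, `flag`.
#' @export
band_or <- function(scores = NULL, labels = NULL,
                    bands = percentile_bands(), counts = NULL,
                    conf_level = 0.95) {
  ref_lab <- attr(bands, "reference")
  if (is.null(counts)) {
    s <- if (is.data.frame(scores)) {
      if ("std_score" %in% names(scores)) scores$std_score else
        scores$raw_score
    } else as.numeric(scores)
    y <- as.numeric(labels)
    # percentile rank on the combined sample; average ranks keep tied
    # scores in the same band
    pr <- (rank(s, ties.method = "average") - 0.5) / length(s) * 100
    grp <- cut(pr, breaks = c(bands$low[1], bands$high),
               labels = bands$label, include.lowest = TRUE)
    counts <- data.frame(label = bands$label,
                         cases = as.vector(table(grp[y == 1])[bands$label]),
                         controls =
                           as.vector(table(grp[y == 0])[bands$label]))
    counts$cases[is.na(counts$cases)] <- 0
    counts$controls[is.na(counts$controls)] <- 0
  }
  counts <- counts[match(bands$label, counts$label), , drop = FALSE]
  ref <- counts[counts$label == ref_lab, ]
  if (ref$cases == 0 || ref$controls == 0)
    stop("reference band has an empty cell")
  out <- counts
  out$or <- NA_real_; out$ci_low <- NA_real_; out$ci_high <- NA_real_
  out$flag <- ""
  for (i in seq_len(nrow(out))) {
    a <- out$cases[i]; b <- out$controls[i]
    cc <- ref$cases; d <- ref$controls
    corr <- a == 0 || b == 0
    if (corr) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
    or <- (a / b) / (cc / d)
    ci <- woolf_ci(or, a, b, cc, d, conf_level)
    out$or[i] <- or; out$ci_low[i] <- ci[1]; out$ci_high[i] <- ci[2]
    if (corr) out$flag[i] <- "continuity_corrected"
  }
  out$or[out$label == ref_lab] <- 1
  out$ci_low[out$label == ref_lab] <- 1
  out$ci_high[out$label == ref_lab] <- 1
  out
}

#' Theoretical band odds ratios under the multiplicative model
#'
#' Assuming the standardized PRS is standard normal and all variants act
#' multiplicatively, the relative odds for a band (a, b) follows the
#' closed form `E[exp(beta Z) | a < Z < b] = exp(beta^2 / 2) *
#' (Phi(b - beta) - Phi(a - beta)) / (Phi(b) - Phi(a))`; band ORs are
#' ratios of these conditional expectations against the reference band.
#'
#' @param or_per_sd Odds ratio per 1 SD of PRS (> 0).
#' @param bands A [percentile_bands()].
#' @return A data.frame with `label` and `or`.
#' @export
theoretical_band_or <- function(or_per_sd, bands = percentile_bands()) {
  stopifnot(or_per_sd > 0)
  beta <- log(or_per_sd)
  cond_mean <- function(lo_p, hi_p) {
    a <- qnorm(lo_p / 100); b <- qnorm(hi_p / 100)
    if (pnorm(b) - pnorm(a) <= 0) stop("empty band")
    exp(beta^2 / 2) * (pnorm(b - beta) - pnorm(a - beta)) /
      (pnorm(b) - pnorm(a))
  }
  e <- mapply(cond_mean, bands$low, bands$high)
  ref <- e[bands$label == attr(bands, "reference")]
  data.frame(label = bands$label, or = e / ref,
             stringsAsFactors = FALSE)
}

#' Full evaluation report for a scored cohort
#'
#' @param scores A standardized `score_set`.
#' @param labels Binary 0/1 outcome vector.
#' @param bands A [percentile_bands()].
#' @return A list with `auc`, `or_per_sd`, `band_table`, `n_cases`,
#'   `n_controls`.
#' @export
evaluate_prs <- function(scores, labels, bands = percentile_bands()) {
  list(auc = prs_auc(scores, labels),
       or_per_sd = or_per_sd(scores, labels),
       band_table = band_or(scores, labels, bands),
       n_cases = sum(labels == 1), n_controls = sum(labels == 0))
}
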