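# Approximate conditional-and-joint forward selection from summary
# statistics with a block LD reference, plus the meta-analysis region
# selection rule (genome-wide leads plus conditionally independent
# secondary signals).

#' Configuration for conditional/joint stepwise selection
#'
#' `z_select` is the selection threshold on the conditional |z|, i.e. the
#' hard-threshold (`kap = 1`) member of the penalized family expressed as
#' a variable p-value threshold (z = 5.45 corresponds to p = 5e-8).
#'
#' @param z_select Selection threshold on |conditional z| (default 5.4).
#' @param r2_cap Collinearity guard: candidates with squared correlation
#'   above this to any selected variant are withheld (default 0.9).
#' @param window_bp LD horizon; variants farther apart are treated as
#'   independent (default 10 Mb; block structure already enforces this).
#' @return A `cojo_config` list.
#' @export
cojo_config <- function(z_select = 5.4, r2_cap = 0.9, window_bp = 1e7) {
  stopifnot(z_select > 0, r2_cap > 0, r2_cap < 1)
  structure(list(z_select = z_select, r2_cap = r2_cap,
                 window_bp = window_bp), class = "cojo_config")
}

# Map a summary set onto the LD reference: returns per-row block id,
# within-block position, standardized effect and its sd.
cojo_index <- function(ss, ld) {
  sskey <- paste(ss$chrom, ss$pos, sep = ":")
  ldkey <- paste(ld$variants$chrom, ld$variants$pos, sep = ":")
  if (anyNA(match(sskey, ldkey)))
    stop("summary set contains variants absent from the LD reference")
  block <- rep(NA_integer_, nrow(ss))
  within <- rep(NA_integer_, nrow(ss))
  for (b in seq_along(ld$blocks)) {
    hit <- match(ld$blocks[[b]]$keys, sskey)
    ok <- which(!is.na(hit))
    block[hit[ok]] <- b
    within[hit[ok]] <- ok
  }
  sdj <- ld$sd[match(sskey, ldkey)]
  list(block = block, within = within, sd = sdj,
       bstd = ss$beta * sdj, sestd = ss$se * sdj)
}

#' Approximate conditional association statistics
#'
#' For each unselected candidate, the conditional effect is the marginal
#' standardized effect minus its LD projection onto the selected
#' variants' joint effects, with variance `(1 - r' R_SS^{-1} r) / n` on
#' the standardized scale (treating the residual variance as 1);
#' candidates correlated above `r2_cap` with a selected variant are
#' flagged `"collinear"` and their conditional statistics withheld.
#' Outputs are de-standardized.
#'
#' @param ss A `summary_set` harmonized to `ld`.
#' @param selected Integer indices (rows of `ss`) of selected variants.
#' @param ld An `ld_reference`.
#' @param cfg A [cojo_config()].
#' @return A data.frame with `beta_cond`, `se_cond`, `z_cond`, `flag`
#'   per row of `ss` (selected rows get `NA` and flag `"selected"`).
#' @export
conditional_stats <- function(ss, selected, ld, cfg = cojo_config()) {
  ix <- cojo_index(ss, ld)
  m <- nrow(ss)
  out <- data.frame(beta_cond = rep(NA_real_, m), se_cond = NA_real_,
                    z_cond = NA_real_, flag = "",
                    stringsAsFactors = FALSE)
  out$flag[selected] <- "selected"
  nvec <- ss$n
  for (b in unique(ix$block)) {
    in_b <- which(ix$block == b)
    sel_b <- intersect(in_b, selected)
    cand_b <- setdiff(in_b, selected)
    if (length(cand_b) == 0) next
    R <- ld$blocks[[b]]$R
    if (length(sel_b) == 0) {
      out$beta_cond[cand_b] <- ix$bstd[cand_b]
      out$se_cond[cand_b] <- 1 / sqrt(nvec[cand_b])
    } else {
      wS <- ix$within[sel_b]
      RSS <- R[wS, wS, drop = FALSE]
      gamma <- solve(RSS, ix$bstd[sel_b])
      for (cc in cand_b) {
        r <- R[ix$within[cc], wS]
        if (max(r^2) > cfg$r2_cap) { out$flag[cc] <- "collinear"; next }
        q <- sum(r * solve(RSS, r))
        out$beta_cond[cc] <- ix$bstd[cc] - sum(r * gamma)
        out$se_cond[cc] <- sqrt(max(1 - q, 1e-12) / nvec[cc])
      }
    }
  }
  out$z_cond <- out$beta_cond / out$se_cond
  # de-standardize reported effects
  out$beta_cond <- out$beta_cond / ix$sd
  out$se_cond <- out$se_cond / ix$sd
  out
}

# Joint standardized effects and SEs of a selected set (per block).
joint_fit <- function(ss, selected, ld, nvec) {
  ix <- cojo_index(ss, ld)
  bj <- sej <- rep(NA_real_, length(selected))
  for (b in unique(ix$block[selected])) {
    sel_b <- selected[ix$block[selected] == b]
    wS <- ix$within[sel_b]
    RSS <- ld$blocks[[b]]$R[wS, wS, drop = FALSE]
    if (rcond(RSS) < 1e-10) return(NULL)
    Rinv <- solve(RSS)
    pos <- match(sel_b, selected)
    bj[pos] <- drop(Rinv %*% ix$bstd[sel_b])
    sej[pos] <- sqrt(diag(Rinv) / nvec[sel_b])
  }
  list(beta_std = bj, se_std = sej, sd = ix$sd[selected])
}

#' Forward stepwise conditional-and-joint selection
#'
#' Iteratively selects the candidate with the largest conditional |z|
#' while it is at least `z_select`, refitting the joint effects of the
#' selected set from the LD-weighted normal equations after each step.
#' If adding a variant makes the joint system ill-conditioned it is
#' dropped with a warning.
#'
#' @param ss A `summary_set` harmonized to `ld`.
#' @param ld An `ld_reference`.
#' @param cfg A [cojo_config()].
#' @return A `weight_set` of joint (raw-scale) effects; attribute
#'   `joint` carries the standardized joint statistics.
#' @export
cojo_forward_select <- function(ss, ld, cfg = cojo_config()) {
  stopifnot(nrow(ss) > 0)
  selected <- integer(0)
  blocked <- integer(0)
  repeat {
    cs <- conditional_stats(ss, selected, ld, cfg)
    cand <- which(!is.na(cs$z_cond))
    cand <- setdiff(cand, blocked)
    if (length(cand) == 0) break
    best <- cand[which.max(abs(cs$z_cond[cand]))]
    if (abs(cs$z_cond[best]) < cfg$z_select) break
    trial <- c(selected, best)
    jf <- joint_fit(ss, trial, ld, ss$n)
    if (is.null(jf)) {
      warning("joint system ill-conditioned; dropping last added variant")
      blocked <- c(blocked, best)
      next
    }
    selected <- trial
  }
  if (length(selected) == 0) {
    empty <- ss[integer(0), c("chrom", "pos", "allele_effect",
                              "allele_other", "id"), drop = FALSE]
    return(weight_set(empty, numeric(0),
                      metadata = list(method = "stepwise",
                                      z_select = cfg$z_select)))
  }
  jf <- joint_fit(ss, selected, ld, ss$n)
  o <- order(selected)
  selected <- selected[o]
  beta_raw <- (jf$beta_std / jf$sd)[o]
  ws <- weight_set(ss[selected, c("chrom", "pos", "allele_effect",
                                  "allele_other", "id"), drop = FALSE],
                   beta_raw,
                   metadata = list(method = "stepwise",
                                   z_select = cfg$z_select,
                                   scale = "raw-dosage"))
  attr(ws, "joint") <- data.frame(
    index = selected, beta_std = jf$beta_std[o], se_std = jf$se_std[o],
    z_joint = (jf$beta_std / jf$se_std)[o])
  ws
}

#' Region selection rule for meta-analysis summary statistics
#'
#' Regions are LD blocks containing at least one variant that is
#' genome-wide significant in the meta-analysis.  Each region
#' contributes its lead variant (smallest meta p) plus conditionally
#' independent secondary signals whose conditional p-value passes
#' `secondary_p` in any stratum.  Joint effects come from the
#' conditional-and-joint machinery applied to the meta-analysis.
#'
#' @param meta A meta-analysis `summary_set` harmonized to `ld`.
#' @param per_stratum A list of stratum `summary_set`s (same variants and
#'   allele orientation as `meta`; e.g. histotype-specific analyses).
#' @param ld An `ld_reference`.
#' @param genomewide_p Lead threshold (default 5e-8).
#' @param secondary_p Secondary-signal threshold (default 1e-5); must be
#'   larger than `genomewide_p`.
#' @param cfg A [cojo_config()].
#' @return A `weight_set` of joint meta effects for the selected
#'   variants.
#' @export
meta_region_select <- function(meta, per_stratum = list(), ld,
                               genomewide_p = 5e-8, secondary_p = 1e-5,
                               cfg = cojo_config()) {
  stopifnot(secondary_p > genomewide_p)
  ix <- cojo_index(meta, ld)
  gw <- which(meta$p < genomewide_p)
  if (length(gw) == 0) {
    empty <- meta[integer(0), c("chrom", "pos", "allele_effect",
                                "allele_other", "id"), drop = FALSE]
    return(weight_set(empty, numeric(0),
                      metadata = list(method = "meta_region")))
  }
  regions <- unique(ix$block[gw])
  # leads: smallest meta p per region
  selected <- vapply(regions, function(b) {
    in_b <- gw[ix$block[gw] == b]
    in_b[which.min(meta$p[in_b])]
  }, integer(1))
  strata <- if (length(per_stratum) > 0) per_stratum else list(meta)
  zsec <- qnorm(secondary_p / 2, lower.tail = FALSE)
  sec_cfg <- cojo_config(z_select = zsec, r2_cap = cfg$r2_cap,
                         window_bp = cfg$window_bp)
  repeat {
    added <- FALSE
    for (s in strata) {
      cs <- conditional_stats(s, selected, ld, sec_cfg)
      cand <- which(!is.na(cs$z_cond) & ix$block %in% regions)
      cand <- setdiff(cand, selected)
      if (length(cand) == 0) next
      best <- cand[which.max(abs(cs$z_cond[cand]))]
      if (abs(cs$z_cond[best]) >= zsec) {
        trial <- sort(c(selected, best))
        if (!is.null(joint_fit(meta, trial, ld, meta$n))) {
          selected <- trial; added <- TRUE
        }
      }
    }
    if (!added) break
  }
  selected <- sort(selected)
  jf <- joint_fit(meta, selected, ld, meta$n)
  ws <- weight_set(meta[selected, c("chrom", "pos", "allele_effect",
                                    "allele_other", "id"), drop = FALSE],
                   jf$beta_std / jf$sd,
                   metadata = list(method = "meta_region",
                                   genomewide_p = genomewide_p,
                                   secondary_p = secondary_p,
                                   scale = "raw-dosage"))
  attr(ws, "joint") <- data.frame(index = selected,
                                  beta_std = jf$beta_std,
                                  se_std = jf$se_std)
  ws
}
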