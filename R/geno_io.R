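# I/O and harmonization for genotype panels, summary statistics and weight
# files.  Variants are keyed by (chrom, pos, allele set), never by rsID.

#' Construct a variant key table
#'
#' A variant key identifies a biallelic variant by chromosome, 1-based
#' position and its two alleles; the first allele is the effect allele
#' (the allele whose dosage is counted and to which weights refer).
#'
#' @param chrom Character vector of chromosome labels.
#' @param pos Integer vector of 1-based base-pair positions.
#' @param allele_effect,allele_other Character vectors of alleles.
#' @param id Optional character vector of variant identifiers (e.g. rsIDs).
#' @return A data.frame with columns `chrom`, `pos`, `allele_effect`,
#'   `allele_other`, `id`.
#' @export
variant_key <- function(chrom, pos, allele_effect, allele_other, id = NULL) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  allele_effect <- toupper(as.character(allele_effect))
  allele_other <- toupper(as.character(allele_other))
  if (any(pos < 1L)) stop("variant positions must be >= 1")
  if (any(!nzchar(allele_effect)) || any(!nzchar(allele_other)))
    stop("alleles must be non-empty")
  if (any(allele_effect == allele_other))
    stop("effect and other allele must differ")
  if (is.null(id))
    id <- if (length(chrom) == 0) character(0) else
      paste0(chrom, ":", pos)
  data.frame(chrom = chrom, pos = pos, allele_effect = allele_effect,
             allele_other = allele_other, id = as.character(id),
             stringsAsFactors = FALSE)
}

#' Construct a dosage panel
#'
#' A dosage panel holds an additive genotype dosage matrix (samples x
#' variants, entries in \[0, 2\], `NA` = missing) together with variant
#' metadata.  Per-variant effect-allele frequency and dosage standard
#' deviation are computed over non-missing entries.
#'
#' @param dosages Numeric matrix, samples in rows, variants in columns.
#' @param sample_ids Character vector of sample identifiers.
#' @param variants Variant key data.frame (see [variant_key()]).
#' @return An object of class `dosage_panel`.
#' @export
dosage_panel <- function(dosages, sample_ids, variants) {
  dosages <- as.matrix(dosages)
  stopifnot(nrow(dosages) == length(sample_ids),
            ncol(dosages) == nrow(variants))
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("dosages must lie in [0, 2]")
  freq <- colMeans(dosages, na.rm = TRUE) / 2
  vsd <- apply(dosages, 2, stats::sd, na.rm = TRUE)
  vsd[is.na(vsd)] <- 0
  structure(list(dosages = dosages,
                 sample_ids = as.character(sample_ids),
                 variants = variants,
                 freq = unname(freq), sd = unname(vsd)),
            class = "dosage_panel")
}

#' @export
print.dosage_panel <- function(x, ...) {
  cat(sprintf("<dosage_panel> %d samples x %d variants (%d missing calls)\n",
              nrow(x$dosages), ncol(x$dosages), sum(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.dosage_panel <- function(x) dim(x$dosages)

#' Subset a dosage panel by samples and/or variants
#'
#' @param panel A `dosage_panel`.
#' @param samples,variants Index vectors (integer or logical); `NULL` keeps
#'   all.
#' @return A `dosage_panel` (frequencies and SDs recomputed on the subset).
#' @export
subset_panel <- function(panel, samples = NULL, variants = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(panel$dosages))
  if (is.null(variants)) variants <- seq_len(ncol(panel$dosages))
  dosage_panel(panel$dosages[samples, variants, drop = FALSE],
               panel$sample_ids[samples],
               panel$variants[variants, , drop = FALSE])
}

new_summary_set <- function(df) {
  stopifnot(all(c("chrom", "pos", "allele_effect", "allele_other",
                  "beta", "se", "z", "p", "freq", "n") %in% names(df)))
  class(df) <- c("summary_set", "data.frame")
  df
}

new_weight_set <- function(df, metadata = list()) {
  stopifnot(all(c("chrom", "pos", "allele_effect", "allele_other",
                  "weight") %in% names(df)))
  key <- paste(df$chrom, df$pos, sep = ":")
  if (anyDuplicated(key)) stop("duplicate variant keys in weight set")
  if (any(!is.finite(df$weight))) stop("weights must be finite")
  structure(df, class = c("weight_set", "data.frame"), metadata = metadata)
}

#' Create a weight set (a PRS model)
#'
#' @param variants Variant key data.frame.
#' @param weight Numeric vector of per-effect-allele-dose log-odds weights.
#' @param metadata Optional list (method name, hyperparameters, scale).
#' @return A `weight_set` data.frame.
#' @export
weight_set <- function(variants, weight, metadata = list()) {
  stopifnot(nrow(variants) == length(weight))
  df <- cbind(variants, data.frame(weight = as.numeric(weight)))
  new_weight_set(df, metadata)
}

# ---------------------------------------------------------------------------
# PLINK bed/bim/fam (bed v1.00, SNP-major)
# ---------------------------------------------------------------------------

#' Read a PLINK .bed/.bim/.fam fileset into a dosage panel
#'
#' Dosage counts the .bim A1 allele (stored as effect allele); missing
#' genotypes become `NA`.
#'
#' @param prefix Path prefix of the `.bed`/`.bim`/`.fam` triplet.
#' @return A `dosage_panel`.
#' @export
read_plink <- function(prefix) {
  bim <- data.table::fread(paste0(prefix, ".bim"), header = FALSE,
                           col.names = c("chrom", "id", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = list(character = c(1, 2, 5, 6)))
  fam <- data.table::fread(paste0(prefix, ".fam"), header = FALSE,
                           colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  bedpath <- paste0(prefix, ".bed")
  raw <- readBin(bedpath, "raw", n = file.size(bedpath))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file: bad magic number")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major bed v1.00 is supported")
  bpv <- ceiling(n / 4)
  if (length(raw) - 3 != bpv * m)
    stop(sprintf("bed payload size mismatch: expected %d bytes, found %d",
                 bpv * m, length(raw) - 3))
  body <- raw[-(1:3)]
  # decode all 2-bit genotype codes at once
  ints <- as.integer(body)
  codes <- rbind(bitwAnd(ints, 3L),
                 bitwAnd(bitwShiftR(ints, 2L), 3L),
                 bitwAnd(bitwShiftR(ints, 4L), 3L),
                 bitwAnd(bitwShiftR(ints, 6L), 3L))
  dim(codes) <- c(4L * bpv, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> missing
  lut <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  dos <- matrix(lut[codes + 1L], nrow = n, ncol = m)
  variants <- variant_key(bim$chrom, bim$pos, bim$a1, bim$a2, bim$id)
  dosage_panel(dos, fam[[2]], variants)
}

#' Write a dosage panel as a PLINK .bed/.bim/.fam fileset
#'
#' Dosages are rounded to hard calls (0/1/2); `NA` becomes the missing
#' genotype code.  The panel's effect allele is written as A1.
#'
#' @param panel A `dosage_panel`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  n <- nrow(panel$dosages); m <- ncol(panel$dosages)
  v <- panel$variants
  data.table::fwrite(data.table::data.table(v$chrom, v$id, 0L, v$pos,
                                            v$allele_effect, v$allele_other),
                     paste0(prefix, ".bim"), sep = "\t", col.names = FALSE)
  data.table::fwrite(data.table::data.table(panel$sample_ids,
                                            panel$sample_ids,
                                            0L, 0L, 0L, -9L),
                     paste0(prefix, ".fam"), sep = "\t", col.names = FALSE)
  g <- round(panel$dosages)
  code <- matrix(1L, n, m)                     # missing
  code[!is.na(g) & g == 2] <- 0L
  code[!is.na(g) & g == 1] <- 2L
  code[!is.na(g) & g == 0] <- 3L
  bpv <- ceiling(n / 4)
  pad <- 4L * bpv - n
  if (pad > 0) code <- rbind(code, matrix(3L, pad, m))  # pad as hom A2
  i1 <- seq(1, 4L * bpv, by = 4)
  bytes <- code[i1, , drop = FALSE] +
    bitwShiftL(code[i1 + 1L, , drop = FALSE], 2L) +
    bitwShiftL(code[i1 + 2L, , drop = FALSE], 4L) +
    bitwShiftL(code[i1 + 3L, , drop = FALSE], 6L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

# ---------------------------------------------------------------------------
# VCF
# ---------------------------------------------------------------------------

#' Read dosages from a VCF file
#'
#' Uses the `DS` FORMAT field as-is, or converts `GT` to an ALT-allele
#' count.  The effect allele is ALT.  Multi-allelic records are rejected.
#'
#' @param vcf_path Path to a VCF (optionally gzipped).
#' @param field `"DS"` or `"GT"`.
#' @return A `dosage_panel`.
#' @export
read_vcf_dosages <- function(vcf_path, field = c("DS", "GT")) {
  field <- match.arg(field)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("multi-allelic records are not supported; split them upstream")
  x <- vcfR::extract.gt(v, element = field)
  if (all(is.na(x)))
    stop(sprintf("FORMAT field %s absent from all records", field))
  if (field == "DS") {
    dos <- matrix(as.numeric(x), nrow = nrow(x))
  } else {
    cnt <- function(g) {
      if (is.na(g)) return(NA_real_)
      sum(strsplit(g, "[/|]")[[1]] == "1")
    }
    dos <- matrix(vapply(x, cnt, numeric(1)), nrow = nrow(x))
  }
  variants <- variant_key(fix[, "CHROM"], as.integer(fix[, "POS"]),
                          alt, fix[, "REF"],
                          ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                 paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                                 fix[, "ID"]))
  dosage_panel(t(dos), colnames(x), variants)
}

# ---------------------------------------------------------------------------
# Summary-statistic tables
# ---------------------------------------------------------------------------

#' Read a GWAS summary-statistic table
#'
#' Columns are resolved through `column_map`; an odds-ratio column is
#' log-transformed to beta.  `z` and `p` are recomputed from `beta/se`
#' (two-sided normal); if the file carries its own p-value column it is
#' checked against the recomputed one and a warning is issued on >10%
#' relative disagreement.  Rows with `se <= 0` are dropped with a message.
#'
#' @param tsv_path Path to a delimited text file.
#' @param column_map Named list mapping fields `chrom, pos, allele_effect,
#'   allele_other, beta` (or `or`), `se, freq, n` (and optionally `id, p,
#'   n_cases, n_controls`) to column names in the file.
#' @return A `summary_set` data.frame.
#' @export
read_summary_table <- function(tsv_path,
                               column_map = list(
                                 chrom = "chrom", pos = "pos",
                                 allele_effect = "effect_allele",
                                 allele_other = "other_allele",
                                 beta = "beta", se = "se",
                                 freq = "freq", n = "n")) {
  dt <- data.table::fread(tsv_path)
  need <- c("chrom", "pos", "allele_effect", "allele_other", "se",
            "freq", "n")
  for (f in need) {
    if (is.null(column_map[[f]]) || !column_map[[f]] %in% names(dt))
      stop(sprintf("column for field '%s' not resolvable", f))
  }
  has_beta <- !is.null(column_map[["beta"]]) &&
    column_map[["beta"]] %in% names(dt)
  has_or <- !is.null(column_map[["or"]]) && column_map[["or"]] %in% names(dt)
  if (!has_beta && !has_or) stop("need a beta or OR column")
  beta <- if (has_beta) as.numeric(dt[[column_map[["beta"]]]]) else
    log(as.numeric(dt[[column_map[["or"]]]]))
  se <- as.numeric(dt[[column_map[["se"]]]])
  bad <- !is.finite(se) | se <= 0
  if (any(bad)) {
    message(sprintf("dropping %d rows with se <= 0", sum(bad)))
    dt <- dt[!bad, ]; beta <- beta[!bad]; se <- se[!bad]
  }
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  if (!is.null(column_map[["p"]]) && column_map[["p"]] %in% names(dt)) {
    p0 <- as.numeric(dt[[column_map[["p"]]]])
    ok <- is.finite(p0) & p0 > 0
    rel <- abs(p[ok] - p0[ok]) / p0[ok]
    if (any(rel > 0.1))
      warning(sprintf(
        "%d rows: provided p disagrees with beta/se by >10%%",
        sum(rel > 0.1)))
  }
  getcol <- function(f, default) {
    if (!is.null(column_map[[f]]) && column_map[[f]] %in% names(dt))
      dt[[column_map[[f]]]] else default
  }
  id <- as.character(getcol("id", paste0(dt[[column_map[["chrom"]]]], ":",
                                         dt[[column_map[["pos"]]]])))
  df <- data.frame(
    chrom = as.character(dt[[column_map[["chrom"]]]]),
    pos = as.integer(dt[[column_map[["pos"]]]]),
    allele_effect =
      toupper(as.character(dt[[column_map[["allele_effect"]]]])),
    allele_other =
      toupper(as.character(dt[[column_map[["allele_other"]]]])),
    id = id, beta = beta, se = se, z = z, p = p,
    freq = as.numeric(dt[[column_map[["freq"]]]]),
    n = as.numeric(dt[[column_map[["n"]]]]),
    n_cases = as.numeric(getcol("n_cases", NA_real_)),
    n_controls = as.numeric(getcol("n_controls", NA_real_)),
    stringsAsFactors = FALSE)
  new_summary_set(df)
}

# ---------------------------------------------------------------------------
# Harmonization
# ---------------------------------------------------------------------------

is_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize a summary or weight set to a dosage panel
#'
#' Variants are matched on (chrom, pos).  When the target's effect allele
#' is the panel's other allele, the effect (beta or weight) sign is flipped
#' and any frequency reflected to `1 - f`.  Strand-ambiguous (A/T, C/G)
#' variants are dropped when `drop_ambiguous` is `TRUE` (the default for
#' cross-dataset use).  Harmonizing an already-aligned pair is a no-op.
#'
#' @param target A `summary_set` or `weight_set`.
#' @param panel A `dosage_panel`.
#' @param drop_ambiguous Drop strand-ambiguous variants?
#' @return A list with elements `target` (aligned rows, panel allele
#'   orientation), `panel_index` (column index into the panel for each
#'   aligned row), and `report` (counts and keys of exclusions).
#' @export
harmonize <- function(target, panel, drop_ambiguous = TRUE) {
  tk <- paste(target$chrom, target$pos, sep = ":")
  pk <- paste(panel$variants$chrom, panel$variants$pos, sep = ":")
  idx <- match(tk, pk)
  unmatched <- which(is.na(idx))
  keep <- !is.na(idx)
  t2 <- target[keep, , drop = FALSE]
  pi2 <- idx[keep]
  pv <- panel$variants[pi2, , drop = FALSE]
  same <- t2$allele_effect == pv$allele_effect &
    t2$allele_other == pv$allele_other
  swapped <- t2$allele_effect == pv$allele_other &
    t2$allele_other == pv$allele_effect
  mismatch <- !(same | swapped)
  ambig <- is_ambiguous(t2$allele_effect, t2$allele_other)
  drop <- mismatch | (drop_ambiguous & ambig)
  eff_col <- if ("weight" %in% names(t2)) "weight" else "beta"
  flip <- swapped & !drop
  if (any(flip)) {
    t2[[eff_col]][flip] <- -t2[[eff_col]][flip]
    if ("z" %in% names(t2)) t2$z[flip] <- -t2$z[flip]
    if ("freq" %in% names(t2)) t2$freq[flip] <- 1 - t2$freq[flip]
    t2$allele_effect[flip] <- pv$allele_effect[flip]
    t2$allele_other[flip] <- pv$allele_other[flip]
  }
  report <- list(n_matched = sum(!drop), n_flipped = sum(flip),
                 n_unmatched = length(unmatched),
                 n_ambiguous_dropped = sum(ambig & drop & !mismatch),
                 n_allele_mismatch = sum(mismatch),
                 unmatched_keys = tk[unmatched],
                 dropped_keys = paste(t2$chrom, t2$pos, sep = ":")[drop])
  list(target = t2[!drop, , drop = FALSE],
       panel_index = pi2[!drop], report = report)
}

# ---------------------------------------------------------------------------
# Weight files
# ---------------------------------------------------------------------------

#' Write a weight set to a TSV file
#'
#' Header: `snp  chrom  pos  effect_allele  other_allele  weight`; weights
#' are written with 12 significant digits so write/read round-trips are
#' lossless at that precision.
#'
#' @param ws A `weight_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(ws, path) {
  df <- data.frame(snp = ws$id, chrom = ws$chrom, pos = ws$pos,
                   effect_allele = ws$allele_effect,
                   other_allele = ws$allele_other,
                   weight = sprintf("%.12g", ws$weight))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a weight set from a TSV file written by [write_weights()]
#'
#' @param path Input path.
#' @return A `weight_set`.
#' @export
read_weights <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "chrom"))
  need <- c("snp", "chrom", "pos", "effect_allele", "other_allele",
            "weight")
  if (!all(need %in% names(dt))) stop("malformed weight file header")
  key <- paste(dt$snp, dt$chrom, dt$pos, sep = ":")
  if (anyDuplicated(key)) stop("duplicate variant rows in weight file")
  if (nrow(dt) == 0) {
    return(new_weight_set(data.frame(chrom = character(), pos = integer(),
                                     allele_effect = character(),
                                     allele_other = character(),
                                     id = character(), weight = numeric())))
  }
  v <- variant_key(dt$chrom, dt$pos, dt$effect_allele, dt$other_allele,
                   dt$snp)
  weight_set(v, as.numeric(dt$weight))
}
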