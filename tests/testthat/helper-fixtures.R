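# Shared fixture builders: everything is generated in code at test time.

# small case-control panel with signal
small_sim <- function(seed = 1, n = 600, m = 60, frac_causal = 0.1,
                      or_sd = 1.8, block_size = 10) {
  cfg <- sim_config(n_samples = n, n_variants = m,
                    block_size = block_size, frac_causal = frac_causal,
                    target_or_per_sd = or_sd, seed = seed)
  sim <- simulate_panel(cfg)
  ph <- simulate_phenotype(sim$panel, sim$truth, cfg)
  list(cfg = cfg, panel = sim$panel, truth = sim$truth,
       y = ph$phenotype, oracle_auc = ph$oracle_auc)
}

# tiny hand-built panel: 3 samples x 2 variants
tiny_panel <- function(dos = rbind(c(2, 1), c(1, 0), c(0, 2))) {
  dosage_panel(dos, c("s1", "s2", "s3"),
               variant_key(c("1", "1"), c(100L, 200L), c("A", "C"),
                           c("G", "T"), c("v1", "v2")))
}

# summary set built directly from vectors (shared allele frame A/G)
mk_summary <- function(beta, se, pos = seq_along(beta), chrom = "1",
                       freq = 0.3, n = 10000) {
  z <- beta / se
  new_ss <- data.frame(chrom = chrom, pos = as.integer(pos),
                       allele_effect = "A", allele_other = "G",
                       id = paste0("s", pos), beta = beta, se = se,
                       z = z, p = 2 * pnorm(-abs(z)), freq = freq,
                       n = n, n_cases = NA_real_, n_controls = NA_real_,
                       stringsAsFactors = FALSE)
  penprs:::new_summary_set(new_ss)
}

synthetic_schedule <- function() {
  read_risk_schedule(system.file("extdata", "synthetic_rates.csv",
                                 package = "penprs"))
}

tab3_counts <- function() {
  read.delim(system.file("extdata", "tab3_band_counts.tsv",
                         package = "penprs"), stringsAsFactors = FALSE)
}
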