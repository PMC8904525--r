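test_that("scoring is the dosage-weight inner product with mean
           imputation of missing calls", {
  panel <- dosage_panel(matrix(c(2, 1, 0), 1, 3), "s1",
                        variant_key(rep("1", 3), c(1L, 2L, 3L),
                                    rep("A", 3), rep("G", 3)))
  ws <- weight_set(panel$variants, c(0.1, -0.2, 0.5))
  expect_equal(score_panel(panel, ws)$raw_score, 0.0)
  # missing dosage contributes 2 * freq * weight
  dos <- rbind(c(2, 1), c(0, NA), c(1, 1), c(1, 0))
  p2 <- dosage_panel(dos, paste0("s", 1:4),
                     variant_key(c("1", "1"), c(1L, 2L), c("A", "A"),
                                 c("G", "G")))
  w2 <- weight_set(p2$variants, c(0.0, 1.0))
  f2 <- mean(dos[-2, 2]) / 2
  expect_equal(score_panel(p2, w2)$raw_score[2], 2 * f2 * 1.0)
  # zero overlap errors
  w3 <- weight_set(variant_key("9", 999L, "A", "G"), 0.3)
  expect_error(score_panel(p2, w3), "overlap")
})

test_that("allele-swapped weight files give identical standardized
           scores", {
  sim <- small_sim(seed = 91, n = 200, m = 20)
  set.seed(92)
  ws <- weight_set(sim$panel$variants, rnorm(20, 0, 0.1))
  sc1 <- standardize_scores(score_panel(sim$panel, ws))
  swapped <- sim$panel$variants
  tmp <- swapped$allele_effect
  swapped$allele_effect <- swapped$allele_other
  swapped$allele_other <- tmp
  ws2 <- weight_set(swapped, -ws$weight)
  sc2 <- standardize_scores(score_panel(sim$panel, ws2))
  # raw scores differ by a constant; standardized scores are identical
  expect_lt(diff(range(sc1$raw_score - sc2$raw_score)), 1e-12)
  expect_equal(sc1$std_score, sc2$std_score, tolerance = 1e-10)
})

test_that("standardization centers the reference group at (0, 1) and
           accepts external parameters verbatim", {
  sim <- small_sim(seed = 93, n = 300, m = 20)
  sc <- score_panel(sim$panel, weight_set(sim$panel$variants,
                                          rnorm(20, 0, 0.1)))
  controls <- sim$panel$sample_ids[sim$y == 0]
  std <- standardize_scores(sc, reference_ids = controls)
  ref <- std$std_score[std$sample_id %in% controls]
  expect_equal(mean(ref), 0, tolerance = 1e-12)
  expect_equal(sd(ref), 1, tolerance = 1e-12)
  ext <- standardize_scores(sc, center = 1.5, scale = 2)
  expect_equal(ext$std_score, (sc$raw_score - 1.5) / 2)
  expect_error(standardize_scores(rep(1, 10)), "zero")
})

test_that("AUC handles separation, ties and matches brute-force pair
           counting", {
  expect_equal(prs_auc(c(2, 3, 0, 1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(prs_auc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_equal(prs_auc(c(3, 1, 2, 0), c(1, 1, 0, 0))$auc, 0.75)
  expect_error(prs_auc(1:4, rep(1, 4)), "both classes")
  brute <- function(s, y) {
    cs <- s[y == 1]; ct <- s[y == 0]
    tot <- 0
    for (a in cs) for (b in ct)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(cs) * length(ct))
  }
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:200, 1)
    s <- sample(0:40, n, replace = TRUE)  # many ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(prs_auc(s, y)$auc, brute(s, y))
  }
})

test_that("DeLong interval covers the true AUC at roughly nominal rate", {
  set.seed(94)
  covered <- 0
  true_auc <- pnorm(0.5 / sqrt(2))
  for (r in 1:60) {
    s <- c(rnorm(150, 0.5), rnorm(150))
    y <- rep(c(1, 0), each = 150)
    ci <- prs_auc(s, y)$ci
    if (true_auc >= ci[1] && true_auc <= ci[2]) covered <- covered + 1
  }
  expect_gte(covered / 60, 0.85)
})

test_that("per-SD OR is location invariant and recovers a generative OR", {
  set.seed(95)
  z <- rnorm(20000)
  y <- rbinom(20000, 1, plogis(-1.5 + log(1.38) * z))
  o1 <- or_per_sd(z, y)
  o2 <- or_per_sd(z + 5, y)
  expect_equal(o1$or, o2$or, tolerance = 1e-8)
  expect_lt(abs(o1$log_or - log(1.38)), 3 * o1$se)
})

test_that("band ORs reproduce the printed percentile-band examples", {
  counts <- tab3_counts()
  lasso_uk <- counts[counts$model == "lasso" &
                       counts$ancestry == "european", ]
  bt <- band_or(counts = lasso_uk)
  expect_equal(round(bt$or[bt$label == "95-100"], 2), 2.23)
  expect_equal(round(bt$or[bt$label == "0-5"], 2), 0.42)
  expect_equal(bt$or[bt$label == "40-60"], 1)
  # equal case:control ratios give OR 1 everywhere
  eq <- data.frame(label = percentile_bands()$label,
                   cases = c(5, 5, 10, 20, 20, 20, 10, 5, 5) * 2,
                   controls = c(5, 5, 10, 20, 20, 20, 10, 5, 5) * 10)
  expect_equal(band_or(counts = eq)$or, rep(1, 9))
})

test_that("band ORs from scores equal band ORs from the induced counts", {
  set.seed(96)
  s <- rnorm(5000)
  y <- rbinom(5000, 1, plogis(-1 + 0.4 * s))
  bands <- percentile_bands()
  from_scores <- band_or(s, y, bands)
  from_counts <- band_or(counts = from_scores[, c("label", "cases",
                                                  "controls")],
                         bands = bands)
  expect_equal(from_scores$or, from_counts$or)
  expect_equal(from_scores$ci_low, from_counts$ci_low)
})

test_that("zero cells get a flagged continuity correction", {
  eq <- data.frame(label = percentile_bands()$label,
                   cases = c(0, 5, 10, 20, 20, 20, 10, 5, 5),
                   controls = rep(100, 9))
  bt <- band_or(counts = eq)
  expect_equal(bt$flag[1], "continuity_corrected")
  expect_true(is.finite(bt$or[1]) && bt$or[1] > 0)
})

test_that("theoretical band ORs obey the null, reciprocity and a
           quadrature oracle", {
  bands <- percentile_bands()
  expect_equal(theoretical_band_or(1, bands)$or, rep(1, 9))
  # symmetry: negating beta mirrors the band ORs (the reference band
  # 40-60 is symmetric about the median)
  up <- theoretical_band_or(1.38, bands)
  dn <- theoretical_band_or(1 / 1.38, bands)
  expect_equal(up$or[up$label == "95-100"],
               dn$or[dn$label == "0-5"], tolerance = 1e-10)
  expect_equal(up$or[up$label == "0-5"],
               dn$or[dn$label == "95-100"], tolerance = 1e-10)
  # quadrature oracle for the top band vs middle quintile
  beta <- log(1.38)
  num <- integrate(function(z) exp(beta * z) * dnorm(z),
                   qnorm(0.95), Inf)$value / 0.05
  den <- integrate(function(z) exp(beta * z) * dnorm(z),
                   qnorm(0.40), qnorm(0.60))$value / 0.2
  expect_equal(up$or[up$label == "95-100"], num / den, tolerance = 1e-6)
})

test_that("AUC and per-SD OR are invariant to positive affine maps", {
  set.seed(97)
  s <- rnorm(3000); y <- rbinom(3000, 1, plogis(-1 + 0.5 * s))
  s2 <- 3.2 * s + 7
  expect_equal(prs_auc(s, y)$auc, prs_auc(s2, y)$auc)
  z1 <- standardize_scores(s); z2 <- standardize_scores(s2)
  expect_equal(or_per_sd(z1, y)$or, or_per_sd(z2, y)$or,
               tolerance = 1e-8)
})
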