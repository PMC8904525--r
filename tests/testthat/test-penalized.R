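test_that("plr operator reproduces soft, firm, hard and enet regions", {
  # soft threshold (lasso, kap = 0)
  expect_equal(plr_threshold(5.0, penalty_spec(3.3, 0)), 1.7)
  # firm threshold (MCP): shrunk region and unshrunk region
  expect_equal(plr_threshold(4.0, penalty_spec(3.0, 0.5)), 2.0)
  expect_equal(plr_threshold(7.0, penalty_spec(3.0, 0.5)), 7.0)
  # elastic-net region (kap < 0): soft threshold then shrink by 1/(1-kap)
  expect_equal(plr_threshold(5.0, penalty_spec(3.3, -2.2)),
               (5 - 3.3) / 3.2)  # 0.53125
  # hard threshold limit
  expect_equal(plr_threshold(c(2.9, 3.1), penalty_spec(3.0, 1)),
               c(0, 3.1))
})

test_that("plr operator is odd, continuous for kap < 1, dead below lam", {
  xs <- seq(-8, 8, by = 0.01)
  for (kap in c(-2.2, -1, 0, 0.4, 0.9)) {
    spec <- penalty_spec(3.0, kap)
    v <- plr_threshold(xs, spec)
    expect_equal(v, -rev(plr_threshold(rev(-xs), spec)))       # odd
    expect_true(all(v[abs(xs) < 3] == 0))                      # dead zone
    expect_lt(max(abs(diff(v))), 0.011 * max(1, 1 / (1 - kap)) + 1e-9)
    # non-expansive outside the dead zone
    expect_true(all(abs(v) <= abs(xs) + 1e-12))
  }
  # kap -> 1- approaches hard thresholding pointwise away from lam
  v9 <- plr_threshold(c(2.0, 4.0), penalty_spec(3, 0.999))
  expect_equal(v9, c(0, 4.0), tolerance = 1e-2)
})

test_that("the enet-region operator minimizes its penalized quadratic", {
  # plr(x; lam, kap<0) should minimize 0.5(b-x)^2 + lam|b| - 0.5*kap*b^2
  for (x in c(5.0, -4.2, 2.0)) for (kap in c(-2.2, -0.7)) {
    got <- plr_threshold(x, penalty_spec(3.3, kap))
    ora <- optimize(function(b)
      0.5 * (b - x)^2 + 3.3 * abs(b) - 0.5 * kap * b^2,
      interval = c(-10, 10), tol = 1e-10)$minimum
    expect_equal(got, ora, tolerance = 1e-4)
  }
})

test_that("full shrinkage returns the intercept-only model", {
  sim <- small_sim(seed = 8)
  fit <- fit_penalized_logistic(sim$panel, sim$y, penalty_spec(50, 0))
  expect_equal(length(fit$active_set), 0)
  expect_equal(fit$intercept, qlogis(mean(sim$y)), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("lasso member matches an independent l1-logistic solver", {
  skip_if_not_installed("glmnet")
  for (seed in 1:6) {
    cfg <- sim_config(n_samples = 500, n_variants = 50, frac_causal = 0.2,
                      target_or_per_sd = 2, seed = seed)
    sim <- simulate_panel(cfg)
    y <- simulate_phenotype(sim$panel, sim$truth, cfg)$phenotype
    lam <- 2.5
    fit <- fit_penalized_logistic(sim$panel, y, penalty_spec(lam, 0),
                                  tol = 1e-9, max_iter = 5000)
    X <- sim$panel$dosages
    n <- nrow(X)
    mu <- colMeans(X); sdn <- sqrt(colMeans(X^2) - mu^2)
    Xs <- scale(X, center = mu, scale = sdn)
    g <- glmnet::glmnet(Xs, y, family = "binomial",
                        lambda = lam / (2 * sqrt(n)),
                        standardize = FALSE, thresh = 1e-14)
    expect_lt(max(abs(fit$beta_std - as.numeric(coef(g))[-1])), 1e-4)
  }
})

test_that("single-variant lasso fit matches a 1-D numeric minimizer", {
  sim <- small_sim(seed = 12, n = 400, m = 1, frac_causal = 1, or_sd = 2,
                   block_size = 1)
  y <- sim$y
  lam <- 1.5
  fit <- fit_penalized_logistic(sim$panel, y, penalty_spec(lam, 0),
                                tol = 1e-10, max_iter = 5000)
  x <- sim$panel$dosages[, 1]
  n <- length(y)
  xs <- (x - mean(x)) / sqrt(mean(x^2) - mean(x)^2)
  pen <- lam * sqrt(n) / 2   # penalty on |beta_std| implied by the z-scale
  obj <- function(th) {
    eta <- th[1] + th[2] * xs
    -sum(y * eta - log1p(exp(eta))) + pen * abs(th[2])
  }
  ora <- optim(c(qlogis(mean(y)), 0), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$par
  expect_equal(fit$beta_std[1], ora[2], tolerance = 1e-4)
})

test_that("windows tile chromosomes with the configured span and overlap", {
  w <- penprs:::tile_windows(c(0, 12e6), 5.5e6, 5e5)
  expect_equal(length(w), 3)
  expect_equal(w[[1]], c(0, 5.5e6))
  expect_equal(w[[2]], c(5.0e6, 10.5e6))
  expect_equal(w[[3]], c(10.0e6, 15.5e6))
  # short chromosome: one window
  expect_equal(length(penprs:::tile_windows(c(100, 2e6), 5.5e6, 5e5)), 1)
})

test_that("stage-1 selection dedups across overlapping windows and has
           power for strong common causal variants", {
  cfg <- sim_config(n_samples = 1200, n_variants = 120, block_size = 15,
                    frac_causal = 0.05, target_or_per_sd = 2.2, seed = 31)
  sim <- simulate_panel(cfg)
  y <- simulate_phenotype(sim$panel, sim$truth, cfg)$phenotype
  sel <- stage1_window_select(sim$panel, y,
                              window_config(3e6, 1e6), grid_config())
  expect_equal(sel, sort(unique(sel)))       # deduplicated
  expect_true(all(sel %in% seq_len(120)))
  # the strongest causal signal is recovered
  ss <- single_variant_assoc(sim$panel, y)
  expect_true(which.max(abs(ss$z)) %in% sel)
})

test_that("stage-2 warm-started kappa path reproduces cold starts", {
  sim <- small_sim(seed = 14, n = 500, m = 40, frac_causal = 0.2,
                   or_sd = 2)
  gcfg <- grid_config(stage2_lam = c(3.0, 3.5),
                      stage2_kap = c(-1, -0.5, 0, 0.5))
  path <- stage2_path_fit(sim$panel, sim$y, gcfg)
  expect_equal(length(path$fits), 2)
  expect_equal(length(path$fits[["3"]]), 4)
  for (lam in c("3", "3.5")) for (kap in c("-1", "-0.5", "0.5")) {
    warm <- path$fits[[lam]][[kap]]
    cold <- fit_penalized_logistic(sim$panel, sim$y,
                                   penalty_spec(as.numeric(lam),
                                                as.numeric(kap)))
    expect_lt(max(abs(warm$beta_std - cold$beta_std)), 1e-4)
  }
})

test_that("hard-threshold member selects |z| >= lam on orthogonal designs", {
  # orthogonal standardized design: independent variants, large n
  cfg <- sim_config(n_samples = 4000, n_variants = 30, block_size = 1,
                    r_adjacent = 0, frac_causal = 0.3,
                    target_or_per_sd = 1.6, seed = 41)
  sim <- simulate_panel(cfg)
  y <- simulate_phenotype(sim$panel, sim$truth, cfg)$phenotype
  lam <- 3.5
  fit <- fit_penalized_logistic(sim$panel, y, penalty_spec(lam, 1),
                                warm = fit_penalized_logistic(
                                  sim$panel, y, penalty_spec(lam, 0)))
  ss <- single_variant_assoc(sim$panel, y)
  marg <- which(abs(ss$z) >= lam)
  # near-orthogonality: active set matches the marginal z threshold
  expect_true(all(fit$active_set %in% which(abs(ss$z) >= lam - 0.35)))
  expect_true(all(which(abs(ss$z) >= lam + 0.35) %in% fit$active_set))
})

test_that("active set size is non-increasing in lambda for the lasso", {
  sim <- small_sim(seed = 16, n = 800, m = 50, frac_causal = 0.3,
                   or_sd = 2)
  sizes <- sapply(seq(2, 5, by = 0.5), function(lam)
    length(fit_penalized_logistic(sim$panel, sim$y,
                                  penalty_spec(lam, 0))$active_set))
  expect_true(all(diff(sizes) <= 0))
})

test_that("cross-validated grid search is deterministic under the seed", {
  sim <- small_sim(seed = 18, n = 500, m = 60, frac_causal = 0.1,
                   or_sd = 2)
  gcfg <- grid_config(stage2_lam = c(3, 4), stage2_kap = c(-0.5, 0, 1),
                      folds = 3, seed = 77)
  cv1 <- cross_validate_grid(sim$panel, sim$y, gcfg = gcfg)
  cv2 <- cross_validate_grid(sim$panel, sim$y, gcfg = gcfg)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$auc_grid, cv2$auc_grid)
  expect_equal(cv1$best$lam, cv2$best$lam)
  expect_equal(cv1$best$kap, cv2$best$kap)
  # fold split is stratified: case fraction equal across folds
  cf <- tapply(sim$y, cv1$folds, mean)
  expect_lt(diff(range(cf)), 0.02)
})

test_that("printed stage-2 grid has 26 x 41 points", {
  g <- grid_config()
  expect_equal(length(g$stage2_lam), 26)
  expect_equal(length(g$stage2_kap), 41)
  expect_equal(length(g$stage2_lam) * length(g$stage2_kap), 1066)
})
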