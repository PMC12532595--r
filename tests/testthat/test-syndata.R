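test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(block_rho = 1), "block_rho")
  expect_error(sim_config(h2_bag = 1), "h2_bag")
  expect_error(sim_config(n_causal = 50, n_variants = 20), "n_causal")
})

test_that("independent blocks give uncorrelated dosages at the target MAF", {
  cfg <- sim_config(n_individuals = 2000, n_variants = 20,
                    ld_block_size = 1, block_rho = 0,
                    maf_range = c(0.5, 0.5), seed = 1)
  panel <- simulate_genotypes(cfg)
  r <- cor(panel$dosages)
  expect_lt(max(abs(r[upper.tri(r)])), 4 / sqrt(2000))
  expect_equal(unname(colMeans(panel$dosages) / 2), rep(0.5, 20),
               tolerance = 0.05)
})

test_that("dosages respect ploidy bounds and positions increase", {
  cfg <- sim_config(n_individuals = 200, n_variants = 60, seed = 2)
  panel <- simulate_genotypes(cfg)
  expect_true(all(panel$dosages >= 0 & panel$dosages <= 2))
  for (ch in unique(panel$variants$chrom)) {
    pos <- panel$variants$pos[panel$variants$chrom == ch]
    expect_true(all(diff(pos) > 0))
  }
  py <- simulate_genotypes(cfg, ploidy_class = "chrY")
  expect_true(all(py$dosages >= 0 & py$dosages <= 1))
})

test_that("AR(1) block LD matches a direct latent-model oracle", {
  rho <- 0.9
  cfg <- sim_config(n_individuals = 5000, n_variants = 10, n_causal = 2,
                    ld_block_size = 10, block_rho = rho,
                    maf_range = c(0.3, 0.3), seed = 3)
  panel <- simulate_genotypes(cfg)
  r2_obs <- mean(diag(cor(panel$dosages)[-1, -10])^2)

  # oracle: simulate the same latent model directly, independent code path
  set.seed(99)
  n <- 200000
  thr <- qnorm(0.3)
  d1 <- d2 <- 0
  z1a <- rnorm(n); z2a <- rho * z1a + sqrt(1 - rho^2) * rnorm(n)
  z1b <- rnorm(n); z2b <- rho * z1b + sqrt(1 - rho^2) * rnorm(n)
  g1 <- (z1a < thr) + (z1b < thr)
  g2 <- (z2a < thr) + (z2b < thr)
  r2_oracle <- cor(g1, g2)^2
  expect_equal(r2_obs, r2_oracle, tolerance = 0.02)
})

test_that("per-variant genotype frequencies satisfy Hardy-Weinberg", {
  cfg <- sim_config(n_individuals = 5000, n_variants = 100,
                    maf_range = c(0.1, 0.5), seed = 4)
  panel <- simulate_genotypes(cfg)
  hwp <- apply(panel$dosages, 2, function(d) {
    obs <- tabulate(d + 1, 3)
    p <- mean(d) / 2
    expct <- 5000 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    suppressWarnings(chisq.test(x = obs, p = expct / 5000)$p.value)
  })
  expect_gte(mean(hwp > 0.001), 0.99)
})

test_that("identical config reproduces byte-identical outputs", {
  cfg <- sim_config(n_individuals = 100, n_variants = 40, seed = 5)
  p1 <- simulate_genotypes(cfg); p2 <- simulate_genotypes(cfg)
  expect_identical(p1, p2)
  s1 <- simulate_cohort(p1, cfg); s2 <- simulate_cohort(p2, cfg)
  expect_identical(s1, s2)
  e1 <- simulate_exposure_gwas(p1, cfg, n_instruments = 2)
  e2 <- simulate_exposure_gwas(p2, cfg, n_instruments = 2)
  expect_identical(e1, e2)
})

test_that("null heritability leaves causal dosages unassociated with BAG", {
  cfg <- sim_config(n_individuals = 1500, n_variants = 100, h2_bag = 0,
                    seed = 6)
  panel <- simulate_genotypes(cfg)
  sim <- simulate_cohort(panel, cfg)
  tvals <- sapply(sim$architecture$causal_ids, function(id) {
    f <- summary(lm(sim$cohort$bag_true ~ panel$dosages[, id]))
    f$coefficients[2, 3]
  })
  expect_gte(mean(abs(tvals) < 3), 0.95)
})

test_that("noiseless features linearly encode age plus BAG", {
  cfg <- sim_config(n_individuals = 300, n_variants = 40,
                    n_features_per_tissue = 15, feature_noise_sd = 0,
                    seed = 7)
  panel <- simulate_genotypes(cfg)
  sim <- simulate_cohort(panel, cfg)
  fit <- lm(sim$signal ~ sim$features_gm)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # perfect-fit warning
  expect_gt(r2, 0.999)
})

test_that("mediated omics fixtures give exact SMR ratios at zero noise", {
  s <- small_sim()
  fx <- simulate_omics_fixtures(s$panel, s$sim$architecture, s$cfg,
                                b_xy = 0.4, smr_noise_sd = 0)
  for (g in fx$manifest$gene) {
    er <- fx$eqtl_records[fx$eqtl_records$gene == g, ]
    oc <- fx$smr_outcome[match(er$variant, fx$smr_outcome$id), ]
    expect_equal(oc$beta / er$beta_zx, rep(0.4, nrow(er)), tolerance = 1e-12)
  }
})

test_that("gene fixtures are sorted, non-overlapping; GO genes exist", {
  s <- small_sim()
  fx <- simulate_omics_fixtures(s$panel, s$sim$architecture, s$cfg)
  for (ch in unique(fx$genes$chrom)) {
    g <- fx$genes[fx$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(diff(g$start) > 0))
    if (nrow(g) > 1)
      expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  go_genes <- unique(unlist(strsplit(fx$go$genes, ",")))
  expect_true(all(go_genes %in% fx$genes$symbol))
  # one root per aspect, no term is its own ancestor
  roots <- fx$go$term[fx$go$parents == ""]
  expect_length(roots, 3)
})

test_that("multi-tissue lookup boundary records filter as constructed", {
  s <- small_sim()
  fx <- simulate_omics_fixtures(s$panel, s$sim$architecture, s$cfg)
  pass_rule <- vapply(split(fx$multi_tissue,
                            paste(fx$multi_tissue$gene,
                                  fx$multi_tissue$variant)),
                      function(d) d$n_tissues[1] >= 10 &&
                        mean(d$m_value >= 0.9) >= 0.5 && d$re2_p[1] < 5e-8,
                      logical(1))
  key <- paste(fx$multi_tissue$gene, fx$multi_tissue$variant)
  expected <- fx$multi_tissue_pass[match(names(pass_rule),
                                         unique(key))]
  expect_equal(unname(pass_rule), expected)
})

test_that("exposure GWAS has powered instruments and independent errors", {
  cfg <- sim_config(n_individuals = 500, n_variants = 600,
                    ld_block_size = 15, seed = 8)
  panel <- simulate_genotypes(cfg)
  eg <- simulate_exposure_gwas(panel, cfg, n_instruments = 30,
                               b_xy_true = 0.5)
  psig <- eg$exposure$p[match(eg$instruments, eg$exposure$id)]
  expect_gte(mean(psig < 5e-8), 0.9)
  expect_lt(abs(cor(eg$internals$err_x, eg$internals$err_y)), 0.1)
  expect_error(simulate_exposure_gwas(panel, cfg, n_instruments = 1000),
               "independent blocks")
})
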