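test_that("dosage GWAS matches the lm() closed form on a toy", {
  dos <- matrix(c(0, 1, 2, 0, 1, 2,
                  1, 1, 0, 2, 0, 1), 6, 2)
  colnames(dos) <- c("vA", "vB")
  panel <- structure(list(
    variants = data.frame(chrom = "1", pos = c(100L, 200L),
                          id = c("vA", "vB"), a1 = "A", a2 = "G",
                          maf = 0.4, ploidy_class = "diploid", info = 1),
    dosages = dos), class = "genotype_panel")
  y <- c(1.2, 0.5, 2.3, 0.1, 1.8, 2.9)
  cov <- data.frame(x = c(0.3, -1, 0.2, 0.5, -0.7, 1.1))
  res <- gwas_linear(panel, y, cov)
  for (j in 1:2) {
    fit <- summary(lm(y ~ dos[, j] + cov$x))$coefficients
    expect_equal(res$beta[j], fit[2, 1], tolerance = 1e-10)
    expect_equal(res$se[j], fit[2, 2], tolerance = 1e-10)
    expect_equal(res$p[j], fit[2, 4], tolerance = 1e-10)
  }
})

test_that("monomorphic variants yield flagged NA rows, not silent drops", {
  dos <- cbind(v1 = c(0, 1, 2, 1, 0, 2), v2 = rep(1, 6))
  panel <- structure(list(
    variants = data.frame(chrom = "1", pos = c(1L, 2L), id = c("v1", "v2"),
                          a1 = "A", a2 = "G", maf = 0.5,
                          ploidy_class = "diploid", info = 1),
    dosages = dos), class = "genotype_panel")
  res <- gwas_linear(panel, rnorm(6))
  expect_equal(nrow(res), 2)
  expect_true(is.na(res$beta[2]))
  expect_equal(res$reason[2], "monomorphic")
  expect_error(gwas_linear(panel, rnorm(6),
                           data.frame(a = 1:6, b = 2 * (1:6))),
               "rank deficient")
})

test_that("adjusted-phenotype GWAS equals covariate-in-model GWAS (FWL)", {
  s <- small_sim()
  covs <- default_covariates(s$sim$cohort)
  y <- s$sim$cohort$bag_true
  y_adj <- as.vector(bagwas:::residualize(y, bagwas:::covariate_matrix(covs)))
  r1 <- gwas_linear(s$panel, y, covs)
  r2 <- gwas_linear(s$panel, y_adj, covs)
  expect_equal(r1$beta / r1$se, r2$beta / r2$se, tolerance = 1e-6)
})

test_that("IVW meta reproduces hand-computed combinations", {
  mk <- function(b, se, n = 1000, a1 = "A", a2 = "G", freq = 0.3)
    data.frame(chrom = "1", pos = 50L, id = "v1", a1 = a1, a2 = a2,
               freq_a1 = freq, beta = b, se = se, z = b / se,
               p = 2 * pnorm(-abs(b / se)), n = n)
  # identical duplicate study: same beta, se / sqrt(2)
  m <- ivw_meta(list(mk(0.1, 0.1), mk(0.1, 0.1)), apply_filters = FALSE)
  expect_equal(m$beta, 0.1)
  expect_equal(m$se, 0.1 / sqrt(2))
  # hand-computed IVW: w = (100, 25)
  m2 <- ivw_meta(list(mk(0.1, 0.1), mk(0.3, 0.2)), apply_filters = FALSE)
  expect_equal(m2$beta, 0.14, tolerance = 1e-12)
  expect_equal(m2$se, 0.089443, tolerance = 1e-5)
  # allele harmonization: swapped alleles with negated beta are identical
  m3 <- ivw_meta(list(mk(0.1, 0.1),
                      mk(-0.3, 0.2, a1 = "G", a2 = "A", freq = 0.7)),
                 apply_filters = FALSE)
  expect_equal(m3$beta, m2$beta)
  expect_equal(m3$se, m2$se)
})

test_that("meta filters remove low-n and heterogeneous variants with a manifest", {
  mk <- function(id, pos, b1, b2, n1 = 1000, n2 = 1000) {
    list(data.frame(chrom = "1", pos = pos, id = id, a1 = "A", a2 = "G",
                    freq_a1 = 0.3, beta = b1, se = 0.05, z = b1 / 0.05,
                    p = 1, n = n1),
         data.frame(chrom = "1", pos = pos, id = id, a1 = "A", a2 = "G",
                    freq_a1 = 0.3, beta = b2, se = 0.05, z = b2 / 0.05,
                    p = 1, n = n2))
  }
  rows1 <- mk("v1", 1L, 0.1, 0.1)
  rows2 <- mk("v2", 2L, 0.1, 0.9)            # Q = 64, p ~ 1e-15
  rows3 <- mk("v3", 3L, 0.1, 0.1, 100, 100)  # low n
  t1 <- rbind(rows1[[1]], rows2[[1]], rows3[[1]])
  t2 <- rbind(rows1[[2]], rows2[[2]], rows3[[2]])
  m <- ivw_meta(list(t1, t2))
  expect_equal(m$id, "v1")
  flt <- attr(m, "filtered")
  expect_setequal(flt$id, c("v2", "v3"))
})

test_that("stepwise conditional selection recovers planted signals exactly", {
  lf <- ldfree_panel(n = 900, m = 30, seed = 13)
  set.seed(13)
  y <- 0.8 * lf$panel$dosages[, "v0005"] + rnorm(900)
  ss <- gwas_linear(lf$panel, y)
  iv <- stepwise_conditional(ss, lf$panel, y, p_threshold = 5e-8)
  expect_equal(iv$id, "v0005")
  expect_equal(iv$cond_beta, iv$beta, tolerance = 1e-12)
  expect_equal(iv$cond_p, iv$p, tolerance = 1e-12)
  # no signal below threshold -> empty, not an error
  yp <- sample(y)
  ssp <- gwas_linear(lf$panel, yp)
  iv0 <- stepwise_conditional(ssp, lf$panel, yp, p_threshold = 5e-8)
  expect_equal(nrow(iv0), 0)
  expect_equal(nrow(stepwise_conditional(ss[0, ], lf$panel, y)), 0)
})

test_that("two causal variants in LD are both selected with joint OLS stats", {
  cfg <- sim_config(n_individuals = 2000, n_variants = 20, n_causal = 2,
                    ld_block_size = 20, block_rho = 0.55, seed = 21)
  panel <- simulate_genotypes(cfg)
  set.seed(21)
  d1 <- panel$dosages[, 3]; d2 <- panel$dosages[, 15]
  y <- 0.5 * d1 + 0.5 * d2 + rnorm(2000)
  ss <- gwas_linear(panel, y)
  iv <- stepwise_conditional(ss, panel, y, p_threshold = 5e-8,
                             collinearity = 0.9)
  expect_setequal(iv$id, c("v0003", "v0015"))
  # joint two-variant OLS oracle
  fit <- summary(lm(y ~ d1 + d2))$coefficients
  expect_equal(iv$cond_beta[match("v0003", iv$id)], fit[2, 1],
               tolerance = 1e-8)
  expect_equal(iv$cond_beta[match("v0015", iv$id)], fit[3, 1],
               tolerance = 1e-8)
})

test_that("cross-trait clumping groups correlated hits and flags novelty", {
  lf <- ldfree_panel(n = 1200, m = 15, seed = 31)
  iv <- data.frame(id = c("v0001", "v0002", "v0003"),
                   trait = c("gm", "wm", "combined"),
                   chrom = "1",
                   pos = lf$panel$variants$pos[1:3],
                   p = c(1e-10, 1e-9, 1e-12))
  iv$chrom <- lf$panel$variants$chrom[1:3]
  # LD-free: every index variant is its own locus
  lt <- clump_and_flag(iv, lf$panel)
  expect_equal(nrow(lt), 3)
  expect_true(all(lt$novel))
  # known list containing a lead variant
  lt2 <- clump_and_flag(iv, lf$panel, known_list = "v0003")
  expect_false(lt2$novel[lt2$lead_id == "v0003"])
  expect_warning(clump_and_flag(iv, lf$panel, known_list = "rs_unknown"),
                 "not in panel")
})

test_that("correlated significant variants collapse to one locus, as brute force", {
  cfg <- sim_config(n_individuals = 1500, n_variants = 10, n_causal = 1,
                    ld_block_size = 10, block_rho = 0.97,
                    maf_range = c(0.45, 0.5), seed = 33)
  panel <- simulate_genotypes(cfg)
  iv <- data.frame(id = c("v0002", "v0003", "v0004"), trait = "gm",
                   chrom = panel$variants$chrom[2:4],
                   pos = panel$variants$pos[2:4],
                   p = c(1e-9, 1e-11, 1e-8))
  r2 <- bagwas:::dosage_r2(panel$dosages[, iv$id])
  expect_true(all(r2[upper.tri(r2)] > 0.5))
  lt <- clump_and_flag(iv, panel)
  expect_equal(nrow(lt), 1)
  expect_equal(lt$lead_id, "v0003")  # smallest p leads
  # brute force: greedy enumeration in p order
  ord <- iv[order(iv$p), ]
  expect_equal(lt$lead_id, ord$id[1])
  expect_equal(lt$n_members, 3)
})
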