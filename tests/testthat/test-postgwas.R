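test_that("variant-to-gene mapping follows the category precedence", {
  tg <- toy_genes()
  # inside an exon of GA
  expect_equal(map_variant_to_gene("1", 1600, tg$genes, tg$exons),
               list(category = "exonic", gene = "GA"))
  # inside the UTR feature
  expect_equal(map_variant_to_gene("1", 1100, tg$genes, tg$exons),
               list(category = "UTR", gene = "GA"))
  # in the intron, 2 bp from an exon boundary: splice region
  expect_equal(map_variant_to_gene("1", 1802, tg$genes, tg$exons)$category,
               "splice")
  # deep intronic
  expect_equal(map_variant_to_gene("1", 2100, tg$genes, tg$exons)$category,
               "intronic")
  # 500 bp upstream of GB (strand -) but intergenic elsewhere
  up <- map_variant_to_gene("1", 9500, tg$genes, tg$exons)
  expect_equal(up$gene, "GB")
  expect_equal(up$category, "upstream")  # 3' end is at 9000, strand "-"
  # intergenic: nearest gene wins
  ig <- map_variant_to_gene("1", 4800, tg$genes, tg$exons)
  expect_equal(ig$category, "intergenic")
  expect_equal(ig$gene, "GB")
  expect_error(map_variant_to_gene("1", 100, tg$genes[0, ]), "empty")
})

test_that("variants inside a gene outrank a nearby gene's flank", {
  genes <- data.frame(chrom = "1", start = c(100L, 2000L),
                      end = c(900L, 5000L), strand = c("+", "+"),
                      symbol = c("A", "B"))
  # 500 bp downstream of A yet inside B: intronic in B wins by precedence
  r <- map_variant_to_gene("1", 2500, genes)
  expect_equal(r, list(category = "intronic", gene = "B"))
  # exact-tie intergenic: smaller start coordinate wins
  genes2 <- data.frame(chrom = "1", start = c(100L, 4100L),
                       end = c(1000L, 5000L), strand = "+",
                       symbol = c("A", "B"))
  expect_equal(map_variant_to_gene("1", 2550, genes2)$gene, "A")
})

test_that("ABF credible sets normalize PIPs and honor the assignment rule", {
  ss1 <- data.frame(id = "v1", pos = 100L, beta = 0.3, se = 0.05,
                    p = 2e-9)
  cs1 <- abf_credible_set(ss1, "v1")
  expect_equal(cs1$variants$pip, 1)
  expect_true(cs1$variants$in_set)
  # two variants with identical z and se split the posterior evenly
  ss2 <- data.frame(id = c("v1", "v2"), pos = c(100L, 200L),
                    beta = c(0.3, 0.3), se = c(0.05, 0.05),
                    p = c(2e-9, 2e-9))
  cs2 <- abf_credible_set(ss2, "v1")
  expect_equal(cs2$variants$pip, c(0.5, 0.5))
  expect_true(all(cs2$variants$in_set))
  expect_equal(sum(cs2$variants$pip), 1, tolerance = 1e-10)
  expect_error(abf_credible_set(ss1, "v1", prior_sd = 0), "prior_sd")
})

test_that("assignment requires a significant strong-LD credible variant", {
  s <- small_sim()
  covs <- default_covariates(s$sim$cohort)
  ss <- gwas_linear(s$panel, s$sim$cohort$bag_true, covs)
  top <- ss$id[which.min(ss$p)]
  blk <- s$panel$variants$block[match(top, s$panel$variants$id)]
  loc <- ss[s$panel$variants$block == blk, ]
  cs <- abf_credible_set(loc, top, s$panel)
  expect_equal(sum(cs$variants$pip), 1, tolerance = 1e-10)
  if (min(loc$p) < 5e-8) expect_true(cs$assigned)
  # an index with no significant credible variant cannot be assigned
  weak <- ss[s$panel$variants$block == blk, ]
  weak$p <- pmax(weak$p, 1e-6)
  cs2 <- abf_credible_set(weak, top, s$panel)
  expect_false(cs2$assigned)
})

test_that("SMR ratio and delta-method SE match hand calculations", {
  er <- data.frame(gene = "G", variant = "v1", tissue = "t",
                   beta_zx = 0.20, se_zx = 0.02, p = 1e-23)
  oc <- data.frame(id = "v1", beta = 0.05, se = 0.01)
  r <- smr_heidi(er, oc)
  expect_equal(r$beta_xy, 0.25)
  expect_equal(r$se_xy, 0.25 * sqrt(0.01^2 / 0.05^2 + 0.02^2 / 0.20^2))
  expect_equal(r$se_xy, 0.055902, tolerance = 1e-5)
  # no valid instrument: skipped with a message
  er2 <- transform(er, p = 1e-4)
  expect_message(r2 <- smr_heidi(er2, oc), "skipped")
  expect_null(r2)
})

test_that("HEIDI separates mediation from linkage", {
  set.seed(5)
  cfg <- sim_config(n_individuals = 3000, n_variants = 12, n_causal = 2,
                    ld_block_size = 12, block_rho = 0.8,
                    maf_range = c(0.2, 0.5), seed = 44)
  panel <- simulate_genotypes(cfg)
  ids <- panel$variants$id
  n_med <- 0; n_link <- 0; B <- 25
  for (b in seq_len(B)) {
    bzx <- rnorm(6, 0.4, 0.03)
    er <- data.frame(gene = "G", variant = ids[1:6], tissue = "t",
                     beta_zx = bzx, se_zx = 0.01,
                     p = 2 * pnorm(-abs(bzx / 0.01)))
    # mediation: outcome proportional to exposure effect (plus noise)
    oc_med <- data.frame(id = ids[1:6],
                         beta = 0.5 * bzx + rnorm(6, 0, 0.004),
                         se = 0.004)
    r_med <- smr_heidi(er, oc_med, panel)
    if (!is.na(r_med$p_heidi) && r_med$p_heidi > 0.01) n_med <- n_med + 1
    # linkage: outcome driven by a second causal variant, not expression
    r_ld <- cor(panel$dosages[, 1:6], panel$dosages[, 10])
    oc_link <- data.frame(id = ids[1:6],
                          beta = 0.25 * as.vector(r_ld) + rnorm(6, 0, 0.004),
                          se = 0.004)
    r_link <- smr_heidi(er, oc_link, panel)
    if (!is.na(r_link$p_heidi) && r_link$p_heidi < 0.01) n_link <- n_link + 1
  }
  expect_gte(n_med / B, 0.9)
  expect_gte(n_link / B, 0.8)
})

test_that("SMR retention combines FDR and HEIDI filters", {
  s <- small_sim()
  fx <- simulate_omics_fixtures(s$panel, s$sim$architecture, s$cfg,
                                smr_noise_sd = 0)
  tab <- smr_table(fx$eqtl_records, fx$smr_outcome, s$panel)
  expect_true(all(tab$passes))
  expect_equal(tab$beta_xy, rep(0.4, nrow(tab)), tolerance = 1e-10)
  expect_true(all(tab$fdr < 0.05))
})

test_that("gene nomination fills the seven categories with the stated rules", {
  s <- small_sim()
  fx <- simulate_omics_fixtures(s$panel, s$sim$architecture, s$cfg,
                                smr_noise_sd = 0)
  covs <- default_covariates(s$sim$cohort)
  ss <- gwas_linear(s$panel, s$sim$cohort$bag_true, covs)
  # focus on the first mediated locus
  idx <- fx$manifest$variant[1]
  blk <- s$panel$variants$block[match(idx, s$panel$variants$id)]
  loc <- ss[s$panel$variants$block == blk, ]
  cs <- abf_credible_set(loc, idx, s$panel)
  smr_eq <- smr_table(fx$eqtl_records, fx$smr_outcome, s$panel)
  nm <- nominate_genes(cs, fx, smr_eqtl = smr_eq, panel = s$panel)
  expect_true(all(nm$category %in% 1:7))
  # PoPS: never more than 3 genes nominated
  expect_lte(sum(nm$category == 7), 3)
  # ranks are competition ranks within category
  for (j in 2:7) {
    sub <- nm[nm$category == j, ]
    if (nrow(sub) > 0) expect_equal(min(sub$rank), 1)
  }
  # multi-tissue boundary records: only (gene, variant) pairs passing the
  # stated filters can enter category 6
  mt <- fx$multi_tissue
  key <- paste(mt$gene, mt$variant)
  pass_genes <- unique(mt$gene[key %in% unique(key)[fx$multi_tissue_pass]])
  in6 <- nm$gene[nm$category == 6]
  expect_true(all(in6 %in% pass_genes))
})

test_that("priority score matches the rank formula and telescopes to one", {
  # per-category contributions over ranks 1..n sum to exactly 1
  for (n_j in c(1, 3, 7)) {
    contrib <- 2 * (n_j + 1 - seq_len(n_j)) / (n_j * (n_j + 1))
    expect_equal(sum(contrib), 1)
  }
  nm <- data.frame(locus_id = 1,
                   gene = c("A", "B", "C", "A", "B", "C"),
                   category = c(2, 2, 2, 1, 1, 1),
                   score = c(30, 20, 10, 0.5, 0.3, 0.2),
                   rank = c(1, 2, 3, NA, NA, NA))
  pr <- priority_score(nm)
  sc <- pr$scores
  expect_equal(sc$p_i[sc$gene == "A"], 0.5 + 0.5)
  expect_equal(sc$p_i[sc$gene == "B"], 0.3 + 1 / 3, tolerance = 1e-9)
  expect_equal(sc$p_i[sc$gene == "C"], 0.2 + 1 / 6, tolerance = 1e-9)
  expect_equal(pr$winner, "A")
  # rank 1 in all six categories with n_j = 1, C_i = 0.8 -> P = 6.8
  nm2 <- do.call(rbind, lapply(2:7, function(j)
    data.frame(locus_id = 1, gene = "A", category = j, score = 1, rank = 1)))
  nm2 <- rbind(nm2, data.frame(locus_id = 1, gene = "A", category = 1,
                               score = 0.8, rank = NA))
  expect_equal(priority_score(nm2)$scores$p_i, 6.8)
  # row order invariance
  pr2 <- priority_score(nm[sample(nrow(nm)), ])
  expect_equal(pr2$scores, pr$scores)
  # duplicate gene rows in a ranked category are rejected
  bad <- rbind(nm, data.frame(locus_id = 1, gene = "A", category = 2,
                              score = 5, rank = 2))
  expect_error(priority_score(bad), "duplicate")
})

test_that("exact priority ties break by distance to the index variant", {
  nm <- data.frame(locus_id = 1, gene = c("A", "B"), category = c(7, 7),
                   score = c(1, 1), rank = c(1, 1))
  genes <- data.frame(chrom = "1", start = c(5000L, 1200L),
                      end = c(6000L, 2200L), strand = "+",
                      symbol = c("A", "B"))
  pr <- priority_score(nm, genes, index_pos = 1500)
  expect_true(pr$tie_break_used)
  expect_equal(pr$winner, "B")
})
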