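# Shared small fixtures, built once per test run.

fixture_env <- new.env()

# 800 individuals x 200 variants, h2 = 0.25: the workhorse cohort
small_sim <- function() {
  if (is.null(fixture_env$small)) {
    cfg <- sim_config(n_individuals = 800, n_variants = 200,
                      n_features_per_tissue = 20, seed = 42)
    panel <- simulate_genotypes(cfg)
    sim <- simulate_cohort(panel, cfg)
    fixture_env$small <- list(cfg = cfg, panel = panel, sim = sim)
  }
  fixture_env$small
}

# LD-free panel: one variant per block
ldfree_panel <- function(n = 500, m = 40, seed = 7) {
  cfg <- sim_config(n_individuals = n, n_variants = m, ld_block_size = 1,
                    block_rho = 0, n_causal = 2, seed = seed)
  list(cfg = cfg, panel = simulate_genotypes(cfg))
}

# tiny hand-made gene models with exon structure for mapping tests
toy_genes <- function() {
  genes <- data.frame(
    chrom = c("1", "1", "2"),
    start = c(1000L, 6000L, 1000L),
    end = c(3000L, 9000L, 2000L),
    strand = c("+", "-", "+"),
    symbol = c("GA", "GB", "GC"),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    symbol = c("GA", "GA", "GA", "GB", "GB"),
    start = c(1000L, 1500L, 2500L, 6000L, 8000L),
    end = c(1200L, 1800L, 3000L, 6500L, 9000L),
    feature = c("UTR", "exon", "exon", "exon", "exon"),
    stringsAsFactors = FALSE)
  list(genes = genes, exons = exons)
}
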