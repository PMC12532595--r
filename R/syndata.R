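#' Simulation configuration for the synthetic BAG cohort
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults describe the study conditions the rest of the package is tested
#' under: a middle-aged to elderly cohort (age 45.2-81.9 years), common
#' variants (MAF > 0.01) arranged in LD blocks, a brain-age-gap (BAG)
#' phenotype with a planted additive genetic architecture, and voxel-like
#' imaging features whose linear readout recovers age plus BAG.
#'
#' @param n_individuals Number of individuals in the cohort.
#' @param n_variants Number of variants on the genotype panel.
#' @param ld_block_size Variants per LD block.
#' @param block_rho AR(1) correlation of the latent Gaussian within a block,
#'   in `[0, 1)`. Between-block correlation is 0 in expectation.
#' @param maf_range Length-2 numeric, lower/upper bound of the effect-allele
#'   frequency, each in `(0, 0.5]`.
#' @param n_causal Number of causal variants planted for the BAG phenotype.
#' @param h2_bag Target SNP-heritability of BAG, in `[0, 1)`.
#' @param age_range Chronological age range in years.
#' @param n_features_per_tissue Number of voxel-like features per tissue
#'   (grey and white matter).
#' @param feature_noise_sd Feature measurement noise, in years-equivalent
#'   units of the age signal.
#' @param retest_fraction Fraction of individuals with a retest session.
#' @param retest_icc_target Target test-retest ICC of the feature readout.
#' @param n_sites Number of scanner sites.
#' @param bag_sd Total standard deviation of BAG in years (free parameter of
#'   the generator; the genetic share of its square is `h2_bag`).
#' @param seed Integer seed; fully determines all generator outputs.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_individuals = 1000, n_variants = 400,
                       ld_block_size = 20, block_rho = 0.6,
                       maf_range = c(0.05, 0.5), n_causal = 20,
                       h2_bag = 0.25, age_range = c(45.2, 81.9),
                       n_features_per_tissue = 40, feature_noise_sd = 1,
                       retest_fraction = 0.1, retest_icc_target = 0.9,
                       n_sites = 3, bag_sd = 3, seed = 1L) {
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("`maf_range` must lie within (0, 0.5]", call. = FALSE)
  if (block_rho < 0 || block_rho >= 1)
    stop("`block_rho` must be in [0, 1)", call. = FALSE)
  if (h2_bag < 0 || h2_bag >= 1)
    stop("`h2_bag` must be in [0, 1)", call. = FALSE)
  if (n_causal > n_variants)
    stop("`n_causal` cannot exceed `n_variants`", call. = FALSE)
  for (f in c("retest_fraction", "retest_icc_target"))
    stopifnot_prob(get(f), f)
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_variants = as.integer(n_variants),
              ld_block_size = as.integer(ld_block_size),
              block_rho = block_rho, maf_range = maf_range,
              n_causal = as.integer(n_causal), h2_bag = h2_bag,
              age_range = age_range,
              n_features_per_tissue = as.integer(n_features_per_tissue),
              feature_noise_sd = feature_noise_sd,
              retest_fraction = retest_fraction,
              retest_icc_target = retest_icc_target,
              n_sites = as.integer(n_sites), bag_sd = bag_sd,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a genotype panel with block LD
#'
#' Genotypes are generated from a latent Gaussian AR(1) process per LD block,
#' thresholded per haplotype at the quantile of the effect-allele frequency.
#' Thresholding each haplotype independently guarantees Hardy-Weinberg
#' equilibrium per variant; the AR(1) parameter tunes the r-squared decay
#' within a block, and between-block correlation is zero in expectation.
#'
#' Dosages respect the ploidy scale: 0-2 for diploid regions (and chrX,
#' chrXY), 0-1 for chrY.
#'
#' @param config A [sim_config()].
#' @param ploidy_class Ploidy class applied to all variants; one of
#'   `"diploid"`, `"chrX"`, `"chrY"`, `"chrXY"`.
#' @return A list of class `"genotype_panel"` with elements `variants`
#'   (data.frame: chrom, pos, id, a1, a2, maf, ploidy_class, info) and
#'   `dosages` (n_individuals x n_variants matrix, columns named by id).
#' @export
simulate_genotypes <- function(config,
                               ploidy_class = c("diploid", "chrX", "chrY",
                                                "chrXY")) {
  stopifnot(inherits(config, "sim_config"))
  ploidy_class <- match.arg(ploidy_class)
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$n_variants
  bs <- config$ld_block_size
  rho <- config$block_rho
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  block <- rep(seq_len(ceiling(m / bs)), each = bs)[seq_len(m)]
  n_hap <- if (ploidy_class == "chrY") 1L else 2L

  dos <- matrix(0L, n, m)
  for (b in unique(block)) {
    idx <- which(block == b)
    for (h in seq_len(n_hap)) {
      z <- matrix(stats::rnorm(n * length(idx)), n, length(idx))
      if (rho > 0 && length(idx) > 1) {
        for (j in 2:length(idx))
          z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
      }
      thr <- stats::qnorm(maf[idx])
      dos[, idx] <- dos[, idx] + (z < rep(thr, each = n))
    }
  }

  # blocks distributed round-robin over 22 autosomes; 5 kb spacing within a
  # block, 20 Mb between successive blocks on the same chromosome, so LD
  # blocks are far outside each other's clumping windows
  pos <- numeric(m)  # double: large panels overflow 32-bit bp coordinates
  chrom <- character(m)
  ublocks <- unique(block)
  for (i in seq_along(ublocks)) {
    idx <- which(block == ublocks[i])
    chr_i <- ((i - 1L) %% 22L) + 1L
    rank_on_chr <- (i - 1L) %/% 22L
    pos[idx] <- rank_on_chr * 2e7 + 5000 * seq_along(idx)
    chrom[idx] <- as.character(chr_i)
  }
  variants <- data.frame(
    chrom = chrom, pos = pos,
    id = sprintf("v%04d", seq_len(m)),
    a1 = "A", a2 = "G", maf = maf,
    ploidy_class = ploidy_class, info = 1.0,
    block = block, stringsAsFactors = FALSE)
  colnames(dos) <- variants$id
  structure(list(variants = variants, dosages = dos),
            class = "genotype_panel")
}

#' Simulate a cohort with a heritable BAG phenotype and imaging features
#'
#' Builds the quantitative BAG phenotype as a centered genetic score scaled
#' to the target heritability, plus small covariate effects (sex, site, TIV)
#' and Gaussian noise. Voxel-like features per tissue load on the signal
#' `age + bag_true` together with nuisance latents and measurement noise, so
#' that with zero feature noise a linear readout of the features reproduces
#' `age + bag_true` exactly. A retest session is generated for a subset of
#' individuals, with the retest signal mixed as
#' `lambda * signal + sqrt(1 - lambda^2) * new noise`, `lambda` set to the
#' ICC target.
#'
#' @param panel A [simulate_genotypes()] panel.
#' @param config The same [sim_config()].
#' @return A list with elements `cohort` (data.frame: id, sex, age, site,
#'   tiv, array, pc1..pc5, bag_true), `features_gm`, `features_wm`,
#'   `retest` (ids + retest feature matrices) and `architecture` (class
#'   `"trait_architecture"`: causal_ids, betas, h2_realized, components).
#' @export
simulate_cohort <- function(panel, config) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "genotype_panel"))
  if (config$h2_bag >= 1) stop("`h2_bag` must be < 1", call. = FALSE)
  set.seed(config$seed + 1L)
  n <- config$n_individuals
  if (nrow(panel$dosages) != n)
    stop("panel and config disagree on the number of individuals",
         call. = FALSE)

  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- stats::rbinom(n, 1, 0.5)
  site <- sample.int(config$n_sites, n, replace = TRUE)
  tiv <- stats::rnorm(n, 1500, 100)
  array <- sample.int(2, n, replace = TRUE)
  pcs <- matrix(stats::rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("pc", 1:5)))

  v_bag <- config$bag_sd^2
  causal_idx <- sort(sample.int(config$n_variants, config$n_causal))
  beta_raw <- stats::rnorm(config$n_causal)
  g_raw <- panel$dosages[, causal_idx, drop = FALSE] %*% beta_raw
  scl <- if (stats::var(g_raw) > 0 && config$h2_bag > 0)
    sqrt(config$h2_bag * v_bag / stats::var(as.vector(g_raw))) else 0
  g <- as.vector(scale(g_raw, scale = FALSE)) * scl

  # covariate effects on BAG: free parameters, kept small relative to bag_sd
  site_eff <- stats::rnorm(config$n_sites, 0, 0.2)
  cov_part <- 0.3 * (sex - 0.5) + site_eff[site] + 0.002 * (tiv - 1500)
  v_noise <- max(v_bag - stats::var(g) - stats::var(cov_part), 0.01 * v_bag)
  noise <- stats::rnorm(n, 0, sqrt(v_noise))
  bag_true <- g + cov_part + noise
  h2_realized <- stats::var(g) / stats::var(bag_true)

  arch <- structure(list(
    causal_ids = panel$variants$id[causal_idx],
    betas = beta_raw * scl, h2_realized = h2_realized,
    components = list(genetic = g, covar = cov_part, noise = noise)),
    class = "trait_architecture")

  signal <- age + bag_true
  gm <- feature_block(signal, config$n_features_per_tissue,
                      config$feature_noise_sd)
  wm <- feature_block(signal, config$n_features_per_tissue,
                      config$feature_noise_sd)

  n_retest <- round(n * config$retest_fraction)
  retest <- NULL
  if (n_retest > 0) {
    ids_rt <- sort(sample.int(n, n_retest))
    lam <- config$retest_icc_target
    s <- signal[ids_rt]
    s2 <- mean(signal) + lam * (s - mean(signal)) +
      sqrt(1 - lam^2) * stats::sd(signal) * stats::rnorm(n_retest)
    rt_gm <- feature_block(s2, config$n_features_per_tissue,
                           config$feature_noise_sd, loadings = gm$loadings)
    rt_wm <- feature_block(s2, config$n_features_per_tissue,
                           config$feature_noise_sd, loadings = wm$loadings)
    retest <- list(ids = ids_rt, features_gm = rt_gm$features,
                   features_wm = rt_wm$features, signal = s2)
  }

  cohort <- data.frame(id = sprintf("ind%05d", seq_len(n)), sex = sex,
                       age = age, site = site, tiv = tiv, array = array,
                       pcs, bag_true = bag_true, stringsAsFactors = FALSE)
  list(cohort = cohort, features_gm = gm$features, features_wm = wm$features,
       retest = retest, architecture = arch, signal = signal)
}

# One tissue's feature block: features = loading * signal + nuisance + noise.
# `loadings` allows the retest session to reuse the test-session readout map.
feature_block <- function(signal, p, noise_sd, loadings = NULL) {
  n <- length(signal)
  q <- 3L
  if (is.null(loadings)) {
    loadings <- list(l = stats::runif(p, 0.5, 1.5),
                     mload = matrix(stats::rnorm(p * q, 0, 0.5), q, p))
  }
  u <- matrix(stats::rnorm(n * q), n, q)
  f <- outer(signal, loadings$l) + u %*% loadings$mload +
    matrix(stats::rnorm(n * p, 0, noise_sd), n, p)
  colnames(f) <- sprintf("f%03d", seq_len(p))
  list(features = f, loadings = loadings)
}

#' Simulate omics fixtures: gene models, eQTL/sQTL, CADD, PoPS, GO
#'
#' Creates the annotation resources downstream gene nomination expects. A
#' designated subset of causal loci is "mediated": their eQTL effects
#' `beta_zx` are drawn and the matching outcome effects are set to
#' `b_xy * beta_zx` (plus noise), so summary-data MR recovers the planted
#' effect of expression on BAG. Multi-tissue eQTL records are generated on
#' both sides of the lookup filters (m-value 0.89 vs 0.90; 9 vs 10 tissues)
#' and the generated truth is recorded in a manifest.
#'
#' @param panel A genotype panel.
#' @param arch The trait architecture from [simulate_cohort()].
#' @param config The [sim_config()].
#' @param n_mediated Number of causal loci given a mediating gene.
#' @param b_xy Planted effect of expression on BAG (outcome units per
#'   expression SD).
#' @param smr_noise_sd Noise on the mediated outcome effects (0 = exact
#'   ratio at every instrument).
#' @return A list of class `"omics_fixture"` with `genes`, `exons`,
#'   `eqtl_records`, `sqtl_records`, `smr_outcome`, `cadd`, `pops`, `go`
#'   and a `manifest` describing the planted truth.
#' @export
simulate_omics_fixtures <- function(panel, arch, config, n_mediated = 4,
                                    b_xy = 0.4, smr_noise_sd = 0) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(arch, "trait_architecture"))
  set.seed(config$seed + 2L)
  v <- panel$variants

  # non-overlapping gene tiles spanning each LD block's neighborhood
  genes <- do.call(rbind, lapply(unique(v$block), function(b) {
    vb <- v[v$block == b, ]
    lo <- max(min(vb$pos) - 30000, 1)
    hi <- max(vb$pos) + 30000
    starts <- seq(lo, hi, by = 40000)
    data.frame(chrom = vb$chrom[1], start = round(starts),
               end = round(starts + 20000 - 1),
               strand = rep(c("+", "-"), length.out = length(starts)),
               stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$chrom, genes$start), ]
  genes$symbol <- sprintf("GENE%03d", seq_len(nrow(genes)))
  rownames(genes) <- NULL
  # simple 3-exon structure with terminal UTRs per gene
  exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    w <- (g$end - g$start + 1) %/% 10
    data.frame(symbol = g$symbol,
               start = g$start + c(0L, 0L, 4L * w, 8L * w, 9L * w),
               end = g$start + c(w - 1L, 2L * w - 1L, 5L * w - 1L,
                                 10L * w - 1L, 10L * w - 1L),
               feature = c("UTR", "exon", "exon", "exon", "UTR"),
               stringsAsFactors = FALSE)
  }))

  causal_idx <- match(arch$causal_ids, v$id)
  # mediated loci live in distinct LD blocks so instrument sets are disjoint
  causal_blocks <- v$block[causal_idx]
  first_per_block <- causal_idx[!duplicated(causal_blocks)]
  n_mediated <- min(n_mediated, length(first_per_block))
  med_idx <- first_per_block[seq_len(n_mediated)]
  # each mediated locus gets its own (nearest unused, same-chromosome) gene
  med_genes <- character(0)
  for (i in med_idx) {
    gc <- genes[genes$chrom == v$chrom[i], ]
    d <- pmax(gc$start - v$pos[i], v$pos[i] - gc$end, 0)
    ord <- gc$symbol[order(d)]
    pick <- setdiff(ord, med_genes)[1]
    if (is.na(pick))  # local tiles exhausted: take any unused gene
      pick <- setdiff(genes$symbol, med_genes)[1]
    med_genes <- c(med_genes, pick)
  }

  # instrument effects drawn once per gene and shared between the eQTL and
  # sQTL probes, so a single mediated outcome table is consistent with both
  recs <- list(); out <- list()
  for (k in seq_len(n_mediated)) {
    vi <- med_idx[k]
    mates <- which(v$block == v$block[vi])
    inst <- unique(c(vi, utils::head(setdiff(mates, vi), 5)))
    bzx <- stats::rnorm(length(inst), 0.35, 0.05) *
      sample(c(-1, 1), length(inst), replace = TRUE)
    bzx[1] <- abs(bzx[1]) + 0.1  # top instrument: strongest effect
    se_zx <- rep(0.01, length(inst))
    recs[[k]] <- data.frame(gene = med_genes[k], variant = v$id[inst],
                            tissue = "cortex", beta_zx = bzx,
                            se_zx = se_zx,
                            p = 2 * stats::pnorm(-abs(bzx / se_zx)),
                            m_value = NA_real_, n_tissues = NA_integer_,
                            re2_p = NA_real_, stringsAsFactors = FALSE)
    bzy <- b_xy * bzx + stats::rnorm(length(inst), 0, smr_noise_sd)
    out[[k]] <- data.frame(id = v$id[inst], beta = bzy,
                           se = rep(0.02, length(inst)),
                           stringsAsFactors = FALSE)
  }
  eq <- list(records = do.call(rbind, recs))
  sq <- list(records = eq$records)
  smr_outcome <- do.call(rbind, out)
  smr_outcome <- smr_outcome[!duplicated(smr_outcome$id), ]
  smr_outcome$z <- smr_outcome$beta / smr_outcome$se
  smr_outcome$p <- 2 * stats::pnorm(-abs(smr_outcome$z))

  # multi-tissue lookup records on both sides of the filters
  mk_mt <- function(gene, variant, n_tis, frac_m09, re2_p) {
    m <- c(rep(0.95, round(n_tis * frac_m09)),
           rep(0.89, n_tis - round(n_tis * frac_m09)))
    data.frame(gene = gene, variant = variant, tissue = sprintf("t%02d",
               seq_len(n_tis)), beta_zx = 0.2, se_zx = 0.05,
               p = 1e-9, m_value = m, n_tissues = n_tis, re2_p = re2_p,
               stringsAsFactors = FALSE)
  }
  mt <- rbind(
    mk_mt(med_genes[1], v$id[med_idx[1]], 12, 0.8, 1e-10),   # passes
    mk_mt(genes$symbol[1], v$id[1], 9, 1.0, 1e-10),          # < 10 tissues
    mk_mt(genes$symbol[2], v$id[2], 12, 0.4, 1e-10),         # m>=0.9 in 40%
    mk_mt(genes$symbol[3], v$id[3], 12, 0.8, 1e-3))          # RE2 p too big
  mt_pass <- c(TRUE, FALSE, FALSE, FALSE)
  multi_tissue <- mt

  # CADD-like scores: every variant annotated; mediated causals made
  # nonsynonymous with high deleteriousness
  csq <- sample(c("nonsynonymous", "synonymous", "intronic", "intergenic",
                  "UTR3"), nrow(v), replace = TRUE,
                prob = c(0.05, 0.1, 0.4, 0.35, 0.1))
  phred <- stats::rexp(nrow(v), 1 / 5)
  csq[med_idx] <- "nonsynonymous"
  phred[med_idx] <- 25 + stats::runif(length(med_idx), 0, 10)
  cadd <- data.frame(variant = v$id, phred_score = round(phred, 2),
                     consequence = csq, stringsAsFactors = FALSE)

  # PoPS-like scores: designated genes top their 500 kb neighborhood
  pops <- data.frame(gene = genes$symbol,
                     score = stats::rnorm(nrow(genes), 0, 0.5),
                     stringsAsFactors = FALSE)
  pops$score[match(med_genes, pops$gene)] <-
    max(pops$score) + 1 + seq_len(n_mediated)

  go <- simulate_go_dag(genes$symbol, config$seed + 3L)

  manifest <- data.frame(gene = med_genes, variant = v$id[med_idx],
                         b_xy = b_xy, mediated = TRUE,
                         stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = exons,
                 eqtl_records = eq$records, sqtl_records = sq$records,
                 smr_outcome = smr_outcome, cadd = cadd, pops = pops,
                 go = go, multi_tissue = multi_tissue,
                 multi_tissue_pass = mt_pass, manifest = manifest),
            class = "omics_fixture")
}

# Small acyclic GO-like DAG: 3 aspects, one root each, two levels below.
simulate_go_dag <- function(symbols, seed, n_leaf_per_mid = 8,
                            leaf_size = 8) {
  set.seed(seed)
  rows <- list()
  for (aspect in c("BP", "MF", "CC")) {
    root <- paste0("GO:", aspect, ":ROOT")
    rows[[length(rows) + 1]] <- data.frame(
      term = root, aspect = aspect, parents = "",
      genes = paste(symbols, collapse = ","), stringsAsFactors = FALSE)
    for (mid in 1:2) {
      mid_id <- sprintf("GO:%s:M%d", aspect, mid)
      leaf_genes <- character(0)
      leaf_rows <- list()
      for (lf in seq_len(n_leaf_per_mid)) {
        g <- sample(symbols, min(leaf_size, length(symbols)))
        leaf_genes <- union(leaf_genes, g)
        leaf_rows[[lf]] <- data.frame(
          term = sprintf("GO:%s:M%d:L%d", aspect, mid, lf), aspect = aspect,
          parents = mid_id, genes = paste(g, collapse = ","),
          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        term = mid_id, aspect = aspect, parents = root,
        genes = paste(leaf_genes, collapse = ","), stringsAsFactors = FALSE)
      rows <- c(rows, leaf_rows)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a two-sample exposure GWAS for Mendelian randomization
#'
#' Emits summary statistics for a synthetic continuous exposure and the
#' matching BAG outcome, embedding a planted causal effect `b_xy_true`
#' (outcome units per exposure SD). Instrument effects are sized so that the
#' designated instruments pass genome-wide significance at the stated sample
#' size; exposure and outcome sampling errors are drawn independently, as the
#' two-sample design requires.
#'
#' @param panel A genotype panel (one instrument per LD block).
#' @param config The [sim_config()].
#' @param n_instruments Number of designated instruments.
#' @param b_xy_true Planted causal effect.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param pleiotropy_sd SD of direct (pleiotropic) instrument effects on the
#'   outcome.
#' @return List of class `"exposure_gwas"`: `exposure` and `outcome` summary
#'   tables (SNP-level: chrom, pos, id, a1, a2, freq_a1, beta, se, z, p, n),
#'   `instruments`, `b_xy_true`, and `internals` holding the two error
#'   streams for contract checks.
#' @export
simulate_exposure_gwas <- function(panel, config, n_instruments = 30,
                                   b_xy_true = 0.5, n_exposure = 20000,
                                   n_outcome = 20000, pleiotropy_sd = 0) {
  stopifnot(inherits(panel, "genotype_panel"))
  set.seed(config$seed + 4L)
  v <- panel$variants
  blocks <- unique(v$block)
  if (n_instruments > length(blocks))
    stop(sprintf("requested %d instruments but only %d independent blocks",
                 n_instruments, length(blocks)), call. = FALSE)
  inst_idx <- vapply(blocks[seq_len(n_instruments)],
                     function(b) which(v$block == b)[1], integer(1))

  p <- v$maf
  se_x <- 1 / sqrt(2 * p * (1 - p) * n_exposure)
  se_y <- 1 / sqrt(2 * p * (1 - p) * n_outcome)
  beta_x_true <- numeric(nrow(v))
  # 8 se gives ~90%+ power at the 5e-8 threshold (z_alpha ~ 5.45)
  beta_x_true[inst_idx] <- 8 * se_x[inst_idx] *
    sample(c(-1, 1), n_instruments, replace = TRUE)
  err_x <- stats::rnorm(nrow(v), 0, se_x)
  err_y <- stats::rnorm(nrow(v), 0, se_y)
  pleio <- if (pleiotropy_sd > 0)
    stats::rnorm(nrow(v), 0, pleiotropy_sd) else numeric(nrow(v))
  beta_y_true <- b_xy_true * beta_x_true + pleio

  mk <- function(beta, se, n) {
    z <- beta / se
    data.frame(chrom = v$chrom, pos = v$pos, id = v$id, a1 = v$a1,
               a2 = v$a2, freq_a1 = v$maf, beta = beta, se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)), n = n,
               stringsAsFactors = FALSE)
  }
  structure(list(
    exposure = mk(beta_x_true + err_x, se_x, n_exposure),
    outcome = mk(beta_y_true + err_y, se_y, n_outcome),
    instruments = v$id[inst_idx], b_xy_true = b_xy_true,
    internals = list(err_x = err_x, err_y = err_y)),
    class = "exposure_gwas")
}
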