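# GSMR-style Mendelian randomization and clumping-and-thresholding
# polygenic scores.

#' Standardize instrument effects to the per-SD scale
#'
#' `beta_sd = z / sqrt(2 p (1 - p) (n + z^2))`; `se_sd = beta_sd / z` for
#' nonzero `z`, else `1 / sqrt(2 p (1 - p) n)`.
#'
#' @param z z-statistic.
#' @param allele_freq Effect-allele frequency in `(0, 1)`.
#' @param n GWAS sample size.
#' @return List with `beta_sd` and `se_sd` (vectors).
#' @export
standardize_effects <- function(z, allele_freq, n) {
  if (any(allele_freq <= 0 | allele_freq >= 1))
    stop("`allele_freq` must lie in (0, 1)", call. = FALSE)
  h <- 2 * allele_freq * (1 - allele_freq)
  beta_sd <- z / sqrt(h * (n + z^2))
  se_sd <- ifelse(z != 0, beta_sd / z, 1 / sqrt(h * n))
  list(beta_sd = beta_sd, se_sd = se_sd)
}

# p-value-informed greedy LD clumping of a summary table against a panel.
# Returns the retained (index) variant ids.
clump_sumstats <- function(sumstats, panel, r2, window_kb, p_max = 1) {
  ss <- sumstats[!is.na(sumstats$p) & sumstats$p <= p_max, ]
  ss <- ss[ss$id %in% panel$variants$id, ]
  ss <- ss[order(ss$p), ]
  v <- panel$variants
  win <- window_kb * 1000
  keep <- character(0)
  removed <- rep(FALSE, nrow(ss))
  pos <- v$pos[match(ss$id, v$id)]
  chrom <- v$chrom[match(ss$id, v$id)]
  for (i in seq_len(nrow(ss))) {
    if (removed[i]) next
    keep <- c(keep, ss$id[i])
    rest <- which(!removed & seq_len(nrow(ss)) > i)
    near <- rest[chrom[rest] == chrom[i] & abs(pos[rest] - pos[i]) <= win]
    if (length(near) > 0) {
      rr <- dosage_r2(panel$dosages[, c(ss$id[i], ss$id[near]),
                                    drop = FALSE])
      removed[near[rr[1, -1] >= r2]] <- TRUE
    }
  }
  keep
}

#' GSMR: multi-instrument Mendelian randomization with HEIDI outliers
#'
#' Instruments are exposure variants with `p < p_select`, LD-clumped at
#' `clump_r2` within `window_kb`. Each instrument contributes the ratio
#' `b_i = beta_zy / beta_zx`; the estimates are combined by generalized
#' least squares with a covariance built from the delta-method ratio
#' variances and the instrument LD correlation (near-diagonal at the
#' default clumping threshold). Instruments whose deviation from the
#' top-instrument ratio is significant at `heidi_p` are removed as
#' pleiotropic outliers and the estimate refit. Reverse-direction MR is the
#' same call with exposure and outcome swapped.
#'
#' @param exposure_stats,outcome_stats Summary-statistic data.frames
#'   sharing variant ids.
#' @param panel Genotype panel for clumping/LD.
#' @param p_select Instrument selection threshold.
#' @param clump_r2,window_kb Instrument clumping parameters.
#' @param heidi_p Outlier-removal threshold.
#' @param min_instruments Minimum instrument count after selection.
#' @return List of class `"mr_estimate"`: `b_xy`, `se`, `p`,
#'   `n_instruments_used`, `outliers_removed` (ids with their HEIDI p),
#'   `instruments`.
#' @export
gsmr <- function(exposure_stats, outcome_stats, panel, p_select = 5e-8,
                 clump_r2 = 0.001, window_kb = 10000, heidi_p = 0.01,
                 min_instruments = 10) {
  inst <- clump_sumstats(exposure_stats, panel, clump_r2, window_kb,
                         p_max = p_select)
  if (length(inst) < min_instruments)
    stop(sprintf("only %d instruments after selection (floor %d)",
                 length(inst), min_instruments), call. = FALSE)
  ex <- exposure_stats[match(inst, exposure_stats$id), ]
  oc <- outcome_stats[match(inst, outcome_stats$id), ]
  ok <- !is.na(oc$beta)
  ex <- ex[ok, ]; oc <- oc[ok, ]; inst <- inst[ok]

  estimate <- function(ex, oc, inst) {
    b <- oc$beta / ex$beta
    # two-step GLS: evaluate the delta-method variances at a first-pass
    # pooled estimate, not at each instrument's own ratio (weighting by a
    # ratio-dependent variance biases the estimate toward zero); the
    # squared instrument effect in the weight is attenuation-corrected by
    # its own sampling variance
    b0 <- stats::median(b)
    vb <- (oc$se^2 + b0^2 * ex$se^2) /
      pmax(ex$beta^2 - ex$se^2, 0.1 * ex$beta^2)
    r_ld <- suppressWarnings(stats::cor(panel$dosages[, inst,
                                                      drop = FALSE]))
    r_ld[!is.finite(r_ld)] <- 0; diag(r_ld) <- 1
    # after clumping at r^2 < 0.001 the instruments are essentially
    # independent; sample correlations below the reference panel's noise
    # floor are set to zero so the GLS inverse does not amplify LD noise
    r_ld[r_ld^2 < 0.01] <- 0
    # first-order GLS covariance: LD correlation scaled by ratio SDs
    V <- r_ld * sqrt(vb %o% vb)
    Vi <- tryCatch(solve(V), error = function(e)
      MASS::ginv(V + diag(1e-10, nrow(V))))
    one <- rep(1, length(b))
    denom <- as.numeric(t(one) %*% Vi %*% one)
    bhat <- as.numeric(t(one) %*% Vi %*% b) / denom
    se <- sqrt(1 / denom)
    # multiplicative over-dispersion scaling (never deflating), as in
    # IVW with multiplicative random effects
    if (length(b) > 1) {
      phi <- sum((b - bhat)^2 / vb) / (length(b) - 1)
      se <- se * sqrt(max(1, phi))
    }
    list(b = bhat, se = se, p = 2 * stats::pnorm(-abs(bhat / se)),
         ratios = b, vb = vb)
  }
  est <- estimate(ex, oc, inst)
  # single-instrument HEIDI: deviation of each ratio from the first-pass
  # pooled estimate (the top instrument's own ratio carries selection bias
  # and would shift every deviation), conservative variance vb_i
  d <- est$ratios - est$b
  p_dev <- 2 * stats::pnorm(-abs(d) / sqrt(est$vb))
  out_ids <- inst[p_dev < heidi_p]
  outliers <- data.frame(id = out_ids, p_heidi = p_dev[p_dev < heidi_p],
                         stringsAsFactors = FALSE)
  if (length(out_ids) > 0) {
    keep <- !(inst %in% out_ids)
    ex <- ex[keep, ]; oc <- oc[keep, ]; inst <- inst[keep]
    est <- estimate(ex, oc, inst)
  }
  structure(list(b_xy = est$b, se = est$se, p = est$p,
                 n_instruments_used = length(inst),
                 outliers_removed = outliers, instruments = inst),
            class = "mr_estimate")
}

#' Clumping-and-thresholding polygenic score with partial-correlation
#' evaluation
#'
#' Training summary statistics are LD-clumped p-first (`r^2 < clump_r2`
#' within `window_kb`); for each p-value threshold the score is the dosage
#' sum weighted by the training betas of retained variants below the
#' threshold (variant sets therefore nest across thresholds). Performance
#' is the partial product-moment correlation between score and phenotype
#' given the covariates (equivalently, the plain correlation of the
#' covariate-residualized score and phenotype); the best threshold
#' maximizes partial r-squared.
#'
#' @param training_sumstats Training GWAS summary statistics.
#' @param target_panel Genotype panel of the target sample.
#' @param target_phenotype Phenotype in the target sample.
#' @param covariates Covariate data.frame for the partial correlation.
#' @param clump_r2,window_kb Clumping parameters (defaults 0.1, 500).
#' @param thresholds P-value thresholds (10 defaults from 5e-8 to 1).
#' @param training_ids,target_ids Optional id vectors; overlap raises an
#'   error (training and target must be disjoint).
#' @return List of class `"pgs_result"`: `table` (threshold, n_variants,
#'   partial_r, partial_r2), `scores` (matrix, one column per threshold),
#'   `best_threshold`.
#' @export
cp_pgs <- function(training_sumstats, target_panel, target_phenotype,
                   covariates = NULL, clump_r2 = 0.1, window_kb = 500,
                   thresholds = c(5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05,
                                  0.1, 0.2, 0.5, 1.0),
                   training_ids = NULL, target_ids = NULL) {
  if (!is.null(training_ids) && !is.null(target_ids) &&
      length(intersect(training_ids, target_ids)) > 0)
    stop("training and target samples overlap", call. = FALSE)
  kept <- clump_sumstats(training_sumstats, target_panel, clump_r2,
                         window_kb)
  ss <- training_sumstats[match(kept, training_sumstats$id), ]
  C <- covariate_matrix(covariates)
  yr <- as.vector(residualize(target_phenotype, C))
  thresholds <- sort(thresholds)
  scores <- matrix(0, nrow(target_panel$dosages), length(thresholds),
                   dimnames = list(NULL, format(thresholds)))
  tab <- data.frame(threshold = thresholds, n_variants = NA_integer_,
                    partial_r = NA_real_, partial_r2 = NA_real_)
  for (i in seq_along(thresholds)) {
    use <- ss$id[ss$p < thresholds[i] |
                   (thresholds[i] >= 1 & ss$p <= 1)]
    tab$n_variants[i] <- length(use)
    if (length(use) > 0) {
      scores[, i] <- target_panel$dosages[, use, drop = FALSE] %*%
        ss$beta[match(use, ss$id)]
    }
    if (length(use) > 0 && stats::sd(scores[, i]) > 0) {
      sr <- as.vector(residualize(scores[, i], C))
      tab$partial_r[i] <- stats::cor(sr, yr)
      tab$partial_r2[i] <- tab$partial_r[i]^2
    } else {
      tab$partial_r[i] <- 0; tab$partial_r2[i] <- 0
    }
  }
  best <- tab$threshold[which.max(tab$partial_r2)]
  structure(list(table = tab, scores = scores, best_threshold = best,
                 variants = kept), class = "pgs_result")
}
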