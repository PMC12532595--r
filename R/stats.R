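# Scalar statistics: standardized effect sizes, sex-difference tests,
# replication sign/binomial tests, winner's-curse-corrected power, Fisher
# annotation enrichment and multiple-testing adjustment.

#' Standardized effect size (correlation) from a z-statistic
#'
#' `r = sign(beta) * sqrt(z^2 / (z^2 + (N - k - 2)))`, where `k` is the
#' number of covariates in the association model.
#'
#' @param beta Effect estimate (only its sign is used).
#' @param z z-statistic of the association.
#' @param n Sample size.
#' @param k Number of covariates.
#' @return Correlation-scale effect size, `|r| < 1`.
#' @export
r_from_z <- function(beta, z, n, k = 0) {
  if (any(n - k - 2 <= 0))
    stop("`n` must exceed `k + 2`", call. = FALSE)
  sign(beta) * sqrt(z^2 / (z^2 + (n - k - 2)))
}

#' Sex-difference z-test on stratified effect estimates
#'
#' `z = (beta_m - beta_f) / sqrt(se_m^2 + se_f^2)`, two-sided normal p.
#'
#' @param beta_m,se_m Effect and SE in males.
#' @param beta_f,se_f Effect and SE in females.
#' @return List with `z` and `p`.
#' @export
sex_difference_test <- function(beta_m, se_m, beta_f, se_f) {
  if (any(se_m <= 0) || any(se_f <= 0))
    stop("standard errors must be positive", call. = FALSE)
  z <- (beta_m - beta_f) / sqrt(se_m^2 + se_f^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Replication sign and binomial tests
#'
#' Counts sign-concordant discovery/replication effect pairs and variants
#' reaching one-tailed nominal significance in the discovery direction, and
#' tests both counts with one-sided upper-tail binomial tests (null
#' proportions 0.5 for sign concordance and `alpha` for replication).
#'
#' @param records Data frame with columns `beta_disc`, `beta_rep`, `p_rep`
#'   (two-sided replication p).
#' @param alpha Nominal one-tailed replication level (default 0.05).
#' @return List: `n`, `concordant`, `p_sign`, `replicated`, `p_binom`.
#' @export
replication_tests <- function(records, alpha = 0.05) {
  if (is.null(records) || nrow(records) == 0)
    stop("empty record list", call. = FALSE)
  conc <- sum(sign(records$beta_disc) == sign(records$beta_rep))
  # one-tailed replication p in the discovery direction from a two-sided p
  p_one <- ifelse(sign(records$beta_disc) == sign(records$beta_rep),
                  records$p_rep / 2, 1 - records$p_rep / 2)
  repl <- sum(p_one < alpha)
  n <- nrow(records)
  list(n = n, concordant = conc,
       p_sign = binom_upper(conc, n, 0.5),
       replicated = repl,
       p_binom = binom_upper(repl, n, alpha))
}

#' One-sided upper-tail binomial p-value
#'
#' `P(X >= x)` for `X ~ Binomial(n, p0)`.
#'
#' @param x Observed count.
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @return Upper-tail probability.
#' @export
binom_upper <- function(x, n, p0) {
  stats::pbinom(x - 1, n, p0, lower.tail = FALSE)
}

#' Winner's-curse correction of an ascertained effect estimate
#'
#' The true mean of a z-statistic observed only because `|z|` exceeded the
#' selection threshold `c` (two-sided truncation) is first estimated by
#' conditional-likelihood maximum likelihood (one-dimensional numeric
#' maximization of the truncated-normal likelihood). Because the raw
#' conditional MLE overcorrects for observations near the threshold, the
#' returned estimate is the combined estimator: the average of the MLE and
#' the observed z, clamped to the observed sign. The corrected beta is
#' `mu_hat * se`.
#'
#' @param beta,se Discovery effect and SE.
#' @param p_threshold Selection threshold on the discovery p-value (e.g.
#'   5e-8 genome-wide, 1e-6 suggestive).
#' @return Corrected beta (same sign as the input, strictly shrunk toward 0
#'   for finite z above the threshold).
#' @export
winners_curse_correct <- function(beta, se, p_threshold = 5e-8) {
  cthr <- stats::qnorm(p_threshold / 2, lower.tail = FALSE)
  vapply(seq_along(beta), function(i) {
    z <- beta[i] / se[i]
    nll <- function(mu) {
      logden <- stats::dnorm(z, mean = mu, log = TRUE)
      logtail <- log(stats::pnorm(-cthr - mu) + stats::pnorm(mu - cthr))
      -(logden - logtail)
    }
    mu_mle <- stats::optimize(nll,
                              interval = c(-abs(z) - 5, abs(z) + 5))$minimum
    mu_hat <- (mu_mle + z) / 2
    # never flip the observed sign, never inflate
    if (sign(mu_hat) != sign(z)) mu_hat <- 0
    if (abs(mu_hat) > abs(z)) mu_hat <- z
    mu_hat * se[i]
  }, numeric(1))
}

#' Replication power with winner's-curse-corrected effects
#'
#' Standardized discovery betas are corrected for winner's curse at each
#' variant's own selection threshold; the replication SE is
#' `1 / sqrt(n_rep * 2 * maf * (1 - maf))` for a unit-variance phenotype;
#' one-tailed power at level `alpha` is
#' `1 - Phi(z_alpha - |beta_corrected| / se_rep)`. Expected replications are
#' the sum of per-variant power.
#'
#' @param records Data frame with `beta_disc`, `se_disc`, `maf`, `n_rep`
#'   and `p_select` (per-variant selection threshold).
#' @param alpha One-tailed replication significance level.
#' @return List: `power` (per variant), `beta_corrected`,
#'   `expected_replications`.
#' @export
replication_power <- function(records, alpha = 0.05) {
  if (any(records$maf <= 0 | records$maf > 0.5))
    stop("`maf` must lie in (0, 0.5]", call. = FALSE)
  bc <- winners_curse_correct(records$beta_disc, records$se_disc,
                              records$p_select)
  se_rep <- 1 / sqrt(records$n_rep * 2 * records$maf * (1 - records$maf))
  pow <- 1 - stats::pnorm(stats::qnorm(1 - alpha) - abs(bc) / se_rep)
  list(power = pow, beta_corrected = bc,
       expected_replications = sum(pow))
}

#' Fisher's exact annotation enrichment
#'
#' For each annotation, a 2x2 two-tailed Fisher's exact test of candidate
#' versus reference proportions. Variants with several annotations count
#' once per annotation. Degenerate cells are handled by the exact test; the
#' odds ratio is reported as `Inf`/`0` rather than imputed.
#'
#' @param candidate_counts Named vector: annotation counts among candidate
#'   variants.
#' @param reference_counts Named vector: counts among the reference panel
#'   (same annotation universe).
#' @param candidate_total,reference_total Total variant counts; default is
#'   the sum of the respective count vectors.
#' @return Data frame: annotation, a/b/c/d cells, proportion ratio, OR, p.
#' @export
fisher_annotation_enrichment <- function(candidate_counts, reference_counts,
                                         candidate_total = sum(candidate_counts),
                                         reference_total = sum(reference_counts)) {
  if (candidate_total == 0) stop("no candidate variants", call. = FALSE)
  ann <- union(names(candidate_counts), names(reference_counts))
  rows <- lapply(ann, function(a) {
    x <- candidate_counts[a]; x <- ifelse(is.na(x), 0, x)
    y <- reference_counts[a]; y <- ifelse(is.na(y), 0, y)
    tab <- matrix(c(x, candidate_total - x, y, reference_total - y), 2)
    ft <- stats::fisher.test(tab)
    or_raw <- (x * (reference_total - y)) / ((candidate_total - x) * y)
    data.frame(annotation = a, a = x, b = candidate_total - x, c = y,
               d = reference_total - y,
               prop_ratio = (x / candidate_total) / (y / reference_total),
               or = or_raw, p = ft$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Multiple-testing adjustment
#'
#' Bonferroni (capped at 1) or Benjamini-Hochberg step-up with monotonicity
#' enforcement, via [stats::p.adjust()].
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  stopifnot_prob(p, "p")
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}
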