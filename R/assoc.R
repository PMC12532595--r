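# Per-variant association, fixed-effects meta-analysis, stepwise conditional
# signal selection and cross-trait LD clumping.

#' Linear dosage GWAS
#'
#' Per variant, OLS of the phenotype on the allelic dosage plus covariates
#' and an intercept, with a two-sided t-test on the dosage term. Dosages are
#' used on their ploidy scale (0-2 for diploid regions, 0-1 for chrY).
#' Monomorphic variants yield an NA row with a reason code rather than being
#' dropped silently.
#'
#' @param panel A genotype panel.
#' @param phenotype Numeric phenotype vector.
#' @param covariates Optional covariate data.frame (factors dummy-coded);
#'   must be full rank.
#' @return Summary-statistic data.frame: chrom, pos, id, a1, a2, freq_a1,
#'   beta, se, z, p, n, reason.
#' @export
gwas_linear <- function(panel, phenotype, covariates = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  y <- as.numeric(phenotype)
  n <- length(y)
  if (nrow(panel$dosages) != n)
    stop("phenotype and panel row counts differ", call. = FALSE)
  C <- covariate_matrix(covariates)
  k <- if (is.null(C)) 0L else ncol(C)
  if (k > 0 && qr(cbind(1, C))$rank < k + 1)
    stop("covariate matrix is rank deficient", call. = FALSE)
  yr <- as.vector(residualize(y, C))
  Xr <- residualize(panel$dosages, C)
  sxx <- colSums(Xr^2)
  mono <- apply(panel$dosages, 2, function(d) stats::var(d) == 0)
  df <- n - k - 2L
  beta <- colSums(Xr * yr) / sxx
  sse <- sum(yr^2) - beta^2 * sxx
  se <- sqrt(pmax(sse, 0) / df / sxx)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  beta[mono] <- se[mono] <- p[mono] <- NA_real_
  v <- panel$variants
  ploidy_max <- ifelse(v$ploidy_class == "chrY", 1, 2)
  data.frame(chrom = v$chrom, pos = v$pos, id = v$id, a1 = v$a1, a2 = v$a2,
             freq_a1 = colMeans(panel$dosages) / ploidy_max,
             beta = beta, se = se, z = beta / se, p = p, n = n,
             reason = ifelse(mono, "monomorphic", NA_character_),
             stringsAsFactors = FALSE)
}

is_palindromic <- function(a1, a2) {
  paste0(a1, a2) %in% c("AT", "TA", "CG", "GC")
}

flip_strand <- function(a) c(A = "T", T = "A", C = "G", G = "C")[a]

#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' Variants are keyed by (chrom, pos); alleles are harmonized against the
#' first cohort (a1/a2 swap flips the sign of beta and the frequency; strand
#' flips are resolved by complementing; palindromic variants are resolved by
#' allele frequency when `|freq - 0.5| > 0.2`, otherwise excluded). After
#' meta-analysis, variants with a combined sample size below 67% of the 90th
#' percentile, or with Cochran's Q heterogeneity p below `het_p`, are
#' removed; the removed rows are attached as the `"filtered"` attribute.
#'
#' @param tables List of at least two summary-statistic data.frames.
#' @param het_p Heterogeneity exclusion threshold (default 1e-6).
#' @param apply_filters Apply the sample-size and heterogeneity filters.
#' @return Meta-analyzed summary-statistic data.frame with `q_het_p` and
#'   `k_cohorts` columns.
#' @export
ivw_meta <- function(tables, het_p = 1e-6, apply_filters = TRUE) {
  if (length(tables) < 2) stop("need >= 2 cohorts", call. = FALSE)
  ref <- tables[[1]]
  ref$key <- paste(ref$chrom, ref$pos, sep = ":")
  harmonized <- list(ref)
  dropped <- character(0)
  for (i in seq_along(tables)[-1]) {
    tb <- tables[[i]]
    tb$key <- paste(tb$chrom, tb$pos, sep = ":")
    j <- match(tb$key, ref$key)
    tb <- tb[!is.na(j), ]; j <- j[!is.na(j)]
    same <- tb$a1 == ref$a1[j] & tb$a2 == ref$a2[j]
    swap <- tb$a1 == ref$a2[j] & tb$a2 == ref$a1[j]
    sflip <- flip_strand(tb$a1) == ref$a1[j] & flip_strand(tb$a2) == ref$a2[j]
    sswap <- flip_strand(tb$a1) == ref$a2[j] & flip_strand(tb$a2) == ref$a1[j]
    pal <- is_palindromic(tb$a1, tb$a2)
    # palindromic: orientation decidable only through the frequency
    amb <- pal & abs(tb$freq_a1 - 0.5) <= 0.2
    pal_swap <- pal & !amb &
      ((tb$freq_a1 > 0.5) != (ref$freq_a1[j] > 0.5))
    do_swap <- (swap | (sswap & !pal) | pal_swap) & !amb
    ok <- (same | swap | sflip | sswap) & !amb
    dropped <- c(dropped, tb$key[!ok])
    tb$beta[do_swap] <- -tb$beta[do_swap]
    tb$freq_a1[do_swap] <- 1 - tb$freq_a1[do_swap]
    tb$a1 <- ref$a1[j]; tb$a2 <- ref$a2[j]
    harmonized[[i]] <- tb[ok, ]
  }
  keys <- ref$key
  k <- length(harmonized)
  b <- se <- matrix(NA_real_, length(keys), k)
  nmat <- matrix(0, length(keys), k)
  for (i in seq_len(k)) {
    j <- match(harmonized[[i]]$key, keys)
    b[j, i] <- harmonized[[i]]$beta
    se[j, i] <- harmonized[[i]]$se
    nmat[j, i] <- harmonized[[i]]$n
  }
  w <- 1 / se^2
  sw <- rowSums(w, na.rm = TRUE)
  beta_meta <- rowSums(w * b, na.rm = TRUE) / sw
  se_meta <- 1 / sqrt(sw)
  z <- beta_meta / se_meta
  kc <- rowSums(!is.na(b))
  q <- rowSums(w * (b - beta_meta)^2, na.rm = TRUE)
  q_p <- ifelse(kc > 1, stats::pchisq(q, kc - 1, lower.tail = FALSE), NA)
  out <- data.frame(chrom = ref$chrom, pos = ref$pos, id = ref$id,
                    a1 = ref$a1, a2 = ref$a2, freq_a1 = ref$freq_a1,
                    beta = beta_meta, se = se_meta, z = z,
                    p = 2 * stats::pnorm(-abs(z)),
                    n = rowSums(nmat), q_het_p = q_p, k_cohorts = kc,
                    stringsAsFactors = FALSE)
  filtered <- NULL
  if (apply_filters) {
    n_min <- 0.67 * stats::quantile(out$n, 0.9, names = FALSE)
    bad_n <- out$n < n_min
    bad_q <- !is.na(out$q_het_p) & out$q_het_p < het_p
    filtered <- cbind(out[bad_n | bad_q, ],
                      filter_reason = ifelse(bad_n[bad_n | bad_q],
                                             "low_n", "heterogeneity"))
    out <- out[!(bad_n | bad_q), ]
  }
  attr(out, "filtered") <- filtered
  attr(out, "dropped_keys") <- dropped
  out
}

#' Stepwise conditional selection of independent association signals
#'
#' Iteratively selects the variant with the smallest conditional p-value,
#' refits jointly with all previously selected variants within the window,
#' and repeats until no conditional p falls below the threshold. Candidates
#' in strong LD (r-squared above the collinearity cutoff) with a selected
#' variant are skipped. Subsidiary signals whose conditional p exceeds their
#' marginal p by more than two orders of magnitude are discarded. The
#' conditional model is an exact joint regression on the individual-level
#' reference data.
#'
#' @param sumstats Marginal summary statistics (needs id, p).
#' @param panel Genotype panel covering the tested variants.
#' @param phenotype Phenotype vector used for the joint refits.
#' @param covariates Optional covariates, as in [gwas_linear()].
#' @param window_kb Conditioning/collinearity window (kb).
#' @param collinearity r-squared cutoff above which candidates are skipped.
#' @param p_threshold Selection threshold (genome-wide 5e-8).
#' @return Data frame of index variants: id, chrom, pos, beta/se/p
#'   (marginal), cond_beta/cond_se/cond_p (joint model).
#' @export
stepwise_conditional <- function(sumstats, panel, phenotype,
                                 covariates = NULL, window_kb = 10000,
                                 collinearity = 0.9, p_threshold = 5e-8) {
  empty <- data.frame(id = character(0), chrom = character(0),
                      pos = integer(0), beta = numeric(0), se = numeric(0),
                      p = numeric(0), cond_beta = numeric(0),
                      cond_se = numeric(0), cond_p = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(sumstats) || nrow(sumstats) == 0) return(empty)
  ss <- sumstats[!is.na(sumstats$p), ]
  ss <- ss[ss$id %in% panel$variants$id, ]
  if (nrow(ss) == 0) return(empty)
  v <- panel$variants
  C <- covariate_matrix(covariates)
  y <- as.numeric(phenotype)
  win <- window_kb * 1000

  cond_scan <- function(selected) {
    # conditional stats for every candidate given the selected variants
    # within the window of each candidate
    res <- data.frame(id = ss$id, p = NA_real_)
    for (i in seq_len(nrow(ss))) {
      vid <- ss$id[i]
      if (vid %in% selected) next
      vi <- match(vid, v$id)
      sel_in <- selected[v$chrom[match(selected, v$id)] == v$chrom[vi] &
                         abs(v$pos[match(selected, v$id)] - v$pos[vi]) <= win]
      D <- cbind(C, panel$dosages[, sel_in, drop = FALSE])
      st <- joint_term_stats(y, panel$dosages[, vid], D)
      res$p[i] <- st$p
    }
    res
  }

  # vectorized first scan straight from marginal stats
  selected <- character(0)
  skipped <- character(0)
  repeat {
    if (length(selected) == 0) {
      cand_p <- stats::setNames(ss$p, ss$id)
    } else {
      sc <- cond_scan(selected)
      cand_p <- stats::setNames(sc$p, sc$id)
    }
    cand_p <- cand_p[!names(cand_p) %in% c(selected, skipped)]
    cand_p <- cand_p[!is.na(cand_p)]
    if (length(cand_p) == 0 || min(cand_p) >= p_threshold) break
    top <- names(cand_p)[which.min(cand_p)]
    if (length(selected) > 0) {
      vi <- match(top, v$id)
      sel_idx <- match(selected, v$id)
      near <- selected[v$chrom[sel_idx] == v$chrom[vi] &
                       abs(v$pos[sel_idx] - v$pos[vi]) <= win]
      if (length(near) > 0) {
        r2 <- dosage_r2(panel$dosages[, c(top, near), drop = FALSE])[1, -1]
        if (any(r2 > collinearity)) { skipped <- c(skipped, top); next }
      }
    }
    selected <- c(selected, top)
  }
  if (length(selected) == 0) return(empty)

  joint_fit <- function(sel) {
    D <- cbind(C, panel$dosages[, sel, drop = FALSE])
    res <- lapply(seq_along(sel), function(i)
      joint_term_stats(y, panel$dosages[, sel[i]],
                       cbind(C, panel$dosages[, sel[-i], drop = FALSE])))
    data.frame(id = sel,
               cond_beta = vapply(res, `[[`, 1, "beta"),
               cond_se = vapply(res, `[[`, 1, "se"),
               cond_p = vapply(res, `[[`, 1, "p"),
               stringsAsFactors = FALSE)
  }
  # discard subsidiary signals degraded > 2 orders of magnitude, then those
  # no longer genome-wide significant in the joint model
  repeat {
    jf <- joint_fit(selected)
    marg_p <- ss$p[match(selected, ss$id)]
    lead <- selected[which.min(marg_p)]
    bad <- (jf$cond_p > marg_p * 100 | jf$cond_p >= p_threshold) &
      selected != lead
    if (!any(bad)) break
    worst <- selected[bad][which.max(jf$cond_p[bad])]
    selected <- setdiff(selected, worst)
  }
  jf <- joint_fit(selected)
  i <- match(selected, ss$id)
  out <- data.frame(id = selected,
                    chrom = v$chrom[match(selected, v$id)],
                    pos = v$pos[match(selected, v$id)],
                    beta = ss$beta[i], se = ss$se[i], p = ss$p[i],
                    stringsAsFactors = FALSE)
  cbind(out, jf[, c("cond_beta", "cond_se", "cond_p")])
}

# Exact OLS stats for the `x` term in y ~ 1 + D + x.
joint_term_stats <- function(y, x, D) {
  n <- length(y)
  yr <- as.vector(residualize(y, D))
  xr <- as.vector(residualize(x, D))
  sxx <- sum(xr^2)
  kD <- if (is.null(D)) 0L else qr(D)$rank
  df <- n - kD - 2L
  if (sxx < 1e-12 || df < 1) return(list(beta = NA, se = NA, p = NA))
  beta <- sum(xr * yr) / sxx
  sse <- sum(yr^2) - beta^2 * sxx
  se <- sqrt(max(sse, 0) / df / sxx)
  list(beta = beta, se = se,
       p = 2 * stats::pt(-abs(beta / se), df))
}

#' Cross-trait LD clumping of index variants and novelty flagging
#'
#' Greedy clumping by ascending p across traits: the best remaining index
#' variant leads a locus; all other index variants within the window with
#' r-squared at or above the cutoff join it. A locus is flagged novel when
#' no known-list variant clumps with its lead under the same parameters.
#'
#' @param index_variants Data frame (id, trait, chrom, pos, p) across traits.
#' @param panel Genotype panel for LD.
#' @param r2 Clumping r-squared threshold (default 0.1).
#' @param window_kb Clumping window (kb).
#' @param known_list Optional character vector of previously reported
#'   variant ids; ids absent from the panel are ignored with a warning.
#' @return Locus table: locus_id, lead_id, lead_trait, lead_p, n_members,
#'   members, traits, novel; per-variant locus assignment in attribute
#'   `"assignment"`.
#' @export
clump_and_flag <- function(index_variants, panel, r2 = 0.1,
                           window_kb = 10000, known_list = NULL) {
  iv <- index_variants
  if (is.null(iv$trait)) iv$trait <- "trait"
  iv <- iv[order(iv$p), ]
  v <- panel$variants
  win <- window_kb * 1000
  iv$locus <- NA_integer_
  locus <- 0L
  for (i in seq_len(nrow(iv))) {
    if (!is.na(iv$locus[i])) next
    locus <- locus + 1L
    iv$locus[i] <- locus
    rest <- which(is.na(iv$locus))
    if (length(rest) > 0) {
      near <- rest[iv$chrom[rest] == iv$chrom[i] &
                   abs(iv$pos[rest] - iv$pos[i]) <= win]
      if (length(near) > 0) {
        rr <- dosage_r2(panel$dosages[, c(iv$id[i], unique(iv$id[near])),
                                      drop = FALSE])
        join <- near[rr[1, match(iv$id[near], colnames(rr))] >= r2]
        iv$locus[join] <- locus
      }
    }
  }
  known <- known_list
  if (!is.null(known)) {
    missing <- setdiff(known, v$id)
    if (length(missing) > 0) {
      warning(length(missing), " known variant(s) not in panel; ignored")
      known <- intersect(known, v$id)
    }
  }
  leads <- iv[!duplicated(iv$locus), ]
  loci <- lapply(seq_len(nrow(leads)), function(li) {
    mem <- iv[iv$locus == leads$locus[li], ]
    novel <- TRUE
    if (!is.null(known) && length(known) > 0) {
      if (leads$id[li] %in% known) novel <- FALSE
      else {
        vi <- match(leads$id[li], v$id)
        kn <- known[v$chrom[match(known, v$id)] == v$chrom[vi] &
                    abs(v$pos[match(known, v$id)] - v$pos[vi]) <= win]
        if (length(kn) > 0) {
          rr <- dosage_r2(panel$dosages[, c(leads$id[li], kn),
                                        drop = FALSE])
          if (any(rr[1, -1] >= r2)) novel <- FALSE
        }
      }
    }
    data.frame(locus_id = leads$locus[li], lead_id = leads$id[li],
               lead_trait = leads$trait[li], lead_p = leads$p[li],
               n_members = nrow(mem),
               members = paste(mem$id, collapse = ","),
               traits = paste(sort(unique(mem$trait)), collapse = ","),
               novel = novel, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, loci)
  attr(out, "assignment") <- iv[, c("id", "trait", "locus")]
  out
}
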