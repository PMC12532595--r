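# Gene-based association (sum of chi-square with LD eigenvalue correction)
# and GO enrichment with permutation FWER joined across aspects plus elim
# refinement.

#' Gene-based sum-of-chi-square association test
#'
#' Variants are assigned to genes by position within `[start, end]`
#' inclusive with zero flanking window. Per gene the statistic is
#' `T = sum(z_i^2)`; under the null T is distributed as a weighted sum of
#' 1-df chi-squares with weights equal to the eigenvalues of the variant LD
#' correlation matrix. The p-value uses the two-moment Satterthwaite match
#' (`scale c = sum(lambda^2)/sum(lambda)`,
#' `df d = sum(lambda)^2/sum(lambda^2)`). Gene-level FDR is
#' Benjamini-Hochberg; significant genes are clumped top-p-first within a
#' 3,000-kb window into distinct loci.
#'
#' @param sumstats Summary statistics (id, chrom, pos, z or beta/se).
#' @param gene_models Gene table (chrom, start, end, symbol).
#' @param panel Genotype panel supplying the LD reference.
#' @param fdr_threshold Significance threshold on the FDR.
#' @param clump_window_kb Clumping window for significant genes.
#' @return Data frame: gene, chrom, start, end, n_variants, T, p, fdr,
#'   significant, locus_id (NA unless significant). Genes with no mapped
#'   variants are dropped with a message.
#' @export
gene_based_test <- function(sumstats, gene_models, panel,
                            fdr_threshold = 0.05, clump_window_kb = 3000) {
  ss <- sumstats
  if (is.null(ss$z)) ss$z <- ss$beta / ss$se
  ss <- ss[!is.na(ss$z), ]
  g <- gene_models
  rows <- vector("list", nrow(g))
  dropped <- 0L
  for (i in seq_len(nrow(g))) {
    vid <- ss$id[ss$chrom == g$chrom[i] & ss$pos >= g$start[i] &
                 ss$pos <= g$end[i]]
    if (length(vid) == 0) { dropped <- dropped + 1L; next }
    z <- ss$z[match(vid, ss$id)]
    T_stat <- sum(z^2)
    if (length(vid) == 1) {
      lam <- 1
    } else {
      R <- suppressWarnings(stats::cor(panel$dosages[, vid, drop = FALSE]))
      R[!is.finite(R)] <- 0; diag(R) <- 1
      lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
      lam <- pmax(lam, 0)
    }
    cc <- sum(lam^2) / sum(lam)
    dd <- sum(lam)^2 / sum(lam^2)
    rows[[i]] <- data.frame(gene = g$symbol[i], chrom = g$chrom[i],
                            start = g$start[i], end = g$end[i],
                            n_variants = length(vid), T = T_stat,
                            p = stats::pchisq(T_stat / cc, dd,
                                              lower.tail = FALSE),
                            stringsAsFactors = FALSE)
  }
  if (dropped > 0)
    message(dropped, " gene(s) had no mapped variants and were dropped")
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$fdr <- stats::p.adjust(out$p, "BH")
  out$significant <- out$fdr < fdr_threshold
  out$locus_id <- NA_integer_
  sig <- which(out$significant)
  sig <- sig[order(out$p[sig])]
  win <- clump_window_kb * 1000
  locus <- 0L
  for (i in sig) {
    if (!is.na(out$locus_id[i])) next
    locus <- locus + 1L
    mid_i <- (out$start[i] + out$end[i]) / 2
    near <- sig[is.na(out$locus_id[sig]) & out$chrom[sig] == out$chrom[i] &
                abs((out$start[sig] + out$end[sig]) / 2 - mid_i) <= win]
    out$locus_id[near] <- locus
    out$locus_id[i] <- locus
  }
  rownames(out) <- NULL
  out
}

# parse the GO fixture into membership structures keyed to gene_results
parse_go <- function(go_fixture, genes_present) {
  terms <- go_fixture$term
  members <- lapply(strsplit(go_fixture$genes, ","), intersect,
                    y = genes_present)
  parents <- strsplit(go_fixture$parents, ",")
  parents <- lapply(parents, function(p) p[nzchar(p)])
  list(terms = terms, aspect = go_fixture$aspect, members = members,
       parents = parents)
}

go_ancestors <- function(terms, parents) {
  idx <- stats::setNames(seq_along(terms), terms)
  anc <- vector("list", length(terms))
  get_anc <- function(i) {
    if (!is.null(anc[[i]])) return(anc[[i]])
    ps <- parents[[i]]
    res <- character(0)
    for (p in ps) if (p %in% terms)
      res <- union(res, c(p, get_anc(idx[[p]])))
    anc[[i]] <<- res
    res
  }
  for (i in seq_along(terms)) get_anc(i)
  anc
}

# one-sided rank-sum z: negative when member genes have low p-value ranks
ranksum_z <- function(W, m, G) {
  mu <- m * (G + 1) / 2
  sig <- sqrt(m * (G - m) * (G + 1) / 12)
  (W - mu) / sig
}

#' GO enrichment with joint-aspect permutation FWER and elim refinement
#'
#' Per term, a one-sided Wilcoxon rank-sum test of whether member genes have
#' lower-than-expected p-value ranks among all tested genes (normal
#' approximation, used identically for the observed data and permutations).
#' Family-wise error rates are estimated by permuting gene labels and taking
#' the per-permutation minimum p across all terms of all three aspects
#' jointly (per-aspect FWERs are also reported). Terms significant at
#' `fwer_threshold` are refined with the elim algorithm: the most specific
#' terms are processed first and a significant term's genes are removed from
#' its ancestors, which are then re-tested against the same permutation
#' null. The number of contributing loci per term counts 3,000-kb position
#' clusters among the term's FDR-significant member genes.
#'
#' @param gene_results Output of [gene_based_test()].
#' @param go_fixture GO table (term, aspect, parents, genes; comma-joined
#'   lists).
#' @param n_permutations Label permutations for the FWER null (>= 10;
#'   a warning below 100).
#' @param seed Seed for the permutations.
#' @param fwer_threshold Reporting and elim threshold.
#' @param clump_window_kb Window for counting contributing loci.
#' @return Data frame: term, aspect, n_genes, wilcoxon_p, fwer_aspect,
#'   fwer_joint, elim_significant, n_contributing_loci.
#' @export
go_enrichment <- function(gene_results, go_fixture, n_permutations = 1000,
                          seed = 1L, fwer_threshold = 0.05,
                          clump_window_kb = 3000) {
  if (n_permutations < 10) stop("need >= 10 permutations", call. = FALSE)
  if (n_permutations < 100) warning("fewer than 100 permutations")
  gr <- gene_results
  go <- parse_go(go_fixture, gr$gene)
  missing_genes <- setdiff(unique(unlist(strsplit(go_fixture$genes, ","))),
                           gr$gene)
  if (length(missing_genes) > 0)
    warning(length(missing_genes),
            " GO member gene(s) absent from gene results; dropped")
  G <- nrow(gr)
  r_obs <- rank(gr$p)
  M <- do.call(rbind, lapply(go$members, function(mem)
    as.numeric(gr$gene %in% mem)))
  m <- rowSums(M)
  keep <- m >= 1 & m < G
  M <- M[keep, , drop = FALSE]
  terms <- go$terms[keep]; aspect <- go$aspect[keep]
  members <- go$members[keep]; parents <- go$parents[keep]
  m <- m[keep]

  z_obs <- ranksum_z(as.vector(M %*% r_obs), m, G)
  p_obs <- stats::pnorm(z_obs)

  set.seed(seed)
  Rperm <- replicate(n_permutations, sample(r_obs))
  Wn <- M %*% Rperm
  Zn <- ranksum_z(Wn, m, G)
  Pn <- stats::pnorm(Zn)                       # terms x permutations
  minp_joint <- apply(Pn, 2, min)
  fwer_joint <- vapply(p_obs, function(p)
    (1 + sum(minp_joint <= p)) / (1 + n_permutations), numeric(1))
  fwer_aspect <- numeric(length(p_obs))
  for (a in unique(aspect)) {
    ia <- which(aspect == a)
    minp_a <- apply(Pn[ia, , drop = FALSE], 2, min)
    fwer_aspect[ia] <- vapply(p_obs[ia], function(p)
      (1 + sum(minp_a <= p)) / (1 + n_permutations), numeric(1))
  }

  # elim: most specific first; a significant term's genes are removed from
  # its ancestors, which are re-tested against the same null
  anc <- go_ancestors(terms, parents)
  depth <- vapply(anc, length, integer(1))
  order_elim <- order(-depth)
  cur_members <- members
  elim_sig <- fwer_joint < fwer_threshold
  retest <- function(mem) {
    mm <- sum(gr$gene %in% mem)
    if (mm < 1 || mm >= G) return(1)
    W <- sum(r_obs[gr$gene %in% mem])
    p <- stats::pnorm(ranksum_z(W, mm, G))
    (1 + sum(minp_joint <= p)) / (1 + n_permutations)
  }
  for (i in order_elim) {
    if (!elim_sig[i]) next
    f <- retest(cur_members[[i]])
    elim_sig[i] <- f < fwer_threshold
    if (elim_sig[i] && length(anc[[i]]) > 0) {
      for (a in anc[[i]]) {
        ai <- match(a, terms)
        if (is.na(ai)) next
        cur_members[[ai]] <- setdiff(cur_members[[ai]], cur_members[[i]])
        elim_sig[ai] <- retest(cur_members[[ai]]) < fwer_threshold
      }
    }
  }

  count_loci <- function(mem) {
    sub <- gr[gr$gene %in% mem & gr$significant, , drop = FALSE]
    if (nrow(sub) == 0) return(0L)
    sub <- sub[order(sub$p), ]
    mid <- (sub$start + sub$end) / 2
    used <- rep(FALSE, nrow(sub)); k <- 0L
    for (i in seq_len(nrow(sub))) {
      if (used[i]) next
      k <- k + 1L
      used[sub$chrom == sub$chrom[i] &
           abs(mid - mid[i]) <= clump_window_kb * 1000] <- TRUE
    }
    k
  }

  data.frame(term = terms, aspect = aspect, n_genes = m,
             wilcoxon_p = p_obs, fwer_aspect = fwer_aspect,
             fwer_joint = fwer_joint, elim_significant = elim_sig,
             n_contributing_loci = vapply(members, count_loci, integer(1)),
             stringsAsFactors = FALSE)
}
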