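# Fine-mapping, variant-to-gene mapping, summary-data MR (SMR/HEIDI),
# seven-stream gene nomination and the composite priority score.

#' Map a variant to a gene and functional category
#'
#' Category precedence: exonic > splice-region (within 2 bp of an
#' exon-intron boundary, intron side) > UTR > intronic > upstream/downstream
#' (within 1 kb) > intergenic. Intergenic variants are assigned to the
#' nearest gene by bp distance; exact ties go to the gene with the smaller
#' start coordinate. When a gene has no exon structure on record, positions
#' inside its body are classified intronic.
#'
#' @param chrom,pos Variant coordinates (1-based).
#' @param genes Gene table (chrom, start, end, strand, symbol).
#' @param exons Optional exon table (symbol, start, end,
#'   feature in {exon, UTR}).
#' @return List with `category` and `gene`.
#' @export
map_variant_to_gene <- function(chrom, pos, genes, exons = NULL) {
  if (is.null(genes) || nrow(genes) == 0)
    stop("empty gene model set", call. = FALSE)
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) stop("no genes on chromosome ", chrom, call. = FALSE)
  inside <- which(g$start <= pos & pos <= g$end)
  if (length(inside) > 0) {
    best <- list(category = "intronic", gene = NA_character_, prio = 4)
    prio <- c(exonic = 1, splice = 2, UTR = 3, intronic = 4)
    for (i in inside) {
      sym <- g$symbol[i]
      ex <- if (!is.null(exons)) exons[exons$symbol == sym, , drop = FALSE]
      cat_i <- "intronic"
      if (!is.null(ex) && nrow(ex) > 0) {
        in_ex <- ex$start <= pos & pos <= ex$end
        if (any(in_ex & ex$feature == "exon")) cat_i <- "exonic"
        else if (any(abs(pos - ex$start[ex$feature == "exon"]) <= 2) ||
                 any(abs(pos - ex$end[ex$feature == "exon"]) <= 2))
          cat_i <- "splice"
        else if (any(in_ex & ex$feature == "UTR")) cat_i <- "UTR"
      }
      if (prio[cat_i] <= best$prio)
        best <- list(category = cat_i, gene = sym, prio = prio[[cat_i]])
    }
    return(best[c("category", "gene")])
  }
  d_up <- g$start - pos    # variant left of gene
  d_dn <- pos - g$end      # variant right of gene
  dist <- pmax(d_up, d_dn, 0)
  near_1kb <- which(dist > 0 & dist <= 1000)
  if (length(near_1kb) > 0) {
    i <- near_1kb[order(dist[near_1kb], g$start[near_1kb])][1]
    # upstream = 5' side of the gene, by strand
    five_prime_left <- g$strand[i] != "-"
    side <- if (pos < g$start[i]) "left" else "right"
    category <- if ((side == "left") == five_prime_left)
      "upstream" else "downstream"
    return(list(category = category, gene = g$symbol[i]))
  }
  i <- order(dist, g$start)[1]
  list(category = "intergenic", gene = g$symbol[i])
}

#' Approximate-Bayes-factor 95% credible set for one locus
#'
#' Single-causal Wakefield approximate Bayes factors:
#' `ABF = sqrt(1 - r) * exp(z^2 r / 2)` with `r = W / (W + se^2)` and
#' `W = prior_sd^2`. PIPs are ABFs normalized over the locus; the credible
#' set is the minimal prefix of the PIP-descending order reaching 0.95.
#' The set is assigned to the locus if it contains at least one genome-wide
#' significant credible variant in strong LD (`r^2 > assign_r2`) within
#' `assign_window_kb` of the index variant.
#'
#' @param locus_sumstats Harmonized summary statistics for one locus
#'   (id, pos, beta, se, p).
#' @param index_variant Id of the locus index variant.
#' @param panel Genotype panel for LD (NULL skips the assignment rule).
#' @param prior_sd Prior SD of the causal effect, in phenotype units
#'   (default 0.3 years, the scale of observed BAG per-allele effects).
#' @param assign_r2,assign_window_kb Assignment-rule parameters.
#' @param p_threshold Genome-wide threshold for the assignment rule.
#' @return List of class `"credible_set"`: `variants` (id, pos, z, p, abf,
#'   pip, in_set), `assigned`, `index_variant`.
#' @export
abf_credible_set <- function(locus_sumstats, index_variant, panel = NULL,
                             prior_sd = 0.3, assign_r2 = 0.8,
                             assign_window_kb = 3000, p_threshold = 5e-8) {
  if (prior_sd <= 0) stop("`prior_sd` must be positive", call. = FALSE)
  ss <- locus_sumstats
  z <- ss$beta / ss$se
  rr <- prior_sd^2 / (prior_sd^2 + ss$se^2)
  labf <- 0.5 * log(1 - rr) + z^2 * rr / 2
  pip <- exp(labf - max(labf))
  pip <- pip / sum(pip)
  ord <- order(pip, decreasing = TRUE)
  cum <- cumsum(pip[ord])
  in_set <- logical(length(pip))
  in_set[ord[seq_len(which(cum >= 0.95)[1])]] <- TRUE
  out <- data.frame(id = ss$id, pos = ss$pos, z = z, p = ss$p,
                    abf = exp(labf), pip = pip, in_set = in_set,
                    stringsAsFactors = FALSE)
  assigned <- NA
  if (!is.null(panel) && index_variant %in% panel$variants$id) {
    ipos <- panel$variants$pos[match(index_variant, panel$variants$id)]
    cand <- out$id[out$in_set & out$p < p_threshold &
                   abs(out$pos - ipos) <= assign_window_kb * 1000]
    cand <- intersect(cand, panel$variants$id)
    assigned <- FALSE
    if (length(cand) > 0) {
      rr2 <- dosage_r2(panel$dosages[, unique(c(index_variant, cand)),
                                     drop = FALSE])
      assigned <- any(rr2[1, -1] > assign_r2) ||
        index_variant %in% cand
    }
  }
  structure(list(variants = out, assigned = assigned,
                 index_variant = index_variant),
            class = "credible_set")
}

#' Summary-data Mendelian randomization with HEIDI for one gene
#'
#' The effect of gene regulation on the outcome is the ratio of the top
#' instrument's outcome and exposure effects, `beta_xy = beta_zy / beta_zx`,
#' with delta-method SE
#' `|beta_xy| * sqrt(se_zy^2/beta_zy^2 + se_zx^2/beta_zx^2)` and a normal
#' test. HEIDI tests heterogeneity of the per-instrument ratios against the
#' top instrument over secondary instruments in intermediate LD
#' (`heidi_r2[1] < r^2 < heidi_r2[2]`, at most `max_instruments`), using the
#' LD-aware delta-method covariance of the deviations; the statistic is
#' chi-squared with one df per secondary instrument. A low HEIDI p indicates
#' linkage rather than mediation/pleiotropy.
#'
#' @param eqtl_records eQTL (or sQTL) records for one gene: variant,
#'   beta_zx, se_zx, p.
#' @param outcome_sumstats Outcome GWAS stats (id, beta, se).
#' @param panel Genotype panel for instrument LD.
#' @param heidi_r2 Secondary-instrument r-squared window.
#' @param max_instruments Cap on secondary instruments.
#' @param instrument_p Validity threshold for the top instrument.
#' @return List of class `"smr_result"`: gene, top_instrument, beta_xy,
#'   se_xy, p_smr, p_heidi, m_instruments; or NULL (with a message) when no
#'   valid instrument exists.
#' @export
smr_heidi <- function(eqtl_records, outcome_sumstats, panel = NULL,
                      heidi_r2 = c(0.05, 0.9), max_instruments = 20,
                      instrument_p = 5e-8) {
  er <- eqtl_records[eqtl_records$variant %in% outcome_sumstats$id, ,
                     drop = FALSE]
  if (nrow(er) == 0 || min(er$p) >= instrument_p) {
    message("gene ", eqtl_records$gene[1] %||% "?",
            " skipped: no instrument with eQTL p < ", instrument_p)
    return(NULL)
  }
  er <- er[order(er$p), ]
  oc <- outcome_sumstats[match(er$variant, outcome_sumstats$id), ]
  b_ratio <- oc$beta / er$beta_zx
  se_ratio <- abs(b_ratio) *
    sqrt(oc$se^2 / oc$beta^2 + er$se_zx^2 / er$beta_zx^2)
  b_xy <- b_ratio[1]
  se_xy <- se_ratio[1]
  p_smr <- 2 * stats::pnorm(-abs(b_xy / se_xy))

  p_heidi <- NA_real_
  m_used <- 1L
  if (!is.null(panel) && nrow(er) > 1) {
    ids <- er$variant
    r_ld <- suppressWarnings(stats::cor(panel$dosages[, ids, drop = FALSE]))
    r_ld[!is.finite(r_ld)] <- 0
    r2_top <- r_ld[1, ]^2
    sec <- which(r2_top > heidi_r2[1] & r2_top < heidi_r2[2])
    sec <- setdiff(sec, 1)
    if (length(sec) > max_instruments) sec <- sec[seq_len(max_instruments)]
    if (length(sec) > 0) {
      idx <- c(1, sec)
      vb <- function(i, j) {
        # delta-method covariance of ratio estimates i and j
        r <- r_ld[idx[i], idx[j]]
        (r * oc$se[idx[i]] * oc$se[idx[j]] +
         b_ratio[idx[i]] * b_ratio[idx[j]] * r *
           er$se_zx[idx[i]] * er$se_zx[idx[j]]) /
          (er$beta_zx[idx[i]] * er$beta_zx[idx[j]])
      }
      m <- length(idx)
      V <- outer(seq_len(m), seq_len(m), Vectorize(vb))
      d <- b_ratio[sec] - b_xy
      Vd <- V[-1, -1, drop = FALSE] -
        matrix(V[-1, 1], m - 1, m - 1) -
        t(matrix(V[-1, 1], m - 1, m - 1)) + V[1, 1]
      Vd_inv <- tryCatch(solve(Vd), error = function(e)
        MASS::ginv(Vd + diag(1e-10, nrow(Vd))))
      T_stat <- as.numeric(t(d) %*% Vd_inv %*% d)
      p_heidi <- stats::pchisq(T_stat, df = length(sec),
                               lower.tail = FALSE)
      m_used <- m
    }
  }
  structure(list(gene = er$gene[1], top_instrument = er$variant[1],
                 beta_xy = b_xy, se_xy = se_xy, p_smr = p_smr,
                 p_heidi = p_heidi, m_instruments = m_used),
            class = "smr_result")
}

#' SMR across genes with FDR and retention flags
#'
#' Runs [smr_heidi()] per gene and applies BH FDR within the probe type;
#' a gene passes when `FDR < 0.05` and `p_heidi > 0.01` (an NA HEIDI p, as
#' for single-instrument genes, does not disqualify).
#'
#' @param records eQTL/sQTL records across genes.
#' @param outcome_sumstats Outcome GWAS stats.
#' @param panel Genotype panel for LD.
#' @param probe_type `"eQTL"` or `"sQTL"`.
#' @param ... Passed to [smr_heidi()].
#' @return Data frame: gene, probe_type, top_instrument, beta_xy, se_xy,
#'   p_smr, p_heidi, fdr, passes.
#' @export
smr_table <- function(records, outcome_sumstats, panel = NULL,
                      probe_type = "eQTL", ...) {
  res <- lapply(split(records, records$gene), function(er)
    smr_heidi(er, outcome_sumstats, panel, ...))
  res <- res[!vapply(res, is.null, TRUE)]
  if (length(res) == 0) return(NULL)
  out <- do.call(rbind, lapply(res, function(r)
    data.frame(gene = r$gene, probe_type = probe_type,
               top_instrument = r$top_instrument, beta_xy = r$beta_xy,
               se_xy = r$se_xy, p_smr = r$p_smr, p_heidi = r$p_heidi,
               m_instruments = r$m_instruments, stringsAsFactors = FALSE)))
  out$fdr <- stats::p.adjust(out$p_smr, "BH")
  out$passes <- out$fdr < 0.05 & (is.na(out$p_heidi) | out$p_heidi > 0.01)
  rownames(out) <- NULL
  out
}

#' Seven-stream gene nomination for one locus
#'
#' Fills the seven evidence categories: (1) per-gene posterior mass of
#' credible variants (the `C_i` stream, unranked); (2) nonsynonymous
#' credible variants ranked by max CADD Phred score; (3) SMR eQTL and
#' (4) SMR sQTL genes ranked by SMR p; (5) single-tissue eQTL genes ranked
#' by the number of significant tissue associations among the lookup
#' variants (index variant plus genome-wide-significant neighbors with
#' `r^2 > 0.8`); (6) multi-tissue eQTL genes after the lookup filters
#' (10+ tissues, m-value >= 0.9 in >= 50% of tissues, RE2 p < 5e-8),
#' ranked by tissue count; (7) up to 3 genes within 500 kb of the index
#' variant with the highest PoPS scores. Ranks are competition ranks.
#'
#' @param credible_set A [abf_credible_set()] result.
#' @param fixture An `"omics_fixture"` (genes, exons, cadd, pops,
#'   eqtl_records, multi_tissue).
#' @param smr_eqtl,smr_sqtl Optional [smr_table()] outputs (rows passing
#'   retention are nominated).
#' @param panel Genotype panel for the strong-LD lookup neighborhood.
#' @param locus_id Locus identifier attached to the rows.
#' @param pops_window_kb PoPS neighborhood half-width (kb).
#' @return Data frame of class `"nomination_table"`: locus_id, gene,
#'   category (1-7), score, rank (NA in category 1); `n_j` attribute gives
#'   per-category gene counts.
#' @export
nominate_genes <- function(credible_set, fixture, smr_eqtl = NULL,
                           smr_sqtl = NULL, panel = NULL, locus_id = 1L,
                           pops_window_kb = 500) {
  genes <- fixture$genes
  cs <- credible_set$variants[credible_set$variants$in_set, , drop = FALSE]
  vtab <- if (!is.null(panel)) panel$variants else NULL
  chrom_of <- function(ids) {
    if (is.null(vtab)) rep(genes$chrom[1], length(ids))
    else vtab$chrom[match(ids, vtab$id)]
  }

  rows <- list()
  add <- function(gene, category, score, rank = NA_real_)
    rows[[length(rows) + 1]] <<- data.frame(
      locus_id = locus_id, gene = gene, category = category,
      score = score, rank = rank, stringsAsFactors = FALSE)

  # (1) credible-variant posterior mass per mapped gene
  if (nrow(cs) > 0) {
    mapped <- vapply(seq_len(nrow(cs)), function(i)
      map_variant_to_gene(chrom_of(cs$id[i]), cs$pos[i], genes,
                          fixture$exons)$gene, character(1))
    mass <- tapply(cs$pip, mapped, sum)
    for (g in names(mass)) add(g, 1L, unname(mass[g]))
  }

  # (2) nonsynonymous credible variants, max CADD per gene
  if (nrow(cs) > 0 && !is.null(fixture$cadd)) {
    cd <- fixture$cadd[match(cs$id, fixture$cadd$variant), ]
    ns <- which(!is.na(cd$consequence) & cd$consequence == "nonsynonymous")
    if (length(ns) > 0) {
      gmap <- vapply(ns, function(i)
        map_variant_to_gene(chrom_of(cs$id[i]), cs$pos[i], genes,
                            fixture$exons)$gene, character(1))
      mx <- tapply(cd$phred_score[ns], gmap, max)
      rk <- competition_rank(as.numeric(mx))
      for (i in seq_along(mx))
        add(names(mx)[i], 2L, unname(mx[i]), rk[i])
    }
  }

  # (3)/(4) SMR probes passing retention
  for (smr in list(list(tab = smr_eqtl, cat = 3L),
                   list(tab = smr_sqtl, cat = 4L))) {
    tb <- smr$tab
    if (!is.null(tb)) {
      tb <- tb[tb$passes, , drop = FALSE]
      if (nrow(tb) > 0) {
        rk <- competition_rank(-log10(tb$p_smr))
        for (i in seq_len(nrow(tb)))
          add(tb$gene[i], smr$cat, tb$p_smr[i], rk[i])
      }
    }
  }

  # lookup variants: index + significant credible neighbors in strong LD
  lookup_ids <- credible_set$index_variant
  if (!is.null(panel) && nrow(cs) > 0) {
    cand <- intersect(cs$id[cs$p < 5e-8], vtab$id)
    cand <- setdiff(cand, lookup_ids)
    if (length(cand) > 0) {
      rr <- dosage_r2(panel$dosages[, c(credible_set$index_variant, cand),
                                    drop = FALSE])
      lookup_ids <- c(lookup_ids, cand[rr[1, -1] > 0.8])
    }
  }

  # (5) single-tissue eQTL lookup: count of significant tissues per gene
  if (!is.null(fixture$eqtl_records)) {
    st <- fixture$eqtl_records
    st <- st[st$variant %in% lookup_ids & st$p < 5e-8, , drop = FALSE]
    if (nrow(st) > 0) {
      cnt <- tapply(st$tissue, st$gene, function(x) length(unique(x)))
      rk <- competition_rank(as.numeric(cnt))
      for (i in seq_along(cnt))
        add(names(cnt)[i], 5L, unname(cnt[i]), rk[i])
    }
  }

  # (6) multi-tissue lookup after the stated filters
  if (!is.null(fixture$multi_tissue)) {
    mt <- fixture$multi_tissue
    mt <- mt[mt$variant %in% lookup_ids, , drop = FALSE]
    if (nrow(mt) > 0) {
      keys <- split(mt, paste(mt$gene, mt$variant))
      keep <- Filter(function(d) {
        d$n_tissues[1] >= 10 && mean(d$m_value >= 0.9) >= 0.5 &&
          d$re2_p[1] < 5e-8
      }, keys)
      if (length(keep) > 0) {
        cnt <- vapply(keep, function(d) sum(d$m_value >= 0.9), numeric(1))
        gene_cnt <- tapply(cnt, vapply(keep, function(d) d$gene[1], ""),
                           max)
        rk <- competition_rank(as.numeric(gene_cnt))
        for (i in seq_along(gene_cnt))
          add(names(gene_cnt)[i], 6L, unname(gene_cnt[i]), rk[i])
      }
    }
  }

  # (7) PoPS: top 3 genes within the window around the index variant
  if (!is.null(fixture$pops) && !is.null(vtab)) {
    ipos <- vtab$pos[match(credible_set$index_variant, vtab$id)]
    ichr <- vtab$chrom[match(credible_set$index_variant, vtab$id)]
    near <- genes[genes$chrom == ichr &
                  pmax(genes$start - ipos, ipos - genes$end, 0) <=
                    pops_window_kb * 1000, ]
    ps <- fixture$pops[fixture$pops$gene %in% near$symbol, , drop = FALSE]
    if (nrow(ps) > 0) {
      ps <- ps[order(-ps$score), ][seq_len(min(3, nrow(ps))), ]
      rk <- competition_rank(ps$score)
      for (i in seq_len(nrow(ps)))
        add(ps$gene[i], 7L, ps$score[i], rk[i])
    }
  }

  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(locus_id = integer(0), gene = character(0),
               category = integer(0), score = numeric(0), rank = numeric(0))
  n_j <- vapply(1:7, function(j) sum(out$category == j), integer(1))
  structure(out, n_j = n_j, class = c("nomination_table", "data.frame"))
}

#' Composite gene priority score
#'
#' `P_i = C_i + sum_j 2 (n_j + 1 - R_ij) / (n_j (n_j + 1))` over the six
#' ranked nomination categories, where `C_i` is the gene's cumulative
#' credible-variant posterior probability and `R_ij` its competition rank in
#' category `j` of `n_j` ranked genes. Within any category, contributions
#' over ranks `1..n_j` sum to exactly 1, so each category contributes one
#' point in total. The gene with the highest `P_i` wins; exact ties go to
#' the gene nearest the index variant when gene positions are supplied.
#'
#' @param nominations A [nominate_genes()] table.
#' @param genes Optional gene table for the tie-break distance.
#' @param index_pos Optional index-variant position for the tie-break.
#' @return List of class `"priority_result"`: `scores` (gene, c_i, p_i),
#'   `winner`, `tie_break_used`.
#' @export
priority_score <- function(nominations, genes = NULL, index_pos = NULL) {
  nm <- as.data.frame(nominations)
  if (nrow(nm) == 0)
    return(structure(list(scores = NULL, winner = NA_character_,
                          tie_break_used = FALSE),
                     class = "priority_result"))
  for (j in 2:7) {
    gj <- nm$gene[nm$category == j]
    if (anyDuplicated(gj))
      stop("duplicate gene rows within category ", j, call. = FALSE)
  }
  all_genes <- unique(nm$gene)
  ci <- stats::setNames(numeric(length(all_genes)), all_genes)
  mass <- nm[nm$category == 1, ]
  ci[mass$gene] <- mass$score
  pi_score <- ci
  for (j in 2:7) {
    sub <- nm[nm$category == j, ]
    n_j <- nrow(sub)
    if (n_j == 0) next
    contrib <- 2 * (n_j + 1 - sub$rank) / (n_j * (n_j + 1))
    pi_score[sub$gene] <- pi_score[sub$gene] + contrib
  }
  scores <- data.frame(gene = all_genes, c_i = unname(ci[all_genes]),
                       p_i = unname(pi_score[all_genes]),
                       stringsAsFactors = FALSE)
  scores <- scores[order(-scores$p_i), ]
  rownames(scores) <- NULL
  top <- scores$gene[scores$p_i == max(scores$p_i)]
  tie_break_used <- length(top) > 1
  winner <- top[1]
  if (tie_break_used && !is.null(genes) && !is.null(index_pos)) {
    gi <- genes[match(top, genes$symbol), ]
    d <- pmax(gi$start - index_pos, index_pos - gi$end, 0)
    winner <- top[order(d, gi$start)][1]
  }
  structure(list(scores = scores, winner = winner,
                 tie_break_used = tie_break_used),
            class = "priority_result")
}
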