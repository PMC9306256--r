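# Region-set enrichment of CpG lists and regulatory-potential target-gene
# selection.

#' Region-set enrichment of a CpG list by Fisher's exact test
#'
#' Each CpG is represented by a fixed-width window centered on it
#' (default 200 bp: \[pos - 100, pos + 100) in 0-based coordinates). For
#' every region set, the 2x2 table counts query CpGs overlapping /
#' not overlapping the set (a, b) against the non-query background CpGs
#' (c, d); a two-sided Fisher exact test gives the p-value and the odds
#' ratio is (a d)/(b c), with a 0.5 continuity correction only when a zero
#' cell occurs (flagged). P-values are BH-adjusted across sets.
#'
#' @param query_cpgs,background_cpgs Probe IDs; the query must be a subset
#'   of the background.
#' @param region_sets A list of [region_set()] objects.
#' @param m The `bm_manifest` supplying 1-based probe coordinates.
#' @param window Window width in bp (default 200).
#' @return data.frame with one row per set: `set`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `continuity` (logical), `p`, `q`.
#' @export
region_enrichment <- function(query_cpgs, background_cpgs, region_sets,
                              m, window = 200) {
    if (!length(background_cpgs)) stop("empty background")
    if (!all(query_cpgs %in% background_cpgs))
        stop("query CpGs must be a subset of the background")
    rest <- setdiff(background_cpgs, query_cpgs)
    win <- function(ids) {
        i <- match(ids, m$probe_id)
        if (anyNA(i)) stop("CpG absent from manifest: ",
                           ids[is.na(i)][1L])
        p0 <- m$pos[i] - 1  # 0-based position
        list(chrom = m$chrom[i], start = p0 - window / 2,
             end = p0 + window / 2)
    }
    wq <- win(query_cpgs); wr <- win(rest)
    rows <- lapply(region_sets, function(rs) {
        a <- sum(region_overlaps(rs, wq$chrom, wq$start, wq$end))
        b <- length(query_cpgs) - a
        cc <- sum(region_overlaps(rs, wr$chrom, wr$start, wr$end))
        d <- length(rest) - cc
        p <- stats::fisher.test(matrix(c(a, b, cc, d), 2L),
                                alternative = "two.sided")$p.value
        zero <- any(c(a, b, cc, d) == 0)
        or <- if (zero) ((a + 0.5) * (d + 0.5)) /
                  ((b + 0.5) * (cc + 0.5))
              else (a * d) / (b * cc)
        data.frame(set = rs$name, a = a, b = b, c = cc, d = d,
                   odds_ratio = or, continuity = zero, p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- stats::p.adjust(out$p, "BH")
    rownames(out) <- NULL
    out
}

#' Select putative target genes of differentially methylated CpGs
#'
#' For each CpG, the candidate genes are the at most `n_per_side` nearest
#' genes within `max_dist` upstream and the same number downstream (by TSS
#' position). A candidate is retained only if, for every required
#' transcription factor, at least one ChIP-seq experiment assigns it a
#' regulatory-potential (RP) score above `rp_min`; a gene absent from the
#' RP table fails that factor.
#'
#' @param cpgs data.frame with `chrom` and `pos` (1-based CpG positions).
#' @param tss_table data.frame with `gene`, `chrom`, `tss` (1-based).
#' @param rp_scores data.frame with `gene`, `factor`, `experiment`,
#'   `score`.
#' @param n_per_side Genes per side (default 10).
#' @param max_dist Distance bound in bp (default 1e6 = 1,000 kb).
#' @param rp_min RP score threshold (default 2, strict).
#' @param required_factors Factors that must all support the gene.
#' @return Sorted character vector of retained gene names.
#' @export
select_target_genes <- function(cpgs, tss_table, rp_scores,
                                n_per_side = 10, max_dist = 1e6,
                                rp_min = 2,
                                required_factors = unique(
                                    rp_scores$factor)) {
    cand <- character()
    for (i in seq_len(nrow(cpgs))) {
        same <- tss_table[tss_table$chrom == cpgs$chrom[i], ,
                          drop = FALSE]
        if (!nrow(same)) next
        delta <- same$tss - cpgs$pos[i]
        near <- abs(delta) <= max_dist
        up <- same$gene[near & delta <= 0]
        dn <- same$gene[near & delta > 0]
        ou <- order(abs(delta[near & delta <= 0]))
        od <- order(delta[near & delta > 0])
        cand <- c(cand, utils::head(up[ou], n_per_side),
                  utils::head(dn[od], n_per_side))
    }
    cand <- unique(cand)
    if (!length(cand)) return(character())
    keep <- vapply(cand, function(g) {
        all(vapply(required_factors, function(f) {
            sc <- rp_scores$score[rp_scores$gene == g &
                                  rp_scores$factor == f]
            length(sc) > 0 && any(sc > rp_min)
        }, TRUE))
    }, TRUE)
    sort(cand[keep])
}
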