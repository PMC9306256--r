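# Mono-allelic methylation screening: nested groups of CpGs with
# intermediate methylation across somatic tissues.

#' Threshold presets for the mono-allelic screen
#'
#' The default preset implements the four-group screen: intermediate beta
#' in (0.3, 0.7), frequent in > 50% of somatic samples (Group I), > 90%
#' with all testis samples polarized (Group II). The `design_screen`
#' preset is the earlier array-design screen: beta in (0.35, 0.65) in over
#' 65% of samples, requiring more than 6 informative samples.
#'
#' @param preset "default" or "design_screen".
#' @return A list `lo`, `hi`, `frac1`, `frac2`, `min_samples`.
#' @export
monoallelic_thresholds <- function(preset = c("default",
                                              "design_screen")) {
    preset <- match.arg(preset)
    if (preset == "default")
        list(lo = 0.3, hi = 0.7, frac1 = 0.5, frac2 = 0.9,
             min_samples = 1L)
    else
        list(lo = 0.35, hi = 0.65, frac1 = 0.65, frac2 = 0.9,
             min_samples = 7L)
}

#' Classify probes into nested mono-allelic methylation groups
#'
#' Group I: intermediately methylated (lo < beta < hi) in more than
#' `frac1` of somatic samples. Group II: Group I, intermediate in more
#' than `frac2` of somatic samples, and polarized (beta > hi or beta < lo)
#' in every testis sample — testis is largely spermatocytes, whose
#' imprints are reset. Group III: Group II and located in an imprinting
#' control region (ICR) or secondary DMR; Group IV: Group II and in an
#' ICR. The groups are nested (IV in III in II in I); the highest
#' applicable group is reported, or "none".
#'
#' @param betas Probes x samples beta matrix.
#' @param annot Sample sheet with a `compartment` column
#'   ("somatic"/"testis"/other).
#' @param m The `bm_manifest` (probe coordinates, 1-based).
#' @param icr_regions,sdmr_regions [region_set()]s of ICRs and secondary
#'   DMRs.
#' @param thresholds A [monoallelic_thresholds()] list.
#' @return data.frame `probe_id`, `frac_intermediate`,
#'   `testis_polarized`, `group` ("none"/"I"/"II"/"III"/"IV").
#' @export
classify_monoallelic <- function(betas, annot, m, icr_regions,
                                 sdmr_regions,
                                 thresholds = monoallelic_thresholds()) {
    th <- thresholds
    som <- which(annot$compartment == "somatic")
    tes <- which(annot$compartment == "testis")
    if (!length(som)) stop("no somatic samples")
    Bs <- betas[, som, drop = FALSE]
    inter <- Bs > th$lo & Bs < th$hi
    n_obs <- rowSums(!is.na(Bs))
    frac <- rowSums(inter, na.rm = TRUE) / pmax(n_obs, 1L)
    g1 <- n_obs >= th$min_samples & frac > th$frac1
    if (!length(tes)) {
        warning("no testis samples; Groups II-IV unavailable")
        pol <- rep(NA, nrow(betas))
        g2 <- rep(FALSE, nrow(betas))
    } else {
        Bt <- betas[, tes, drop = FALSE]
        pol <- apply(Bt, 1L, function(b) {
            b <- b[!is.na(b)]
            length(b) > 0 && all(b > th$hi | b < th$lo)
        })
        g2 <- g1 & frac > th$frac2 & pol
    }
    i <- match(rownames(betas), m$probe_id)
    p0 <- m$pos[i] - 1
    has_pos <- !is.na(p0)
    in_icr <- in_sdmr <- rep(FALSE, nrow(betas))
    in_icr[has_pos] <- region_overlaps(icr_regions, m$chrom[i][has_pos],
                                       p0[has_pos], p0[has_pos] + 1)
    in_sdmr[has_pos] <- region_overlaps(sdmr_regions, m$chrom[i][has_pos],
                                        p0[has_pos], p0[has_pos] + 1)
    g3 <- g2 & (in_icr | in_sdmr)
    g4 <- g2 & in_icr
    group <- rep("none", nrow(betas))
    group[g1] <- "I"; group[g2] <- "II"; group[g3] <- "III"
    group[g4] <- "IV"
    data.frame(probe_id = rownames(betas), frac_intermediate = frac,
               testis_polarized = pol, group = group,
               stringsAsFactors = FALSE, row.names = NULL)
}
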