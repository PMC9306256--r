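#' Apply the probe designability filter
#'
#' A candidate Infinium probe design is retained only when it maps uniquely
#' and hybridizes cleanly: every subsequence (30, 35, 40 nt and the full
#' probe) of both the methylated and unmethylated allele versions must align
#' with mapping quality strictly greater than 20; no SNP and no off-target
#' CpG may lie within 10 nt of the probe 3'-end (strictly more than 10 nt
#' away); the probe sequence must contain fewer than six CpGs; and the 0-1
#' design score (hybridization efficiency from GC content and melting
#' temperature, computed upstream and taken as an input) must exceed 0.3.
#'
#' @param candidates A data.frame (or single-row list) with columns
#'   `mapq_30_M`, `mapq_35_M`, `mapq_40_M`, `mapq_full_M`, `mapq_30_U`,
#'   `mapq_35_U`, `mapq_40_U`, `mapq_full_U`, `dist_snp_3p`, `dist_cpg_3p`,
#'   `cpg_count`, `design_score`.
#' @return A data.frame with logical `pass` and character `failed_rules`
#'   (comma-joined subset of "mapq", "dist_snp", "dist_cpg", "cpg_count",
#'   "design_score"; empty string when passing), one row per candidate.
#' @export
filter_designable <- function(candidates) {
    candidates <- as.data.frame(candidates)
    req <- c(sprintf("mapq_%s_%s", rep(c("30", "35", "40", "full"), 2L),
                     rep(c("M", "U"), each = 4L)),
             "dist_snp_3p", "dist_cpg_3p", "cpg_count", "design_score")
    missing <- setdiff(req, names(candidates))
    if (length(missing))
        stop("candidate table missing fields: ", paste(missing, collapse = ", "))
    if (anyNA(candidates[req]))
        stop("candidate table contains missing values in required fields")
    if (any(candidates$dist_snp_3p < 0) || any(candidates$dist_cpg_3p < 0))
        stop("3'-end distances must be >= 0")
    if (any(candidates$design_score < 0 | candidates$design_score > 1))
        stop("design_score must lie in [0, 1]")

    mapq_cols <- req[1:8]
    mapq_ok <- Reduce(`&`, lapply(mapq_cols, function(cn) candidates[[cn]] > 20))
    rules <- cbind(
        mapq = mapq_ok,
        dist_snp = candidates$dist_snp_3p > 10,
        dist_cpg = candidates$dist_cpg_3p > 10,
        cpg_count = candidates$cpg_count < 6,
        design_score = candidates$design_score > 0.3)
    failed <- apply(rules, 1L, function(r)
        paste(colnames(rules)[!r], collapse = ","))
    data.frame(pass = rowSums(!rules) == 0L, failed_rules = failed,
               stringsAsFactors = FALSE)
}
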