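#' Construct and validate a probe manifest
#'
#' The manifest is the static description of every probe on the array:
#' chemistry (Infinium-I vs Infinium-II), design color channel, target class
#' (CG, CH, SNP or control), genomic coordinate (1-based, array-annotation
#' convention; absent for controls), design-category tags, the default
#' quality mask (probes with the `uk` prefix or multi-mapping designs), an
#' optional human syntenic probe ID, and — for SNP probes — reference and
#' alternate alleles plus per-strain reference genotypes.
#'
#' @param df A data.frame with columns `probe_id`, `chemistry` ("I"/"II"),
#'   `channel` ("Red"/"Green" for Infinium-I, "Both" for Infinium-II),
#'   `target` ("CG"/"CH"/"SNP"/"control"), `chrom`, `pos` (1-based, NA
#'   allowed for controls), `strand` ("+"/"-"/"*"), `categories`
#'   (semicolon-joined tags), `mask_default` (logical), and optionally
#'   `human_syntenic_id`, `snp_ref_allele`, `snp_alt_allele` and any number
#'   of `genotype_<strain>` columns coded 0/1/NA.
#' @return The validated data.frame with class `bm_manifest`.
#' @export
manifest <- function(df) {
    req <- c("probe_id", "chemistry", "channel", "target", "chrom", "pos",
             "strand", "categories", "mask_default")
    missing <- setdiff(req, names(df))
    if (length(missing))
        stop("manifest missing columns: ", paste(missing, collapse = ", "))
    if (anyDuplicated(df$probe_id))
        stop("duplicate probe_id in manifest: ",
             df$probe_id[duplicated(df$probe_id)][1L])
    if (!all(df$chemistry %in% c("I", "II")))
        stop("chemistry must be 'I' or 'II'")
    i1 <- df$chemistry == "I"
    if (!all(df$channel[i1] %in% c("Red", "Green")))
        stop("Infinium-I probes must have channel Red or Green")
    if (!all(df$channel[!i1] == "Both"))
        stop("Infinium-II probes must have channel 'Both'")
    if (!all(df$target %in% c("CG", "CH", "SNP", "control")))
        stop("target must be one of CG, CH, SNP, control")
    pos_ok <- is.na(df$pos) | df$pos >= 1
    if (!all(pos_ok)) stop("manifest positions are 1-based (pos >= 1)")
    df$mask_default <- as.logical(df$mask_default)
    rownames(df) <- df$probe_id
    class(df) <- c("bm_manifest", "data.frame")
    df
}

#' @export
print.bm_manifest <- function(x, ...) {
    cat(sprintf("bm_manifest: %d probes (%d Infinium-I, %d Infinium-II)\n",
                nrow(x), sum(x$chemistry == "I"), sum(x$chemistry == "II")))
    tab <- table(x$target)
    cat("  targets:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "), "\n")
    gt <- grep("^genotype_", names(x), value = TRUE)
    if (length(gt))
        cat("  strain genotype columns:", length(gt), "\n")
    invisible(x)
}

#' Read a manifest TSV
#'
#' @param path Path to a tab-separated manifest with the columns described
#'   in [manifest()].
#' @return A `bm_manifest`.
#' @export
load_manifest <- function(path) {
    if (!file.exists(path)) stop("manifest file not found: ", path)
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
    if (anyDuplicated(df$probe_id)) {
        line <- which(duplicated(df$probe_id))[1L] + 1L  # + header line
        stop(sprintf("duplicate probe_id '%s' at line %d",
                     df$probe_id[duplicated(df$probe_id)][1L], line))
    }
    bad <- which(!is.na(df$pos) & (is.na(suppressWarnings(as.numeric(df$pos))) |
                                   as.numeric(df$pos) < 1))
    if (length(bad))
        stop(sprintf("malformed coordinate at line %d", bad[1L] + 1L))
    df$pos <- as.numeric(df$pos)
    if (is.null(df$categories)) df$categories <- ""
    df$categories[is.na(df$categories)] <- ""
    manifest(df)
}

#' Write a manifest TSV
#' @param m A `bm_manifest`.
#' @param path Output path.
#' @export
write_manifest <- function(m, path) {
    utils::write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

# Internal: does each probe carry a category tag?
has_category <- function(m, tag) {
    vapply(strsplit(ifelse(is.na(m$categories), "", m$categories), ";",
                    fixed = TRUE),
           function(x) tag %in% x, TRUE)
}

#' Extract the strain genotype reference from a manifest
#'
#' @param m A `bm_manifest` with `genotype_<strain>` columns on its SNP
#'   probes (0 = homozygous reference allele, 1 = homozygous alternate,
#'   NA = unknown).
#' @return A list with `G` (strains x SNPs matrix in 0/1/NA), `strains`,
#'   and `snps` (probe IDs).
#' @export
strain_reference <- function(m) {
    gt_cols <- grep("^genotype_", names(m), value = TRUE)
    if (length(gt_cols) < 2L)
        stop("manifest must carry genotype columns for at least 2 strains")
    snp <- m$target == "SNP"
    if (!any(snp)) stop("manifest has no SNP probes")
    G <- t(as.matrix(as.data.frame(m)[snp, gt_cols, drop = FALSE]))
    rownames(G) <- sub("^genotype_", "", gt_cols)
    colnames(G) <- m$probe_id[snp]
    storage.mode(G) <- "numeric"
    list(G = G, strains = rownames(G), snps = colnames(G))
}
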