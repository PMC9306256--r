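#' Construct a two-channel signal frame
#'
#' Raw Infinium intensities for one sample: per probe, the methylated (M)
#' and unmethylated (U) allele intensities in the Green and Red channels.
#' For an Infinium-I probe only the design channel is "in band"; the other
#' channel's readings are out-of-band (OOB) and act as a background proxy.
#' Infinium-II probes read M in Green and U in Red.
#'
#' @param df A data.frame with columns `probe_id`, `MG`, `UG`, `MR`, `UR`
#'   (non-negative fluorescence intensities).
#' @return The validated data.frame with class `signal_frame`.
#' @export
signal_frame <- function(df) {
    req <- c("probe_id", "MG", "UG", "MR", "UR")
    missing <- setdiff(req, names(df))
    if (length(missing))
        stop("signal frame missing columns: ", paste(missing, collapse = ", "))
    for (cn in c("MG", "UG", "MR", "UR")) {
        df[[cn]] <- as.numeric(df[[cn]])
        if (anyNA(df[[cn]]) || any(df[[cn]] < 0))
            stop("signal intensities must be non-negative and non-missing (",
                 cn, ")")
    }
    if (anyDuplicated(df$probe_id)) stop("duplicate probe_id in signal frame")
    rownames(df) <- df$probe_id
    class(df) <- c("signal_frame", "data.frame")
    df
}

#' Read a per-sample signal TSV (probe_id, MG, UG, MR, UR)
#' @param path File path.
#' @return A [signal_frame()].
#' @export
read_signals <- function(path) {
    if (!file.exists(path)) stop("signal file not found: ", path)
    signal_frame(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a signal frame as TSV
#' @param s A [signal_frame()].
#' @param path Output path.
#' @export
write_signals <- function(s, path) {
    utils::write.table(as.data.frame(s), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a beta matrix (probes x samples) as TSV with NA for masked entries
#' @param betas Numeric matrix, probes in rows.
#' @param path Output path.
#' @export
write_beta_matrix <- function(betas, path) {
    df <- data.frame(probe_id = rownames(betas), betas,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Read a beta matrix TSV written by [write_beta_matrix()]
#' @param path File path.
#' @return Numeric matrix with probe IDs as rownames.
#' @export
read_beta_matrix <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    storage.mode(m) <- "numeric"
    m
}
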