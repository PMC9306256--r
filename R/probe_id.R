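#' Parse an array probe identifier
#'
#' Probe IDs on the mouse methylation array carry a four-letter suffix that
#' uniquely identifies replicate designs of the same locus:
#' `<prefix><stem>_<T|B><C|O><1|2><replicate>`. The first suffix letter says
#' whether the probe was designed against the top (`T`) or bottom (`B`)
#' strand of the 122-mer template, the second whether it targets the
#' bisulfite-converted (`C`) or opposite/synthesized (`O`) strand, the digit
#' gives the Infinium chemistry (I or II), and the trailing integer
#' enumerates replicate designs.
#'
#' @param id Character vector of probe IDs.
#' @return A data.frame with columns `prefix` (cg/ch/rs/uk/ctl), `stem`,
#'   `template_strand` (T/B), `probe_strand` (C/O), `chemistry` (1/2) and
#'   `replicate` (integer >= 1), one row per input ID.
#' @examples
#' parse_probe_id("cg47072751_BC21")
#' @export
parse_probe_id <- function(id) {
    if (!is.character(id) || length(id) < 1L || anyNA(id) || any(!nzchar(id)))
        stop("probe id must be a non-empty character vector")
    m <- regmatches(id, regexec(
        "^(cg|ch|rs|uk|ctl)([A-Za-z0-9]+)_([TB])([CO])([12])([0-9]+)$", id))
    bad <- vapply(m, length, 1L) == 0L
    if (any(bad)) {
        tok <- id[bad][1L]
        # name the offending token: prefix or suffix
        if (!grepl("^(cg|ch|rs|uk|ctl)", tok))
            stop(sprintf("unknown probe prefix in '%s'", tok))
        stop(sprintf("malformed probe-id suffix in '%s' (expected _[TB][CO][12][0-9]+)",
                     tok))
    }
    parts <- do.call(rbind, lapply(m, function(x) x[-1L]))
    rep <- as.integer(parts[, 6L])
    if (any(rep < 1L))
        stop("probe replicate index must be >= 1")
    data.frame(
        prefix = parts[, 1L], stem = parts[, 2L],
        template_strand = parts[, 3L], probe_strand = parts[, 4L],
        chemistry = as.integer(parts[, 5L]), replicate = rep,
        stringsAsFactors = FALSE)
}

#' Format probe-ID parts back into an identifier
#'
#' Inverse of [parse_probe_id()]: `format_probe_id(parse_probe_id(x))`
#' reproduces `x` for canonical IDs.
#'
#' @param parts A data.frame as returned by [parse_probe_id()].
#' @return Character vector of probe IDs.
#' @export
format_probe_id <- function(parts) {
    stopifnot(all(c("prefix", "stem", "template_strand", "probe_strand",
                    "chemistry", "replicate") %in% names(parts)))
    sprintf("%s%s_%s%s%d%d", parts$prefix, parts$stem,
            parts$template_strand, parts$probe_strand,
            as.integer(parts$chemistry), as.integer(parts$replicate))
}
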