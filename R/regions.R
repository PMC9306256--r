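#' Construct a genomic region set
#'
#' A lightweight container for a named collection of genomic intervals in
#' 0-based half-open coordinates (the BED convention), used for imprinting
#' control regions, secondary DMRs and ChIP peak sets.
#'
#' @param name Character label for the set.
#' @param chrom,start,end Parallel vectors of interval coordinates,
#'   0-based half-open (`start < end`).
#' @return An object of class `region_set`: a list with `name` and a
#'   data.frame `intervals` (chrom, start, end).
#' @export
region_set <- function(name, chrom = character(), start = integer(),
                       end = integer()) {
    stopifnot(length(chrom) == length(start), length(start) == length(end))
    start <- as.numeric(start); end <- as.numeric(end)
    if (any(start >= end))
        stop("region_set requires start < end (0-based half-open)")
    structure(list(
        name = as.character(name),
        intervals = data.frame(chrom = as.character(chrom),
                               start = start, end = end,
                               stringsAsFactors = FALSE)),
        class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
    cat(sprintf("region_set '%s': %d interval(s)\n", x$name,
                nrow(x$intervals)))
    if (nrow(x$intervals)) print(utils::head(x$intervals, 5L))
    invisible(x)
}

#' @export
length.region_set <- function(x) nrow(x$intervals)

#' Read a BED3 file as a region set
#'
#' @param path Path to a 3+ column BED file (0-based half-open). An empty
#'   file yields an empty, valid set.
#' @param name Set label; defaults to the file name.
#' @return A [region_set()].
#' @export
load_regions <- function(path, name = basename(path)) {
    if (!file.exists(path)) stop("BED file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
    if (!length(lines)) return(region_set(name))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    for (i in seq_along(fields)) {
        f <- fields[[i]]
        if (length(f) < 3L)
            stop(sprintf("malformed BED line %d: fewer than 3 columns", i))
        s <- suppressWarnings(as.numeric(f[2L]))
        e <- suppressWarnings(as.numeric(f[3L]))
        if (is.na(s) || is.na(e) || s >= e)
            stop(sprintf("malformed coordinate at BED line %d", i))
    }
    region_set(name,
               chrom = vapply(fields, `[`, "", 1L),
               start = as.numeric(vapply(fields, `[`, "", 2L)),
               end   = as.numeric(vapply(fields, `[`, "", 3L)))
}

#' Write a region set as BED3
#' @param x A [region_set()].
#' @param path Output path.
#' @export
write_regions <- function(x, path) {
    stopifnot(inherits(x, "region_set"))
    df <- x$intervals
    utils::write.table(
        data.frame(df$chrom, format(df$start, scientific = FALSE,
                                    trim = TRUE),
                   format(df$end, scientific = FALSE, trim = TRUE)),
        path, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    invisible(path)
}

# Internal: convert 0-based half-open intervals to GRanges (1-based closed).
.rs_granges <- function(x) {
    df <- x$intervals
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Query point/interval overlap against a region set
#'
#' @param x A [region_set()].
#' @param chrom,start,end Query intervals, 0-based half-open. For point
#'   queries (a single base at 0-based position p) use `start = p,
#'   end = p + 1`.
#' @return Logical vector: does each query overlap any interval in `x`?
#' @export
region_overlaps <- function(x, chrom, start, end) {
    stopifnot(inherits(x, "region_set"))
    if (!length(chrom)) return(logical())
    if (!nrow(x$intervals)) return(rep(FALSE, length(chrom)))
    q <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(start = start + 1, end = end))
    IRanges::overlapsAny(q, .rs_granges(x))
}

#' Sort and merge overlapping intervals of a region set
#' @param x A [region_set()].
#' @return A [region_set()] with sorted, disjoint intervals.
#' @export
region_reduce <- function(x) {
    stopifnot(inherits(x, "region_set"))
    if (!nrow(x$intervals)) return(x)
    g <- GenomicRanges::reduce(.rs_granges(x))
    region_set(x$name,
               chrom = as.character(GenomicRanges::seqnames(g)),
               start = GenomicRanges::start(g) - 1,
               end = GenomicRanges::end(g))
}
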