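# Human/mouse DNA fraction estimation for patient-derived xenografts:
# channel-switch variant-probe ratios, cross-array intensity ratios, and
# LOESS titration standard curves.

#' Human/(Human+Mouse) signal ratio from channel-switch variant probes
#'
#' Channel-switch probes differ between human and mouse at the extension
#' base, so the human template fluoresces in the channel opposite the
#' probe's (mouse) design channel. Per probe, r = H / (H + M) where H is
#' the in-band allele total in the human channel and M the total in the
#' mouse (design) channel; the sample summary is the median of the
#' per-probe ratios.
#'
#' Use raw or noob-corrected signals here. The Type-I dye-bias quantile
#' map is calibrated on in-band totals and misbehaves on the
#' background-level values the minority channel takes at extreme mixing
#' fractions, so dye-corrected frames should not be used; residual dye
#' bias is absorbed by the titration standard curve.
#'
#' @param signals A [signal_frame()].
#' @param m A `bm_manifest` with channel-switch probes tagged
#'   `channel_switch` in `categories`.
#' @return A list: `ratios` (data.frame probe_id, r) and `ratio` (median).
#' @export
variant_probe_ratio <- function(signals, m) {
    sw <- which(has_category(m, "channel_switch"))
    if (!length(sw)) stop("manifest has no channel-switch probes")
    mm <- m[sw, ]
    s <- signals[match(mm$probe_id, signals$probe_id), ]
    grn <- s$MG + s$UG
    red <- s$MR + s$UR
    red_design <- mm$channel == "Red"
    H <- ifelse(red_design, grn, red)
    M <- ifelse(red_design, red, grn)
    tot <- H + M
    r <- ifelse(tot > 0, H / tot, NA_real_)
    if (anyNA(r)) {
        warning(sum(is.na(r)), " channel-switch probe(s) with zero total ",
                "signal skipped")
    }
    list(ratios = data.frame(probe_id = mm$probe_id, r = r,
                             stringsAsFactors = FALSE),
         ratio = stats::median(r, na.rm = TRUE))
}

#' Cross-array intensity ratio for a sample run on both array types
#'
#' medianH / (medianH + medianM), where medianH and medianM are the medians
#' of per-probe total intensity over the human and mouse arrays'
#' species-specific (non-syntenic) probe subsets.
#'
#' @param human_signals,mouse_signals [signal_frame()]s for the same sample
#'   on the two arrays.
#' @param m_human,m_mouse The two manifests. Non-syntenic probes are those
#'   with target CG/CH, no `human_syntenic_id` and no `channel_switch` tag.
#' @return The ratio in \[0, 1\].
#' @export
intensity_ratio <- function(human_signals, mouse_signals, m_human,
                            m_mouse) {
    nonsyn <- function(m) {
        hs <- if (is.null(m$human_syntenic_id)) rep(NA_character_, nrow(m))
              else m$human_syntenic_id
        m$target %in% c("CG", "CH") & is.na(hs) &
            !has_category(m, "channel_switch")
    }
    tot <- function(s) s$MG + s$UG + s$MR + s$UR
    ph <- m_human$probe_id[nonsyn(m_human)]
    pm <- m_mouse$probe_id[nonsyn(m_mouse)]
    if (!length(ph) || !length(pm))
        stop("empty non-syntenic probe subset")
    medH <- stats::median(tot(human_signals)[
        match(ph, human_signals$probe_id)], na.rm = TRUE)
    medM <- stats::median(tot(mouse_signals)[
        match(pm, mouse_signals$probe_id)], na.rm = TRUE)
    medH / (medH + medM)
}

#' Fit a titration standard curve
#'
#' Per calibration series, a degree-1 LOESS of observed signal ratio on the
#' known mixing fraction; the curve is the pointwise mean of the per-series
#' fits on a fine fraction grid, then projected to a monotone
#' non-decreasing function by isotonic regression so that it is invertible
#' (LOESS itself is not guaranteed monotone).
#'
#' @param series A list of data.frames (or a single data.frame) with
#'   columns `fraction` (strictly increasing within a series) and `ratio`,
#'   optionally `calibration_label`.
#' @param span LOESS span (default 0.75).
#' @param grid_step Evaluation grid step on \[0, 1\] (default 0.005).
#' @return An object of class `standard_curve`: list with `grid`,
#'   `fitted` (monotone), `fitted_raw` (pre-projection mean of fits),
#'   `span`, `n_series`.
#' @export
fit_standard_curve <- function(series, span = 0.75, grid_step = 0.005) {
    if (is.data.frame(series)) {
        series <- if (!is.null(series$calibration_label))
            split(series, series$calibration_label) else list(series)
    }
    grid <- seq(0, 1, by = grid_step)
    fits <- lapply(series, function(s) {
        if (nrow(s) < 5) stop("each titration series needs >= 5 points")
        if (any(diff(s$fraction) <= 0))
            stop("titration fractions must be strictly increasing")
        fit <- stats::loess(ratio ~ fraction, data = s, span = span,
                            degree = 1,
                            control = stats::loess.control(
                                surface = "direct"))
        stats::predict(fit, newdata = data.frame(fraction = grid))
    })
    raw <- Reduce(`+`, fits) / length(fits)
    iso <- stats::isoreg(grid, raw)$yf
    if (max(iso) - min(iso) < 1e-6)
        warning("fitted standard curve is (near-)constant and will not ",
                "be invertible")
    structure(list(grid = grid, fitted = iso, fitted_raw = raw,
                   span = span, n_series = length(fits)),
              class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
    cat(sprintf(
        "standard_curve: %d series, span %.2f, ratio range [%.3f, %.3f]\n",
        x$n_series, x$span, min(x$fitted), max(x$fitted)))
    invisible(x)
}

#' @export
predict.standard_curve <- function(object, fractions, ...) {
    stats::approx(object$grid, object$fitted, xout = fractions,
                  rule = 2)$y
}

#' @export
plot.standard_curve <- function(x, ...) {
    graphics::plot(x$grid, x$fitted, type = "l",
                   xlab = "known human fraction",
                   ylab = "fitted signal ratio", ...)
    graphics::lines(x$grid, x$fitted_raw, lty = 2, col = "grey50")
    invisible(x)
}

#' Invert a standard curve at an observed ratio
#'
#' Linear-interpolated inverse of the monotone fitted curve; ratios outside
#' the fitted range are clamped to 0 or 1 with a warning.
#'
#' @param ratio Observed signal ratio(s).
#' @param curve A [fit_standard_curve()] object.
#' @return Estimated mixing fraction(s) in \[0, 1\].
#' @export
estimate_fraction <- function(ratio, curve) {
    stopifnot(inherits(curve, "standard_curve"))
    lo <- min(curve$fitted); hi <- max(curve$fitted)
    if (hi - lo < 1e-6)
        stop("standard curve is not invertible (constant fitted ratios)")
    out <- numeric(length(ratio))
    below <- ratio < lo; above <- ratio > hi
    if (any(below | above))
        warning("ratio outside the fitted range; estimate clamped")
    out[below] <- 0; out[above] <- 1
    mid <- !(below | above)
    if (any(mid)) {
        # invert on the strictly increasing portion: keep first grid point
        # of each flat run so approx sees unique x
        keep <- c(TRUE, diff(curve$fitted) > 0)
        out[mid] <- stats::approx(curve$fitted[keep], curve$grid[keep],
                                  xout = ratio[mid], rule = 2)$y
    }
    clip01(out)
}
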