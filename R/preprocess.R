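# Preprocessing: detection p-values from out-of-band signal, normexp
# background subtraction, nonlinear dye-bias correction, beta summarization.

#' Collect out-of-band intensities
#'
#' Infinium-I probes fluoresce only in their design channel; their readings
#' in the opposite channel measure pure background. Green OOB comes from
#' Red-channel Infinium-I probes (their MG/UG), Red OOB from Green-channel
#' Infinium-I probes (their MR/UR).
#'
#' @param signals A [signal_frame()].
#' @param m A `bm_manifest` resolving each probe's chemistry and channel.
#' @return A list with numeric vectors `oob_green` and `oob_red`.
#' @export
extract_oob <- function(signals, m) {
    m <- m[match(signals$probe_id, m$probe_id), ]
    if (anyNA(m$probe_id))
        stop("signal frame contains probes absent from the manifest")
    i1 <- m$chemistry == "I"
    if (!any(i1))
        stop("manifest has no Infinium-I probes; background cannot be estimated")
    # channel-switch (human/mouse variant) probes fluoresce in both
    # channels, so their opposite channel is not a background proxy
    i1 <- i1 & !has_category(m, "channel_switch")
    red1 <- i1 & m$channel == "Red"
    grn1 <- i1 & m$channel == "Green"
    list(oob_green = c(signals$MG[red1], signals$UG[red1]),
         oob_red   = c(signals$MR[grn1], signals$UR[grn1]))
}

# Empirical survival p-value with add-one smoothing: never exactly 0.
.p_emp <- function(x, oob) {
    n <- length(oob)
    so <- sort(oob)
    # count of oob >= x, via position in the sorted vector
    cnt <- n - findInterval(x, so, left.open = TRUE)
    (cnt + 1) / (n + 1)
}

#' pOOBAH detection p-values
#'
#' The probability that a probe's in-band signal arises from background
#' alone, measured as the empirical survival fraction of the out-of-band
#' intensity pool at the probe's in-band allele total, with add-one
#' smoothing: p = (#\{oob >= x\} + 1) / (|oob| + 1). Infinium-I probes are
#' tested in their design channel (x = M + U there); Infinium-II probes take
#' the smaller of the per-channel p-values (M tested in Green, U in Red,
#' each with its same-channel partner total).
#'
#' @param signals A [signal_frame()] of raw (uncorrected) intensities.
#' @param oob Out-of-band pool from [extract_oob()].
#' @param m The `bm_manifest`.
#' @return A data.frame `probe_id`, `p` with p in (0, 1].
#' @export
pooah <- function(signals, oob, m) {
    if (!length(oob$oob_green) || !length(oob$oob_red))
        stop("empty out-of-band channel; pOOBAH requires Infinium-I probes ",
             "in both channels")
    m <- m[match(signals$probe_id, m$probe_id), ]
    p <- numeric(nrow(signals))
    i1g <- m$chemistry == "I" & m$channel == "Green"
    i1r <- m$chemistry == "I" & m$channel == "Red"
    i2 <- m$chemistry == "II"
    p[i1g] <- .p_emp(signals$MG[i1g] + signals$UG[i1g], oob$oob_green)
    p[i1r] <- .p_emp(signals$MR[i1r] + signals$UR[i1r], oob$oob_red)
    p[i2] <- pmin(.p_emp(signals$MG[i2] + signals$UG[i2], oob$oob_green),
                  .p_emp(signals$MR[i2] + signals$UR[i2], oob$oob_red))
    data.frame(probe_id = signals$probe_id, p = p,
               stringsAsFactors = FALSE)
}

#' Normal-exponential conditional mean
#'
#' Posterior mean of the true signal s given an observed intensity
#' x = s + b, under s ~ Exponential(alpha) and b ~ Normal(mu_b, sigma_b^2):
#' with mu_s = x - mu_b - sigma_b^2/alpha,
#' E\[s|x\] = mu_s + sigma_b * phi(mu_s/sigma_b) / Phi(mu_s/sigma_b).
#' Evaluated on the log scale so the Mills-ratio term is stable for
#' intensities far below background.
#'
#' @param x Observed intensities.
#' @param mu_b,sigma_b Background mean and s.d. (sigma_b > 0).
#' @param alpha Exponential mean of the true signal (> 0).
#' @return E\[s|x\], strictly positive.
#' @export
normexp_conditional_mean <- function(x, mu_b, sigma_b, alpha) {
    stopifnot(sigma_b > 0, alpha > 0)
    mu_s <- x - mu_b - sigma_b^2 / alpha
    t <- mu_s / sigma_b
    mills <- exp(stats::dnorm(t, log = TRUE) -
                 stats::pnorm(t, log.p = TRUE))
    e <- mu_s + sigma_b * mills
    # guard: the exact posterior mean is positive; clip fp underflow
    pmax(e, .Machine$double.eps)
}

# Estimate normexp parameters for one channel from OOB + in-band intensities.
.normexp_params <- function(oob, inband, alpha_floor = 10) {
    mu_b <- mean(oob)
    sigma_b <- stats::sd(oob)
    if (!is.finite(sigma_b) || sigma_b <= 0) {
        warning("degenerate out-of-band spread; using sigma_b floor")
        sigma_b <- 1
    }
    alpha <- max(mean(inband) - mu_b, alpha_floor)
    list(mu_b = mu_b, sigma_b = sigma_b, alpha = alpha)
}

#' Noob background subtraction
#'
#' Normal-exponential deconvolution using out-of-band intensities to
#' estimate the background distribution: per channel, the background mean
#' and s.d. are the OOB moments, the exponential signal mean is the in-band
#' mean excess over background (floored), and every intensity x in that
#' channel is replaced by E\[s|x\] + offset (see
#' [normexp_conditional_mean()]). Corrected intensities are strictly
#' greater than `offset`.
#'
#' @param signals A [signal_frame()].
#' @param oob Out-of-band pool from [extract_oob()].
#' @param m The `bm_manifest`.
#' @param offset Additive offset after correction (default 15).
#' @param alpha_floor Lower bound on the exponential signal mean.
#' @return A corrected [signal_frame()] with attribute `normexp_params`
#'   (per-channel mu_b, sigma_b, alpha).
#' @export
noob <- function(signals, oob, m, offset = 15, alpha_floor = 10) {
    if (length(oob$oob_green) < 10 || length(oob$oob_red) < 10)
        stop("need at least 10 out-of-band values per channel for noob")
    m <- m[match(signals$probe_id, m$probe_id), ]
    i1g <- m$chemistry == "I" & m$channel == "Green"
    i1r <- m$chemistry == "I" & m$channel == "Red"
    i2 <- m$chemistry == "II"
    inband_g <- c(signals$MG[i1g], signals$UG[i1g], signals$MG[i2])
    inband_r <- c(signals$MR[i1r], signals$UR[i1r], signals$UR[i2])
    pg <- .normexp_params(oob$oob_green, inband_g, alpha_floor)
    pr <- .normexp_params(oob$oob_red, inband_r, alpha_floor)
    out <- signals
    out$MG <- normexp_conditional_mean(signals$MG, pg$mu_b, pg$sigma_b,
                                       pg$alpha) + offset
    out$UG <- normexp_conditional_mean(signals$UG, pg$mu_b, pg$sigma_b,
                                       pg$alpha) + offset
    out$MR <- normexp_conditional_mean(signals$MR, pr$mu_b, pr$sigma_b,
                                       pr$alpha) + offset
    out$UR <- normexp_conditional_mean(signals$UR, pr$mu_b, pr$sigma_b,
                                       pr$alpha) + offset
    attr(out, "normexp_params") <- list(green = pg, red = pr)
    out
}

# Monotone quantile map sending channel `from` onto the geometric-mean
# target distribution. Returns a function of intensity.
.quantile_map <- function(from_totals, red_totals, grn_totals,
                          ngrid = 512L) {
    q <- seq(0, 1, length.out = ngrid)
    Qr <- stats::quantile(red_totals, q, names = FALSE, type = 7)
    Qg <- stats::quantile(grn_totals, q, names = FALSE, type = 7)
    Qt <- sqrt(Qr * Qg)
    Qf <- stats::quantile(from_totals, q, names = FALSE, type = 7)
    function(x) stats::approx(Qf, Qt, xout = x, rule = 2,
                              ties = "ordered")$y
}

#' Nonlinear dye-bias correction
#'
#' The Red and Green channels have systematically different intensity
#' scales. Using Infinium-I probes — whose in-band totals measure the same
#' kind of quantity in a single known channel — this builds the empirical
#' quantile functions of the Red-probe and Green-probe totals and maps every
#' intensity in each channel onto their quantile-wise geometric mean, so
#' that after correction matched quantiles of the two Type-I total
#' distributions agree. The map is monotone non-decreasing and idempotent
#' up to interpolation error.
#'
#' @param signals A [signal_frame()] (typically noob-corrected).
#' @param m The `bm_manifest`.
#' @param min_probes Minimum Infinium-I probes required per channel.
#' @return A corrected [signal_frame()].
#' @export
dyebias_typeI_norm <- function(signals, m, min_probes = 30L) {
    mm <- m[match(signals$probe_id, m$probe_id), ]
    if (anyNA(mm$probe_id))
        stop("signal frame contains probes absent from the manifest")
    i1r <- mm$chemistry == "I" & mm$channel == "Red"
    i1g <- mm$chemistry == "I" & mm$channel == "Green"
    if (sum(i1r) < min_probes || sum(i1g) < min_probes)
        stop("need at least ", min_probes,
             " Infinium-I probes per channel for dye-bias correction")
    red_tot <- signals$MR[i1r] + signals$UR[i1r]
    grn_tot <- signals$MG[i1g] + signals$UG[i1g]
    map_red <- .quantile_map(red_tot, red_tot, grn_tot)
    map_grn <- .quantile_map(grn_tot, red_tot, grn_tot)
    out <- signals
    out$MR <- map_red(signals$MR)
    out$UR <- map_red(signals$UR)
    out$MG <- map_grn(signals$MG)
    out$UG <- map_grn(signals$UG)
    out
}

#' Summarize corrected signals into beta values
#'
#' beta = M / (M + U) with the allele pair taken from the design channel for
#' Infinium-I probes and across channels (M in Green, U in Red) for
#' Infinium-II. Probes are masked to NA when the detection p-value exceeds
#' `p_threshold` (reason "detection"), when the total signal is zero
#' (reason "detection"), or when the manifest flags them as masked by
#' default (`uk`/multi-mapping designs; reason "default_mask", removable
#' with `apply_default_mask = FALSE`).
#'
#' @param signals A corrected [signal_frame()].
#' @param pvals Detection p-values from [pooah()].
#' @param m The `bm_manifest`.
#' @param p_threshold Detection mask threshold (default 0.2).
#' @param apply_default_mask Apply the manifest's default mask (default
#'   TRUE).
#' @return A data.frame `probe_id`, `beta`, `mask_reason`
#'   ("none"/"detection"/"default_mask"); `beta` is NA exactly when
#'   `mask_reason != "none"`.
#' @export
get_betas <- function(signals, pvals, m, p_threshold = 0.2,
                      apply_default_mask = TRUE) {
    mm <- m[match(signals$probe_id, m$probe_id), ]
    p <- pvals$p[match(signals$probe_id, pvals$probe_id)]
    i1r <- mm$chemistry == "I" & mm$channel == "Red"
    i1g <- mm$chemistry == "I" & mm$channel == "Green"
    M <- ifelse(i1r, signals$MR, ifelse(i1g, signals$MG, signals$MG))
    U <- ifelse(i1r, signals$UR, ifelse(i1g, signals$UG, signals$UR))
    tot <- M + U
    beta <- ifelse(tot > 0, M / tot, NA_real_)
    reason <- rep("none", nrow(signals))
    reason[is.na(p) | p > p_threshold | tot == 0] <- "detection"
    if (apply_default_mask) reason[mm$mask_default] <- "default_mask"
    beta[reason != "none"] <- NA_real_
    data.frame(probe_id = signals$probe_id, beta = beta,
               mask_reason = reason, stringsAsFactors = FALSE)
}

#' Fraction of probes detected above background
#'
#' @param pvals Detection p-values from [pooah()].
#' @param alpha Significance level (default 0.05).
#' @return Fraction of probes with p <= alpha.
#' @export
probe_success_rate <- function(pvals, alpha = 0.05) {
    mean(pvals$p <= alpha)
}

#' Run the full preprocessing pipeline on one sample
#'
#' Detection p-values are computed on the raw signals (background
#' comparison is only meaningful before background subtraction), then noob
#' background correction, dye-bias correction, and beta summarization:
#' pOOBAH -> noob -> dye bias -> beta.
#'
#' @param signals A raw [signal_frame()].
#' @param m The `bm_manifest`.
#' @param p_threshold Detection mask threshold (default 0.2).
#' @param offset Noob offset.
#' @param apply_default_mask See [get_betas()].
#' @return A list with `betas` (data.frame from [get_betas()]), `pvals`,
#'   and `signals` (the corrected frame).
#' @export
process_signals <- function(signals, m, p_threshold = 0.2, offset = 15,
                            apply_default_mask = TRUE) {
    oob <- extract_oob(signals, m)
    pv <- pooah(signals, oob, m)
    corrected <- noob(signals, oob, m, offset = offset)
    corrected <- dyebias_typeI_norm(corrected, m)
    list(betas = get_betas(corrected, pv, m, p_threshold = p_threshold,
                           apply_default_mask = apply_default_mask),
         pvals = pv, signals = corrected)
}
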