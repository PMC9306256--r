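# SNP-probe strain genotyping: allele fractions, maximum-likelihood strain
# classification, mixed-background detection, backcross tracing.

#' Alternate-allele fraction from SNP probes
#'
#' SNP (rs) probes quantify the alternate allele like a methylation signal:
#' the M-allele slot carries the alternate allele, so
#' v = alt / (ref + alt) is the probe's beta value. Probes failing
#' detection (p > threshold) or with zero total signal are NA.
#'
#' @param signals A [signal_frame()].
#' @param m The `bm_manifest`.
#' @param pvals Optional detection p-values from [pooah()].
#' @param p_threshold Detection mask threshold (default 0.2).
#' @return Named numeric vector of VAF in \[0, 1\] (NA where masked),
#'   one entry per SNP probe.
#' @export
snp_vaf <- function(signals, m, pvals = NULL, p_threshold = 0.2) {
    snp <- which(m$target == "SNP")
    if (!length(snp)) stop("manifest has no SNP probes")
    mm <- m[snp, ]
    s <- signals[match(mm$probe_id, signals$probe_id), ]
    i1r <- mm$chemistry == "I" & mm$channel == "Red"
    i1g <- mm$chemistry == "I" & mm$channel == "Green"
    alt <- ifelse(i1r, s$MR, ifelse(i1g, s$MG, s$MG))
    ref <- ifelse(i1r, s$UR, ifelse(i1g, s$UG, s$UR))
    tot <- alt + ref
    v <- ifelse(tot > 0, alt / tot, NA_real_)
    if (!is.null(pvals)) {
        p <- pvals$p[match(mm$probe_id, pvals$probe_id)]
        v[!is.na(p) & p > p_threshold] <- NA_real_
    }
    names(v) <- mm$probe_id
    v
}

#' Gaussian log-likelihood of a VAF vector under a genotype row
#'
#' Sum over SNPs of log N(v_i; g_i, tau^2), with heterozygous loci expected
#' at 0.5 and missing entries (in v or g) skipped.
#'
#' @param v Named VAF vector.
#' @param g Genotype dosage row (0 / 0.5 / 1, NA allowed), aligned to `v`
#'   by names when both are named.
#' @param tau Observation noise s.d. (default 0.1).
#' @return Scalar log-likelihood.
#' @export
strain_loglik <- function(v, g, tau = 0.1) {
    if (!is.null(names(v)) && !is.null(names(g)))
        g <- g[names(v)]
    ok <- !is.na(v) & !is.na(g)
    if (!any(ok)) stop("no overlapping non-missing SNPs")
    sum(stats::dnorm(v[ok], mean = g[ok], sd = tau, log = TRUE))
}

#' Classify the closest strain by maximum likelihood
#'
#' Evaluates [strain_loglik()] for every reference strain and reports the
#' maximizer, with the log-likelihood margin over the runner-up. Ties are
#' broken lexicographically with a warning.
#'
#' @param v Named VAF vector.
#' @param ref A [strain_reference()] list (G, strains, snps).
#' @param tau Observation noise s.d.
#' @return Object of class `strain_call`: list with `best_strain`,
#'   `loglik` (named per strain), `margin`, `tau`, and `mixture` (NULL
#'   until [detect_mixture()] fills it).
#' @export
classify_strain <- function(v, ref, tau = 0.1) {
    ll <- vapply(ref$strains,
                 function(s) strain_loglik(v, ref$G[s, ], tau), 0)
    ord <- order(ll, decreasing = TRUE)
    top <- ll[ord[1L]]
    ties <- names(ll)[ll == top]
    if (length(ties) > 1L) {
        warning("likelihood tie between strains ",
                paste(sort(ties), collapse = ", "),
                "; broken lexicographically")
        best <- sort(ties)[1L]
    } else best <- names(ll)[ord[1L]]
    margin <- if (length(ll) > 1L) top - ll[ord[2L]] else Inf
    structure(list(best_strain = best, loglik = ll,
                   margin = unname(margin), tau = tau, mixture = NULL),
              class = "strain_call")
}

#' @export
print.strain_call <- function(x, ...) {
    cat(sprintf("strain_call: %s (log-likelihood margin %.2f, tau %.3f)\n",
                x$best_strain, x$margin, x$tau))
    if (!is.null(x$mixture))
        cat(sprintf("  mixed background: %.0f%% %s / %.0f%% %s\n",
                    100 * x$mixture$pi, x$mixture$strainA,
                    100 * (1 - x$mixture$pi), x$mixture$strainB))
    invisible(x)
}

#' Detect a two-strain mixed genetic background
#'
#' Over all ordered strain pairs (A, B) and mixing proportions pi on a
#' grid, maximizes the likelihood of expected allele fractions
#' pi * g_A + (1 - pi) * g_B. The mixture is reported only when its
#' log-likelihood exceeds the best single-strain log-likelihood by
#' `delta_threshold`, applied per comparison: the total required
#' improvement is `delta_threshold + log(number of ordered pairs
#' searched)`, a Bayes-factor-style penalty for the multiplicity of the
#' pair search. The grid is restricted to minor components of at
#' least `min_minor` (default 0.1): a putative admixture below the
#' measurement-noise scale is indistinguishable from the one-sided noise
#' that allele fractions show near 0 and 1, so near-degenerate mixtures
#' are not searched.
#'
#' @param v Named VAF vector.
#' @param ref A [strain_reference()] list.
#' @param tau Observation noise s.d.
#' @param grid_step pi grid resolution (default 0.01).
#' @param delta_threshold Required log-likelihood improvement (default 2).
#' @param min_minor Smallest reportable minor-component proportion
#'   (default 0.1).
#' @return NULL, or a list `strainA`, `strainB`, `pi`, `loglik`, `delta`.
#' @export
detect_mixture <- function(v, ref, tau = 0.1, grid_step = 0.01,
                           delta_threshold = 2, min_minor = 0.1) {
    strains <- ref$strains
    if (length(strains) < 2L) stop("need >= 2 reference strains")
    # allele fractions are bounded in [0,1], so noise at homozygous loci
    # is one-sided; expected fractions are shrunk toward 0.5 by the
    # half-normal boundary excess, identically in both model arms
    eps <- tau * stats::dnorm(0)
    Gadj <- eps + ref$G * (1 - 2 * eps)
    best_single <- max(vapply(
        strains, function(s) strain_loglik(v, Gadj[s, ], tau), 0))
    snps <- intersect(names(v)[!is.na(v)], ref$snps)
    vv <- v[snps]
    pis <- seq(min_minor, 1 - min_minor, by = grid_step)
    best <- list(loglik = -Inf)
    lognorm <- -log(tau * sqrt(2 * pi))
    for (a in strains) for (b in strains) {
        if (a == b) next
        ga <- Gadj[a, snps]; gb <- Gadj[b, snps]
        ok <- !is.na(ga) & !is.na(gb)
        if (!any(ok)) next
        # residual sum of squares is quadratic in the mixing proportion:
        # sum((v - gb) - pi*(ga - gb))^2 = A - 2*pi*B + pi^2*C
        r <- vv[ok] - gb[ok]; d <- ga[ok] - gb[ok]
        A <- sum(r^2); B <- sum(r * d); C <- sum(d^2)
        rss <- A - 2 * pis * B + pis^2 * C
        ll <- sum(ok) * lognorm - rss / (2 * tau^2)
        k <- which.max(ll)
        if (ll[k] > best$loglik)
            best <- list(strainA = a, strainB = b, pi = pis[k],
                         loglik = ll[k])
    }
    n_pairs <- length(strains) * (length(strains) - 1L)
    delta <- best$loglik - best_single
    if (!is.finite(delta) || delta <= delta_threshold + log(n_pairs))
        return(NULL)
    best$delta <- delta
    best
}

#' Backcross donor allele fraction and per-SNP genotype calls
#'
#' Over SNPs segregating between donor and recipient (oriented so that
#' v = 1 is donor-homozygous), calls each SNP donor-homozygous
#' (v > hom_threshold), heterozygous, or recipient-homozygous
#' (v < 1 - hom_threshold), and reports the mean donor allele fraction.
#'
#' @param v Named VAF vector on the donor orientation (donor allele
#'   fraction per SNP).
#' @param segregating_snps SNP probe IDs segregating between the strains;
#'   defaults to all of `v`.
#' @param hom_threshold Homozygous-call threshold (default 0.75; the
#'   heterozygous band is \[1 - hom_threshold, hom_threshold\]).
#' @return List: `donor_fraction` (mean of non-missing v), `calls`
#'   (data.frame snp, v, call in donor_hom/het/recipient_hom).
#' @export
backcross_fraction <- function(v, segregating_snps = NULL,
                               hom_threshold = 0.75) {
    if (is.null(segregating_snps)) {
        if (!length(v)) stop("empty segregating SNP set")
        vv <- v
        segregating_snps <- if (is.null(names(v)))
            as.character(seq_along(v)) else names(v)
    } else {
        if (!length(segregating_snps)) stop("empty segregating SNP set")
        vv <- v[segregating_snps]
    }
    call <- ifelse(is.na(vv), NA_character_,
            ifelse(vv > hom_threshold, "donor_hom",
            ifelse(vv < 1 - hom_threshold, "recipient_hom", "het")))
    list(donor_fraction = mean(vv, na.rm = TRUE),
         calls = data.frame(snp = segregating_snps, v = unname(vv),
                            call = call, stringsAsFactors = FALSE))
}
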