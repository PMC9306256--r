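# Shared fixture builders and independent oracles.

# A tiny hand-built Infinium-I/II manifest.
tiny_manifest <- function(n_red = 5, n_grn = 3, n_ii = 4) {
    mk <- function(n, off, chem, channel) {
        if (n == 0) return(NULL)
        data.frame(
            probe_id = sprintf("cg%08d_TC%d1", off + seq_len(n),
                               ifelse(chem == "I", 1L, 2L)),
            chemistry = chem, channel = channel, target = "CG",
            chrom = "chr1", pos = 1000 + 100 * (off + seq_len(n)),
            strand = "+", categories = "", mask_default = FALSE,
            stringsAsFactors = FALSE)
    }
    manifest(rbind(mk(n_red, 0, "I", "Red"),
                   mk(n_grn, n_red, "I", "Green"),
                   mk(n_ii, n_red + n_grn, "II", "Both")))
}

# Quadrature oracle for the normal-exponential posterior mean, computed on
# the log scale so large intensities do not underflow.
normexp_quadrature <- function(x, mu_b, sigma_b, alpha) {
    logf <- function(s) stats::dexp(s, 1 / alpha, log = TRUE) +
        stats::dnorm(x - s, mu_b, sigma_b, log = TRUE)
    s0 <- max(x - mu_b, sigma_b)  # near the posterior mode
    K <- logf(s0)
    lo <- max(0, x - mu_b - 12 * sigma_b)
    hi <- x - mu_b + 12 * sigma_b + 5 * alpha
    num <- stats::integrate(function(s) s * exp(logf(s) - K), lo, hi,
                            rel.tol = 1e-12, abs.tol = 0)$value
    den <- stats::integrate(function(s) exp(logf(s) - K), lo, hi,
                            rel.tol = 1e-12, abs.tol = 0)$value
    num / den
}

# O(n^2) pair-counting AUC oracle.
auc_bruteforce <- function(values, is_target) {
    x <- values[is_target]; y <- values[!is_target]
    s <- 0
    for (xi in x) for (yi in y)
        s <- s + (xi > yi) + 0.5 * (xi == yi)
    s / (length(x) * length(y))
}

# Two-sided Fisher exact p by full hypergeometric enumeration.
fisher_enumeration <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    xs <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(xs, m, n, k)
    p_obs <- stats::dhyper(a, m, n, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Default sample sheet for methylome simulations.
make_annot <- function(n, tissues = c("liver", "spleen"),
                       ages = seq(2, 24, length.out = n),
                       compartment = "somatic") {
    data.frame(sample = sprintf("s%02d", seq_len(n)),
               tissue = rep(tissues, length.out = n),
               strain = "C57BL/6J",
               sex = rep(c("F", "M"), length.out = n),
               age = ages, tumor = FALSE,
               compartment = rep(compartment, length.out = n),
               stringsAsFactors = FALSE)
}
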