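test_that("out-of-band extraction collects the opposite channel", {
    m <- tiny_manifest(n_red = 5, n_grn = 3, n_ii = 4)
    sig <- signal_frame(data.frame(probe_id = m$probe_id,
                                   MG = 1:12, UG = 13:24,
                                   MR = 25:36, UR = 37:48))
    oob <- extract_oob(sig, m)
    expect_length(oob$oob_green, 10)  # 5 Red type-I probes x 2 alleles
    expect_length(oob$oob_red, 6)
    expect_setequal(oob$oob_green, c(1:5, 13:17))
    m0 <- tiny_manifest(n_red = 0, n_grn = 0, n_ii = 4)
    sig0 <- signal_frame(data.frame(probe_id = m0$probe_id,
                                    MG = 1:4, UG = 1:4, MR = 1:4,
                                    UR = 1:4))
    expect_error(extract_oob(sig0, m0), "Infinium-I")
})

test_that("pOOBAH p-values follow the smoothed empirical survival", {
    set.seed(3)
    oob_vals <- sample(1:99)  # 99 distinct values
    m <- tiny_manifest(n_red = 0, n_grn = 1, n_ii = 0)
    # direct check of the counting rule via the exported pipeline on a
    # single green type-I probe against a constructed pool
    oob <- list(oob_green = oob_vals, oob_red = oob_vals)
    probe_p <- function(total) {
        sig <- signal_frame(data.frame(probe_id = m$probe_id,
                                       MG = total / 2, UG = total / 2,
                                       MR = 0, UR = 0))
        pooah(sig, oob, m)$p
    }
    expect_equal(probe_p(1000), 1 / 100)     # above all 99 values
    expect_equal(probe_p(0), 1.0)            # below all
    expect_equal(probe_p(50), (50 + 1) / 100)  # at the median: 50 >= it
})

test_that("pOOBAH is calibrated on background-only draws", {
    set.seed(19)
    bg <- function(n) pmax(0, rnorm(n, 500, 100))
    oob <- list(oob_green = bg(10000), oob_red = bg(10000))
    n <- 10000
    half <- bg(n) / 2
    m <- manifest(data.frame(
        probe_id = sprintf("cg%08d_TC11", 1:n), chemistry = "I",
        channel = "Green", target = "CG", chrom = "chr1",
        pos = seq_len(n), strand = "+", categories = "",
        mask_default = FALSE))
    sig <- signal_frame(data.frame(probe_id = m$probe_id, MG = half,
                                   UG = half, MR = 0, UR = 0))
    p <- pooah(sig, oob, m)$p
    ks <- suppressWarnings(stats::ks.test(p, "punif"))
    expect_lt(unname(ks$statistic), 0.05)
    # p is non-increasing in intensity
    ord <- order(half)
    expect_true(all(diff(p[ord]) <= 0 + 1e-12))
})

test_that("noob matches the quadrature oracle and its limits", {
    # closed form vs numerical integration across a parameter grid
    for (mu in c(200, 500, 1000)) for (sg in c(30, 100, 200))
        for (al in c(500, 2000, 5000)) {
            xs <- c(mu - 2 * sg, mu, mu + sg, mu + al, mu + 3 * al)
            for (x in xs)
                expect_equal(normexp_conditional_mean(x, mu, sg, al),
                             normexp_quadrature(x, mu, sg, al),
                             tolerance = 1e-9)
        }
    # specified spot check
    expect_equal(normexp_conditional_mean(3000, 500, 100, 2000),
                 normexp_quadrature(3000, 500, 100, 2000),
                 tolerance = 1e-9)
    # sigma_b -> 0, mu_b = 0: correction approaches identity for large x
    expect_equal(normexp_conditional_mean(5000, 0, 1e-4, 2000), 5000,
                 tolerance = 1e-6)
    # x = 0 stays within (0, sigma_b + a small slack]
    e0 <- normexp_conditional_mean(0, 500, 100, 2000)
    expect_gt(e0, 0)
    expect_lt(e0, 100 + 1)
})

test_that("noob output is positive, monotone, and offset-bounded", {
    set.seed(5)
    m <- tiny_manifest(n_red = 20, n_grn = 20, n_ii = 30)
    bg <- function(n) pmax(0, rnorm(n, 400, 80))
    sig <- signal_frame(data.frame(
        probe_id = m$probe_id,
        MG = bg(70) + rexp(70, 1 / 3000), UG = bg(70),
        MR = bg(70) + rexp(70, 1 / 3000), UR = bg(70)))
    oob <- extract_oob(sig, m)
    out <- noob(sig, oob, m, offset = 15)
    expect_true(all(out$MG > 15) && all(out$UR > 15))
    # monotone in input at fixed parameters
    pars <- attr(out, "normexp_params")$green
    xs <- seq(0, 8000, length.out = 200)
    ys <- normexp_conditional_mean(xs, pars$mu_b, pars$sigma_b,
                                   pars$alpha)
    expect_true(all(diff(ys) > 0))
    # degenerate OOB spread falls back with a warning
    sig2 <- sig
    sig2$MG[m$chemistry == "I" & m$channel == "Red"] <- 100
    sig2$UG[m$chemistry == "I" & m$channel == "Red"] <- 100
    expect_warning(noob(sig2, extract_oob(sig2, m), m), "degenerate")
})

test_that("dye-bias correction equalizes type-I quantiles, idempotently", {
    set.seed(8)
    m <- tiny_manifest(n_red = 500, n_grn = 500, n_ii = 200)
    base <- rexp(1200, 1 / 3000) + 50
    sig <- signal_frame(data.frame(
        probe_id = m$probe_id,
        MG = base * 0.6, UG = base * 0.4,
        MR = base * 2 * 0.6, UR = base * 2 * 0.4))  # red doubled
    out <- dyebias_typeI_norm(sig, m)
    i1r <- m$chemistry == "I" & m$channel == "Red"
    i1g <- m$chemistry == "I" & m$channel == "Green"
    # matched mid-range quantiles of the corrected total distributions
    # (the map is calibrated on totals but applied per allele, so the
    # low quantiles keep a little distortion from the additive floor)
    qs <- seq(0.2, 0.9, 0.1)
    qr <- quantile(out$MR[i1r] + out$UR[i1r], qs)
    qg <- quantile(out$MG[i1g] + out$UG[i1g], qs)
    expect_lt(max(abs(qr / qg - 1)), 0.2)
    # before correction they differed two-fold
    expect_equal(median(sig$MR[i1r] + sig$UR[i1r]) /
                 median(sig$MG[i1g] + sig$UG[i1g]), 2,
                 tolerance = 0.15)
    # mapping is monotone
    ord <- order(sig$MR)
    expect_true(all(diff(out$MR[ord]) >= -1e-9))
    # applying twice changes mid-range values only marginally
    out2 <- dyebias_typeI_norm(out, m)
    mid <- out$MR > quantile(out$MR, 0.1) &
        out$MR < quantile(out$MR, 0.9)
    expect_lt(median(abs(out2$MR[mid] / out$MR[mid] - 1)), 0.05)
    # identical channel distributions: mid-range near-identity
    sig_id <- signal_frame(data.frame(
        probe_id = m$probe_id, MG = base * 0.5, UG = base * 0.5,
        MR = base * 0.5, UR = base * 0.5))
    out_id <- dyebias_typeI_norm(sig_id, m)
    mid_id <- sig_id$MG > quantile(sig_id$MG, 0.1) &
        sig_id$MG < quantile(sig_id$MG, 0.9)
    expect_lt(median(abs(out_id$MG[mid_id] / sig_id$MG[mid_id] - 1)),
              0.05)
    # too few type-I probes
    m5 <- tiny_manifest(5, 5, 5)
    sig5 <- signal_frame(data.frame(probe_id = m5$probe_id, MG = 1:15,
                                    UG = 1:15, MR = 1:15, UR = 1:15))
    expect_error(dyebias_typeI_norm(sig5, m5), "at least")
})

test_that("beta summarization masks by detection p and default mask", {
    df <- as.data.frame(tiny_manifest(n_red = 1, n_grn = 1, n_ii = 2))
    df$probe_id[4] <- "uk00000999_TC21"
    df$mask_default[4] <- TRUE
    m <- manifest(df)
    sig <- signal_frame(data.frame(
        probe_id = m$probe_id,
        MG = c(5, 300, 300, 300), UG = c(5, 100, 50, 50),
        MR = c(300, 7, 40, 40), UR = c(100, 3, 100, 100)))
    pv <- data.frame(probe_id = m$probe_id, p = c(0.01, 0.25, 0.01,
                                                  0.01))
    b <- get_betas(sig, pv, m)
    expect_equal(b$beta[1], 0.75)          # type-I Red: MR/(MR+UR)
    expect_true(is.na(b$beta[2]))          # p = 0.25 > 0.2
    expect_equal(b$mask_reason[2], "detection")
    expect_equal(b$beta[3], 300 / 400)     # type-II: MG/(MG+UR)
    expect_true(is.na(b$beta[4]))
    expect_equal(b$mask_reason[4], "default_mask")
    bk <- get_betas(sig, pv, m, apply_default_mask = FALSE)
    expect_false(is.na(bk$beta[4]))
    # zero total -> masked as detection
    sig0 <- sig; sig0$MR[1] <- 0; sig0$UR[1] <- 0
    b0 <- get_betas(sig0, pv, m)
    expect_true(is.na(b0$beta[1]))
    expect_equal(b0$mask_reason[1], "detection")
    # beta invariant under common positive rescaling
    sig2 <- sig
    for (cn in c("MG", "UG", "MR", "UR")) sig2[[cn]] <- sig2[[cn]] * 7
    expect_equal(get_betas(sig2, pv, m)$beta, b$beta)
})

test_that("probe success rate is the detected fraction", {
    pv <- data.frame(probe_id = letters[1:4],
                     p = c(0.001, 0.001, 0.5, 0.5))
    expect_equal(probe_success_rate(pv), 0.5)
    expect_equal(probe_success_rate(pv, alpha = 0.6), 1.0)
    pv$p <- rep(1.0, 4)
    expect_equal(probe_success_rate(pv), 0.0)
})
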