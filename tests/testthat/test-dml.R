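test_that("two-group fit matches the closed-form t-test oracle", {
    set.seed(31)
    y <- c(rnorm(10, 0.2, 0.01), rnorm(10, 0.7, 0.01))
    annot <- data.frame(tissue = rep(c("A", "B"), each = 10))
    res <- fit_dml(matrix(y, 1, dimnames = list("p1", NULL)), annot,
                   terms = "tissue")
    tt <- stats::t.test(y[11:20], y[1:10], var.equal = TRUE)
    expect_equal(res$F[1, 1], unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p[1, 1], tt$p.value, tolerance = 1e-10)
    expect_equal(res$effect[1, 1], 0.5, tolerance = 0.02)
    expect_lt(res$p[1, 1], 1e-6)
})

test_that("F-test p-values are uniform under the null", {
    set.seed(32)
    n <- 40
    annot <- data.frame(
        tissue = rep(c("liver", "spleen", "brain", "colon"), each = 10),
        strain = rep(c("B6", "129"), 20),
        sex = rep(c("F", "M"), each = 2, length.out = n),
        age = runif(n, 2, 24))
    B <- matrix(runif(1000 * n, 0.2, 0.8), 1000, n,
                dimnames = list(sprintf("p%04d", 1:1000), NULL))
    res <- fit_dml(B, annot)
    for (tm in res$terms) {
        ks <- suppressWarnings(stats::ks.test(res$p[, tm], "punif"))
        expect_lt(unname(ks$statistic), 0.05)
    }
    # constant probe: F = 0, p = 1
    Bc <- matrix(0.5, 1, n, dimnames = list("const", NULL))
    rc <- fit_dml(Bc, annot)
    expect_equal(unname(rc$F[1, ]), rep(0, 4))
    expect_equal(unname(rc$p[1, ]), rep(1, 4))
    # probes with missing values fit on complete cases
    B2 <- B[1:3, , drop = FALSE]; B2[2, c(3, 8)] <- NA
    r2 <- fit_dml(B2, annot)
    expect_false(anyNA(r2$p[2, ]))
})

test_that("significance calls apply the documented thresholds", {
    mk <- function(p, q, eff, coef) {
        structure(list(
            F = matrix(1, 1, 1, dimnames = list("p1", "t")),
            p = matrix(p, 1, 1, dimnames = list("p1", "t")),
            q = matrix(q, 1, 1, dimnames = list("p1", "t")),
            effect = matrix(eff, 1, 1, dimnames = list("p1", "t")),
            coef = matrix(coef, 1, 1, dimnames = list("p1", "t")),
            terms = "t", n_samples = 20), class = "dml_result")
    }
    # tissue mode: p < 0.05 and effect > 0.1
    expect_true(call_significant(mk(0.04, 0.2, 0.15, 0.15), "t"))
    expect_false(call_significant(mk(0.04, 0.2, 0.08, 0.08), "t"))
    expect_false(call_significant(mk(0.06, 0.2, 0.15, 0.15), "t"))
    # tumor mode: q < 0.01 and |coef| > 0.1, split by sign
    s <- call_significant(mk(1e-4, 0.005, 0.12, 0.12), "t",
                          p_max = 0.01, use_bh = TRUE,
                          split_sign = TRUE)
    expect_true(s$hyper); expect_false(s$hypo)
    s2 <- call_significant(mk(1e-4, 0.005, 0.05, 0.05), "t",
                           p_max = 0.01, use_bh = TRUE,
                           split_sign = TRUE)
    expect_false(s2$hyper)
    s3 <- call_significant(mk(1e-4, 0.005, 0.12, -0.12), "t",
                           p_max = 0.01, use_bh = TRUE,
                           split_sign = TRUE)
    expect_true(s3$hypo)
})

test_that("AUC equals the pair-counting oracle on random instances", {
    expect_equal(auc_one_vs_rest(c(0.9, 0.8, 0.1, 0.7),
                                 c(TRUE, TRUE, FALSE, FALSE)), 1.0)
    expect_equal(auc_one_vs_rest(rep(0.5, 6),
                                 rep(c(TRUE, FALSE), 3)), 0.5)
    set.seed(33)
    for (i in 1:100) {
        n <- sample(6:50, 1)
        v <- sample(seq(0, 1, 0.05), n, TRUE)  # ties likely
        lab <- sample(c(TRUE, FALSE), n, TRUE)
        if (!any(lab) || all(lab)) lab[c(1, n)] <- c(TRUE, FALSE)
        expect_equal(auc_one_vs_rest(v, lab), auc_bruteforce(v, lab))
    }
    expect_error(auc_one_vs_rest(1:3, rep(TRUE, 3)), "non-empty")
})

test_that("tissue signatures take perfectly separating probes, ranked", {
    set.seed(34)
    annot <- data.frame(tissue = rep(c("liver", "rest1", "rest2"),
                                     each = 4))
    n <- 400
    B <- matrix(runif(n * 12, 0.3, 0.7), n, 12,
                dimnames = list(sprintf("p%05d", 1:n), NULL))
    # plant 300 perfect markers with known ordering of differences
    deltas <- seq(0.30, 0.899, length.out = 300)
    for (j in 1:300) {
        B[j, ] <- 0.05
        B[j, annot$tissue == "liver"] <- 0.05 + deltas[j]
    }
    # an imperfect marker (overlap): AUC < 1, must be excluded
    B[301, ] <- c(0.9, 0.9, 0.9, 0.2, 0.95, 0.1, 0.1, 0.1, 0.1, 0.1,
                  0.1, 0.1)
    sig <- tissue_signature(B, annot, "liver", K = 200)
    expect_equal(nrow(sig$hyper), 200)
    # exactly the 200 largest-difference planted markers
    expect_setequal(sig$hyper$probe_id, sprintf("p%05d", 101:300))
    expect_false("p00301" %in% sig$hyper$probe_id)
    expect_true(all(diff(abs(sig$hyper$mean_diff)) <= 1e-12))
    # hypo direction finds probes low in the target
    B[302, ] <- 0.9; B[302, annot$tissue == "liver"] <- 0.1
    sig2 <- tissue_signature(B, annot, "liver", K = 200)
    expect_true("p00302" %in% sig2$hypo$probe_id)
    expect_error(tissue_signature(B, annot, "nowhere"), ">= 2")
})

test_that("tissue/species decomposition labels by the 0.4 and 3x rules", {
    annot <- data.frame(
        tissue = rep(c("liver", "brain"), each = 4),
        species = rep(c("human", "mouse"), 4))
    mk <- function(vals) matrix(vals, 1, 8,
                                dimnames = list("p1", NULL))
    # human 0.8 everywhere, mouse 0.2 everywhere
    d1 <- decompose_tissue_species(mk(rep(c(0.8, 0.2), 4)), annot)
    expect_equal(d1$species_effect, 0.6)
    expect_equal(d1$tissue_effect, 0)
    expect_equal(d1$label, "species")
    # tissue split in both species
    d2 <- decompose_tissue_species(
        mk(c(rep(0.9, 4), rep(0.1, 4))), annot)
    expect_equal(d2$tissue_effect, 0.8)
    expect_equal(d2$label, "tissue")
    # effects 0.5 and 0.3: ratio below 3, no label
    vals <- rep(0, 8)
    vals[annot$tissue == "liver"] <- 0.25
    vals[annot$species == "human"] <- vals[annot$species == "human"] +
        0.5
    d3 <- decompose_tissue_species(mk(vals + 0.1), annot)
    expect_equal(d3$tissue_effect, 0.25)
    expect_equal(d3$species_effect, 0.5)
    expect_equal(d3$label, "none")
})

test_that("region enrichment matches the hypergeometric enumeration", {
    m <- manifest(data.frame(
        probe_id = sprintf("cg%02d_TC11", 1:8), chemistry = "I",
        channel = "Red", target = "CG", chrom = "chr1",
        pos = c(100, 300, 500, 700, 2000, 4000, 6000, 8000),
        strand = "+", categories = "", mask_default = FALSE))
    rs <- region_set("peaks", chrom = "chr1", start = 0, end = 800)
    er <- region_enrichment(m$probe_id[c(1, 2, 3, 5)], m$probe_id,
                            list(rs), m)
    # (a,b,c,d) = (3,1,1,3): odds ratio 9
    expect_equal(unlist(er[1, c("a", "b", "c", "d")],
                        use.names = FALSE), c(3, 1, 1, 3))
    expect_equal(er$odds_ratio, 9.0)
    expect_false(er$continuity)
    expect_equal(er$p, fisher_enumeration(3, 1, 1, 3))
    # no-overlap query: no positive enrichment
    er0 <- region_enrichment(m$probe_id[5:6], m$probe_id, list(rs), m)
    expect_lte(er0$odds_ratio, 1)
    expect_true(er0$continuity)  # a = 0 cell
    expect_error(region_enrichment(m$probe_id[1], character(),
                                   list(rs), m), "background|subset")
})

test_that("fisher.test agrees with enumeration on all small tables", {
    for (mrow in 1:8) for (nrow_ in 1:8) for (k in 1:min(8, mrow +
                                                         nrow_)) {
        for (a in max(0, k - nrow_):min(k, mrow)) {
            b <- mrow - a; cc <- k - a; d <- nrow_ - cc
            p_ref <- fisher_enumeration(a, b, cc, d)
            p_got <- stats::fisher.test(matrix(c(a, b, cc, d),
                                               2))$p.value
            expect_equal(p_got, p_ref, tolerance = 1e-10)
        }
    }
})

test_that("target-gene selection applies distance, count and RP rules", {
    cpgs <- data.frame(chrom = "chr1", pos = 5e6)
    tss <- data.frame(
        gene = c(sprintf("up%02d", 1:12), "far", sprintf("dn%02d", 1:3)),
        chrom = "chr1",
        tss = c(5e6 - seq(1e4, 9.9e5, length.out = 12), 5e6 + 1.2e6,
                5e6 + c(2e4, 4e4, 6e4)))
    rp <- expand.grid(gene = tss$gene, factor = c("Cdx2", "Hnf4a",
                                                  "Hnf4g"),
                      experiment = c("e1", "e2"),
                      stringsAsFactors = FALSE)
    rp$score <- 5
    got <- select_target_genes(cpgs, tss, rp)
    # 12 upstream genes capped at 10 nearest; "far" beyond 1 Mb excluded
    expect_equal(sum(startsWith(got, "up")), 10)
    expect_false("far" %in% got)
    expect_true(all(sprintf("dn%02d", 1:3) %in% got))
    # the two most distant upstream genes were dropped
    expect_false("up12" %in% got)
    # failing one factor excludes the gene
    rp2 <- rp[!(rp$gene == "dn01" & rp$factor == "Hnf4g"), ]
    expect_false("dn01" %in% select_target_genes(cpgs, tss, rp2))
    # a low score in all experiments of one factor also excludes
    rp3 <- rp
    rp3$score[rp3$gene == "dn02" & rp3$factor == "Cdx2"] <- 2  # not > 2
    expect_false("dn02" %in% select_target_genes(cpgs, tss, rp3))
    # absent gene fails
    rp4 <- rp[rp$gene != "dn03", ]
    expect_false("dn03" %in% select_target_genes(cpgs, tss, rp4))
})
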