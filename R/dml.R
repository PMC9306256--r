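# Differential methylation: per-probe multivariate OLS with per-term
# F-tests, one-vs-rest tissue signatures, and human-mouse tissue/species
# effect decomposition.

# RSS of each column of Y under the projection defined by qr(X).
.rss <- function(qrX, Y) colSums(qr.resid(qrX, Y)^2)

#' Pre-filter a beta matrix for regression analyses
#'
#' Removes probes with missing data in more than `max_missing` of the
#' samples, probes constitutively unmethylated (max beta <
#' `const_low`) or methylated (min beta > `const_high`), and optionally
#' probes on the sex chromosomes.
#'
#' @param betas Probes x samples beta matrix.
#' @param m Optional `bm_manifest` (needed for the sex-chromosome filter).
#' @param max_missing Maximum tolerated missing fraction (default 0.25).
#' @param const_low,const_high Constitutive-methylation bounds (defaults
#'   0.2 and 0.8).
#' @param drop_sex_chrom Drop chrX/chrY probes (default TRUE when `m`
#'   given).
#' @return The filtered beta matrix.
#' @export
dml_prefilter <- function(betas, m = NULL, max_missing = 0.25,
                          const_low = 0.2, const_high = 0.8,
                          drop_sex_chrom = !is.null(m)) {
    keep <- rowMeans(is.na(betas)) <= max_missing
    mx <- apply(betas, 1L, max, na.rm = TRUE)
    mn <- apply(betas, 1L, min, na.rm = TRUE)
    keep <- keep & is.finite(mx) & is.finite(mn) &
        !(mx < const_low) & !(mn > const_high)
    if (drop_sex_chrom) {
        if (is.null(m)) stop("sex-chromosome filter needs a manifest")
        chrom <- m$chrom[match(rownames(betas), m$probe_id)]
        keep <- keep & !(chrom %in% c("chrX", "chrY", "X", "Y"))
    }
    betas[keep, , drop = FALSE]
}

#' Per-probe multivariate regression with per-term F-tests
#'
#' Fits, for every probe, an additive ordinary-least-squares model of beta
#' on the requested predictors (e.g. tissue + strain + sex + age) and
#' tests each term with a full-vs-reduced F-test (the reduced model omits
#' that term). Effect sizes are delta-beta style: for a categorical term,
#' the spread of model-adjusted level means (max - min); for a continuous
#' term, |slope| times the observed predictor range. P-values are
#' BH-adjusted across probes within each term.
#'
#' @param betas Probes x samples beta matrix (NA allowed; probes with NAs
#'   are fitted on their complete cases).
#' @param annot Sample sheet data.frame, one row per column of `betas`;
#'   must contain every term.
#' @param terms Character vector of predictor column names.
#' @param raw_effect Use raw group-mean differences instead of
#'   model-adjusted level means for categorical effect sizes.
#' @return Object of class `dml_result`: list of probes x terms matrices
#'   `F`, `p`, `q`, `effect`, `coef` (single coefficient for 1-df terms,
#'   NA otherwise), plus `terms`, `n_samples`.
#' @export
fit_dml <- function(betas, annot, terms = c("tissue", "strain", "sex",
                                            "age"),
                    raw_effect = FALSE) {
    stopifnot(ncol(betas) == nrow(annot))
    miss <- setdiff(terms, names(annot))
    if (length(miss)) stop("annot lacks term(s): ",
                           paste(miss, collapse = ", "))
    dat <- annot[terms]
    for (tm in terms) {
        x <- dat[[tm]]
        if (is.character(x) || is.logical(x)) dat[[tm]] <- factor(x)
        if (is.factor(dat[[tm]]) && nlevels(droplevels(dat[[tm]])) < 2L)
            stop("categorical term '", tm, "' needs >= 2 levels")
    }
    form <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
    X <- stats::model.matrix(form, dat)
    if (nrow(X) <= ncol(X))
        stop("need more samples than model parameters")
    asg <- attr(X, "assign")
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
        warning("rank-deficient design; F-tests may be unreliable")
    red <- lapply(seq_along(terms), function(k) {
        Xr <- X[, asg != k, drop = FALSE]
        list(qr = qr(Xr), df = sum(asg == k))
    })
    np <- nrow(betas); nt <- length(terms)
    Fm <- pm <- em <- cm <- matrix(
        NA_real_, np, nt, dimnames = list(rownames(betas), terms))
    dfres <- nrow(X) - ncol(X)

    compute <- function(idx, Xl, qrl, redl, dfresl, rowsel) {
        Y <- t(betas[idx, rowsel, drop = FALSE])
        rss_f <- .rss(qrl, Y)
        coefs <- qr.coef(qrl, Y)  # ncol(X) x length(idx)
        for (k in seq_len(nt)) {
            rss_r <- .rss(redl[[k]]$qr, Y)
            dfk <- redl[[k]]$df
            Fv <- ((rss_r - rss_f) / dfk) / (rss_f / dfresl)
            # constant response: no variance to explain
            degen <- rss_f < 1e-12 & (rss_r - rss_f) < 1e-12
            Fv[degen] <- 0
            Fm[idx, k] <<- Fv
            pm[idx, k] <<- ifelse(Fv == 0 & degen, 1,
                                  stats::pf(Fv, dfk, dfresl,
                                            lower.tail = FALSE))
            rows_k <- which(asg == k)
            if (is.factor(dat[[terms[k]]])) {
                if (raw_effect) {
                    f <- droplevels(factor(dat[[terms[k]]][rowsel]))
                    gm <- apply(Y, 2L, function(y)
                        tapply(y, f, mean, na.rm = TRUE))
                    em[idx, k] <<- apply(gm, 2L, max) - apply(gm, 2L, min)
                } else {
                    lev <- rbind(0, coefs[rows_k, , drop = FALSE])
                    em[idx, k] <<- apply(lev, 2L, max) -
                        apply(lev, 2L, min)
                }
            } else {
                rng <- diff(range(dat[[terms[k]]][rowsel]))
                em[idx, k] <<- abs(coefs[rows_k, ]) * rng
            }
            if (length(rows_k) == 1L) cm[idx, k] <<- coefs[rows_k, ]
        }
    }

    complete <- !apply(is.na(betas), 1L, any)
    if (any(complete))
        compute(which(complete), X, qrX, red, dfres, seq_len(nrow(X)))
    for (i in which(!complete)) {
        obs <- which(!is.na(betas[i, ]))
        if (length(obs) <= ncol(X)) {
            warning("probe ", rownames(betas)[i],
                    ": too few complete observations; result missing")
            next
        }
        Xi <- X[obs, , drop = FALSE]
        if (qr(Xi)$rank < ncol(Xi)) {
            warning("probe ", rownames(betas)[i],
                    ": rank-deficient design on complete cases; ",
                    "result missing")
            next
        }
        redi <- lapply(seq_along(terms), function(k)
            list(qr = qr(Xi[, asg != k, drop = FALSE]),
                 df = sum(asg == k)))
        compute(i, Xi, qr(Xi), redi, length(obs) - ncol(Xi), obs)
    }
    qm <- apply(pm, 2L, function(p) stats::p.adjust(p, "BH"))
    if (np == 1L) qm <- matrix(qm, 1L, nt,
                               dimnames = dimnames(pm))
    structure(list(F = Fm, p = pm, q = qm, effect = em, coef = cm,
                   terms = terms, n_samples = nrow(annot)),
              class = "dml_result")
}

#' @export
print.dml_result <- function(x, ...) {
    cat(sprintf("dml_result: %d probes x %d terms (%s), n = %d samples\n",
                nrow(x$p), length(x$terms),
                paste(x$terms, collapse = ", "), x$n_samples))
    invisible(x)
}

#' Call significant probes from a DML fit
#'
#' Tissue-mode default: raw p < 0.05 and effect size (delta beta) > 0.1.
#' Tumor/age mode (`use_bh = TRUE`, `p_max = 0.01`): BH-adjusted p below
#' the cutoff and, when `effect_min` applies to the term's single
#' coefficient, |coef| above it; calls are split by coefficient sign into
#' hyper- and hypomethylated sets.
#'
#' @param result A [fit_dml()] object.
#' @param term Term name.
#' @param p_max P-value cutoff (default 0.05).
#' @param effect_min Effect-size cutoff (default 0.1; set 0 to disable).
#' @param use_bh Test the BH-adjusted p instead of the raw p.
#' @param split_sign Also split calls by the term coefficient's sign.
#' @param effect_on_coef With `split_sign`, apply `effect_min` to |coef|
#'   rather than the categorical effect size.
#' @return Logical vector per probe, or with `split_sign` a list
#'   `hyper`/`hypo` of logical vectors.
#' @export
call_significant <- function(result, term, p_max = 0.05, effect_min = 0.1,
                             use_bh = FALSE, split_sign = FALSE,
                             effect_on_coef = split_sign) {
    stopifnot(inherits(result, "dml_result"), term %in% result$terms)
    p <- if (use_bh) result$q[, term] else result$p[, term]
    eff <- if (effect_on_coef) abs(result$coef[, term])
           else result$effect[, term]
    sig <- !is.na(p) & p < p_max & (effect_min <= 0 |
                                    (!is.na(eff) & eff > effect_min))
    if (!split_sign) return(sig)
    cf <- result$coef[, term]
    list(hyper = sig & !is.na(cf) & cf > 0,
         hypo = sig & !is.na(cf) & cf < 0)
}

#' One-vs-rest AUC for a single probe
#'
#' Mann-Whitney AUC of `values` for discriminating the target group from
#' the rest, ties counted 1/2.
#'
#' @param values Numeric vector.
#' @param is_target Logical vector: target-group membership.
#' @return AUC in \[0, 1\] (1 = target values all above the rest).
#' @export
auc_one_vs_rest <- function(values, is_target) {
    ok <- !is.na(values)
    values <- values[ok]; is_target <- is_target[ok]
    n1 <- sum(is_target); n2 <- sum(!is_target)
    if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
    r <- rank(values)  # mid-ranks give the 1/2 tie convention
    (sum(r[is_target]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Derive one-vs-rest tissue methylation signatures
#'
#' Candidate probes must perfectly discriminate the target tissue from all
#' other tissues: AUC exactly 1 (hypermethylated in the target) or exactly
#' 0 (hypomethylated). Candidates are ranked by the absolute difference of
#' group mean beta (ties broken by probe ID) and the top `K` per direction
#' returned.
#'
#' @param betas Probes x samples beta matrix.
#' @param annot Sample sheet with a `tissue` column.
#' @param target_tissue Tissue label to discriminate.
#' @param K Signature size per direction (default 200).
#' @return List of two data.frames `hyper` and `hypo` (`probe_id`,
#'   `mean_diff`), each with at most K rows, sorted by |mean_diff|
#'   descending.
#' @export
tissue_signature <- function(betas, annot, target_tissue, K = 200) {
    in_t <- annot$tissue == target_tissue
    if (sum(in_t) < 2 || sum(!in_t) < 2)
        stop("need >= 2 samples in the target tissue and in the rest")
    Bt <- betas[, in_t, drop = FALSE]
    Br <- betas[, !in_t, drop = FALSE]
    min_t <- apply(Bt, 1L, min); max_t <- apply(Bt, 1L, max)
    min_r <- apply(Br, 1L, min); max_r <- apply(Br, 1L, max)
    diff <- rowMeans(Bt) - rowMeans(Br)
    pick <- function(sel) {
        d <- diff[sel]
        ids <- rownames(betas)[sel]
        ord <- order(-abs(d), ids)
        utils::head(data.frame(probe_id = ids[ord],
                               mean_diff = unname(d[ord]),
                               stringsAsFactors = FALSE), K)
    }
    # strict separation <=> AUC exactly 1 (or 0)
    list(hyper = pick(which(!is.na(min_t) & min_t > max_r)),
         hypo = pick(which(!is.na(max_t) & max_t < min_r)))
}

#' Decompose methylation variation into tissue and species effects
#'
#' For probes measured across tissues in two species: cell means per
#' tissue x species combination; the tissue effect is the spread
#' (max - min) of the tissue marginal means (averaging species), the
#' species effect the spread of the species marginal means. A probe is
#' labelled species-specific when species effect > 0.4 and
#' species/tissue ratio > 3, tissue-specific when tissue effect > 0.4 and
#' tissue/species ratio > 3, otherwise unlabelled.
#'
#' @param betas Probes x samples beta matrix.
#' @param annot Sample sheet with `tissue` and `species` columns.
#' @param effect_min Effect threshold (default 0.4).
#' @param ratio_min Dominance ratio threshold (default 3).
#' @return data.frame `probe_id`, `tissue_effect`, `species_effect`,
#'   `label` ("tissue"/"species"/"none").
#' @export
decompose_tissue_species <- function(betas, annot, effect_min = 0.4,
                                     ratio_min = 3) {
    tis <- factor(annot$tissue); sp <- factor(annot$species)
    if (nlevels(tis) < 2 || nlevels(sp) < 2)
        stop("need >= 2 tissues and 2 species")
    cells <- interaction(tis, sp, drop = FALSE, sep = "\r")
    full_cells <- levels(cells)
    if (!all(full_cells %in% unique(as.character(cells))))
        warning("missing tissue x species cells; marginal means use ",
                "available cells")
    groups <- split(seq_len(ncol(betas)), cells, drop = TRUE)
    cell_means <- vapply(groups, function(j)
        rowMeans(betas[, j, drop = FALSE], na.rm = TRUE),
        numeric(nrow(betas)))
    if (nrow(betas) == 1L)
        cell_means <- matrix(cell_means, 1L,
                             dimnames = list(rownames(betas),
                                             names(groups)))
    key <- do.call(rbind, strsplit(colnames(cell_means), "\r",
                                   fixed = TRUE))
    marg <- function(fac) {
        lev <- unique(key[, fac])
        sapply(lev, function(l) rowMeans(
            cell_means[, key[, fac] == l, drop = FALSE], na.rm = TRUE))
    }
    mt <- marg(1L); ms <- marg(2L)
    if (nrow(betas) == 1L) { mt <- matrix(mt, 1L); ms <- matrix(ms, 1L) }
    te <- apply(mt, 1L, max) - apply(mt, 1L, min)
    se <- apply(ms, 1L, max) - apply(ms, 1L, min)
    label <- rep("none", nrow(betas))
    label[se > effect_min & se > ratio_min * te] <- "species"
    label[te > effect_min & te > ratio_min * se] <- "tissue"
    data.frame(probe_id = rownames(betas), tissue_effect = te,
               species_effect = se, label = label,
               stringsAsFactors = FALSE, row.names = NULL)
}
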