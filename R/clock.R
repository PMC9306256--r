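# Elastic-net epigenetic age clock.

#' Fit an elastic-net epigenetic age clock
#'
#' Penalized linear regression of chronological age (months) on the beta
#' matrix with elastic-net mixing `mixing` (default 0.5 between lasso and
#' ridge); the penalty strength is chosen along the glmnet path by k-fold
#' cross-validation minimizing mean absolute error. Training-set probe
#' means are stored so that masked beta values can be imputed at
#' prediction time.
#'
#' @param betas Probes x samples beta matrix (NA imputed by probe
#'   training means before fitting).
#' @param ages Numeric ages in months, one per sample.
#' @param mixing Elastic-net mixing parameter alpha in \[0, 1\]
#'   (default 0.5).
#' @param folds Cross-validation folds (default 10).
#' @param seed Seed controlling the fold assignment.
#' @param penalty Optional fixed penalty (lambda) overriding the CV
#'   choice.
#' @return Object of class `meth_clock`: `intercept` (months), `weights`
#'   (named vector, nonzero coefficients only, months per beta unit),
#'   `mixing`, `penalty`, `imputation_values` (training means for the
#'   weighted probes), `training` (n, folds, cv_mae).
#' @export
fit_clock <- function(betas, ages, mixing = 0.5, folds = 10, seed = 1,
                      penalty = NULL) {
    stopifnot(ncol(betas) == length(ages))
    if (stats::sd(ages) == 0) stop("ages are constant; cannot fit a clock")
    if (ncol(betas) < 2 * folds)
        stop("need at least 2 samples per cross-validation fold")
    betas <- betas[rowSums(!is.na(betas)) > 0, , drop = FALSE]
    X <- t(betas)
    pmeans <- colMeans(X, na.rm = TRUE)
    nai <- which(is.na(X), arr.ind = TRUE)
    if (nrow(nai)) X[nai] <- pmeans[nai[, 2L]]
    foldid <- with_seed(seed,
                        sample(rep(seq_len(folds),
                                   length.out = length(ages))))
    cv <- glmnet::cv.glmnet(X, ages, alpha = mixing,
                            type.measure = "mae", foldid = foldid)
    lam <- if (is.null(penalty)) cv$lambda.min else penalty
    cf <- as.matrix(stats::coef(cv$glmnet.fit, s = lam))[, 1L]
    w <- cf[-1L]
    w <- w[w != 0]
    cv_mae <- cv$cvm[which.min(abs(cv$lambda - lam))]
    structure(list(intercept = unname(cf[1L]), weights = w,
                   mixing = mixing, penalty = lam,
                   imputation_values = pmeans[names(w)],
                   training = list(n = length(ages), folds = folds,
                                   cv_mae = cv_mae)),
              class = "meth_clock")
}

#' @export
print.meth_clock <- function(x, ...) {
    cat(sprintf(
        "meth_clock: %d CpGs, intercept %.2f months, alpha %.2f, ",
        length(x$weights), x$intercept, x$mixing))
    cat(sprintf("lambda %.4g (CV MAE %.2f months, n = %d)\n",
                x$penalty, x$training$cv_mae, x$training$n))
    invisible(x)
}

#' @export
coef.meth_clock <- function(object, ...) {
    c("(Intercept)" = object$intercept, object$weights)
}

#' Predict chronological age from beta values
#'
#' age = intercept + sum(weights * beta), with missing beta values
#' replaced by the stored training means. Samples with more than half of
#' the weighted probes missing are flagged low-confidence.
#'
#' @param betas Probes x samples beta matrix (or a named vector for one
#'   sample).
#' @param model A [fit_clock()] object.
#' @return data.frame `sample`, `age` (months), `frac_missing`,
#'   `low_confidence`.
#' @export
predict_age <- function(betas, model) {
    stopifnot(inherits(model, "meth_clock"))
    if (is.null(dim(betas)))
        betas <- matrix(betas, ncol = 1L,
                        dimnames = list(names(betas), "sample1"))
    probes <- names(model$weights)
    miss_probe <- !(probes %in% rownames(betas))
    B <- matrix(NA_real_, length(probes), ncol(betas),
                dimnames = list(probes, colnames(betas)))
    present <- probes[!miss_probe]
    B[present, ] <- betas[present, , drop = FALSE]
    frac_missing <- colMeans(is.na(B))
    nai <- which(is.na(B), arr.ind = TRUE)
    if (nrow(nai)) B[nai] <- model$imputation_values[nai[, 1L]]
    age <- model$intercept + as.numeric(crossprod(B, model$weights))
    data.frame(sample = colnames(B), age = age,
               frac_missing = frac_missing,
               low_confidence = frac_missing > 0.5,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
predict.meth_clock <- function(object, newdata, ...) {
    predict_age(newdata, object)
}

#' Serialize a clock model (TSV weights + JSON header)
#' @param model A [fit_clock()] object.
#' @param path Base path; writes `<path>.tsv` and `<path>.json`.
#' @export
write_clock <- function(model, path) {
    utils::write.table(
        data.frame(probe_id = names(model$weights),
                   weight = unname(model$weights)),
        paste0(path, ".tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    hdr <- list(intercept = model$intercept, mixing = model$mixing,
                penalty = model$penalty,
                imputation_values = as.list(model$imputation_values),
                training = model$training)
    writeLines(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA),
               paste0(path, ".json"))
    invisible(path)
}

#' Load a clock model written by [write_clock()]
#' @param path Base path used at write time.
#' @return A `meth_clock`.
#' @export
read_clock <- function(path) {
    wt <- utils::read.delim(paste0(path, ".tsv"),
                            stringsAsFactors = FALSE)
    hdr <- jsonlite::fromJSON(paste0(path, ".json"))
    w <- wt$weight; names(w) <- wt$probe_id
    structure(list(intercept = hdr$intercept, weights = w,
                   mixing = hdr$mixing, penalty = hdr$penalty,
                   imputation_values = unlist(hdr$imputation_values),
                   training = hdr$training),
              class = "meth_clock")
}
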