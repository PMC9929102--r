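## Phenotype construction: rare-taxon filtering, rarefaction, variance
## stabilization, mixed-model residualization.

#' Filter rare taxa
#'
#' Keeps a taxon iff at least 20% of samples reach a read count of 5
#' (the only reading of the "count < 5 in < 20% of samples" rule that
#' removes rare taxa).
#'
#' @param t a [TraitTable]
#' @param min_count count a sample must reach (default 5)
#' @param min_fraction required fraction of samples at or above `min_count`
#' @return filtered [TraitTable]
#' @export
filterRareTaxa <- function(t, min_count = 5, min_fraction = 0.2) {
    k <- traitCounts(t)
    if (!nrow(k) || !ncol(k)) stop("empty trait table")
    keep <- rowMeans(k >= min_count) >= min_fraction
    t[keep, ]
}

#' Rarefy samples to a fixed depth
#'
#' Samples with fewer than `depth` total reads are dropped (with a warning);
#' the rest are subsampled without replacement to exactly `depth` reads.
#'
#' @param t a [TraitTable]
#' @param depth target reads per sample (default 5000)
#' @param seed RNG seed
#' @return rarefied [TraitTable]
#' @export
rarefyCounts <- function(t, depth = 5000, seed = 1) {
    stopifnot(depth >= 1)
    k <- traitCounts(t)
    tot <- colSums(k)
    keep <- tot >= depth
    if (!any(keep)) {
        warning("all samples below rarefaction depth; empty table returned")
        return(t[, keep])
    }
    if (any(!keep))
        warning(sum(!keep), " sample(s) below depth ", depth, " dropped")
    t <- t[, keep]
    k <- traitCounts(t)
    set.seed(seed)
    sub <- t(vegan::rrarefy(t(k), depth))
    out <- t
    SummarizedExperiment::assay(out, "counts") <- sub
    out
}

## DESeq-style median-of-ratios size factors; fallback reference over the
## positive entries when no taxon is positive in every sample
.sizeFactors <- function(k) {
    lg <- log(k)
    allpos <- rowSums(!is.finite(lg)) == 0
    if (any(allpos)) {
        ref <- rowMeans(lg[allpos, , drop = FALSE])
        s <- apply(lg[allpos, , drop = FALSE], 2,
                   function(col) exp(median(col - ref)))
    } else {
        warning("no taxon positive in all samples; positive-subset reference used")
        lg[!is.finite(lg)] <- NA
        ref <- rowMeans(lg, na.rm = TRUE)
        s <- apply(lg, 2, function(col) exp(median(col - ref, na.rm = TRUE)))
    }
    s
}

#' Variance-stabilizing transformation for NB counts
#'
#' Computes median-of-ratios size factors, a per-taxon negative-binomial
#' dispersion by method of moments on size-normalized counts, and applies the
#' NB closed-form stabilizer y = (2/sqrt(a)) asinh(sqrt(a K / s)); with the
#' dispersion floored at 1e-8 this reduces to the Poisson form 2 sqrt(K/s).
#'
#' @param t a [TraitTable]
#' @return samples x taxa matrix of transformed values, with size factors and
#'   dispersions as attributes
#' @export
vstCounts <- function(t) {
    k <- traitCounts(t)
    s <- .sizeFactors(k)
    norm <- sweep(k, 2, s, "/")
    m <- rowMeans(norm)
    v <- apply(norm, 1, var)
    alpha <- pmax((v - m) / m^2, 1e-8)
    y <- sweep(sweep(k, 2, s, "/"), 1, alpha, function(x, a)
        (2 / sqrt(a)) * asinh(sqrt(a * x)))
    out <- t(y)
    attr(out, "size_factors") <- s
    attr(out, "dispersion") <- alpha
    out
}

#' Residualize a trait against nuisance covariates
#'
#' Fits a random-intercept mixed model by REML (default: generation as fixed
#' effect, cage as random effect), subtracts the fixed-effect fit and the
#' predicted (shrunken) random intercepts, and standardizes the residuals to
#' zero mean and unit variance. With a single cage, or when the mixed fit
#' fails, the model reduces to fixed effects only.
#'
#' @param y numeric trait vector aligned to `cov`
#' @param cov covariate data.frame (see [assertCovariates])
#' @param fixed character vector of fixed-effect covariate names
#' @param random name of the random-intercept grouping column
#' @param conditional use conditional residuals (subtract predicted random
#'   intercepts); `FALSE` gives marginal residuals
#' @return standardized residual vector with the fitted cage variance as
#'   attribute `"cage_var"`
#' @export
residualizeTrait <- function(y, cov, fixed = "generation", random = "cage",
                             conditional = TRUE) {
    assertCovariates(cov)
    stopifnot(length(y) == nrow(cov))
    df <- cov
    for (f in fixed) df[[f]] <- factor(df[[f]])
    sy <- sd(y)
    df$.y <- if (sy > 0) (y - mean(y)) / sy else y - mean(y)
    fixpart <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
    cage_var <- 0
    r <- NULL
    if (length(unique(df[[random]])) > 1L) {
        fml <- stats::as.formula(paste0(".y ~ ", fixpart, " + (1|", random, ")"))
        fit <- tryCatch(
            lme4::lmer(fml, data = df, REML = TRUE,
                       control = lme4::lmerControl(check.conv.singular = "ignore")),
            error = function(e) NULL)
        if (!is.null(fit)) {
            vc <- as.data.frame(lme4::VarCorr(fit))
            cage_var <- vc$vcov[vc$grp == random]
            r <- if (conditional) residuals(fit)
                 else df$.y - (stats::model.matrix(fit) %*% lme4::fixef(fit))[, 1]
        }
    }
    if (is.null(r)) {
        fit <- lm(stats::as.formula(paste0(".y ~ ", fixpart)), data = df)
        r <- residuals(fit)
    }
    r <- as.numeric(r)
    sdr <- sd(r)
    ## y is standardized before fitting, so a residual SD below 1e-8 means the
    ## design explains the trait exactly; do not rescale numerical noise
    r <- if (sdr > 1e-8) (r - mean(r)) / sdr else r - mean(r)
    attr(r, "cage_var") <- cage_var
    r
}
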