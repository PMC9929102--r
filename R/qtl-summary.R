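## QTL summary statistics: variance explained, variance decomposition,
## covariate correlations, founder deconvolution, result assembly.

#' Proportion of variance explained by a QTL
#'
#' h2 = 1 - 10^(-(2/n) LOD): the likelihood-ratio conversion of a LOD score
#' into the fraction of phenotypic variance attributable to the locus.
#'
#' @param lod LOD score (>= 0)
#' @param n number of mice with phenotype
#' @return fraction in \[0, 1)
#' @export
varianceExplained <- function(lod, n) {
    stopifnot(all(lod >= 0), all(n >= 1))
    1 - 10^(-(2 / n) * lod)
}

#' Effective sample size by inversion of the variance-explained formula
#'
#' Given a reported LOD and variance-explained pair, returns the n that
#' satisfies h2 = 1 - 10^(-(2/n) LOD). Used to recover the effective cohort
#' size behind published QTL tables.
#'
#' @param lod LOD score
#' @param h2 variance explained as a fraction (not percent)
#' @export
inferEffectiveN <- function(lod, h2) {
    stopifnot(all(lod > 0), all(h2 > 0), all(h2 < 1))
    -2 * lod / log10(1 - h2)
}

#' Covariate variance decomposition
#'
#' The cage fraction is the cage-intercept variance over total variance from
#' a random-intercept model; the residuals of that model are then regressed
#' on sex, generation and diet (fixed effects, sequential in that order) and
#' each covariate's fraction is its sequential sum of squares over the total
#' sum of squares of the residual response.
#'
#' @param y variance-stabilized trait vector
#' @param cov covariate data.frame (see [assertCovariates])
#' @return named vector of fractions (cage, sex, generation, diet)
#' @export
partitionVariance <- function(y, cov) {
    assertCovariates(cov)
    stopifnot(length(y) == nrow(cov))
    cage_var <- 0; res <- y - mean(y)
    if (length(unique(cov$cage)) > 1L) {
        fit <- tryCatch(
            lme4::lmer(y ~ 1 + (1 | cage), data = cbind(cov, y = y), REML = TRUE,
                       control = lme4::lmerControl(check.conv.singular = "ignore")),
            error = function(e) NULL)
        if (!is.null(fit)) {
            vc <- as.data.frame(lme4::VarCorr(fit))
            cage_var <- vc$vcov[vc$grp == "cage"]
            resid_var <- vc$vcov[vc$grp == "Residual"]
            res <- residuals(fit)
            cage_frac <- cage_var / (cage_var + resid_var)
        }
    }
    if (!exists("cage_frac", inherits = FALSE)) cage_frac <- 0
    df <- data.frame(res = res, sex = cov$sex,
                     generation = factor(cov$generation),
                     diet = factor(cov$diet))
    flag <- vapply(df[-1], function(v) length(unique(v)) > 1L, TRUE)
    terms <- names(flag)[flag]
    out <- c(cage = cage_frac, sex = 0, generation = 0, diet = 0)
    if (length(terms)) {
        fit2 <- lm(stats::as.formula(paste("res ~", paste(terms, collapse = " + "))),
                   data = df)
        a <- anova(fit2)
        tot <- sum(a$`Sum Sq`)
        ## covariate fractions are of the residual (non-cage) response; scale
        ## by the non-cage share so all fractions refer to total variance
        for (tm in terms)
            out[tm] <- (1 - out[["cage"]]) * a[tm, "Sum Sq"] / tot
    }
    out
}

#' Spearman correlation of a trait with the coded covariates
#'
#' Rank correlation of the trait with the numeric covariate codings
#' (sex 0/1, generation 18-20, diet 0/1/2).
#'
#' @param y trait vector (residual or abundance)
#' @param cov covariate data.frame
#' @return named vector (rho_sex, rho_gen, rho_diet); NA with a warning for a
#'   constant trait
#' @export
spearmanCovariateRho <- function(y, cov) {
    assertCovariates(cov)
    if (sd(y) == 0) {
        warning("constant trait; Spearman correlations undefined")
        return(c(rho_sex = NA_real_, rho_gen = NA_real_, rho_diet = NA_real_))
    }
    f <- function(v) if (sd(v) == 0) NA_real_ else cor(y, v, method = "spearman")
    c(rho_sex = f(cov$sex), rho_gen = f(cov$generation), rho_diet = f(cov$diet))
}

#' Founder deconvolution at a QTL peak
#'
#' Labels each mouse with its maximum-posterior founder-origin state at the
#' peak locus (ties break to the lowest state index), then, within each diet,
#' compares the standardized residuals across founder labels by
#' Kruskal-Wallis followed by pairwise two-sided rank tests with BH
#' adjustment. Labels with fewer than `min_n` mice in a diet are excluded
#' from the pairwise tests.
#'
#' @param G a [FounderPosteriors]
#' @param peak marker id or index of the peak locus
#' @param r standardized residual trait vector
#' @param cov covariate data.frame
#' @param min_n minimum group size for pairwise tests
#' @return list per diet with the omnibus p, group medians and the pairwise
#'   table
#' @export
deconvolveFounders <- function(G, peak, r, cov, min_n = 3) {
    assertCovariates(cov)
    m <- if (is.character(peak)) match(peak, G@map$marker) else peak
    if (is.na(m)) stop("peak marker not found")
    P <- G@probs[, m, ]
    lab <- max.col(P, ties.method = "first")
    states <- apply(G@states, 1, paste, collapse = "/")
    out <- list()
    for (d in sort(unique(cov$diet))) {
        i <- which(cov$diet == d)
        li <- factor(lab[i], levels = seq_len(10), labels = states)
        li <- droplevels(li)
        kw <- if (nlevels(li) > 1L) kruskal.test(r[i], li)$p.value else NA_real_
        med <- tapply(r[i], li, median)
        big <- names(which(table(li) >= min_n))
        pw <- NULL
        if (length(big) >= 2L) {
            cmb <- combn(big, 2)
            pv <- apply(cmb, 2, function(g)
                suppressWarnings(wilcox.test(r[i][li == g[1]],
                                             r[i][li == g[2]])$p.value))
            pw <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ], p = pv,
                             padj = p.adjust(pv, "BH"))
        }
        out[[paste0("diet", d)]] <- list(kw_p = kw, medians = med,
                                         labels = li, pairwise = pw)
    }
    out
}

#' Assemble a QTL result row
#'
#' Combines a scan curve, its permutation threshold and the covariate
#' statistics into one row mirroring a published QTL table: peak, LOD,
#' threshold, support interval (start/end bp and width in Mb), variance
#' explained, covariate variance decomposition and Spearman correlations.
#'
#' @param trait trait (lineage) label
#' @param curve a `LodCurve`
#' @param threshold genome-wide threshold from [permutationThreshold]
#' @param y_vst variance-stabilized trait values (for the decomposition)
#' @param cov covariate data.frame
#' @param cfg a [scanConfig]
#' @return one-row data.frame
#' @export
qtlResult <- function(trait, curve, threshold, y_vst, cov, cfg = scanConfig()) {
    si <- supportInterval(curve, cfg)
    n <- attr(curve, "n")
    pv <- partitionVariance(y_vst, cov)
    rho <- spearmanCovariateRho(y_vst, cov)
    data.frame(trait = trait, model = attr(curve, "model"),
               chrom = si$chrom, peak_marker = si$peak_marker,
               lod = si$lod, threshold = as.numeric(threshold),
               start_bp = si$start, end_bp = si$end,
               width_mb = (si$end - si$start) / 1e6,
               h2 = varianceExplained(si$lod, n),
               var_cage = pv[["cage"]], var_sex = pv[["sex"]],
               var_generation = pv[["generation"]], var_diet = pv[["diet"]],
               rho_sex = rho[["rho_sex"]], rho_gen = rho[["rho_gen"]],
               rho_diet = rho[["rho_diet"]], n = n,
               significant = si$lod >= as.numeric(threshold))
}

#' Reported fungal QTL table
#'
#' Loads the diet-interaction fungal QTL table distributed with the package
#' (published mapping results for a four-founder AIL cohort: peak SNP, LOD,
#' interval start/end in bp, printed interval width in Mb, printed percent
#' variance explained, Spearman correlations and taxonomic rank). Used to
#' validate the package's interval-width and variance-explained arithmetic
#' against printed values.
#'
#' @return data.frame
#' @export
reportedQtlTable <- function() {
    f <- system.file("extdata", "fungal_qtl_reported.tsv", package = "mycoQTL")
    read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               quote = "", comment.char = "")
}
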