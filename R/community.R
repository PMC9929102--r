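## Community ecology statistics: alpha/beta diversity with covariate
## adjustment, constrained ordination, differential abundance, biomarker and
## indicator-species calls.

.countsMatrix <- function(x) {
    if (is(x, "TraitTable")) traitCounts(x) else as.matrix(x)
}

#' Alpha diversity per sample
#'
#' Chao1 = S_obs + F1^2/(2 F2) (bias-corrected F1(F1-1)/(2(F2+1)) when no
#' doubletons), Shannon = -sum p ln p (nats), Simpson = 1 - sum p^2.
#'
#' @param t a [TraitTable] (integer counts; Chao1 needs singleton/doubleton
#'   counts)
#' @return data.frame with columns sample, chao1, shannon, simpson, flag
#' @export
alphaDiversity <- function(t) {
    k <- .countsMatrix(t)
    res <- apply(k, 2, function(x) {
        tot <- sum(x)
        if (tot == 0) return(c(0, 0, 0, 1))
        s <- sum(x > 0)
        f1 <- sum(x == 1); f2 <- sum(x == 2)
        chao <- if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / 2
        p <- x[x > 0] / tot
        c(chao, -sum(p * log(p)), 1 - sum(p^2), 0)
    })
    data.frame(sample = colnames(k), chao1 = res[1, ], shannon = res[2, ],
               simpson = res[3, ], flag = res[4, ] == 1, row.names = NULL)
}

## profile-ML Box-Cox lambda on a fixed grid
.boxcoxLambda <- function(x, grid = seq(-2, 2, by = 0.01)) {
    bc <- MASS::boxcox(x ~ 1, lambda = grid, plotit = FALSE)
    bc$x[which.max(bc$y)]
}

.boxcoxTransform <- function(x, lambda) {
    if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' Covariate-adjusted alpha-diversity ANOVA
#'
#' Each index is Box-Cox transformed (lambda by profile maximum likelihood on
#' a \[-2, 2\] grid, step 0.01; zero values shifted by +1e-6), residualized on
#' sex and generation, and the standardized residuals compared across diets
#' by one-way ANOVA with Tukey pairwise comparisons, FDR-adjusted.
#'
#' @param div output of [alphaDiversity]
#' @param cov covariate data.frame (see [assertCovariates])
#' @return list per index: `lambda`, `anova_p`, `pairwise` (diff, lwr, upr,
#'   p_adj)
#' @export
adjustedAlphaAnova <- function(div, cov) {
    assertCovariates(cov)
    stopifnot(nrow(div) == nrow(cov))
    if (any(table(factor(cov$diet, levels = 0:2)) < 2))
        stop("every diet needs at least 2 samples")
    out <- list()
    for (idx in c("chao1", "shannon", "simpson")) {
        x <- div[[idx]]
        if (any(x <= 0)) x <- x + 1e-6 - min(0, min(x))
        lam <- .boxcoxLambda(x)
        tx <- .boxcoxTransform(x, lam)
        res <- residuals(lm(tx ~ sex + factor(generation),
                            data = cbind(cov, tx = tx)))
        res <- as.numeric(scale(res))
        diet <- factor(cov$diet, levels = 0:2, labels = c("CAL", "CON", "WES"))
        fit <- aov(res ~ diet)
        p <- summary(fit)[[1]][["Pr(>F)"]][1]
        tk <- TukeyHSD(fit)$diet
        pw <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                         lwr = tk[, "lwr"], upr = tk[, "upr"],
                         p_adj = p.adjust(tk[, "p adj"], "BH"),
                         row.names = NULL)
        out[[idx]] <- list(lambda = lam, anova_p = p, pairwise = pw)
    }
    out
}

#' Beta-diversity distance matrix
#'
#' Bray-Curtis dissimilarity, or the abundance-based Jaccard distance derived
#' from it as 2B/(1+B).
#'
#' @param t a [TraitTable] or samples-in-columns count matrix
#' @param metric `"bray"` or `"jaccard"`
#' @return a `dist` over samples
#' @export
betaDistance <- function(t, metric = c("bray", "jaccard")) {
    metric <- match.arg(metric)
    x <- t(.countsMatrix(t))             # samples x taxa for vegan
    zero <- rowSums(x) == 0
    B <- vegan::vegdist(x, method = "bray")
    if (any(zero)) {
        warning("all-zero sample(s); involved distances set to 0")
        Bm <- as.matrix(B)
        Bm[zero, ] <- 0; Bm[, zero] <- 0
        B <- as.dist(Bm)
    }
    if (metric == "jaccard") 2 * B / (1 + B) else B
}

#' Constrained ordination of a distance matrix
#'
#' Distance-based redundancy analysis (capscale): principal-coordinate
#' embedding of the distance matrix constrained by diet while conditioning on
#' sex and generation, with a permutation test of the constrained pseudo-F
#' and resampling-based pairwise diet post hocs on the constrained scores
#' (centroid distance statistic, step-down adjusted p, bootstrap CI).
#'
#' @param D a sample `dist`
#' @param cov covariate data.frame (see [assertCovariates])
#' @param n_perm permutations for the overall test
#' @param n_boot resamples for the post-hoc CIs
#' @param seed RNG seed
#' @return list with the capscale model, `F`, `p` and a `pairwise` table
#' @export
constrainedOrdination <- function(D, cov, n_perm = 999, n_boot = 500, seed = 1) {
    assertCovariates(cov)
    if (n_perm < 99) warning("fewer than 99 permutations; p-values unstable")
    df <- data.frame(diet = factor(cov$diet), sex = cov$sex,
                     generation = factor(cov$generation))
    set.seed(seed)
    mod <- vegan::capscale(D ~ diet + Condition(sex + generation), data = df)
    an <- vegan::anova.cca(mod, permutations = n_perm)
    sc <- vegan::scores(mod, display = "sites",
                        choices = seq_len(max(1, mod$CCA$rank)))
    sc <- as.matrix(sc)
    ## pairwise centroid-distance post hocs by label permutation within pair,
    ## bootstrap CI, Holm-type step-down adjustment
    lev <- levels(df$diet)
    cmb <- combn(lev, 2)
    est <- p <- lwr <- upr <- numeric(ncol(cmb))
    cdist <- function(s, g, a, b)
        sqrt(sum((colMeans(s[g == a, , drop = FALSE]) -
                  colMeans(s[g == b, , drop = FALSE]))^2))
    for (j in seq_len(ncol(cmb))) {
        a <- cmb[1, j]; b <- cmb[2, j]
        i <- df$diet %in% c(a, b)
        s <- sc[i, , drop = FALSE]; g <- droplevels(df$diet[i])
        est[j] <- cdist(s, g, a, b)
        null <- replicate(n_perm, cdist(s, sample(g), a, b))
        p[j] <- (1 + sum(null >= est[j])) / (n_perm + 1)
        bs <- replicate(n_boot, {
            ia <- sample(which(g == a), replace = TRUE)
            ib <- sample(which(g == b), replace = TRUE)
            sqrt(sum((colMeans(s[ia, , drop = FALSE]) -
                      colMeans(s[ib, , drop = FALSE]))^2))
        })
        lwr[j] <- quantile(bs, 0.025); upr[j] <- quantile(bs, 0.975)
    }
    pairwise <- data.frame(comparison = paste(cmb[1, ], cmb[2, ], sep = "-"),
                           estimate = est, lwr = lwr, upr = upr,
                           p = p, p_adj = p.adjust(p, "holm"))
    list(model = mod, F = an$F[1], p = an$`Pr(>F)`[1],
         scores = sc, pairwise = pairwise)
}

#' Kruskal-Wallis plus pairwise Mann-Whitney with FDR
#'
#' Per taxon: omnibus Kruskal-Wallis across groups; where the omnibus p is
#' below `alpha`, all pairwise two-sided rank-sum tests; Benjamini-Hochberg
#' adjustment across the whole pairwise family.
#'
#' @param t a [TraitTable] or matrix of (relative) abundances,
#'   taxa in rows
#' @param groups group labels per sample (e.g. diet codes)
#' @param alpha omnibus screening level
#' @return data.frame (taxon, kw_p, group1, group2, p, padj); taxa failing
#'   the screen have no pairwise rows
#' @export
kwMwuFdr <- function(t, groups, alpha = 0.05) {
    x <- .countsMatrix(t)
    g <- factor(groups)
    if (nlevels(g) < 2) stop("need at least two groups")
    rows <- list()
    for (tx in rownames(x)) {
        v <- x[tx, ]
        kw <- if (length(unique(v)) == 1L) 1
              else suppressWarnings(kruskal.test(v, g)$p.value)
        if (is.na(kw)) kw <- 1
        if (kw < alpha) {
            cmb <- combn(levels(g), 2)
            for (j in seq_len(ncol(cmb))) {
                pv <- suppressWarnings(
                    wilcox.test(v[g == cmb[1, j]], v[g == cmb[2, j]])$p.value)
                rows[[length(rows) + 1L]] <-
                    data.frame(taxon = tx, kw_p = kw, group1 = cmb[1, j],
                               group2 = cmb[2, j], p = if (is.na(pv)) 1 else pv)
            }
        } else {
            rows[[length(rows) + 1L]] <-
                data.frame(taxon = tx, kw_p = kw, group1 = NA, group2 = NA,
                           p = NA_real_)
        }
    }
    out <- do.call(rbind, rows)
    out$padj <- NA_real_
    sel <- !is.na(out$p)
    out$padj[sel] <- p.adjust(out$p[sel], "BH")
    out
}

#' Biomarker discovery (LEfSe-style)
#'
#' Per taxon: Kruskal-Wallis screen across classes at `alpha`; survivors are
#' scored by a single-feature linear-discriminant effect size, the log10 of
#' the largest between-class separation of per-million relative abundances on
#' the discriminant axis. Taxa whose Kruskal-Wallis test is also significant
#' for sex or for generation are removed (diet-specificity filter).
#'
#' @param t a [TraitTable] or matrix of counts/abundances (taxa in rows)
#' @param classes class labels (diet) per sample
#' @param nuisance optional named list of nuisance label vectors (e.g.
#'   `list(sex = ..., generation = ...)`) for the specificity filter
#' @param alpha Kruskal-Wallis screening level
#' @param lda_threshold minimum effect size (log10 scale, default 2)
#' @return data.frame (taxon, direction, effect_size, kw_p)
#' @export
lefseLite <- function(t, classes, nuisance = NULL, alpha = 0.05,
                      lda_threshold = 2) {
    x <- .countsMatrix(t)
    g <- factor(classes)
    if (nlevels(g) < 2) stop("need at least two classes")
    rel <- sweep(x, 2, pmax(colSums(x), 1), "/") * 1e6   # per-million
    rows <- list()
    for (tx in rownames(rel)) {
        v <- rel[tx, ]
        if (length(unique(v)) == 1L) next
        kw <- suppressWarnings(kruskal.test(v, g)$p.value)
        if (is.na(kw) || kw >= alpha) next
        drop <- FALSE
        for (nu in nuisance) {
            pnu <- suppressWarnings(kruskal.test(v, factor(nu))$p.value)
            if (!is.na(pnu) && pnu < alpha) { drop <- TRUE; break }
        }
        if (drop) next
        mns <- tapply(v, g, mean)
        ## single-feature LDA: discriminant is the feature axis; effect size
        ## is the largest between-class mean separation on it
        eff <- log10(max(abs(outer(mns, mns, "-"))) + 1)
        if (eff < lda_threshold) next
        rows[[length(rows) + 1L]] <-
            data.frame(taxon = tx, direction = names(which.max(mns)),
                       effect_size = eff, kw_p = kw)
    }
    if (!length(rows))
        return(data.frame(taxon = character(), direction = character(),
                          effect_size = numeric(), kw_p = numeric()))
    do.call(rbind, rows)
}

## group-equalized IndVal for one taxon over all group combinations
.indvalG <- function(v, g, combos) {
    mg <- tapply(v, g, mean)
    occ <- tapply(v > 0, g, mean)
    ns <- tabulate(g)
    best <- -Inf; bestC <- NULL
    for (C in combos) {
        A <- sum(mg[C]) / sum(mg)
        if (!is.finite(A)) A <- 0
        B <- sum(occ[C] * ns[C]) / sum(ns[C])
        iv <- sqrt(A * B)
        if (iv > best) { best <- iv; bestC <- C }
    }
    c(stat = best, combo = paste(levels(g)[bestC], collapse = "+"))
}

#' Indicator species analysis
#'
#' Group-equalized indicator values IndVal.g = sqrt(A * B) with A the
#' specificity (group-mean abundance over summed group means, correcting for
#' group size) and B the fidelity (occurrence fraction in the group),
#' evaluated for all single groups and group combinations short of the full
#' set; significance by permutation of the class labels. An optional
#' nuisance filter removes taxa whose indicator test is also significant for
#' sex or generation.
#'
#' @param t a [TraitTable] or matrix (taxa in rows)
#' @param classes class labels per sample
#' @param n_perm label permutations
#' @param nuisance optional named list of nuisance label vectors
#' @param alpha significance level used by the nuisance filter
#' @param seed RNG seed
#' @return data.frame (taxon, group, indval, p)
#' @export
indicatorSpecies <- function(t, classes, n_perm = 999, nuisance = NULL,
                             alpha = 0.05, seed = 1) {
    x <- .countsMatrix(t)
    g <- factor(classes)
    if (any(tabulate(g, nlevels(g)) == 0)) stop("every class needs samples")
    if (nlevels(g) < 2) stop("need at least two classes")
    K <- nlevels(g)
    combos <- unlist(lapply(seq_len(K - 1), function(k)
        utils::combn(K, k, simplify = FALSE)), recursive = FALSE)
    set.seed(seed)
    nsmp <- length(g)
    perms <- replicate(n_perm, sample.int(nsmp), simplify = FALSE)
    res <- lapply(rownames(x), function(tx) {
        v <- x[tx, ]
        if (all(v == 0)) return(NULL)
        obs <- .indvalG(v, g, combos)
        stat <- as.numeric(obs["stat"])
        cnt <- sum(vapply(perms, function(idx)
            as.numeric(.indvalG(v, g[idx], combos)["stat"]) >= stat, TRUE))
        data.frame(taxon = tx, group = obs["combo"], indval = stat,
                   p = (1 + cnt) / (n_perm + 1))
    })
    out <- do.call(rbind, res)
    if (is.null(out)) return(data.frame(taxon = character(), group = character(),
                                        indval = numeric(), p = numeric()))
    rownames(out) <- NULL
    if (!is.null(nuisance) && nrow(out)) {
        keep <- rep(TRUE, nrow(out))
        for (nu in nuisance) {
            gn <- factor(nu)
            Kn <- nlevels(gn)
            cn <- unlist(lapply(seq_len(max(Kn - 1, 1)), function(k)
                utils::combn(Kn, k, simplify = FALSE)), recursive = FALSE)
            for (i in which(keep)) {
                v <- x[out$taxon[i], ]
                obs <- as.numeric(.indvalG(v, gn, cn)["stat"])
                cnt <- sum(vapply(seq_len(n_perm), function(b)
                    as.numeric(.indvalG(v, gn[sample.int(length(gn))], cn)["stat"]) >= obs,
                    TRUE))
                if ((1 + cnt) / (n_perm + 1) < alpha) keep[i] <- FALSE
            }
        }
        out <- out[keep, , drop = FALSE]
    }
    out
}
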