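## Kinship-corrected genome scans: additive and interaction LOD curves,
## permutation genome-wide thresholds, 1.5-LOD support intervals.

#' Scan configuration
#'
#' @param n_perm number of permutations for genome-wide thresholds
#' @param alpha_gw genome-wide significance level
#' @param lod_drop LOD drop defining the support interval
#' @param seed RNG seed for permutations
#' @export
scanConfig <- function(n_perm = 1000, alpha_gw = 0.05, lod_drop = 1.5, seed = 1) {
    stopifnot(n_perm >= 1, alpha_gw > 0, alpha_gw <= 1, lod_drop >= 0)
    list(n_perm = as.integer(n_perm), alpha_gw = alpha_gw,
         lod_drop = lod_drop, seed = as.integer(seed))
}

#' Eigendecomposition of a kinship matrix
#'
#' Precompute once and pass to the scan functions when scanning many traits
#' against the same cohort.
#'
#' @param K symmetric positive-semidefinite kinship matrix
#' @export
kinshipEigen <- function(K) {
    ev <- eigen((K + t(K)) / 2, symmetric = TRUE)
    if (min(ev$values) < -1e-8 * sum(diag(K)))
        stop("kinship matrix is not positive semidefinite")
    list(U = ev$vectors, lambda = pmax(ev$values, 0))
}

## REML estimate of the genetic variance proportion under the null
## (covariates-only) model, on the rotated data
.remlH2 <- function(ystar, Xstar, lambda) {
    n <- length(ystar); p <- qr(Xstar)$rank
    nll <- function(h2) {
        V <- h2 * lambda + (1 - h2)
        w <- 1 / V
        Xw <- Xstar * sqrt(w)
        yw <- ystar * sqrt(w)
        fit <- lm.fit(Xw, yw)
        rss <- sum(fit$residuals^2)
        XtX <- crossprod(Xw)
        0.5 * (sum(log(V)) + determinant(XtX, logarithm = TRUE)$modulus +
               (n - p) * log(rss))
    }
    opt <- optimize(nll, c(1e-6, 0.99))
    opt$minimum
}

## covariate design: intercept + sex + diet contrasts (CON, WES vs CAL)
.covDesign <- function(cov) {
    cbind(intercept = 1, sex = cov$sex,
          dietCON = as.numeric(cov$diet == 1),
          dietWES = as.numeric(cov$diet == 2))
}

## whitened scan inputs shared by scans and permutation thresholds
.scanSetup <- function(y, G, cov, K = NULL, eig = NULL, h2 = NULL,
                       model = c("Add", "IntDiet", "IntSex")) {
    model <- match.arg(model)
    assertCovariates(cov)
    n <- length(y)
    D <- G@dosage
    stopifnot(dim(D)[1] == n, nrow(cov) == n)
    if (model == "IntDiet" && !all(0:2 %in% cov$diet))
        stop("all three diet levels must be present for a diet-interaction scan")
    if (model == "IntSex" && length(unique(cov$sex)) < 2L)
        stop("both sexes must be present for a sex-interaction scan")
    X0 <- .covDesign(cov)
    M <- dim(D)[2]
    if (is.null(eig) && !is.null(K)) eig <- kinshipEigen(K)
    if (!is.null(eig)) {
        ystar <- crossprod(eig$U, y)[, 1]
        X0star <- crossprod(eig$U, X0)
        if (is.null(h2)) h2 <- .remlH2(ystar, X0star, eig$lambda)
        sw <- sqrt(1 / (h2 * eig$lambda + (1 - h2)))
        ytil <- ystar * sw
        X0til <- X0star * sw
        rot <- function(m) crossprod(eig$U, m) * sw
    } else {
        h2 <- 0
        ytil <- y
        X0til <- X0
        rot <- identity
    }
    ## per-marker genotype blocks: 3 free founder-dosage columns
    blocks <- vector("list", M)
    inter <- NULL
    for (m in seq_len(M)) blocks[[m]] <- rot(D[, m, 1:3, drop = TRUE])
    if (model == "IntDiet") {
        inter <- vector("list", M)
        z1 <- as.numeric(cov$diet == 1); z2 <- as.numeric(cov$diet == 2)
        for (m in seq_len(M)) {
            B <- D[, m, 1:3, drop = TRUE]
            inter[[m]] <- rot(cbind(B * z1, B * z2))
        }
    } else if (model == "IntSex") {
        inter <- vector("list", M)
        for (m in seq_len(M))
            inter[[m]] <- rot(D[, m, 1:3, drop = TRUE] * cov$sex)
    }
    list(model = model, n = n, h2 = h2, ytil = ytil, X0til = X0til,
         blocks = blocks, inter = inter, map = G@map)
}

## rank-aware orthonormal basis of a design matrix
.qbasis <- function(X) {
    q <- qr(X)
    qr.Q(q)[, seq_len(q$rank), drop = FALSE]
}

## LOD matrix (markers x traits) for a whitened trait matrix Y
.lodMatrix <- function(Y, setup) {
    Y <- as.matrix(Y)
    n <- setup$n
    yty <- colSums(Y^2)
    M <- length(setup$blocks)
    lod <- matrix(0, M, ncol(Y))
    if (is.null(setup$inter)) {
        Q0 <- .qbasis(setup$X0til)
        rss0 <- yty - colSums(crossprod(Q0, Y)^2)
        for (m in seq_len(M)) {
            Q1 <- .qbasis(cbind(setup$X0til, setup$blocks[[m]]))
            rss1 <- yty - colSums(crossprod(Q1, Y)^2)
            lod[m, ] <- (n / 2) * log10(rss0 / rss1)
        }
    } else {
        for (m in seq_len(M)) {
            Qn <- .qbasis(cbind(setup$X0til, setup$blocks[[m]]))
            Qf <- .qbasis(cbind(setup$X0til, setup$blocks[[m]], setup$inter[[m]]))
            rssn <- yty - colSums(crossprod(Qn, Y)^2)
            rssf <- yty - colSums(crossprod(Qf, Y)^2)
            lod[m, ] <- (n / 2) * log10(rssn / rssf)
        }
    }
    pmax(lod, 0)
}

.asLodCurve <- function(lod, setup) {
    out <- data.frame(marker = setup$map$marker, chrom = setup$map$chrom,
                      bp = setup$map$bp, lod = as.vector(lod))
    attr(out, "model") <- setup$model
    attr(out, "h2") <- setup$h2
    attr(out, "n") <- setup$n
    class(out) <- c("LodCurve", "data.frame")
    out
}

#' Additive genome scan
#'
#' Fits the residualized trait against expected founder dosages with sex and
#' diet as fixed effects and the kinship matrix as a random effect. The
#' genetic variance proportion is estimated once per trait by REML under the
#' covariates-only model on the eigendecomposition of K; the data are rotated
#' to independence and each marker is tested by generalized least squares,
#' LOD = (n/2) log10(RSS_null / RSS_full).
#'
#' @param y residualized trait vector
#' @param G a [FounderPosteriors]
#' @param cov covariate data.frame (see [assertCovariates])
#' @param K kinship matrix (NULL for ordinary least squares)
#' @param eig optional precomputed [kinshipEigen] decomposition
#' @param h2 optional fixed genetic variance proportion (skips REML)
#' @return a `LodCurve` data.frame (marker, chrom, bp, lod) with the model
#'   tag, fitted h2 and n as attributes
#' @export
scanAdditive <- function(y, G, cov, K = NULL, eig = NULL, h2 = NULL) {
    setup <- .scanSetup(y, G, cov, K, eig, h2, "Add")
    .asLodCurve(.lodMatrix(setup$ytil, setup), setup)
}

#' Interaction genome scan
#'
#' Tests genotype-by-covariate interaction: the full model adds products of
#' the founder dosages with the interaction term (diet as two indicator
#' contrasts, or sex) to the additive model; the interaction LOD is the LOD
#' difference between the full and the genotype-only model, floored at zero.
#'
#' @inheritParams scanAdditive
#' @param term `"diet"` or `"sex"`
#' @export
scanInteraction <- function(y, G, cov, K = NULL, term = c("diet", "sex"),
                            eig = NULL, h2 = NULL) {
    term <- match.arg(term)
    model <- if (term == "diet") "IntDiet" else "IntSex"
    setup <- .scanSetup(y, G, cov, K, eig, h2, model)
    .asLodCurve(.lodMatrix(setup$ytil, setup), setup)
}

#' Permutation genome-wide LOD threshold
#'
#' Permutes the rotated (whitened) phenotype `n_perm` times, records the
#' genome-wide maximum of the model's LOD statistic (the full-null difference
#' for interaction models) for each permutation, and returns the empirical
#' (1 - alpha_gw) quantile (type-7 interpolation).
#'
#' @inheritParams scanAdditive
#' @param model `"Add"`, `"IntDiet"` or `"IntSex"`
#' @param cfg a [scanConfig]
#' @return threshold, with the permutation maxima as attribute `"maxima"`
#' @export
permutationThreshold <- function(y, G, cov, K = NULL,
                                 model = c("Add", "IntDiet", "IntSex"),
                                 cfg = scanConfig(), eig = NULL, h2 = NULL) {
    model <- match.arg(model)
    if (cfg$n_perm < 20) warning("fewer than 20 permutations; quantile unstable")
    setup <- .scanSetup(y, G, cov, K, eig, h2, model)
    set.seed(cfg$seed)
    n <- setup$n
    Y <- vapply(seq_len(cfg$n_perm), function(i) setup$ytil[sample.int(n)],
                numeric(n))
    maxima <- apply(.lodMatrix(Y, setup), 2, max)
    thr <- as.numeric(quantile(maxima, 1 - cfg$alpha_gw, type = 7))
    attr(thr, "maxima") <- maxima
    thr
}

#' 1.5-LOD support interval
#'
#' On the peak's chromosome, the interval spans the contiguous run of markers
#' around the peak whose LOD stays within `lod_drop` of the maximum; ties at
#' the peak resolve to the lowest genomic coordinate. Width is
#' (end - start) / 1e6 Mb exactly.
#'
#' @param curve a `LodCurve` from a scan
#' @param cfg a [scanConfig] (supplies `lod_drop`)
#' @param threshold optional genome-wide threshold the peak must exceed
#' @return list with `chrom`, `peak_marker`, `peak_bp`, `lod`, `start`,
#'   `end`, `width_mb` and an `edge` flag when the interval hits a
#'   chromosome end
#' @export
supportInterval <- function(curve, cfg = scanConfig(), threshold = NULL) {
    pk <- which.max(curve$lod)          # first index = lowest coordinate tie-break
    if (!is.null(threshold) && curve$lod[pk] < threshold)
        stop("no genome-wide-significant peak in this curve")
    ch <- curve$chrom[pk]
    i <- which(curve$chrom == ch)
    lods <- curve$lod[i]
    p <- match(pk, i)
    cut <- lods[p] - cfg$lod_drop
    lo <- p; while (lo > 1 && lods[lo - 1] >= cut) lo <- lo - 1
    hi <- p; while (hi < length(i) && lods[hi + 1] >= cut) hi <- hi + 1
    start <- curve$bp[i[lo]]; end <- curve$bp[i[hi]]
    list(chrom = ch, peak_marker = curve$marker[pk], peak_bp = curve$bp[pk],
         lod = curve$lod[pk], start = start, end = end,
         width_mb = (end - start) / 1e6,
         edge = (lo == 1 && lods[1] >= cut) || (hi == length(i) && lods[hi] >= cut))
}
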