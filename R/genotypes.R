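## Marker QC and founder-haplotype reconstruction.

#' Filter markers for informativeness
#'
#' Retains markers with minor allele frequency strictly above `maf_min`,
#' missingness strictly below `max_missing`, and at least two distinct
#' founder genotypes (markers at which all four founders carry the same
#' homozygous call are uninformative for founder reconstruction and are
#' removed). Marker order is preserved.
#'
#' @param geno cohort [GenotypeMatrix]
#' @param founders founder [GenotypeMatrix] with exactly 4 individuals typed
#'   at the same markers
#' @param maf_min minor-allele-frequency threshold (exclusive)
#' @param max_missing missingness threshold (exclusive)
#' @return list with `geno` and `founders` restricted to surviving markers
#' @export
filterMarkers <- function(geno, founders, maf_min = 0.05, max_missing = 0.1) {
    stopifnot(is(geno, "GenotypeMatrix"), is(founders, "GenotypeMatrix"))
    if (nrow(founders@calls) != 4L)
        stop("founders must contain exactly 4 individuals")
    if (!identical(geno@map$marker, founders@map$marker))
        stop("marker sets of cohort and founders do not align")
    calls <- geno@calls
    p <- colMeans(calls, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    maf[is.nan(maf)] <- 0
    miss <- colMeans(is.na(calls))
    ndist <- apply(founders@calls, 2, function(v) length(unique(na.omit(v))))
    keep <- maf > maf_min & miss < max_missing & ndist >= 2L
    list(geno = GenotypeMatrix(calls[, keep, drop = FALSE], geno@map[keep, ]),
         founders = GenotypeMatrix(founders@calls[, keep, drop = FALSE],
                                   founders@map[keep, ]))
}

## ordered diplotype state space (16) and its unordered collapse (10)
.stateSpace <- function() {
    ord <- expand.grid(a = 1:4, b = 1:4)
    unord <- t(apply(ord, 1, sort))
    states10 <- unique(unord)
    u_of_o <- match(paste(unord[, 1], unord[, 2]), paste(states10[, 1], states10[, 2]))
    list(ordered = as.matrix(ord), states10 = states10, u_of_o = u_of_o)
}

## per-marker 16 x 4 emission table: P(obs = 0,1,2 | state) and 1 for missing
.emissionTable <- function(fa, e, ord) {
    t1 <- fa[ord[, 1]]; t2 <- fa[ord[, 2]]
    p1 <- t1 * (1 - e) + (1 - t1) * e
    p2 <- t2 * (1 - e) + (1 - t2) * e
    cbind((1 - p1) * (1 - p2),
          p1 * (1 - p2) + (1 - p1) * p2,
          p1 * p2,
          1)
}

#' Reconstruct founder-origin posteriors by HMM
#'
#' Runs a forward-backward hidden Markov model per chromosome over the
#' 10 unordered founder-diplotype states of a four-way cross. Transitions
#' between adjacent markers derive from the Haldane recombination fraction
#' r = (1 - exp(-2d))/2 at the inter-marker distance d in Morgans, with map
#' distances multiplied by an effective-generation factor (default
#' `n_generations/2`) reflecting the recombination accumulated in an AIL.
#' Emissions give the probability of each observed call given the two founder
#' alleles with per-allele error `geno_error`; missing calls emit uniformly.
#' Expected per-founder allele dosages (summing to 2) are computed from the
#' posteriors.
#'
#' @param geno filtered cohort [GenotypeMatrix]
#' @param founders aligned founder [GenotypeMatrix] (4 individuals)
#' @param n_generations intercross generations (sets the default map
#'   expansion)
#' @param geno_error per-allele genotyping error probability
#' @param gen_factor effective-generation map scaling (default
#'   `n_generations/2`)
#' @param cm_per_mb physical-to-genetic conversion used when the map has no
#'   cM positions
#' @return a [FounderPosteriors] object
#' @export
reconstructFounderPosteriors <- function(geno, founders, n_generations = 20,
                                         geno_error = 0.01,
                                         gen_factor = n_generations / 2,
                                         cm_per_mb = 0.5) {
    stopifnot(is(geno, "GenotypeMatrix"), is(founders, "GenotypeMatrix"))
    if (!identical(geno@map$marker, founders@map$marker))
        stop("marker sets of cohort and founders do not align")
    map <- geno@map
    if (is.null(map$cM) || all(is.na(map$cM))) map$cM <- map$bp / 1e6 * cm_per_mb
    ss <- .stateSpace()
    ord <- ss$ordered
    n <- nrow(geno@calls); M <- ncol(geno@calls)
    fa <- founders@calls / 2           # founder allele frequency per strain
    fa[is.na(fa)] <- 0.5
    ndist <- apply(founders@calls, 2, function(v) length(unique(na.omit(v))))
    if (all(ndist <= 1L)) {
        warning("no marker distinguishes the founders; posteriors are uniform")
        probs <- array(1 / 10, dim = c(n, M, 10L),
                       dimnames = list(rownames(geno@calls), map$marker, NULL))
        dosage <- array(2 / 4, dim = c(n, M, 4L),
                        dimnames = list(rownames(geno@calls), map$marker, NULL))
        return(FounderPosteriors(probs, dosage, states = ss$states10, map = map))
    }

    probs16 <- array(0, dim = c(n, M, 16L))
    obs <- geno@calls
    obsIdx <- obs + 1L
    obsIdx[is.na(obsIdx)] <- 4L

    for (ch in unique(map$chrom)) {
        j <- which(map$chrom == ch)
        Mc <- length(j)
        ## emissions for this chromosome: list of n x 16 matrices
        E <- vector("list", Mc)
        for (k in seq_len(Mc)) {
            tab <- .emissionTable(fa[, j[k]], geno_error, ord)
            E[[k]] <- t(tab)[obsIdx[, j[k]], , drop = FALSE]
        }
        ## transition kernels per interval
        Tm <- vector("list", max(Mc - 1L, 0L))
        if (Mc > 1L) {
            d <- diff(map$cM[j]) / 100 * gen_factor
            r <- 0.5 * (1 - exp(-2 * d))
            for (k in seq_len(Mc - 1L)) {
                K <- matrix(r[k] / 4, 4, 4); diag(K) <- (1 - r[k]) + r[k] / 4
                Tm[[k]] <- kronecker(K, K)
            }
        }
        ## forward pass (scaled)
        Fwd <- vector("list", Mc)
        f <- matrix(1 / 16, n, 16L) * E[[1L]]
        f <- .renorm(f)
        Fwd[[1L]] <- f
        if (Mc > 1L) for (k in 2:Mc) {
            f <- (f %*% Tm[[k - 1L]]) * E[[k]]
            f <- .renorm(f)
            Fwd[[k]] <- f
        }
        ## backward pass and posterior
        b <- matrix(1, n, 16L)
        probs16[, j[Mc], ] <- .renorm(Fwd[[Mc]] * b)
        if (Mc > 1L) for (k in (Mc - 1L):1L) {
            b <- (b * E[[k + 1L]]) %*% t(Tm[[k]])
            b <- .renorm(b)
            probs16[, j[k], ] <- .renorm(Fwd[[k]] * b)
        }
    }

    ## collapse ordered -> unordered states; expected founder dosages
    probs <- array(0, dim = c(n, M, 10L),
                   dimnames = list(rownames(obs), map$marker, NULL))
    for (u in 1:10) {
        acc <- matrix(0, n, M)
        for (o in which(ss$u_of_o == u)) acc <- acc + probs16[, , o]
        probs[, , u] <- acc
    }
    dosage <- array(0, dim = c(n, M, 4L),
                    dimnames = list(rownames(obs), map$marker, NULL))
    cnt <- sapply(1:4, function(f) (ss$states10[, 1] == f) + (ss$states10[, 2] == f))
    for (f_i in 1:4) {
        acc <- matrix(0, n, M)
        for (u in 1:10) if (cnt[u, f_i] > 0) acc <- acc + probs[, , u] * cnt[u, f_i]
        dosage[, , f_i] <- acc
    }
    FounderPosteriors(probs, dosage, states = ss$states10, map = map)
}

## row-normalize with uniform fallback for all-zero rows
.renorm <- function(x) {
    s <- rowSums(x)
    bad <- s <= 0 | !is.finite(s)
    if (any(bad)) { x[bad, ] <- 1; s[bad] <- ncol(x) }
    x / s
}

#' Kinship from founder posteriors
#'
#' K\[i, j\] is the mean over loci of the probability that mice i and j are
#' in the same founder-origin state, i.e. the inner product of their
#' state-probability vectors. A mouse whose diplotype is fully certain at
#' every locus has self-kinship 1; uniform posteriors give 1/10 everywhere.
#' The alternative `"dosage"` method uses founder-dosage inner products
#' scaled so a certain homozygote has self-kinship 1.
#'
#' @param post a [FounderPosteriors]
#' @param method `"probs"` (default) or `"dosage"`
#' @return symmetric positive-semidefinite kinship matrix
#' @export
kinshipFromPosteriors <- function(post, method = c("probs", "dosage")) {
    method <- match.arg(method)
    d <- dim(post@probs)
    if (method == "probs") {
        Pm <- matrix(post@probs, nrow = d[1])      # n x (M*10)
        K <- tcrossprod(Pm) / d[2]
    } else {
        Dm <- matrix(post@dosage, nrow = d[1])
        K <- tcrossprod(Dm) / (4 * d[2])
    }
    dimnames(K) <- list(dimnames(post@probs)[[1]], dimnames(post@probs)[[1]])
    (K + t(K)) / 2
}
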