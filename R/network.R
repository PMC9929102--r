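## Compositionality-aware correlation network: SparCC-style estimation,
## bootstrap significance, inter-kingdom edge filtering, key drivers,
## conserved edges.

## one Dirichlet-resampled log-fraction matrix (samples x taxa)
.logFractions <- function(k) {
    g <- matrix(rgamma(length(k), shape = k + 1), nrow(k))
    log(g / rowSums(g))
}

## solve basis variances from the log-ratio variance matrix T given the
## pair-exclusion mask; sparsity assumption: sum_j t_ij ~ d_i w_i + sum_j w_j
.basisSolve <- function(Tm, incl) {
    m <- nrow(Tm)
    A <- incl * 1
    diag(A) <- rowSums(incl)
    b <- rowSums(Tm * incl)
    w <- tryCatch(solve(A, b), error = function(e) rep(mean(diag(Tm)), m))
    pos <- w[w > 0]
    w[w <= 0] <- if (length(pos)) min(pos) * 1e-3 else 1e-6
    w
}

#' SparCC-style compositional correlation matrix
#'
#' Estimates correlations between basis abundances from count compositions:
#' fractions are drawn with a unit pseudocount (Dirichlet resampling,
#' averaged over `n_estimate_iter` draws), the log-ratio variance matrix
#' T\[i,j\] = var(log(x_i/x_j)) is computed for all pairs, basis variances are
#' solved from the sparsity-assumption linear system, and the most strongly
#' correlated pair (|r| above `exclusion_threshold`) is excluded from the
#' system and the solve repeated for up to `exclusion_iter` rounds. Estimates
#' are clipped to \[-1, 1\].
#'
#' @param t a [TraitTable] or count matrix (taxa in rows), or a list of two
#'   tables which are concatenated (e.g. fungal + bacterial)
#' @param n_estimate_iter Dirichlet resampling iterations
#' @param exclusion_iter maximum pair-exclusion rounds
#' @param exclusion_threshold |r| above which a pair is excluded from the
#'   basis solve
#' @param seed RNG seed
#' @return symmetric correlation matrix with unit diagonal
#' @export
sparccCorrelation <- function(t, n_estimate_iter = 20, exclusion_iter = 10,
                              exclusion_threshold = 0.1, seed = 1) {
    if (is.list(t) && !is(t, "TraitTable"))
        t <- do.call(rbind, lapply(t, .countsMatrix))
    k <- .countsMatrix(t)
    if (nrow(k) < 4) stop("at least 4 taxa required for basis identifiability")
    if (any(rowSums(k) == 0)) stop("taxa with all-zero counts must be removed")
    set.seed(seed)
    ks <- t(k)                            # samples x taxa
    m <- ncol(ks)
    Tm <- matrix(0, m, m)
    for (it in seq_len(n_estimate_iter)) {
        Y <- .logFractions(ks)
        C <- stats::cov(Y)
        v <- diag(C)
        Tm <- Tm + (outer(v, v, "+") - 2 * C)
    }
    Tm <- Tm / n_estimate_iter
    incl <- matrix(TRUE, m, m); diag(incl) <- FALSE
    corFromBasis <- function(w) {
        r <- (outer(w, w, "+") - Tm) / (2 * sqrt(outer(w, w)))
        r <- pmin(pmax(r, -1), 1)
        diag(r) <- 1
        r
    }
    w <- .basisSolve(Tm, incl)
    r <- corFromBasis(w)
    for (round in seq_len(exclusion_iter)) {
        cand <- abs(r) * incl
        cand[lower.tri(cand, diag = TRUE)] <- 0
        top <- which(cand == max(cand), arr.ind = TRUE)[1, ]
        if (cand[top[1], top[2]] <= exclusion_threshold) break
        ## never let a taxon drop out of the system entirely
        if (sum(incl[top[1], ]) <= 2 || sum(incl[top[2], ]) <= 2) break
        incl[top[1], top[2]] <- incl[top[2], top[1]] <- FALSE
        w <- .basisSolve(Tm, incl)
        r <- corFromBasis(w)
    }
    dimnames(r) <- list(rownames(k), rownames(k))
    r
}

#' Bootstrap p-values for SparCC correlations
#'
#' Each bootstrap shuffles every taxon's counts independently across samples
#' (destroying all true association), recomputes the correlation matrix, and
#' the two-sided p-value per pair is (1 + #\{|r_boot| >= |r_obs|\}) /
#' (n_boot + 1), with Benjamini-Hochberg adjustment across all pairs.
#'
#' @inheritParams sparccCorrelation
#' @param n_boot number of bootstrap permutations (>= 99)
#' @return list with `r` (observed), `p` and `padj` matrices
#' @export
sparccBootstrap <- function(t, n_boot = 999, n_estimate_iter = 20,
                            exclusion_iter = 10, exclusion_threshold = 0.1,
                            seed = 1) {
    stopifnot(n_boot >= 99)
    if (is.list(t) && !is(t, "TraitTable"))
        t <- do.call(rbind, lapply(t, .countsMatrix))
    k <- .countsMatrix(t)
    r_obs <- sparccCorrelation(k, n_estimate_iter, exclusion_iter,
                               exclusion_threshold, seed = seed)
    m <- nrow(k); nsmp <- ncol(k)
    set.seed(seed + 1L)
    cnt <- matrix(0, m, m)
    for (b in seq_len(n_boot)) {
        kb <- k
        for (i in seq_len(m)) kb[i, ] <- kb[i, sample.int(nsmp)]
        rb <- sparccCorrelation(kb, n_estimate_iter, exclusion_iter,
                                exclusion_threshold,
                                seed = sample.int(.Machine$integer.max, 1))
        cnt <- cnt + (abs(rb) >= abs(r_obs))
    }
    p <- (1 + cnt) / (n_boot + 1)
    diag(p) <- 1
    padj <- p
    ut <- upper.tri(p)
    padj[ut] <- p.adjust(p[ut], "BH")
    padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
    list(r = r_obs, p = p, padj = padj)
}

#' Inter-kingdom edge network
#'
#' Keeps fungal-bacterial pairs with adjusted p below `alpha_adj`; edges
#' within a kingdom are discarded. Node degrees are computed on the retained
#' edge set.
#'
#' @param r correlation matrix
#' @param padj matching matrix of BH-adjusted p-values
#' @param kingdoms named character vector ("fungal"/"bacterial") covering all
#'   taxa in `r`
#' @param alpha_adj adjusted-significance cutoff
#' @param p optional matrix of raw p-values carried onto the edges
#' @return a [CorrelationNetwork]
#' @export
interkingdomEdges <- function(r, padj, kingdoms, alpha_adj = 0.05, p = NULL) {
    taxa <- rownames(r)
    if (is.null(taxa)) stop("correlation matrix must carry taxon names")
    if (!all(taxa %in% names(kingdoms)))
        stop("kingdom label missing for some taxa")
    kg <- kingdoms[taxa]
    if (!all(kg %in% c("fungal", "bacterial")))
        stop("kingdoms must be 'fungal' or 'bacterial'")
    if (is.null(p)) p <- padj
    idx <- which(upper.tri(r), arr.ind = TRUE)
    cross <- kg[idx[, 1]] != kg[idx[, 2]]
    sig <- padj[idx] < alpha_adj
    keep <- idx[cross & sig, , drop = FALSE]
    edges <- data.frame(taxon_a = taxa[keep[, 1]], taxon_b = taxa[keep[, 2]],
                        r = r[keep], p = p[keep], padj = padj[keep],
                        sign = ifelse(r[keep] < 0, -1L, 1L))
    deg <- table(factor(c(edges$taxon_a, edges$taxon_b), levels = taxa))
    nodes <- data.frame(taxon = taxa, kingdom = unname(kg),
                        degree = as.integer(deg))
    CorrelationNetwork(nodes, edges)
}

#' Key-driver taxa
#'
#' Taxa whose degree in the significant inter-kingdom network is at least
#' `min_degree`.
#'
#' @param net a [CorrelationNetwork]
#' @param min_degree degree cutoff (inclusive, default 10)
#' @return data.frame (taxon, kingdom, degree) sorted by decreasing degree
#' @export
keyDrivers <- function(net, min_degree = 10) {
    n <- networkNodes(net)
    out <- n[n$degree >= min_degree, , drop = FALSE]
    out[order(-out$degree, out$taxon), , drop = FALSE]
}

#' Conserved edges between two networks
#'
#' Intersects the unordered taxon pairs of two networks (e.g. the standing
#' DNA and active RNA bacterial communities against fungi); correlation and
#' sign are taken from the first network, and pairs whose signs disagree
#' between the networks are dropped with a message.
#'
#' @param net_a,net_b [CorrelationNetwork] objects (a = reference, e.g. DNA)
#' @return a [CorrelationNetwork] of the shared edges
#' @export
conservedEdges <- function(net_a, net_b) {
    ea <- networkEdges(net_a); eb <- networkEdges(net_b)
    keyOf <- function(e) {
        a <- pmin(e$taxon_a, e$taxon_b); b <- pmax(e$taxon_a, e$taxon_b)
        paste(a, b, sep = "||")
    }
    ka <- keyOf(ea); kb <- keyOf(eb)
    shared <- ka %in% kb
    ea2 <- ea[shared, , drop = FALSE]
    if (nrow(ea2)) {
        sb <- setNames(eb$sign, kb)[keyOf(ea2)]
        disc <- ea2$sign != sb
        if (any(disc))
            message(sum(disc), " shared edge(s) dropped for discordant sign")
        ea2 <- ea2[!disc, , drop = FALSE]
    }
    na <- networkNodes(net_a)
    deg <- table(factor(c(ea2$taxon_a, ea2$taxon_b), levels = na$taxon))
    nodes <- data.frame(taxon = na$taxon, kingdom = na$kingdom,
                        degree = as.integer(deg))
    CorrelationNetwork(nodes, ea2)
}
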