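## Synthetic four-founder AIL cohorts with known ground truth.
## All generators are deterministic given `seed`.

#' Simulate founder haplotypes and a marker map
#'
#' Draws four binary founder haplotypes and a marker map with genetic
#' positions uniform on \[0, `cM_per_chrom`\]. Physical positions are derived
#' from the genetic map at 2 Mb/cM (the reciprocal of the package's default
#' 0.5 cM/Mb conversion).
#'
#' @param n_chrom number of chromosomes (>= 1)
#' @param markers_per_chrom markers per chromosome (>= 1)
#' @param cM_per_chrom genetic length of each chromosome in cM
#' @param diversity probability that a monomorphic marker is forced to
#'   separate at least two founders (1 = every marker polymorphic)
#' @param seed RNG seed
#' @return a [FounderHaplotypes] object
#' @export
simulateFounders <- function(n_chrom, markers_per_chrom, cM_per_chrom,
                             diversity = 1, seed = 1) {
    stopifnot(n_chrom >= 1, markers_per_chrom >= 1, cM_per_chrom >= 0)
    set.seed(seed)
    maps <- vector("list", n_chrom)
    alle <- vector("list", n_chrom)
    for (ch in seq_len(n_chrom)) {
        cm <- sort(runif(markers_per_chrom, 0, cM_per_chrom))
        bp <- round(cm * 2e6)
        ## enforce strictly increasing bp even when cM ties after rounding
        bp <- bp + seq_along(bp)
        a <- matrix(rbinom(4L * markers_per_chrom, 1, 0.5), nrow = 4L)
        mono <- which(apply(a, 2, function(v) length(unique(v)) == 1L))
        force <- mono[runif(length(mono)) < diversity]
        for (m in force) a[sample.int(4L, 1L), m] <- 1 - a[1L, m]
        maps[[ch]] <- data.frame(
            marker = sprintf("chr%d_m%d", ch, seq_len(markers_per_chrom)),
            chrom = ch, bp = bp, cM = cm)
        alle[[ch]] <- a
    }
    FounderHaplotypes(do.call(cbind, alle), do.call(rbind, maps))
}

## One recombinant gamete from a parent's two haplotype-origin vectors.
## Haldane model: crossover count ~ Poisson(map length in Morgans),
## positions uniform in cM, no interference.
.gamete <- function(h1, h2, cm) {
    L <- max(cm) - min(cm)
    nco <- if (L > 0) rpois(1L, L / 100) else 0L
    start <- sample.int(2L, 1L)
    if (nco == 0L) return(if (start == 1L) h1 else h2)
    xo <- sort(runif(nco, min(cm), max(cm)))
    seg <- findInterval(cm, xo)           # 0..nco, parity picks the strand
    use1 <- (seg %% 2L == 0L) == (start == 1L)
    ifelse(use1, h1, h2)
}

#' Simulate an advanced intercross line
#'
#' Breeds a four-founder population forward by random mating for
#' `n_generations` generations with Haldane-model recombination, then types
#' the final generation at the founder markers. Observed genotypes are the
#' sum of founder alleles at the true origins, with optional per-allele
#' genotyping error and missingness.
#'
#' @param founders a [FounderHaplotypes] object
#' @param n_generations number of intercross generations (>= 2)
#' @param n_mice cohort size in the final generation
#' @param geno_error per-allele flip probability in \[0, 1)
#' @param missing_rate per-call masking probability in \[0, 1)
#' @param n_pairs breeding pairs per generation (default: at least 50,
#'   more if `n_mice` requires it)
#' @param seed RNG seed
#' @return list with `geno` (a [GenotypeMatrix]) and `truth`
#'   (a [TrueDiplotypes])
#' @export
simulateAIL <- function(founders, n_generations, n_mice,
                        geno_error = 0, missing_rate = 0,
                        n_pairs = NULL, seed = 1) {
    stopifnot(is(founders, "FounderHaplotypes"), n_generations >= 2,
              n_mice >= 1, geno_error >= 0, geno_error < 1,
              missing_rate >= 0, missing_rate < 1)
    set.seed(seed)
    map <- founders@map
    A <- founders@alleles
    M <- ncol(A)
    chroms <- unique(map$chrom)
    idxByChr <- lapply(chroms, function(ch) which(map$chrom == ch))
    cmByChr <- lapply(idxByChr, function(i) map$cM[i])

    npairs <- if (is.null(n_pairs)) max(50L, ceiling(n_mice / 2)) else n_pairs
    popsize <- 2L * npairs
    ## generation 1: balanced founder crosses (each haplotype an intact founder)
    h1 <- matrix(rep_len(rep(1:4, each = ceiling(popsize / 4)), popsize * M),
                 nrow = popsize)
    h2 <- matrix(rep_len(rep(c(2:4, 1), each = ceiling(popsize / 4)), popsize * M),
                 nrow = popsize)

    breed <- function(h1, h2, n_off) {
        n <- nrow(h1)
        dams <- sample.int(n, n %/% 2)
        sires <- setdiff(sample.int(n, n), dams)[seq_along(dams)]
        pick <- cbind(dams[sample.int(length(dams), n_off, replace = TRUE)],
                      sires[sample.int(length(sires), n_off, replace = TRUE)])
        o1 <- matrix(0L, n_off, M)
        o2 <- matrix(0L, n_off, M)
        for (i in seq_len(n_off)) {
            for (c_i in seq_along(idxByChr)) {
                j <- idxByChr[[c_i]]; cm <- cmByChr[[c_i]]
                o1[i, j] <- .gamete(h1[pick[i, 1], j], h2[pick[i, 1], j], cm)
                o2[i, j] <- .gamete(h1[pick[i, 2], j], h2[pick[i, 2], j], cm)
            }
        }
        list(h1 = o1, h2 = o2)
    }

    for (g in seq_len(n_generations - 1L)) {
        n_off <- if (g == n_generations - 1L) n_mice else popsize
        off <- breed(h1, h2, n_off)
        h1 <- off$h1; h2 <- off$h2
    }

    ## observed genotypes: allele sum at true origins, with per-allele error
    a1 <- matrix(A[cbind(as.vector(h1), rep(seq_len(M), each = n_mice))], n_mice)
    a2 <- matrix(A[cbind(as.vector(h2), rep(seq_len(M), each = n_mice))], n_mice)
    if (geno_error > 0) {
        f1 <- matrix(runif(n_mice * M) < geno_error, n_mice)
        f2 <- matrix(runif(n_mice * M) < geno_error, n_mice)
        a1 <- abs(a1 - f1); a2 <- abs(a2 - f2)
    }
    calls <- a1 + a2
    if (missing_rate > 0)
        calls[matrix(runif(n_mice * M) < missing_rate, n_mice)] <- NA
    rownames(calls) <- sprintf("mouse%d", seq_len(n_mice))
    colnames(calls) <- map$marker
    origin <- array(c(h1, h2), dim = c(n_mice, M, 2L),
                    dimnames = list(rownames(calls), map$marker, NULL))
    list(geno = GenotypeMatrix(calls, map),
         truth = TrueDiplotypes(origin, map))
}

#' Assign cohort covariates
#'
#' Randomizes mice to diets with the given fractions, assigns sex by a fair
#' coin (coded males = 1, females = 0), fills cages to capacity within diet,
#' and draws generation labels uniformly from `generations`.
#'
#' @param n_mice cohort size
#' @param diet_fractions length-3 nonnegative vector summing to 1
#'   (CAL, CON, WES)
#' @param cage_capacity mice per cage
#' @param generations set of generation labels (subset of 18:20)
#' @param seed RNG seed
#' @return covariate data.frame (sex, diet, generation, cage) passing
#'   [assertCovariates]
#' @export
assignCovariates <- function(n_mice, diet_fractions = c(250, 145, 196) / 591,
                             cage_capacity = 5, generations = 18:20, seed = 1) {
    stopifnot(n_mice >= 1, length(diet_fractions) == 3,
              abs(sum(diet_fractions) - 1) < 1e-8, cage_capacity >= 1)
    if (length(generations) == 0) stop("generation set must be nonempty")
    stopifnot(all(generations %in% 18:20))
    set.seed(seed)
    diet <- sample(0:2, n_mice, replace = TRUE, prob = diet_fractions)
    sex <- rbinom(n_mice, 1, 0.5)
    gen <- sample(rep_len(generations, max(n_mice, length(generations))), n_mice)
    cage <- integer(n_mice)
    nxt <- 1L
    for (d in 0:2) {
        i <- which(diet == d)
        if (!length(i)) next
        k <- ceiling(seq_along(i) / cage_capacity)
        cage[i] <- nxt + k - 1L
        nxt <- nxt + max(k)
    }
    data.frame(sex = sex, diet = diet, generation = gen,
               cage = sprintf("cage%03d", cage),
               row.names = sprintf("mouse%d", seq_len(n_mice)))
}

#' Specify a planted QTL effect
#'
#' @param taxon target taxon id (name or index into the simulated table)
#' @param marker marker id or index
#' @param beta per-founder additive effects (length 4, trait-SD units before
#'   rescaling)
#' @param mode `"none"`, `"diet"` or `"sex"` interaction
#' @param multipliers per-level interaction multipliers (length 3 for diet,
#'   2 for sex; ignored for `"none"`)
#' @param varfrac target fraction of log-count phenotypic variance in \[0, 1)
#' @return a `qtlEffect` list for [simulateTaxonCounts]
#' @export
qtlEffect <- function(taxon, marker, beta, mode = c("none", "diet", "sex"),
                      multipliers = NULL, varfrac = 0.1) {
    mode <- match.arg(mode)
    stopifnot(length(beta) == 4, varfrac >= 0, varfrac < 1)
    if (mode == "diet" && is.null(multipliers)) multipliers <- c(1, 1, 1)
    if (mode == "sex" && is.null(multipliers)) multipliers <- c(1, 1)
    if (!is.null(multipliers)) stopifnot(all(is.finite(multipliers)))
    structure(list(taxon = taxon, marker = marker, beta = beta, mode = mode,
                   multipliers = multipliers, varfrac = varfrac),
              class = "qtlEffect")
}

## true founder dosage (n x 4) of one marker from TrueDiplotypes
.trueDosage <- function(truth, m) {
    o <- truth@origin
    d <- sapply(1:4, function(f) (o[, m, 1] == f) + (o[, m, 2] == f))
    matrix(d, nrow = dim(o)[1])
}

#' Simulate overdispersed taxon counts with planted QTL effects
#'
#' Per-sample log-means are baseline + planted genetic effects (scaled so the
#' realized log-count variance fraction matches each effect's target) + cage
#' random intercepts + generation offsets + log library-size factors; counts
#' are negative binomial with a single dispersion per taxon. Effect scaling
#' uses a pilot simulation of the same taxon without the effect to measure
#' the non-genetic log1p-count variance.
#'
#' @param truth a [TrueDiplotypes] from [simulateAIL]
#' @param covariates covariate data.frame (see [assertCovariates])
#' @param effects list of [qtlEffect] specifications
#' @param n_taxa number of taxa
#' @param nb_dispersion negative-binomial dispersion alpha
#'   (variance = mu + alpha mu^2)
#' @param cage_sd SD of cage random intercepts on the log scale
#' @param libsize_range range of library sizes; sizes are log-uniform on it
#' @param gen_effect per-generation offsets on the log scale
#'   (named by 18:20 order)
#' @param base_log_mean mean of per-taxon baseline log counts
#' @param seed RNG seed
#' @return a fungal [TraitTable] with covariates in `colData`
#' @export
simulateTaxonCounts <- function(truth, covariates, effects = list(),
                                n_taxa = 20, nb_dispersion = 0.5,
                                cage_sd = 0.5, libsize_range = c(5000, 50000),
                                gen_effect = c(-0.05, 0, 0.05),
                                base_log_mean = log(100), seed = 1) {
    assertCovariates(covariates)
    n <- dim(truth@origin)[1]
    stopifnot(nrow(covariates) == n, nb_dispersion > 0, cage_sd >= 0)
    markers <- dimnames(truth@origin)[[2]]
    for (e in effects) {
        m <- if (is.character(e$marker)) match(e$marker, markers) else e$marker
        if (is.na(m) || m < 1 || m > dim(truth@origin)[2])
            stop("effect marker not found: ", e$marker)
        ti <- if (is.character(e$taxon)) e$taxon else paste0("taxon", e$taxon)
        NULL
    }
    vf <- vapply(effects, function(e) e$varfrac, 0)
    tx <- vapply(effects, function(e)
        if (is.character(e$taxon)) e$taxon else paste0("taxon", e$taxon), "")
    if (length(vf) && any(tapply(vf, tx, sum) >= 1))
        stop("variance fractions for one taxon must total < 1")

    set.seed(seed)
    b0 <- rnorm(n_taxa, base_log_mean, 0.7)
    cages <- unique(covariates$cage)
    cint <- matrix(rnorm(length(cages) * n_taxa, 0, cage_sd), length(cages),
                   dimnames = list(cages, NULL))
    lib <- exp(runif(n, log(libsize_range[1]), log(libsize_range[2])))
    loglib <- log(lib / exp(mean(log(lib))))
    genoff <- gen_effect[match(covariates$generation, 18:20)]

    eta0 <- outer(rep(1, n), b0) + cint[covariates$cage, , drop = FALSE] +
        genoff + loglib
    size <- 1 / nb_dispersion

    ## planted effects, scaled against pilot (effect-free) log1p-count variance
    eta <- eta0
    for (e in effects) {
        ti <- if (is.character(e$taxon)) match(e$taxon, paste0("taxon", seq_len(n_taxa)))
              else e$taxon
        m <- if (is.character(e$marker)) match(e$marker, markers) else e$marker
        g <- as.vector(.trueDosage(truth, m) %*% e$beta)
        if (e$mode == "diet") g <- g * e$multipliers[covariates$diet + 1]
        if (e$mode == "sex") g <- g * e$multipliers[covariates$sex + 1]
        if (e$varfrac > 0 && var(g) > 0) {
            pilot <- rnbinom(n, mu = exp(eta0[, ti]), size = size)
            v0 <- var(log1p(pilot))
            g <- g * sqrt((e$varfrac / (1 - e$varfrac)) * v0 / var(g))
        } else g <- g * 0
        eta[, ti] <- eta[, ti] + g
    }

    counts <- matrix(rnbinom(n * n_taxa, mu = exp(eta), size = size), n)
    counts <- t(counts)   # taxa x samples
    rownames(counts) <- paste0("taxon", seq_len(n_taxa))
    colnames(counts) <- rownames(covariates)
    lineage <- paste0("Fungi;Phylum_", rownames(counts))
    TraitTable(counts, lineage = lineage, community = "fungal",
               covariates = covariates)
}

#' Simulate paired compositions with known basis correlations
#'
#' Draws log-normal basis abundances with the given correlation structure,
#' splits taxa into a fungal and a bacterial block, and samples each sample
#' multinomially to a fixed sequencing depth (default 5000, the package's
#' rarefaction depth).
#'
#' @param basis_correlation symmetric positive-semidefinite correlation matrix
#' @param n_samples number of samples
#' @param depth reads per sample
#' @param n_fungal number of taxa in the fungal block (default: half)
#' @param log_sd SD of basis log-abundances
#' @param seed RNG seed
#' @return list with `fungal` and `bacterial` [TraitTable]s
#' @export
simulateCoupledCompositions <- function(basis_correlation, n_samples,
                                        depth = 5000, n_fungal = NULL,
                                        log_sd = 1, seed = 1) {
    R <- as.matrix(basis_correlation)
    m <- nrow(R)
    if (!isSymmetric(R, tol = 1e-8) || any(abs(diag(R) - 1) > 1e-8))
        stop("basis correlation must be symmetric with unit diagonal")
    ev <- eigen(R, symmetric = TRUE)
    if (min(ev$values) < -1e-8 * max(ev$values))
        stop("basis correlation must be positive semidefinite")
    if (is.null(n_fungal)) n_fungal <- floor(m / 2)
    stopifnot(n_fungal >= 1, n_fungal < m, n_samples >= 1, depth >= 1)
    set.seed(seed)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), m)
    z <- matrix(rnorm(n_samples * m), n_samples) %*% t(L)
    mu <- rnorm(m, 0, 1)
    w <- exp(sweep(z * log_sd, 2, mu, "+"))
    frac <- w / rowSums(w)
    counts <- apply(frac, 1, function(p) rmultinom(1, depth, p))  # m x n
    rownames(counts) <- c(paste0("fungus", seq_len(n_fungal)),
                          paste0("bacterium", seq_len(m - n_fungal)))
    colnames(counts) <- paste0("sample", seq_len(n_samples))
    fi <- seq_len(n_fungal)
    list(fungal = TraitTable(counts[fi, , drop = FALSE],
                             lineage = paste0("Fungi;", rownames(counts)[fi]),
                             community = "fungal"),
         bacterial = TraitTable(counts[-fi, , drop = FALSE],
                                lineage = paste0("Bacteria;", rownames(counts)[-fi]),
                                community = "bacterial-DNA"))
}
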