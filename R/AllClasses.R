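#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats anova aov as.dist coef cor dist kruskal.test lm lm.fit
#'   mad median na.omit optimize p.adjust pnorm quantile residuals rbinom
#'   rgamma rmultinom rnbinom rnorm rpois runif sd setNames var wilcox.test
#'   TukeyHSD rchisq predict model.matrix
#' @importFrom utils head read.table write.table combn
NULL

## ---------------------------------------------------------------------------
## FounderHaplotypes: phased binary alleles of the four inbred founder strains
## ---------------------------------------------------------------------------

#' Founder haplotypes for a four-way advanced intercross
#'
#' Holds one binary haplotype per founder strain together with the marker map.
#' Rows of `alleles` are founders, columns are markers. The map carries the
#' chromosome, physical position (bp) and genetic position (cM) of every
#' marker; bp must be strictly increasing and cM non-decreasing within a
#' chromosome.
#'
#' @slot alleles 4 x M binary matrix (values 0/1), rownames are founder names.
#' @slot map data.frame with columns `marker`, `chrom`, `bp`, `cM`.
#' @export
setClass("FounderHaplotypes",
         representation(alleles = "matrix", map = "data.frame"))

setValidity("FounderHaplotypes", function(object) {
    a <- object@alleles; m <- object@map
    if (nrow(a) != 4L) return("exactly four founder haplotypes required")
    if (!all(a %in% c(0, 1))) return("allele values must be 0 or 1")
    if (ncol(a) != nrow(m)) return("map rows must match allele columns")
    if (!all(c("marker", "chrom", "bp", "cM") %in% names(m)))
        return("map must have columns marker, chrom, bp, cM")
    for (ch in unique(m$chrom)) {
        i <- m$chrom == ch
        if (any(diff(m$bp[i]) <= 0)) return("bp must be strictly increasing within a chromosome")
        if (any(diff(m$cM[i]) < 0)) return("cM must be non-decreasing within a chromosome")
    }
    TRUE
})

#' @describeIn FounderHaplotypes constructor
#' @param alleles,map see slots
#' @export
FounderHaplotypes <- function(alleles, map) {
    if (is.null(rownames(alleles)))
        rownames(alleles) <- c("MRL", "NZM", "BXD2", "CAST")
    new("FounderHaplotypes", alleles = alleles, map = as.data.frame(map))
}

#' Founder allele matrix
#' @param x a FounderHaplotypes object
#' @export
founderAlleles <- function(x) x@alleles

#' Marker map accessor
#' @param x an object with a marker map (FounderHaplotypes, GenotypeMatrix,
#'   TrueDiplotypes or FounderPosteriors)
#' @export
markerMap <- function(x) x@map

setMethod("show", "FounderHaplotypes", function(object) {
    cat(sprintf("FounderHaplotypes: %d founders x %d markers on %d chromosome(s)\n",
                nrow(object@alleles), ncol(object@alleles),
                length(unique(object@map$chrom))))
})

## ---------------------------------------------------------------------------
## GenotypeMatrix: observed biallelic calls for a cohort
## ---------------------------------------------------------------------------

#' Observed genotype calls
#'
#' Biallelic genotypes coded as minor-allele dosage 0/1/2 with `NA` for
#' missing, one row per individual, one column per marker, markers sorted by
#' (chromosome, bp).
#'
#' @slot calls individuals x markers numeric matrix with values 0/1/2/NA.
#' @slot map marker map as in [FounderHaplotypes].
#' @export
setClass("GenotypeMatrix",
         representation(calls = "matrix", map = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
    ok <- object@calls %in% c(0, 1, 2) | is.na(object@calls)
    if (!all(ok)) return("genotype codes must be 0, 1, 2 or NA")
    if (ncol(object@calls) != nrow(object@map)) return("map rows must match call columns")
    o <- order(match(object@map$chrom, unique(object@map$chrom)), object@map$bp)
    if (is.unsorted(o)) return("markers must be sorted by (chromosome, bp)")
    TRUE
})

#' @describeIn GenotypeMatrix constructor
#' @param calls,map see slots
#' @export
GenotypeMatrix <- function(calls, map) {
    new("GenotypeMatrix", calls = calls, map = as.data.frame(map))
}

#' Genotype call matrix
#' @param x a GenotypeMatrix
#' @export
genotypeCalls <- function(x) x@calls

setMethod("show", "GenotypeMatrix", function(object) {
    cat(sprintf("GenotypeMatrix: %d individuals x %d markers (%.1f%% missing)\n",
                nrow(object@calls), ncol(object@calls),
                100 * mean(is.na(object@calls))))
})

## ---------------------------------------------------------------------------
## TrueDiplotypes: simulation ground truth of founder origin
## ---------------------------------------------------------------------------

#' True founder origins of simulated AIL chromosomes
#'
#' Ground truth used to validate haplotype reconstruction: for every mouse and
#' marker the founder index (1-4) of the maternally and paternally inherited
#' chromosome copy.
#'
#' @slot origin individuals x markers x 2 integer array of founder indices.
#' @slot map marker map as in [FounderHaplotypes].
#' @export
setClass("TrueDiplotypes",
         representation(origin = "array", map = "data.frame"))

setValidity("TrueDiplotypes", function(object) {
    if (length(dim(object@origin)) != 3L || dim(object@origin)[3] != 2L)
        return("origin must be individuals x markers x 2")
    if (!all(object@origin %in% 1:4)) return("founder indices must be in 1..4")
    TRUE
})

#' @describeIn TrueDiplotypes constructor
#' @param origin,map see slots
#' @export
TrueDiplotypes <- function(origin, map) {
    new("TrueDiplotypes", origin = origin, map = as.data.frame(map))
}

#' True founder-origin array
#' @param x a TrueDiplotypes object
#' @export
trueOrigin <- function(x) x@origin

setMethod("show", "TrueDiplotypes", function(object) {
    d <- dim(object@origin)
    cat(sprintf("TrueDiplotypes: %d individuals x %d markers\n", d[1], d[2]))
})

## ---------------------------------------------------------------------------
## FounderPosteriors: HMM state probabilities and founder dosages
## ---------------------------------------------------------------------------

#' Posterior founder-origin probabilities
#'
#' Output of the haplotype-reconstruction HMM. The state space is the 10
#' unordered founder pairs of a four-way cross; `dosage` is the expected
#' per-founder allele count (rows sum to 2) used as the additive genotype
#' predictor in QTL scans.
#'
#' @slot probs individuals x markers x 10 array; each (i, m) slice sums to 1.
#' @slot dosage individuals x markers x 4 array; each (i, m) slice sums to 2.
#' @slot states 10 x 2 integer matrix giving the founder pair of each state.
#' @slot map marker map as in [FounderHaplotypes].
#' @export
setClass("FounderPosteriors",
         representation(probs = "array", dosage = "array",
                        states = "matrix", map = "data.frame"))

setValidity("FounderPosteriors", function(object) {
    d <- dim(object@probs)
    if (length(d) != 3L || d[3] != 10L) return("probs must be n x M x 10")
    if (!all(dim(object@dosage) == c(d[1], d[2], 4L)))
        return("dosage must be n x M x 4")
    ps <- apply(object@probs, c(1, 2), sum)
    if (any(abs(ps - 1) > 1e-9)) return("state probabilities must sum to 1")
    ds <- apply(object@dosage, c(1, 2), sum)
    if (any(abs(ds - 2) > 1e-9) || any(object@dosage < -1e-12))
        return("dosages must be nonnegative and sum to 2")
    TRUE
})

#' @describeIn FounderPosteriors constructor
#' @param probs,dosage,states,map see slots
#' @export
FounderPosteriors <- function(probs, dosage, states, map) {
    new("FounderPosteriors", probs = probs, dosage = dosage,
        states = states, map = as.data.frame(map))
}

#' Posterior state probabilities
#' @param x a FounderPosteriors object
#' @export
posteriorProbs <- function(x) x@probs

#' Expected founder-allele dosages
#' @param x a FounderPosteriors object
#' @export
founderDosage <- function(x) x@dosage

#' Unordered founder-pair state definitions
#' @param x a FounderPosteriors object
#' @export
diplotypeStates <- function(x) x@states

setMethod("show", "FounderPosteriors", function(object) {
    d <- dim(object@probs)
    cat(sprintf("FounderPosteriors: %d individuals x %d markers, 10 diplotype states\n",
                d[1], d[2]))
})

## ---------------------------------------------------------------------------
## TraitTable: taxon count table (the phenotype source)
## ---------------------------------------------------------------------------

#' Taxon count table
#'
#' A [SummarizedExperiment::SummarizedExperiment] with taxa as rows and
#' samples as columns, a `"counts"` assay of nonnegative integers, a
#' `lineage` column in `rowData` (semicolon-delimited taxonomy string) and a
#' community label (fungal, bacterial-DNA or bacterial-RNA).
#'
#' @slot community community label.
#' @export
setClass("TraitTable",
         contains = "SummarizedExperiment",
         representation(community = "character"))

setValidity("TraitTable", function(object) {
    k <- SummarizedExperiment::assay(object, "counts")
    if (any(k < 0) || any(abs(k - round(k)) > 1e-8))
        return("counts must be nonnegative integers")
    if (is.null(rownames(object)) || anyDuplicated(colnames(object)))
        return("taxon rownames required; sample names must be unique")
    if (!"lineage" %in% names(SummarizedExperiment::rowData(object)))
        return("rowData must contain a lineage column")
    if (!object@community %in% c("fungal", "bacterial-DNA", "bacterial-RNA"))
        return("community must be fungal, bacterial-DNA or bacterial-RNA")
    TRUE
})

#' @describeIn TraitTable constructor
#' @param counts taxa x samples integer matrix with dimnames
#' @param lineage character vector of taxonomy strings (defaults to rownames)
#' @param community community label
#' @param covariates optional per-sample covariate data.frame (see
#'   [assertCovariates])
#' @export
TraitTable <- function(counts, lineage = NULL,
                       community = c("fungal", "bacterial-DNA", "bacterial-RNA"),
                       covariates = NULL) {
    community <- match.arg(community)
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("taxon", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
    if (is.null(lineage)) lineage <- rownames(counts)
    cd <- if (is.null(covariates)) S4Vectors::DataFrame(row.names = colnames(counts))
          else S4Vectors::DataFrame(covariates, row.names = colnames(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(lineage = lineage),
        colData = cd)
    new("TraitTable", se, community = community)
}

#' Count matrix of a TraitTable (taxa x samples)
#' @param x a TraitTable
#' @export
traitCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' Taxonomy lineage strings
#' @param x a TraitTable
#' @export
taxonLineage <- function(x) {
    setNames(as.character(SummarizedExperiment::rowData(x)$lineage), rownames(x))
}

#' Community label (fungal / bacterial-DNA / bacterial-RNA)
#' @param x a TraitTable
#' @export
communityLabel <- function(x) x@community

#' Per-sample covariates stored in a TraitTable
#' @param x a TraitTable
#' @export
sampleCovariates <- function(x) as.data.frame(SummarizedExperiment::colData(x))

setMethod("show", "TraitTable", function(object) {
    cat(sprintf("TraitTable (%s): %d taxa x %d samples, median depth %d\n",
                object@community, nrow(object), ncol(object),
                as.integer(median(colSums(traitCounts(object))))))
})

## ---------------------------------------------------------------------------
## CorrelationNetwork: significant inter-kingdom edges
## ---------------------------------------------------------------------------

#' Inter-kingdom correlation network
#'
#' Significant fungal-bacterial correlation edges with their SparCC-style
#' correlation, bootstrap p-value, BH-adjusted p-value and sign, plus per-node
#' degree on the retained edge set.
#'
#' @slot nodes data.frame with columns `taxon`, `kingdom`, `degree`.
#' @slot edges data.frame with columns `taxon_a`, `taxon_b`, `r`, `p`,
#'   `padj`, `sign`.
#' @export
setClass("CorrelationNetwork",
         representation(nodes = "data.frame", edges = "data.frame"))

setValidity("CorrelationNetwork", function(object) {
    e <- object@edges
    need <- c("taxon_a", "taxon_b", "r", "p", "padj", "sign")
    if (!all(need %in% names(e))) return("edges missing required columns")
    if (nrow(e) && (any(abs(e$r) > 1 + 1e-12) || any(e$p <= 0 | e$p > 1)))
        return("edge r must lie in [-1,1] and p in (0,1]")
    deg <- table(c(e$taxon_a, e$taxon_b))
    d0 <- setNames(object@nodes$degree, object@nodes$taxon)
    d1 <- setNames(rep(0L, nrow(object@nodes)), object@nodes$taxon)
    d1[names(deg)] <- as.integer(deg)
    if (!identical(as.integer(d0[order(names(d0))]), as.integer(d1[order(names(d1))])))
        return("node degrees must equal incident edge counts")
    TRUE
})

#' @describeIn CorrelationNetwork constructor
#' @param nodes,edges see slots
#' @export
CorrelationNetwork <- function(nodes, edges) {
    new("CorrelationNetwork", nodes = as.data.frame(nodes),
        edges = as.data.frame(edges))
}

#' Edge table of a CorrelationNetwork
#' @param x a CorrelationNetwork
#' @export
networkEdges <- function(x) x@edges

#' Node table of a CorrelationNetwork
#' @param x a CorrelationNetwork
#' @export
networkNodes <- function(x) x@nodes

setMethod("show", "CorrelationNetwork", function(object) {
    e <- object@edges
    cat(sprintf("CorrelationNetwork: %d nodes, %d edges (%.1f%% negative)\n",
                nrow(object@nodes), nrow(e),
                if (nrow(e)) 100 * mean(e$sign < 0) else 0))
})

## ---------------------------------------------------------------------------
## Covariate table validation (plain data.frame; codings fixed by convention)
## ---------------------------------------------------------------------------

#' Validate a covariate table
#'
#' Covariates follow the study's codings: `sex` with males = 1 and
#' females = 0; `diet` with CAL = 0, CON = 1, WES = 2; `generation` in
#' \{18, 19, 20\}; `cage` an arbitrary cage identifier (every sample must
#' have one).
#'
#' @param cov data.frame with columns sex, diet, generation, cage
#' @return the validated data.frame, invisibly usable downstream
#' @export
assertCovariates <- function(cov) {
    stopifnot(is.data.frame(cov))
    need <- c("sex", "diet", "generation", "cage")
    if (!all(need %in% names(cov)))
        stop("covariate table must have columns: ", paste(need, collapse = ", "))
    if (!all(cov$sex %in% c(0, 1))) stop("sex must be coded 0 (female) / 1 (male)")
    if (!all(cov$diet %in% c(0, 1, 2))) stop("diet must be coded 0 (CAL) / 1 (CON) / 2 (WES)")
    if (!all(cov$generation %in% c(18, 19, 20))) stop("generation must be 18, 19 or 20")
    if (any(is.na(cov$cage))) stop("every sample must have a cage")
    invisible(cov)
}
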