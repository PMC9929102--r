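## PLINK-text (.ped/.map) and TSV interchange.

#' Write genotypes as PLINK text
#'
#' Writes a tab-delimited .ped/.map pair. Alleles are coded 1/2 (2 = the
#' counted allele), missing calls as "0 0"; the .map carries chromosome,
#' marker id, cM and bp.
#'
#' @param geno a [GenotypeMatrix]
#' @param prefix output path prefix (writes `<prefix>.ped` and
#'   `<prefix>.map`)
#' @param covariates optional covariate data.frame; sex is carried into the
#'   .ped sex column (PLINK coding 1 = male, 2 = female)
#' @export
writePlinkText <- function(geno, prefix, covariates = NULL) {
    calls <- geno@calls
    n <- nrow(calls)
    sex <- if (!is.null(covariates)) ifelse(covariates$sex == 1, 1L, 2L)
           else rep(0L, n)
    a1 <- matrix("1", n, ncol(calls)); a2 <- matrix("1", n, ncol(calls))
    a1[calls >= 1] <- "2"
    a2[calls == 2] <- "2"
    a1[is.na(calls)] <- "0"; a2[is.na(calls)] <- "0"
    alle <- matrix("", n, 2 * ncol(calls))
    alle[, seq(1, 2 * ncol(calls), 2)] <- a1
    alle[, seq(2, 2 * ncol(calls), 2)] <- a2
    ids <- rownames(calls)
    if (is.null(ids)) ids <- paste0("ind", seq_len(n))
    ped <- cbind("FAM", ids, "0", "0", sex, "-9", alle)
    write.table(ped, paste0(prefix, ".ped"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    m <- geno@map
    cm <- if (is.null(m$cM)) rep(0, nrow(m)) else m$cM
    write.table(data.frame(m$chrom, m$marker, cm, m$bp),
                paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(prefix)
}

#' Read PLINK-text genotypes
#'
#' Reads a tab- or whitespace-delimited .ped/.map pair written by
#' [writePlinkText] or another tool using the 1/2 allele coding; "0" marks a
#' missing allele.
#'
#' @param prefix path prefix of the `.ped`/`.map` pair
#' @return a [GenotypeMatrix]
#' @export
readPlinkText <- function(prefix) {
    map <- read.table(paste0(prefix, ".map"), header = FALSE,
                      col.names = c("chrom", "marker", "cM", "bp"))
    ped <- read.table(paste0(prefix, ".ped"), header = FALSE,
                      colClasses = "character")
    M <- nrow(map)
    if (ncol(ped) != 6 + 2 * M) stop(".ped column count does not match .map")
    al <- as.matrix(ped[, -(1:6)])
    a1 <- al[, seq(1, 2 * M, 2), drop = FALSE]
    a2 <- al[, seq(2, 2 * M, 2), drop = FALSE]
    calls <- (a1 == "2") + (a2 == "2")
    calls[a1 == "0" | a2 == "0"] <- NA
    calls <- matrix(as.numeric(calls), nrow(ped), M,
                    dimnames = list(ped[, 2], map$marker))
    GenotypeMatrix(calls, data.frame(marker = map$marker, chrom = map$chrom,
                                     bp = map$bp, cM = map$cM))
}

#' Write a TraitTable as TSV
#'
#' Writes the count matrix (taxa x samples, with a `taxon` id column) and a
#' two-column taxonomy file mapping taxon id to its semicolon-delimited
#' lineage.
#'
#' @param t a [TraitTable]
#' @param counts_file,taxonomy_file output paths
#' @export
writeTraitTable <- function(t, counts_file, taxonomy_file = NULL) {
    k <- traitCounts(t)
    write.table(data.frame(taxon = rownames(k), k, check.names = FALSE),
                counts_file, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(taxonomy_file))
        write.table(data.frame(taxon = rownames(k), lineage = taxonLineage(t)),
                    taxonomy_file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(counts_file)
}

#' Read a TraitTable from TSV
#'
#' @param counts_file TSV with a `taxon` column and one column per sample
#' @param taxonomy_file optional TSV with columns `taxon`, `lineage`
#' @param community community label
#' @return a [TraitTable]
#' @export
readTraitTable <- function(counts_file, taxonomy_file = NULL,
                           community = "fungal") {
    d <- read.table(counts_file, header = TRUE, sep = "\t",
                    check.names = FALSE)
    k <- as.matrix(d[, -1, drop = FALSE])
    rownames(k) <- d$taxon
    lineage <- NULL
    if (!is.null(taxonomy_file)) {
        tx <- read.table(taxonomy_file, header = TRUE, sep = "\t")
        lineage <- tx$lineage[match(d$taxon, tx$taxon)]
    }
    TraitTable(k, lineage = lineage, community = community)
}
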