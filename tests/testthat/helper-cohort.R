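# Shared simulated cohorts, built once per test run.
.fixtures <- new.env()

# small cohort for fast unit tests: 2 chromosomes x 60 markers, 120 mice
smallCohort <- function() {
  if (!is.null(.fixtures$small)) return(.fixtures$small)
  fh <- simulateFounders(n_chrom = 2, markers_per_chrom = 60,
                         cM_per_chrom = 40, seed = 21)
  sim <- simulateAIL(fh, n_generations = 20, n_mice = 120, seed = 22)
  cov <- assignCovariates(120, seed = 23)
  fg <- GenotypeMatrix(2 * founderAlleles(fh), markerMap(fh))
  post <- reconstructFounderPosteriors(sim$geno, fg, n_generations = 20,
                                       geno_error = 0.002)
  K <- kinshipFromPosteriors(post)
  .fixtures$small <- list(fh = fh, geno = sim$geno, truth = sim$truth,
                          founders = fg, cov = cov, post = post, K = K,
                          eig = kinshipEigen(K))
  .fixtures$small
}

# study-scale cohort for the acceptance checks: 5 x 100 markers, 400 mice
accCohort <- function() {
  if (!is.null(.fixtures$acc)) return(.fixtures$acc)
  fh <- simulateFounders(n_chrom = 5, markers_per_chrom = 100,
                         cM_per_chrom = 40, seed = 11)
  sim <- simulateAIL(fh, n_generations = 20, n_mice = 400, seed = 12)
  cov <- assignCovariates(400, seed = 13)
  fg <- GenotypeMatrix(2 * founderAlleles(fh), markerMap(fh))
  post <- reconstructFounderPosteriors(sim$geno, fg, n_generations = 20,
                                       geno_error = 0.002)
  K <- kinshipFromPosteriors(post)
  .fixtures$acc <- list(fh = fh, geno = sim$geno, truth = sim$truth,
                        founders = fg, cov = cov, post = post, K = K,
                        eig = kinshipEigen(K))
  .fixtures$acc
}

# unordered founder-pair code (10*a+b with a<=b) for accuracy checks
unorderedTruth <- function(truth) {
  o <- trueOrigin(truth)
  pmin(o[, , 1], o[, , 2]) * 10 + pmax(o[, , 1], o[, , 2])
}

argmaxState <- function(post) {
  st <- diplotypeStates(post)
  am <- apply(posteriorProbs(post), c(1, 2), which.max)
  matrix(st[as.vector(am), 1] * 10 + st[as.vector(am), 2], nrow(am))
}

# independent OLS LOD computation used as oracle against the scan code
olsLod <- function(y, post, cov) {
  X0 <- cbind(1, cov$sex, as.numeric(cov$diet == 1), as.numeric(cov$diet == 2))
  D <- founderDosage(post)
  n <- length(y)
  vapply(seq_len(dim(D)[2]), function(m) {
    rs0 <- sum(lm.fit(X0, y)$residuals^2)
    rs1 <- sum(lm.fit(cbind(X0, D[, m, 1:3]), y)$residuals^2)
    (n / 2) * log10(rs0 / rs1)
  }, 0)
}
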