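test_that("additive scan equals the OLS oracle on a hand-sized instance", {
  set.seed(11)
  n <- 12
  map <- data.frame(marker = c("m1", "m2"), chrom = 1, bp = c(1e6, 2e6),
                    cM = c(1, 2))
  probs <- array(rgamma(n * 2 * 10, 1), c(n, 2, 10))
  probs <- sweep(probs, c(1, 2), apply(probs, c(1, 2), sum), "/")
  st <- cbind(c(1, 1, 1, 1, 2, 2, 2, 3, 3, 4), c(1, 2, 3, 4, 2, 3, 4, 3, 4, 4))
  cnt <- sapply(1:4, function(f) (st[, 1] == f) + (st[, 2] == f))
  dos <- array(0, c(n, 2, 4))
  for (f in 1:4) for (u in 1:10) dos[, , f] <- dos[, , f] + probs[, , u] * cnt[u, f]
  G <- FounderPosteriors(probs, dos, st, map)
  cov <- data.frame(sex = rep(0:1, 6), diet = rep(0:2, each = 4),
                    generation = rep(18:20, 4), cage = rep(c("a", "b"), each = 6))
  y <- rnorm(n)
  cur <- scanAdditive(y, G, cov, K = diag(n))
  expect_equal(cur$lod, olsLod(y, G, cov), tolerance = 1e-6)
})

test_that("identity-kinship scans equal OLS and interaction LOD is nonnegative", {
  co <- smallCohort()
  n <- nrow(co$cov)
  set.seed(12)
  for (rep in 1:5) {
    y <- rnorm(n)
    cur <- scanAdditive(y, co$post, co$cov, K = diag(n))
    expect_lt(max(abs(cur$lod - olsLod(y, co$post, co$cov))), 1e-6)
    ci <- scanInteraction(y, co$post, co$cov, eig = co$eig, term = "diet")
    expect_true(all(ci$lod >= 0))
    cs <- scanInteraction(y, co$post, co$cov, eig = co$eig, term = "sex")
    expect_true(all(cs$lod >= 0))
  }
  # a diet level missing from the data is an explicit error
  cov2 <- co$cov; cov2$diet[cov2$diet == 2] <- 1
  expect_error(scanInteraction(rnorm(n), co$post, cov2, term = "diet"),
               "diet level")
})

test_that("permutation thresholds: boundary quantile and determinism", {
  co <- smallCohort()
  set.seed(13)
  y <- rnorm(nrow(co$cov))
  cfg <- scanConfig(n_perm = 50, alpha_gw = 1, seed = 5)
  thr <- suppressWarnings(permutationThreshold(y, co$post, co$cov,
                                               model = "Add", cfg = cfg,
                                               eig = co$eig))
  expect_equal(as.numeric(thr), min(attr(thr, "maxima")))

  cfg2 <- scanConfig(n_perm = 60, alpha_gw = 0.05, seed = 9)
  t1 <- permutationThreshold(y, co$post, co$cov, model = "Add", cfg = cfg2,
                             eig = co$eig)
  t2 <- permutationThreshold(y, co$post, co$cov, model = "Add", cfg = cfg2,
                             eig = co$eig)
  expect_identical(as.numeric(t1), as.numeric(t2))
  expect_warning(permutationThreshold(y, co$post, co$cov, model = "Add",
                                      cfg = scanConfig(10, seed = 2),
                                      eig = co$eig),
                 "permutations")
})

test_that("variance explained: closed form, published values, monotonicity", {
  expect_equal(varianceExplained(0, 417), 0)
  expect_equal(100 * varianceExplained(10.35, 417), 10.8, tolerance = 2e-3)
  expect_equal(100 * varianceExplained(13.46, 417), 13.81, tolerance = 2e-3)
  lods <- seq(0, 40, by = 0.5)
  h2s <- varianceExplained(lods, 400)
  expect_true(all(diff(h2s) > 0))
  expect_true(all(varianceExplained(10, c(100, 200, 400)) ==
                  sort(varianceExplained(10, c(100, 200, 400)), decreasing = TRUE)))
  expect_equal(varianceExplained(1e6, 100), 1)
  # inversion recovers n
  expect_equal(inferEffectiveN(10.35, varianceExplained(10.35, 417)), 417,
               tolerance = 1e-9)
})

test_that("support intervals: width arithmetic, degenerate peaks, edges", {
  curve <- data.frame(marker = paste0("m", 1:7), chrom = 1,
                      bp = c(1e6, 2e6, 3e6, 4e6, 5e6, 6e6, 7e6),
                      lod = c(0.1, 0.4, 2.0, 6.0, 1.9, 0.5, 0.2))
  si <- supportInterval(curve, scanConfig(lod_drop = 1.5))
  expect_equal(si$start, 4e6)                 # only the peak stays within 1.5
  expect_equal(si$end, 4e6)
  expect_equal(si$width_mb, 0)

  curve$lod <- c(0.1, 5.0, 5.5, 6.0, 5.0, 4.6, 0.2)
  si2 <- supportInterval(curve, scanConfig(lod_drop = 1.5))
  expect_identical(si2$width_mb, (si2$end - si2$start) / 1e6)
  expect_equal(si2$start, 2e6); expect_equal(si2$end, 6e6)
  expect_false(si2$edge)

  curve$lod <- c(6.0, 5.9, 5.0, 4.8, 1.0, 0.5, 0.2)
  si3 <- supportInterval(curve, scanConfig(lod_drop = 1.5))
  expect_true(si3$edge)

  expect_error(supportInterval(curve, threshold = 100), "significant")
})

test_that("variance decomposition: dominance, conservation, recovery", {
  set.seed(15)
  n <- 600
  cages <- rep(sprintf("c%02d", 1:60), each = 10)
  cov <- data.frame(sex = rbinom(n, 1, 0.5), diet = sample(0:2, n, TRUE),
                    generation = sample(18:20, n, TRUE), cage = cages)
  # pure cage effects dominate
  ci <- rnorm(60, sd = 3)
  y_dom <- ci[as.integer(factor(cages))] + rnorm(n, sd = 0.1)
  pv <- partitionVariance(y_dom, cov)
  expect_gt(pv[["cage"]], 0.9)
  expect_lte(sum(pv), 1 + 1e-6)

  # planted fractions cage .3, sex .1, diet .05 recovered within .05
  vc <- 0.3; vs <- 0.1; vd <- 0.05
  y <- sqrt(vc) * scale(ci[as.integer(factor(cages))])[, 1] +
       sqrt(vs) * scale(cov$sex)[, 1] +
       sqrt(vd) * scale(cov$diet)[, 1] +
       sqrt(1 - vc - vs - vd) * rnorm(n)
  pv2 <- partitionVariance(y, cov)
  expect_lt(abs(pv2[["cage"]] - vc), 0.05)
  expect_lt(abs(pv2[["sex"]] - vs), 0.05)
  expect_lt(abs(pv2[["diet"]] - vd), 0.05)
  expect_lte(sum(pv2), 1 + 1e-6)
})

test_that("Spearman covariate correlations: signs, nulls, degenerate traits", {
  set.seed(16)
  cov <- assignCovariates(400, seed = 17)
  rho <- spearmanCovariateRho(as.numeric(cov$diet), cov)
  expect_equal(rho[["rho_diet"]], 1)
  rho2 <- spearmanCovariateRho(-as.numeric(cov$diet) + rnorm(400, sd = 1e-6), cov)
  expect_lt(rho2[["rho_diet"]], 0)

  hits <- mean(vapply(1:100, function(i) {
    r <- spearmanCovariateRho(rnorm(400), cov)
    all(abs(r) < 0.15)
  }, TRUE))
  expect_gte(hits, 0.95)

  expect_warning(rr <- spearmanCovariateRho(rep(1, 400), cov), "constant")
  expect_true(all(is.na(rr)))
})

test_that("founder deconvolution: certain labels, tie-break, diet-specific effects", {
  co <- smallCohort()
  # certain posteriors reproduce the true diplotype labels
  o <- trueOrigin(co$truth)
  st <- diplotypeStates(co$post)
  m <- 30
  tru <- pmin(o[, m, 1], o[, m, 2]) * 10 + pmax(o[, m, 1], o[, m, 2])
  n <- length(tru)
  pr <- array(0, c(n, 1, 10))
  for (i in seq_len(n)) pr[i, 1, which(st[, 1] * 10 + st[, 2] == tru[i])] <- 1
  dos <- array(0, c(n, 1, 4))
  cnt <- sapply(1:4, function(f) (st[, 1] == f) + (st[, 2] == f))
  for (f in 1:4) for (u in 1:10) dos[, , f] <- dos[, , f] + pr[, , u] * cnt[u, f]
  fp <- FounderPosteriors(pr, dos, st, markerMap(co$post)[m, , drop = FALSE])
  dec <- deconvolveFounders(fp, 1, rnorm(n), co$cov)
  for (d in sort(unique(co$cov$diet))) {
    i <- which(co$cov$diet == d)
    expect_identical(as.character(dec[[paste0("diet", d)]]$labels),
                     paste(tru[i] %/% 10, tru[i] %% 10, sep = "/"))
  }

  # exact ties resolve to the lowest state index
  prt <- array(0.1, c(4, 1, 10))
  fpt <- FounderPosteriors(prt, array(0.5, c(4, 1, 4)), st,
                           markerMap(co$post)[1, , drop = FALSE])
  cvt <- data.frame(sex = c(0, 1, 0, 1), diet = c(0, 0, 1, 2),
                    generation = 18, cage = "c1")
  dect <- deconvolveFounders(fpt, 1, rnorm(4), cvt)
  expect_true(all(unlist(lapply(dect, function(d) as.character(d$labels))) == "1/1"))

  # an effect on MRL carriers only under CAL is detected there, not under WES
  eig <- co$eig
  hits0 <- hits2 <- 0
  for (s in 1:8) {
    tt <- simulateTaxonCounts(co$truth, co$cov,
        effects = list(qtlEffect(1, m, c(1.5, 0, 0, 0), mode = "diet",
                                 multipliers = c(1, 0, 0), varfrac = 0.15)),
        n_taxa = 25, seed = 700 + s)
    r <- residualizeTrait(vstCounts(tt)[, 1], co$cov)
    dec2 <- deconvolveFounders(co$post, m, r, co$cov)
    p0 <- dec2$diet0$kw_p; p2 <- dec2$diet2$kw_p
    if (!is.na(p0) && p0 < 0.05) hits0 <- hits0 + 1
    if (!is.na(p2) && p2 < 0.05) hits2 <- hits2 + 1
  }
  expect_gte(hits0, 6)
  expect_lte(hits2, 3)
})

test_that("QTL result rows keep the width identity and printed-table fields", {
  co <- smallCohort()
  set.seed(18)
  tt <- simulateTaxonCounts(co$truth, co$cov,
      effects = list(qtlEffect(2, 25, c(1, -1, 0, 0), varfrac = 0.2)),
      n_taxa = 25, seed = 19)
  v <- vstCounts(tt)
  r <- residualizeTrait(v[, 2], co$cov)
  cur <- scanAdditive(r, co$post, co$cov, eig = co$eig)
  thr <- permutationThreshold(r, co$post, co$cov, model = "Add",
                              cfg = scanConfig(100, seed = 20), eig = co$eig)
  row <- qtlResult("taxon2", cur, thr, v[, 2], co$cov)
  expect_identical(row$width_mb, (row$end_bp - row$start_bp) / 1e6)
  expect_true(row$h2 >= 0 && row$h2 < 1)
  expect_true(all(c(row$var_cage, row$var_sex, row$var_generation,
                    row$var_diet) >= 0))
  expect_equal(row$n, nrow(co$cov))
})
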