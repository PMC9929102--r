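test_that("alpha diversity matches closed forms and a direct-summation oracle", {
  # uniform sample over S taxa, no singletons: Shannon = ln S, Chao1 = S
  S <- 12
  k <- matrix(10, S, 1, dimnames = list(paste0("t", 1:S), "u"))
  d <- alphaDiversity(TraitTable(k))
  expect_equal(d$shannon, log(S))
  expect_equal(d$chao1, S)
  expect_equal(d$simpson, 1 - 1 / S)

  # single-taxon sample
  k1 <- matrix(c(50, 0, 0), 3, 1, dimnames = list(paste0("t", 1:3), "s"))
  d1 <- alphaDiversity(TraitTable(k1))
  expect_equal(d1$shannon, 0)
  expect_equal(d1$simpson, 0)

  # random sample vs naive implementation
  set.seed(21)
  x <- rpois(20, 4)
  x[1:3] <- 1; x[4:5] <- 2
  k2 <- matrix(x, 20, 1, dimnames = list(paste0("t", 1:20), "s"))
  d2 <- alphaDiversity(TraitTable(k2))
  p <- x[x > 0] / sum(x)
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  expect_equal(d2$shannon, -sum(p * log(p)), tolerance = 1e-10)
  expect_equal(d2$simpson, 1 - sum(p^2), tolerance = 1e-10)
  expect_equal(d2$chao1, sum(x > 0) + f1^2 / (2 * f2), tolerance = 1e-10)
  expect_gte(d2$chao1, sum(x > 0))

  # empty sample flagged
  k0 <- matrix(0, 3, 1, dimnames = list(paste0("t", 1:3), "e"))
  d0 <- alphaDiversity(TraitTable(k0))
  expect_true(d0$flag)
  expect_equal(d0$shannon, 0)
})

test_that("Box-Cox selection and the adjusted alpha-diversity ANOVA", {
  # log-normal data selects lambda ~ 0 (unbiasedness over replicates)
  lams <- vapply(1:10, function(s) {
    set.seed(22 + s)
    mycoQTL:::.boxcoxLambda(exp(rnorm(1000, 2, 0.5)))
  }, 0)
  expect_lte(abs(mean(lams)), 0.05)

  # planted diet shift is found by the pairwise comparisons
  n <- 300
  cov <- assignCovariates(n, diet_fractions = c(1, 1, 1) / 3, seed = 23)
  hits <- 0
  for (s in 1:6) {
    set.seed(100 + s)
    base <- exp(rnorm(n, 3, 0.3) + 0.2 * cov$sex)
    base[cov$diet == 2] <- base[cov$diet == 2] * exp(0.5 * 0.3)
    div <- data.frame(sample = rownames(cov), chao1 = base, shannon = base,
                      simpson = base / (1 + base), flag = FALSE)
    aa <- adjustedAlphaAnova(div, cov)
    pw <- aa$shannon$pairwise
    wes <- grepl("WES", pw$comparison)
    if (all(pw$p_adj[wes] < 0.05)) hits <- hits + 1
  }
  expect_gte(hits, 5)

  expect_error(adjustedAlphaAnova(
    data.frame(sample = "s", chao1 = 1, shannon = 1, simpson = 0.5),
    data.frame(sex = 0, diet = 0, generation = 18, cage = "c")), "diet")
})

test_that("beta distances: identity, disjoint support, explicit formula", {
  k <- matrix(c(5, 3, 0,
                5, 3, 0,
                0, 0, 7), 3, 3,
              dimnames = list(paste0("t", 1:3), c("a", "b", "c")))
  B <- as.matrix(betaDistance(TraitTable(k), "bray"))
  expect_equal(B["a", "b"], 0)
  expect_equal(B["a", "c"], 1)                       # disjoint supports
  J <- as.matrix(betaDistance(TraitTable(k), "jaccard"))
  expect_equal(J["a", "c"], 1)
  expect_equal(J["a", "b"], 0)

  set.seed(24)
  x <- rpois(10, 5); y <- rpois(10, 5)
  k2 <- cbind(a = x, b = y)
  rownames(k2) <- paste0("t", 1:10)
  B2 <- as.matrix(betaDistance(TraitTable(k2), "bray"))
  bray <- sum(abs(x - y)) / sum(x + y)
  expect_equal(B2["a", "b"], bray, tolerance = 1e-12)
  expect_equal(as.matrix(betaDistance(TraitTable(k2), "jaccard"))["a", "b"],
               2 * bray / (1 + bray), tolerance = 1e-12)

  k3 <- cbind(k, z = c(0, 0, 0))
  expect_warning(B3 <- betaDistance(TraitTable(k3), "bray"), "all-zero")
  expect_equal(as.matrix(B3)["z", "a"], 0)
})

test_that("constrained ordination: null calibration, power, conditioning", {
  set.seed(25)
  n <- 90
  cov <- assignCovariates(n, diet_fractions = c(1, 1, 1) / 3, seed = 26)
  # null: taxa independent of diet; p roughly uniform
  ps <- vapply(1:40, function(s) {
    set.seed(300 + s)
    k <- matrix(rnbinom(30 * n, mu = 20, size = 2), 30,
                dimnames = list(paste0("t", 1:30), rownames(cov)))
    D <- betaDistance(TraitTable(k), "bray")
    constrainedOrdination(D, cov, n_perm = 99, n_boot = 50, seed = s)$p
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # strong planted separation
  set.seed(27)
  k <- matrix(rnbinom(30 * n, mu = 20, size = 4), 30,
              dimnames = list(paste0("t", 1:30), rownames(cov)))
  k[1:10, cov$diet == 2] <- k[1:10, cov$diet == 2] + 40
  D <- betaDistance(TraitTable(k), "bray")
  res <- constrainedOrdination(D, cov, n_perm = 999, n_boot = 50, seed = 28)
  expect_lte(res$p, 0.01)
  wes <- grepl("WES", res$pairwise$comparison)
  expect_true(all(res$pairwise$p_adj[wes] <= 0.05))

  # conditioning away the separating covariate collapses the pseudo-F:
  # plant the shift on sex (a conditioner) rather than diet
  k2 <- matrix(rnbinom(30 * n, mu = 20, size = 4), 30,
               dimnames = list(paste0("t", 1:30), rownames(cov)))
  k2[1:10, cov$sex == 1] <- k2[1:10, cov$sex == 1] + 60
  D2 <- betaDistance(TraitTable(k2), "bray")
  df <- data.frame(diet = factor(cov$diet), sex = cov$sex,
                   generation = factor(cov$generation))
  f_uncond <- vegan::anova.cca(vegan::capscale(D2 ~ sex, data = df),
                               permutations = 99)$F[1]
  f_cond <- constrainedOrdination(D2, cov, n_perm = 99, n_boot = 50,
                                  seed = 29)$F
  expect_gte(f_uncond / f_cond, 10)
})

test_that("KW + MWU + FDR: power on a planted shift, null control, ties", {
  set.seed(30)
  n_arm <- 100
  diet <- rep(0:2, each = n_arm)
  hits <- 0
  for (s in 1:6) {
    set.seed(400 + s)
    k <- matrix(rnbinom(15 * 3 * n_arm, mu = 30, size = 3), 15)
    rownames(k) <- paste0("t", 1:15)
    k[1, diet == 2] <- rnbinom(n_arm, mu = 60, size = 3)   # 2-fold in WES
    rel <- sweep(k, 2, colSums(k), "/")
    out <- kwMwuFdr(rel, diet)
    t1 <- out[out$taxon == "t1" & !is.na(out$p), ]
    wes <- (t1$group1 == "2") | (t1$group2 == "2")
    if (nrow(t1) && all(t1$padj[wes] < 0.05)) hits <- hits + 1
  }
  expect_gte(hits, 5)

  # null: few taxa pass 5% FDR
  fp <- 0; tot <- 0
  for (s in 1:100) {
    set.seed(600 + s)
    k <- matrix(rnbinom(10 * 90, mu = 30, size = 3), 10)
    rownames(k) <- paste0("t", 1:10)
    out <- kwMwuFdr(k, rep(0:2, each = 30))
    sig <- unique(out$taxon[!is.na(out$padj) & out$padj < 0.05])
    fp <- fp + length(sig); tot <- tot + 10
  }
  expect_lte(fp / tot, 0.07)

  # identical groups: everything flat
  k <- matrix(rep(c(5, 9, 2), each = 30), 3, 30, byrow = TRUE,
              dimnames = list(paste0("t", 1:3), NULL))
  out <- kwMwuFdr(k, rep(0:1, 15))
  expect_true(all(out$kw_p == 1))
  expect_true(all(is.na(out$p)))
})

test_that("biomarker calls: planted, confounded, and flat taxa", {
  set.seed(31)
  n <- 240
  cov <- assignCovariates(n, diet_fractions = c(1, 1, 1) / 3, seed = 32)
  k <- matrix(rnbinom(12 * n, mu = 50, size = 3), 12,
              dimnames = list(paste0("t", 1:12), rownames(cov)))
  k[1, cov$diet == 2] <- rnbinom(sum(cov$diet == 2), mu = 250, size = 3)
  k[2, cov$sex == 1] <- rnbinom(sum(cov$sex == 1), mu = 250, size = 3)
  k[3, ] <- 40                                           # flat
  out <- lefseLite(k, cov$diet,
                   nuisance = list(sex = cov$sex, generation = cov$generation))
  expect_true("t1" %in% out$taxon)
  expect_equal(out$direction[out$taxon == "t1"], "2")
  expect_false("t2" %in% out$taxon)                      # sex-driven, excluded
  expect_false("t3" %in% out$taxon)
  expect_error(lefseLite(k, rep(1, n)), "two classes")
})

test_that("indicator species: perfect indicator, brute-force toy, null rate", {
  # taxon present in all CAL samples and nowhere else
  classes <- rep(c("CAL", "CON", "WES"), each = 10)
  k <- matrix(0, 2, 30, dimnames = list(c("t1", "t2"), NULL))
  k[1, classes == "CAL"] <- 5
  k[2, ] <- rep(c(3, 4, 5), 10)
  out <- indicatorSpecies(k, classes, n_perm = 199, seed = 33)
  r1 <- out[out$taxon == "t1", ]
  expect_equal(r1$indval, 1)
  expect_equal(r1$group, "CAL")
  expect_lte(r1$p, 1 / 100)

  # hand-sized 3-class toy vs exhaustive computation
  cls <- factor(rep(c("A", "B", "C"), each = 2))
  v <- c(4, 6, 1, 0, 0, 0)
  kt <- rbind(t1 = v, t2 = c(1, 2, 3, 4, 5, 6))
  res <- indicatorSpecies(kt, cls, n_perm = 99, seed = 34)
  mg <- tapply(v, cls, mean)           # A = 5, B = 0.5, C = 0
  combos <- list(1, 2, 3, c(1, 2), c(1, 3), c(2, 3))
  occ <- tapply(v > 0, cls, mean)
  ivs <- vapply(combos, function(C)
    sqrt(sum(mg[C]) / sum(mg) * (sum(occ[C] * 2) / (2 * length(C)))), 0)
  expect_equal(res$indval[res$taxon == "t1"], max(ivs), tolerance = 1e-12)

  # shuffled labels: few significant calls
  set.seed(35)
  fp <- 0; tot <- 0
  for (s in 1:40) {
    kk <- matrix(rnbinom(8 * 45, mu = 10, size = 2), 8,
                 dimnames = list(paste0("t", 1:8), NULL))
    res0 <- indicatorSpecies(kk, sample(rep(0:2, 15)), n_perm = 99,
                             seed = 100 + s)
    fp <- fp + sum(res0$p < 0.05); tot <- tot + nrow(res0)
  }
  expect_lte(fp / tot, 0.07)

  expect_error(indicatorSpecies(k, rep("CAL", 30)), "two classes")
})
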