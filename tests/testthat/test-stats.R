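test_that("Spearman correlation handles reversals, ties and binary vectors", {
  expect_equal(spearmanRcc(1:3, 3:1)$rho, -1)
  expect_equal(spearmanRcc(1:5, 1:5)$rho, 1)
  # binary y against distinct x sorted so the 1s sit on top
  r <- spearmanRcc(c(4, 3, 2, 1), c(1, 1, 0, 0))
  expect_equal(r$rho, 4 / sqrt(20), tolerance = 1e-12)
  expect_warning(res <- spearmanRcc(rep(1, 5), 1:5), "constant")
  expect_true(res$undefined)
  # invariance under strictly monotone transforms
  set.seed(1)
  x <- rnorm(30)
  y <- rnorm(30)
  expect_equal(spearmanRcc(x, y)$rho, spearmanRcc(exp(x), y^3 + y)$rho,
    tolerance = 1e-12)
})

test_that("Spearman agrees with a longhand rank-Pearson oracle", {
  set.seed(2)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    x <- sample(1:8, n, TRUE)  # plenty of ties
    y <- rnorm(n) + x / 2
    got <- spearmanRcc(x, y)
    expect_equal(got$rho, brutePearson(bruteRanks(x), bruteRanks(y)),
      tolerance = 1e-10)
  }
})

test_that("the maximum attainable correlation rearranges labels optimally", {
  expect_equal(maxAttainableSrcc(c(1, 1, 0, 0), c(7, 5, 3, 1)),
    4 / sqrt(20), tolerance = 1e-12)
  expect_warning(res <- maxAttainableSrcc(rep(1, 4), 1:4), "undefined")
  expect_true(is.na(res))
  # brute force over all label placements: the reported value is the max
  set.seed(3)
  for (i in 1:10) {
    n <- 7
    k <- sample(2:4, 1)
    deg <- sample(1:5, n, TRUE)
    if (length(unique(deg)) < 2) next
    best <- max(apply(combn(n, k), 2, function(idx) {
      lab <- numeric(n)
      lab[idx] <- 1
      suppressWarnings(spearmanRcc(lab, deg)$rho)
    }), na.rm = TRUE)
    expect_equal(maxAttainableSrcc(
      { lab <- numeric(n); lab[seq_len(k)] <- 1; lab }, deg),
      best, tolerance = 1e-10)
  }
})

test_that("partial Spearman reduces, degenerates and matches residual correlations", {
  # z rank-orthogonal to x with y = x: partial equals the plain SRCC
  x <- c(1, 2, 3, 4)
  z <- c(2, 4, 1, 3)   # sum(x*z) = 25 -> rank correlation exactly 0
  expect_equal(stats::cor(rank(x), rank(z)), 0)
  expect_equal(partialSpearman(x, c(2, 3, 5, 7), z)$rho,
    spearmanRcc(x, c(2, 3, 5, 7))$rho, tolerance = 1e-12)
  # y = z: the control removes everything; degenerate value 0
  set.seed(4)
  y <- sample(1:50)
  xq <- rnorm(50)
  expect_warning(res <- partialSpearman(xq, y, y), "collinear")
  expect_equal(res$rho, 0, tolerance = 1e-12)
  expect_true(res$undefined)
  # symmetry in x and y
  a <- rnorm(40); b <- rnorm(40); cc <- rnorm(40)
  expect_equal(partialSpearman(a, b, cc)$rho,
    partialSpearman(b, a, cc)$rho, tolerance = 1e-12)
  # two-method agreement with rank-residual correlations
  for (i in 1:100) {
    n <- 50
    x1 <- rnorm(n)
    y1 <- rnorm(n) + 0.5 * x1
    z1 <- rnorm(n) + 0.3 * y1
    rx <- rank(x1); ry <- rank(y1); rz <- rank(z1)
    ex <- residuals(lm(rx ~ rz))
    ey <- residuals(lm(ry ~ rz))
    expect_equal(partialSpearman(x1, y1, z1)$rho,
      brutePearson(ex, ey), tolerance = 1e-10)
  }
})

test_that("Wilcoxon rank-sum uses the exact small-sample null", {
  r <- wilcoxonRankSum(c(1, 2), c(3, 4))
  expect_true(r$exact)
  expect_equal(r$p.value, 2 / 6, tolerance = 1e-12)
  same <- wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p.value, 0.99)
  # exhaustive enumeration oracle for small tie-free samples
  set.seed(5)
  for (i in 1:20) {
    na <- sample(3:6, 1)
    nb <- sample(3:6, 1)
    v <- sample(1:100, na + nb)
    a <- v[seq_len(na)]
    b <- v[-seq_len(na)]
    expect_equal(wilcoxonRankSum(a, b)$p.value, bruteWilcoxP(a, b),
      tolerance = 1e-10)
  }
  # large-sample shift alternative is detected
  set.seed(6)
  big <- wilcoxonRankSum(rnorm(200, 1), rnorm(200))
  expect_false(big$exact)
  expect_lt(big$p.value, 0.05)
})

test_that("per-complex permutation test matches exhaustive enumeration", {
  fx <- fourProteinComplex("A")
  net <- Interactome(fx$edges)
  mods <- ModuleSet(list(CPLX = fx$members))
  ess <- EssentialityMap(tested = fx$members, essential = fx$essential)
  res <- perComplexPermutationTest(net, mods, ess, nPerm = 10000,
    seed = 17)
  expect_equal(res$nComplexesTested, 1L)
  expect_equal(res$nHigherEssential, 1L)
  # exact null: only the {2,2} draw of C(4,2) = 6 beats the rest
  pExact <- 1 / 6
  se <- sqrt(pExact * (1 - pExact) / 10000)
  expect_lt(abs(res$empiricalP - pExact), 3 * se + 1 / 10001)
  # seeded runs are bit-reproducible
  res2 <- perComplexPermutationTest(net, mods, ess, nPerm = 10000,
    seed = 17)
  expect_identical(res$empiricalP, res2$empiricalP)
})

test_that("identical degrees never count as higher and give p = 1", {
  mem <- sprintf("K%d", 1:4)
  edges <- t(combn(mem, 2))         # clique: all degrees equal
  net <- Interactome(edges)
  mods <- ModuleSet(list(CL = mem))
  ess <- EssentialityMap(mem, mem[1:2])
  res <- perComplexPermutationTest(net, mods, ess, nPerm = 500,
    seed = 3)
  expect_equal(res$nHigherEssential, 0L)
  expect_equal(res$empiricalP, 1)
})

test_that("independent complexes give a product-form null", {
  fxs <- lapply(c("A", "B", "C"), fourProteinComplex)
  net <- Interactome(do.call(rbind, lapply(fxs, `[[`, "edges")))
  mods <- ModuleSet(setNames(lapply(fxs, `[[`, "members"),
    c("CA", "CB", "CC")))
  ess <- EssentialityMap(unlist(lapply(fxs, `[[`, "members")),
    unlist(lapply(fxs, `[[`, "essential")))
  res <- perComplexPermutationTest(net, mods, ess, nPerm = 20000,
    seed = 23)
  expect_equal(res$nComplexesTested, 3L)
  expect_equal(res$nHigherEssential, 3L)
  pExact <- (1 / 6)^3               # all three higher simultaneously
  se <- sqrt(pExact * (1 - pExact) / 20000)
  expect_lt(abs(res$empiricalP - pExact), 3 * se + 1 / 20001)
  # no eligible complexes: explicit empty status
  essNone <- EssentialityMap(unlist(lapply(fxs, `[[`, "members")),
    character())
  empty <- perComplexPermutationTest(net, mods, essNone, nPerm = 10)
  expect_equal(empty$status, "no eligible complexes")
  expect_true(is.na(empty$empiricalP))
})
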