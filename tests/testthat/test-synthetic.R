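test_that("generator configs validate their probability structure", {
  expect_error(generatorConfig(pOut = 0.5, pCrosstalk = 0.2), "pOut")
  expect_error(generatorConfig(pIn = 0.001, pOut = 0.1,
    pCrosstalk = 0.2), "pOut")
  expect_error(generatorConfig(baseRate = 1.2), "\\[0, 1\\]")
  expect_error(generateInteractome(generatorConfig(nProteins = 50,
    nModules = 10, sizeRange = c(30, 50))), "exceed")
})

test_that("degenerate probabilities produce cliques and silence", {
  cfg <- generatorConfig(nProteins = 36, nModules = 3,
    sizeRange = c(10, 10), pIn = 1, pOut = 0, pCrosstalk = 0.5,
    nCrosstalkPairs = 0, seed = 2)
  sim <- generateInteractome(cfg)
  cls <- classifyEdges(sim$network, sim$modules)
  expect_equal(sum(cls == "intermodular"), 0L)
  expect_equal(sum(cls == "intramodular"), 3 * choose(10, 2))
})

test_that("intramodule edge counts match binomial moments over seeds", {
  nIntra <- vapply(1:200, function(s) {
    sim <- generateInteractome(generatorConfig(nProteins = 12,
      nModules = 1, sizeRange = c(10, 10), pIn = 0.5,
      nCrosstalkPairs = 0, pCrosstalk = 0.9, seed = s))
    nrow(interactions(sim$network))
  }, 0)
  # almost all edges intramodular here (2 leftover proteins, pOut tiny)
  expected <- choose(10, 2) * 0.5
  se <- sqrt(choose(10, 2) * 0.25 / 200)
  expect_lt(abs(mean(nIntra) - expected), 4 * se + 0.3)
})

test_that("planted pairs are enriched in proportion to their probabilities", {
  planted <- matrix(c(1L, 2L), 1)
  counts <- vapply(1:100, function(s) {
    sim <- generateInteractome(generatorConfig(nProteins = 60,
      nModules = 3, sizeRange = c(20, 20), pIn = 0.3, pOut = 0.01,
      pCrosstalk = 0.3, nCrosstalkPairs = 1, crosstalkPairs = planted,
      seed = s))
    mem <- moduleMembers(sim$modules)
    c(countCrosstalk(sim$network, mem$M001, mem$M002),
      countCrosstalk(sim$network, mem$M001, mem$M003))
  }, c(0, 0))
  nCells <- 400
  expect_lt(abs(mean(counts[1, ]) - nCells * 0.3),
    4 * sqrt(nCells * 0.3 * 0.7 / 100))
  expect_lt(abs(mean(counts[2, ]) - nCells * 0.01),
    4 * sqrt(nCells * 0.01 * 0.99 / 100))
})

test_that("essentiality follows the configured degree coupling", {
  # beta = 0: essentiality independent of intramodular degree
  rhos <- vapply(1:30, function(s) {
    sim <- generateInteractome(generatorConfig(nProteins = 400,
      nModules = 8, sizeRange = c(30, 50), nCrosstalkPairs = 4,
      alpha = 0, beta = 0, seed = s))
    ess <- assignEssentiality(sim)
    tab <- computeDegrees(sim$network, sim$modules, ess)
    tab <- tab[!is.na(tab$largestModuleSize), ]
    suppressWarnings(spearmanRcc(as.numeric(tab$essential), tab$intra)$rho)
  }, 0)
  expect_lt(abs(mean(rhos, na.rm = TRUE)), 0.05)

  # steep beta: essential members out-connect non-essential ones inside
  # essential modules in nearly every replicate
  # alpha centres the logistic at the typical intramodular degree so
  # both classes exist while the separation is steep
  hits <- vapply(1:20, function(s) {
    sim <- generateInteractome(generatorConfig(nProteins = 1000,
      nModules = 20, sizeRange = c(30, 50), nCrosstalkPairs = 4,
      alpha = -24, beta = 2, seed = 100 + s))
    ess <- assignEssentiality(sim)
    tab <- computeDegrees(sim$network, sim$modules, ess)
    inEss <- tab$protein %in% unlist(
      moduleMembers(sim$modules)[sim$truth$essentialModules])
    sub <- tab[inEss, ]
    if (!any(sub$essential) || all(sub$essential)) return(NA)
    mean(sub$intra[sub$essential]) > mean(sub$intra[!sub$essential])
  }, TRUE)
  expect_gte(mean(hits, na.rm = TRUE), 0.95)

  # zero base rate: no essential proteins outside essential modules
  sim <- generateInteractome(generatorConfig(nProteins = 400,
    nModules = 8, sizeRange = c(30, 50), nCrosstalkPairs = 4,
    baseRate = 0, seed = 77))
  ess <- assignEssentiality(sim)
  outside <- setdiff(proteins(sim$network), unlist(
    moduleMembers(sim$modules)[sim$truth$essentialModules]))
  expect_length(intersect(essentialProteins(ess), outside), 0L)
})

test_that("toy ontologies are valid, aligned with modules and Lin-consistent", {
  mods <- ModuleSet(setNames(
    lapply(0:9, function(i) sprintf("P%03d", i * 10 + 1:10)),
    sprintf("M%02d", 1:10)))
  toy <- generateToyOntology(mods, proteomeSize = 120)
  leaves <- grep("^GO:2", termIds(toy$ontology), value = TRUE)
  expect_length(leaves, 10L)
  expect_true(all(termCounts(toy$annotations)[leaves] <= 50))
  expect_equal(termProbability(toy$annotations, "GO:0008150",
    toy$ontology), 100 / 120)
  # two modules under one mid-level parent: leaf similarity from the
  # closed-form Lin expression with the parent as the ancestor
  l1 <- leaves[1]
  l2 <- leaves[2]
  pv <- function(t) termProbability(toy$annotations, t, toy$ontology)
  mid <- termParents(toy$ontology)[[l1]]
  expect_equal(linTermSimilarity(l1, l2, toy$annotations, toy$ontology),
    2 * log(pv(mid)) / (log(pv(l1)) + log(pv(l2))), tolerance = 1e-12)
  # deeper ontologies keep validity
  deep <- generateToyOntology(mods, depth = 5, proteomeSize = 120)
  expect_true(validObject(deep$ontology))
})

test_that("fixtures are deterministic, parseable and faithful", {
  cfg <- generatorConfig(nProteins = 250, nModules = 5,
    sizeRange = c(20, 40), nCrosstalkPairs = 2, seed = 13)
  sim <- simulateStudy(cfg)
  d1 <- tempfile()
  d2 <- tempfile()
  writeFixture(sim, d1)
  writeFixture(simulateStudy(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
      readLines(file.path(d2, f)))
  }
  fx <- readFixture(d1)
  expect_identical(interactions(fx$network), interactions(sim$network))
  expect_identical(moduleMembers(fx$modules), moduleMembers(sim$modules))
  expect_setequal(essentialProteins(fx$essentiality),
    essentialProteins(sim$essentiality))
  expect_identical(fx$annotations@propagated,
    sim$annotations@propagated)
  expect_setequal(fx$manifest$plantedPairs,
    apply(sim$truth$plantedPairs, 1, paste, collapse = "|"))
  # generated objects satisfy the class invariants
  expect_true(validObject(sim$network))
  expect_true(validObject(sim$modules))
  expect_true(validObject(sim$essentiality))
  expect_true(validObject(sim$annotations))
})
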