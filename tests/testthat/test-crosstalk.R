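test_that("cross-talk counting excludes doubly annotated endpoints", {
  net <- Interactome(rbind(c("a", "c"), c("b", "d"), c("a", "d"),
    c("x", "y")))
  expect_equal(countCrosstalk(net, c("a", "b"), c("c", "d")), 3L)
  # an endpoint in both modules makes the edge intramodular
  net2 <- Interactome(rbind(c("x", "y")))
  expect_equal(countCrosstalk(net2, c("x", "q"), c("x", "y")), 0L)
  expect_equal(countCrosstalk(net, c("a", "b"), c("e", "f")), 0L)
})

test_that("vertex-disjoint support is detected via the star/triangle rule", {
  expect_true(hasIndependentPair(rbind(c("a", "c"), c("b", "d"))))
  expect_false(hasIndependentPair(rbind(c("a", "c"), c("a", "d"))))
  star <- cbind("hub", paste0("v", 1:5))
  expect_false(hasIndependentPair(star))
  expect_true(hasIndependentPair(rbind(star, c("w1", "w2"))))
  expect_false(hasIndependentPair(rbind(c("a", "b"), c("b", "c"),
    c("a", "c"))))
  expect_false(hasIndependentPair(rbind(c("a", "b"))))
  # brute-force matching oracle on random small edge sets
  set.seed(7)
  for (i in 1:50) {
    v <- sprintf("n%d", 1:6)
    k <- sample(2:6, 1)
    em <- t(replicate(k, sample(v, 2)))
    em <- em[em[, 1] != em[, 2], , drop = FALSE]
    if (nrow(em) < 2) next
    pairsDisjoint <- FALSE
    for (a in seq_len(nrow(em) - 1)) {
      for (b in seq.int(a + 1, nrow(em))) {
        if (!length(intersect(em[a, ], em[b, ]))) pairsDisjoint <- TRUE
      }
    }
    expect_identical(hasIndependentPair(em), pairsDisjoint)
  }
})

test_that("odds-scores apply the pseudocount and are monotone", {
  expect_equal(oddsScore(3, 3), 1)
  expect_equal(oddsScore(9, 1.5), 4)
  expect_lte(oddsScore(0, 7), 1)
  expect_gt(oddsScore(5, 2), oddsScore(4, 2))
  expect_gt(oddsScore(5, 2), oddsScore(5, 3))
})

test_that("stub-rewiring preserves degrees, modules and edge counts", {
  sim <- simulateStudy(generatorConfig(nProteins = 200, nModules = 6,
    sizeRange = c(15, 25), nCrosstalkPairs = 2, pOut = 0.02,
    pCrosstalk = 0.2, seed = 19))
  cls <- classifyEdges(sim$network, sim$modules)
  inter <- interactions(sim$network)[cls == "intermodular", ]
  degIn <- table(c(inter))
  rounds <- stubRewireIntermodular(sim$network, sim$modules,
    nRounds = 20, seed = 31)
  for (em in rounds) {
    expect_equal(nrow(em), nrow(inter))                   # count kept
    expect_true(all(em[, 1] != em[, 2]))                  # no loops
    expect_equal(anyDuplicated(paste(em[, 1], em[, 2])), 0L)
    degOut <- table(c(em))
    expect_identical(degOut[order(names(degOut))],
      degIn[order(names(degIn))])                         # degrees kept
    expect_true(all(classifyEdges(em, sim$modules) == "intermodular"))
  }
  # seeded reproducibility
  r2 <- stubRewireIntermodular(sim$network, sim$modules, nRounds = 20,
    seed = 31)
  expect_identical(rounds, r2)
})

test_that("a two-edge toy rewires into one of its two valid pairings", {
  net <- Interactome(rbind(c("a1", "b1"), c("a2", "b2")))
  mods <- ModuleSet(list(A = c("a1", "a2"), B = c("b1", "b2")))
  rounds <- stubRewireIntermodular(net, mods, nRounds = 50, seed = 3)
  keys <- vapply(rounds, function(em)
    paste(sort(paste(em[, 1], em[, 2])), collapse = ";"), "")
  valid <- c("a1 b1;a2 b2", "a1 b2;a2 b1")
  expect_true(all(keys %in% valid))
  expect_equal(sort(unique(keys)), sort(valid))   # both states visited
})

# planted pairs must stay sparse relative to the module count: if they
# dominate the intermodular degree sequence, the degree-preserving null
# itself reproduces the enrichment and no pair can reach a high odds
.recoverySim <- function() {
  simulateStudy(generatorConfig(nProteins = 1000, nModules = 20,
    sizeRange = c(30, 50), nCrosstalkPairs = 5, seed = 29))
}

test_that("planted cross-talk pairs are recovered and thresholds are anti-monotone", {
  sim <- .recoverySim()
  mn <- inferCrosstalkNetwork(sim$network, sim$modules,
    sim$essentiality, nRounds = 50, seed = 37)
  truth <- apply(sim$truth$plantedPairs, 1, function(r)
    paste(sort(r), collapse = "|"))
  found <- with(crosstalkEdges(mn), mapply(function(x, y)
    paste(sort(c(x, y)), collapse = "|"), m1, m2))
  expect_gte(sum(found %in% truth) / max(length(found), 1), 0.8)
  expect_gte(sum(truth %in% found) / length(truth), 0.8)

  prevEdges <- NULL
  for (thr in c(2, 5, 10, 20)) {
    mt <- applyOddsThreshold(mn, sim$modules, sim$essentiality, thr)
    cur <- nrow(crosstalkEdges(mt))
    if (!is.null(prevEdges)) expect_lte(cur, prevEdges)
    ids <- with(crosstalkEdges(mt), paste(m1, m2))
    expect_true(is.null(prevEdges) || all(ids %in% prevIds))
    prevEdges <- cur
    prevIds <- ids
  }
})

test_that("module essentiality analysis reports correlations and degenerate flags", {
  sim <- .recoverySim()
  mn <- inferCrosstalkNetwork(sim$network, sim$modules,
    sim$essentiality, nRounds = 50, seed = 37)
  an <- crosstalkEssentialityAnalysis(mn)
  expect_true(is.finite(an$srccBinary$rho))
  expect_true(is.finite(an$srccPartialSize$rho))
  expect_equal(an$hubCurve$nConsidered[1], min(20L, nrow(moduleNodes(mn))))
  # module with 4 accepted partners and 8 members: normalised degree 0.5
  nodes <- moduleNodes(mn)
  expect_equal(nodes$normalizedDegree,
    nodes$crosstalkDegree / nodes$size)

  # degenerate: every module essential
  essAll <- EssentialityMap(proteins(sim$network),
    unlist(lapply(moduleMembers(sim$modules), `[`, 1)))
  mnAll <- applyOddsThreshold(mn, sim$modules, essAll, 5)
  anAll <- crosstalkEssentialityAnalysis(mnAll)
  expect_true(anAll$srccBinary$undefined)
  expect_true(is.finite(anAll$srccFracEssential$rho))
})

test_that("functionally related module pairs can be filtered out", {
  # two modules fully annotated with a shared slim term, one unrelated
  mem <- list(M1 = sprintf("A%d", 1:4), M2 = sprintf("B%d", 1:4),
    M3 = sprintf("C%d", 1:4))
  mods <- ModuleSet(mem)
  parents <- list(root = character(), shared = "root", lone = "root")
  ont <- Ontology(parents)
  direct <- c(
    setNames(rep("shared", 8), c(mem$M1, mem$M2)),
    setNames(rep("lone", 4), mem$M3))
  ann <- propagateAnnotations(
    AnnotationSet(split(unname(direct), names(direct)),
      proteomeSize = 12), ont)
  # a network with heavy M1-M2 and M1-M3 cross-talk
  e <- rbind(cbind(mem$M1, mem$M2), cbind(mem$M1, rev(mem$M3)))
  net <- Interactome(e)
  ess <- EssentialityMap(unlist(mem), mem$M1[1])
  mn <- inferCrosstalkNetwork(net, mods, ess, oddsThreshold = 0,
    nRounds = 10, seed = 5)
  expect_equal(nrow(crosstalkEdges(mn)), 2L)
  fl <- filterFunctionallyRelated(mn, mods, ess, c("shared", "lone"),
    ann, annotationFraction = 0.5)
  kept <- crosstalkEdges(fl)
  expect_equal(nrow(kept), 1L)                       # M1-M2 removed
  expect_setequal(c(kept$m1, kept$m2), c("M1", "M3"))

  # a module with 3 of 8 members annotated misses a 0.5 threshold: no
  # shared annotation, edge kept
  mem2 <- list(N1 = sprintf("D%d", 1:8), N2 = sprintf("E%d", 1:4))
  mods2 <- ModuleSet(mem2)
  direct2 <- c(setNames(rep("shared", 3), mem2$N1[1:3]),
    setNames(rep("shared", 4), mem2$N2))
  ann2 <- propagateAnnotations(
    AnnotationSet(split(unname(direct2), names(direct2)),
      proteomeSize = 12), ont)
  e2 <- cbind(mem2$N1[1:4], mem2$N2)
  mn2 <- inferCrosstalkNetwork(Interactome(e2), mods2, NULL,
    oddsThreshold = 0, nRounds = 10, seed = 5)
  fl2 <- filterFunctionallyRelated(mn2, mods2, NULL, c("shared"),
    ann2, annotationFraction = 0.5)
  expect_equal(nrow(crosstalkEdges(fl2)), nrow(crosstalkEdges(mn2)))
})
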