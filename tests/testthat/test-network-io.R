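test_that("interaction tables parse with normalisation and self-loop removal", {
  f <- writeTempTable(data.frame(a = c("yal001c", "YBR002W", "YCL003C"),
    b = c("YAL001C", "ycl003c", "YDL004C"),
    system = "Two-hybrid", source = "PMID1", bait = NA))
  rec <- parseInteractionTable(f)
  expect_equal(nrow(rec), 2L)                      # self-record dropped
  expect_true(all(rec$a == toupper(rec$a)))
  expect_equal(rec$system[1], "Two-hybrid")

  # duplicated rows survive parsing; dedup happens at graph build
  f2 <- writeTempTable(recTable(c("A1", "A1", "B1"), c("B1", "B1", "C1")))
  expect_equal(nrow(parseInteractionTable(f2)), 3L)

  fEmpty <- writeTempTable(recTable(character(), character()))
  expect_warning(rec0 <- parseInteractionTable(fEmpty), "empty")
  expect_equal(nrow(rec0), 0L)

  fBad <- writeTempTable(data.frame(x = "A", b = "B"))
  expect_error(parseInteractionTable(fBad), "mandatory column 'a'")
})

test_that("sticky-protein filter removes per-source records above a strict bound", {
  partners <- sprintf("Q%03d", 1:31)
  rec <- rbind(recTable(rep("X0", 31), partners, source = "S"),
    recTable(rep("X0", 5), sprintf("R%03d", 1:5), source = "T"))
  out <- filterStickyProteins(rec, maxPerSource = 30)
  expect_equal(nrow(out), 5L)                     # 31 from S removed
  expect_true(all(out$source == "T"))

  rec30 <- recTable(rep("X0", 30), sprintf("Q%03d", 1:30), source = "S")
  expect_equal(nrow(filterStickyProteins(rec30, 30)), 30L)  # boundary kept

  # one record shared by two sticky proteins is removed once, no dupes
  shared <- recTable("X0", "Y0", source = "S")
  recBoth <- rbind(
    recTable(rep("X0", 30), sprintf("QX%02d", 1:30), source = "S"),
    recTable(rep("Y0", 30), sprintf("QY%02d", 1:30), source = "S"),
    shared)
  out2 <- filterStickyProteins(recBoth, 30)
  keyAll <- paste(recBoth$a, recBoth$b)
  keySticky <- keyAll[recBoth$a %in% c("X0", "Y0") &
    recBoth$source == "S"]
  expect_equal(nrow(out2), 0L)  # every record here touches X0 or Y0
  expect_equal(anyDuplicated(paste(out2$a, out2$b)), 0L)
  # set-difference oracle on a mixed table
  recMix <- rbind(recBoth, recTable("Z1", "Z2", source = "S"))
  out3 <- filterStickyProteins(recMix, 30)
  expect_equal(paste(out3$a, out3$b), "Z1 Z2")
})

test_that("evidence classes admit the configured experimental systems", {
  rec <- rbind(
    recTable("A1", "B1", system = "Two-hybrid"),
    recTable("A1", "B1", system = "Affinity Capture-MS"),
    recTable("C1", "D1", system = "Affinity Capture-RNA"),
    recTable("E1", "F1", system = "Biochemical Activity"),
    recTable("G1", "H1", system = "Synthetic Lethality"))
  dir <- selectEvidenceClass(rec, "direct")
  expect_equal(nrow(interactions(dir)), 2L)   # A1-B1 and E1-F1
  # the shared pair keeps only the admitted record's provenance
  pv <- provenance(dir)
  expect_equal(pv$system[pv$a == "A1"], "Two-hybrid")

  pd <- selectEvidenceClass(rec, "pulldown")
  expect_equal(nrow(interactions(pd)), 1L)

  full <- selectEvidenceClass(rec, "full")
  expect_false("C1" %in% proteins(full))      # RNA evidence excluded
  expect_true("G1" %in% proteins(full))       # unknown systems fall in full
  expect_error(selectEvidenceClass(rec, "bogus"))
})

test_that("high-throughput filter enforces experiment size and bait counts", {
  bigOk <- recTable(sprintf("A%02d", 1:60), sprintf("B%02d", 1:60),
    source = "HT1", bait = rep(sprintf("BA%02d", 1:11), length.out = 60))
  small <- recTable(sprintf("C%02d", 1:49), sprintf("D%02d", 1:49),
    source = "LT1", bait = rep(sprintf("BB%02d", 1:20), length.out = 49))
  fewBaits <- recTable(sprintf("E%02d", 1:60), sprintf("F%02d", 1:60),
    source = "HT2", bait = rep(sprintf("BC%02d", 1:10), length.out = 60))
  out <- filterHighThroughput(rbind(bigOk, small, fewBaits))
  expect_setequal(unique(out$source), "HT1")   # 49 records and 10 baits fail
  expect_equal(nrow(out), 60L)
  noBait <- recTable("A1", "B1")
  expect_error(filterHighThroughput(noBait), "bait")
})

test_that("restriction to tested proteins induces a subgraph and is idempotent", {
  net <- Interactome(rbind(c("A1", "B1"), c("B1", "C1"), c("C1", "D1"),
    c("D1", "E1")))
  ess <- EssentialityMap(tested = c("A1", "B1", "C1"), essential = "A1")
  sub <- restrictToTested(net, ess)
  expect_setequal(proteins(sub), c("A1", "B1", "C1"))
  expect_equal(nrow(interactions(sub)), 2L)   # C1-D1 and D1-E1 dropped
  again <- restrictToTested(sub, ess)
  expect_identical(interactions(again), interactions(sub))

  allTested <- EssentialityMap(tested = proteins(net), essential = "A1")
  expect_identical(interactions(restrictToTested(net, allTested)),
    interactions(net))
})

test_that("built interactomes are simple and filters only shrink edge sets", {
  set.seed(42)
  for (rep in 1:5) {
    ids <- sprintf("P%02d", 1:15)
    rec <- recTable(sample(ids, 60, TRUE), sample(ids, 60, TRUE),
      system = sample(c("Two-hybrid", "FRET", "Affinity Capture-MS"),
        60, TRUE),
      source = sample(c("S1", "S2"), 60, TRUE))
    rec <- rec[rec$a != rec$b, ]
    net <- selectEvidenceClass(rec, "full")
    e <- interactions(net)
    expect_true(all(e[, 1] != e[, 2]))
    expect_equal(anyDuplicated(paste(e[, 1], e[, 2])), 0L)
    # sticky-then-class yields a subgraph of class alone
    eSticky <- interactions(selectEvidenceClass(
      filterStickyProteins(rec, 5), "full"))
    expect_true(all(paste(eSticky[, 1], eSticky[, 2]) %in%
      paste(e[, 1], e[, 2])))
  }
})

test_that("interactomes and essentiality lists round-trip through TSV", {
  net <- Interactome(rbind(c("A1", "B1"), c("B1", "C1")))
  pre <- tempfile()
  writeInteractome(net, pre)
  back <- parseInteractionTable(paste0(pre, "_edges.tsv"),
    interactionDialect(a = "a", b = "b"))
  expect_equal(nrow(back), 2L)
  ess <- EssentialityMap(c("A1", "B1", "C1"), c("B1"))
  f <- tempfile()
  writeEssentiality(ess, f)
  back2 <- readEssentiality(f)
  expect_setequal(testedProteins(back2), testedProteins(ess))
  expect_setequal(essentialProteins(back2), "B1")
})
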