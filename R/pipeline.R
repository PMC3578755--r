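# End-to-end orchestration and paper-style result tables.

.correlationRow <- function(name, res) {
  data.frame(measure = name, rho = res$rho, p.value = res$p.value,
    n = res$n,
    controlledFor = if (is.null(res$controlledFor)) NA_character_
      else res$controlledFor)
}

# all protein-level statistics for one module universe
.analyseUniverse <- function(net, modules, ess, groupSize, nPerm,
    nRounds, oddsThreshold, swapsPerEdge, permSeed, rewireSeed,
    skipCrosstalk) {
  degAll <- computeDegrees(net, modules, ess,
    restrictToModuleMembers = FALSE)
  deg <- degAll[degAll$totalAnnotated > 0L & !is.na(degAll$essential), ,
    drop = FALSE]
  essv <- as.numeric(deg$essential)

  corr <- rbind(
    .correlationRow("srcc_intra", spearmanRcc(essv, deg$intra)),
    .correlationRow("srcc_inter", spearmanRcc(essv, deg$inter)),
    .correlationRow("srcc_total", spearmanRcc(essv, deg$totalAnnotated)),
    .correlationRow("partial_total_given_intra",
      partialSpearman(essv, deg$totalAnnotated, deg$intra)),
    .correlationRow("partial_total_given_inter",
      partialSpearman(essv, deg$totalAnnotated, deg$inter)))
  corr$controlledFor[4:5] <- c("intra", "inter")
  maxAtt <- suppressWarnings(maxAttainableSrcc(deg$essential,
    deg$totalAnnotated))

  curves <- list(
    intra = hubFractionCurve(deg, "intra", groupSize),
    inter = hubFractionCurve(deg, "inter", groupSize),
    total = hubFractionCurve(deg, "totalAnnotated", groupSize))

  wilcox <- lapply(c(intra = "intra", inter = "inter",
    total = "totalAnnotated"), function(f) {
    a <- deg[[f]][deg$essential]
    b <- deg[[f]][!deg$essential]
    if (!length(a) || !length(b))
      return(list(statistic = NA_real_, p.value = NA_real_, exact = NA))
    wilcoxonRankSum(a, b)
  })

  permTest <- perComplexPermutationTest(net, modules, ess,
    nPerm = nPerm, seed = permSeed)

  crosstalk <- NULL
  if (!skipCrosstalk) {
    mn <- inferCrosstalkNetwork(net, modules, ess,
      oddsThreshold = oddsThreshold, nRounds = nRounds,
      seed = rewireSeed, swapsPerEdge = swapsPerEdge)
    analysis <- tryCatch(crosstalkEssentialityAnalysis(mn),
      error = function(e) NULL)
    crosstalk <- list(network = mn, analysis = analysis)
  }
  list(degreeTable = degAll, correlations = corr,
    maxAttainableSrcc = maxAtt, hubCurves = curves, wilcoxon = wilcox,
    permutationTest = permTest, crosstalk = crosstalk)
}

#' Run the complete analysis pipeline
#'
#' For each supplied module universe, computes the degree table,
#' hub-fraction curves, rank correlations (with partial variants and
#' the maximum attainable value), Wilcoxon comparisons of essential vs
#' non-essential degree distributions, the per-complex permutation
#' test, and (unless skipped) the cross-talk module network with its
#' essentiality analysis. A single master seed deterministically
#' derives the per-stage seeds, so reruns with identical inputs and
#' configuration reproduce identical numbers.
#'
#' @param net an \code{\link{Interactome}} (already restricted to
#'   tested proteins if desired).
#' @param universes a named list of \code{\link{ModuleSet}}s (a bare
#'   \code{ModuleSet} is treated as one universe named after its
#'   origin).
#' @param ess an \code{\link{EssentialityMap}}.
#' @param groupSize hub-curve group size for proteins.
#' @param nPerm permutations for the per-complex test.
#' @param nRounds randomisation rounds for cross-talk inference.
#' @param oddsThreshold cross-talk acceptance threshold.
#' @param swapsPerEdge proposed swaps per edge per rewiring round.
#' @param seed master seed.
#' @param skipCrosstalk omit the module-network stage.
#' @return a report bundle: per-universe result lists (see
#'   \code{.analyseUniverse} internals) plus a machine-readable
#'   \code{manifest} echoing the configuration and derived seeds.
#' @export
runPipeline <- function(net, universes, ess, groupSize = 50,
    nPerm = 10000, nRounds = 100, oddsThreshold = 5, swapsPerEdge = 10,
    seed = 1, skipCrosstalk = FALSE) {
  if (is(universes, "ModuleSet")) {
    nm <- unique(moduleOrigin(universes))[1]
    universes <- stats::setNames(list(universes), nm)
  }
  if (is.null(names(universes)) || any(!nzchar(names(universes))))
    stop("universes must be a named list of ModuleSet objects")
  permSeed <- .deriveSeed(seed, "permutation")
  rewireSeed <- .deriveSeed(seed, "rewire")
  results <- lapply(universes, function(mods)
    .analyseUniverse(net, mods, ess, groupSize, nPerm, nRounds,
      oddsThreshold, swapsPerEdge, permSeed, rewireSeed, skipCrosstalk))
  manifest <- list(
    packageVersion = as.character(utils::packageVersion("modessence")),
    nProteins = length(proteins(net)),
    nInteractions = nrow(interactions(net)),
    universes = names(universes),
    config = list(groupSize = groupSize, nPerm = nPerm,
      nRounds = nRounds, oddsThreshold = oddsThreshold,
      swapsPerEdge = swapsPerEdge, seed = seed,
      derivedSeeds = list(permutation = permSeed, rewire = rewireSeed),
      skipCrosstalk = skipCrosstalk))
  structure(list(results = results, manifest = manifest),
    class = "modessenceReport")
}

#' @export
print.modessenceReport <- function(x, ...) {
  cat("modessence report:", length(x$results), "module universe(s):",
    paste(names(x$results), collapse = ", "), "\n")
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(" ", nm, ": permutation p =",
      format(r$permutationTest$empiricalP, digits = 3))
    if (!is.null(r$crosstalk))
      cat("; cross-talks =", nrow(crosstalkEdges(r$crosstalk$network)))
    cat("\n")
  }
  invisible(x)
}

#' Write a report bundle as TSV tables and a JSON manifest
#'
#' Emits, per module universe: the degree table, the hub curves, the
#' correlation table, the Wilcoxon summaries, a one-row permutation
#' table (complexes tested, complexes with higher essential degree,
#' empirical p), and the cross-talk node/edge tables plus a one-row
#' summary (number of cross-talks, number of modules with at least one
#' cross-talk, fraction of those containing an essential protein). An
#' empty module network still produces a summary row of zeros.
#'
#' @param report result of \code{\link{runPipeline}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeResultTables <- function(report, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  paths <- character()
  emit <- function(df, name) {
    p <- file.path(dir, name)
    .writeTsv(df, p)
    paths <<- c(paths, p)
  }
  for (nm in names(report$results)) {
    r <- report$results[[nm]]
    emit(r$degreeTable, sprintf("degrees_%s.tsv", nm))
    for (f in names(r$hubCurves))
      emit(r$hubCurves[[f]], sprintf("hubcurve_%s_%s.tsv", nm, f))
    emit(r$correlations, sprintf("correlations_%s.tsv", nm))
    wil <- do.call(rbind, lapply(names(r$wilcoxon), function(f)
      data.frame(degree = f, statistic = r$wilcoxon[[f]]$statistic,
        p.value = r$wilcoxon[[f]]$p.value)))
    emit(wil, sprintf("wilcoxon_%s.tsv", nm))
    pt <- r$permutationTest
    emit(data.frame(universe = nm, nComplexesTested = pt$nComplexesTested,
      nHigherEssential = pt$nHigherEssential,
      empiricalP = pt$empiricalP), sprintf("permutation_%s.tsv", nm))
    if (!is.null(r$crosstalk)) {
      mn <- r$crosstalk$network
      nodes <- moduleNodes(mn)
      emit(crosstalkEdges(mn), sprintf("crosstalk_edges_%s.tsv", nm))
      emit(nodes, sprintf("crosstalk_nodes_%s.tsv", nm))
      active <- nodes[nodes$crosstalkDegree > 0L, , drop = FALSE]
      emit(data.frame(universe = nm,
        nCrosstalks = nrow(crosstalkEdges(mn)),
        nModules = nrow(active),
        fractionEssentialModules = if (nrow(active))
          mean(active$binaryEssential) else 0),
        sprintf("crosstalk_summary_%s.tsv", nm))
    }
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(report$manifest, mp, auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  invisible(c(paths, mp))
}
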