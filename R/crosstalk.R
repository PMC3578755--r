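# Cross-talk inference: counting, stub-rewiring null, odds-scores,
# module-network construction and essentiality analysis.

#' Count cross-talk interactions between two modules
#'
#' Counts edges with one endpoint in \code{m1} and the other in
#' \code{m2}, excluding edges with an endpoint annotated with both
#' modules (those are intramodular).
#'
#' @param net an \code{\link{Interactome}}.
#' @param m1,m2 character vectors: the two modules' member sets (must
#'   denote different modules).
#' @return integer count.
#' @export
countCrosstalk <- function(net, m1, m2) {
  e <- interactions(net)
  both <- intersect(m1, m2)
  fwd <- e[, 1] %in% m1 & e[, 2] %in% m2
  rev <- e[, 1] %in% m2 & e[, 2] %in% m1
  hit <- (fwd | rev) & !(e[, 1] %in% both) & !(e[, 2] %in% both)
  sum(hit)
}

#' Do the supporting edges contain two vertex-disjoint interactions?
#'
#' A module pair only counts as a cross-talk if it is supported by at
#' least two independent (non-overlapping) interactions, i.e. the
#' supporting edge set has matching number >= 2. An edge set has
#' matching number <= 1 exactly when it is a star (all edges share one
#' vertex) or a triangle.
#'
#' @param edges two-column matrix of supporting edges.
#' @return logical flag.
#' @export
hasIndependentPair <- function(edges) {
  edges <- as.matrix(edges)
  if (nrow(edges) < 2L) return(FALSE)
  common <- intersect(edges[1, ], edges[2, ])
  for (i in seq_len(nrow(edges))) {
    common <- intersect(common, edges[i, ])
    if (!length(common)) break
  }
  if (length(common)) return(FALSE)          # star
  length(unique(c(edges))) > 3L              # triangle otherwise
}

#' Pseudocounted odds-score of a module pair
#'
#' \eqn{(n_{real} + 1) / (n_{rand} + 1)}: the ratio of observed to
#' mean-randomised cross-talk interaction counts, with a pseudocount of
#' 1 that downweighs very rare cross-talks whose randomised means are
#' near zero.
#'
#' @param nReal observed cross-talk interaction count(s).
#' @param nRandMean mean count(s) over randomised networks.
#' @return numeric odds-score(s), monotone increasing in \code{nReal}
#'   and decreasing in \code{nRandMean}.
#' @export
oddsScore <- function(nReal, nRandMean) {
  stopifnot(all(nRandMean >= 0))
  (nReal + 1) / (nRandMean + 1)
}

# --- internal integer-indexed machinery -------------------------------

# integer protein indices, integer module membership, intermodular edges
.crosstalkSetup <- function(net, modules) {
  prots <- proteins(net)
  mids <- moduleIds(modules)
  memb <- .membershipIndex(modules)
  membInt <- lapply(prots, function(p) {
    m <- memb[[p]]
    if (is.null(m)) integer() else sort(match(m, mids))
  })
  e <- interactions(net)
  eInt <- cbind(match(e[, 1], prots), match(e[, 2], prots))
  cls <- classifyEdges(e, modules)
  list(proteins = prots, moduleIds = mids, membInt = membInt,
    interEdges = eInt[cls == "intermodular", , drop = FALSE])
}

# counts per unordered module pair for an integer edge matrix; keys are
# (lo - 1) * K + hi. For globally intermodular edges the "endpoint in
# both modules" exclusion is automatic (endpoint module sets are
# disjoint), so every (module of u) x (module of v) pair counts.
.pairKeyCounts <- function(eInt, membInt, K) {
  if (!nrow(eInt)) return(integer())
  Mu <- membInt[eInt[, 1]]
  Mv <- membInt[eInt[, 2]]
  lu <- lengths(Mu)
  lv <- lengths(Mv)
  if (all(lu == 1L) && all(lv == 1L)) {
    m1 <- unlist(Mu, use.names = FALSE)
    m2 <- unlist(Mv, use.names = FALSE)
  } else {
    m1 <- unlist(mapply(function(x, y) rep(x, each = length(y)), Mu, Mv,
      SIMPLIFY = FALSE), use.names = FALSE)
    m2 <- unlist(mapply(function(x, y) rep(y, times = length(x)), Mu, Mv,
      SIMPLIFY = FALSE), use.names = FALSE)
  }
  key <- (pmin(m1, m2) - 1) * K + pmax(m1, m2)
  cnt <- table(key)
  out <- as.integer(cnt)
  names(out) <- names(cnt)
  out
}

#' Randomise the intermodular edges of a network by stub-rewiring
#'
#' Produces degree-preserving randomisations of the intermodular edge
#' set (edges whose module-annotated endpoints share no module). Each
#' round starts from the observed intermodular edges and applies
#' \code{swapsPerEdge * |E|} proposed double-edge swaps; proposals that
#' would create a self-loop, a duplicate edge, or an edge whose
#' endpoints share a module are rejected, so every round preserves each
#' protein's intermodular degree exactly, the module annotation, and the
#' total number of cross-talk interactions. Rounds are independent and
#' the sampler is uniform over the reachable valid configurations.
#'
#' @param net an \code{\link{Interactome}}.
#' @param modules a \code{\link{ModuleSet}}.
#' @param nRounds number of randomised rounds.
#' @param seed optional RNG seed.
#' @param swapsPerEdge proposed swaps per edge per round.
#' @return list of \code{nRounds} two-column character matrices, each a
#'   randomised intermodular edge set.
#' @export
stubRewireIntermodular <- function(net, modules, nRounds = 100,
    seed = NULL, swapsPerEdge = 10) {
  setup <- .crosstalkSetup(net, modules)
  if (!nrow(setup$interEdges))
    stop("the intermodular edge set is empty; nothing to rewire")
  rounds <- .withSeed(seed,
    .rewireRoundsCpp(setup$interEdges - 1L, lapply(setup$membInt,
      function(x) x - 1L), length(setup$proteins), as.integer(nRounds),
      swapsPerEdge))
  lapply(rounds, function(em) {
    out <- cbind(setup$proteins[em[, 1] + 1L],
      setup$proteins[em[, 2] + 1L])
    .canonicalPairs(out[, 1], out[, 2])
  })
}

#' Infer a module-level cross-talk network
#'
#' For every module pair, counts the observed cross-talk interactions
#' and compares them with the average over \code{nRounds}
#' stub-rewired networks (the same randomised rounds are shared by all
#' pairs; a pair absent from a round counts 0 there). A pair becomes an
#' edge of the module network iff it has at least two vertex-disjoint
#' supporting interactions and odds-score at least
#' \code{oddsThreshold}. Module nodes carry their size, binary
#' essentiality (1 iff at least one member is essential), fraction of
#' essential members, cross-talk degree (number of accepted partners)
#' and normalised cross-talk degree (degree / size).
#'
#' @param net an \code{\link{Interactome}}.
#' @param modules a \code{\link{ModuleSet}}.
#' @param ess an \code{\link{EssentialityMap}} (or \code{NULL}: all
#'   essentiality fields become \code{NA}/0).
#' @param oddsThreshold minimum odds-score for acceptance.
#' @param nRounds number of randomisation rounds.
#' @param seed optional RNG seed.
#' @param swapsPerEdge proposed swaps per edge per round.
#' @return a \code{\link{ModuleNetwork}}.
#' @export
inferCrosstalkNetwork <- function(net, modules, ess = NULL,
    oddsThreshold = 5, nRounds = 100, seed = NULL, swapsPerEdge = 10) {
  setup <- .crosstalkSetup(net, modules)
  K <- length(setup$moduleIds)
  eInt <- setup$interEdges
  realCnt <- .pairKeyCounts(eInt, setup$membInt, K)
  keys <- names(realCnt)
  randSum <- numeric(length(keys))
  names(randSum) <- keys
  if (nrow(eInt) && nRounds > 0) {
    rounds <- .withSeed(seed,
      .rewireRoundsCpp(eInt - 1L,
        lapply(setup$membInt, function(x) x - 1L),
        length(setup$proteins), as.integer(nRounds), swapsPerEdge))
    for (em in rounds) {
      cnt <- .pairKeyCounts(em + 1L, setup$membInt, K)
      hit <- match(names(cnt), keys)
      ok <- !is.na(hit)
      randSum[hit[ok]] <- randSum[hit[ok]] + cnt[ok]
    }
  }
  nRandMean <- if (nRounds > 0) randSum / nRounds else randSum

  # independence flag on the real supporting edges of each pair
  key <- as.numeric(keys)
  lo <- (key - 1) %/% K + 1
  hi <- (key - 1) %% K + 1
  mem <- moduleMembers(modules)
  e <- interactions(net)
  indep <- logical(length(keys))
  for (i in seq_along(keys)) {
    mA <- mem[[lo[i]]]
    mB <- mem[[hi[i]]]
    both <- intersect(mA, mB)
    hitE <- ((e[, 1] %in% mA & e[, 2] %in% mB) |
             (e[, 1] %in% mB & e[, 2] %in% mA)) &
      !(e[, 1] %in% both) & !(e[, 2] %in% both)
    # keep only globally intermodular support, consistent with counting
    cls <- classifyEdges(e[hitE, , drop = FALSE], modules)
    indep[i] <- hasIndependentPair(
      e[hitE, , drop = FALSE][cls == "intermodular", , drop = FALSE])
  }

  pairs <- data.frame(
    m1 = setup$moduleIds[lo], m2 = setup$moduleIds[hi],
    nReal = as.integer(realCnt), nRandMean = as.numeric(nRandMean),
    odds = oddsScore(as.integer(realCnt), as.numeric(nRandMean)),
    independent = indep)
  pairs <- pairs[order(-pairs$odds, pairs$m1, pairs$m2), , drop = FALSE]
  rownames(pairs) <- NULL
  .assembleModuleNetwork(pairs, modules, ess,
    params = list(oddsThreshold = oddsThreshold, nRounds = nRounds,
      seed = seed, swapsPerEdge = swapsPerEdge))
}

.assembleModuleNetwork <- function(pairs, modules, ess, params) {
  accepted <- pairs[pairs$independent &
    pairs$odds >= params$oddsThreshold, , drop = FALSE]
  mem <- moduleMembers(modules)
  sizes <- lengths(mem)
  essSet <- if (is.null(ess)) character() else essentialProteins(ess)
  nEss <- vapply(mem, function(x) sum(x %in% essSet), 0L)
  deg <- integer(length(mem))
  names(deg) <- moduleIds(modules)
  if (nrow(accepted)) {
    tab <- table(c(accepted$m1, accepted$m2))
    deg[names(tab)] <- as.integer(tab)
  }
  nodes <- data.frame(module = moduleIds(modules),
    size = as.integer(sizes),
    binaryEssential = as.integer(nEss > 0L),
    fracEssential = nEss / sizes,
    crosstalkDegree = as.integer(deg),
    normalizedDegree = as.numeric(deg) / sizes)
  rownames(nodes) <- NULL
  new("ModuleNetwork", nodes = nodes, edges = accepted, pairs = pairs,
    params = params)
}

#' Re-threshold a module network
#'
#' Recomputes the accepted cross-talks and module degrees of an
#' inferred \code{\link{ModuleNetwork}} at a different odds-score
#' threshold, without re-randomising. Raising the threshold can only
#' remove edges.
#'
#' @param mn a \code{\link{ModuleNetwork}}.
#' @param modules the \code{\link{ModuleSet}} it was built from.
#' @param ess the \code{\link{EssentialityMap}} (or \code{NULL}).
#' @param oddsThreshold the new threshold.
#' @return a \code{\link{ModuleNetwork}}.
#' @export
applyOddsThreshold <- function(mn, modules, ess, oddsThreshold) {
  params <- mn@params
  params$oddsThreshold <- oddsThreshold
  .assembleModuleNetwork(mn@pairs, modules, ess, params)
}

#' Relate module cross-talk degree to module essentiality
#'
#' Reports the rank correlation between binary module essentiality and
#' cross-talk degree; the partial correlation controlling for module
#' size; correlations with the normalised degree and with the fraction
#' of essential members; a Wilcoxon rank-sum comparison of the degree
#' distributions of essential vs non-essential modules; and the
#' hub-module fraction curve (modules added in groups of
#' \code{groupSize} by non-increasing cross-talk degree). Degenerate
#' inputs (e.g. every module essential) leave the binary correlations
#' flagged undefined while the fraction-essential variant is still
#' computed.
#'
#' @param mn a \code{\link{ModuleNetwork}}.
#' @param groupSize group size for the hub-module curve.
#' @param includeZeroDegree include modules with no accepted cross-talk
#'   (default) or restrict to modules with at least one.
#' @return list of correlation results (see \code{\link{spearmanRcc}}),
#'   the Wilcoxon comparison and the hub curve.
#' @export
crosstalkEssentialityAnalysis <- function(mn, groupSize = 20,
    includeZeroDegree = TRUE) {
  nodes <- moduleNodes(mn)
  if (!includeZeroDegree)
    nodes <- nodes[nodes$crosstalkDegree > 0L, , drop = FALSE]
  if (nrow(nodes) < 4L)
    stop("need at least four modules with degrees")
  bin <- nodes$binaryEssential
  deg <- nodes$crosstalkDegree
  degenerate <- length(unique(bin)) < 2L
  safe <- function(expr) {
    tryCatch(suppressWarnings(expr), error = function(e)
      list(rho = NA_real_, p.value = NA_real_, n = nrow(nodes),
        controlledFor = NA_character_, undefined = TRUE))
  }
  wil <- if (degenerate) {
    list(statistic = NA_real_, p.value = NA_real_, exact = NA)
  } else {
    wilcoxonRankSum(deg[bin == 1L], deg[bin == 0L])
  }
  list(
    srccBinary = safe(spearmanRcc(bin, deg)),
    srccPartialSize = safe(partialSpearman(bin, deg, nodes$size)),
    srccNormalized = safe(spearmanRcc(bin, nodes$normalizedDegree)),
    srccFracEssential = safe(spearmanRcc(nodes$fracEssential, deg)),
    wilcoxon = wil,
    hubCurve = hubFractionCurve(
      data.frame(essential = as.logical(bin), degree = deg),
      "degree", groupSize = groupSize))
}

#' Drop cross-talks between functionally related modules
#'
#' Annotates every module with the expert-selected (slim) terms carried
#' by at least \code{annotationFraction} of its members (propagated
#' annotations; only slim terms annotating at most \code{maxSlimSize}
#' proteins are considered), then removes cross-talk edges whose two
#' modules share a slim annotation and recomputes the module degrees.
#'
#' @param mn a \code{\link{ModuleNetwork}}.
#' @param modules the \code{\link{ModuleSet}} it was built from.
#' @param ess the \code{\link{EssentialityMap}} (or \code{NULL}).
#' @param slimTerms character vector of expert-selected term ids.
#' @param ann a propagated \code{\link{AnnotationSet}}.
#' @param annotationFraction membership fraction required to annotate a
#'   module with a term.
#' @param maxSlimSize largest annotation count for a usable slim term.
#' @return a \code{\link{ModuleNetwork}} with the related cross-talks
#'   removed.
#' @export
filterFunctionallyRelated <- function(mn, modules, ess, slimTerms, ann,
    annotationFraction = 0.5, maxSlimSize = 500) {
  tc <- termCounts(ann)
  slimTerms <- slimTerms[slimTerms %in% names(tc) &
    tc[slimTerms] <= maxSlimSize]
  prop <- propagatedAnnotations(ann)
  prot <- rep(names(prop), lengths(prop))
  term <- unlist(prop, use.names = FALSE)
  withTerm <- split(prot[term %in% slimTerms],
    factor(term[term %in% slimTerms], levels = slimTerms))
  mem <- moduleMembers(modules)
  slimOf <- lapply(mem, function(m) {
    frac <- vapply(withTerm, function(ps)
      sum(m %in% ps) / length(m), 0)
    slimTerms[frac >= annotationFraction]
  })
  pairs <- mn@pairs
  related <- mapply(function(a, b)
    length(intersect(slimOf[[a]], slimOf[[b]])) > 0L,
    pairs$m1, pairs$m2)
  params <- mn@params
  params$slimFiltered <- TRUE
  .assembleModuleNetwork(pairs[!related, , drop = FALSE], modules, ess,
    params)
}
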