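# Interaction classification, degree statistics, hub-fraction curves.

#' Classify edges relative to a module universe
#'
#' An edge is \emph{unannotated} unless both endpoints belong to at
#' least one module; \emph{intramodular} if the endpoints share a
#' module; \emph{intermodular} otherwise. Classification is symmetric in
#' the two endpoints.
#'
#' @param edges a two-column character matrix of protein pairs, or an
#'   \code{\link{Interactome}}.
#' @param modules a \code{\link{ModuleSet}}.
#' @return factor with levels \code{intramodular}, \code{intermodular},
#'   \code{unannotated}, one per edge.
#' @export
classifyEdges <- function(edges, modules) {
  if (is(edges, "Interactome")) edges <- interactions(edges)
  memb <- .membershipIndex(modules)
  Mu <- memb[edges[, 1]]
  Mv <- memb[edges[, 2]]
  annotated <- lengths(Mu) > 0L & lengths(Mv) > 0L
  # treat missing proteins as unannotated
  annotated[is.na(annotated)] <- FALSE
  share <- rep(FALSE, nrow(edges))
  share[annotated] <- mapply(function(x, y) any(x %in% y),
    Mu[annotated], Mv[annotated], USE.NAMES = FALSE)
  out <- ifelse(!annotated, "unannotated",
    ifelse(share, "intramodular", "intermodular"))
  factor(out, levels = c("intramodular", "intermodular", "unannotated"))
}

#' Per-protein degree statistics against a module universe
#'
#' For every protein in the (optionally restricted) network the table
#' reports its intramodular, intermodular and total annotated degrees;
#' the size of the largest module containing it; its degree counted only
#' inside that largest module; and the normalised intramodular degree
#' (degree in the largest module divided by that module's size,
#' including the protein itself). Each edge counts once per protein no
#' matter how many shared modules cover it. When multiple containing
#' modules tie for largest, the lexicographically smallest module id is
#' used.
#'
#' @param net an \code{\link{Interactome}}.
#' @param modules a \code{\link{ModuleSet}}.
#' @param ess optional \code{\link{EssentialityMap}}; essentiality is
#'   \code{NA} for untested proteins.
#' @param restrictToModuleMembers analyse the induced subnetwork on
#'   module members only (the "complex subnetwork"); proteins in no
#'   module are excluded from the table.
#' @return data.frame with one row per protein: \code{protein},
#'   \code{intra}, \code{inter}, \code{totalAnnotated},
#'   \code{largestModule}, \code{largestModuleSize},
#'   \code{intraInLargest}, \code{normalizedIntra}, \code{essential}.
#' @export
computeDegrees <- function(net, modules, ess = NULL,
    restrictToModuleMembers = FALSE) {
  nodes <- proteins(net)
  e <- interactions(net)
  if (restrictToModuleMembers) {
    memberSet <- universe(modules)
    nodes <- intersect(nodes, memberSet)
    e <- e[e[, 1] %in% memberSet & e[, 2] %in% memberSet, , drop = FALSE]
  }
  cls <- classifyEdges(e, modules)
  tallies <- function(lab) {
    idx <- cls == lab
    tab <- table(factor(c(e[idx, 1], e[idx, 2]), levels = nodes))
    as.integer(tab)
  }
  intra <- tallies("intramodular")
  inter <- tallies("intermodular")

  memb <- .membershipIndex(modules)
  sizes <- moduleSizes(modules)
  largest <- vapply(nodes, function(p) {
    m <- memb[[p]]
    if (is.null(m) || !length(m)) return(NA_character_)
    s <- sizes[m]
    cand <- m[s == max(s)]
    sort(cand)[1]
  }, "", USE.NAMES = FALSE)
  largestSize <- ifelse(is.na(largest), NA_integer_, sizes[largest])

  # degree inside the largest module only
  mem <- moduleMembers(modules)
  adj <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = nodes))
  intraLargest <- mapply(function(p, lm) {
    if (is.na(lm)) return(NA_integer_)
    if (!(p %in% mem[[lm]])) return(NA_integer_)
    sum(adj[[p]] %in% mem[[lm]])
  }, nodes, largest, USE.NAMES = FALSE)

  essential <- rep(NA, length(nodes))
  if (!is.null(ess)) {
    essential[nodes %in% testedProteins(ess)] <- FALSE
    essential[nodes %in% essentialProteins(ess)] <- TRUE
  }
  data.frame(protein = nodes, intra = intra, inter = inter,
    totalAnnotated = intra + inter, largestModule = largest,
    largestModuleSize = as.integer(largestSize),
    intraInLargest = as.integer(intraLargest),
    normalizedIntra = as.integer(intraLargest) / as.integer(largestSize),
    essential = essential)
}

#' Cumulative hub-fraction curve
#'
#' Orders proteins by non-increasing degree, adds them in groups of
#' \code{groupSize} and reports, at each cut, the cumulative fraction of
#' essential proteins among those considered. With
#' \code{extendTies = TRUE}, a group is extended so that proteins of
#' equal degree never straddle a group boundary. A final partial group
#' is reported when the table size is not a multiple of
#' \code{groupSize}. Proteins with unknown (NA) essentiality are
#' excluded.
#'
#' @param table a degree table from \code{\link{computeDegrees}} (or any
#'   data.frame with the named degree column and an \code{essential}
#'   column).
#' @param degreeField name of the degree column to rank by.
#' @param groupSize number of proteins added per step.
#' @param extendTies keep tied degrees within one group.
#' @return data.frame with columns \code{nConsidered} and
#'   \code{fractionEssential}; empty for an empty table.
#' @export
hubFractionCurve <- function(table, degreeField, groupSize = 50,
    extendTies = FALSE) {
  keep <- !is.na(table$essential) & !is.na(table[[degreeField]])
  deg <- table[[degreeField]][keep]
  ess <- as.logical(table$essential[keep])
  n <- length(deg)
  if (n == 0L)
    return(data.frame(nConsidered = integer(), fractionEssential = numeric()))
  ord <- order(-deg)
  deg <- deg[ord]
  ess <- ess[ord]
  cuts <- integer()
  i <- 0L
  while (i < n) {
    i <- min(i + groupSize, n)
    if (extendTies) while (i < n && deg[i + 1L] == deg[i]) i <- i + 1L
    cuts <- c(cuts, i)
  }
  data.frame(nConsidered = cuts,
    fractionEssential = cumsum(ess)[cuts] / cuts)
}
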