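#' @import methods
NULL

.canonicalPairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  cbind(a = a, b = b)
}

.edgeKeys <- function(edges) paste(edges[, 1], edges[, 2], sep = "\r")

#' Interactome: an undirected simple protein interaction graph
#'
#' An \code{Interactome} stores a simple undirected graph over protein
#' identifiers together with per-edge provenance: the experimental system,
#' the source (publication/experiment) identifier and, where known, the
#' bait protein of each supporting record. Records supporting the same
#' protein pair collapse to a single edge; all their provenance rows are
#' retained.
#'
#' @slot proteins character vector of protein identifiers (the node set).
#' @slot edges two-column character matrix of unordered protein pairs,
#'   stored with \code{a <= b}; no self-loops, no duplicates.
#' @slot provenance data.frame with columns \code{a}, \code{b},
#'   \code{system}, \code{source}, \code{bait}; one row per supporting
#'   record, pair columns in canonical order.
#'
#' @exportClass Interactome
setClass("Interactome",
  slots = c(proteins = "character", edges = "matrix", provenance = "data.frame"))

setValidity("Interactome", function(object) {
  e <- object@edges
  if (ncol(e) != 2L) return("edges must have two columns")
  if (nrow(e)) {
    if (!is.character(e)) return("edges must be a character matrix")
    if (any(e[, 1] == e[, 2])) return("self-loops are not allowed")
    if (any(e[, 1] > e[, 2])) return("edges must be stored with a <= b")
    if (anyDuplicated(.edgeKeys(e))) return("duplicate edges are not allowed")
    if (!all(c(e) %in% object@proteins))
      return("every edge endpoint must be listed in proteins")
  }
  if (anyDuplicated(object@proteins)) return("duplicated protein ids")
  TRUE
})

#' Construct an Interactome from an edge table
#'
#' @param edges two-column character matrix or data.frame of protein pairs.
#' @param proteins optional node set; defaults to the edge endpoints.
#' @param provenance optional provenance data.frame (columns \code{a},
#'   \code{b}, \code{system}, \code{source}, \code{bait}).
#' @return an \code{Interactome}.
#' @export
Interactome <- function(edges, proteins = NULL, provenance = NULL) {
  edges <- as.matrix(edges)
  mode(edges) <- "character"
  if (nrow(edges)) {
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    edges <- .canonicalPairs(edges[, 1], edges[, 2])
    edges <- edges[!duplicated(.edgeKeys(edges)), , drop = FALSE]
    edges <- edges[order(edges[, 1], edges[, 2], method = "radix"), , drop = FALSE]
  } else {
    edges <- matrix(character(), 0, 2, dimnames = list(NULL, c("a", "b")))
  }
  if (is.null(proteins)) proteins <- sort(unique(c(edges)))
  if (is.null(provenance)) {
    provenance <- data.frame(a = edges[, 1], b = edges[, 2],
      system = rep(NA_character_, nrow(edges)),
      source = rep(NA_character_, nrow(edges)),
      bait = rep(NA_character_, nrow(edges)))
  }
  new("Interactome", proteins = proteins, edges = edges,
    provenance = provenance)
}

#' EssentialityMap: proteins tested for essentiality
#'
#' @slot tested character vector of proteins assayed in a deletion screen.
#' @slot essential subset of \code{tested} whose deletion is lethal.
#' @exportClass EssentialityMap
setClass("EssentialityMap",
  slots = c(tested = "character", essential = "character"))

setValidity("EssentialityMap", function(object) {
  if (!all(object@essential %in% object@tested))
    return("essential proteins must be a subset of tested proteins")
  if (anyDuplicated(object@tested)) return("duplicated tested ids")
  TRUE
})

#' @param tested,essential character vectors of protein ids.
#' @rdname EssentialityMap-class
#' @export
EssentialityMap <- function(tested, essential) {
  new("EssentialityMap", tested = unique(as.character(tested)),
    essential = unique(as.character(essential)))
}

#' ModuleSet: a catalogue of functional modules
#'
#' A \code{ModuleSet} holds named protein sets over a shared namespace:
#' protein complexes, specific biological-process terms, or processes
#' filtered against the complex catalogue.
#'
#' @slot ids character vector of unique module identifiers.
#' @slot members named list (by id) of character vectors of protein ids.
#' @slot origin one of \code{"complex"}, \code{"process"},
#'   \code{"filtered_process"} per module.
#' @slot declaredSize for process modules, the full annotation count of
#'   the defining term (NA otherwise).
#' @exportClass ModuleSet
setClass("ModuleSet",
  slots = c(ids = "character", members = "list", origin = "character",
    declaredSize = "integer"))

setValidity("ModuleSet", function(object) {
  n <- length(object@ids)
  if (length(object@members) != n || length(object@origin) != n ||
      length(object@declaredSize) != n)
    return("slot lengths disagree")
  if (anyDuplicated(object@ids)) return("module ids must be unique")
  if (n && any(lengths(object@members) == 0L))
    return("modules must have at least one member")
  TRUE
})

#' @param members named list of protein-id vectors (names are module ids).
#' @param origin module origin label, recycled.
#' @param declaredSize optional declared annotation counts.
#' @rdname ModuleSet-class
#' @export
ModuleSet <- function(members, origin = "complex", declaredSize = NULL) {
  ids <- names(members)
  if (is.null(ids)) stop("members must be a named list")
  members <- lapply(members, function(x) sort(unique(as.character(x))))
  if (is.null(declaredSize)) declaredSize <- rep(NA_integer_, length(ids))
  new("ModuleSet", ids = ids, members = members,
    origin = rep(origin, length.out = length(ids)),
    declaredSize = as.integer(declaredSize))
}

#' Ontology: a term DAG
#'
#' @slot terms character vector of term ids (obsolete terms excluded).
#' @slot parents named list giving each term's direct parents
#'   (is_a and, optionally, part_of).
#' @slot termNamespace named character vector of per-term namespaces.
#' @slot termName named character vector of human-readable labels.
#' @exportClass Ontology
setClass("Ontology",
  slots = c(terms = "character", parents = "list",
    termNamespace = "character", termName = "character"))

setValidity("Ontology", function(object) {
  if (anyDuplicated(object@terms)) return("duplicated term ids")
  if (!all(names(object@parents) %in% object@terms))
    return("parents must be keyed by known terms")
  pu <- unlist(object@parents, use.names = FALSE)
  if (length(pu) && !all(pu %in% object@terms))
    return("parent terms must themselves be terms")
  TRUE
})

#' @param parents named list of parent-id vectors per term.
#' @param namespace per-term namespace labels (named or recycled).
#' @param name optional per-term labels.
#' @rdname Ontology-class
#' @export
Ontology <- function(parents, namespace = "biological_process", name = NULL) {
  terms <- names(parents)
  if (is.null(terms)) stop("parents must be a named list")
  ns <- rep(namespace, length.out = length(terms))
  names(ns) <- terms
  if (is.null(name)) {
    name <- terms
    names(name) <- terms
  }
  ont <- new("Ontology", terms = terms,
    parents = lapply(parents, as.character), termNamespace = ns,
    termName = name)
  cyc <- .findCycle(ont)
  if (!is.null(cyc))
    stop("cyclic parent structure: ", paste(cyc, collapse = " -> "))
  ont
}

# returns NULL if acyclic, else one cycle as a character vector
.findCycle <- function(ontology) {
  state <- new.env(parent = emptyenv())
  for (t in ontology@terms) assign(t, 0L, envir = state)  # 0 new, 1 open, 2 done
  path <- character()
  visit <- function(t) {
    s <- get(t, envir = state)
    if (s == 1L) {
      i <- match(t, path)
      return(c(path[i:length(path)], t))
    }
    if (s == 2L) return(NULL)
    assign(t, 1L, envir = state)
    path <<- c(path, t)
    for (p in ontology@parents[[t]]) {
      res <- visit(p)
      if (!is.null(res)) return(res)
    }
    path <<- path[-length(path)]
    assign(t, 2L, envir = state)
    NULL
  }
  for (t in ontology@terms) {
    res <- visit(t)
    if (!is.null(res)) return(res)
  }
  NULL
}

#' AnnotationSet: protein-to-term annotations
#'
#' Direct annotations come from a GAF file or generator; propagated
#' annotations are closed under ontology ancestors (the true-path rule).
#' Term counts are computed on the propagated sets.
#'
#' @slot direct named list, protein -> direct term ids.
#' @slot propagated named list, protein -> ancestor-closed term ids
#'   (empty until \code{\link{propagateAnnotations}} is called).
#' @slot termCount named integer vector of propagated annotation counts.
#' @slot proteomeSize reference proteome size used for term probabilities.
#' @exportClass AnnotationSet
setClass("AnnotationSet",
  slots = c(direct = "list", propagated = "list", termCount = "integer",
    proteomeSize = "integer"))

setValidity("AnnotationSet", function(object) {
  if (length(object@propagated)) {
    if (!identical(names(object@propagated), names(object@direct)))
      return("propagated must be keyed like direct")
    ok <- mapply(function(d, p) all(d %in% p), object@direct,
      object@propagated)
    if (!all(ok)) return("direct annotations must be within propagated")
  }
  if (length(object@proteomeSize) != 1L || is.na(object@proteomeSize) ||
      object@proteomeSize < 0L)
    return("proteomeSize must be a single nonnegative integer")
  TRUE
})

#' @param direct named list, protein -> term ids.
#' @param proteomeSize reference proteome size; defaults to the number of
#'   annotated proteins.
#' @rdname AnnotationSet-class
#' @export
AnnotationSet <- function(direct, proteomeSize = NULL) {
  direct <- lapply(direct, function(x) sort(unique(as.character(x))))
  if (is.null(proteomeSize)) proteomeSize <- length(direct)
  new("AnnotationSet", direct = direct, propagated = list(),
    termCount = integer(), proteomeSize = as.integer(proteomeSize))
}

#' ModuleNetwork: an inferred cross-talk network over modules
#'
#' Nodes are modules annotated with size and essentiality; edges are
#' module pairs accepted as cross-talks (at least two vertex-disjoint
#' supporting interactions and odds-score at or above the threshold).
#'
#' @slot nodes data.frame: module, size, binaryEssential, fracEssential,
#'   crosstalkDegree, normalizedDegree.
#' @slot edges data.frame of accepted cross-talks: m1, m2, nReal,
#'   nRandMean, odds, independent.
#' @slot pairs data.frame of all module pairs with at least one observed
#'   cross-talk interaction (pre-threshold), same columns as edges.
#' @slot params list echoing the inference parameters.
#' @exportClass ModuleNetwork
setClass("ModuleNetwork",
  slots = c(nodes = "data.frame", edges = "data.frame",
    pairs = "data.frame", params = "list"))

setValidity("ModuleNetwork", function(object) {
  need <- c("module", "size", "binaryEssential", "fracEssential",
    "crosstalkDegree", "normalizedDegree")
  if (!all(need %in% names(object@nodes)))
    return("nodes is missing required columns")
  TRUE
})
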