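# Accessors and show methods.

#' @rdname Interactome-class
#' @export
setMethod("proteins", "Interactome", function(x) x@proteins)

#' @rdname Interactome-class
#' @export
setMethod("interactions", "Interactome", function(x) x@edges)

#' @rdname Interactome-class
#' @export
setMethod("provenance", "Interactome", function(x) x@provenance)

setMethod("show", "Interactome", function(object) {
  cat("Interactome with", length(object@proteins), "proteins and",
    nrow(object@edges), "interactions\n")
  src <- unique(object@provenance$source)
  src <- src[!is.na(src)]
  if (length(src))
    cat("  provenance:", nrow(object@provenance), "records from",
      length(src), "sources\n")
})

#' @rdname EssentialityMap-class
#' @export
setMethod("testedProteins", "EssentialityMap", function(x) x@tested)

#' @rdname EssentialityMap-class
#' @export
setMethod("essentialProteins", "EssentialityMap", function(x) x@essential)

setMethod("show", "EssentialityMap", function(object) {
  cat("EssentialityMap:", length(object@tested), "tested proteins,",
    length(object@essential), "essential\n")
})

#' @rdname ModuleSet-class
#' @export
setMethod("moduleIds", "ModuleSet", function(x) x@ids)

#' @rdname ModuleSet-class
#' @export
setMethod("moduleMembers", "ModuleSet", function(x) x@members)

#' @rdname ModuleSet-class
#' @export
setMethod("moduleOrigin", "ModuleSet", function(x) x@origin)

#' @rdname ModuleSet-class
#' @export
setMethod("moduleSizes", "ModuleSet", function(x) {
  n <- lengths(x@members)
  names(n) <- x@ids
  n
})

#' @rdname ModuleSet-class
#' @export
setMethod("universe", "ModuleSet",
  function(x) sort(unique(unlist(x@members, use.names = FALSE))))

setMethod("show", "ModuleSet", function(object) {
  sz <- lengths(object@members)
  cat("ModuleSet with", length(object@ids), "modules (",
    paste(unique(object@origin), collapse = "/"), ")\n")
  if (length(sz))
    cat("  sizes:", min(sz), "-", max(sz), "; universe:",
      length(universe(object)), "proteins\n")
})

#' Subset a ModuleSet by module id
#'
#' @param x a \code{ModuleSet}.
#' @param i character or integer index of modules to keep.
#' @return a \code{ModuleSet}.
#' @export
setMethod("[", "ModuleSet", function(x, i) {
  if (is.character(i)) i <- match(i, x@ids)
  new("ModuleSet", ids = x@ids[i], members = x@members[i],
    origin = x@origin[i], declaredSize = x@declaredSize[i])
})

#' @rdname Ontology-class
#' @export
setMethod("termIds", "Ontology", function(x) x@terms)

#' @rdname Ontology-class
#' @export
setMethod("termParents", "Ontology", function(x) x@parents)

#' @rdname Ontology-class
#' @export
setMethod("ontologyRoots", "Ontology",
  function(x) x@terms[lengths(x@parents[x@terms]) == 0L])

setMethod("show", "Ontology", function(object) {
  cat("Ontology with", length(object@terms), "terms (",
    paste(unique(object@termNamespace), collapse = ", "), "),",
    length(ontologyRoots(object)), "root(s)\n")
})

#' @rdname AnnotationSet-class
#' @export
setMethod("directAnnotations", "AnnotationSet", function(x) x@direct)

#' @rdname AnnotationSet-class
#' @export
setMethod("propagatedAnnotations", "AnnotationSet", function(x) {
  if (!length(x@propagated))
    stop("annotations have not been propagated; call propagateAnnotations()")
  x@propagated
})

#' @rdname AnnotationSet-class
#' @export
setMethod("termCounts", "AnnotationSet", function(x) x@termCount)

#' @rdname AnnotationSet-class
#' @export
setMethod("proteomeSize", "AnnotationSet", function(x) x@proteomeSize)

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet:", length(object@direct), "annotated proteins;",
    "proteome size", object@proteomeSize, "\n")
  if (length(object@propagated))
    cat("  propagated over", length(object@termCount), "terms\n")
  else cat("  (direct annotations only; not yet propagated)\n")
})

#' @rdname ModuleNetwork-class
#' @export
setMethod("moduleNodes", "ModuleNetwork", function(x) x@nodes)

#' @rdname ModuleNetwork-class
#' @export
setMethod("crosstalkEdges", "ModuleNetwork", function(x) x@edges)

#' @rdname ModuleNetwork-class
#' @export
setMethod("crosstalkPairs", "ModuleNetwork", function(x) x@pairs)

setMethod("show", "ModuleNetwork", function(object) {
  cat("ModuleNetwork:", nrow(object@nodes), "modules,",
    nrow(object@edges), "accepted cross-talks\n")
  if (nrow(object@edges)) {
    deg <- object@nodes$crosstalkDegree
    cat("  modules with >=1 cross-talk:", sum(deg > 0),
      "; fraction essential among them:",
      round(mean(object@nodes$binaryEssential[deg > 0]), 3), "\n")
  }
})
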