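#' @rdname Interactome-class
#' @param object,x an object.
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @rdname Interactome-class
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' @rdname Interactome-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname EssentialityMap-class
#' @export
setGeneric("testedProteins", function(x) standardGeneric("testedProteins"))

#' @rdname EssentialityMap-class
#' @export
setGeneric("essentialProteins",
  function(x) standardGeneric("essentialProteins"))

#' @rdname ModuleSet-class
#' @export
setGeneric("moduleIds", function(x) standardGeneric("moduleIds"))

#' @rdname ModuleSet-class
#' @export
setGeneric("moduleMembers", function(x) standardGeneric("moduleMembers"))

#' @rdname ModuleSet-class
#' @export
setGeneric("moduleOrigin", function(x) standardGeneric("moduleOrigin"))

#' @rdname ModuleSet-class
#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))

#' @rdname ModuleSet-class
#' @export
setGeneric("universe", function(x) standardGeneric("universe"))

#' @rdname Ontology-class
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))

#' @rdname Ontology-class
#' @export
setGeneric("termParents", function(x) standardGeneric("termParents"))

#' @rdname Ontology-class
#' @export
setGeneric("ontologyRoots", function(x) standardGeneric("ontologyRoots"))

#' @rdname AnnotationSet-class
#' @export
setGeneric("directAnnotations",
  function(x) standardGeneric("directAnnotations"))

#' @rdname AnnotationSet-class
#' @export
setGeneric("propagatedAnnotations",
  function(x) standardGeneric("propagatedAnnotations"))

#' @rdname AnnotationSet-class
#' @export
setGeneric("termCounts", function(x) standardGeneric("termCounts"))

#' @rdname AnnotationSet-class
#' @export
setGeneric("proteomeSize", function(x) standardGeneric("proteomeSize"))

#' @rdname ModuleNetwork-class
#' @export
setGeneric("moduleNodes", function(x) standardGeneric("moduleNodes"))

#' @rdname ModuleNetwork-class
#' @export
setGeneric("crosstalkEdges", function(x) standardGeneric("crosstalkEdges"))

#' @rdname ModuleNetwork-class
#' @export
setGeneric("crosstalkPairs", function(x) standardGeneric("crosstalkPairs"))
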