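# OBO/GAF parsing, true-path propagation, specific-term selection.

#' Parse an OBO 1.2 ontology file
#'
#' Loads term stanzas with their \code{is_a} (and, by default,
#' \code{part_of}) parents. Obsolete terms are dropped, as are parent
#' references to terms not defined in the file. A cyclic parent
#' structure is a format error.
#'
#' @param path path to the OBO file.
#' @param includePartOf include \code{relationship: part_of} edges in the
#'   parent structure (standard true-path practice).
#' @return an \code{\link{Ontology}}.
#' @export
parseOBO <- function(path, includePartOf = TRUE) {
  lines <- readLines(path)
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("no stanzas found in OBO file: ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  ids <- character()
  parents <- list()
  ns <- character()
  nm <- character()
  for (k in seq_along(starts)) {
    if (lines[starts[k]] != "[Term]") next
    block <- lines[starts[k]:ends[k]]
    val <- function(tag) sub(paste0("^", tag, ":\\s*"), "",
      grep(paste0("^", tag, ":"), block, value = TRUE))
    if (length(val("is_obsolete")) && any(val("is_obsolete") == "true"))
      next
    id <- val("id")[1]
    if (is.na(id) || !nzchar(id)) next
    par <- sub("\\s*!.*$", "", val("is_a"))
    if (includePartOf) {
      rel <- sub("\\s*!.*$", "", val("relationship"))
      po <- grep("^part_of\\s", rel, value = TRUE)
      par <- c(par, sub("^part_of\\s+", "", po))
    }
    ids <- c(ids, id)
    parents[[id]] <- unique(trimws(par))
    v <- val("namespace")
    ns[id] <- if (length(v)) v[1] else NA_character_
    v <- val("name")
    nm[id] <- if (length(v)) v[1] else id
  }
  # drop references to undefined (e.g., obsolete) parents
  parents <- lapply(parents, function(p) p[p %in% ids])
  Ontology(parents[ids],
    namespace = ifelse(is.na(ns[ids]), "biological_process", ns[ids]),
    name = nm[ids])
}

#' Parse a GAF 2.x annotation file
#'
#' Builds the direct protein-to-term mapping from a tab-delimited Gene
#' Association File. Comment lines (\code{!}) are skipped, as are rows
#' with a \code{NOT} qualifier, rows whose term is unknown to the
#' ontology (reported), rows outside the requested namespace, and
#' malformed rows (reported with their line numbers).
#'
#' @param path path to the GAF file.
#' @param ontology an \code{\link{Ontology}} used to resolve term
#'   namespaces.
#' @param namespace keep only terms of this namespace; \code{NULL} keeps
#'   all.
#' @param proteomeSize reference proteome size recorded on the result;
#'   defaults to the number of annotated proteins.
#' @return an \code{\link{AnnotationSet}} with direct annotations only.
#' @export
parseGAF <- function(path, ontology, namespace = "biological_process",
    proteomeSize = NULL) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "!") & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- lengths(fields) < 5L
  if (any(bad))
    message("skipping ", sum(bad), " malformed GAF row(s) at line(s): ",
      paste(utils::head(lineno[bad], 10L), collapse = ", "))
  fields <- fields[!bad]
  if (!length(fields))
    return(AnnotationSet(list(), proteomeSize = proteomeSize))
  protein <- toupper(vapply(fields, `[`, "", 2L))
  qualifier <- vapply(fields, `[`, "", 4L)
  term <- vapply(fields, `[`, "", 5L)
  ok <- !grepl("(^|\\|)NOT($|\\|)", qualifier)
  unknown <- !(term %in% termIds(ontology))
  if (any(unknown & ok))
    message("skipping ", sum(unknown & ok),
      " annotation(s) with unknown term id(s): ",
      paste(utils::head(unique(term[unknown & ok]), 5L), collapse = ", "))
  ok <- ok & !unknown
  if (!is.null(namespace))
    ok <- ok & ontology@termNamespace[term] %in% namespace
  direct <- split(term[ok], protein[ok])
  AnnotationSet(direct, proteomeSize = proteomeSize)
}

# all ancestors (excluding the term itself) for every term, memoised
.ancestorClosure <- function(ontology) {
  anc <- vector("list", length(ontology@terms))
  names(anc) <- ontology@terms
  done <- logical(length(ontology@terms))
  names(done) <- ontology@terms
  visit <- function(t) {
    if (done[[t]]) return(anc[[t]])
    out <- character()
    for (p in ontology@parents[[t]]) out <- c(out, p, visit(p))
    out <- unique(out)
    anc[[t]] <<- out
    done[[t]] <<- TRUE
    out
  }
  for (t in ontology@terms) visit(t)
  anc
}

#' Propagate annotations by the true-path rule
#'
#' Closes every protein's term set under ontology ancestors: if a term
#' annotates a protein, all of its parent terms annotate it too. Term
#' counts are recomputed on the propagated sets, so the root term counts
#' every annotated protein.
#'
#' @param ann an \code{\link{AnnotationSet}}.
#' @param ontology an \code{\link{Ontology}}.
#' @return the \code{AnnotationSet} with propagated sets and term counts
#'   filled in. Idempotent.
#' @export
propagateAnnotations <- function(ann, ontology) {
  anc <- .ancestorClosure(ontology)
  prop <- lapply(ann@direct, function(ts) {
    ts <- ts[ts %in% ontology@terms]
    sort(unique(c(ts, unlist(anc[ts], use.names = FALSE))))
  })
  cnt <- table(unlist(prop, use.names = FALSE))
  tc <- as.integer(cnt)
  names(tc) <- names(cnt)
  new("AnnotationSet", direct = ann@direct, propagated = prop,
    termCount = tc, proteomeSize = ann@proteomeSize)
}

#' Select specific terms by annotation count
#'
#' Returns the terms whose propagated annotation count lies in
#' \code{[minAnnotated, maxAnnotated]}. The interaction-categorisation
#' analysis uses terms annotating at most 50 proteins; the
#' filtered-process catalogue additionally requires at least 5.
#'
#' @param ann a propagated \code{\link{AnnotationSet}}.
#' @param maxAnnotated inclusive upper bound on the annotation count.
#' @param minAnnotated inclusive lower bound.
#' @return character vector of term ids.
#' @export
selectSpecificTerms <- function(ann, maxAnnotated = 50, minAnnotated = 0) {
  if (minAnnotated > maxAnnotated)
    stop("minAnnotated must not exceed maxAnnotated")
  tc <- termCounts(ann)
  if (!length(tc))
    stop("annotations have not been propagated; call propagateAnnotations()")
  sort(names(tc)[tc >= minAnnotated & tc <= maxAnnotated])
}

#' Probability of a term
#'
#' The fraction of proteins annotated with the term (after propagation)
#' among the reference proteome. A term known to the ontology but
#' annotating no protein has probability 0.
#'
#' @param ann a propagated \code{\link{AnnotationSet}}.
#' @param term a term id (vectorised).
#' @param ontology an \code{\link{Ontology}}; terms outside it are an
#'   error.
#' @return numeric vector of fractions in [0, 1].
#' @export
termProbability <- function(ann, term, ontology) {
  unknown <- !(term %in% termIds(ontology))
  if (any(unknown))
    stop("unknown term(s): ", paste(term[unknown], collapse = ", "))
  tc <- termCounts(ann)
  cnt <- ifelse(term %in% names(tc), tc[term], 0L)
  unname(cnt / proteomeSize(ann))
}
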