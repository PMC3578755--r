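# Lin term similarity, protein semantic similarity, weighted degree.

# named probability vector over all ontology terms (0 for unannotated)
.termProbVector <- function(ann, ontology) {
  p <- rep(0, length(ontology@terms))
  names(p) <- ontology@terms
  tc <- termCounts(ann)
  p[names(tc)] <- tc / proteomeSize(ann)
  p
}

# self-inclusive ancestor sets for every term
.selfAncestors <- function(ontology) {
  anc <- .ancestorClosure(ontology)
  mapply(function(t, a) c(t, a), names(anc), anc, SIMPLIFY = FALSE)
}

#' Lin semantic similarity of two ontology terms
#'
#' \deqn{tSS(t_1, t_2) = \frac{2 \log p(a^*)}{\log p(t_1) + \log p(t_2)}}
#' where \eqn{p(t)} is the fraction of the reference proteome annotated
#' with \eqn{t} (after true-path propagation) and \eqn{a^*} is the
#' common ancestor of minimum probability (the most informative one,
#' which resolves "a least common ancestor" in a DAG). Identical
#' non-root terms score exactly 1; terms whose only common ancestor is a
#' root (probability 1) score exactly 0. The log base cancels. Values
#' are clamped to [0, 1]. A term of probability 0 has undefined
#' similarity and raises an error.
#'
#' @param t1,t2 term ids.
#' @param ann a propagated \code{\link{AnnotationSet}}.
#' @param ontology an \code{\link{Ontology}}.
#' @return a similarity in [0, 1].
#' @export
linTermSimilarity <- function(t1, t2, ann, ontology) {
  p <- .termProbVector(ann, ontology)
  anc <- .selfAncestors(ontology)
  .linTerm(t1, t2, p, anc, ontologyRoots(ontology))
}

.linTerm <- function(t1, t2, p, anc, roots) {
  if (is.null(anc[[t1]]) || is.null(anc[[t2]]))
    stop("unknown term(s): ", paste(setdiff(c(t1, t2), names(anc)),
      collapse = ", "))
  p1 <- p[[t1]]
  p2 <- p[[t2]]
  if (p1 == 0 || p2 == 0)
    stop("similarity undefined for term(s) with probability 0")
  if (t1 == t2 && !(t1 %in% roots)) return(1)
  common <- intersect(anc[[t1]], anc[[t2]])
  if (!length(common)) return(NA_real_)
  # sharing only a root carries no information
  if (all(common %in% roots)) return(0)
  pa <- min(p[common])
  if (pa >= 1) return(0)
  val <- 2 * log(pa) / (log(p1) + log(p2))
  min(max(val, 0), 1)
}

# minimum-probability term of a set (ties: first after sort, for
# determinism); returns its probability
.minProb <- function(terms, p) min(p[terms])

#' Protein semantic similarity
#'
#' Extends Lin term similarity to proteins with multiple (true-path
#' propagated) annotations. The default \code{"most-specific"}
#' aggregation scores
#' \deqn{pSS(p_1, p_2) = \frac{2 \log p(s^*)}{\log p(m_1) + \log p(m_2)}}
#' where \eqn{s^*} is the minimum-probability term shared by the two
#' propagated sets and \eqn{m_1, m_2} are each protein's own
#' minimum-probability terms. (A naive maximum over term pairs
#' degenerates to 1 for any shared annotation, which motivates this
#' form.) The alternative \code{"bma"} aggregation is the best-match
#' average of Lin similarities over the two proteins' direct
#' annotations. Either protein unannotated makes the similarity
#' undefined, reported as \code{NA} rather than 0.
#'
#' @param p1,p2 protein ids.
#' @param ann a propagated \code{\link{AnnotationSet}}.
#' @param ontology an \code{\link{Ontology}}.
#' @param aggregation \code{"most-specific"} (default) or \code{"bma"}.
#' @return a similarity in [0, 1], or \code{NA} when undefined.
#' @export
proteinSemanticSimilarity <- function(p1, p2, ann, ontology,
    aggregation = c("most-specific", "bma")) {
  aggregation <- match.arg(aggregation)
  p <- .termProbVector(ann, ontology)
  anc <- .selfAncestors(ontology)
  .pss(p1, p2, ann, p, anc, ontologyRoots(ontology), aggregation)
}

.pss <- function(p1, p2, ann, p, anc, roots, aggregation) {
  prop <- ann@propagated
  s1 <- prop[[p1]]
  s2 <- prop[[p2]]
  if (is.null(s1) || !length(s1) || is.null(s2) || !length(s2))
    return(NA_real_)
  if (aggregation == "bma") {
    d1 <- ann@direct[[p1]]
    d2 <- ann@direct[[p2]]
    sim <- outer(d1, d2,
      Vectorize(function(a, b) .linTerm(a, b, p, anc, roots)))
    return(min(max((mean(apply(sim, 1, max)) +
      mean(apply(sim, 2, max))) / 2, 0), 1))
  }
  shared <- intersect(s1, s2)
  if (!length(shared)) return(NA_real_)
  if (all(shared %in% roots)) return(0)
  ps <- .minProb(shared, p)
  pm1 <- .minProb(s1, p)
  pm2 <- .minProb(s2, p)
  if (ps >= 1) return(0)
  denom <- log(pm1) + log(pm2)
  if (denom == 0) return(0)  # annotated with root only
  min(max(2 * log(ps) / denom, 0), 1)
}

#' Semantic-similarity-weighted degree
#'
#' The semantic similarity degree of a protein is the sum, over its
#' annotated interactions (both endpoints annotated), of the protein
#' semantic similarity of the interacting pair: a continuous measure of
#' how intramodular the protein's interaction neighbourhood is.
#' Interactions whose similarity is undefined contribute 0 and are
#' tallied in the \code{nUndefined} diagnostic.
#'
#' @param net an \code{\link{Interactome}}.
#' @param ann a propagated \code{\link{AnnotationSet}}.
#' @param ontology an \code{\link{Ontology}}.
#' @param aggregation passed to
#'   \code{\link{proteinSemanticSimilarity}}.
#' @return data.frame: \code{protein}, \code{semsimDegree},
#'   \code{annotatedDegree}, \code{nUndefined}, plus an
#'   \code{aggregation} attribute recording the variant used.
#' @export
semsimWeightedDegree <- function(net, ann, ontology,
    aggregation = c("most-specific", "bma")) {
  aggregation <- match.arg(aggregation)
  p <- .termProbVector(ann, ontology)
  anc <- .selfAncestors(ontology)
  roots <- ontologyRoots(ontology)
  prop <- ann@propagated
  if (!length(prop))
    stop("annotations have not been propagated; call propagateAnnotations()")
  e <- interactions(net)
  annotated <- e[, 1] %in% names(prop) & e[, 2] %in% names(prop)
  ea <- e[annotated, , drop = FALSE]
  # memoise on the pair of annotation signatures: proteins annotated with
  # the same term sets share their similarity
  sig <- vapply(prop, paste, "", collapse = "|")
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  w <- numeric(nrow(ea))
  for (i in seq_len(nrow(ea))) {
    k <- paste(sort(c(sig[[ea[i, 1]]], sig[[ea[i, 2]]])), collapse = "\r")
    v <- cache[[k]]
    if (is.null(v)) {
      v <- .pss(ea[i, 1], ea[i, 2], ann, p, anc, roots, aggregation)
      cache[[k]] <- v
    }
    w[i] <- v
  }
  nodes <- proteins(net)
  undef <- is.na(w)
  w0 <- ifelse(undef, 0, w)
  fu <- factor(c(ea[, 1], ea[, 2]), levels = nodes)
  sdeg <- as.numeric(tapply(c(w0, w0), fu, sum, default = 0))
  adeg <- as.integer(table(fu))
  nund <- as.integer(tapply(c(undef, undef), fu, sum, default = 0))
  out <- data.frame(protein = nodes, semsimDegree = sdeg,
    annotatedDegree = adeg, nUndefined = nund)
  attr(out, "aggregation") <- aggregation
  out
}
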