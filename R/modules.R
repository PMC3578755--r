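# Module catalogues: complexes and filtered biological processes.

#' Jaccard index of two protein sets
#'
#' @param a,b character vectors of protein ids.
#' @return \code{|a intersect b| / |a union b|}. Two empty sets are an
#'   undefined input and raise an error.
#' @export
jaccardIndex <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) stop("Jaccard index of two empty sets is undefined")
  length(intersect(a, b)) / u
}

#' Read a module catalogue
#'
#' One module per line: \code{module_id<TAB>protein1,protein2,...}.
#'
#' @param path path to the TSV (no header).
#' @param origin origin label for the modules.
#' @return a \code{\link{ModuleSet}}.
#' @export
readModuleSet <- function(path, origin = "complex") {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
    comment.char = "", stringsAsFactors = FALSE, colClasses = "character")
  members <- strsplit(df[[2]], ",", fixed = TRUE)
  members <- lapply(members, toupper)
  names(members) <- df[[1]]
  ModuleSet(members, origin = origin)
}

#' Write a module catalogue
#'
#' @param modules a \code{\link{ModuleSet}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeModuleSet <- function(modules, path) {
  lines <- paste(moduleIds(modules),
    vapply(moduleMembers(modules), paste, "", collapse = ","), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# deterministic processing order: descending size, ties by ascending id
.moduleOrder <- function(modules) {
  order(-lengths(moduleMembers(modules)),
    moduleIds(modules), method = "radix")
}

# Remove every module that is a strict subset of another module in the
# catalogue (equal member sets: the lexicographically larger id goes).
.removeSubsets <- function(modules) {
  mem <- moduleMembers(modules)
  ids <- moduleIds(modules)
  n <- length(ids)
  drop <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(mem[[i]] %in% mem[[j]])) {
        if (length(mem[[i]]) < length(mem[[j]])) {
          drop[i] <- TRUE
        } else if (length(mem[[i]]) == length(mem[[j]]) && ids[i] > ids[j]) {
          drop[i] <- TRUE  # identical sets: keep the smaller id
        }
      }
    }
  }
  modules[which(!drop)]
}

# Greedy Jaccard sweep: walk modules by descending size (ties by id) and
# drop any module overlapping an already-retained one at or above the
# threshold ("the smaller complex is removed"; equal sizes drop the
# lexicographically larger id, which the ordering guarantees).
.removeOverlapping <- function(modules, jaccardThreshold) {
  ord <- .moduleOrder(modules)
  mem <- moduleMembers(modules)
  kept <- integer()
  for (i in ord) {
    clash <- FALSE
    for (j in kept) {
      if (jaccardIndex(mem[[i]], mem[[j]]) >= jaccardThreshold) {
        clash <- TRUE
        break
      }
    }
    if (!clash) kept <- c(kept, i)
  }
  modules[sort(kept)]
}

#' Deduplicate a complex catalogue
#'
#' Applies, in order: (1) removal of complexes whose members are a
#' strict subset of another complex; (2) removal of the smaller complex
#' of any pair whose Jaccard index reaches \code{jaccardThreshold};
#' (3) removal of the listed ribosome complexes, whose large subunit
#' lists would otherwise dominate per-protein statistics. Processing is
#' deterministic (descending size, ties by id).
#'
#' @param raw a \code{\link{ModuleSet}} of complexes.
#' @param jaccardThreshold overlap threshold for pair removal.
#' @param ribosomeIds module ids to drop outright; ids not present in
#'   the catalogue produce a warning, not an error.
#' @return the deduplicated \code{\link{ModuleSet}}.
#' @export
deduplicateComplexes <- function(raw, jaccardThreshold = 0.5,
    ribosomeIds = character()) {
  out <- .removeSubsets(raw)
  out <- .removeOverlapping(out, jaccardThreshold)
  miss <- setdiff(ribosomeIds, moduleIds(out))
  missRaw <- setdiff(miss, moduleIds(raw))
  if (length(missRaw))
    warning("ribosome id(s) not found in catalogue: ",
      paste(missRaw, collapse = ", "))
  out[which(!(moduleIds(out) %in% ribosomeIds))]
}

#' Build process modules from selected terms
#'
#' One module per term; members are the proteins annotated with the term
#' after true-path propagation. The term's full annotation count is
#' recorded as the declared size.
#'
#' @param ann a propagated \code{\link{AnnotationSet}}.
#' @param terms character vector of term ids (e.g. from
#'   \code{\link{selectSpecificTerms}}).
#' @return a \code{\link{ModuleSet}} with origin \code{"process"}.
#' @export
buildProcessModules <- function(ann, terms) {
  prop <- propagatedAnnotations(ann)
  prot <- rep(names(prop), lengths(prop))
  term <- unlist(prop, use.names = FALSE)
  keep <- term %in% terms
  members <- split(prot[keep], factor(term[keep], levels = sort(terms)))
  members <- members[lengths(members) > 0L]
  ModuleSet(members, origin = "process",
    declaredSize = lengths(members))
}

#' Subtract complex contributions from process modules
#'
#' For every process and every raw complex whose intersection with the
#' process reaches \code{intersectionThreshold} proteins, the
#' intersection is no longer associated with the process (intersections
#' are assessed against the original membership, so the result does not
#' depend on complex order). A process is dropped if fewer than 2
#' proteins remain, or fewer than half the number of proteins its term
#' is known to annotate. Survivors are then deduplicated exactly like
#' complexes (subset and Jaccard removal).
#'
#' @param processes a \code{\link{ModuleSet}} of process modules.
#' @param complexesRaw the pre-deduplication complex catalogue (the
#'   subtraction runs against the original complex set).
#' @param intersectionThreshold minimum shared proteins that trigger
#'   subtraction.
#' @param jaccardThreshold overlap threshold for the final dedup sweep.
#' @return a \code{\link{ModuleSet}} with origin
#'   \code{"filtered_process"}.
#' @export
filterProcessesAgainstComplexes <- function(processes, complexesRaw,
    intersectionThreshold = 2, jaccardThreshold = 0.5) {
  cmem <- moduleMembers(complexesRaw)
  pmem <- moduleMembers(processes)
  declared <- processes@declaredSize
  declared[is.na(declared)] <- lengths(pmem)[is.na(declared)]
  out <- vector("list", length(pmem))
  keep <- logical(length(pmem))
  for (i in seq_along(pmem)) {
    p <- pmem[[i]]
    cut <- character()
    for (cm in cmem) {
      inter <- intersect(p, cm)
      if (length(inter) >= intersectionThreshold) cut <- c(cut, inter)
    }
    left <- setdiff(p, cut)
    if (length(left) >= 2L && length(left) >= declared[i] / 2) {
      out[[i]] <- left
      keep[i] <- TRUE
    }
  }
  names(out) <- moduleIds(processes)
  filtered <- ModuleSet(out[keep], origin = "filtered_process",
    declaredSize = declared[keep])
  filtered <- .removeSubsets(filtered)
  .removeOverlapping(filtered, jaccardThreshold)
}
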