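# Reading interaction tables and building evidence-class interactomes.

#' Default column mapping for tab-delimited interaction tables
#'
#' Maps the record fields to column names of the input table. The two
#' protein-id columns are mandatory; \code{system}, \code{source} and
#' \code{bait} are optional and filled with \code{NA} when absent.
#'
#' @param a,b column names of the two interactor ids.
#' @param system column name of the experimental-system label.
#' @param source column name of the experiment/publication id.
#' @param bait column name of the bait protein id.
#' @return a named list usable as the \code{dialect} argument of
#'   \code{\link{parseInteractionTable}}.
#' @export
interactionDialect <- function(a = "a", b = "b", system = "system",
    source = "source", bait = "bait") {
  list(a = a, b = b, system = system, source = source, bait = bait)
}

#' Parse a tab-delimited protein interaction table
#'
#' Reads a header-bearing, tab-delimited table of interaction records
#' (BioGRID-Tab-like). Protein ids are upper-cased; self-interactions are
#' dropped. Duplicate rows are retained: deduplication happens when an
#' \code{\link{Interactome}} is built.
#'
#' @param path path to the table.
#' @param dialect column mapping, see \code{\link{interactionDialect}}.
#' @return data.frame of records with columns \code{a}, \code{b},
#'   \code{system}, \code{source}, \code{bait}.
#' @export
parseInteractionTable <- function(path, dialect = interactionDialect()) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
    comment.char = "", stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(raw) == 0L) {
    warning("empty interaction table: ", path)
    return(data.frame(a = character(), b = character(),
      system = character(), source = character(), bait = character()))
  }
  for (fld in c("a", "b")) {
    if (!dialect[[fld]] %in% names(raw))
      stop("interaction table is missing mandatory column '",
        dialect[[fld]], "' (field ", fld, ")")
  }
  pick <- function(fld) {
    col <- dialect[[fld]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]]
    else rep(NA_character_, nrow(raw))
  }
  rec <- data.frame(a = toupper(raw[[dialect$a]]),
    b = toupper(raw[[dialect$b]]), system = pick("system"),
    source = pick("source"), bait = toupper(pick("bait")))
  rec[rec$a != rec$b, , drop = FALSE]
}

#' Remove interactions of sticky proteins
#'
#' If a protein has more than \code{maxPerSource} interaction records
#' from a single experimental data source, all of that protein's records
#' from that source are removed (its records from other sources are
#' kept). The bound is strict: a protein with exactly
#' \code{maxPerSource} records from one source is untouched.
#'
#' @param records record data.frame as from
#'   \code{\link{parseInteractionTable}}.
#' @param maxPerSource maximum tolerated records per (protein, source).
#' @param countUniquePartners count distinct partners instead of records
#'   when deciding stickiness.
#' @return the filtered record data.frame.
#' @export
filterStickyProteins <- function(records, maxPerSource = 30,
    countUniquePartners = FALSE) {
  if (nrow(records) == 0L) return(records)
  long <- data.frame(
    protein = c(records$a, records$b),
    partner = c(records$b, records$a),
    source = rep(records$source, 2L),
    row = rep(seq_len(nrow(records)), 2L))
  key <- paste(long$protein, long$source, sep = "\r")
  cnt <- if (countUniquePartners) {
    tapply(long$partner, key, function(x) length(unique(x)))
  } else {
    tapply(long$partner, key, length)
  }
  sticky <- names(cnt)[cnt > maxPerSource]
  if (!length(sticky)) return(records)
  drop <- unique(long$row[key %in% sticky])
  records[-drop, , drop = FALSE]
}

.directSystems <- c("biochemical activity", "co-crystal structure",
  "far western", "fret", "protein-peptide", "reconstituted complex",
  "two-hybrid")
.pulldownSystems <- c("affinity capture-western", "affinity capture-ms")
.excludedSystems <- c("affinity capture-rna", "protein-rna")

#' Build an evidence-class interactome from interaction records
#'
#' Three evidence classes are supported. \code{direct} keeps systems
#' probing direct physical contact (biochemical activity, co-crystal
#' structure, far western, FRET, protein-peptide, reconstituted complex,
#' two-hybrid). \code{pulldown} keeps co-complex evidence (affinity
#' capture-western, affinity capture-MS). \code{full} keeps every system
#' except the RNA-mediated ones (affinity capture-RNA, protein-RNA).
#' System labels are compared case-insensitively. Records of the same
#' pair collapse to one edge whose provenance lists only the admitted
#' records.
#'
#' @param records record data.frame.
#' @param class one of \code{"direct"}, \code{"pulldown"}, \code{"full"}.
#' @param directSystems,pulldownSystems,excludedSystems configurable
#'   system vocabularies.
#' @return an \code{\link{Interactome}}.
#' @export
selectEvidenceClass <- function(records,
    class = c("direct", "pulldown", "full"),
    directSystems = .directSystems, pulldownSystems = .pulldownSystems,
    excludedSystems = .excludedSystems) {
  class <- match.arg(class)
  sys <- tolower(records$system)
  keep <- switch(class,
    direct = sys %in% tolower(directSystems),
    pulldown = sys %in% tolower(pulldownSystems),
    full = !(sys %in% tolower(excludedSystems)))
  keep[is.na(keep)] <- (class == "full")
  records <- records[keep, , drop = FALSE]
  pairs <- if (nrow(records)) .canonicalPairs(records$a, records$b)
    else matrix(character(), 0, 2)
  prov <- data.frame(a = pairs[, 1], b = pairs[, 2],
    system = records$system, source = records$source, bait = records$bait)
  Interactome(pairs, provenance = prov)
}

#' Restrict records to high-throughput experiments
#'
#' Keeps records whose source (experiment/publication) contributed at
#' least \code{minExperimentSize} records and used strictly more than
#' \code{minBaits} distinct bait proteins.
#'
#' @param records record data.frame; the \code{bait} column must be
#'   populated.
#' @param minExperimentSize minimum records per source (inclusive).
#' @param minBaits minimum distinct baits per source (exclusive).
#' @return the filtered record data.frame.
#' @export
filterHighThroughput <- function(records, minExperimentSize = 50,
    minBaits = 10) {
  if (nrow(records) == 0L) return(records)
  if (all(is.na(records$bait)))
    stop("high-throughput filtering needs bait information; ",
      "supply a bait column in the dialect")
  nrec <- table(records$source)
  nbait <- tapply(records$bait, records$source,
    function(x) length(unique(x[!is.na(x)])))
  ok <- names(nrec)[nrec >= minExperimentSize &
    nbait[names(nrec)] > minBaits]
  records[records$source %in% ok, , drop = FALSE]
}

#' Restrict an interactome to essentiality-tested proteins
#'
#' Returns the induced subgraph on the tested proteins; edges with an
#' untested endpoint are dropped. Idempotent.
#'
#' @param net an \code{\link{Interactome}}.
#' @param ess an \code{\link{EssentialityMap}}.
#' @return an \code{\link{Interactome}}.
#' @export
restrictToTested <- function(net, ess) {
  tested <- testedProteins(ess)
  e <- interactions(net)
  keep <- e[, 1] %in% tested & e[, 2] %in% tested
  prov <- provenance(net)
  prov <- prov[prov$a %in% tested & prov$b %in% tested, , drop = FALSE]
  Interactome(e[keep, , drop = FALSE],
    proteins = intersect(proteins(net), tested), provenance = prov)
}

#' Read an essentiality list
#'
#' Two-column tab-delimited file: protein id and a 0/1 essentiality flag;
#' every listed protein counts as tested.
#'
#' @param path path to the file (with header).
#' @return an \code{\link{EssentialityMap}}.
#' @export
readEssentiality <- function(path) {
  df <- .readTsv(path)
  EssentialityMap(tested = toupper(df[[1]]),
    essential = toupper(df[[1]][df[[2]] == "1"]))
}

#' Write an interactome as edge-list and provenance TSVs
#'
#' @param net an \code{\link{Interactome}}.
#' @param prefix output path prefix; writes \code{<prefix>_edges.tsv} and
#'   \code{<prefix>_provenance.tsv}.
#' @return invisibly, the paths written.
#' @export
writeInteractome <- function(net, prefix) {
  pe <- paste0(prefix, "_edges.tsv")
  pp <- paste0(prefix, "_provenance.tsv")
  .writeTsv(as.data.frame(interactions(net)), pe)
  .writeTsv(provenance(net), pp)
  invisible(c(pe, pp))
}

#' Write an essentiality map as a two-column TSV
#'
#' @param ess an \code{\link{EssentialityMap}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeEssentiality <- function(ess, path) {
  tested <- testedProteins(ess)
  .writeTsv(data.frame(protein = tested,
    essential = as.integer(tested %in% essentialProteins(ess))), path)
  invisible(path)
}
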