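# Seeded synthetic modular interactomes with planted cross-talk
# enrichment and degree-coupled essentiality.

#' Configuration for the synthetic-data generator
#'
#' The defaults describe the study conditions the package's analyses
#' assume: a modular interactome of 2000 proteins organised into 40
#' disjoint complexes of 30-50 proteins with dense intramodule
#' (\code{pIn = 0.3}) and sparse background intermodule
#' (\code{pOut = 0.005}) wiring; 20 planted cross-talk module pairs at
#' \code{pCrosstalk = 0.15}, drawn preferentially (bias 0.75) between
#' essential modules; half the modules essential, with a member's
#' essentiality probability following
#' \eqn{logistic(\alpha + \beta d_{intra})} inside essential modules
#' (\code{alpha = -5}, \code{beta = 0.4}, centring the probability near
#' 0.5 at the typical intramodular degree of ~12 with a dynamic range of
#' roughly 0.07-0.93) and a small background rate
#' (\code{baseRate = 0.01}) elsewhere.
#'
#' @param nProteins number of proteins.
#' @param nModules number of complexes.
#' @param sizeRange inclusive (min, max) complex sizes; total membership
#'   must fit in \code{nProteins} (leftover proteins stay unannotated).
#' @param pIn intramodule edge probability.
#' @param pOut background intermodule edge probability.
#' @param nCrosstalkPairs number of planted enriched module pairs.
#' @param pCrosstalk edge probability across planted pairs.
#' @param crosstalkPairs optional explicit two-column matrix of module
#'   indices overriding the random choice of planted pairs.
#' @param fracEssentialModules fraction of modules flagged essential.
#' @param essentialBias probability that a planted-pair endpoint is
#'   drawn from the essential modules.
#' @param alpha,beta intercept and slope (log-odds per unit intramodular
#'   degree) of the essentiality model inside essential modules.
#' @param baseRate essentiality probability outside essential modules.
#' @param overlapFraction fraction of each module's members additionally
#'   inserted into a second module (exercises multi-membership paths).
#' @param seed master RNG seed for the generator.
#' @return a validated \code{GeneratorConfig} list.
#' @export
generatorConfig <- function(nProteins = 2000, nModules = 40,
    sizeRange = c(30, 50), pIn = 0.3, pOut = 0.005,
    nCrosstalkPairs = 20, pCrosstalk = 0.15, crosstalkPairs = NULL,
    fracEssentialModules = 0.5, essentialBias = 0.75, alpha = -5,
    beta = 0.4, baseRate = 0.01, overlapFraction = 0, seed = 1) {
  cfg <- list(nProteins = as.integer(nProteins),
    nModules = as.integer(nModules), sizeRange = as.integer(sizeRange),
    pIn = pIn, pOut = pOut, nCrosstalkPairs = as.integer(nCrosstalkPairs),
    pCrosstalk = pCrosstalk, crosstalkPairs = crosstalkPairs,
    fracEssentialModules = fracEssentialModules,
    essentialBias = essentialBias, alpha = alpha, beta = beta,
    baseRate = baseRate, overlapFraction = overlapFraction,
    seed = as.integer(seed))
  probs <- c(pIn = pIn, pOut = pOut, pCrosstalk = pCrosstalk,
    fracEssentialModules = fracEssentialModules,
    essentialBias = essentialBias, baseRate = baseRate,
    overlapFraction = overlapFraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (!(pOut < pCrosstalk)) stop("need pOut < pCrosstalk")
  if (!(pOut < pIn)) stop("need pOut < pIn")
  if (length(cfg$sizeRange) != 2L || cfg$sizeRange[1] < 2L ||
      cfg$sizeRange[1] > cfg$sizeRange[2])
    stop("sizeRange must be (min, max) with min >= 2")
  if (cfg$nModules * cfg$sizeRange[2] < cfg$sizeRange[1])
    stop("invalid module plan")
  class(cfg) <- "GeneratorConfig"
  cfg
}

# map linear indices to pairs within one set (pairs ordered (1,2),(1,3)...)
.unrankWithin <- function(idx, n) {
  cums <- cumsum(seq.int(n - 1L, 1L))
  i <- findInterval(idx - 0.5, c(0, cums))
  j <- idx - c(0L, cums)[i] + i
  cbind(i, j)
}

# Bernoulli(p) edge sample over all unordered pairs of `ids`
.samplePairsWithin <- function(ids, p) {
  n <- length(ids)
  N <- n * (n - 1) / 2
  if (N < 1 || p <= 0) return(NULL)
  k <- stats::rbinom(1L, N, p)
  if (k == 0L) return(NULL)
  ij <- .unrankWithin(sort(sample.int(N, k)), n)
  cbind(ids[ij[, 1]], ids[ij[, 2]])
}

# Bernoulli(p) edge sample over the bipartite pair block A x B
.samplePairsAcross <- function(a, b, p) {
  N <- length(a) * length(b)
  if (N < 1 || p <= 0) return(NULL)
  k <- stats::rbinom(1L, N, p)
  if (k == 0L) return(NULL)
  idx <- sample.int(N, k)
  cbind(a[(idx - 1L) %/% length(b) + 1L],
    b[(idx - 1L) %% length(b) + 1L])
}

#' Generate a synthetic modular interactome
#'
#' Partitions proteins into complexes (leftover proteins remain
#' unannotated), wires every intramodule pair with probability
#' \code{pIn} and every intermodule pair with \code{pOut}, except the
#' cross-pairs of the planted cross-talk module pairs, which are wired
#' with \code{pCrosstalk}. Essential-module flags are drawn first so
#' planted pairs can be biased towards essential modules. Fully
#' deterministic under the configuration seed.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @return list with \code{network} (\code{\link{Interactome}}),
#'   \code{modules} (\code{\link{ModuleSet}}) and \code{truth} (planted
#'   pairs, essential-module ids, config echo).
#' @export
generateInteractome <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  .withSeed(.deriveSeed(cfg$seed, "network"), {
    sizeSpan <- seq.int(cfg$sizeRange[1], cfg$sizeRange[2])
    sizes <- sizeSpan[sample.int(length(sizeSpan), cfg$nModules,
      replace = TRUE)]
    if (sum(sizes) > cfg$nProteins)
      stop("module sizes exceed nProteins; enlarge nProteins or shrink ",
        "sizeRange")
    prots <- sprintf("P%05d", seq_len(cfg$nProteins))
    bounds <- cumsum(c(0L, sizes))
    members <- lapply(seq_len(cfg$nModules), function(i)
      prots[(bounds[i] + 1L):bounds[i + 1L]])
    names(members) <- sprintf("M%03d", seq_len(cfg$nModules))
    if (cfg$overlapFraction > 0 && cfg$nModules > 1L) {
      for (i in seq_len(cfg$nModules)) {
        nAdd <- round(cfg$overlapFraction * sizes[i])
        if (nAdd < 1L) next
        other <- setdiff(unlist(members[-i], use.names = FALSE),
          members[[i]])
        members[[i]] <- c(members[[i]],
          sample(other, min(nAdd, length(other))))
      }
    }
    modules <- ModuleSet(members, origin = "complex")

    nEss <- round(cfg$fracEssentialModules * cfg$nModules)
    essMods <- sort(sample.int(cfg$nModules, nEss))

    planted <- cfg$crosstalkPairs
    if (is.null(planted) && cfg$nCrosstalkPairs > 0L) {
      planted <- matrix(integer(), 0, 2)
      nonEss <- setdiff(seq_len(cfg$nModules), essMods)
      pickEnd <- function() {
        fromEss <- stats::runif(1) < cfg$essentialBias
        pool <- if (fromEss && length(essMods)) essMods
          else if (length(nonEss)) nonEss else essMods
        pool[sample.int(length(pool), 1L)]
      }
      guard <- 0L
      while (nrow(planted) < cfg$nCrosstalkPairs) {
        guard <- guard + 1L
        if (guard > 10000L)
          stop("could not draw the requested number of distinct planted ",
            "pairs")
        pr <- sort(c(pickEnd(), pickEnd()))
        if (pr[1] == pr[2]) next
        if (nrow(planted) &&
            any(planted[, 1] == pr[1] & planted[, 2] == pr[2])) next
        planted <- rbind(planted, pr)
      }
      rownames(planted) <- NULL
    }
    plantedKey <- if (is.null(planted) || !nrow(planted)) character()
      else paste(planted[, 1], planted[, 2])

    edges <- list()
    for (i in seq_len(cfg$nModules))
      edges[[length(edges) + 1L]] <-
        .samplePairsWithin(members[[i]], cfg$pIn)
    for (i in seq_len(cfg$nModules - 1L)) {
      for (j in seq.int(i + 1L, cfg$nModules)) {
        p <- if (paste(i, j) %in% plantedKey) cfg$pCrosstalk else cfg$pOut
        edges[[length(edges) + 1L]] <- .samplePairsAcross(
          setdiff(members[[i]], members[[j]]),
          setdiff(members[[j]], members[[i]]), p)
      }
    }
    unann <- setdiff(prots, unlist(members, use.names = FALSE))
    if (length(unann)) {
      edges[[length(edges) + 1L]] <- .samplePairsWithin(unann, cfg$pOut)
      edges[[length(edges) + 1L]] <- .samplePairsAcross(unann,
        setdiff(prots, unann), cfg$pOut)
    }
    em <- do.call(rbind, edges)
    if (is.null(em)) em <- matrix(character(), 0, 2)
    net <- Interactome(em, proteins = prots)
    net@provenance$system <- rep("synthetic", nrow(net@provenance))
    net@provenance$source <- rep("SIM", nrow(net@provenance))
    list(network = net, modules = modules,
      truth = list(
        plantedPairs = if (is.null(planted)) matrix(integer(), 0, 2)
          else matrix(names(members)[planted], ncol = 2),
        essentialModules = names(members)[essMods],
        config = cfg))
  })
}

#' Assign essentiality labels to a synthetic interactome
#'
#' Every protein counts as tested. Inside essential modules the
#' essentiality probability is \eqn{logistic(\alpha + \beta d)} with
#' \eqn{d} the protein's intramodular degree on the generated network;
#' everywhere else it is \code{baseRate}.
#'
#' @param sim result of \code{\link{generateInteractome}}.
#' @param cfg generator configuration; defaults to the one echoed in
#'   \code{sim$truth}.
#' @return an \code{\link{EssentialityMap}}.
#' @export
assignEssentiality <- function(sim, cfg = sim$truth$config) {
  degt <- computeDegrees(sim$network, sim$modules)
  intra <- degt$intra
  names(intra) <- degt$protein
  prots <- proteins(sim$network)
  inEss <- rep(FALSE, length(prots))
  names(inEss) <- prots
  for (id in sim$truth$essentialModules)
    inEss[moduleMembers(sim$modules)[[id]]] <- TRUE
  p <- ifelse(inEss, stats::plogis(cfg$alpha +
    cfg$beta * intra[prots]), cfg$baseRate)
  .withSeed(.deriveSeed(cfg$seed, "essentiality"), {
    essential <- prots[stats::runif(length(prots)) < p]
    EssentialityMap(tested = prots, essential = essential)
  })
}

#' Generate a toy ontology aligned with a module catalogue
#'
#' Builds a small biological-process DAG: one leaf term per module
#' annotating exactly its members, grouped in fives under mid-level
#' parent terms, under a single root (deeper chains are inserted below
#' the root for \code{depth > 3}). Leaf term sizes stay at module size,
#' so the default modules yield specific terms (at most 50 proteins).
#'
#' @param modules a \code{\link{ModuleSet}}.
#' @param depth levels from root to leaf, at least 2.
#' @param proteomeSize reference proteome size for term probabilities;
#'   defaults to the module universe size.
#' @param groupSize modules per mid-level parent.
#' @return list with \code{ontology} (\code{\link{Ontology}}) and
#'   \code{annotations} (a propagated \code{\link{AnnotationSet}}).
#' @export
generateToyOntology <- function(modules, depth = 3, proteomeSize = NULL,
    groupSize = 5) {
  stopifnot(depth >= 2)
  ids <- moduleIds(modules)
  n <- length(ids)
  root <- "GO:0008150"
  leaf <- sprintf("GO:%07d", 2000000L + seq_len(n))
  names(leaf) <- ids
  parents <- list()
  parents[[root]] <- character()
  nm <- c("biological_process")
  names(nm) <- root
  chain <- root
  if (depth > 3) {
    for (k in seq_len(depth - 3L)) {
      t <- sprintf("GO:%07d", 500000L + k)
      parents[[t]] <- chain
      nm[t] <- sprintf("broad process level %d", k)
      chain <- t
    }
  }
  if (depth >= 3) {
    nMid <- ceiling(n / groupSize)
    mid <- sprintf("GO:%07d", 1000000L + seq_len(nMid))
    for (k in seq_len(nMid)) {
      parents[[mid[k]]] <- chain
      nm[mid[k]] <- sprintf("process group %d", k)
    }
    leafParent <- mid[ceiling(seq_len(n) / groupSize)]
  } else {
    leafParent <- rep(chain, n)
  }
  for (k in seq_len(n)) {
    parents[[leaf[k]]] <- leafParent[k]
    nm[leaf[k]] <- sprintf("process of module %s", ids[k])
  }
  ontology <- Ontology(parents, namespace = "biological_process",
    name = nm[names(parents)])
  mem <- moduleMembers(modules)
  prot <- unlist(mem, use.names = FALSE)
  term <- rep(leaf[ids], lengths(mem))
  direct <- split(term, prot)
  if (is.null(proteomeSize)) proteomeSize <- length(universe(modules))
  ann <- AnnotationSet(direct, proteomeSize = proteomeSize)
  list(ontology = ontology,
    annotations = propagateAnnotations(ann, ontology))
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running \code{\link{generateInteractome}},
#' \code{\link{assignEssentiality}} and
#' \code{\link{generateToyOntology}} under one configuration.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @return list with \code{network}, \code{modules}, \code{essentiality},
#'   \code{ontology}, \code{annotations} and \code{truth}.
#' @export
simulateStudy <- function(cfg = generatorConfig()) {
  sim <- generateInteractome(cfg)
  ess <- assignEssentiality(sim)
  onto <- generateToyOntology(sim$modules,
    proteomeSize = cfg$nProteins)
  list(network = sim$network, modules = sim$modules, essentiality = ess,
    ontology = onto$ontology, annotations = onto$annotations,
    truth = sim$truth)
}

#' Write a synthetic study as plain-text fixture files
#'
#' Emits an interaction table (TSV), module catalogue (TSV), OBO 1.2
#' ontology, GAF 2.2 annotations, essentiality list (TSV) and a JSON
#' ground-truth manifest (planted pairs, essential modules, seed and
#' config echo). Two runs from the same configuration produce
#' byte-identical files, and parsing the files back reproduces the
#' in-memory objects.
#'
#' @param sim result of \code{\link{simulateStudy}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths written.
#' @export
writeFixture <- function(sim, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create fixture directory: ", dir)
  paths <- c(edges = file.path(dir, "edges.tsv"),
    modules = file.path(dir, "modules.tsv"),
    obo = file.path(dir, "ontology.obo"),
    gaf = file.path(dir, "annotations.gaf"),
    essentiality = file.path(dir, "essentiality.tsv"),
    manifest = file.path(dir, "manifest.json"))
  e <- interactions(sim$network)
  .writeTsv(data.frame(a = e[, 1], b = e[, 2], system = "synthetic",
    source = "SIM", bait = e[, 1]), paths["edges"])
  writeModuleSet(sim$modules, paths["modules"])
  .writeObo(sim$ontology, paths["obo"])
  .writeGaf(sim$annotations, sim$ontology, paths["gaf"])
  writeEssentiality(sim$essentiality, paths["essentiality"])
  cfg <- sim$truth$config
  manifest <- list(seed = cfg$seed,
    plantedPairs = apply(sim$truth$plantedPairs, 1, paste,
      collapse = "|"),
    essentialModules = sim$truth$essentialModules,
    config = unclass(cfg)[!vapply(unclass(cfg), is.null, TRUE)])
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  invisible(paths)
}

.writeObo <- function(ontology, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in termIds(ontology)) {
    writeLines(c("[Term]", paste0("id: ", t),
      paste0("name: ", ontology@termName[[t]]),
      paste0("namespace: ", ontology@termNamespace[[t]]),
      paste0("is_a: ", ontology@parents[[t]]), ""), con)
  }
  invisible(path)
}

.writeGaf <- function(ann, ontology, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("!gaf-version: 2.2", con)
  direct <- directAnnotations(ann)
  aspect <- c(biological_process = "P", molecular_function = "F",
    cellular_component = "C")
  for (p in names(direct)) {
    for (t in direct[[p]]) {
      asp <- aspect[[ontology@termNamespace[[t]]]]
      writeLines(paste(c("SYN", p, p, "", t, "SYN:0000001", "IEA", "",
        asp, "", "", "protein", "taxon:4932", "20260101", "SYN", "", ""),
        collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read back a fixture directory
#'
#' @param dir directory written by \code{\link{writeFixture}}.
#' @return list with \code{network}, \code{modules}, \code{ontology},
#'   \code{annotations} (propagated), \code{essentiality},
#'   \code{manifest}.
#' @export
readFixture <- function(dir) {
  rec <- parseInteractionTable(file.path(dir, "edges.tsv"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
    simplifyVector = TRUE)
  net <- Interactome(cbind(rec$a, rec$b),
    proteins = sprintf("P%05d", seq_len(manifest$config$nProteins)))
  ontology <- parseOBO(file.path(dir, "ontology.obo"))
  ann <- parseGAF(file.path(dir, "annotations.gaf"), ontology,
    proteomeSize = manifest$config$nProteins)
  list(network = net,
    modules = readModuleSet(file.path(dir, "modules.tsv")),
    ontology = ontology,
    annotations = propagateAnnotations(ann, ontology),
    essentiality = readEssentiality(file.path(dir, "essentiality.tsv")),
    manifest = manifest)
}
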