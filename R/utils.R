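# Internal helpers.

# Evaluate expr under a temporary RNG seed, restoring global RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic per-stage seed derived from a master seed (kept < 2^31).
.deriveSeed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000003L) * 1009L + match(stage,
    c("network", "essentiality", "permutation", "rewire", "ontology")) * 101L
}

# protein -> character vector of module ids (empty vector if unannotated)
.membershipIndex <- function(modules) {
  ids <- rep(moduleIds(modules), lengths(moduleMembers(modules)))
  prot <- unlist(moduleMembers(modules), use.names = FALSE)
  split(ids, factor(prot, levels = unique(prot)))
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE)
}

.readTsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
    comment.char = "", stringsAsFactors = FALSE,
    colClasses = "character", ...)
}
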