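# Shared fixture builders and independent oracles, all built in code.

recTable <- function(a, b, system = "Two-hybrid", source = "S1",
    bait = NA_character_) {
  data.frame(a = a, b = b,
    system = rep(system, length.out = length(a)),
    source = rep(source, length.out = length(a)),
    bait = rep(bait, length.out = length(a)))
}

writeTempTable <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

# a hand-built ontology + annotation pair with controllable counts:
# `annot` maps term -> number of distinct proteins directly annotated
handOntology <- function(parents, annot, proteomeSize) {
  ont <- Ontology(parents)
  prot <- character()
  term <- character()
  i <- 0L
  for (t in names(annot)) {
    if (annot[[t]] == 0L) next
    ps <- sprintf("H%04d", i + seq_len(annot[[t]]))
    i <- i + annot[[t]]
    prot <- c(prot, ps)
    term <- c(term, rep(t, length(ps)))
  }
  ann <- AnnotationSet(split(term, prot), proteomeSize = proteomeSize)
  list(ontology = ont, annotations = propagateAnnotations(ann, ont))
}

# ---- independent semantic-similarity oracle (brute-force) ------------

bruteAncestorsOf <- function(parents, t) {
  out <- character()
  frontier <- t
  while (length(frontier)) {
    ps <- setdiff(unique(unlist(parents[frontier], use.names = FALSE)),
      out)
    out <- c(out, ps)
    frontier <- ps
  }
  out
}

bruteLin <- function(t1, t2, parents, prob, roots) {
  if (t1 == t2 && !(t1 %in% roots)) return(1)
  ca <- intersect(c(t1, bruteAncestorsOf(parents, t1)),
    c(t2, bruteAncestorsOf(parents, t2)))
  if (!length(ca)) return(NA_real_)
  if (all(ca %in% roots)) return(0)
  best <- Inf
  for (a in ca) if (prob[[a]] < best) best <- prob[[a]]
  if (best >= 1) return(0)
  val <- 2 * log(best) / (log(prob[[t1]]) + log(prob[[t2]]))
  min(max(val, 0), 1)
}

brutePss <- function(s1, s2, prob, roots) {
  shared <- intersect(s1, s2)
  if (!length(shared)) return(NA_real_)
  if (all(shared %in% roots)) return(0)
  ps <- min(unlist(prob[shared]))
  pm1 <- min(unlist(prob[s1]))
  pm2 <- min(unlist(prob[s2]))
  if (ps >= 1) return(0)
  den <- log(pm1) + log(pm2)
  if (den == 0) return(0)
  min(max(2 * log(ps) / den, 0), 1)
}

# ---- independent rank-statistics oracles -----------------------------

# Pearson correlation written out longhand
brutePearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# average ranks computed longhand
bruteRanks <- function(x) {
  out <- numeric(length(x))
  for (i in seq_along(x))
    out[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  out
}

# exhaustive two-sided rank-sum p-value (tie-free, small n)
bruteWilcoxP <- function(a, b) {
  n <- length(a) + length(b)
  pooled <- c(a, b)
  r <- bruteRanks(pooled)
  wObs <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  combs <- combn(n, length(a))
  ws <- apply(combs, 2, function(idx)
    sum(r[idx]) - length(a) * (length(a) + 1) / 2)
  mu <- length(a) * length(b) / 2
  mean(abs(ws - mu) >= abs(wObs - mu) - 1e-12)
}

# a tiny complex whose essential members (first two) have intracomplex
# degree 2 and whose non-essential members have degree 1
fourProteinComplex <- function(prefix) {
  mem <- paste0(prefix, c("E1", "E2", "N1", "N2"))
  edges <- rbind(c(mem[1], mem[2]), c(mem[1], mem[3]), c(mem[2], mem[4]))
  list(members = mem, edges = edges,
    essential = mem[1:2])
}
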