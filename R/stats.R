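# Rank correlations, rank-sum tests, per-complex permutation test.

#' Spearman rank correlation with large-sample p-value
#'
#' Computed as the Pearson correlation of average-tied ranks; the
#' p-value uses the t approximation with n - 2 degrees of freedom. A
#' constant input vector makes the correlation undefined: \code{rho} is
#' \code{NA} and the result is flagged.
#'
#' @param x,y numeric vectors of equal length (n >= 2); pairs with NA
#'   are dropped.
#' @return list with \code{rho}, \code{p.value}, \code{n},
#'   \code{controlledFor} (\code{NA}) and \code{undefined}.
#' @export
spearmanRcc <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok])
  y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 2L) stop("need at least two complete observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p.value = NA_real_, n = n,
      controlledFor = NA_character_, undefined = TRUE))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (n >= 3L && abs(rho) < 1) {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  } else if (abs(rho) == 1) 0 else NA_real_
  list(rho = rho, p.value = p, n = n, controlledFor = NA_character_,
    undefined = FALSE)
}

#' Maximum attainable Spearman correlation for binary essentiality
#'
#' Because essentiality is binary and heavily tied, the Spearman
#' correlation with a degree cannot reach 1. This computes the value it
#' would take were the essentiality labels rearranged so that all
#' essential proteins occupy the highest degree ranks, keeping the
#' degree ties as observed.
#'
#' @param essential logical/0-1 vector.
#' @param degrees numeric vector of the same length.
#' @return the maximum attainable correlation (NA, with a warning, when
#'   degenerate: all degrees equal, or labels all one class).
#' @export
maxAttainableSrcc <- function(essential, degrees) {
  stopifnot(length(essential) == length(degrees))
  essential <- as.logical(essential)
  k <- sum(essential)
  n <- length(essential)
  if (k == 0L || k == n || length(unique(degrees)) < 2L) {
    warning("maximum attainable correlation undefined (constant vector)")
    return(NA_real_)
  }
  opt <- numeric(n)
  opt[order(degrees, decreasing = TRUE)[seq_len(k)]] <- 1
  stats::cor(rank(opt), rank(degrees))
}

#' First-order partial Spearman correlation
#'
#' All three vectors are rank-transformed (average ties), then the
#' partial Pearson correlation of x and y given z is computed:
#' \eqn{(r_{xy} - r_{xz} r_{yz}) / \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}},
#' with a t-approximate p-value on n - 3 degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @param z numeric control vector.
#' @return list with \code{rho}, \code{p.value}, \code{n},
#'   \code{controlledFor}, \code{undefined}. \code{rho} is \code{NA} and
#'   flagged when either correlation with z is exactly +/-1.
#' @export
partialSpearman <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(x) == length(z))
  ok <- !is.na(x) & !is.na(y) & !is.na(z)
  rx <- rank(as.numeric(x[ok]))
  ry <- rank(as.numeric(y[ok]))
  rz <- rank(as.numeric(z[ok]))
  n <- length(rx)
  if (n < 4L) stop("need at least four complete observations")
  if (length(unique(rx)) < 2L || length(unique(ry)) < 2L ||
      length(unique(rz)) < 2L) {
    warning("constant vector: partial correlation undefined")
    return(list(rho = NA_real_, p.value = NA_real_, n = n,
      controlledFor = "z", undefined = TRUE))
  }
  rxy <- stats::cor(rx, ry)
  rxz <- stats::cor(rx, rz)
  ryz <- stats::cor(ry, rz)
  if (abs(rxz) >= 1 || abs(ryz) >= 1) {
    # z rank-identical (or reversed) to an argument: the control absorbs
    # all of that argument's variation and the numerator vanishes with
    # the denominator, so the degenerate value is 0 - flagged as such
    warning("control variable collinear with an argument: ",
      "partial correlation degenerate")
    return(list(rho = 0, p.value = NA_real_, n = n,
      controlledFor = "z", undefined = TRUE))
  }
  rho <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  rho <- min(max(rho, -1), 1)
  p <- if (abs(rho) < 1) {
    tstat <- rho * sqrt((n - 3) / (1 - rho^2))
    2 * stats::pt(abs(tstat), df = n - 3, lower.tail = FALSE)
  } else 0
  list(rho = rho, p.value = p, n = n, controlledFor = "z",
    undefined = FALSE)
}

#' Two-sided Wilcoxon rank sum test
#'
#' Uses the exact null distribution when the combined sample is small
#' (at most \code{exactLimit}) and tie-free, and the tie-corrected
#' normal approximation otherwise.
#'
#' @param a,b nonempty numeric vectors.
#' @param exactLimit largest combined sample size for the exact null.
#' @return list with \code{statistic} (rank-sum W of \code{a}),
#'   \code{p.value} and \code{exact}.
#' @export
wilcoxonRankSum <- function(a, b, exactLimit = 20) {
  stopifnot(length(a) > 0L, length(b) > 0L)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b)) <= exactLimit && !ties
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
    correct = !exact, alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
    exact = exact)
}

# within-complex interaction degree of every member of one module
.intraComplexDegrees <- function(edges, members) {
  keep <- edges[, 1] %in% members & edges[, 2] %in% members
  tab <- table(factor(c(edges[keep, 1], edges[keep, 2]),
    levels = members))
  as.integer(tab)
}

#' Per-complex permutation test for essential-protein centrality
#'
#' Tests whether, within complexes containing both essential and
#' non-essential proteins, the essential ones have a higher average
#' intracomplex degree. A complex is eligible when it has at least
#' \code{minEssential} essential and \code{minNonessential}
#' non-essential tested members, each with at least one intracomplex
#' interaction. The observed statistic is the number of eligible
#' complexes in which the essential members' mean intracomplex degree
#' strictly exceeds the non-essential members' (ties count against).
#' Under the default \code{"within"} null, essentiality labels are
#' permuted independently within each eligible complex among its
#' intracomplex-interacting members, preserving the per-complex
#' essential count; \code{"global"} shuffles labels across the pooled
#' members instead. The empirical p-value is
#' \eqn{(\#\{perm \ge obs\} + 1) / (nPerm + 1)}, so it is never 0.
#'
#' @param net an \code{\link{Interactome}}.
#' @param complexes a \code{\link{ModuleSet}}.
#' @param ess an \code{\link{EssentialityMap}}; untested members are
#'   excluded.
#' @param minEssential,minNonessential eligibility thresholds.
#' @param nPerm number of permutations.
#' @param seed optional RNG seed (restores the caller's RNG state).
#' @param scheme \code{"within"} (default) or \code{"global"}.
#' @return list with \code{nComplexesTested}, \code{nHigherEssential},
#'   \code{empiricalP}, \code{nPerm}, \code{scheme} and a
#'   \code{perComplex} data.frame (complex id, sizes, mean degrees,
#'   higher flag). With no eligible complex, counts are 0 and
#'   \code{empiricalP} is \code{NA} with \code{status = "no eligible
#'   complexes"}.
#' @export
perComplexPermutationTest <- function(net, complexes, ess,
    minEssential = 2, minNonessential = 2, nPerm = 10000, seed = NULL,
    scheme = c("within", "global")) {
  scheme <- match.arg(scheme)
  e <- interactions(net)
  tested <- testedProteins(ess)
  essential <- essentialProteins(ess)
  degs <- list()
  flags <- list()
  rows <- list()
  for (id in moduleIds(complexes)) {
    mem <- moduleMembers(complexes)[[id]]
    d <- .intraComplexDegrees(e, mem)
    keep <- d >= 1L & mem %in% tested
    mem <- mem[keep]
    d <- d[keep]
    f <- mem %in% essential
    if (sum(f) >= minEssential && sum(!f) >= minNonessential) {
      degs[[id]] <- d
      flags[[id]] <- f
      rows[[id]] <- data.frame(complex = id, nEssential = sum(f),
        nNonessential = sum(!f), meanEssentialDegree = mean(d[f]),
        meanNonessentialDegree = mean(d[!f]),
        higher = mean(d[f]) > mean(d[!f]))
    }
  }
  if (!length(degs)) {
    return(list(nComplexesTested = 0L, nHigherEssential = 0L,
      empiricalP = NA_real_, nPerm = nPerm, scheme = scheme,
      status = "no eligible complexes",
      perComplex = data.frame()))
  }
  perComplex <- do.call(rbind, rows)
  rownames(perComplex) <- NULL
  observed <- sum(perComplex$higher)
  m <- lengths(degs)
  k <- vapply(flags, sum, 0L)
  tot <- vapply(degs, sum, 0)
  perm <- .withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      if (scheme == "within") {
        hits <- mapply(function(d, mm, kk, tt) {
          se <- sum(d[sample.int(mm, kk)])
          se / kk > (tt - se) / (mm - kk)
        }, degs, m, k, tot)
      } else {
        pool <- sample(rep(unlist(flags, use.names = FALSE)))
        idx <- split(seq_len(sum(m)), rep(seq_along(m), m))
        hits <- mapply(function(d, ii) {
          f <- pool[ii]
          sum(f) > 0 && sum(!f) > 0 &&
            mean(d[f]) > mean(d[!f])
        }, degs, idx)
      }
      sum(hits)
    }, 0)
  })
  list(nComplexesTested = length(degs), nHigherEssential = observed,
    empiricalP = (sum(perm >= observed) + 1) / (nPerm + 1),
    nPerm = nPerm, scheme = scheme, status = "ok",
    perComplex = perComplex)
}
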