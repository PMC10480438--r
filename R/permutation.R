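## Seeded randomisation-test framework: three permutation schemes plus the
## roster-reassignment scheme for sibling cohabitation; one-sided p-values
## with the add-one counting rule so p is never 0.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.permP <- function(observed, null, side) {
  n <- length(null)
  hits <- if (side == "greater") sum(null >= observed) else sum(null <= observed)
  (1 + hits) / (1 + n)
}

.permResult <- function(observed, null, side, scheme, seed) {
  new("PermutationResult",
    observed = observed, null_sample = as.numeric(null),
    p_value = .permP(observed, null, side), n_iter = length(null),
    scheme = scheme, side = side,
    seed = if (is.null(seed)) NA_real_ else as.numeric(seed)
  )
}

#' Two-sample randomisation test (mean difference)
#'
#' Observed statistic is `mean(x) - mean(y)`. Under the null the two samples
#' are pooled and re-divided randomly according to the original sample
#' sizes. One-sided; p uses the add-one rule
#' `(1 + #permuted at least as extreme) / (1 + n_iter)`, ties counted as
#' extreme.
#'
#' @param x,y numeric samples (non-empty).
#' @param n_iter number of permutations (default 10000).
#' @param side `"greater"` or `"less"`.
#' @param seed optional RNG seed; the session RNG state is restored
#'   afterwards.
#' @return A [PermutationResult-class].
#' @export
permTwoSample <- function(x, y, n_iter = 10000L, side = c("greater", "less"),
                          seed = NULL) {
  side <- match.arg(side)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (n_iter < 1L) stop("n_iter must be at least 1")
  obs <- mean(x) - mean(y)
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  tot <- sum(pooled)
  null <- .withSeed(seed, {
    vapply(seq_len(n_iter), function(i) {
      s1 <- sum(pooled[sample.int(n, n1)])
      s1 / n1 - (tot - s1) / (n - n1)
    }, numeric(1L))
  })
  .permResult(obs, null, side, "two_sample", seed)
}

#' Paired randomisation test (mean difference of pairs)
#'
#' Observed statistic is `mean(x - y)`; the null randomly swaps each pair
#' (sign flips of the differences).
#'
#' @param x,y paired numeric samples of equal length.
#' @inheritParams permTwoSample
#' @return A [PermutationResult-class].
#' @export
permPaired <- function(x, y, n_iter = 10000L, side = c("greater", "less"),
                       seed = NULL) {
  side <- match.arg(side)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 1L) stop("need at least one pair")
  if (n_iter < 1L) stop("n_iter must be at least 1")
  d <- x - y
  obs <- mean(d)
  n <- length(d)
  null <- .withSeed(seed, {
    vapply(seq_len(n_iter), function(i) {
      mean(d * sample(c(-1, 1), n, replace = TRUE))
    }, numeric(1L))
  })
  .permResult(obs, null, side, "paired", seed)
}

#' Correlation randomisation test (Pearson's r)
#'
#' Observed statistic is the Pearson correlation; the null permutes one
#' variable while the other is unchanged.
#'
#' @param x,y numeric vectors of equal length (>= 3), non-zero variance.
#' @inheritParams permTwoSample
#' @return A [PermutationResult-class].
#' @export
permCorrelation <- function(x, y, n_iter = 10000L,
                            side = c("greater", "less"), seed = NULL) {
  side <- match.arg(side)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  if (n_iter < 1L) stop("n_iter must be at least 1")
  obs <- cor(x, y)
  n <- length(x)
  null <- .withSeed(seed, {
    vapply(seq_len(n_iter), function(i) cor(x, y[sample.int(n)]), numeric(1L))
  })
  .permResult(obs, null, side, "correlation", seed)
}

#' Sibling-cohabitation randomisation test
#'
#' Tests whether sibling adult-female dyads share a harem more often than
#' expected: the observed statistic is [siblingCohabitationStat()], and the
#' null reassigns the adult females randomly to harems preserving per-harem
#' female counts. One-sided, greater.
#'
#' @param ped a [Pedigree-class].
#' @param rosters named vector, adult-female id -> harem (at least 2 harems).
#' @inheritParams permTwoSample
#' @return A [PermutationResult-class].
#' @export
permSiblingCohabitation <- function(ped, rosters, n_iter = 10000L,
                                    seed = NULL) {
  if (length(unique(unname(rosters))) < 2L) stop("need at least 2 harems")
  if (n_iter < 1L) stop("n_iter must be at least 1")
  ids <- names(rosters)
  obs <- as.numeric(siblingCohabitationStat(ped, rosters))
  ## precompute sibling dyads once; the statistic is then a fast count
  dy <- t(utils::combn(ids, 2L))
  cls <- kinshipTable(ped, data.frame(id_a = dy[, 1L], id_b = dy[, 2L]))
  sib <- cls %in% c("full_sibling", "maternal_half_sibling",
    "paternal_half_sibling")
  ai <- match(dy[sib, 1L], ids)
  bi <- match(dy[sib, 2L], ids)
  labels <- unname(rosters)
  n <- length(labels)
  null <- .withSeed(seed, {
    vapply(seq_len(n_iter), function(i) {
      perm <- labels[sample.int(n)]
      sum(perm[ai] == perm[bi])
    }, numeric(1L))
  })
  .permResult(obs, null, "greater", "roster_reassignment", seed)
}

#' Collect randomisation results into the results-table dialect
#'
#' @param results named list of [PermutationResult-class] objects.
#' @param n1,n2 optional sample sizes to report per test.
#' @return data.frame `test_name`, `scheme`, `side`, `n1`, `n2`, `observed`,
#'   `p_value`, `n_iter`, `seed`.
#' @export
permResultsTable <- function(results, n1 = NA, n2 = NA) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(
      test_name = nm, scheme = r@scheme, side = r@side,
      n1 = if (length(n1) > 1L) n1[[nm]] else n1,
      n2 = if (length(n2) > 1L) n2[[nm]] else n2,
      observed = r@observed, p_value = r@p_value, n_iter = r@n_iter,
      seed = r@seed, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
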