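#' Exact test of independence for an r x c contingency table
#'
#' Freeman-Halton generalization of Fisher's exact test: all tables with the
#' observed margins are enumerated, each weighted by its multivariate
#' hypergeometric probability, and the p value is the total probability of
#' tables no more probable than the observed one (probabilities within
#' 1e-12 of the observed table's count as "as extreme"). Used to compare
#' colour-morph frequencies between groups (e.g. males vs females) at low
#' sample sizes. Above `enumerationBound` total counts, a seeded Monte-Carlo
#' estimate over tables drawn from the margin-conditional null
#' ([stats::r2dtable()]) is used instead when `monteCarlo = TRUE`.
#'
#' @param table nonnegative integer matrix (r x c) of counts.
#' @param enumerationBound largest total count enumerated exactly (default
#'   200).
#' @param monteCarlo use Monte-Carlo estimation above the bound.
#' @param B number of Monte-Carlo tables.
#' @param seed RNG seed for the Monte-Carlo mode.
#' @return Object of class `exactTest`: list with `pValue`, `nTables`
#'   (tables enumerated or sampled), `margins`, `method`.
#' @examples
#' freemanHaltonExact(matrix(c(3, 1, 1, 3), 2))$pValue  # 34/70
#' @export
freemanHaltonExact <- function(table, enumerationBound = 200,
                               monteCarlo = FALSE, B = 1e5, seed = 1L) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must contain nonnegative integers")
  tab <- round(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("all row and column margins must be positive")
  N <- sum(tab)
  # log multivariate hypergeometric probability of a table with these margins
  logConst <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1)
  logProb <- function(m) logConst - sum(lgamma(m + 1))
  pObs <- exp(logProb(tab))
  if (N > enumerationBound) {
    if (!monteCarlo)
      stop("total count ", N, " exceeds the enumeration bound; ",
           "set monteCarlo = TRUE for a seeded Monte-Carlo estimate")
    p <- withr::with_seed(seed, {
      draws <- stats::r2dtable(B, rs, cs)
      mean(vapply(draws, function(m) exp(logProb(m)), numeric(1)) <=
             pObs + 1e-12)
    })
    return(structure(list(pValue = p, nTables = B,
                          margins = list(row = rs, col = cs),
                          method = "monte-carlo"),
                     class = "exactTest"))
  }
  r <- length(rs); cc <- length(cs)
  pTotal <- 0
  nTables <- 0L
  # depth-first enumeration of all tables with the fixed margins
  recurse <- function(rowIdx, colRemaining, acc) {
    if (rowIdx == r) {
      m <- rbind(acc, colRemaining)
      nTables <<- nTables + 1L
      pr <- exp(logProb(m))
      if (pr <= pObs + 1e-12) pTotal <<- pTotal + pr
      return(invisible())
    }
    target <- rs[rowIdx]
    fill <- function(colIdx, remaining, row) {
      if (colIdx == cc) {
        if (remaining <= colRemaining[cc]) {
          row[cc] <- remaining
          recurse(rowIdx + 1L, colRemaining - row, rbind(acc, row))
        }
        return(invisible())
      }
      for (v in 0:min(remaining, colRemaining[colIdx])) {
        row[colIdx] <- v
        fill(colIdx + 1L, remaining - v, row)
      }
    }
    fill(1L, target, numeric(cc))
  }
  recurse(1L, cs, matrix(numeric(0), 0, cc))
  structure(list(pValue = min(pTotal, 1), nTables = nTables,
                 margins = list(row = rs, col = cs),
                 method = "enumeration"),
            class = "exactTest")
}

#' @export
print.exactTest <- function(x, ...) {
  cat(sprintf("Exact r x c test (%s, %d tables): p = %.4g\n",
              x$method, x$nTables, x$pValue))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment of a vector of p values (delegating to
#' [stats::p.adjust()] with `method = "BH"`), preserving input order;
#' adjusted values are monotone in raw rank and capped at 1.
#'
#' @param pvalues numeric vector of raw p values in (0, 1].
#' @return Adjusted p values, same order.
#' @examples
#' fdrBH(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdrBH <- function(pvalues) {
  if (length(pvalues) == 0L) stop("empty p value vector")
  if (anyNA(pvalues) || any(pvalues <= 0 | pvalues > 1))
    stop("p values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
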