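#' Canonical morph labels, in tie-break order
#'
#' @return Character vector `("orange", "yellow", "grey", "orange_yellow")`.
#' @export
morphLevels <- function() c("orange", "yellow", "grey", "orange_yellow")

.featureNames <- c("prop_red", "prop_yellow", "prop_grey",
                   "throat_cc", "throat_ac", "bib_cc", "bib_ac")

.asFeatureMatrix <- function(table, features) {
  if (is.null(features)) {
    features <- intersect(.featureNames, names(table))
    if (length(features) == 0L)
      features <- setdiff(names(table),
                          c("id", "morph", "week", "peak", "timepoint"))
  }
  missing <- setdiff(features, names(table))
  if (length(missing))
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  X <- as.matrix(table[, features, drop = FALSE])
  if (!is.numeric(X) || any(!is.finite(X)))
    stop("all features must be finite numerics")
  X
}

.groupFactor <- function(labels) {
  labels <- as.character(labels)
  canon <- morphLevels()
  lv <- if (all(unique(labels) %in% canon)) canon[canon %in% labels]
        else unique(labels)
  factor(labels, levels = lv)
}

#' Canonical discriminant analysis of colour variables
#'
#' Fits the canonical (linear) discriminant analysis that underpins
#' objective morph classification: eigen-decomposition of the within-group
#' versus between-group scatter (`W^-1 B`) of the colour features, giving
#' `min(p, g - 1)` canonical axes, the share of discriminable variation on
#' each, Wilks' lambda `prod 1/(1 + lambda_i) = det(W)/det(W + B)` and its
#' Rao F approximation. Canonical coefficients are scaled to unit pooled
#' within-group variance.
#'
#' @param table data.frame with a `morph` column and the seven colour
#'   variables (`prop_red`, `prop_yellow`, `prop_grey`, `throat_cc`,
#'   `throat_ac`, `bib_cc`, `bib_ac`), or any numeric feature columns named
#'   via `features`.
#' @param features optional character vector naming the feature columns.
#' @param groupCol name of the grouping column (default `"morph"`).
#' @param prior `"equal"` (default) or `"proportional"` class priors for
#'   classification.
#' @return Object of class `cda`: list with `eigenvalues`,
#'   `percentVariance`, `coefficients` (p x s), `centroids` (canonical
#'   space), `wilksLambda`, `F`, `df1`, `df2`, `pValue`, `groupMeans`,
#'   `pooledCov`, `counts`, `prior`, `features`, `levels`.
#' @examples
#' tab <- genFeatureTable(seed = 1)
#' fit <- canonicalDiscriminant(tab)
#' fit$percentVariance
#' @export
canonicalDiscriminant <- function(table, features = NULL, groupCol = "morph",
                                  prior = c("equal", "proportional")) {
  prior <- match.arg(prior)
  if (!groupCol %in% names(table)) stop("no '", groupCol, "' column")
  g <- .groupFactor(table[[groupCol]])
  X <- .asFeatureMatrix(table, features)
  p <- ncol(X)
  n <- nrow(X)
  ng <- nlevels(g)
  if (ng < 2L) stop("at least 2 groups are required")
  counts <- table(g)
  if (n <= p + ng)
    stop("need n > n_features + n_groups for an invertible pooled covariance")
  grand <- colMeans(X)
  M <- rowsum(X, g) / as.vector(counts)
  W <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  for (k in levels(g)) {
    Xk <- X[g == k, , drop = FALSE]
    C <- sweep(Xk, 2, M[k, ])
    W <- W + crossprod(C)
  }
  B <- crossprod(sweep(M, 2, grand) * sqrt(as.vector(counts)))
  if (rcond(W) < 1e-12) {
    sdw <- sqrt(diag(W))
    corW <- W / outer(sdw, sdw)
    bad <- colnames(X)[apply(abs(corW - diag(p)) > 0.999, 1, any)]
    stop("pooled within-group scatter is (near) singular; collinear features: ",
         paste(unique(bad), collapse = ", "))
  }
  eig <- eigen(solve(W, B))
  ev <- Re(eig$values)
  vec <- Re(eig$vectors)
  ord <- order(ev, decreasing = TRUE)
  s <- min(p, ng - 1L)
  ev <- pmax(ev[ord][seq_len(s)], 0)
  V <- vec[, ord[seq_len(s)], drop = FALSE]
  pooled <- W / (n - ng)
  # unit within-group variance scaling of the canonical coefficients
  sc <- sqrt(diag(t(V) %*% pooled %*% V))
  V <- sweep(V, 2, sc, "/")
  dimnames(V) <- list(colnames(X), paste0("CV", seq_len(s)))
  lambdaAll <- pmax(Re(eig$values), 0)
  wilks <- prod(1 / (1 + lambdaAll))
  df1 <- p * (ng - 1L)
  m <- n - 1 - (p + ng) / 2
  denom <- p^2 + (ng - 1)^2 - 5
  t2 <- if (denom > 0) sqrt((p^2 * (ng - 1)^2 - 4) / denom) else 1
  df2 <- m * t2 - df1 / 2 + 1
  Fstat <- (1 - wilks^(1 / t2)) / wilks^(1 / t2) * df2 / df1
  pv <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  structure(list(
    eigenvalues = ev,
    percentVariance = 100 * ev / sum(ev),
    coefficients = V,
    centroids = M %*% V,
    wilksLambda = wilks,
    F = Fstat, df1 = df1, df2 = df2, pValue = pv,
    groupMeans = M, pooledCov = pooled,
    counts = as.vector(counts), prior = prior,
    features = colnames(X), levels = levels(g)),
    class = "cda")
}

#' @export
print.cda <- function(x, ...) {
  cat(sprintf("Canonical discriminant analysis: %d groups, %d features\n",
              length(x$levels), length(x$features)))
  cat(sprintf("  Wilks' lambda = %.4f, F(%d, %.2f) = %.2f, p = %.3g\n",
              x$wilksLambda, x$df1, x$df2, x$F, x$pValue))
  cat("  % variance per canonical axis:",
      paste(sprintf("%.1f", x$percentVariance), collapse = " / "), "\n")
  invisible(x)
}

#' Classify observations with a fitted discriminant
#'
#' Linear discriminant scores with the pooled within-group covariance:
#' `d_k(x) = x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log prior_k`; the highest
#' score wins, with ties broken by the fitted group order (orange, yellow,
#' grey, orange_yellow for the canonical labels).
#'
#' @param fit a `cda` from [canonicalDiscriminant()].
#' @param table data.frame with the same feature columns (one or more rows).
#' @return data.frame with column `assigned` plus one score column per
#'   class.
#' @export
classifyMorph <- function(fit, table) {
  stopifnot(inherits(fit, "cda"))
  X <- .asFeatureMatrix(table, fit$features)
  Sinv <- solve(fit$pooledCov)
  prior <- if (fit$prior == "equal") rep(1 / length(fit$levels), length(fit$levels))
           else fit$counts / sum(fit$counts)
  scores <- sapply(seq_along(fit$levels), function(k) {
    mu <- fit$groupMeans[fit$levels[k], ]
    drop(X %*% Sinv %*% mu) - drop(mu %*% Sinv %*% mu) / 2 + log(prior[k])
  })
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  colnames(scores) <- fit$levels
  # which.max takes the first maximum: fitted group order breaks exact ties
  assigned <- fit$levels[apply(scores, 1, which.max)]
  out <- data.frame(assigned = assigned, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(scores))
}

#' Leave-one-out cross-validated morph assignment
#'
#' For each row, refits the discriminant on the remaining rows and
#' classifies the held-out one; returns the aggregated confusion matrix and
#' per-class and overall correct-assignment rates. Deterministic given the
#' table.
#'
#' @inheritParams canonicalDiscriminant
#' @return Object of class `looResult`: list with `confusion` (true x
#'   assigned), `perClassRate`, `overallRate`, `n`.
#' @export
crossValidateLOO <- function(table, features = NULL, groupCol = "morph",
                             prior = c("equal", "proportional")) {
  prior <- match.arg(prior)
  g <- .groupFactor(table[[groupCol]])
  if (any(table(g) < 2L))
    stop("every group needs n >= 2 to be held out and retained")
  n <- nrow(table)
  assigned <- character(n)
  for (i in seq_len(n)) {
    fit <- canonicalDiscriminant(table[-i, , drop = FALSE], features = features,
                                 groupCol = groupCol, prior = prior)
    assigned[i] <- classifyMorph(fit, table[i, , drop = FALSE])$assigned
  }
  conf <- table(true = g, assigned = factor(assigned, levels = levels(g)))
  perClass <- diag(conf) / rowSums(conf)
  structure(list(confusion = conf,
                 perClassRate = perClass,
                 overallRate = sum(diag(conf)) / n,
                 n = n),
            class = "looResult")
}

#' @export
print.looResult <- function(x, ...) {
  cat(sprintf("Leave-one-out cross-validation (n = %d): overall %.1f%% correct\n",
              x$n, 100 * x$overallRate))
  print(round(100 * x$perClassRate, 1))
  invisible(x)
}
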