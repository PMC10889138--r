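## Weighted co-expression core: soft-threshold adjacency, topological
## overlap, module detection by average-linkage clustering with a static
## height cut plus eigengene merging, module eigengenes, module-trait
## correlation, and hub-gene ranking by intramodular connectivity.
##
## The adjacency is Pearson-based: unsigned a_ij = |cor|^beta (default) or
## signed ((1+cor)/2)^beta. Topological overlap:
##   w_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij),
##   L_ij = sum_{u != i,j} a_iu a_uj,  w_ii = 1.

#' Soft-threshold scan for scale-free topology
#'
#' For each candidate power, computes the connectivity distribution and the
#' R^2 of the regression of log10 p(k) on log10 k over occupancy bins
#' (the scale-free fit index), plus mean and max connectivity.
#'
#' @param expr Expression matrix, features x samples (log scale
#'   recommended, e.g. log2(FPKM+1)).
#' @param powers Candidate soft-threshold powers (default 1:12).
#' @param signed Use the signed adjacency transform?
#' @param nBins Number of connectivity bins for the fit (default 10).
#' @return data.frame with columns `power`, `fitR2`, `slope`, `meanK`,
#'   `maxK`.
#' @export
softThresholdScan <- function(expr, powers = 1:12, signed = FALSE,
                              nBins = 10) {
  expr <- .dropConstantRows(as.matrix(expr))
  if (ncol(expr) < 8) {
    warning("fewer than 8 samples; soft-threshold scan will be unstable")
  }
  cc <- cor(t(expr))
  out <- lapply(powers, function(b) {
    a <- if (signed) ((1 + cc) / 2)^b else abs(cc)^b
    diag(a) <- 0
    k <- rowSums(a)
    data.frame(
      power = b, fitR2 = .scaleFreeR2(k, nBins)$r2,
      slope = .scaleFreeR2(k, nBins)$slope,
      meanK = mean(k), maxK = max(k)
    )
  })
  do.call(rbind, out)
}

## R^2 of log10 p(k) ~ log10 k over equal-width occupancy bins
.scaleFreeR2 <- function(k, nBins = 10) {
  if (max(k) - min(k) < 1e-8) { # degenerate connectivity spectrum
    return(list(r2 = NA_real_, slope = NA_real_))
  }
  br <- seq(min(k), max(k), length.out = nBins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  pk <- tabulate(bin, nBins) / length(k)
  mid <- (br[-1] + br[-(nBins + 1)]) / 2
  ok <- pk > 0 & mid > 0
  if (sum(ok) < 3) {
    return(list(r2 = NA_real_, slope = NA_real_))
  }
  fit <- stats::lm(log10(pk[ok]) ~ log10(mid[ok]))
  list(r2 = summary(fit)$r.squared, slope = stats::coef(fit)[2])
}

.dropConstantRows <- function(expr, error = FALSE) {
  v <- apply(expr, 1, var)
  bad <- !is.finite(v) | v == 0
  if (any(bad)) {
    msg <- paste(
      "zero-variance feature(s):",
      paste(head(rownames(expr)[bad], 10), collapse = ", ")
    )
    if (error) stop(msg)
    warning(msg, "; dropped")
    expr <- expr[!bad, , drop = FALSE]
  }
  expr
}

#' Soft-thresholded adjacency
#'
#' @param expr Expression matrix, features x samples (rows are features;
#'   log2(FPKM+1) is the conventional input).
#' @param power Soft-threshold exponent beta >= 1 (default 7).
#' @param signed Signed transform `((1+cor)/2)^beta` instead of
#'   `|cor|^beta`?
#' @return A [CoexNetwork-class] (TOM not yet computed).
#' @examples
#' x <- matrix(rnorm(60), 6, 10, dimnames = list(paste0("g", 1:6), NULL))
#' net <- adjacencyMatrix(x, power = 7)
#' connectivity(net)
#' @export
adjacencyMatrix <- function(expr, power = 7, signed = FALSE) {
  if (power < 1) stop("power must be >= 1")
  expr <- .dropConstantRows(as.matrix(expr), error = TRUE)
  cc <- cor(t(expr))
  a <- if (signed) ((1 + cc) / 2)^power else abs(cc)^power
  # clamp tiny numerical overshoot
  a[a > 1] <- 1
  diag(a) <- 1
  methods::new("CoexNetwork",
    adjacency = a, tom = matrix(numeric(), 0, 0),
    power = power, signed = signed
  )
}

#' Topological overlap matrix
#'
#' Computes `w_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_{u != i,j} a_iu a_uj` and `w_ii = 1`.
#'
#' @param network A [CoexNetwork-class] from [adjacencyMatrix()].
#' @return The network with its `tom` slot filled.
#' @export
tomSimilarity <- function(network) {
  a <- adjacency(network)
  diag(a) <- 0
  k <- rowSums(a)
  L <- a %*% a # with zero diagonal, u = i and u = j terms vanish
  kmin <- outer(k, k, pmin)
  denom <- kmin + 1 - a
  if (any(denom <= 0)) stop("non-positive TOM denominator")
  w <- (L + a) / denom
  diag(w) <- 1
  w[w > 1] <- 1
  dimnames(w) <- dimnames(a)
  methods::initialize(network, tom = w)
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' `1 - w`, cut statically at dissimilarity `cutHeight` (default 0.95, the
#' static-cut convention; pass `cutQuantile` instead to cut at a quantile
#' of the merge heights); branches smaller than `minSize` become
#' unassigned (label 0); finally, modules whose eigengenes correlate above
#' `mergeCor` are merged (requires `expr`). Modules are relabelled 1..k by
#' decreasing size.
#'
#' @param network A [CoexNetwork-class] with TOM computed (or a
#'   dissimilarity matrix).
#' @param minSize Minimum module size (default 30).
#' @param cutHeight Fixed dissimilarity height for the static cut
#'   (default 0.95).
#' @param cutQuantile Optional quantile of the merge heights; when given
#'   it overrides `cutHeight`. Fragile when many unclustered background
#'   features crowd the top of the dendrogram; the fixed height is the
#'   recommended rule.
#' @param mergeCor Eigengene correlation above which modules merge
#'   (default 0.8); skipped when `expr` is `NULL`.
#' @param expr Expression matrix (features x samples) used for eigengene
#'   merging; feature names must cover the network's features.
#' @return A [ModuleSet-class].
#' @export
detectModules <- function(network, minSize = 30, cutHeight = 0.95,
                          cutQuantile = NULL, mergeCor = 0.8, expr = NULL) {
  diss <- if (methods::is(network, "CoexNetwork")) {
    1 - tomMatrix(network)
  } else {
    as.matrix(network)
  }
  if (max(abs(diss - t(diss))) > 1e-10) stop("dissimilarity must be symmetric")
  ids <- rownames(diss)
  n <- nrow(diss)
  if (minSize > n) {
    warning("minSize exceeds feature count; all features unassigned")
    return(methods::new("ModuleSet",
      labels = setNames(integer(n), ids),
      mergeHeights = numeric(), params = list(minSize = minSize)
    ))
  }
  hc <- hclust(as.dist(diss), method = "average")
  if (!is.null(cutQuantile)) {
    cutHeight <- as.numeric(quantile(hc$height, cutQuantile))
  }
  raw <- cutree(hc, h = cutHeight)
  tab <- table(raw)
  keep <- as.integer(names(tab)[tab >= minSize])
  labels <- integer(n)
  for (i in seq_along(keep)) labels[raw == keep[i]] <- i
  names(labels) <- ids

  if (!is.null(expr) && max(labels) > 1) {
    labels <- .mergeCloseModules(labels, expr, mergeCor)
  }
  labels <- .relabelBySize(labels)
  if (all(labels == 0)) warning("all features unassigned")
  methods::new("ModuleSet",
    labels = labels, mergeHeights = hc$height,
    params = list(
      minSize = minSize, cutQuantile = cutQuantile,
      mergeCor = mergeCor, cutHeight = cutHeight
    )
  )
}

## iteratively merge the pair of modules with the most correlated
## eigengenes until none exceeds the threshold
.mergeCloseModules <- function(labels, expr, mergeCor) {
  expr <- as.matrix(expr)[names(labels), , drop = FALSE]
  repeat {
    k <- max(labels)
    if (k < 2) {
      return(labels)
    }
    eg <- moduleEigengenes(expr, labels)
    cc <- cor(t(eg))
    diag(cc) <- -Inf
    if (max(cc) <= mergeCor) {
      return(labels)
    }
    ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    a <- min(ij)
    b <- max(ij)
    labels[labels == b] <- a
    labels[labels > b] <- labels[labels > b] - 1L
  }
}

.relabelBySize <- function(labels) {
  lb <- labels[labels > 0]
  if (!length(lb)) {
    return(labels)
  }
  tab <- sort(table(lb), decreasing = TRUE)
  map <- setNames(seq_along(tab), names(tab))
  labels[labels > 0] <- map[as.character(lb)]
  storage.mode(labels) <- "integer"
  labels
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of the
#' standardized (per-feature z-scored) module submatrix, unit-norm over
#' samples and sign-oriented so that its correlation with the mean module
#' profile is nonnegative. A size-1 module returns that feature's
#' standardized profile (rescaled to unit norm).
#'
#' @param expr Expression matrix, features x samples.
#' @param labels Named module label vector (from [moduleLabels()]) or a
#'   [ModuleSet-class].
#' @return Matrix, modules x samples, rownames `ME1`, `ME2`, ...
#' @export
moduleEigengenes <- function(expr, labels) {
  if (methods::is(labels, "ModuleSet")) labels <- moduleLabels(labels)
  expr <- as.matrix(expr)
  if (!all(names(labels) %in% rownames(expr))) {
    stop("expression matrix lacks some labelled features")
  }
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("no non-grey modules")
  eg <- t(vapply(mods, function(m) {
    sub <- expr[names(labels)[labels == m], , drop = FALSE]
    z <- t(scale(t(sub)))
    z[!is.finite(z)] <- 0
    if (nrow(z) == 1) {
      v <- as.numeric(z)
      return(v / sqrt(sum(v^2)))
    }
    sv <- svd(z, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (cor(e, colMeans(z)) < 0) e <- -e
    e
  }, numeric(ncol(expr))))
  dimnames(eg) <- list(paste0("ME", mods), colnames(expr))
  eg
}

#' Pearson correlation with closed-form p-values
#'
#' p-values come from the t map `t = r sqrt((n-2)/(1-r^2))` with n-2
#' degrees of freedom, two-sided; `|r| = 1` maps to p = 0.
#'
#' @param x Matrix, variables x samples.
#' @param y Matrix, variables x samples (same samples).
#' @return List with matrices `r` and `p` (rows of `x` by rows of `y`).
#' @export
corWithP <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (ncol(x) != ncol(y)) stop("sample dimensions differ")
  n <- ncol(x)
  if (n < 4) stop("need >= 4 samples")
  r <- cor(t(x), t(y))
  r2 <- pmin(r^2, 1)
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * pt(tt, df = n - 2, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  p[p > 1] <- 1
  list(r = r, p = p)
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with each trait, with
#' closed-form t-based p-values.
#'
#' @param eigengenes Matrix from [moduleEigengenes()] (modules x samples).
#' @param traits data.frame or matrix of traits, samples x traits, rows
#'   aligned to eigengene columns.
#' @return List with matrices `r` and `p` (modules x traits).
#' @export
moduleTraitCor <- function(eigengenes, traits) {
  traits <- as.matrix(traits)
  if (nrow(traits) != ncol(eigengenes)) {
    stop("traits must have one row per sample")
  }
  corWithP(eigengenes, t(traits))
}

#' Hub genes by intramodular connectivity
#'
#' Ranks the module's features by `kWithin = sum_{j in module} a_ij`
#' (descending; exact ties broken lexicographically by feature id) and
#' returns the top `topN`.
#'
#' @param network A [CoexNetwork-class].
#' @param labels Module labels (named vector or [ModuleSet-class]).
#' @param module Module label to rank.
#' @param topN Number of hub genes (default 5).
#' @return data.frame with columns `feature_id`, `kWithin`.
#' @export
hubGenes <- function(network, labels, module, topN = 5) {
  if (methods::is(labels, "ModuleSet")) labels <- moduleLabels(labels)
  ids <- names(labels)[labels == module]
  if (!length(ids)) stop("module ", module, " does not exist")
  a <- adjacency(network)[ids, ids, drop = FALSE]
  diag(a) <- 0
  kw <- rowSums(a)
  ord <- order(-kw, names(kw))
  if (topN > length(ids)) {
    warning("module smaller than topN; returning all members")
    topN <- length(ids)
  }
  sel <- ord[seq_len(topN)]
  data.frame(feature_id = names(kw)[sel], kWithin = unname(kw[sel]))
}
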