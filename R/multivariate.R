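## OPLS-DA with VIP scoring for trait screening, plus the small
## closed-form computations (degree of leaf curling, 2^-ddCt relative
## expression) and hypergeometric gene-set enrichment.

#' Fit an OPLS-DA model
#'
#' NIPALS orthogonal projections to latent structures: `nOrtho` components
#' of variation orthogonal to the class response are removed one by one,
#' then a single predictive component is fitted. With `nOrtho = 0` the
#' model reduces to plain PLS-DA (whose first weight vector is
#' proportional to `X'y`). Binary classes use a centered +/-1 response;
#' more levels are dummy-coded and fitted by PLS2 iteration.
#'
#' Weight vectors are unit norm and sign-oriented so their
#' largest-magnitude element is positive, making fits reproducible.
#'
#' @param X Matrix samples x variables. Columns are standardized
#'   internally (unit variance); a constant column is an error.
#' @param classes Factor (or coercible) of class labels, one per sample.
#' @param nOrtho Number of orthogonal components to strip (default 1).
#' @return An object of class `oplsModel`: list with elements `W` (p x 1
#'   predictive weights), `scores` (predictive scores), `loadings`,
#'   `Wortho`, `scoresOrtho` (p x nOrtho / n x nOrtho), `ssY` (explained
#'   sum of squares of the response per predictive component), `nVar`,
#'   `variables`, `classes`.
#' @seealso [vipScores()]
#' @export
oplsFit <- function(X, classes, nOrtho = 1) {
  X <- as.matrix(X)
  if (nOrtho < 0) stop("nOrtho must be >= 0")
  classes <- factor(classes)
  if (nlevels(classes) < 2) stop("need >= 2 classes")
  if (length(classes) != nrow(X)) stop("one class label per sample required")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    stop(
      "constant variable(s): ",
      paste(colnames(X)[sds == 0], collapse = ", ")
    )
  }
  vars <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  Xs <- scale(X)
  Y <- if (nlevels(classes) == 2) {
    matrix(scale(ifelse(classes == levels(classes)[1], -1, 1),
      scale = FALSE
    ), ncol = 1)
  } else {
    scale(stats::model.matrix(~ classes - 1), scale = FALSE)
  }

  Wo <- matrix(0, ncol(Xs), 0)
  To <- matrix(0, nrow(Xs), 0)
  Xf <- Xs
  for (h in seq_len(nOrtho)) {
    w <- .plsWeight(Xf, Y)
    t1 <- Xf %*% w
    p1 <- crossprod(Xf, t1) / sum(t1^2)
    wo <- p1 - as.numeric(crossprod(w, p1)) * w
    if (sqrt(sum(wo^2)) < 1e-10) break # no orthogonal variation left
    wo <- .orientSign(wo / sqrt(sum(wo^2)))
    to <- Xf %*% wo
    po <- crossprod(Xf, to) / sum(to^2)
    Xf <- Xf - to %*% t(po)
    Wo <- cbind(Wo, wo)
    To <- cbind(To, to)
  }
  w <- .orientSign(.plsWeight(Xf, Y))
  t1 <- Xf %*% w
  p1 <- crossprod(Xf, t1) / sum(t1^2)
  q1 <- crossprod(Y, t1) / sum(t1^2)
  ssY <- sum((t1 %*% t(q1))^2)
  rownames(w) <- vars
  structure(
    list(
      W = w, scores = as.numeric(t1), loadings = as.numeric(p1),
      Wortho = Wo, scoresOrtho = To, ssY = ssY,
      nVar = ncol(Xs), variables = vars, classes = classes
    ),
    class = "oplsModel"
  )
}

## PLS weight for (possibly multi-column) Y: dominant direction of X'Y,
## computed by the NIPALS inner loop; for single-column Y this is X'y
## normalized, in closed form.
.plsWeight <- function(X, Y) {
  if (ncol(Y) == 1) {
    w <- crossprod(X, Y[, 1])
    return(w / sqrt(sum(w^2)))
  }
  u <- Y[, 1]
  w <- NULL
  for (it in 1:500) {
    w_new <- crossprod(X, u)
    w_new <- w_new / sqrt(sum(w_new^2))
    t1 <- X %*% w_new
    q1 <- crossprod(Y, t1) / sum(t1^2)
    u <- Y %*% q1 / sum(q1^2)
    if (!is.null(w) && max(abs(w_new - w)) < 1e-12) {
      w <- w_new
      break
    }
    w <- w_new
  }
  w
}

.orientSign <- function(w) {
  i <- which.max(abs(w))
  if (w[i] < 0) -w else w
}

#' @export
print.oplsModel <- function(x, ...) {
  cat(
    "OPLS-DA model:", x$nVar, "variables,",
    ncol(x$Wortho), "orthogonal component(s),",
    nlevels(x$classes), "classes\n"
  )
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a(w_ja^2 SS_a) / sum_a SS_a)` over the predictive
#' component(s); orthogonal components are excluded. With unit-norm
#' weights, `sum_j VIP_j^2 = p`. Variables with VIP > 1 carry the
#' screening flag.
#'
#' @param model An `oplsModel` from [oplsFit()].
#' @return data.frame with columns `variable`, `vip`, `selected`.
#' @examples
#' X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' X[, 1] <- X[, 1] + rep(c(-2, 2), each = 10)
#' fit <- oplsFit(X, rep(c("lo", "hi"), each = 10), nOrtho = 0)
#' vipScores(fit)
#' @export
vipScores <- function(model) {
  if (!inherits(model, "oplsModel")) stop("need an oplsModel")
  if (model$ssY <= 0) stop("zero explained sum of squares")
  w2 <- model$W[, 1]^2 # single predictive component; SS weights cancel
  vip <- sqrt(model$nVar * w2 / sum(w2))
  data.frame(
    variable = model$variables, vip = as.numeric(vip),
    selected = as.numeric(vip) > 1, row.names = NULL
  )
}

#' Degree of leaf curling
#'
#' `DLC = (Lg - Ln) / Lg * 100` (percent), from the stretched leaf width
#' `Lg` and the natural curled width `Ln`.
#'
#' @param Lg Stretched (flattened) leaf width; must be positive.
#' @param Ln Natural curled width; `0 <= Ln <= Lg`.
#' @return DLC in percent (vectorized).
#' @examples
#' dlc(2, 1) # 50
#' @export
dlc <- function(Lg, Ln) {
  if (any(Lg <= 0)) stop("Lg must be positive")
  if (any(Ln < 0) || any(Ln > Lg)) stop("require 0 <= Ln <= Lg")
  (Lg - Ln) / Lg * 100
}

#' Relative expression from qPCR
#'
#' The 2^-ddCt rule: relative expression versus a reference gene and
#' reference condition.
#'
#' @param ddct Delta-delta-Ct value(s) in cycles.
#' @return `2^-ddct` (vectorized).
#' @examples
#' relativeExpression(c(0, 1, -2)) # 1, 0.5, 4
#' @export
relativeExpression <- function(ddct) {
  if (any(!is.finite(ddct))) stop("ddCt must be finite")
  2^(-ddct)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and each gene set (intersected with the universe), BH-adjusted across
#' sets and ranked by p-value.
#'
#' @param query Character vector of genes (must be a subset of
#'   `universe`).
#' @param universe Character vector: the gene universe.
#' @param geneSets Named list of character vectors (e.g. from
#'   [readGeneSets()]).
#' @return data.frame with columns `set`, `setSize`, `overlap`, `pvalue`,
#'   `qvalue`, ordered by increasing p.
#' @export
enrichmentTest <- function(query, universe, geneSets) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe)) {
    stop(
      "query gene(s) outside universe: ",
      paste(head(setdiff(query, universe), 5), collapse = ", ")
    )
  }
  sets <- lapply(geneSets, intersect, universe)
  sets <- sets[lengths(sets) > 0]
  if (!length(sets)) stop("no gene set overlaps the universe")
  N <- length(universe)
  k <- length(query)
  res <- data.frame(
    set = names(sets),
    setSize = lengths(sets),
    overlap = vapply(sets, function(s) length(intersect(s, query)), 0L),
    row.names = NULL
  )
  res$pvalue <- phyper(res$overlap - 1, res$setSize, N - res$setSize, k,
    lower.tail = FALSE
  )
  res$qvalue <- bhAdjust(res$pvalue)
  res[order(res$pvalue, res$set), , drop = FALSE]
}
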