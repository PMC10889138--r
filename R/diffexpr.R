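## Normalization and negative-binomial differential expression.
##
## The NB test is a desk-scale stand-in for the DESeq2/edgeR machinery the
## field uses: median-of-ratios size factors, method-of-moments gene-wise
## dispersion shrunk toward a parametric mean-dispersion trend
## (alpha(mu) = a0 + a1/mu), and a Wald test on the log fold change with
## the NB delta-method standard error, referred to the standard normal
## (the DESeq2 convention). Thresholding follows the study rules:
## fold change >= 2 with BH FDR <= 0.01 for mRNA/lncRNA, fold change
## >= 1.5 with raw p <= 0.05 for miRNA.

#' Median-of-ratios size factors
#'
#' `factor_j = median_g count_gj / geomean_g`, over genes positive in every
#' sample; factors are rescaled to geometric mean 1.
#'
#' @param counts Count matrix, genes x samples (>= 2 samples).
#' @param pseudocount Add 0.5 to all counts for the reference computation
#'   (use when no gene is positive in all samples).
#' @return Named positive numeric vector, one factor per sample.
#' @export
sizeFactorsMoR <- function(counts, pseudocount = FALSE) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples")
  work <- if (pseudocount) counts + 0.5 else counts
  pos <- rowSums(work > 0) == ncol(work)
  if (!any(pos)) {
    stop(
      "no gene is positive in all samples; ",
      "retry with pseudocount = TRUE"
    )
  }
  logg <- rowMeans(log(work[pos, , drop = FALSE]))
  sf <- apply(work[pos, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - logg))
  })
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' FPKM and TPM normalization
#'
#' `fpkmNormalize()` computes fragments per kilobase per million:
#' `count / (length_kb * total / 1e6)`. `tpmNormalize()` computes
#' transcripts per million, whose columns sum to 1e6; with unit lengths it
#' is counts-proportional (the miRNA convention).
#'
#' @param counts Count matrix, features x samples.
#' @param lengths Feature lengths in nt (recycled; `tpmNormalize()`
#'   defaults to 1).
#' @param totals Per-sample library sizes; defaults to column sums.
#' @return Matrix of normalized values (same dimnames).
#' @examples
#' m <- matrix(c(10, 90), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' tpmNormalize(m) # sums to 1e6
#' @export
fpkmNormalize <- function(counts, lengths, totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("feature lengths must be positive")
  if (any(totals <= 0)) stop("zero library total")
  len_kb <- rep_len(lengths, nrow(counts)) / 1000
  sweep(counts / len_kb, 2, totals / 1e6, "/")
}

#' @rdname fpkmNormalize
#' @export
tpmNormalize <- function(counts, lengths = 1) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("feature lengths must be positive")
  rate <- counts / (rep_len(lengths, nrow(counts)) / 1000)
  tot <- colSums(rate)
  if (any(tot <= 0)) stop("zero library total")
  sweep(rate, 2, tot / 1e6, "/")
}

#' Negative-binomial Wald test for two groups
#'
#' @param counts Count matrix, genes x samples.
#' @param group Factor (or coercible) with exactly two levels; the first
#'   level is the reference, log2 fold changes are second vs first. Each
#'   group needs >= 2 replicates.
#' @param sizeFactors Optional per-sample size factors; computed by
#'   [sizeFactorsMoR()] when `NULL`.
#' @param shrink Weight (0-1) pulling the log gene-wise dispersion toward
#'   the fitted trend (default 0.9; strong shrinkage keeps the Wald test
#'   calibrated at 3 replicates per group).
#' @return data.frame with columns `feature_id`, `baseMean`, `log2FC`,
#'   `se`, `stat`, `pvalue`, `qvalue` (BH across genes).
#' @seealso [callDE()] for thresholding, [bhAdjust()].
#' @export
nbTest <- function(counts, group, sizeFactors = NULL, shrink = 0.9) {
  counts <- as.matrix(counts)
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (any(table(group) < 2)) stop("each group needs >= 2 replicates")
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMoR(counts)
  q <- sweep(counts, 2, sizeFactors, "/")
  ia <- group == levels(group)[1]
  ib <- group == levels(group)[2]
  na <- sum(ia)
  nb <- sum(ib)
  qa <- q[, ia, drop = FALSE]
  qb <- q[, ib, drop = FALSE]
  mua <- rowMeans(qa)
  mub <- rowMeans(qb)
  baseMean <- rowMeans(q)

  # method-of-moments dispersion pooled within groups: var = mu + alpha mu^2
  va <- apply(qa, 1, var)
  vb <- apply(qb, 1, var)
  s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  mbar <- (na * mua + nb * mub) / (na + nb)
  m2bar <- (na * mua^2 + nb * mub^2) / (na + nb)
  disp_mom <- (s2 - mbar) / pmax(m2bar, 1e-8)
  trend <- .dispersionTrend(disp_mom, mbar)
  alpha <- .shrinkDispersion(disp_mom, trend, shrink)

  log2fc <- log2((mub + 0.5) / (mua + 0.5))
  inv_sa <- sum(1 / sizeFactors[ia])
  inv_sb <- sum(1 / sizeFactors[ib])
  v_log <- inv_sa / (na^2 * (mua + 0.5)) + alpha / na +
    inv_sb / (nb^2 * (mub + 0.5)) + alpha / nb
  se_nat <- sqrt(v_log)
  stat <- (log2fc * log(2)) / se_nat
  pvalue <- 2 * pnorm(-abs(stat))
  data.frame(
    feature_id = rownames(counts) %||% paste0("g", seq_len(nrow(counts))),
    baseMean = baseMean,
    log2FC = log2fc,
    se = se_nat / log(2),
    stat = stat,
    pvalue = pvalue,
    qvalue = bhAdjust(pvalue),
    row.names = NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## parametric mean-dispersion trend alpha(mu) = a0 + a1/mu fit on genes
## with a positive moment estimate; falls back to the median when the fit
## is degenerate. Returns fitted values floored at 1e-8.
.dispersionTrend <- function(disp, mu) {
  ok <- is.finite(disp) & disp > 0 & mu > 0
  floor_a <- 1e-8
  if (sum(ok) < 10) {
    md <- if (any(ok)) median(disp[ok]) else floor_a
    return(rep(max(md, floor_a), length(disp)))
  }
  fit <- tryCatch(
    stats::lm(d ~ im, data = data.frame(d = disp[ok], im = 1 / mu[ok])),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(rep(max(median(disp[ok]), floor_a), length(disp)))
  }
  co <- stats::coef(fit)
  tr <- co[1] + co[2] / pmax(mu, 1e-8)
  bad <- !is.finite(tr) | tr <= 0
  tr[bad] <- max(median(disp[ok]), floor_a)
  pmax(tr, floor_a)
}

## log-space shrinkage of gene-wise dispersion toward the trend; genes
## whose moment estimate is non-positive fall back to the trend (Poisson
## floor 1e-8)
.shrinkDispersion <- function(disp, trend, shrink) {
  stopifnot(shrink >= 0, shrink <= 1)
  out <- trend
  ok <- is.finite(disp) & disp > 0
  out[ok] <- exp((1 - shrink) * log(disp[ok]) + shrink * log(trend[ok]))
  pmax(out, 1e-8)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]), with input
#' validation.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Vector of BH-adjusted q-values.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Call differential expression at fold-change / significance thresholds
#'
#' A feature is `up` if `log2FC >= log2(fcMin)` and its (adjusted) p-value
#' is at most `alphaMax`; `down` if `log2FC <= -log2(fcMin)` under the same
#' significance rule; otherwise `ns`. Both boundaries are inclusive
#' (fold change >= fcMin, FDR/p <= alphaMax).
#'
#' @param results data.frame from [nbTest()].
#' @param fcMin Minimum fold change (default 2; use 1.5 for miRNA).
#' @param alphaMax Maximum FDR or p-value (default 0.01; 0.05 for miRNA).
#' @param useQ Test the BH q-value (`TRUE`, mRNA/lncRNA rule) or the raw
#'   p-value (`FALSE`, miRNA rule)?
#' @return `results` with added `significant` (logical) and `direction`
#'   (`"up"`, `"down"`, `"ns"`) columns.
#' @export
callDE <- function(results, fcMin = 2, alphaMax = 0.01, useQ = TRUE) {
  if (fcMin <= 0 || alphaMax <= 0) stop("thresholds must be positive")
  crit <- if (useQ) results$qvalue else results$pvalue
  lfc <- log2(fcMin)
  up <- results$log2FC >= lfc & crit <= alphaMax
  dn <- results$log2FC <= -lfc & crit <= alphaMax
  results$significant <- up | dn
  results$direction <- ifelse(up, "up", ifelse(dn, "down", "ns"))
  results
}
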