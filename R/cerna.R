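## Assembly of lncRNA-miRNA-mRNA competitive triplets: intersect module /
## differential-expression evidence with the miRNA target-pair layer, then
## keep (lncRNA, miRNA, mRNA) combinations in which both partners share
## the miRNA as a target and are negatively co-expressed with it.

#' Candidate mRNAs for the ceRNA network
#'
#' Three-way intersection: differentially expressed mRNAs, mRNAs in the
#' trait-associated module(s), and mRNAs targeted by a differential miRNA.
#'
#' @param deMrnas Character vector of DE mRNA ids.
#' @param moduleGenes Character vector of genes in the selected module(s).
#' @param targetPairs data.frame of miRNA-target pairs (columns
#'   `mirna_id`, `target_id`), already restricted to differential miRNAs.
#' @return Character vector (sorted); empty with a warning if the
#'   intersection is empty.
#' @export
candidateMrnas <- function(deMrnas, moduleGenes, targetPairs) {
  if (!length(deMrnas) || !length(moduleGenes) || !nrow(targetPairs)) {
    stop("all three evidence layers must be non-empty")
  }
  out <- sort(intersect(
    intersect(unique(deMrnas), unique(moduleGenes)),
    unique(targetPairs$target_id)
  ))
  if (!length(out)) warning("empty candidate mRNA set")
  out
}

#' Assemble competitive triplets
#'
#' For every miRNA that targets both a candidate mRNA `g` and a candidate
#' lncRNA `l` (per `targetPairs`), the triplet `(l, m, g)` is emitted iff
#' `r(m, g) <= negRMax` and `r(m, l) <= negRMax` with both correlation
#' p-values `<= pMax`. Correlations are Pearson, computed across samples
#' on the supplied expression matrices. Output is ordered lexicographically
#' by (lncRNA, miRNA, mRNA) and is invariant to input row order.
#'
#' @param candidates Character vector of candidate mRNA ids (from
#'   [candidateMrnas()]).
#' @param lncCandidates Character vector of candidate (differentially
#'   expressed) lncRNA ids.
#' @param targetPairs data.frame with `mirna_id`, `target_id` covering
#'   both mRNA and lncRNA targets.
#' @param mirnaExpr,mrnaExpr,lncExpr Expression matrices (features x
#'   samples, sample-aligned; log scale recommended).
#' @param negRMax Maximum (i.e. most positive) allowed miRNA correlation
#'   (default -0.5).
#' @param pMax Maximum correlation p-value (default 0.05).
#' @param requirePositiveLncMrna Optionally also require
#'   `r(lncRNA, mRNA) > 0` (common ceRNA practice; off by default).
#' @return data.frame with columns `lncrna_id`, `mirna_id`, `mrna_id`,
#'   `r_mirna_mrna`, `p_mirna_mrna`, `r_mirna_lncrna`, `p_mirna_lncrna`,
#'   `r_lncrna_mrna`.
#' @export
assembleTriplets <- function(candidates, lncCandidates, targetPairs,
                             mirnaExpr, mrnaExpr, lncExpr,
                             negRMax = -0.5, pMax = 0.05,
                             requirePositiveLncMrna = FALSE) {
  empty <- data.frame(
    lncrna_id = character(), mirna_id = character(), mrna_id = character(),
    r_mirna_mrna = numeric(), p_mirna_mrna = numeric(),
    r_mirna_lncrna = numeric(), p_mirna_lncrna = numeric(),
    r_lncrna_mrna = numeric()
  )
  mp <- targetPairs[targetPairs$target_id %in% candidates, , drop = FALSE]
  lp <- targetPairs[targetPairs$target_id %in% lncCandidates, , drop = FALSE]
  mirs <- intersect(unique(mp$mirna_id), unique(lp$mirna_id))
  if (!length(mirs)) {
    return(empty)
  }
  absent <- setdiff(mirs, rownames(mirnaExpr))
  if (length(absent)) {
    warning(
      "miRNA(s) absent from expression matrix, skipped: ",
      paste(absent, collapse = ", ")
    )
    mirs <- setdiff(mirs, absent)
  }
  rows <- list()
  for (m in sort(mirs)) {
    gs <- sort(intersect(unique(mp$target_id[mp$mirna_id == m]), rownames(mrnaExpr)))
    ls <- sort(intersect(unique(lp$target_id[lp$mirna_id == m]), rownames(lncExpr)))
    if (!length(gs) || !length(ls)) next
    cg <- corWithP(mirnaExpr[m, , drop = FALSE], mrnaExpr[gs, , drop = FALSE])
    cl <- corWithP(mirnaExpr[m, , drop = FALSE], lncExpr[ls, , drop = FALSE])
    ok_g <- gs[cg$r[1, ] <= negRMax & cg$p[1, ] <= pMax]
    ok_l <- ls[cl$r[1, ] <= negRMax & cl$p[1, ] <= pMax]
    if (!length(ok_g) || !length(ok_l)) next
    grid <- expand.grid(
      lncrna_id = ok_l, mrna_id = ok_g,
      stringsAsFactors = FALSE
    )
    r_lm <- vapply(seq_len(nrow(grid)), function(i) {
      cor(
        as.numeric(lncExpr[grid$lncrna_id[i], ]),
        as.numeric(mrnaExpr[grid$mrna_id[i], ])
      )
    }, 0)
    keep <- rep(TRUE, nrow(grid))
    if (requirePositiveLncMrna) keep <- r_lm > 0
    if (!any(keep)) next
    rows[[length(rows) + 1]] <- data.frame(
      lncrna_id = grid$lncrna_id[keep], mirna_id = m,
      mrna_id = grid$mrna_id[keep],
      r_mirna_mrna = cg$r[1, match(grid$mrna_id[keep], gs)],
      p_mirna_mrna = cg$p[1, match(grid$mrna_id[keep], gs)],
      r_mirna_lncrna = cl$r[1, match(grid$lncrna_id[keep], ls)],
      p_mirna_lncrna = cl$p[1, match(grid$lncrna_id[keep], ls)],
      r_lncrna_mrna = r_lm[keep]
    )
  }
  if (!length(rows)) {
    return(empty)
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$lncrna_id, res$mirna_id, res$mrna_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Summarize an assembled ceRNA network
#'
#' @param triplets data.frame from [assembleTriplets()].
#' @return List with `n_lncrna`, `n_mirna`, `n_mrna` (distinct nodes per
#'   type), `n_edges_lnc_mir`, `n_edges_mir_mrna` and `n_edges` (both
#'   bipartite layers after deduplication).
#' @examples
#' networkSummary(data.frame(
#'   lncrna_id = "l1", mirna_id = "m1", mrna_id = "g1"
#' ))
#' @export
networkSummary <- function(triplets) {
  e_lm <- unique(triplets[, c("lncrna_id", "mirna_id")])
  e_mg <- unique(triplets[, c("mirna_id", "mrna_id")])
  list(
    n_lncrna = length(unique(triplets$lncrna_id)),
    n_mirna = length(unique(triplets$mirna_id)),
    n_mrna = length(unique(triplets$mrna_id)),
    n_edges_lnc_mir = nrow(e_lm),
    n_edges_mir_mrna = nrow(e_mg),
    n_edges = nrow(e_lm) + nrow(e_mg)
  )
}
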