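## The three relation layers the ceRNA assembly consumes:
##   - miRNA -> transcript target pairs by plant-style complementarity
##     scoring (mismatch +1, G:U wobble +0.5, penalties doubled at miRNA
##     positions 2-13, Watson-Crick match 0; lower scores are better)
##   - lncRNA cis targets by genomic proximity (100 kb window)
##   - lncRNA trans targets by expression correlation (r > 0.9, p < 0.01)

.WC_PAIRS <- c(A = "U", U = "A", G = "C", C = "G")

.normalizeRna <- function(seq) {
  s <- toupper(seq)
  s <- chartr("T", "U", s)
  bad <- grepl("[^ACGU]", s)
  if (any(bad)) {
    stop(
      "invalid character(s) in sequence(s): ",
      paste(head(which(bad), 5), collapse = ", ")
    )
  }
  s
}

#' Plant-style miRNA target complementarity score
#'
#' Scores an ungapped alignment of a miRNA (5'->3') against a candidate
#' target site (5'->3', so the miRNA pairs with the site read in reverse).
#' Per miRNA position: Watson-Crick pair 0, G:U wobble 0.5, mismatch 1;
#' penalties are doubled at positions 2-13 (the core). Lower is better;
#' a perfect complement scores 0.
#'
#' @param mirnaSeq miRNA sequence, 5'->3' (A/C/G/U, T accepted).
#' @param siteSeq Target site sequence, 5'->3', same length.
#' @return Nonnegative penalty score.
#' @examples
#' mirnaTargetScore("UGGAAGACUAGUGAUUUUGUUGU",
#'                  revComplementRna("UGGAAGACUAGUGAUUUUGUUGU")) # 0
#' @export
mirnaTargetScore <- function(mirnaSeq, siteSeq) {
  m <- strsplit(.normalizeRna(mirnaSeq), "")[[1]]
  s <- strsplit(.normalizeRna(siteSeq), "")[[1]]
  if (length(m) != length(s)) stop("miRNA and site must have equal length")
  s_rev <- rev(s) # miRNA position i pairs with site position L - i + 1
  wc <- .WC_PAIRS[m] == s_rev
  wobble <- (m == "G" & s_rev == "U") | (m == "U" & s_rev == "G")
  pen <- ifelse(wc, 0, ifelse(wobble, 0.5, 1))
  core <- seq_along(m) >= 2 & seq_along(m) <= 13
  sum(pen * ifelse(core, 2, 1))
}

#' Reverse complement of an RNA sequence
#'
#' @param seq RNA (or DNA) sequence string.
#' @return Reverse complement as an RNA string.
#' @export
revComplementRna <- function(seq) {
  s <- rev(strsplit(.normalizeRna(seq), "")[[1]])
  paste(unname(.WC_PAIRS[s]), collapse = "")
}

#' Predict miRNA targets by sliding-window complementarity
#'
#' Slides each miRNA across each transcript and reports every window whose
#' penalty score is at most `maxScore`. Windows are prefiltered with a
#' mismatch-count scan (any window scoring <= maxScore has at most
#' `2 * maxScore` non-Watson-Crick positions) and then scored exactly, so
#' the result equals an exhaustive position-by-position rescan. Output is
#' ordered by (transcript id, position, miRNA id).
#'
#' @param mirnas Named character vector (or `RNAStringSet`/`DNAStringSet`)
#'   of miRNA sequences, 5'->3'.
#' @param transcripts Named character vector (or `XStringSet`) of
#'   transcript sequences, 5'->3'.
#' @param maxScore Score cutoff (default 4).
#' @return data.frame with columns `mirna_id`, `target_id`, `score`,
#'   `position` (1-based start of the site on the transcript).
#' @export
predictTargets <- function(mirnas, transcripts, maxScore = 4) {
  mir <- .asRnaCharacter(mirnas)
  txs <- .asRnaCharacter(transcripts)
  if (is.null(names(mir)) || is.null(names(txs))) {
    stop("mirnas and transcripts must be named")
  }
  # DNA alphabet for the Biostrings prefilter
  tx_dna <- DNAStringSet(chartr("U", "T", txs))
  out <- vector("list", length(mir))
  max_mm <- floor(2 * maxScore)
  for (i in seq_along(mir)) {
    pat <- DNAString(chartr("U", "T", revComplementRna(mir[[i]])))
    if (max_mm >= length(pat)) {
      hits_by_tx <- lapply(width(tx_dna) - length(pat) + 1L, function(nw) {
        if (nw < 1) integer() else seq_len(nw)
      })
    } else {
      mh <- vmatchPattern(pat, tx_dna, max.mismatch = max_mm)
      hits_by_tx <- Biostrings::startIndex(mh)
      hits_by_tx <- lapply(hits_by_tx, function(s) if (is.null(s)) integer() else s)
    }
    rows <- list()
    for (j in seq_along(txs)) {
      starts <- hits_by_tx[[j]]
      starts <- starts[starts >= 1 & starts + nchar(mir[[i]]) - 1 <= nchar(txs[[j]])]
      if (!length(starts)) next
      sc <- vapply(starts, function(s0) {
        site <- substr(txs[[j]], s0, s0 + nchar(mir[[i]]) - 1)
        mirnaTargetScore(mir[[i]], site)
      }, 0)
      keep <- sc <= maxScore
      if (!any(keep)) next
      rows[[length(rows) + 1]] <- data.frame(
        mirna_id = names(mir)[i], target_id = names(txs)[j],
        score = sc[keep], position = as.integer(starts[keep])
      )
    }
    out[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(
      mirna_id = character(), target_id = character(),
      score = numeric(), position = integer()
    ))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$target_id, res$position, res$mirna_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.asRnaCharacter <- function(x) {
  if (methods::is(x, "XStringSet")) {
    setNames(.normalizeRna(as.character(x)), names(x))
  } else {
    setNames(.normalizeRna(unlist(x)), names(x))
  }
}

#' Cis targets of lncRNAs by genomic proximity
#'
#' Links a coding gene to a lncRNA when the gene span overlaps the lncRNA
#' span or lies within `window` bp of it (gap distance strictly below
#' `window`) on the same chromosome, either strand. Distance is 0 for
#' overlapping spans, else the gap length in bp.
#'
#' @param lncrnas `GRanges` of lncRNA spans (needs a `tx_id` metadata
#'   column) or a [TxAnnotation-class] (its lncRNA_candidate transcripts
#'   are used).
#' @param coding `GRanges` of coding gene/transcript spans (needs
#'   `gene_id`), or missing when `lncrnas` is a `TxAnnotation`.
#' @param window Window size in bp (default 1e5).
#' @return data.frame with columns `lncrna_id`, `gene_id`, `mode`
#'   (`"cis"`), `distance`.
#' @export
cisTargets <- function(lncrnas, coding, window = 1e5) {
  if (methods::is(lncrnas, "TxAnnotation")) {
    tx <- transcriptRanges(lncrnas)
    coding <- tx[tx$biotype == "coding"]
    lncrnas <- tx[tx$biotype == "lncRNA_candidate"]
  }
  if (!length(lncrnas) || !length(coding)) {
    return(data.frame(
      lncrna_id = character(), gene_id = character(),
      mode = character(), distance = integer()
    ))
  }
  lid <- lncrnas$tx_id %||% names(lncrnas)
  gid <- coding$gene_id %||% names(coding)
  d <- suppressWarnings(outerDistance(lncrnas, coding))
  hit <- which(!is.na(d) & d < window, arr.ind = TRUE)
  if (!nrow(hit)) {
    return(data.frame(
      lncrna_id = character(), gene_id = character(),
      mode = character(), distance = integer()
    ))
  }
  res <- data.frame(
    lncrna_id = lid[hit[, 1]], gene_id = gid[hit[, 2]],
    mode = "cis", distance = as.integer(d[hit])
  )
  res <- res[order(res$lncrna_id, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## pairwise gap distances between two GRanges (NA across chromosomes);
## 0 for overlapping or adjacent spans, else the gap in bp
outerDistance <- function(x, y) {
  m <- matrix(NA_real_, length(x), length(y))
  cx <- as.character(seqnames(x))
  cy <- as.character(seqnames(y))
  for (chr in unique(cx)) {
    ix <- which(cx == chr)
    iy <- which(cy == chr)
    if (!length(iy)) next
    for (i in ix) {
      gap <- pmax(
        start(y)[iy] - end(x)[i] - 1L,
        start(x)[i] - end(y)[iy] - 1L
      )
      m[i, iy] <- pmax(gap, 0L)
    }
  }
  m
}

#' Trans targets of lncRNAs by expression correlation
#'
#' Pearson correlation of each lncRNA profile with each coding-gene
#' profile across samples; pairs with `r > rMin` and `p < pMax` (both
#' strict, per the screening rule r > 0.9, p < 0.01) are linked.
#'
#' @param lncExpr Matrix, lncRNAs x samples (log scale recommended).
#' @param mrnaExpr Matrix, mRNAs x samples (same samples).
#' @param rMin Correlation threshold (strict >; default 0.9).
#' @param pMax p-value threshold (strict <; default 0.01).
#' @return data.frame with columns `lncrna_id`, `gene_id`, `mode`
#'   (`"trans"`), `r`, `p`.
#' @export
transTargets <- function(lncExpr, mrnaExpr, rMin = 0.9, pMax = 0.01) {
  lncExpr <- as.matrix(lncExpr)
  mrnaExpr <- as.matrix(mrnaExpr)
  if (ncol(lncExpr) < 4) stop("need >= 4 samples")
  if (ncol(lncExpr) < 10) {
    warning("fewer than 10 samples; trans-target correlations are unstable")
  }
  lv <- apply(lncExpr, 1, var)
  mv <- apply(mrnaExpr, 1, var)
  if (any(lv == 0) || any(mv == 0)) {
    warning("zero-variance feature(s) skipped")
    lncExpr <- lncExpr[lv > 0, , drop = FALSE]
    mrnaExpr <- mrnaExpr[mv > 0, , drop = FALSE]
  }
  cp <- corWithP(lncExpr, mrnaExpr)
  hit <- which(cp$r > rMin & cp$p < pMax, arr.ind = TRUE)
  res <- data.frame(
    lncrna_id = rownames(lncExpr)[hit[, 1]],
    gene_id = rownames(mrnaExpr)[hit[, 2]],
    mode = if (nrow(hit)) "trans" else character(),
    r = cp$r[hit], p = cp$p[hit]
  )
  res <- res[order(res$lncrna_id, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
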