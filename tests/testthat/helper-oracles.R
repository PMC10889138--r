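# Independent brute-force oracles. These deliberately share no code with
# the implementation: plain loops and closed forms only.

# Benjamini-Hochberg step-up by the definition: sort p, q_i = min over
# j >= i of p_(j) * m / j, capped at 1, mapped back to input order.
bhBrute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(ps[i:m] * m / (i:m), 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# topological overlap by the O(n^3) triple loop
tomBrute <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        w[i, j] <- 1
        next
      }
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      ki <- sum(a[i, ])
      kj <- sum(a[j, ])
      w[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  dimnames(w) <- dimnames(a)
  w
}

# positional classification by all-pairs interval arithmetic on plain
# data frames (1-based closed intervals)
classifyBrute <- function(annotation, lncIds) {
  tx <- transcriptRanges(annotation)
  exl <- exonRanges(annotation)
  df <- data.frame(
    tx_id = tx$tx_id, gene_id = tx$gene_id, biotype = tx$biotype,
    chr = as.character(GenomicRanges::seqnames(tx)),
    strand = as.character(GenomicRanges::strand(tx)),
    start = IRanges::start(tx), end = IRanges::end(tx)
  )
  exd <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    g <- exl[[df$tx_id[i]]]
    data.frame(
      tx = df$tx_id[i], s = IRanges::start(g), e = IRanges::end(g)
    )
  }))
  ovl <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2) + 1)
  coding <- df[df$biotype == "coding", ]
  vapply(lncIds, function(id) {
    li <- df[df$tx_id == id, ]
    lex <- exd[exd$tx == id, ]
    same_bp <- 0
    opp_bp <- 0
    for (ci in seq_len(nrow(coding))) {
      if (coding$chr[ci] != li$chr) next
      cex <- exd[exd$tx == coding$tx_id[ci], ]
      for (a in seq_len(nrow(lex))) {
        for (b in seq_len(nrow(cex))) {
          o <- ovl(lex$s[a], lex$e[a], cex$s[b], cex$e[b])
          if (coding$strand[ci] == li$strand) same_bp <- same_bp + o
          if (coding$strand[ci] != li$strand) opp_bp <- opp_bp + o
        }
      }
    }
    if (same_bp > 0) {
      return("sense")
    }
    if (opp_bp > 0) {
      return("antisense")
    }
    for (ci in seq_len(nrow(coding))) {
      if (coding$chr[ci] != li$chr) next
      cex <- exd[exd$tx == coding$tx_id[ci], ]
      cex <- cex[order(cex$s), ]
      if (nrow(cex) < 2) next
      for (b in seq_len(nrow(cex) - 1)) {
        is <- cex$e[b] + 1
        ie <- cex$s[b + 1] - 1
        if (ie >= is && li$start >= is && li$end <= ie) {
          return("intronic")
        }
      }
    }
    "intergenic"
  }, "")
}

# upper-tail hypergeometric by explicit combinatorial sums
hyperBrute <- function(overlap, setSize, universe, querySize) {
  tot <- choose(universe, querySize)
  num <- 0
  for (x in overlap:min(setSize, querySize)) {
    num <- num + choose(setSize, x) * choose(universe - setSize, querySize - x)
  }
  num / tot
}

# target-score rescan: every window of every transcript, scored from the
# pairing table directly
rescanTargets <- function(mirnas, transcripts, maxScore) {
  pen1 <- function(m, t) {
    wc <- (m == "A" && t == "U") || (m == "U" && t == "A") ||
      (m == "G" && t == "C") || (m == "C" && t == "G")
    if (wc) {
      return(0)
    }
    if ((m == "G" && t == "U") || (m == "U" && t == "G")) {
      return(0.5)
    }
    1
  }
  out <- list()
  for (mn in names(mirnas)) {
    m <- strsplit(mirnas[[mn]], "")[[1]]
    L <- length(m)
    for (tn in names(transcripts)) {
      tvec <- strsplit(transcripts[[tn]], "")[[1]]
      if (length(tvec) < L) next
      for (s0 in seq_len(length(tvec) - L + 1)) {
        win <- tvec[s0:(s0 + L - 1)]
        sc <- 0
        for (i in seq_len(L)) {
          p <- pen1(m[i], win[L - i + 1])
          if (i >= 2 && i <= 13) p <- 2 * p
          sc <- sc + p
        }
        if (sc <= maxScore) {
          out[[length(out) + 1]] <- data.frame(
            mirna_id = mn, target_id = tn, score = sc, position = s0
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(
      mirna_id = character(), target_id = character(),
      score = numeric(), position = integer()
    ))
  }
  res <- do.call(rbind, out)
  res[order(res$target_id, res$position, res$mirna_id), , drop = FALSE]
}

# construct a vector with exact sample correlation r to x
withExactCor <- function(x, r, seed_vec = NULL) {
  n <- length(x)
  z <- if (is.null(seed_vec)) seq_len(n)^2 else seed_vec
  z <- stats::residuals(stats::lm(z ~ x))
  z <- z / stats::sd(z)
  xs <- (x - mean(x)) / stats::sd(x)
  r * xs + sqrt(1 - r^2) * z
}
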