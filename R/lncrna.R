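## Positional classification of lncRNA candidates against the coding
## annotation. Four classes, decided in priority order:
##   sense      - exonic overlap with a coding exon on the same strand
##   antisense  - exonic overlap with a coding exon on the opposite strand
##   intronic   - fully inside a single intron of one coding transcript
##                (either strand), no exonic overlap
##   intergenic - everything else
## Overlap means >= 1 shared base between exon intervals. Classification is
## done against coding transcripts and aggregated over isoforms by the same
## priority (exon evidence beats intron containment).

.LNC_CLASSES <- c("antisense", "intergenic", "intronic", "sense")

#' Filter lncRNA candidates by length and coding potential
#'
#' Keeps transcripts whose summed exon length is at least `minLen`
#' nucleotides (transcripts shorter than 200 nt are discarded by default)
#' and whose precomputed coding flag is `FALSE`. Coding-potential
#' assessment itself (CPC2/Pfam/Rfam) is out of scope and consumed as the
#' flag.
#'
#' @param annotation A [TxAnnotation-class].
#' @param codingFlag Named logical vector (by tx_id): `TRUE` if the
#'   transcript has coding potential. Transcripts absent from the vector
#'   are assumed non-coding.
#' @param minLen Minimum transcript length in nt (default 200).
#' @return Character vector of surviving transcript ids.
#' @export
filterLncCandidates <- function(annotation, codingFlag = NULL, minLen = 200) {
  len <- transcriptLengths(annotation)
  keep <- len >= minLen
  if (!is.null(codingFlag)) {
    flag <- codingFlag[names(len)]
    flag[is.na(flag)] <- FALSE
    keep <- keep & !flag
  }
  names(len)[keep]
}

#' Classify lncRNAs by position relative to coding genes
#'
#' @param annotation A [TxAnnotation-class] containing both the lncRNAs to
#'   classify and the coding transcripts (biotype `"coding"`).
#' @param lncIds Transcript ids to classify; defaults to all transcripts
#'   with biotype `"lncRNA_candidate"`.
#' @return data.frame with columns `tx_id`, `class`, `partner_gene`
#'   (supporting coding gene, `NA` for intergenic) and `overlap_bp`
#'   (exonic overlap in bp; 0 for intronic/intergenic).
#' @examples
#' sim <- simulateStudy(simConfig(seed = 1))
#' cls <- classifyLncRNAs(sim$annotation)
#' table(cls$class)
#' @export
classifyLncRNAs <- function(annotation, lncIds = NULL) {
  tx <- transcriptRanges(annotation)
  exl <- exonRanges(annotation)
  if (is.null(lncIds)) lncIds <- tx$tx_id[tx$biotype == "lncRNA_candidate"]
  if (!length(lncIds)) {
    return(data.frame(
      tx_id = character(), class = character(),
      partner_gene = character(), overlap_bp = integer()
    ))
  }
  missing_ids <- setdiff(lncIds, tx$tx_id)
  if (length(missing_ids)) {
    stop("unknown transcript id(s): ", paste(missing_ids, collapse = ", "))
  }
  coding_idx <- which(tx$biotype == "coding")
  coding_ex <- unlist(exl[coding_idx], use.names = FALSE)
  coding_grp <- rep(coding_idx, lengths(exl[coding_idx]))
  introns <- .codingIntrons(tx, exl, coding_idx)

  # lncRNAs on chromosomes absent from the coding annotation fall through
  # to intergenic (with a warning)
  coding_chr <- unique(as.character(seqnames(tx)[coding_idx]))

  res <- lapply(lncIds, function(id) {
    i <- match(id, tx$tx_id)
    lex <- exl[[i]]
    chr <- as.character(seqnames(tx)[i])
    if (!chr %in% coding_chr) {
      warning(
        "chromosome ", chr, " absent from coding annotation; ",
        id, " classified intergenic"
      )
      return(data.frame(
        tx_id = id, class = "intergenic",
        partner_gene = NA_character_, overlap_bp = 0L
      ))
    }
    hits <- findOverlaps(lex, coding_ex, ignore.strand = TRUE)
    if (length(hits)) {
      ov <- width(IRanges::pintersect(
        ranges(lex)[queryHits(hits)], ranges(coding_ex)[subjectHits(hits)]
      ))
      same_chr <- as.character(seqnames(coding_ex))[subjectHits(hits)] == chr
      ov[!same_chr] <- 0L
      same_strand <- as.character(strand(coding_ex))[subjectHits(hits)] ==
        as.character(strand(tx)[i])
      partner <- tx$gene_id[coding_grp[subjectHits(hits)]]
      keep <- ov > 0
      if (any(keep & same_strand)) {
        sel <- keep & same_strand
        bp <- stats::aggregate(ov[sel], list(gene = partner[sel]), sum)
        best <- bp[which.max(bp$x), ]
        return(data.frame(
          tx_id = id, class = "sense",
          partner_gene = best$gene, overlap_bp = as.integer(best$x)
        ))
      }
      if (any(keep)) {
        sel <- keep
        bp <- stats::aggregate(ov[sel], list(gene = partner[sel]), sum)
        best <- bp[which.max(bp$x), ]
        return(data.frame(
          tx_id = id, class = "antisense",
          partner_gene = best$gene, overlap_bp = as.integer(best$x)
        ))
      }
    }
    # intronic: the whole lncRNA span inside a single intron
    span <- granges(tx[i])
    ih <- findOverlaps(span, introns, type = "within", ignore.strand = TRUE)
    if (length(ih)) {
      return(data.frame(
        tx_id = id, class = "intronic",
        partner_gene = introns$gene_id[subjectHits(ih)[1]], overlap_bp = 0L
      ))
    }
    data.frame(
      tx_id = id, class = "intergenic",
      partner_gene = NA_character_, overlap_bp = 0L
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## introns of coding transcripts as a GRanges with gene_id
.codingIntrons <- function(tx, exl, coding_idx) {
  pieces <- lapply(coding_idx, function(i) {
    g <- exl[[i]]
    if (length(g) < 2) {
      return(NULL)
    }
    s <- sort(g)
    ir <- IRanges(end(s)[-length(s)] + 1L, start(s)[-1] - 1L)
    ir <- ir[width(ir) > 0]
    if (!length(ir)) {
      return(NULL)
    }
    GRanges(seqnames(tx)[i], ir,
      strand = strand(tx)[i],
      gene_id = tx$gene_id[i]
    )
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (!length(pieces)) {
    return(GRanges(gene_id = character()))
  }
  do.call(c, pieces)
}

#' Summarize positional classes
#'
#' @param classes data.frame from [classifyLncRNAs()] or a character vector
#'   of class labels.
#' @return data.frame with per-class `count` and `percent`
#'   (count/total x 100, rounded to 2 decimals), classes in fixed order
#'   antisense, intergenic, intronic, sense.
#' @examples
#' summarizeClasses(rep(c("antisense", "sense"), c(3, 1)))
#' @export
summarizeClasses <- function(classes) {
  if (is.data.frame(classes)) classes <- classes$class
  if (!length(classes)) stop("no classes to summarize")
  bad <- setdiff(unique(classes), .LNC_CLASSES)
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  counts <- vapply(.LNC_CLASSES, function(cl) sum(classes == cl), 0L)
  present <- counts > 0
  data.frame(
    class = .LNC_CLASSES[present],
    count = as.integer(counts[present]),
    percent = round(100 * counts[present] / sum(counts), 2),
    row.names = NULL
  )
}
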