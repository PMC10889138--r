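#' Transcript-level genome annotation
#'
#' Container for the transcript models the pipeline works with: one
#' `GRanges` of transcript spans (with `tx_id`, `gene_id` and `biotype`
#' metadata columns) and a parallel `GRangesList` of exons per transcript.
#' Coordinates follow the Bioconductor convention (1-based, closed
#' intervals); the GTF reader/writer converts at the boundary only.
#'
#' `biotype` is one of `"coding"`, `"lncRNA_candidate"` or `"miRNA"`.
#'
#' @slot transcripts `GRanges` of transcript spans.
#' @slot exons `GRangesList`, one element per transcript, named by `tx_id`,
#'   exons sorted by start and non-overlapping.
#'
#' @seealso [TxAnnotation()] for the constructor, [readGTF()].
#' @export
setClass("TxAnnotation",
  slots = c(transcripts = "GRanges", exons = "GRangesList")
)

.validTxAnnotation <- function(object) {
  tx <- object@transcripts
  ex <- object@exons
  msg <- character()
  req <- c("tx_id", "gene_id", "biotype")
  if (!all(req %in% names(mcols(tx)))) {
    msg <- c(msg, sprintf(
      "transcripts must carry metadata columns %s",
      paste(req, collapse = ", ")
    ))
    return(msg)
  }
  if (anyDuplicated(tx$tx_id)) {
    msg <- c(msg, "duplicate tx_id in transcripts")
  }
  bad_bt <- setdiff(unique(tx$biotype), c("coding", "lncRNA_candidate", "miRNA"))
  if (length(bad_bt)) {
    msg <- c(msg, sprintf("unknown biotype(s): %s", paste(bad_bt, collapse = ", ")))
  }
  if (!identical(names(ex), as.character(tx$tx_id))) {
    msg <- c(msg, "exons must be named by tx_id in transcript order")
  } else if (length(tx)) {
    exu <- unlist(ex, use.names = FALSE)
    grp <- rep(seq_along(ex), lengths(ex))
    if (any(start(exu) < start(tx)[grp]) || any(end(exu) > end(tx)[grp])) {
      msg <- c(msg, "exon outside its transcript span")
    }
    if (!all(as.character(strand(exu)) %in% c("+", "-"))) {
      msg <- c(msg, "exon strand must be + or -")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("TxAnnotation", .validTxAnnotation)

#' Construct a TxAnnotation
#'
#' @param transcripts `GRanges` with `tx_id`, `gene_id`, `biotype` metadata
#'   columns.
#' @param exons `GRangesList` named by `tx_id` (same order as
#'   `transcripts`). If missing, each transcript becomes a single exon.
#' @return A [TxAnnotation-class] object.
#' @export
TxAnnotation <- function(transcripts, exons) {
  if (missing(exons)) {
    exons <- methods::as(transcripts, "GRangesList")
    names(exons) <- transcripts$tx_id
  }
  # normalize exon order within each transcript
  exons <- GRangesList(lapply(exons, function(g) g[order(start(g))]))
  methods::new("TxAnnotation", transcripts = transcripts, exons = exons)
}

#' @describeIn TxAnnotation-class number of transcripts
#' @param x A `TxAnnotation`.
#' @export
setMethod("length", "TxAnnotation", function(x) length(x@transcripts))

setMethod("show", "TxAnnotation", function(object) {
  bt <- table(object@transcripts$biotype)
  cat(
    "TxAnnotation with", length(object), "transcripts on",
    length(unique(as.character(seqnames(object@transcripts)))),
    "sequence(s)\n biotypes:",
    paste(sprintf("%s=%d", names(bt), as.integer(bt)), collapse = ", "), "\n"
  )
})

#' Accessors for TxAnnotation
#'
#' `transcriptRanges()` returns the transcript-span `GRanges`;
#' `exonRanges()` the per-transcript exon `GRangesList`;
#' `transcriptLengths()` the summed exon length (nt) per transcript.
#'
#' @param x A [TxAnnotation-class].
#' @return See individual descriptions.
#' @export
transcriptRanges <- function(x) x@transcripts

#' @rdname transcriptRanges
#' @export
exonRanges <- function(x) x@exons

#' @rdname transcriptRanges
#' @export
transcriptLengths <- function(x) {
  setNames(sum(width(x@exons)), names(x@exons))
}

#' Weighted co-expression network
#'
#' Holds the soft-thresholded adjacency and (optionally) the topological
#' overlap matrix (TOM) of a set of features. The adjacency is
#' `|cor|^power` (unsigned, the default) or `((1+cor)/2)^power` (signed);
#' entries lie in [0,1] and the diagonal is 1 by convention but excluded
#' from connectivity sums.
#'
#' @slot adjacency symmetric numeric matrix in [0,1], dimnames = features.
#' @slot tom topological overlap matrix (same shape), or a 0x0 matrix
#'   before [tomSimilarity()] has been called.
#' @slot power soft-threshold exponent (beta).
#' @slot signed logical; signed adjacency transform?
#' @seealso [adjacencyMatrix()], [tomSimilarity()], [detectModules()]
#' @export
setClass("CoexNetwork",
  slots = c(
    adjacency = "matrix", tom = "matrix",
    power = "numeric", signed = "logical"
  )
)

.validCoexNetwork <- function(object) {
  a <- object@adjacency
  msg <- character()
  if (nrow(a) != ncol(a)) msg <- c(msg, "adjacency must be square")
  if (is.null(rownames(a))) msg <- c(msg, "adjacency needs feature dimnames")
  if (length(a) && (min(a) < -1e-12 || max(a) > 1 + 1e-12)) {
    msg <- c(msg, "adjacency entries must lie in [0,1]")
  }
  if (length(a) && max(abs(a - t(a))) > 1e-10) {
    msg <- c(msg, "adjacency must be symmetric")
  }
  if (length(object@tom) && !identical(dim(object@tom), dim(a))) {
    msg <- c(msg, "TOM dimensions must match adjacency")
  }
  if (object@power < 1) msg <- c(msg, "power must be >= 1")
  if (length(msg)) msg else TRUE
}
setValidity("CoexNetwork", .validCoexNetwork)

setMethod("show", "CoexNetwork", function(object) {
  cat(
    "CoexNetwork:", nrow(object@adjacency), "features,",
    if (object@signed) "signed" else "unsigned",
    sprintf("adjacency (beta = %g),", object@power),
    if (length(object@tom)) "TOM computed\n" else "TOM not computed\n"
  )
})

#' Accessors for CoexNetwork
#'
#' `adjacency()` returns the adjacency matrix, `tomMatrix()` the
#' topological overlap matrix (error if not yet computed), `softPower()`
#' the soft-threshold exponent, and `connectivity()` the whole-network
#' connectivity k_i = sum_{j != i} a_ij.
#'
#' @param x A [CoexNetwork-class].
#' @return Matrix / numeric vector as described.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname adjacency
#' @export
setMethod("adjacency", "CoexNetwork", function(x) x@adjacency)

#' @rdname adjacency
#' @export
setGeneric("tomMatrix", function(x) standardGeneric("tomMatrix"))

#' @rdname adjacency
#' @export
setMethod("tomMatrix", "CoexNetwork", function(x) {
  if (!length(x@tom)) stop("TOM not computed yet; call tomSimilarity() first")
  x@tom
})

#' @rdname adjacency
#' @export
softPower <- function(x) x@power

#' @rdname adjacency
#' @export
setGeneric("connectivity", function(x) standardGeneric("connectivity"))

#' @rdname adjacency
#' @export
setMethod("connectivity", "CoexNetwork", function(x) {
  a <- x@adjacency
  diag(a) <- 0
  rowSums(a)
})

#' Module assignment from co-expression clustering
#'
#' @slot labels named integer vector, one per feature; 0 marks unassigned
#'   ("grey") features, modules are numbered 1..k by decreasing size.
#' @slot mergeHeights dendrogram merge heights from the average-linkage
#'   clustering that produced the assignment.
#' @slot params list of the parameters used (minSize, cutQuantile,
#'   mergeCor, cutHeight).
#' @seealso [detectModules()], [moduleEigengenes()]
#' @export
setClass("ModuleSet",
  slots = c(labels = "integer", mergeHeights = "numeric", params = "list")
)

.validModuleSet <- function(object) {
  msg <- character()
  if (is.null(names(object@labels))) msg <- c(msg, "labels must be named")
  lb <- unique(sort(object@labels))
  lb <- lb[lb > 0]
  if (length(lb) && !identical(lb, seq_along(lb))) {
    msg <- c(msg, "non-grey labels must be contiguous 1..k")
  }
  if (length(msg)) msg else TRUE
}
setValidity("ModuleSet", .validModuleSet)

setMethod("show", "ModuleSet", function(object) {
  sz <- moduleSizes(object)
  cat(
    "ModuleSet:", length(object@labels), "features,",
    length(sz), "modules,", sum(object@labels == 0), "unassigned\n"
  )
  if (length(sz)) {
    cat(" sizes:", paste(sz, collapse = ", "), "\n")
  }
})

#' Accessors for ModuleSet
#'
#' `moduleLabels()` returns the named label vector (0 = unassigned);
#' `moduleSizes()` the per-module feature counts; `moduleGenes()` the
#' feature ids in one module.
#'
#' @param x A [ModuleSet-class].
#' @param module Integer module label.
#' @return See descriptions.
#' @export
moduleLabels <- function(x) x@labels

#' @rdname moduleLabels
#' @export
moduleSizes <- function(x) {
  lb <- x@labels[x@labels > 0]
  if (!length(lb)) {
    return(integer())
  }
  tab <- table(lb)
  setNames(as.integer(tab), names(tab))
}

#' @rdname moduleLabels
#' @export
moduleGenes <- function(x, module) names(x@labels)[x@labels == module]
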