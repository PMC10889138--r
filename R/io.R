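## Readers/writers for the external formats the pipeline touches.
## GTF is the canonical annotation dialect (GFF3 accepted read-only through
## the same importer); expression travels as TSV count matrices with a
## mandatory unit tag; traits and sample sheets as CSV; gene sets as GMT;
## the assembled network as SIF plus node/edge tables.

#' Read a GTF/GFF annotation into a TxAnnotation
#'
#' Exon records are grouped per transcript and sorted; transcript spans are
#' taken from `transcript` records when present, otherwise from the exon
#' range. The `biotype` attribute (or `gene_biotype`/`transcript_biotype`)
#' is mapped onto the internal biotype vocabulary; records without one are
#' treated as coding.
#'
#' @param path Path to a GTF (or GFF3) file with `gene_id` and
#'   `transcript_id` attributes.
#' @return A [TxAnnotation-class].
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "ceRNAflow")
#' ann <- readGTF(gtf)
#' transcriptLengths(ann)
#' @export
readGTF <- function(path) {
  gr <- rtracklayer::import(path)
  if (!all(c("type", "transcript_id", "gene_id") %in% names(mcols(gr)))) {
    stop("GTF must carry type, gene_id and transcript_id attributes: ", path)
  }
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stop("no exon records in ", path)
  if (anyNA(ex$transcript_id)) stop("exon record without transcript_id in ", path)
  bt_col <- intersect(
    c("biotype", "transcript_biotype", "gene_biotype"),
    names(mcols(gr))
  )[1]
  ord <- order(as.factor(ex$transcript_id), start(ex))
  ex <- ex[ord]
  exl <- methods::as(split(granges(ex), ex$transcript_id), "GRangesList")
  tx_ids <- names(exl)
  first <- ex[!duplicated(ex$transcript_id)]
  first <- first[match(tx_ids, first$transcript_id)]
  spans <- range(exl)
  if (any(lengths(spans) != 1L)) {
    bad <- tx_ids[lengths(spans) != 1L]
    stop(
      "transcript spans multiple chromosomes/strands: ",
      paste(bad, collapse = ", ")
    )
  }
  tx <- unlist(spans)
  biotype <- if (!is.na(bt_col)) as.character(mcols(first)[[bt_col]]) else NA
  biotype[is.na(biotype)] <- "coding"
  biotype[biotype %in% c("protein_coding", "mRNA")] <- "coding"
  biotype[biotype %in% c("lncRNA", "lincRNA")] <- "lncRNA_candidate"
  mcols(tx) <- DataFrame(
    tx_id = tx_ids, gene_id = as.character(first$gene_id), biotype = biotype
  )
  # transcript records, when present, must agree with the exon-derived span
  txrec <- gr[gr$type == "transcript"]
  if (length(txrec)) {
    m <- match(tx$tx_id, txrec$transcript_id)
    ok <- !is.na(m)
    if (any(start(tx)[ok] < start(txrec)[m[ok]]) ||
      any(end(tx)[ok] > end(txrec)[m[ok]])) {
      stop("exon outside its transcript record span in ", path)
    }
  }
  TxAnnotation(tx, exl)
}

#' Write a TxAnnotation to GTF
#'
#' Emits one `transcript` and one `exon` record per feature with `gene_id`,
#' `transcript_id` and `biotype` attributes; coordinates are written in the
#' GTF convention (1-based, inclusive). `writeGTF(readGTF(x))` round-trips
#' coordinates exactly.
#'
#' @param annotation A [TxAnnotation-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeGTF <- function(annotation, path) {
  tx <- transcriptRanges(annotation)
  exl <- exonRanges(annotation)
  ex <- unlist(exl, use.names = FALSE)
  grp <- rep(seq_along(exl), lengths(exl))
  txr <- granges(tx)
  mcols(txr) <- DataFrame(
    type = "transcript", gene_id = tx$gene_id,
    transcript_id = tx$tx_id, biotype = tx$biotype
  )
  exr <- granges(ex)
  mcols(exr) <- DataFrame(
    type = "exon", gene_id = tx$gene_id[grp],
    transcript_id = tx$tx_id[grp], biotype = tx$biotype[grp]
  )
  out <- c(txr, exr)
  out <- out[order(as.factor(seqnames(out)), start(out))]
  names(out) <- NULL # keep rtracklayer from emitting ID attributes
  rtracklayer::export(out, path, format = "gtf")
  invisible(path)
}

#' Build a SummarizedExperiment expression container
#'
#' @param counts Numeric matrix, features x samples, with dimnames.
#' @param samples Optional data.frame of sample metadata (`variety`,
#'   `time_h`, `replicate`), rownames or `sample` column matching columns
#'   of `counts`.
#' @param unit Unit tag, one of `"counts"`, `"FPKM"`, `"TPM"`, `"log2"`.
#' @return A `SummarizedExperiment` with `metadata(x)$unit` set.
#' @export
makeExpressionSet <- function(counts, samples = NULL,
                              unit = c("counts", "FPKM", "TPM", "log2")) {
  unit <- match.arg(unit)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature and sample dimnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop(
      "duplicate feature id(s): ",
      paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", ")
    )
  }
  if (anyDuplicated(colnames(counts))) {
    stop(
      "duplicate sample id(s): ",
      paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", ")
    )
  }
  if (!is.numeric(counts)) stop("expression values must be numeric")
  if (unit == "counts" && (any(counts < 0) || any(counts != round(counts)))) {
    stop("counts must be nonnegative integers")
  }
  cd <- if (is.null(samples)) {
    DataFrame(row.names = colnames(counts))
  } else {
    samples <- as.data.frame(samples)
    if ("sample" %in% names(samples)) rownames(samples) <- samples$sample
    if (!all(colnames(counts) %in% rownames(samples))) {
      stop("sample sheet is missing samples: ", paste(
        setdiff(colnames(counts), rownames(samples)),
        collapse = ", "
      ))
    }
    DataFrame(samples[colnames(counts), , drop = FALSE])
  }
  se <- SummarizedExperiment(assays = list(x = counts), colData = cd)
  metadata(se)$unit <- unit
  se
}

#' Read / write a TSV expression matrix
#'
#' The format is a tab-separated table whose first column holds feature ids
#' and whose header row holds sample ids. Round trips are exact for integer
#' counts.
#'
#' @param path File path.
#' @param samples Optional sample sheet (see [makeExpressionSet()]).
#' @param unit Unit tag for the values read.
#' @return `readCounts()`: a `SummarizedExperiment`; `writeCounts()`:
#'   `path`, invisibly.
#' @export
readCounts <- function(path, samples = NULL, unit = "counts") {
  df <- utils::read.table(path,
    header = TRUE, sep = "\t", check.names = FALSE,
    colClasses = "character"
  )
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop(
      "duplicate feature id(s) in ", path, ": ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    )
  }
  if (anyDuplicated(names(df)[-1])) {
    stop(
      "duplicate sample id(s) in ", path, ": ",
      paste(unique(names(df)[-1][duplicated(names(df)[-1])]), collapse = ", ")
    )
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "numeric")
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-numeric value at feature '%s', sample '%s' in %s",
      ids[bad[1]], colnames(mat)[bad[2]], path
    ))
  }
  rownames(mat) <- ids
  makeExpressionSet(mat, samples = samples, unit = unit)
}

#' @rdname readCounts
#' @param x `SummarizedExperiment` or matrix to write.
#' @export
writeCounts <- function(x, path) {
  mat <- if (methods::is(x, "SummarizedExperiment")) assay(x) else as.matrix(x)
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV with columns `sample`, `variety`, `time_h`, `replicate`.
#'
#' @param path File path.
#' @return data.frame with rownames = sample ids.
#' @export
readSampleSheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample", "variety", "time_h", "replicate")
  if (!all(req %in% names(df))) {
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in ", path)
  rownames(df) <- df$sample
  df
}

#' Read a physiological trait table
#'
#' CSV, first column sample id, remaining columns numeric trait values
#' (SOD, POD, CAT, T-AOC, MDA, OH, proline, SS, SP by convention).
#' Missing values in `required` traits are an error; elsewhere they are
#' mean-imputed with a warning.
#'
#' @param path File path.
#' @param samples Optional character vector of expected sample ids; traits
#'   are checked and reordered against it.
#' @param required Traits that must be present and complete (warning if a
#'   required column is absent).
#' @return data.frame of traits, rownames = sample ids.
#' @export
readTraits <- function(path, samples = NULL,
                       required = c("SOD", "POD")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate sample ids in ", path)
  tr <- df[, -1, drop = FALSE]
  for (j in seq_along(tr)) {
    v <- suppressWarnings(as.numeric(tr[[j]]))
    if (any(!is.na(tr[[j]]) & is.na(v))) {
      stop(sprintf("trait column '%s' is non-numeric in %s", names(tr)[j], path))
    }
    tr[[j]] <- v
  }
  rownames(tr) <- ids
  miss <- setdiff(required, names(tr))
  if (length(miss)) {
    warning("trait table is missing required trait(s): ", paste(miss, collapse = ", "))
  }
  for (nm in intersect(required, names(tr))) {
    if (anyNA(tr[[nm]])) stop("missing values in required trait '", nm, "'")
  }
  for (nm in setdiff(names(tr), required)) {
    if (anyNA(tr[[nm]])) {
      warning("mean-imputing missing values in trait '", nm, "'")
      tr[[nm]][is.na(tr[[nm]])] <- mean(tr[[nm]], na.rm = TRUE)
    }
  }
  if (!is.null(samples)) {
    unknown <- setdiff(ids, samples)
    if (length(unknown)) {
      warning("trait table has unknown sample id(s): ", paste(unknown, collapse = ", "))
    }
    absent <- setdiff(samples, ids)
    if (length(absent)) {
      stop("trait table lacks sample(s): ", paste(absent, collapse = ", "))
    }
    tr <- tr[samples, , drop = FALSE]
  }
  tr
}

#' Read a miRNA-target pair table
#'
#' TSV with columns `mirna_id`, `target_id` and optionally `score` and
#' `position`. Absent scores load as `NA`.
#'
#' @param path File path.
#' @return data.frame with columns mirna_id, target_id, score, position.
#' @export
readTargetPairs <- function(path) {
  df <- utils::read.table(path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE, check.names = FALSE
  )
  if (!all(c("mirna_id", "target_id") %in% names(df))) {
    stop("target pair file must have columns mirna_id, target_id")
  }
  if (!"score" %in% names(df)) df$score <- NA_real_
  if (!"position" %in% names(df)) df$position <- NA_integer_
  df[, c("mirna_id", "target_id", "score", "position")]
}

#' Read a GMT gene-set file
#'
#' Each line: set name, description, then member gene ids, tab-separated.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
readGeneSets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  setNames(
    lapply(parts, function(p) unique(p[-(1:2)])),
    vapply(parts, `[[`, "", 1L)
  )
}

#' Export an assembled ceRNA network
#'
#' Writes three files for an external viewer (e.g. Cytoscape):
#' `<prefix>_nodes.tsv` (id, type), `<prefix>_edges.tsv`
#' (source, interaction, target) and `<prefix>.sif` with lines
#' `lncRNA interacts miRNA` and `miRNA targets mRNA`.
#'
#' @param triplets data.frame of triplets from [assembleTriplets()] (needs
#'   columns `lncrna_id`, `mirna_id`, `mrna_id`).
#' @param prefix Output path prefix.
#' @param allowEmpty Write headers-only files when `triplets` has no rows?
#' @return Invisible character vector of the three paths.
#' @export
writeNetworkFiles <- function(triplets, prefix, allowEmpty = FALSE) {
  paths <- paste0(prefix, c("_nodes.tsv", "_edges.tsv", ".sif"))
  if (!nrow(triplets)) {
    if (!allowEmpty) stop("empty triplet list; pass allowEmpty = TRUE to export")
    writeLines("id\ttype", paths[1])
    writeLines("source\tinteraction\ttarget", paths[2])
    writeLines(character(), paths[3])
    return(invisible(paths))
  }
  nodes <- unique(rbind(
    data.frame(id = triplets$lncrna_id, type = "lncRNA"),
    data.frame(id = triplets$mirna_id, type = "miRNA"),
    data.frame(id = triplets$mrna_id, type = "mRNA")
  ))
  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup)) {
    stop("node(s) with two types: ", paste(unique(dup), collapse = ", "))
  }
  edges <- unique(rbind(
    data.frame(
      source = triplets$lncrna_id, interaction = "interacts",
      target = triplets$mirna_id
    ),
    data.frame(
      source = triplets$mirna_id, interaction = "targets",
      target = triplets$mrna_id
    )
  ))
  utils::write.table(nodes, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(edges, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste(edges$source, edges$interaction, edges$target), paths[3])
  invisible(paths)
}
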