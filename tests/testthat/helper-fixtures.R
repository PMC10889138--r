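# Shared fixtures. The reference synthetic study and its pipeline run are
# expensive (~0.5 min together), so they are built once per session and
# reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

sharedStudy <- function() {
  if (is.null(.fixture_cache$study)) {
    .fixture_cache$study <- simulateStudy(simConfig(seed = 1))
  }
  .fixture_cache$study
}

sharedRun <- function() {
  if (is.null(.fixture_cache$run)) {
    .fixture_cache$run <- runPipeline(sharedStudy())
  }
  .fixture_cache$run
}

# small, fast study for structural pipeline tests
smallConfig <- function(seed = 42, ...) {
  simConfig(
    nCoding = 120, nLnc = 12, nMirna = 12, nModules = 2,
    moduleSizes = c(30, 30), nDeGenes = 10, nTriplets = 2,
    seed = seed, ...
  )
}

tripletKey <- function(d) paste(d$lncrna_id, d$mirna_id, d$mrna_id)

# hand-built annotation: two coding genes and four lncRNAs, one per
# positional class, on one chromosome
toyAnnotation <- function() {
  tx <- GenomicRanges::GRanges(
    "chrT",
    IRanges::IRanges(
      start = c(1000, 50000, 1100, 2200, 4200, 30000),
      end = c(5000, 54000, 1500, 2600, 4600, 30500)
    ),
    strand = c("+", "-", "-", "+", "+", "+"),
    tx_id = c("gA", "gB", "anti", "intr", "sens", "inter"),
    gene_id = c("gA", "gB", "anti", "intr", "sens", "inter"),
    biotype = c("coding", "coding", rep("lncRNA_candidate", 4))
  )
  # gA: exons 1000-2000 and 4000-5000 (+); intron 2001-3999
  # gB: single exon 50000-54000 (-)
  ex <- GenomicRanges::GRangesList(
    gA = GenomicRanges::GRanges("chrT",
      IRanges::IRanges(c(1000, 4000), c(2000, 5000)),
      strand = "+"
    ),
    gB = GenomicRanges::GRanges("chrT",
      IRanges::IRanges(50000, 54000),
      strand = "-"
    ),
    anti = GenomicRanges::GRanges("chrT",
      IRanges::IRanges(1100, 1500),
      strand = "-"
    ),
    intr = GenomicRanges::GRanges("chrT",
      IRanges::IRanges(2200, 2600),
      strand = "+"
    ),
    sens = GenomicRanges::GRanges("chrT",
      IRanges::IRanges(4200, 4600),
      strand = "+"
    ),
    inter = GenomicRanges::GRanges("chrT",
      IRanges::IRanges(30000, 30500),
      strand = "+"
    )
  )
  TxAnnotation(tx, ex)
}
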