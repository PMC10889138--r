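test_that("the generator is deterministic under a fixed seed", {
  cfg <- smallConfig(seed = 99)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(smallConfig(seed = 99))
  expect_identical(
    SummarizedExperiment::assay(s1$mrna),
    SummarizedExperiment::assay(s2$mrna)
  )
  expect_identical(
    SummarizedExperiment::assay(s1$mirna),
    SummarizedExperiment::assay(s2$mirna)
  )
  expect_identical(s1$traits, s2$traits)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$truth$triplets, s2$truth$triplets)
  # annotation serializes byte-identically
  f1 <- withr::local_tempfile(fileext = ".gtf")
  f2 <- withr::local_tempfile(fileext = ".gtf")
  writeGTF(s1$annotation, f1)
  writeGTF(s2$annotation, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the data
  s3 <- simulateStudy(smallConfig(seed = 100))
  expect_false(identical(
    SummarizedExperiment::assay(s1$mrna),
    SummarizedExperiment::assay(s3$mrna)
  ))
})

test_that("counts are nonnegative integers and ids partition the matrices", {
  sim <- simulateStudy(smallConfig(seed = 41))
  for (ty in c("mrna", "lncrna", "mirna")) {
    cnt <- SummarizedExperiment::assay(sim[[ty]])
    expect_true(is.integer(cnt))
    expect_true(all(cnt >= 0))
  }
  ids <- c(
    rownames(sim$mrna), rownames(sim$lncrna), rownames(sim$mirna)
  )
  expect_equal(anyDuplicated(ids), 0L)
  # every emitted transcript id appears in exactly one matrix
  expect_setequal(transcriptRanges(sim$annotation)$tx_id, ids)
})

test_that("the count model has the stated mean-variance relation", {
  # alpha = 0.2 at mu = 100: variance ~ mu + alpha mu^2 = 2100 within 10%
  cfg <- simConfig(
    nCoding = 350, nLnc = 4, nMirna = 4, nModules = 5,
    moduleSizes = rep(70L, 5), nbDispersion = 0.2,
    baseMeanLog2Range = c(log2(100), log2(100)),
    geneAmplitude = 0, nTriplets = 0, nDeGenes = 0,
    lncClassCounts = c(1L, 1L, 1L, 1L), seed = 7
  )
  sim <- simulateStudy(cfg)
  draws <- as.numeric(SummarizedExperiment::assay(sim$mrna)) # 10500 draws
  expect_gt(length(draws), 10000)
  expect_equal(mean(draws), 100, tolerance = 0.05)
  expect_equal(var(draws), 2100, tolerance = 0.1)
  # dispersion must be positive
  expect_error(simConfig(nbDispersion = 0), "positive")
})

test_that("noise-free limits give perfect module-member correlation", {
  cfg <- simConfig(
    nCoding = 60, nLnc = 4, nMirna = 4, nModules = 1,
    moduleSizes = 60L, withinModuleCor = 0.999, nbDispersion = 0.001,
    traitNoiseSd = 0, nTriplets = 0, nDeGenes = 0,
    traitDrivers = c(SOD = 1L), lncClassCounts = c(1L, 1L, 1L, 1L),
    baseMeanLog2Range = c(9, 11), seed = 8
  )
  sim <- simulateStudy(cfg)
  eg <- sim$truth$eigengenes
  logx <- log2(SummarizedExperiment::assay(sim$mrna) + 1)
  cors <- apply(logx, 1, function(g) cor(g, eg[1, ]))
  expect_gt(min(abs(cors)), 0.97)
  # zero trait noise, sign -1: module-trait correlation is exactly -1
  expect_equal(cor(sim$traits$SOD, eg[1, ]), -1, tolerance = 1e-12)
})

test_that("trait generation validates drivers and keeps null traits null", {
  sim <- sharedStudy()
  eg <- sim$truth$eigengenes
  # pure-noise traits stay uncorrelated with every eigengene (n = 30)
  for (tn in c("CAT", "proline", "SS")) {
    expect_lt(max(abs(cor(sim$traits[[tn]], t(eg)))), 0.5)
  }
  cfg <- smallConfig()
  expect_error(
    simulateTraits(eg[1:2, ], rnorm(30), simConfig(
      nModules = 5, traitDrivers = c(SOD = 5L)
    )),
    "unknown driver"
  )
})

test_that("annotation placement realizes every requested class", {
  res <- simulateAnnotation(smallConfig(seed = 2))
  expect_setequal(
    unique(res$classes$class),
    c("antisense", "intergenic", "intronic", "sense")
  )
  # truth labels are reproduced by the classifier (same geometry)
  cls <- classifyLncRNAs(res$annotation)
  expect_identical(
    setNames(cls$class, cls$tx_id)[res$classes$tx_id],
    setNames(res$classes$class, res$classes$tx_id)
  )
  # unrealizable request: more lncRNAs than host positions
  expect_error(
    simulateAnnotation(simConfig(
      nCoding = 3, nLnc = 8, moduleSizes = rep(0L, 5),
      nTriplets = 0, nDeGenes = 0
    )),
    "cannot place"
  )
})

test_that("studies round-trip through their on-disk formats", {
  sim <- simulateStudy(smallConfig(seed = 43))
  dir <- withr::local_tempdir()
  paths <- writeStudy(sim, dir)
  back_m <- readCounts(paths["mrna"])
  expect_identical(
    SummarizedExperiment::assay(back_m),
    SummarizedExperiment::assay(sim$mrna) * 1
  )
  tr <- readTraits(paths["traits"], samples = sim$samples$sample)
  expect_equal(as.matrix(tr), as.matrix(sim$traits), tolerance = 1e-12)
  ann <- readGTF(paths["annotation"])
  expect_identical(
    classifyLncRNAs(ann)$class,
    classifyLncRNAs(sim$annotation)$class
  )
  tp <- readTargetPairs(paths["pairs"])
  expect_equal(nrow(tp), nrow(sim$truth$targetPairs))
  sheet <- readSampleSheet(paths["samples"])
  expect_identical(sheet$sample, sim$samples$sample)
})
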