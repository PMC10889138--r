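test_that("complementarity penalties follow the plant scoring rules", {
  mir <- "UGGAAGACUAGUGAUUUUGUUGU" # 23 nt, 5'->3'
  site <- revComplementRna(mir)
  expect_equal(mirnaTargetScore(mir, site), 0)

  # one mismatch at miRNA position 10 (core): penalty doubled to 2
  s <- strsplit(site, "")[[1]]
  L <- nchar(mir)
  pos <- 10
  tpos <- L - pos + 1 # site base pairing miRNA position 10
  mbase <- substr(mir, pos, pos)
  # replace with a base that neither pairs nor wobbles
  repl <- setdiff(c("A", "C", "G", "U"), c(
    s[tpos],
    if (mbase == "G") "U", if (mbase == "U") "G"
  ))[1]
  s[tpos] <- repl
  expect_equal(mirnaTargetScore(mir, paste(s, collapse = "")), 2)

  # G:U wobble: 0.5 outside the core (position 1), 1.0 inside (position 5)
  mir2 <- paste(rep("G", 21), collapse = "")
  site2 <- revComplementRna(mir2) # all C
  s2 <- strsplit(site2, "")[[1]]
  s2[21] <- "U" # pairs miRNA position 1
  expect_equal(mirnaTargetScore(mir2, paste(s2, collapse = "")), 0.5)
  s3 <- strsplit(site2, "")[[1]]
  s3[21 - 5 + 1] <- "U" # pairs miRNA position 5 (core)
  expect_equal(mirnaTargetScore(mir2, paste(s3, collapse = "")), 1.0)

  # DNA letters accepted, invalid letters rejected
  expect_equal(mirnaTargetScore(chartr("U", "T", mir), chartr("U", "T", site)), 0)
  expect_error(mirnaTargetScore("ACGX", "ACGU"), "invalid character")
  expect_error(mirnaTargetScore("ACGU", "ACG"), "equal length")
})

test_that("sliding-window prediction finds planted sites at the right cutoffs", {
  set.seed(30)
  mir <- setNames(paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = ""), "m1")
  site <- revComplementRna(mir[[1]])
  flank <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
  tx <- setNames(paste0(flank(57), site, flank(40)), "t1")
  hits <- predictTargets(mir, tx, maxScore = 4)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$score, 0)
  expect_equal(hits$position, 58L)

  # a 3-penalty site is reported at cutoff 4 but not at cutoff 2:
  # one core mismatch (2) + one non-core mismatch (1)
  sv <- strsplit(site, "")[[1]]
  mb <- function(i) substr(mir[[1]], i, i)
  hard <- function(m, t) {
    setdiff(c("A", "C", "G", "U"), c(t, if (m == "G") "U", if (m == "U") "G"))[1]
  }
  sv[21 - 5 + 1] <- hard(mb(5), sv[21 - 5 + 1])
  sv[21 - 1 + 1] <- hard(mb(1), sv[21 - 1 + 1])
  tx2 <- setNames(paste0(flank(10), paste(sv, collapse = ""), flank(10)), "t2")
  expect_equal(predictTargets(mir, tx2, maxScore = 4)$score, 3)
  expect_equal(nrow(predictTargets(mir, tx2, maxScore = 2)), 0L)
})

test_that("prediction equals an exhaustive position-by-position rescan", {
  sim <- simulateStudy(simConfig(
    nCoding = 40, nLnc = 8, nMirna = 6, nModules = 2,
    moduleSizes = c(10, 10), nTriplets = 3, nDeGenes = 4, seed = 31
  ))
  pred <- predictTargets(sim$sequences$mirna, sim$sequences$transcripts,
    maxScore = 4
  )
  ref <- rescanTargets(sim$sequences$mirna, sim$sequences$transcripts, 4)
  rownames(pred) <- rownames(ref) <- NULL
  expect_equal(pred, ref)
  # every planted pair is recovered with score 0 at the planted position
  tp <- sim$truth$targetPairs
  found <- merge(tp[, c("mirna_id", "target_id")], pred)
  expect_equal(nrow(found), nrow(tp))
  expect_true(all(found$score == 0))
  expect_true(all(found$position == 100))
})

test_that("cis windows apply the documented gap-distance boundary", {
  lnc <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500000, 500999),
    strand = "+",
    tx_id = "lncA"
  )
  gene_at <- function(gap) {
    GenomicRanges::GRanges("chr1",
      IRanges::IRanges(501000 + gap, 501000 + gap + 4000),
      strand = "+", gene_id = paste0("gap", gap)
    )
  }
  coding <- c(gene_at(99999), gene_at(100001))
  res <- cisTargets(lnc, coding, window = 1e5)
  expect_identical(res$gene_id, "gap99999")
  expect_equal(res$distance, 99999L)

  # overlapping gene: linked with distance 0
  ov <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500500, 505000),
    strand = "-", gene_id = "overlap"
  )
  res2 <- cisTargets(lnc, ov)
  expect_equal(res2$distance, 0L)

  # brute-force all-pairs agreement and translation invariance
  set.seed(32)
  ls <- sort(sample(1:2e6, 15))
  gs <- sort(sample(1:2e6, 25))
  lncs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(ls, width = 600),
    strand = "+", tx_id = paste0("l", 1:15)
  )
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(gs, width = 3000),
    strand = "+", gene_id = paste0("g", 1:25)
  )
  res3 <- cisTargets(lncs, genes, window = 1e5)
  brute <- do.call(rbind, lapply(1:15, function(i) {
    do.call(rbind, lapply(1:25, function(j) {
      gap <- max(gs[j] - (ls[i] + 599) - 1, ls[i] - (gs[j] + 2999) - 1, 0)
      if (gap < 1e5) {
        data.frame(
          lncrna_id = paste0("l", i), gene_id = paste0("g", j),
          distance = gap
        )
      }
    }))
  }))
  brute <- brute[order(brute$lncrna_id, brute$gene_id), ]
  rownames(brute) <- NULL
  expect_equal(res3[, c("lncrna_id", "gene_id", "distance")], brute)

  shift <- function(gr, k) {
    GenomicRanges::shift(gr, k)
  }
  res4 <- cisTargets(shift(lncs, 12345), shift(genes, 12345), window = 1e5)
  expect_equal(res4, res3)
})

test_that("trans targets require strictly r > 0.9 and p < 0.01", {
  set.seed(33)
  x <- as.numeric(scale(rnorm(30)))
  lnc <- rbind(l1 = x)
  near <- withExactCor(x, 0.95, rnorm(30))
  mrna <- rbind(copy = x, near = near, anti = -x)
  res <- transTargets(lnc, mrna)
  expect_setequal(res$gene_id, c("copy", "near"))
  # the threshold is a strict inequality: a pair sitting exactly at rMin
  # (rMin set to its own achieved correlation) is excluded
  r_near <- cor(x, near)
  res_edge <- transTargets(lnc, rbind(near = near), rMin = r_near)
  expect_equal(nrow(res_edge), 0L)
  res_in <- transTargets(lnc, rbind(near = near), rMin = r_near - 1e-9)
  expect_equal(nrow(res_in), 1L)
  expect_equal(res$r[res$gene_id == "copy"], 1)
  # correlations match the direct definition
  expect_equal(res$r[res$gene_id == "near"], cor(x, mrna["near", ]),
    tolerance = 1e-12
  )
  # zero-variance features are skipped with a warning
  withflat <- rbind(mrna, flat = rep(2, 30))
  expect_warning(transTargets(lnc, withflat), "zero-variance")
  expect_error(transTargets(lnc[, 1:3, drop = FALSE], mrna[, 1:3]), ">= 4")
  expect_warning(
    transTargets(lnc[, 1:6, drop = FALSE], mrna[, 1:6]),
    "fewer than 10"
  )
})
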