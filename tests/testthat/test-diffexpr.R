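test_that("median-of-ratios size factors match closed forms and DESeq2", {
  m <- matrix(c(5, 10, 5, 10), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(unname(sizeFactorsMoR(m)), c(1, 1))

  # one column exactly 2x the other: factors in ratio 2
  m2 <- matrix(c(10, 40, 20, 80), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  sf <- sizeFactorsMoR(m2)
  expect_equal(unname(sf["s2"] / sf["s1"]), 2)
  expect_equal(exp(mean(log(sf))), 1)

  # single-gene matrix: factors proportional to that gene's counts
  m1 <- matrix(c(2, 8, 4), 1, 3, dimnames = list("a", c("s1", "s2", "s3")))
  sf1 <- sizeFactorsMoR(m1)
  expect_equal(unname(sf1 / sf1[1]), c(2, 8, 4) / 2)

  # all-zero-containing genes: advise pseudocount mode
  mz <- matrix(c(0, 3, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(sizeFactorsMoR(mz), "pseudocount")
  expect_length(sizeFactorsMoR(mz, pseudocount = TRUE), 2)

  # independent cross-check against the reference implementation
  skip_if_not_installed("DESeq2")
  set.seed(8)
  big <- matrix(rnbinom(300 * 6, mu = 80, size = 5) + 1L, 300, 6,
    dimnames = list(paste0("g", 1:300), paste0("s", 1:6))
  )
  ref <- DESeq2::estimateSizeFactorsForMatrix(big)
  ours <- sizeFactorsMoR(big)
  # same up to the geometric-mean-1 rescaling convention
  expect_equal(unname(ours), unname(ref / exp(mean(log(ref)))), tolerance = 1e-10)
})

test_that("FPKM and TPM obey their defining identities", {
  m <- matrix(c(10, 990), 2, 1, dimnames = list(c("a", "b"), "s1"))
  f <- fpkmNormalize(m, lengths = c(1000, 1000), totals = 1e6)
  expect_equal(f["a", "s1"], 10)
  tp <- tpmNormalize(m, lengths = c(1000, 500))
  expect_equal(unname(colSums(tp)), 1e6)
  # TPM = FPKM / sum(FPKM) * 1e6, per sample
  set.seed(2)
  cnt <- matrix(rpois(50, 60) + 1, 10, 5,
    dimnames = list(paste0("g", 1:10), paste0("s", 1:5))
  )
  lens <- sample(200:3000, 10)
  f2 <- fpkmNormalize(cnt, lens)
  t2 <- tpmNormalize(cnt, lens)
  expect_equal(t2, sweep(f2, 2, colSums(f2) / 1e6, "/"), tolerance = 1e-12)
  expect_error(fpkmNormalize(cnt, lens, totals = rep(0, 5)), "zero library")
})

test_that("NB Wald test behaves on degenerate and symmetric designs", {
  cnt <- matrix(rep(c(10L, 200L, 35L), each = 6), 3, 6, byrow = TRUE,
    dimnames = list(paste0("g", 1:3), paste0("s", 1:6))
  )
  grp <- rep(c("A", "B"), each = 3)
  res <- nbTest(cnt, grp)
  expect_equal(res$log2FC, rep(0, 3))
  expect_equal(res$pvalue, rep(1, 3))

  set.seed(4)
  cnt2 <- matrix(rnbinom(120 * 6, mu = 100, size = 10), 120, 6,
    dimnames = list(paste0("g", 1:120), paste0("s", 1:6))
  )
  a <- nbTest(cnt2, rep(c("A", "B"), each = 3))
  b <- nbTest(cnt2, rep(c("B", "A"), each = 3))
  expect_equal(a$log2FC, -b$log2FC, tolerance = 1e-12)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-12)
  expect_error(nbTest(cnt2[, 1:3], c("A", "A", "B")), "2 replicates")
})

test_that("rescaling one library changes only its size factor", {
  set.seed(5)
  cnt <- matrix(rnbinom(200 * 6, mu = 150, size = 8) + 1L, 200, 6,
    dimnames = list(paste0("g", 1:200), paste0("s", 1:6))
  )
  grp <- rep(c("A", "B"), each = 3)
  base <- nbTest(cnt, grp)
  scaled <- cnt
  scaled[, 2] <- scaled[, 2] * 4L
  sf0 <- sizeFactorsMoR(cnt)
  sf1 <- sizeFactorsMoR(scaled)
  # the scaled sample's factor grows by exactly c relative to the others
  expect_equal(unname(sf1[2] / sf0[2] / (sf1[1] / sf0[1])), 4, tolerance = 1e-12)
  # test results are stable: the geometric-mean reference shifts the
  # normalized scale by c^(1/n), so the pseudocount and 1/mu terms move
  # the statistics slightly, but estimates and the significance ranking
  # are preserved
  res <- nbTest(scaled, grp)
  expect_equal(res$log2FC, base$log2FC, tolerance = 5e-3)
  expect_equal(res$stat, base$stat, tolerance = 5e-2)
  expect_gt(cor(res$pvalue, base$pvalue, method = "spearman"), 0.9999)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bhAdjust(0.04), 0.04)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(6)
  for (n in c(7, 100, 2000)) {
    p <- runif(n)^2
    expect_equal(bhAdjust(p), bhBrute(p), tolerance = 1e-12)
  }
})

test_that("DE calls apply the fold-change and FDR rules inclusively", {
  res <- data.frame(
    feature_id = c("up_edge", "weak_fc", "dn", "ns"),
    log2FC = c(1.0, 0.9, -2.0, 0.2),
    pvalue = c(0.001, 0.0001, 0.002, 0.5),
    qvalue = c(0.009, 0.001, 0.01, 0.8)
  )
  out <- callDE(res, fcMin = 2, alphaMax = 0.01, useQ = TRUE)
  expect_identical(out$direction, c("up", "ns", "down", "ns"))
  # miRNA rule: FC >= 1.5 on the raw p-value
  out2 <- callDE(res, fcMin = 1.5, alphaMax = 0.05, useQ = FALSE)
  expect_identical(out2$direction, c("up", "up", "down", "ns"))
  expect_error(callDE(res, fcMin = -1), "positive")
})

test_that("planted fold changes are recovered at the screening thresholds", {
  # low-dispersion conditions with moderate module amplitude, so that the
  # caller (not library-composition drift) is what is being measured
  sim <- simulateStudy(simConfig(
    seed = 1, nbDispersion = 0.02,
    geneAmplitude = 1.2
  ))
  s <- sim$samples
  cnt <- SummarizedExperiment::assay(sim$mrna)
  sel <- s$variety == "JH" & s$time_h %in% c(0, 48)
  grp <- factor(ifelse(s$time_h[sel] == 0, "t0", "t1"), c("t0", "t1"))
  res <- callDE(nbTest(cnt[, s$sample[sel]], grp), fcMin = 2, alphaMax = 0.01)
  planted <- sim$truth$deBackground # background genes with a +/-2 step
  called <- setNames(res$direction, res$feature_id)[names(planted)]
  expect_gte(mean(called == ifelse(planted > 0, "up", "down")), 0.9)
})
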