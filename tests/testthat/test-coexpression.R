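test_that("soft-threshold adjacency matches its closed form and a brute-force loop", {
  # a pair with exact correlation -0.5
  x <- as.numeric(scale(sin(1:12)))
  y <- withExactCor(x, -0.5)
  expr <- rbind(g1 = x, g2 = y)
  net <- adjacencyMatrix(expr, power = 7)
  expect_equal(adjacency(net)["g1", "g2"], 0.5^7, tolerance = 1e-12)
  expect_equal(adjacency(net)["g1", "g2"], 0.0078125, tolerance = 1e-12)

  # perfectly correlated pair: a = 1 for any power
  expr2 <- rbind(g1 = x, g2 = 3 * x + 2)
  for (b in c(1, 7, 12)) {
    expect_equal(adjacency(adjacencyMatrix(expr2, b))["g1", "g2"], 1)
  }

  # random matrix vs explicit pairwise loop
  set.seed(10)
  m <- matrix(rnorm(200), 20, 10, dimnames = list(paste0("g", 1:20), NULL))
  a <- adjacency(adjacencyMatrix(m, power = 6))
  for (i in 1:20) {
    for (j in 1:20) {
      expect_equal(a[i, j], abs(cor(m[i, ], m[j, ]))^6, tolerance = 1e-12)
    }
  }
  # beta = 1 is raw |cor|
  expect_equal(
    adjacency(adjacencyMatrix(m, power = 1)) - diag(20),
    abs(cor(t(m))) - diag(20),
    tolerance = 1e-12
  )
  expect_error(
    adjacencyMatrix(rbind(m, flat = rep(1, 10)), 7),
    "zero-variance"
  )
})

test_that("topological overlap obeys its closed forms", {
  mkNet <- function(a) {
    methods::new("CoexNetwork",
      adjacency = a, tom = matrix(numeric(), 0, 0),
      power = 1, signed = FALSE
    )
  }
  # no edges: overlap 0 off-diagonal, 1 on the diagonal
  a0 <- diag(4)
  dimnames(a0) <- list(paste0("g", 1:4), paste0("g", 1:4))
  w0 <- tomMatrix(tomSimilarity(mkNet(a0)))
  expect_equal(unname(w0), diag(4))

  # equal-weight triangle: w_ij = (a^2 + a) / (a + 1) = a
  for (aa in c(0.2, 0.5, 0.9)) {
    a <- matrix(aa, 3, 3)
    diag(a) <- 1
    dimnames(a) <- list(paste0("g", 1:3), paste0("g", 1:3))
    w <- tomMatrix(tomSimilarity(mkNet(a)))
    expect_equal(w[1, 2], aa, tolerance = 1e-12)
  }

  # complete unit-weight graph: overlap 1 everywhere
  a1 <- matrix(1, 6, 6)
  dimnames(a1) <- list(paste0("g", 1:6), paste0("g", 1:6))
  expect_equal(unname(tomMatrix(tomSimilarity(mkNet(a1)))), matrix(1, 6, 6))
})

test_that("TOM equals the O(n^3) brute force and stays within [0,1], symmetric", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(rnorm(20 * 8), 20, 8, dimnames = list(paste0("g", 1:20), NULL))
    net <- tomSimilarity(adjacencyMatrix(m, power = 6))
    w <- tomMatrix(net)
    expect_equal(w, tomBrute(adjacency(net)), tolerance = 1e-10)
    expect_true(all(w >= 0 & w <= 1))
    expect_lt(max(abs(w - t(w))), 1e-12)
  }
})

test_that("module detection recovers planted blocks and honors invariances", {
  set.seed(12)
  n <- 100
  e1 <- rnorm(12)
  e2 <- rnorm(12)
  expr <- rbind(
    t(sapply(1:50, function(i) sqrt(0.9) * e1 + sqrt(0.1) * rnorm(12))),
    t(sapply(1:50, function(i) sqrt(0.9) * e2 + sqrt(0.1) * rnorm(12)))
  )
  rownames(expr) <- paste0("g", 1:n)
  truth <- rep(1:2, each = 50)
  net <- tomSimilarity(adjacencyMatrix(expr, 7))
  ms <- detectModules(net, minSize = 30, expr = expr)
  expect_equal(length(moduleSizes(ms)), 2L)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(moduleLabels(ms), truth), 1)

  # permuting gene order gives identical modules up to label names
  perm <- sample(n)
  net_p <- tomSimilarity(adjacencyMatrix(expr[perm, ], 7))
  ms_p <- detectModules(net_p, minSize = 30, expr = expr[perm, ])
  expect_equal(
    mclust::adjustedRandIndex(
      moduleLabels(ms_p)[rownames(expr)], moduleLabels(ms)
    ), 1
  )

  # minSize larger than the feature count: everything grey, with a warning
  expect_warning(ms0 <- detectModules(net, minSize = 1000), "minSize")
  expect_equal(sum(moduleLabels(ms0)), 0L)
})

test_that("eigengenes summarize modules with the documented orientation", {
  prof <- as.numeric(scale(c(3, 1, 4, 1, 5, 9, 2, 6)))
  expr <- rbind(
    g1 = 2 * prof + 5, g2 = -3 * prof + 1, g3 = prof,
    g4 = rnorm(8)
  )
  labels <- setNames(c(1L, 1L, 1L, 0L), rownames(expr))
  eg <- moduleEigengenes(expr, labels)
  # identical (up to sign/scale) profiles: eigengene proportional to them
  expect_equal(abs(cor(eg["ME1", ], prof)), 1, tolerance = 1e-10)
  # orientation: positively correlated with the mean standardized profile
  z <- t(scale(t(expr[1:3, ])))
  expect_gte(cor(eg["ME1", ], colMeans(z)), 0)
  expect_equal(sum(eg["ME1", ]^2), 1)

  # a size-1 module returns that gene's standardized profile
  labels2 <- setNames(c(1L, 2L, 2L, 0L), rownames(expr))
  eg2 <- moduleEigengenes(expr, labels2)
  expect_equal(abs(cor(eg2["ME1", ], prof)), 1, tolerance = 1e-10)

  # gene reordering leaves eigengenes unchanged
  ord <- c(3, 1, 4, 2)
  eg3 <- moduleEigengenes(expr[ord, ], labels[ord])
  expect_equal(eg3, eg)
})

test_that("module-trait correlation maps to the closed-form t p-values", {
  set.seed(13)
  eg <- matrix(rnorm(60), 2, 30, dimnames = list(c("ME1", "ME2"), NULL))
  # trait equal to an eigengene: r = 1, p below 1e-10
  traits <- data.frame(T1 = eg[1, ], T2 = withExactCor(eg[2, ], 0))
  mt <- moduleTraitCor(eg, traits)
  expect_equal(mt$r["ME1", "T1"], 1)
  expect_lt(mt$p["ME1", "T1"], 1e-10)
  # exact zero correlation maps to p = 1
  expect_equal(mt$r["ME2", "T2"], 0, tolerance = 1e-12)
  expect_equal(mt$p["ME2", "T2"], 1, tolerance = 1e-10)
  # generic agreement with cor.test
  ct <- cor.test(eg[2, ], traits$T1)
  expect_equal(mt$r["ME2", "T1"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(mt$p["ME2", "T1"], ct$p.value, tolerance = 1e-12)
})

test_that("hub ranking follows intramodular connectivity with lexicographic ties", {
  hub <- as.numeric(scale(rnorm(20, sd = 1)))
  set.seed(14)
  leaves <- t(sapply(1:6, function(i) 0.8 * hub + 0.6 * rnorm(20)))
  expr <- rbind(center = hub, leaves)
  rownames(expr) <- c("center", paste0("leaf", 1:6))
  net <- adjacencyMatrix(expr, 7)
  labels <- setNames(rep(1L, 7), rownames(expr))
  hg <- hubGenes(net, labels, 1, topN = 3)
  expect_identical(hg$feature_id[1], "center")

  # exact tie: two identical profiles rank lexicographically
  expr2 <- rbind(bGene = hub, aGene = hub, zzz = rnorm(20))
  net2 <- adjacencyMatrix(expr2, 7)
  labels2 <- setNames(rep(1L, 3), rownames(expr2))
  hg2 <- hubGenes(net2, labels2, 1, topN = 2)
  expect_identical(hg2$feature_id, c("aGene", "bGene"))
  expect_warning(hubGenes(net2, labels2, 1, topN = 10), "smaller")
  expect_error(hubGenes(net2, labels2, 7), "does not exist")
})

test_that("soft-threshold scan reports the connectivity spectrum", {
  set.seed(15)
  e1 <- rnorm(12)
  expr <- rbind(
    t(sapply(1:40, function(i) sqrt(0.85) * e1 + sqrt(0.15) * rnorm(12))),
    matrix(rnorm(60 * 12), 60, 12)
  )
  rownames(expr) <- paste0("g", 1:100)
  scan <- softThresholdScan(expr, powers = c(1, 7))
  expect_equal(scan$power, c(1, 7))
  # beta = 1 mean connectivity equals mean off-diagonal |cor|
  cc <- abs(cor(t(expr)))
  diag(cc) <- 0
  expect_equal(scan$meanK[1], mean(rowSums(cc)), tolerance = 1e-12)
  # higher power suppresses weak background links
  expect_lt(scan$meanK[2], scan$meanK[1])
  expect_warning(
    softThresholdScan(expr[, 1:2], powers = 7),
    "fewer than 8 samples"
  )
})
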