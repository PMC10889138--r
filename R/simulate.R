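## Synthetic-study generator. Emits a toy genome annotation, count
## matrices (mRNA / lncRNA / miRNA), a physiological trait table, miRNA
## and transcript sequences with planted target sites, and complete ground
## truth, with the statistical structure the downstream pipeline assumes:
##
##  - 2 varieties x 5 time points (0/4/12/24/48 h) x 3 replicates;
##  - latent module eigengenes; gene log2-mean = base + amplitude * latent;
##    counts ~ negative binomial with var = mu + alpha mu^2;
##  - two "driver" eigengenes carry the cold-stress time trend and drive
##    the SOD- and POD-like traits (sign -1); one further trait separates
##    the early (0/4/12 h) from the late (24/48 h) stress phase, so that
##    exactly SOD, POD and OH are discriminative for OPLS-DA;
##  - lncRNA loci realizing all four positional classes by construction;
##  - planted ceRNA triplets: each miRNA's latent is anti-correlated (at
##    `tripletCoupling`) with the latents of its lncRNA and mRNA partners,
##    and exact complementary sites are embedded in their sequences.
##
## Draw order (single RNG stream seeded from `seed`): sequences ->
## module/eigengene latents -> gene latents -> miRNA latents -> lncRNA
## latents -> counts (mRNA, lncRNA, miRNA) -> traits.

#' Simulation configuration
#'
#' Constructor for the [SimConfig-class] of [simulateStudy()]. Defaults
#' are the package's reference study conditions; see the methods vignette
#' for the rationale.
#'
#' @param nCoding,nLnc,nMirna Feature counts (coding genes, lncRNAs,
#'   miRNAs).
#' @param nModules Number of planted co-expression modules.
#' @param moduleSizes Integer vector of module sizes (sum <= `nCoding`).
#' @param varieties Two variety labels.
#' @param timePoints Time points in hours.
#' @param replicates Replicates per variety x time point.
#' @param nbDispersion NB dispersion alpha in `var = mu + alpha mu^2`
#'   (> 0).
#' @param baseMeanLog2Range Range of per-feature baseline log2 means.
#' @param withinModuleCor Latent within-module correlation rho in (0, 1).
#' @param traitNoiseSd Gaussian noise sd added to driver traits (>= 0).
#' @param deEffectLog2fc Planted log2 fold change for background DE genes.
#' @param nDeGenes Number of background coding genes with a planted
#'   time-step effect.
#' @param nTriplets Number of planted ceRNA triplets.
#' @param tripletCoupling Strength in (0, 1] of the miRNA anti-correlation
#'   with its partners.
#' @param geneAmplitude,mirnaAmplitude log2 amplitude of the latent signal
#'   for genes/lncRNAs and miRNAs.
#' @param classMix Share in (0, 1) of the cold-stress time trend in the
#'   driver eigengenes (their mutual correlation is `classMix^2`).
#' @param lncClassCounts Integer vector of length 4: lncRNAs per
#'   positional class (antisense, intergenic, intronic, sense); defaults
#'   to proportions typical of plant annotations, summing to `nLnc`.
#' @param traitDrivers Named integer vector mapping driver traits to
#'   module labels (default `c(SOD = 1, POD = 2)`, sign -1).
#' @param seed Integer RNG seed.
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(nCoding = 800, nLnc = 60, nMirna = 60,
                      nModules = 5, moduleSizes = rep(50L, nModules),
                      varieties = c("JH", "JL"),
                      timePoints = c(0, 4, 12, 24, 48),
                      replicates = 3,
                      nbDispersion = 0.1,
                      baseMeanLog2Range = c(5, 9),
                      withinModuleCor = 0.9,
                      traitNoiseSd = 0.1,
                      deEffectLog2fc = 2,
                      nDeGenes = 60,
                      nTriplets = 10,
                      tripletCoupling = 0.9,
                      geneAmplitude = 2,
                      mirnaAmplitude = 1.5,
                      classMix = 0.75,
                      lncClassCounts = NULL,
                      traitDrivers = c(SOD = 1L, POD = 2L),
                      seed = 1) {
  if (is.null(lncClassCounts)) {
    props <- c(antisense = 0.43, intergenic = 0.38, intronic = 0.08, sense = 0.11)
    lncClassCounts <- floor(nLnc * props)
    rem <- nLnc - sum(lncClassCounts)
    if (rem > 0) {
      add <- order(nLnc * props - lncClassCounts, decreasing = TRUE)[seq_len(rem)]
      lncClassCounts[add] <- lncClassCounts[add] + 1L
    }
  }
  methods::new("SimConfig",
    nCoding = as.integer(nCoding), nLnc = as.integer(nLnc),
    nMirna = as.integer(nMirna), nModules = as.integer(nModules),
    moduleSizes = as.integer(moduleSizes), varieties = varieties,
    timePoints = as.numeric(timePoints), replicates = as.integer(replicates),
    nbDispersion = nbDispersion, baseMeanLog2Range = baseMeanLog2Range,
    withinModuleCor = withinModuleCor, traitNoiseSd = traitNoiseSd,
    deEffectLog2fc = deEffectLog2fc, nDeGenes = as.integer(nDeGenes),
    nTriplets = as.integer(nTriplets), tripletCoupling = tripletCoupling,
    geneAmplitude = geneAmplitude, mirnaAmplitude = mirnaAmplitude,
    classMix = classMix, lncClassCounts = as.integer(lncClassCounts),
    traitDrivers = traitDrivers, seed = as.integer(seed)
  )
}

#' @rdname simConfig
#' @export
setClass("SimConfig", slots = c(
  nCoding = "integer", nLnc = "integer", nMirna = "integer",
  nModules = "integer", moduleSizes = "integer",
  varieties = "character", timePoints = "numeric", replicates = "integer",
  nbDispersion = "numeric", baseMeanLog2Range = "numeric",
  withinModuleCor = "numeric", traitNoiseSd = "numeric",
  deEffectLog2fc = "numeric", nDeGenes = "integer",
  nTriplets = "integer", tripletCoupling = "numeric",
  geneAmplitude = "numeric", mirnaAmplitude = "numeric",
  classMix = "numeric", lncClassCounts = "integer",
  traitDrivers = "integer", seed = "integer"
))

.validSimConfig <- function(object) {
  msg <- character()
  cnts <- c(
    object@nCoding, object@nLnc, object@nMirna, object@nModules,
    object@replicates
  )
  if (any(cnts <= 0)) msg <- c(msg, "all counts must be positive")
  if (object@nLnc < 4) msg <- c(msg, "need nLnc >= 4 (one per positional class)")
  if (length(object@moduleSizes) != object@nModules) {
    msg <- c(msg, "moduleSizes must have nModules entries")
  }
  if (sum(object@moduleSizes) > object@nCoding) {
    msg <- c(msg, "module sizes must sum to <= nCoding")
  }
  if (length(object@varieties) != 2) msg <- c(msg, "exactly 2 varieties")
  if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be positive")
  if (object@withinModuleCor <= 0 || object@withinModuleCor >= 1) {
    msg <- c(msg, "withinModuleCor must lie in (0,1)")
  }
  if (object@traitNoiseSd < 0) msg <- c(msg, "traitNoiseSd must be >= 0")
  if (object@tripletCoupling <= 0 || object@tripletCoupling > 1) {
    msg <- c(msg, "tripletCoupling must lie in (0,1]")
  }
  if (object@classMix <= 0 || object@classMix >= 1) {
    msg <- c(msg, "classMix must lie in (0,1)")
  }
  if (length(object@lncClassCounts) != 4 ||
    sum(object@lncClassCounts) != object@nLnc) {
    msg <- c(msg, "lncClassCounts must have 4 entries summing to nLnc")
  }
  if (any(object@traitDrivers < 1) ||
    any(object@traitDrivers > object@nModules)) {
    msg <- c(msg, "unknown driver module id in traitDrivers")
  }
  if (object@nTriplets > 0 && object@nMirna < object@nTriplets) {
    msg <- c(msg, "need nMirna >= nTriplets")
  }
  if (object@nTriplets > sum(object@moduleSizes[object@traitDrivers])) {
    msg <- c(msg, "too many triplets for the driver modules")
  }
  if (object@nTriplets > object@lncClassCounts[2]) {
    msg <- c(msg, "need at least nTriplets intergenic lncRNAs")
  }
  if (length(msg)) msg else TRUE
}
setValidity("SimConfig", .validSimConfig)

setMethod("show", "SimConfig", function(object) {
  cat(
    "SimConfig:", object@nCoding, "coding /", object@nLnc, "lncRNA /",
    object@nMirna, "miRNA;", object@nModules, "modules;",
    length(object@varieties) * length(object@timePoints) * object@replicates,
    "samples; seed", object@seed, "\n"
  )
})

## ---- annotation ----------------------------------------------------------

.GENE_SPACING <- 250000L # bp between coding gene starts
.GENE_EXON1 <- 1000L # exon lengths; intron spans 2000 bp between them
.GENE_INTRON <- 2000L
.GENE_EXON2 <- 1000L

#' Simulate the toy genome annotation
#'
#' Coding genes are placed on two chromosomes on a regular grid (250 kb
#' apart), each with two 1 kb exons flanking a 2 kb intron, alternating
#' strand. lncRNA loci are then constructed per requested positional
#' class: antisense/sense overlap a host coding exon on the
#' opposite/same strand, intronic lie fully inside a host intron, and
#' intergenic sit midway between adjacent genes (> 100 kb from both).
#' miRNA loci are 21 nt single-exon entries on their own chromosome.
#'
#' @param config A [SimConfig-class].
#' @return List with `annotation` (a [TxAnnotation-class]) and `classes`
#'   (data.frame `tx_id`, `class`, `host_gene`: the truth labels).
#' @export
simulateAnnotation <- function(config) {
  stopifnot(methods::is(config, "SimConfig"))
  methods::validObject(config)
  nc <- config@nCoding
  cls_counts <- setNames(config@lncClassCounts, .LNC_CLASSES)
  n_hosted <- sum(cls_counts[c("antisense", "intronic", "sense")])
  if (nc < 1) {
    stop(
      "cannot place class ",
      names(cls_counts)[cls_counts > 0][1], ": no coding genes"
    )
  }
  if (config@nLnc > nc) {
    stop(
      "cannot place class intergenic: need nCoding >= nLnc ",
      "distinct host positions"
    )
  }
  per_chr <- ceiling(nc / 2)
  gid <- sprintf("g%04d", seq_len(nc))
  lev <- c("chr1", "chr2", "chr3") # shared seqlevels so GRanges combine cleanly
  chr <- rep(c("chr1", "chr2"), each = per_chr)[seq_len(nc)]
  idx_on_chr <- unlist(lapply(table(chr)[unique(chr)], seq_len), use.names = FALSE)
  gstart <- 10000L + (idx_on_chr - 1L) * .GENE_SPACING
  gstrand <- rep(c("+", "-"), length.out = nc)
  glen <- .GENE_EXON1 + .GENE_INTRON + .GENE_EXON2
  tx_list <- GRanges(factor(chr, lev), IRanges(gstart, gstart + glen - 1L),
    strand = gstrand,
    tx_id = gid, gene_id = gid, biotype = "coding"
  )
  ex_list <- lapply(seq_len(nc), function(i) {
    GRanges(factor(chr[i], lev), IRanges(
      c(gstart[i], gstart[i] + .GENE_EXON1 + .GENE_INTRON),
      width = c(.GENE_EXON1, .GENE_EXON2)
    ), strand = gstrand[i])
  })

  # lncRNAs: classes in a fixed order, each with a distinct host gene;
  # intergenic first so that triplet lncRNAs (drawn from intergenic) have
  # stable low ids
  classes <- c(
    rep("intergenic", cls_counts["intergenic"]),
    rep("antisense", cls_counts["antisense"]),
    rep("intronic", cls_counts["intronic"]),
    rep("sense", cls_counts["sense"])
  )
  lid <- sprintf("lnc%03d", seq_len(config@nLnc))
  host <- seq_len(config@nLnc) # distinct host gene per lncRNA
  lnc_tx <- vector("list", config@nLnc)
  lnc_ex <- vector("list", config@nLnc)
  flip <- c("+" = "-", "-" = "+")
  for (i in seq_len(config@nLnc)) {
    h <- host[i]
    s0 <- gstart[h]
    cl <- classes[i]
    reg <- switch(cl,
      antisense = c(s0 + 200L, s0 + 699L),
      sense = c(
        s0 + .GENE_EXON1 + .GENE_INTRON + 200L,
        s0 + .GENE_EXON1 + .GENE_INTRON + 699L
      ),
      intronic = c(s0 + .GENE_EXON1 + 200L, s0 + .GENE_EXON1 + 799L),
      intergenic = c(
        s0 + .GENE_SPACING %/% 2L,
        s0 + .GENE_SPACING %/% 2L + 499L
      )
    )
    st <- switch(cl,
      antisense = flip[gstrand[h]],
      sense = gstrand[h],
      intronic = flip[gstrand[h]],
      intergenic = gstrand[h]
    )
    lnc_tx[[i]] <- GRanges(factor(chr[h], lev), IRanges(reg[1], reg[2]),
      strand = st,
      tx_id = lid[i], gene_id = lid[i], biotype = "lncRNA_candidate"
    )
    lnc_ex[[i]] <- GRanges(factor(chr[h], lev), IRanges(reg[1], reg[2]), strand = st)
  }

  mid <- sprintf("mir%02d", seq_len(config@nMirna))
  mstart <- 1000L + (seq_len(config@nMirna) - 1L) * 1000L
  mir_tx <- GRanges(factor("chr3", lev), IRanges(mstart, width = 21L),
    strand = "+",
    tx_id = mid, gene_id = mid, biotype = "miRNA"
  )
  mir_ex <- lapply(seq_len(config@nMirna), function(i) granges(mir_tx[i]))

  tx <- c(tx_list, do.call(c, lnc_tx), mir_tx)
  exl <- GRangesList(c(ex_list, lnc_ex, mir_ex))
  names(exl) <- tx$tx_id
  ann <- methods::new("TxAnnotation", transcripts = tx, exons = exl)
  list(
    annotation = ann,
    classes = data.frame(tx_id = lid, class = classes, host_gene = gid[host])
  )
}

## ---- expression, sequences, traits ---------------------------------------

.sampleSheet <- function(config) {
  grid <- expand.grid(
    replicate = seq_len(config@replicates),
    time_h = config@timePoints,
    variety = config@varieties,
    stringsAsFactors = FALSE
  )[, c("variety", "time_h", "replicate")]
  grid$sample <- sprintf("%s_%gh_R%d", grid$variety, grid$time_h, grid$replicate)
  rownames(grid) <- grid$sample
  grid[, c("sample", "variety", "time_h", "replicate")]
}

.randomSeq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, "")
}

#' Simulate the full synthetic study
#'
#' Runs the complete generator: annotation, sequences with planted target
#' sites, latent eigengenes, count matrices, traits, and the ground-truth
#' bundle. All randomness flows from `config@seed`; identical configs give
#' identical output.
#'
#' @param config A [SimConfig-class] from [simConfig()].
#' @return A list of class `ceRNAStudy`:
#' \describe{
#'   \item{config}{the input configuration}
#'   \item{annotation, classes}{see [simulateAnnotation()]}
#'   \item{samples}{sample sheet (variety, time_h, replicate)}
#'   \item{mrna, lncrna, mirna}{`SummarizedExperiment` count matrices}
#'   \item{sequences}{list `mirna`, `transcripts` of named RNA strings}
#'   \item{traits}{data.frame samples x 9 traits}
#'   \item{truth}{list: `moduleLabels` (named, 0 = background),
#'     `eigengenes` (modules x samples), `traitDrivers`, `traitSigns`,
#'     `phase` (early/late factor), `logMu` (latent log2-mean matrices),
#'     `deBackground`, `triplets`, `targetPairs`}
#' }
#' @examples
#' sim <- simulateStudy(simConfig(nCoding = 60, nLnc = 8, nMirna = 4,
#'   nModules = 2, moduleSizes = c(20, 20), nDeGenes = 5, nTriplets = 2,
#'   seed = 7))
#' sim$truth$triplets
#' @export
simulateStudy <- function(config = simConfig()) {
  stopifnot(methods::is(config, "SimConfig"))
  methods::validObject(config)
  set.seed(config@seed)

  ann <- simulateAnnotation(config)
  samples <- .sampleSheet(config)
  n <- nrow(samples)
  nc <- config@nCoding
  nl <- config@nLnc
  nm <- config@nMirna
  gid <- sprintf("g%04d", seq_len(nc))
  lid <- sprintf("lnc%03d", seq_len(nl))
  mid <- sprintf("mir%02d", seq_len(nm))

  ## module membership: modules fill the first sum(moduleSizes) genes
  labels <- integer(nc)
  pos <- 1L
  for (m in seq_len(config@nModules)) {
    labels[pos:(pos + config@moduleSizes[m] - 1L)] <- m
    pos <- pos + config@moduleSizes[m]
  }
  names(labels) <- gid

  ## triplets: mRNA partners are the leading genes of the driver modules,
  ## lncRNA partners the leading intergenic lncRNAs, one miRNA each
  drv <- unique(unname(config@traitDrivers))
  trip_mod <- rep(drv, length.out = config@nTriplets)
  trip_mrna <- character(config@nTriplets)
  used <- integer(0)
  for (k in seq_len(config@nTriplets)) {
    cand <- setdiff(which(labels == trip_mod[k]), used)
    trip_mrna[k] <- gid[cand[1]]
    used <- c(used, cand[1])
  }
  trip_lnc <- lid[seq_len(config@nTriplets)] # intergenic by construction
  trip_mir <- mid[seq_len(config@nTriplets)]
  triplets <- if (config@nTriplets > 0) {
    data.frame(
      lncrna_id = trip_lnc, mirna_id = trip_mir, mrna_id = trip_mrna,
      module = trip_mod
    )
  } else {
    data.frame(
      lncrna_id = character(), mirna_id = character(),
      mrna_id = character(), module = integer()
    )
  }

  ## 1) sequences (draw order is part of the contract)
  seq_mir <- setNames(.randomSeq(nm, 21L), mid)
  tx_len <- 300L
  seq_tx <- setNames(.randomSeq(nc + nl, tx_len), c(gid, lid))
  site_pos <- 100L
  for (k in seq_len(config@nTriplets)) {
    site <- revComplementRna(seq_mir[[trip_mir[k]]])
    for (tgt in c(trip_mrna[k], trip_lnc[k])) {
      s <- seq_tx[[tgt]]
      substr(s, site_pos, site_pos + nchar(site) - 1L) <- site
      seq_tx[[tgt]] <- s
    }
  }
  targetPairs <- if (config@nTriplets > 0) {
    data.frame(
      mirna_id = rep(trip_mir, 2L),
      target_id = c(trip_mrna, trip_lnc),
      score = 0, position = site_pos
    )
  } else {
    data.frame(
      mirna_id = character(), target_id = character(),
      score = numeric(), position = integer()
    )
  }

  ## 2) latent eigengenes
  timeScore <- as.numeric(scale(samples$time_h))
  phase <- factor(ifelse(samples$time_h >= 24, "late", "early"),
    levels = c("early", "late")
  )
  classContrast <- as.numeric(scale(ifelse(phase == "late", 1, -1)))
  a <- config@classMix
  cond <- interaction(samples$variety, samples$time_h, drop = TRUE)
  E <- matrix(0, config@nModules, n,
    dimnames = list(paste0("M", seq_len(config@nModules)), samples$sample)
  )
  # Eigengene variation is condition-level (replicates share it, with a
  # small jitter), as in a real time course. The condition-level noise is
  # orthogonalized against the time trend, the phase contrast and the
  # other modules, so planted modules are distinct by construction: the
  # only shared signal is the time trend the two driver modules carry.
  nCond <- nlevels(cond)
  condRows <- match(levels(cond), cond)
  B <- cbind(timeScore[condRows], classContrast[condRows])
  U <- matrix(rnorm(nCond * config@nModules), nCond, config@nModules)
  for (m in seq_len(config@nModules)) {
    basis <- if (m > 1) cbind(B, U[, seq_len(m - 1)]) else B
    U[, m] <- stats::residuals(stats::lm.fit(basis, U[, m]))
    U[, m] <- U[, m] / sd(U[, m])
  }
  for (m in seq_len(config@nModules)) {
    u <- U[as.integer(cond), m]
    E[m, ] <- if (m %in% drv) {
      a * timeScore + sqrt(1 - a^2) * u + 0.15 * rnorm(n)
    } else {
      u + 0.15 * rnorm(n)
    }
    E[m, ] <- as.numeric(scale(E[m, ]))
  }

  ## 3) gene latents and log2 means
  rho <- config@withinModuleCor
  tau <- config@geneAmplitude
  bg_amp <- 0.3 # log2 sd of background (signal-free, housekeeping-like) profiles
  base_g <- runif(nc, config@baseMeanLog2Range[1], config@baseMeanLog2Range[2])
  Z <- matrix(rnorm(nc * n), nc, n)
  amp_g <- ifelse(labels > 0, tau, bg_amp)
  for (i in seq_len(nc)) {
    if (labels[i] > 0) {
      Z[i, ] <- sqrt(rho) * E[labels[i], ] + sqrt(1 - rho) * Z[i, ]
    }
  }
  logmu_m <- base_g + amp_g * Z
  dimnames(logmu_m) <- list(gid, samples$sample)

  ## background DE genes: time-step effect in both varieties
  bg <- which(labels == 0)
  n_de <- min(config@nDeGenes, length(bg))
  de_idx <- bg[seq_len(n_de)]
  de_dir <- rep(c(1, -1), length.out = n_de)
  stressed <- samples$time_h > 0
  for (j in seq_along(de_idx)) {
    logmu_m[de_idx[j], stressed] <- logmu_m[de_idx[j], stressed] +
      de_dir[j] * config@deEffectLog2fc
  }

  ## miRNA latents: anti-correlated with the driver eigengene at the
  ## coupling strength
  cpl <- config@tripletCoupling
  base_mi <- runif(nm, 6, 10)
  M <- matrix(rnorm(nm * n), nm, n)
  amp_mi <- rep(bg_amp, nm)
  for (k in seq_len(config@nTriplets)) {
    M[k, ] <- -(cpl * E[trip_mod[k], ] + sqrt(1 - cpl^2) * M[k, ])
    amp_mi[k] <- config@mirnaAmplitude
  }
  logmu_mi <- base_mi + amp_mi * M
  dimnames(logmu_mi) <- list(mid, samples$sample)

  ## lncRNA latents: triplet lncRNAs are anti-coupled to their miRNA's
  ## latent (strength = tripletCoupling); the rest are quiet background
  base_l <- runif(nl, 4, 7)
  L <- matrix(rnorm(nl * n), nl, n)
  amp_l <- rep(bg_amp, nl)
  for (k in seq_len(config@nTriplets)) {
    L[k, ] <- -cpl * M[k, ] + sqrt(1 - cpl^2) * L[k, ]
    amp_l[k] <- tau
  }
  logmu_l <- base_l + amp_l * L
  dimnames(logmu_l) <- list(lid, samples$sample)

  ## 4) counts
  alpha <- config@nbDispersion
  draw <- function(logmu) {
    k <- matrix(
      rnbinom(length(logmu), mu = 2^as.vector(logmu), size = 1 / alpha),
      nrow(logmu), ncol(logmu),
      dimnames = dimnames(logmu)
    )
    storage.mode(k) <- "integer"
    k
  }
  cnt_m <- draw(logmu_m)
  cnt_l <- draw(logmu_l)
  cnt_mi <- draw(logmu_mi)

  ## 5) traits: drivers = -eigengene + noise; OH separates the phases;
  ## the rest are pure noise
  traits <- data.frame(row.names = samples$sample)
  sdn <- config@traitNoiseSd
  signs <- setNames(rep(-1, length(config@traitDrivers)), names(config@traitDrivers))
  for (tn in names(config@traitDrivers)) {
    traits[[tn]] <- signs[tn] * E[config@traitDrivers[tn], ] + rnorm(n, 0, sdn)
  }
  traits[["OH"]] <- classContrast + rnorm(n, 0, sdn)
  for (tn in c("CAT", "T-AOC", "MDA", "proline", "SS", "SP")) {
    traits[[tn]] <- rnorm(n)
  }

  structure(list(
    config = config,
    annotation = ann$annotation,
    classes = ann$classes,
    samples = samples,
    mrna = makeExpressionSet(cnt_m, samples, unit = "counts"),
    lncrna = makeExpressionSet(cnt_l, samples, unit = "counts"),
    mirna = makeExpressionSet(cnt_mi, samples, unit = "counts"),
    sequences = list(mirna = seq_mir, transcripts = seq_tx),
    traits = traits,
    truth = list(
      moduleLabels = labels,
      eigengenes = E,
      traitDrivers = config@traitDrivers,
      traitSigns = signs,
      phase = setNames(phase, samples$sample),
      logMu = list(mrna = logmu_m, lncrna = logmu_l, mirna = logmu_mi),
      deBackground = setNames(de_dir, gid[de_idx]),
      triplets = triplets,
      targetPairs = targetPairs
    )
  ), class = "ceRNAStudy")
}

#' @export
print.ceRNAStudy <- function(x, ...) {
  cat(
    "ceRNAStudy:", nrow(x$samples), "samples;",
    nrow(x$mrna), "mRNAs,", nrow(x$lncrna), "lncRNAs,",
    nrow(x$mirna), "miRNAs;", nrow(x$truth$triplets),
    "planted triplets (seed", x$config@seed, ")\n"
  )
  invisible(x)
}

#' Simulate traits from eigengenes
#'
#' Standalone trait generator (the counterpart of the trait block of
#' [simulateStudy()]): each driver trait is
#' `sign * eigengene + N(0, traitNoiseSd)`, the OH-like trait separates
#' the two stress phases, and the remaining traits are standard-normal
#' noise.
#'
#' @param eigengenes Matrix modules x samples (rownames `M1`, ...).
#' @param classContrast Numeric vector (one per sample): the standardized
#'   class contrast for the discriminative trait.
#' @param config A [SimConfig-class] (uses `traitDrivers`,
#'   `traitNoiseSd`).
#' @param signs Named vector of driver signs (default -1 for each driver).
#' @return data.frame samples x 9 traits.
#' @export
simulateTraits <- function(eigengenes, classContrast, config,
                           signs = NULL) {
  drivers <- config@traitDrivers
  if (any(drivers > nrow(eigengenes))) {
    stop(
      "unknown driver module id(s): ",
      paste(drivers[drivers > nrow(eigengenes)], collapse = ", ")
    )
  }
  if (is.null(signs)) signs <- setNames(rep(-1, length(drivers)), names(drivers))
  n <- ncol(eigengenes)
  traits <- data.frame(row.names = colnames(eigengenes))
  for (tn in names(drivers)) {
    traits[[tn]] <- signs[tn] * eigengenes[drivers[tn], ] +
      rnorm(n, 0, config@traitNoiseSd)
  }
  traits[["OH"]] <- classContrast + rnorm(n, 0, config@traitNoiseSd)
  for (tn in c("CAT", "T-AOC", "MDA", "proline", "SS", "SP")) {
    traits[[tn]] <- rnorm(n)
  }
  traits
}

#' Ground-truth differential features for a time contrast
#'
#' Computes the latent (noise-free) log2 fold change of `time` vs 0 h
#' within one variety from the generator's log2-mean matrices and flags
#' features beyond the fold-change threshold. This is the reference
#' against which DE recall is measured.
#'
#' @param study A `ceRNAStudy` from [simulateStudy()].
#' @param type `"mrna"`, `"lncrna"` or `"mirna"`.
#' @param variety Variety label.
#' @param time Stress time point (hours, > 0).
#' @param fcMin Fold-change threshold (default 2).
#' @return Named logical vector: is the feature truly DE at this contrast?
#' @export
truthDeFlags <- function(study, type = c("mrna", "lncrna", "mirna"),
                         variety, time, fcMin = 2) {
  type <- match.arg(type)
  logmu <- study$truth$logMu[[type]]
  s <- study$samples
  ia <- s$variety == variety & s$time_h == 0
  ib <- s$variety == variety & s$time_h == time
  if (!any(ib)) stop("no samples at time ", time)
  lfc <- rowMeans(logmu[, ib, drop = FALSE]) - rowMeans(logmu[, ia, drop = FALSE])
  abs(lfc) >= log2(fcMin)
}

#' Write a synthetic study to disk
#'
#' Persists the generator output in the pipeline's external formats: GTF
#' annotation, TSV count matrices, CSV sample sheet and trait table, TSV
#' target-pair truth and a JSON truth bundle. Everything is re-readable
#' with the package's readers.
#'
#' @param study A `ceRNAStudy`.
#' @param dir Output directory (created if needed).
#' @return Invisible named vector of the file paths.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    annotation = file.path(dir, "annotation.gtf"),
    mrna = file.path(dir, "mrna_counts.tsv"),
    lncrna = file.path(dir, "lncrna_counts.tsv"),
    mirna = file.path(dir, "mirna_counts.tsv"),
    samples = file.path(dir, "samples.csv"),
    traits = file.path(dir, "traits.csv"),
    pairs = file.path(dir, "target_pairs.tsv"),
    truth = file.path(dir, "truth.json")
  )
  writeGTF(study$annotation, paths["annotation"])
  writeCounts(study$mrna, paths["mrna"])
  writeCounts(study$lncrna, paths["lncrna"])
  writeCounts(study$mirna, paths["mirna"])
  utils::write.csv(study$samples, paths["samples"], row.names = FALSE)
  utils::write.csv(
    data.frame(sample = rownames(study$traits), study$traits, check.names = FALSE),
    paths["traits"],
    row.names = FALSE
  )
  utils::write.table(study$truth$targetPairs, paths["pairs"],
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_json(
    list(
      moduleLabels = as.list(study$truth$moduleLabels),
      triplets = study$truth$triplets,
      classes = study$classes,
      deBackground = as.list(study$truth$deBackground)
    ),
    paths["truth"],
    auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
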