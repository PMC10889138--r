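## Config-driven orchestration: normalize -> differential expression ->
## lncRNA classification -> co-expression modules -> OPLS-DA VIP ->
## trait-module selection -> targeting -> ceRNA assembly, with a
## machine-readable run report and optional on-disk artifacts.

#' Build and validate a pipeline configuration
#'
#' All thresholds default to the study's printed screening rules: fold
#' change >= 2 with FDR <= 0.01 for mRNA/lncRNA, fold change >= 1.5 with
#' p <= 0.05 for miRNA, soft power 7, a 100 kb cis window, trans rule
#' r > 0.9 / p < 0.01, and VIP > 1 for trait screening. Unknown keys are
#' rejected.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return Validated named list of parameters (class `runConfig`).
#' @export
runConfig <- function(...) {
  cfg <- list(
    fcMrna = 2, fdrMrna = 0.01,
    fcMirna = 1.5, pMirna = 0.05,
    power = 7, minModuleSize = 30, cutHeight = 0.95, mergeCor = 0.8,
    fpkmMin = 1, fpkmMinProp = 0.1,
    cisWindow = 1e5, transRMin = 0.9, transPMax = 0.01,
    nOrtho = 1, vipMin = 1, traitModuleP = 0.05,
    maxTargetScore = 4,
    negRMax = -0.5, cernaPMax = 0.05,
    requirePositiveLncMrna = FALSE,
    minLncLen = 200
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  with(cfg, {
    if (fdrMrna <= 0 || fdrMrna > 1) stop("fdrMrna must lie in (0, 1]")
    if (pMirna <= 0 || pMirna > 1) stop("pMirna must lie in (0, 1]")
    if (fcMrna <= 1 || fcMirna <= 1) stop("fold-change thresholds must exceed 1")
    if (power < 1) stop("power must be >= 1")
    if (cisWindow <= 0) stop("cisWindow must be positive")
    if (negRMax >= 0) stop("negRMax must be negative")
  })
  structure(cfg, class = "runConfig")
}

#' Run the full ceRNA inference pipeline
#'
#' Executes all stages on a synthetic or file-backed study and returns a
#' run report plus the stage results. Stages: FPKM/TPM normalization;
#' per-contrast NB differential expression (each time point vs 0 h within
#' each variety); lncRNA positional classification; co-expression modules
#' on log2(FPKM+1) with module--trait correlation; OPLS-DA VIP screening
#' of traits (early vs late stress phase); trait-module selection; miRNA
#' target prediction (from sequences, or a supplied pair table) plus
#' cis/trans lncRNA targets; ceRNA triplet assembly. The pipeline draws no
#' random numbers: rerunning with the same inputs reproduces identical
#' artifacts.
#'
#' @param study A `ceRNAStudy` from [simulateStudy()], or a list with the
#'   same components built from files (`annotation`, `mrna`, `lncrna`,
#'   `mirna`, `samples`, `traits`, and either `sequences` or
#'   `targetPairs`).
#' @param config A [runConfig()].
#' @param outDir Optional directory for artifacts (DE tables, module
#'   assignment, eigengenes, module-trait table, VIP table, pairs, links,
#'   triplets, network export, `report.json`).
#' @return List of class `ceRNARun` with elements `report` (the
#'   machine-readable summary), `de`, `classes`, `network`, `modules`,
#'   `eigengenes`, `moduleTrait`, `vip`, `selectedModules`, `pairs`,
#'   `cis`, `trans`, `triplets`.
#' @export
runPipeline <- function(study, config = runConfig(), outDir = NULL) {
  if (!inherits(config, "runConfig")) stop("config must come from runConfig()")
  .stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  samples <- study$samples
  ann <- study$annotation

  ## --- normalize ---------------------------------------------------------
  norm <- .stage("normalize", {
    lens <- transcriptLengths(ann)
    cm <- assay(study$mrna)
    cl <- assay(study$lncrna)
    cmi <- assay(study$mirna)
    lib_m <- colSums(cm) + colSums(cl) # shared library for the RNA-seq side
    fpkm_m <- fpkmNormalize(cm, lens[rownames(cm)], lib_m)
    fpkm_l <- fpkmNormalize(cl, lens[rownames(cl)], lib_m)
    tpm_mi <- tpmNormalize(cmi, lengths = 1)
    list(
      fpkm_m = fpkm_m, fpkm_l = fpkm_l, tpm_mi = tpm_mi,
      log_m = log2(fpkm_m + 1), log_l = log2(fpkm_l + 1),
      log_mi = log2(tpm_mi + 1)
    )
  })

  ## --- differential expression ------------------------------------------
  de <- .stage("diffexpr", {
    contrasts <- expand.grid(
      variety = unique(samples$variety),
      time = setdiff(sort(unique(samples$time_h)), 0),
      stringsAsFactors = FALSE
    )
    runDe <- function(cnt, fc, alpha, useQ) {
      out <- list()
      for (i in seq_len(nrow(contrasts))) {
        v <- contrasts$variety[i]
        tt <- contrasts$time[i]
        sel <- samples$variety == v & samples$time_h %in% c(0, tt)
        grp <- factor(ifelse(samples$time_h[sel] == 0, "t0", "t1"),
          levels = c("t0", "t1")
        )
        res <- callDE(nbTest(cnt[, samples$sample[sel], drop = FALSE], grp),
          fcMin = fc, alphaMax = alpha, useQ = useQ
        )
        out[[sprintf("%s_%gh", v, tt)]] <- res
      }
      out
    }
    de_m <- runDe(assay(study$mrna), config$fcMrna, config$fdrMrna, TRUE)
    de_l <- runDe(assay(study$lncrna), config$fcMrna, config$fdrMrna, TRUE)
    de_mi <- runDe(assay(study$mirna), config$fcMirna, config$pMirna, FALSE)
    sigUnion <- function(lst) {
      sort(unique(unlist(lapply(lst, function(r) r$feature_id[r$significant]))))
    }
    list(
      mrna = de_m, lncrna = de_l, mirna = de_mi,
      deMrnas = sigUnion(de_m), deLncrnas = sigUnion(de_l),
      deMirnas = sigUnion(de_mi)
    )
  })

  ## --- lncRNA classification ---------------------------------------------
  classes <- .stage("classify", {
    tx <- transcriptRanges(ann)
    lnc_ids <- filterLncCandidates(ann, minLen = config$minLncLen)
    lnc_ids <- intersect(lnc_ids, tx$tx_id[tx$biotype == "lncRNA_candidate"])
    classifyLncRNAs(ann, lnc_ids)
  })

  ## --- co-expression modules ---------------------------------------------
  mod <- .stage("modules", {
    expr <- norm$log_m
    keep <- rowMeans(norm$fpkm_m > config$fpkmMin) >= config$fpkmMinProp &
      apply(expr, 1, var) > 0
    expr <- expr[keep, , drop = FALSE]
    net <- tomSimilarity(adjacencyMatrix(expr, power = config$power))
    ms <- detectModules(net,
      minSize = config$minModuleSize,
      cutHeight = config$cutHeight,
      mergeCor = config$mergeCor, expr = expr
    )
    eg <- if (length(moduleSizes(ms))) moduleEigengenes(expr, ms) else NULL
    mt <- if (!is.null(eg)) moduleTraitCor(eg, study$traits) else NULL
    list(network = net, modules = ms, eigengenes = eg, moduleTrait = mt)
  })

  ## --- VIP screening ------------------------------------------------------
  vip <- .stage("vip", {
    phase <- factor(ifelse(samples$time_h >= 24, "late", "early"),
      levels = c("early", "late")
    )
    fit <- oplsFit(as.matrix(study$traits), phase, nOrtho = config$nOrtho)
    vipScores(fit)
  })

  ## --- trait-module selection ---------------------------------------------
  sel <- .stage("select", {
    if (is.null(mod$moduleTrait)) {
      list(modules = integer(), table = NULL)
    } else {
      selectTraitModules(mod$moduleTrait, vip,
        vipMin = config$vipMin,
        pCap = config$traitModuleP
      )
    }
  })

  ## --- targeting -----------------------------------------------------------
  tg <- .stage("targeting", {
    pairs <- if (!is.null(study$sequences)) {
      mir_seq <- study$sequences$mirna[intersect(
        de$deMirnas,
        names(study$sequences$mirna)
      )]
      if (length(mir_seq)) {
        predictTargets(mir_seq, study$sequences$transcripts,
          maxScore = config$maxTargetScore
        )
      } else {
        data.frame(
          mirna_id = character(), target_id = character(),
          score = numeric(), position = integer()
        )
      }
    } else if (!is.null(study$targetPairs)) {
      study$targetPairs[study$targetPairs$mirna_id %in% de$deMirnas, ,
        drop = FALSE
      ]
    } else {
      stop("need sequences or a precomputed target-pair table")
    }
    cis <- cisTargets(ann, window = config$cisWindow)
    cis <- cis[cis$lncrna_id %in% de$deLncrnas, , drop = FALSE]
    trans <- if (length(de$deLncrnas) && length(de$deMrnas)) {
      transTargets(
        norm$log_l[de$deLncrnas, , drop = FALSE],
        norm$log_m[de$deMrnas, , drop = FALSE],
        rMin = config$transRMin, pMax = config$transPMax
      )
    } else {
      data.frame()
    }
    list(pairs = pairs, cis = cis, trans = trans)
  })

  ## --- ceRNA assembly ------------------------------------------------------
  cerna <- .stage("cerna", {
    emptyTriplets <- data.frame(
      lncrna_id = character(), mirna_id = character(), mrna_id = character(),
      r_mirna_mrna = numeric(), p_mirna_mrna = numeric(),
      r_mirna_lncrna = numeric(), p_mirna_lncrna = numeric(),
      r_lncrna_mrna = numeric()
    )
    if (!length(sel$modules) || !nrow(tg$pairs) || !length(de$deMrnas)) {
      list(candidates = character(), triplets = emptyTriplets)
    } else {
      modGenes <- unlist(lapply(
        sel$modules,
        function(m) moduleGenes(mod$modules, m)
      ))
      cand <- suppressWarnings(candidateMrnas(de$deMrnas, modGenes, tg$pairs))
      trip <- assembleTriplets(
        cand, de$deLncrnas, tg$pairs,
        norm$log_mi, norm$log_m, norm$log_l,
        negRMax = config$negRMax, pMax = config$cernaPMax,
        requirePositiveLncMrna = config$requirePositiveLncMrna
      )
      list(candidates = cand, triplets = trip)
    }
  })

  report <- list(
    version = as.character(utils::packageVersion("ceRNAflow")),
    config = unclass(config),
    n_samples = nrow(samples),
    n_features = c(
      mrna = nrow(study$mrna), lncrna = nrow(study$lncrna),
      mirna = nrow(study$mirna)
    ),
    de_counts = list(
      mrna = vapply(de$mrna, function(r) sum(r$significant), 0L),
      lncrna = vapply(de$lncrna, function(r) sum(r$significant), 0L),
      mirna = vapply(de$mirna, function(r) sum(r$significant), 0L)
    ),
    de_union = c(
      mrna = length(de$deMrnas), lncrna = length(de$deLncrnas),
      mirna = length(de$deMirnas)
    ),
    lnc_classes = if (nrow(classes)) summarizeClasses(classes) else NULL,
    n_modules = length(moduleSizes(mod$modules)),
    module_sizes = moduleSizes(mod$modules),
    module_trait = if (!is.null(mod$moduleTrait)) {
      list(r = mod$moduleTrait$r, p = mod$moduleTrait$p)
    } else {
      NULL
    },
    vip = vip,
    selected_modules = sel$modules,
    n_target_pairs = nrow(tg$pairs),
    n_cis = nrow(tg$cis), n_trans = nrow(tg$trans),
    n_candidates = length(cerna$candidates),
    n_triplets = nrow(cerna$triplets),
    network = networkSummary(cerna$triplets)
  )

  run <- structure(list(
    report = report, de = de, classes = classes,
    network = mod$network, modules = mod$modules,
    eigengenes = mod$eigengenes, moduleTrait = mod$moduleTrait,
    vip = vip, selectedModules = sel$modules, selectedTable = sel$table,
    pairs = tg$pairs, cis = tg$cis, trans = tg$trans,
    candidates = cerna$candidates, triplets = cerna$triplets
  ), class = "ceRNARun")

  if (!is.null(outDir)) .writeRunArtifacts(run, study, outDir)
  run
}

#' @export
print.ceRNARun <- function(x, ...) {
  r <- x$report
  cat(
    "ceRNARun:", r$n_modules, "modules;",
    paste(r$de_union, collapse = "/"),
    "DE (mRNA/lncRNA/miRNA);",
    r$n_triplets, "triplet(s)\n"
  )
  invisible(x)
}

#' Select trait-anchored modules
#'
#' Restricts to traits with VIP above `vipMin`, then, for each such trait,
#' picks the module with the largest `|r|` whose p-value is below `pCap`;
#' exact ties go to the lexicographically smaller module label.
#'
#' @param moduleTrait List with matrices `r` and `p` from
#'   [moduleTraitCor()] (rownames `ME<k>`).
#' @param vip data.frame from [vipScores()].
#' @param vipMin VIP screening threshold (default 1).
#' @param pCap Module-trait p-value cap (default 0.05).
#' @return List with `modules` (sorted unique selected module labels,
#'   integer) and `table` (per-trait winner with r and p).
#' @export
selectTraitModules <- function(moduleTrait, vip, vipMin = 1, pCap = 0.05) {
  traits <- vip$variable[vip$vip > vipMin]
  traits <- intersect(traits, colnames(moduleTrait$r))
  if (!length(traits)) {
    warning("no trait passes the VIP screen; empty selection")
    return(list(modules = integer(), table = NULL))
  }
  rows <- lapply(traits, function(tr) {
    r <- setNames(moduleTrait$r[, tr], rownames(moduleTrait$r))
    p <- setNames(moduleTrait$p[, tr], rownames(moduleTrait$p))
    ok <- p < pCap
    if (!any(ok)) {
      return(NULL)
    }
    cand <- names(r)[ok]
    cand <- cand[order(-abs(r[cand]), cand)]
    win <- cand[1]
    data.frame(
      trait = tr, module = as.integer(sub("^ME", "", win)),
      r = unname(r[win]), p = unname(p[win])
    )
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    warning("no module passes the p-value cap; empty selection")
    return(list(modules = integer(), table = NULL))
  }
  tab <- do.call(rbind, rows)
  list(modules = sort(unique(tab$module)), table = tab)
}

## persist stage artifacts as flat files + JSON report
.writeRunArtifacts <- function(run, study, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (ty in c("mrna", "lncrna", "mirna")) {
    for (cn in names(run$de[[ty]])) {
      utils::write.table(run$de[[ty]][[cn]],
        file.path(outDir, sprintf("de_%s_%s.tsv", ty, cn)),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
  }
  utils::write.table(run$classes, file.path(outDir, "lnc_classes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  lb <- moduleLabels(run$modules)
  utils::write.table(
    data.frame(feature_id = names(lb), module = unname(lb)),
    file.path(outDir, "modules.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(run$eigengenes)) {
    utils::write.table(
      data.frame(module = rownames(run$eigengenes), run$eigengenes,
        check.names = FALSE
      ),
      file.path(outDir, "eigengenes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  if (!is.null(run$moduleTrait)) {
    utils::write.table(
      data.frame(
        module = rownames(run$moduleTrait$r), run$moduleTrait$r,
        check.names = FALSE
      ),
      file.path(outDir, "module_trait_r.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  utils::write.table(run$vip, file.path(outDir, "vip.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(run$pairs, file.path(outDir, "target_pairs.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(run$cis, file.path(outDir, "cis_links.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(run$trans, file.path(outDir, "trans_links.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(run$triplets, file.path(outDir, "triplets.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (nrow(run$triplets)) {
    writeNetworkFiles(run$triplets, file.path(outDir, "cerna"))
  }
  write_json(run$report, file.path(outDir, "report.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE
  )
  invisible(outDir)
}
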