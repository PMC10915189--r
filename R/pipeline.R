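## End-to-end orchestration: QC -> (PBLUP + ssGBLUP) REML -> GEBV ->
## ssGWAS -> thresholds/counts -> LD around the top region -> annotation
## and enrichment.  Every numeric output is deterministic given the
## config and seed.

.writeTableWithHeader <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the full single-step GWAS pipeline
#'
#' Either simulates a dataset (config entry `simulate`, passed to
#' [simConfig()]) or loads one from `paths` (pedigree/phenotypes CSVs and
#' PLINK text genotypes).  Applies the SNP QC filters, estimates variance
#' components by AI-REML under PBLUP and ssGBLUP, solves the ssGBLUP MME
#' for GEBVs, back-solves SNP effects with p-values, classifies against
#' the Bonferroni thresholds, reports LD around the most significant
#' marker, and (when gene/term files are configured) annotates significant
#' markers and runs hypergeometric enrichment.  Without genotypes the
#' pipeline runs PBLUP only and skips the GWAS stages with a notice.
#'
#' @param config list or YAML file path.  Recognised entries: `simulate`
#'   (list of [simConfig()] arguments), `paths` (pedigree, phenotypes,
#'   ped, map, genes, terms), `trait`, `fixed`, `qc` (call_rate, maf,
#'   hwe_p), `blend_w`, `reml` (tol, max_iter), `ld_window_bp`,
#'   `dprime_threshold`, `seed`.
#' @param outDir run directory (created).
#' @param seed overrides `config$seed` when given.
#' @return invisibly, a list with the main in-memory results and the
#'   output file paths.
#' @export
runPipeline <- function(config, outDir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (!is.null(seed)) config$seed <- seed
  seed <- config$seed %||% 1L
  trait <- config$trait %||% "trait"
  fixed <- config$fixed %||% c("hys", "sex")
  qc <- config$qc %||% list()
  blendW <- config$blend_w %||% 0.95
  remlOpts <- config$reml %||% list()
  ldWin <- config$ld_window_bp %||% 2e6
  dprTh <- config$dprime_threshold %||% 0.8

  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  logPath <- file.path(outDir, "run_log.txt")
  logCon <- file(logPath, "w")
  on.exit(close(logCon), add = TRUE)
  logMsg <- function(...) {
    msg <- paste0(...)
    writeLines(msg, logCon)
    message(msg)
  }
  stage <- function(name, expr) {
    logMsg("[stage] ", name)
    tryCatch(expr, error = function(e) {
      logMsg("[FAILED] ", name, ": ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  results <- list(outDir = outDir)

  ## ---- data ----
  dat <- stage("load_data", {
    if (!is.null(config$simulate)) {
      args <- config$simulate
      args$seed <- args$seed %||% seed
      cfg <- do.call(simConfig, args)
      simulateDataset(cfg)
    } else {
      p <- config$paths
      stopifnot(!is.null(p$pedigree), !is.null(p$phenotypes))
      ped <- readPedigree(p$pedigree)
      phen <- read.table(p$phenotypes, header = TRUE, sep = ",",
                         stringsAsFactors = FALSE)
      geno <- if (!is.null(p$ped) && !is.null(p$map))
        readPlinkText(p$ped, p$map) else NULL
      list(pedigree = ped, genotypes = geno, phenotypes = phen,
           truth = NULL)
    }
  })
  ped <- dat$pedigree
  phen <- dat$phenotypes
  geno <- dat$genotypes
  hasGeno <- !is.null(geno) && nAnimals(geno) > 0
  logMsg("animals: ", nAnimals(ped), "; phenotyped: ", nrow(phen),
         "; genotyped: ", if (hasGeno) nAnimals(geno) else 0)

  ## ---- QC ----
  qcHeader <- character()
  if (hasGeno) {
    qcRes <- stage("genotype_qc", qcFilter(
      geno,
      callRate = qc$call_rate %||% 0.90,
      maf = qc$maf %||% 0.01,
      hweP = qc$hwe_p %||% 1e-6))
    geno <- qcRes$genotypes
    rep <- qcRes$report
    qcHeader <- c(sprintf("qc call_rate=%g maf=%g hwe_p=%g",
                          rep$thresholds["call_rate"],
                          rep$thresholds["maf"], rep$thresholds["hwe_p"]),
                  sprintf("snps before=%d after=%d removed call_rate=%d maf=%d hwe=%d",
                          rep$n_snps_before, rep$n_snps_after,
                          rep$removed["call_rate"], rep$removed["maf"],
                          rep$removed["hwe"]))
    .writeTableWithHeader(
      data.frame(filter = names(rep$removed), removed = rep$removed),
      file.path(outDir, "qc_report.tsv"), qcHeader)
    results$qc <- rep
  }

  ## ---- kinship ----
  kin <- stage("pedigree_kinship", {
    F <- inbreeding(ped)
    Ainv <- aInverse(ped, F)
    list(F = F, Ainv = Ainv)
  })

  gblup <- NULL
  if (hasGeno) {
    gblup <- stage("genomic_matrices", {
      a22 <- a22Matrix(ped, animalIds(geno))
      vr <- vanRadenG(imputeMean(geno))
      bt <- blendTuneG(vr$G, a22$A22, blendW = blendW)
      gIdx <- match(animalIds(geno), animalIds(ped))
      Hinv <- hInverse(kin$Ainv, a22$A22inv, bt$GstarInv, gIdx)
      c(list(a22 = a22, Hinv = Hinv, gIdx = gIdx), vr, bt)
    })
  }

  ## ---- REML (PBLUP and ssGBLUP) ----
  des <- stage("build_design", buildDesign(phen, ped, trait = trait,
                                           fixed = fixed))
  tol <- remlOpts$tol %||% 1e-8
  maxIter <- remlOpts$max_iter %||% 200L
  vcP <- stage("reml_pblup",
               aiReml(des$y, des$X, des$Z, kin$Ainv, tol = tol,
                      maxIter = maxIter))
  vcRows <- data.frame(trait = trait, method = "PBLUP",
                       sigma_a2 = vcP@sigmaA2, sigma_e2 = vcP@sigmaE2,
                       sigma_p2 = vcP@sigmaA2 + vcP@sigmaE2,
                       h2 = round(vcP@h2, 2), se_h2 = round(vcP@seH2, 2),
                       converged = vcP@converged)
  vcS <- NULL
  if (hasGeno) {
    vcS <- stage("reml_ssgblup",
                 aiReml(des$y, des$X, des$Z, gblup$Hinv, tol = tol,
                        maxIter = maxIter))
    vcRows <- rbind(vcRows, data.frame(
      trait = trait, method = "ssGBLUP",
      sigma_a2 = vcS@sigmaA2, sigma_e2 = vcS@sigmaE2,
      sigma_p2 = vcS@sigmaA2 + vcS@sigmaE2,
      h2 = round(vcS@h2, 2), se_h2 = round(vcS@seH2, 2),
      converged = vcS@converged))
  }
  .writeTableWithHeader(vcRows, file.path(outDir, "variance_components.tsv"),
                        c(paste0("seed=", seed), qcHeader))
  results$varianceComponents <- vcRows

  if (!hasGeno) {
    logMsg("no genotypes supplied: GWAS, LD and annotation stages skipped")
    sol <- stage("solve_pblup", solveMME(des$y, des$X, des$Z, kin$Ainv,
                                         vcP@sigmaA2, vcP@sigmaE2))
    .writeTableWithHeader(
      data.frame(id = names(sol$a), ebv = unname(sol$a)),
      file.path(outDir, "gebv.tsv"), paste0("method=PBLUP seed=", seed))
    results$solution <- sol
    return(invisible(results))
  }

  ## ---- GEBV + ssGWAS ----
  sol <- stage("solve_ssgblup",
               solveMME(des$y, des$X, des$Z, gblup$Hinv,
                        vcS@sigmaA2, vcS@sigmaE2, pevIdx = gblup$gIdx))
  .writeTableWithHeader(
    data.frame(id = names(sol$a), gebv = unname(sol$a)),
    file.path(outDir, "gebv.tsv"),
    paste0("method=ssGBLUP seed=", seed))

  gwas <- stage("ssgwas", {
    aG <- sol$a[gblup$gIdx]
    bs <- backsolveSnpEffects(gblup$W, gblup$GstarInv, aG, gblup$k)
    tab <- snpEffectTable(bs, gblup$Gstar, sol$Caa, vcS@sigmaA2,
                          vcS@sigmaE2, markers(geno))
    th <- gwasThresholds(nrow(tab))
    cls <- classifyAndCount(tab, th)
    tab$class <- as.character(cls$class)
    list(table = tab, thresholds = th, counts = cls$counts)
  })
  thHeader <- sprintf("m=%d bonferroni=%.3g suggestive=%.3g",
                      gwas$thresholds$m, gwas$thresholds$bonferroni,
                      gwas$thresholds$suggestive)
  .writeTableWithHeader(gwas$table, file.path(outDir, "snp_effects.tsv"),
                        c(thHeader, qcHeader))
  .writeTableWithHeader(
    data.frame(class = names(gwas$counts), count = gwas$counts),
    file.path(outDir, "threshold_counts.tsv"), thHeader)
  mt <- manhattanTable(gwas$table, gwas$thresholds)
  .writeTableWithHeader(mt, file.path(outDir, "manhattan.tsv"),
                        c(thHeader,
                          sprintf("bonferroni_line=%.4f suggestive_line=%.4f",
                                  attr(mt, "bonferroni_line"),
                                  attr(mt, "suggestive_line"))))
  results$gwas <- gwas

  ## ---- LD around the top marker ----
  ldRep <- stage("ld_top_region", {
    top <- gwas$table[which.min(gwas$table$p_value), ]
    map <- markers(geno)
    sel <- map$chrom == top$chrom & abs(map$bp - top$bp) <= ldWin
    if (sum(sel) < 2) {
      logMsg("fewer than 2 markers within the LD window; skipping LD")
      NULL
    } else {
      ldRegionReport(geno, snpIds = map$snp_id[sel],
                     dprimeThreshold = dprTh)
    }
  })
  if (!is.null(ldRep)) {
    ldHeatmap(ldRep, file.path(outDir, "ld_region.tsv"))
    if (nrow(ldRep$runs))
      .writeTableWithHeader(ldRep$runs, file.path(outDir, "ld_runs.tsv"),
                            sprintf("dprime_threshold=%g", dprTh))
    results$ld <- ldRep
  }

  ## ---- annotation / enrichment ----
  p <- config$paths
  if (!is.null(p$genes)) {
    ann <- stage("annotate", {
      genes <- readGeneTable(p$genes)
      sig <- gwas$table[gwas$table$class != "ns", , drop = FALSE]
      if (!nrow(sig)) NULL else annotateSnps(sig, genes)
    })
    if (!is.null(ann)) {
      .writeTableWithHeader(ann, file.path(outDir, "annotation.tsv"),
                            thHeader)
      results$annotation <- ann
      if (!is.null(p$terms)) {
        enr <- stage("enrich", {
          terms <- read.table(p$terms, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
          glist <- unique(unlist(lapply(
            strsplit(ann$genes[!is.na(ann$genes)], ", "),
            function(x) sub(" \\(.*\\)$", "", x))))
          universe <- unique(terms$gene_id)
          glist <- intersect(glist, universe)
          if (!length(glist)) NULL
          else hypergeomEnrichment(glist, terms, universe)
        })
        if (!is.null(enr)) {
          .writeTableWithHeader(enr, file.path(outDir, "enrichment.tsv"),
                                "alpha=0.05 (raw p)")
          results$enrichment <- enr
        }
      }
    }
  }
  yaml::write_yaml(list(seed = seed, trait = trait, fixed = fixed,
                        qc = qc, blend_w = blendW,
                        thresholds = list(m = gwas$thresholds$m,
                                          bonferroni = gwas$thresholds$bonferroni,
                                          suggestive = gwas$thresholds$suggestive)),
                   file.path(outDir, "params.yaml"))
  logMsg("pipeline complete")
  invisible(results)
}
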