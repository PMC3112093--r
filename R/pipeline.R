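#' Build and validate a pipeline run configuration
#'
#' @param fixture packaged fixture name (default `"gsis69"`), or `NULL` with
#'   `fixtureDir` pointing at an on-disk fixture.
#' @param fixtureDir optional fixture directory overriding the packaged one.
#' @param hitTable optional path to a homology hit table; enables the
#'   shared-homologue cluster stage.
#' @param treeDir optional directory of per-gene NHX trees named
#'   `<abbrev>.nhx` (the focal leaf must be the file's gene abbreviation);
#'   enables the duplication stages.
#' @param outputDir directory for the JSON report and TSV tables
#'   (default `tempdir()`).
#' @param scheme ANOVA grouping scheme (default `"six_group"`).
#' @param alpha significance level in (0, 1) (default 0.05).
#' @param linkage dendrogram linkage (default `"complete"`).
#' @param evalueCutoff hit-table E-value cutoff (default 10).
#' @param gapOpening,gapExtension alignment penalties (defaults 10, 0.5).
#' @param threshold high-conservation threshold (default 99).
#' @param seed RNG seed fixing all stochastic stages (default 1).
#' @return validated config (class `RunConfig`).
#' @export
runConfig <- function(fixture = "gsis69", fixtureDir = NULL,
                      hitTable = NULL, treeDir = NULL,
                      outputDir = tempdir(), scheme = "six_group",
                      alpha = 0.05, linkage = "complete",
                      evalueCutoff = 10, gapOpening = 10,
                      gapExtension = 0.5, threshold = 99, seed = 1L) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  for (p in c(hitTable)) if (!is.null(p) && !file.exists(p))
    stop("no such file: ", p)
  for (p in c(fixtureDir, treeDir)) if (!is.null(p) && !dir.exists(p))
    stop("no such directory: ", p)
  structure(list(fixture = fixture, fixtureDir = fixtureDir,
                 hitTable = hitTable, treeDir = treeDir,
                 outputDir = outputDir, scheme = scheme, alpha = alpha,
                 linkage = linkage, evalueCutoff = evalueCutoff,
                 gapOpening = gapOpening, gapExtension = gapExtension,
                 threshold = threshold, seed = seed),
            class = "RunConfig")
}

skippedStage <- function(name, why) {
  warning("stage '", name, "' skipped: ", why, call. = FALSE)
  list(skipped = TRUE, reason = why)
}

#' Run the full evolutionary analysis end-to-end
#'
#' Executes, in order: conservation summary with quintile bins and
#' pathway-outlier detection; class composition and its goodness-of-fit
#' against the genome-wide reference; shared-homologue clusters (when a hit
#' table is configured); duplication vectors, dendrogram and per-group
#' (anti)clustering tests (when gene trees are configured); the pathway
#' divergence ANOVA with Tukey HSD; the divergence-duplication Spearman
#' correlation (when duplication counts are available); and the
#' disease-gene comparisons. Stages whose inputs are missing are reported as
#' skipped with a warning, never silently omitted. The report is written as
#' JSON plus per-stage TSV tables and the whole run is deterministic under
#' the configured seed.
#'
#' @param config a [runConfig()] object.
#' @return the report, invisibly (also written to
#'   `file.path(config$outputDir, "report.json")`).
#' @export
runFullAnalysis <- function(config = runConfig()) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  fx <- loadFixture(if (is.null(config$fixture)) "gsis69" else config$fixture,
                    dir = config$fixtureDir)
  recs <- records(fx)
  report <- list(schema_version = "1.0",
                 package_version = as.character(
                   utils::packageVersion("gsisEvol")),
                 parameters = unclass(config),
                 n_records = nrow(recs))
  logMsg("loaded fixture with ", nrow(recs), " records")

  ## conservation ----------------------------------------------------------
  cons <- conservationSummary(recs, threshold = config$threshold)
  bins <- quintileBins(recs)
  grouping5 <- assignAnovaGroups(recs, "five_group_figure3")
  outl <- withCallingHandlers(
    pathwayOutliers(recs, grouping5),
    warning = function(w) {
      logMsg("outliers: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  report$conservation <- list(summary = cons,
                              quintile_bins = as.list(bins),
                              outliers = outl)
  logMsg("conservation: mean ", round(cons$mean, 1), "%, ",
         nrow(outl), " outlier(s)")

  ## composition -----------------------------------------------------------
  comp <- classComposition(recs)
  ct <- compareComposition(stats::setNames(comp$count, comp$class),
                           referenceProportions(fx))
  report$composition <- list(counts = comp, test = ct)
  logMsg("composition chi2 = ", round(ct$chi2, 2), ", p = ",
         signif(ct$p, 3))

  ## shared-homologue clusters --------------------------------------------
  report$shared_homolog_clusters <- if (is.null(config$hitTable)) {
    skippedStage("shared_homolog_clusters", "no hit table configured")
  } else {
    tab <- readHitTable(config$hitTable, cutoff = config$evalueCutoff)
    profs <- buildHitProfiles(tab)
    cl <- sharedHomologClusters(profs)
    logMsg("shared-homologue clusters: ", length(cl), " component(s) from ",
           nrow(tab), " retained hits")
    list(skipped = FALSE, clusters = cl)
  }

  ## duplication -----------------------------------------------------------
  report$duplication <- if (is.null(config$treeDir)) {
    skippedStage("duplication", "no gene-tree directory configured")
  } else {
    files <- list.files(config$treeDir, pattern = "\\.nhx$",
                        full.names = TRUE)
    if (!length(files)) {
      skippedStage("duplication", "gene-tree directory holds no .nhx files")
    } else {
      hists <- lapply(files, function(f) {
        gene <- sub("\\.nhx$", "", basename(f))
        extractDuplicationVector(readGeneTree(f), gene)
      })
      dh <- combineHistories(hists)
      dm <- euclideanDistanceMatrix(dh)
      hc <- hierarchicalCluster(dm, linkage = config$linkage)
      memb <- assignAnovaGroups(
        recs[recs$abbrev %in% rownames(dm), , drop = FALSE], config$scheme)
      groups <- names(which(table(memb) >= 2))
      tests <- lapply(groups, function(g)
        groupClusteringTest(dm, memb, g, nGroupsTested = length(groups),
                            alpha = config$alpha))
      names(tests) <- groups
      recs$n_duplications[match(rownames(dm), recs$abbrev)] <-
        as.integer(rowSums(dupCounts(dh)))
      utils::write.table(
        data.frame(gene = rownames(dupCounts(dh)), dupCounts(dh),
                   check.names = FALSE),
        file.path(config$outputDir, "duplication_vectors.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      logMsg("duplication: ", nrow(dm), " genes, ", length(groups),
             " group test(s)")
      list(skipped = FALSE,
           n_genes = nrow(dm),
           zero_height_clusters = as.list(hc$clusters),
           dendrogram_newick = ape::write.tree(ape::as.phylo(hc$hclust)),
           group_tests = lapply(tests, function(tst) list(
             group = tst@group, n_within_pairs = tst@nWithinPairs,
             n_background_pairs = tst@nBackgroundPairs,
             u_statistic = tst@uStatistic, p_raw = tst@pRaw,
             p_bonferroni = tst@pBonferroni, direction = tst@direction)))
    }
  }

  ## ANOVA + Tukey ---------------------------------------------------------
  an <- divergenceAnova(recs, config$scheme)
  tk <- tukeyHsd(recs, config$scheme, alpha = config$alpha)
  an$fit <- NULL
  an$group_means <- as.list(an$group_means)
  report$anova <- an
  report$tukey <- tk
  logMsg("ANOVA F = ", round(an$f_statistic, 2), " (df ", an$df_between,
         "), p = ", signif(an$p, 3))

  ## correlation -----------------------------------------------------------
  hasDup <- is.finite(recs$n_duplications)
  report$correlation <- if (sum(hasDup) < 3) {
    skippedStage("correlation", "no duplication counts available")
  } else {
    sc <- spearmanCorrelation(recs$hm_similarity[hasDup],
                              recs$n_duplications[hasDup])
    logMsg("Spearman rho = ", round(sc$rho, 3), ", p = ",
           signif(sc$p_two_tailed, 3))
    c(list(skipped = FALSE), sc)
  }

  ## disease ---------------------------------------------------------------
  dis <- diseaseComparisons(recs)
  dis$possel_table <- as.data.frame(dis$possel_table)
  report$disease <- dis
  logMsg("disease: ", dis$n_disease, " genes, t-test p = ",
         signif(dis$t_p, 3))

  ## write -----------------------------------------------------------------
  utils::write.table(
    data.frame(protein = names(bins), quintile = unname(bins)),
    file.path(config$outputDir, "quintile_bins.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(outl,
    file.path(config$outputDir, "pathway_outliers.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tk, file.path(config$outputDir, "tukey.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report,
                       file.path(config$outputDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  logMsg("report written to ", file.path(config$outputDir, "report.json"))
  invisible(report)
}
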