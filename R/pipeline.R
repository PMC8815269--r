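# End-to-end orchestration of the screen: risk genes -> per-gene drug
# lists -> co-occurrence merge -> FDA/CNS filter -> drug-set enrichment ->
# viability validation.

#' Build a screen configuration
#'
#' @param collection A [GeneSetCollection] or GMT file path.
#' @param profiles A [RankedProfiles] or rank-matrix TSV path.
#' @param viability A [ViabilityExperiment] or viability CSV path
#'   (may be \code{NULL} to skip the validation stages).
#' @param riskGenes Character vector of risk gene ids.
#' @param reference Reference treatment id.
#' @param alphaList Per-gene list threshold (default 1e-2).
#' @param cutoff Co-occurrence cut-off (default 4).
#' @param alphaScreen Screen significance threshold (default 1e-3).
#' @param nPerm Permutations for empirical p-values (default 999).
#' @param seed Integer seed.
#' @param outDir Optional output directory for stage artifacts.
#' @return A [ScreenConfig].
#' @export
screenConfig <- function(collection, profiles, viability = NULL,
                         riskGenes, reference = "TMZ", alphaList = 1e-2,
                         cutoff = 4, alphaScreen = 1e-3, nPerm = 999,
                         seed = 1, outDir = NA_character_) {
  new("ScreenConfig", collection = collection, profiles = profiles,
    viability = viability, riskGenes = as.character(riskGenes),
    reference = as.character(reference), alphaList = alphaList,
    cutoff = cutoff, alphaScreen = alphaScreen, nPerm = nPerm,
    seed = seed, outDir = outDir)
}

resolveInput <- function(x, reader, what) {
  if (is.character(x)) {
    if (!file.exists(x))
      stop("missing input (", what, "): ", x, call. = FALSE)
    return(reader(x))
  }
  x
}

#' Run the full in-silico screen
#'
#' Executes the stages in order: pathway annotation lookup per risk gene,
#' pathway-profile computation and replicate aggregation, per-gene drug
#' ranking, significance filtering, co-occurrence merge, FDA/CNS filter,
#' drug-set enrichment of the kept drugs, replicate concordance filter,
#' mean-sensitivity ranking with Mann-Whitney tests against the
#' reference, and the direct screening protocol. Inputs are validated
#' before any stage runs; with \code{outDir} set, every stage's output is
#' persisted as TSV/JSON together with a manifest recording the
#' configuration, seed and file checksums (re-running an identical
#' configuration reproduces byte-identical outputs).
#'
#' Risk genes with no pathway annotation are skipped with a message (a
#' GWAS gene list typically only partially maps into a pathway corpus).
#'
#' @param config A [ScreenConfig].
#' @return A list of class \code{"ScreenReport"}: \code{geneLists}
#'   (per-risk-gene drug lists), \code{significant} (after the alpha
#'   filter), \code{candidates} ([MergedCandidates]),
#'   \code{keptApprovedCns}, \code{dsea} (table or \code{NULL}),
#'   \code{concordance}, \code{ranking}, \code{directScreen},
#'   \code{manifest}.
#' @export
runScreen <- function(config) {
  stopifnot(is(config, "ScreenConfig"))
  # pre-flight: resolve and validate every input before any stage runs
  gsc <- resolveInput(config@collection, readGmt, "collection")
  profiles <- resolveInput(config@profiles, readRankMatrix, "profiles")
  vm <- if (!is.null(config@viability))
    resolveInput(config@viability, readViabilityTable, "viability")
  else NULL
  if (!is(gsc, "GeneSetCollection")) stop("invalid collection input",
    call. = FALSE)
  if (!is(profiles, "RankedProfiles")) stop("invalid profiles input",
    call. = FALSE)
  if (!is.null(vm) && !is(vm, "ViabilityExperiment"))
    stop("invalid viability input", call. = FALSE)

  seed <- as.integer(config@seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE))
  }

  gsc <- stage("bind_universe",
    suppressWarnings(bindUniverseQuiet(gsc, geneUniverse(profiles))))
  pep <- stage("pep", computePeps(profiles, gsc, nPerm = 0, seed = seed))
  pepDrug <- stage("aggregate", aggregateReplicates(pep))

  # per-risk-gene drug lists
  geneLists <- list()
  for (g in config@riskGenes) {
    query <- intersect(pathwaysOfGene(gsc, g), pathwayIds(pepDrug))
    if (!length(query)) {
      message("risk gene without pathway annotation, skipped: ", g)
      next
    }
    geneLists[[g]] <- stage(paste0("gene2drug:", g),
      rankDrugsForPathwaySet(pepDrug, query, nPerm = config@nPerm,
        seed = subSeed(seed, 7L + match(g, config@riskGenes)),
        geneId = g))
  }
  if (!length(geneLists))
    stop("no risk gene maps to any pathway of the collection",
      call. = FALSE)

  significant <- stage("filter_significant",
    lapply(geneLists, filterSignificant, alpha = config@alphaList))
  candidates <- stage("merge",
    cooccurrenceMerge(significant, cutoff = config@cutoff))
  keptApproved <- if (!is.null(vm))
    stage("fda_cns", filterFdaCns(candidates, treatmentMeta(vm)))
  else keptDrugs(candidates)

  dsea <- NULL
  drugSet <- intersect(keptApproved, drugIds(pepDrug))
  if (length(drugSet) && length(drugSet) < length(drugIds(pepDrug)))
    dsea <- stage("dsea", dseaTable(pepDrug, drugSet,
      nPerm = config@nPerm, seed = subSeed(seed, 3L)))

  concordance <- NULL; ranking <- NULL; screen <- NULL
  if (!is.null(vm)) {
    concordance <- stage("concordance", replicateConcordanceFilter(vm))
    validated <- setdiff(intersect(keptApproved, treatmentIds(vm)),
      concordance$excluded)
    if (length(validated))
      ranking <- stage("ranking", meanSensitivityRanking(vm,
        treatments = validated, reference = config@reference))
    screen <- stage("direct_screen", directScreen(vm,
      reference = config@reference, alpha = config@alphaScreen))
  }

  report <- structure(list(geneLists = geneLists,
    significant = significant, candidates = candidates,
    keptApprovedCns = keptApproved, dsea = dsea,
    concordance = concordance, ranking = ranking, directScreen = screen,
    config = config, manifest = NULL), class = "ScreenReport")
  if (!is.na(config@outDir))
    report$manifest <- writeScreenReport(report, config@outDir)
  report
}

#' @export
print.ScreenReport <- function(x, ...) {
  cat("In-silico screen report\n")
  cat(sprintf("  per-gene lists: %d (risk genes mapped)\n",
    length(x$geneLists)))
  show(x$candidates)
  cat(sprintf("  FDA-approved + CNS-active kept: %d (%s)\n",
    length(x$keptApprovedCns),
    paste(utils::head(x$keptApprovedCns, 8), collapse = ", ")))
  if (!is.null(x$dsea))
    cat(sprintf("  drug-set enrichment: %d pathway(s), %d at p < 0.05\n",
      nrow(x$dsea), sum(x$dsea$p_value < 0.05, na.rm = TRUE)))
  if (!is.null(x$directScreen)) print(x$directScreen)
  invisible(x)
}

# Persist every stage output and return the manifest.
writeScreenReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wrote <- character()
  put <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
      row.names = FALSE)
    wrote <<- c(wrote, path)
  }
  put(do.call(rbind, report$geneLists), "gene_lists.tsv")
  put(do.call(rbind, report$significant), "gene_lists_significant.tsv")
  writeCandidateTable(report$candidates,
    file.path(dir, "candidates.tsv"))
  wrote <- c(wrote, file.path(dir, "candidates.tsv"))
  put(data.frame(drug_id = report$keptApprovedCns), "kept_approved_cns.tsv")
  if (!is.null(report$dsea)) put(report$dsea, "dsea.tsv")
  if (!is.null(report$ranking)) put(report$ranking, "ranking.tsv")
  if (!is.null(report$directScreen)) {
    put(report$directScreen$summaries, "direct_screen.tsv")
    s <- report$directScreen
    jsonlite::write_json(list(reference = s$reference,
      n_treatments = s$n_treatments, n_higher_mean = s$n_higher_mean,
      frac_higher = s$frac_higher, n_significant = s$n_significant,
      frac_significant = s$frac_significant, alpha = s$alpha),
      file.path(dir, "direct_screen.json"), auto_unbox = TRUE,
      digits = NA)
    wrote <- c(wrote, file.path(dir, "direct_screen.json"))
  }
  cfg <- report$config
  manifest <- list(
    config = list(riskGenes = cfg@riskGenes, reference = cfg@reference,
      alphaList = cfg@alphaList, cutoff = cfg@cutoff,
      alphaScreen = cfg@alphaScreen, nPerm = cfg@nPerm,
      seed = cfg@seed),
    files = as.list(stats::setNames(unname(tools::md5sum(wrote)),
      basename(wrote))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA)
  manifest
}
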