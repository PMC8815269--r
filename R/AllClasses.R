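#' @import methods
NULL

#' Gene set collection
#'
#' A named collection of flat gene sets (GO/KEGG-style biological processes
#' or pathways), optionally bound to a gene universe. The universe is the
#' ordered gene dimension of a perturbagen profile corpus; when a collection
#' is bound to one, set members outside the universe are dropped (platform
#' coverage is always partial) and empty sets are removed.
#'
#' @slot sets Named list; each element a character vector of unique member
#'   gene identifiers. Names are the set ids.
#' @slot info \code{data.frame} with one row per set: \code{id},
#'   \code{name} (free-text description) and \code{source} (\code{"GO"},
#'   \code{"KEGG"} or \code{"other"}).
#' @slot universe Character vector of gene identifiers the collection is
#'   bound to; \code{character(0)} when unbound.
#'
#' @seealso [readGmt()], [bindUniverse()], [pathwaysOfGene()]
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
  slots = c(sets = "list", info = "data.frame", universe = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  ids <- names(object@sets)
  if (length(object@sets) > 0 && (is.null(ids) || anyDuplicated(ids)))
    msg <- c(msg, "set ids must be present and unique")
  if (any(!vapply(object@sets, is.character, logical(1))))
    msg <- c(msg, "set members must be character vectors")
  if (any(vapply(object@sets, length, integer(1)) == 0L))
    msg <- c(msg, "gene sets must be non-empty")
  if (any(vapply(object@sets, anyDuplicated, integer(1)) > 0L))
    msg <- c(msg, "gene sets must not contain duplicate members")
  if (!identical(sort(colnames(object@info)), sort(c("id", "name", "source"))))
    msg <- c(msg, "info must have columns id, name, source")
  if (nrow(object@info) != length(object@sets) ||
      (length(ids) && !identical(object@info$id, ids)))
    msg <- c(msg, "info rows must match sets (same ids, same order)")
  if (length(object@universe)) {
    if (anyDuplicated(object@universe))
      msg <- c(msg, "universe identifiers must be unique")
    out <- vapply(object@sets,
      function(s) any(!(s %in% object@universe)), logical(1))
    if (any(out))
      msg <- c(msg, "all set members must belong to the bound universe")
  }
  if (length(msg)) msg else TRUE
})

#' Ranked perturbagen profiles
#'
#' A Connectivity-Map-like corpus: one total ranking of the gene universe
#' per treatment instance (drug x replicate). Rank 1 is the most
#' up-regulated gene under the treatment.
#'
#' @slot ranks Integer matrix, genes x instances; each column is a
#'   permutation of \code{1..n}. Row names are the gene universe (canonical
#'   order), column names the instance ids (\code{"drug::replicate"}).
#' @slot drug Character vector, drug id per column.
#' @slot replicate Character vector, replicate id per column.
#'
#' @seealso [readRankMatrix()], [computePeps()]
#' @exportClass RankedProfiles
setClass("RankedProfiles",
  slots = c(ranks = "matrix", drug = "character", replicate = "character"))

setValidity("RankedProfiles", function(object) {
  msg <- character()
  r <- object@ranks
  if (!is.integer(r)) msg <- c(msg, "ranks must be an integer matrix")
  if (is.null(rownames(r)) || anyDuplicated(rownames(r)))
    msg <- c(msg, "ranks must have unique gene row names")
  if (nrow(r) == 0L) msg <- c(msg, "gene universe must be non-empty")
  n <- nrow(r)
  if (is.integer(r) && ncol(r) > 0) {
    ok <- apply(r, 2L, function(col) !anyNA(col) &&
      identical(sort.int(as.integer(col)), seq_len(n)))
    if (!all(ok))
      msg <- c(msg, sprintf("column(s) %s are not permutations of 1..n",
        paste(which(!ok), collapse = ", ")))
  }
  if (length(object@drug) != ncol(r) || length(object@replicate) != ncol(r))
    msg <- c(msg, "drug and replicate must have one entry per column")
  if (length(msg)) msg else TRUE
})

#' Pathway expression profiles (PEPs)
#'
#' Pathway-level view of a profile corpus: per treatment instance (or per
#' drug, after replicate aggregation) an enrichment score, an optional
#' empirical p-value and a pathway rank for every pathway of a collection.
#' Pathway rank 1 is the most up-regulated pathway.
#'
#' @slot es Numeric matrix, pathways x columns, of KS running-sum
#'   enrichment scores in \code{[-1, 1]}.
#' @slot pval Numeric matrix of empirical p-values (all \code{NA} when
#'   computed without permutations or after aggregation).
#' @slot ranks Integer matrix; each column a permutation of \code{1..P},
#'   ordered by descending enrichment score with ties broken by pathway id.
#' @slot drug Character, drug id per column.
#' @slot replicate Character, replicate id per column; \code{NA} for
#'   drug-level (aggregated) profiles.
#'
#' @seealso [computePeps()], [aggregateReplicates()],
#'   [rankDrugsForPathwaySet()], [dseaTable()]
#' @exportClass PathwayProfiles
setClass("PathwayProfiles",
  slots = c(es = "matrix", pval = "matrix", ranks = "matrix",
            drug = "character", replicate = "character"))

setValidity("PathwayProfiles", function(object) {
  msg <- character()
  d <- dim(object@es)
  if (!identical(dim(object@pval), d) || !identical(dim(object@ranks), d))
    msg <- c(msg, "es, pval and ranks must share dimensions")
  if (is.null(rownames(object@es)) || anyDuplicated(rownames(object@es)))
    msg <- c(msg, "pathway row names must be present and unique")
  if (any(abs(object@es) > 1, na.rm = TRUE))
    msg <- c(msg, "enrichment scores must lie in [-1, 1]")
  P <- d[1L]
  if (P > 0 && d[2L] > 0) {
    ok <- apply(object@ranks, 2L, function(col)
      identical(sort.int(as.integer(col)), seq_len(P)))
    if (!all(ok)) msg <- c(msg, "each rank column must be a permutation of 1..P")
  }
  if (length(object@drug) != d[2L] || length(object@replicate) != d[2L])
    msg <- c(msg, "drug and replicate must have one entry per column")
  if (length(msg)) msg else TRUE
})

#' Viability screen experiment
#'
#' Long-format sensitivities from a pooled-barcode viability screen
#' (PRISM-style), plus treatment and cell-line annotations. Sensitivity is
#' stored so that higher values mean greater viability reduction (more
#' killing); PRISM-style viability log-fold-changes are negated at ingest.
#' Repeated screening of one treatment under distinct
#' \code{screen_dataset_id}s is retained as separate replicate series.
#'
#' @slot data \code{data.frame} with columns \code{treatment_id},
#'   \code{cell_line}, \code{screen_dataset_id}, \code{sensitivity}; at
#'   most one row per (treatment, cell line, dataset) triple, all values
#'   finite. Missing cells are simply absent rows.
#' @slot treatments \code{data.frame}: \code{treatment_id}, \code{name},
#'   \code{fda_approved}, \code{cns_active}.
#' @slot mutations Logical matrix, cell lines x genes (may have 0 columns).
#' @slot expression Numeric matrix, genes x cell lines (may be empty).
#'
#' @seealso [readViabilityTable()], [directScreen()],
#'   [meanSensitivityRanking()]
#' @exportClass ViabilityExperiment
setClass("ViabilityExperiment",
  slots = c(data = "data.frame", treatments = "data.frame",
            mutations = "matrix", expression = "matrix"))

setValidity("ViabilityExperiment", function(object) {
  msg <- character()
  need <- c("treatment_id", "cell_line", "screen_dataset_id", "sensitivity")
  if (!all(need %in% colnames(object@data)))
    msg <- c(msg, paste("data must have columns",
      paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@data[, need[1:3]]))
      msg <- c(msg,
        "at most one entry per (treatment, cell line, dataset) triple")
    if (any(!is.finite(object@data$sensitivity)))
      msg <- c(msg, "sensitivities must be finite")
  }
  tn <- c("treatment_id", "name", "fda_approved", "cns_active")
  if (!all(tn %in% colnames(object@treatments)))
    msg <- c(msg, paste("treatments must have columns",
      paste(tn, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Merged candidate drugs from per-gene lists
#'
#' Result of the co-occurrence merge: for each drug, the number of
#' per-risk-gene candidate lists containing it, its best (minimum) p-value
#' across those lists, and the drugs kept at the co-occurrence cut-off,
#' ordered by descending count, then ascending best p, then drug id.
#'
#' @slot counts Named integer vector (drug -> number of lists; all >= 1).
#' @slot minP Named numeric vector (drug -> minimum p across lists).
#' @slot kept Character vector of drug ids passing the cut-off, ordered.
#' @slot cutoff The co-occurrence cut-off used (count >= cutoff is kept).
#'
#' @seealso [cooccurrenceMerge()], [filterFdaCns()]
#' @exportClass MergedCandidates
setClass("MergedCandidates",
  slots = c(counts = "integer", minP = "numeric", kept = "character",
            cutoff = "numeric"))

setValidity("MergedCandidates", function(object) {
  msg <- character()
  if (length(object@counts) && any(object@counts < 1L))
    msg <- c(msg, "co-occurrence counts must be >= 1")
  if (!identical(names(object@counts), names(object@minP)))
    msg <- c(msg, "counts and minP must be named identically")
  if (any(!(object@kept %in% names(object@counts))))
    msg <- c(msg, "kept drugs must appear in counts")
  if (length(msg)) msg else TRUE
})

#' Screen configuration
#'
#' Bundles the inputs and tuning parameters of the end-to-end screen
#' (see [runScreen()]). Inputs may be in-memory objects or file paths
#' understood by the package readers.
#'
#' @slot collection A [GeneSetCollection] or a GMT file path.
#' @slot profiles A [RankedProfiles] or a rank-matrix TSV path.
#' @slot viability A [ViabilityExperiment] or a viability CSV path.
#' @slot riskGenes Character vector of risk gene identifiers.
#' @slot reference Reference treatment id (e.g. the standard-of-care drug).
#' @slot alphaList Per-gene drug list significance threshold (default 1e-2).
#' @slot cutoff Co-occurrence cut-off (default 4; count >= cutoff kept).
#' @slot alphaScreen Viability screen significance threshold (default 1e-3).
#' @slot nPerm Number of permutations for empirical p-values (default 999).
#' @slot seed Integer seed controlling every random draw.
#' @slot outDir Output directory for stage artifacts, or \code{NA}.
#'
#' @seealso [screenConfig()], [runScreen()]
#' @exportClass ScreenConfig
setClass("ScreenConfig",
  slots = c(collection = "ANY", profiles = "ANY", viability = "ANY",
            riskGenes = "character", reference = "character",
            alphaList = "numeric", cutoff = "numeric",
            alphaScreen = "numeric", nPerm = "numeric", seed = "numeric",
            outDir = "character"))

setValidity("ScreenConfig", function(object) {
  msg <- character()
  if (!length(object@riskGenes)) msg <- c(msg, "riskGenes must be non-empty")
  if (length(object@reference) != 1L)
    msg <- c(msg, "reference must be a single treatment id")
  for (s in c("alphaList", "alphaScreen")) {
    v <- slot(object, s)
    if (length(v) != 1L || v <= 0 || v >= 1)
      msg <- c(msg, paste(s, "must lie in (0, 1)"))
  }
  if (object@cutoff < 1) msg <- c(msg, "cutoff must be >= 1")
  if (object@nPerm < 0) msg <- c(msg, "nPerm must be >= 0")
  if (length(msg)) msg else TRUE
})
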