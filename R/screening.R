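# Candidate selection: significance filter, co-occurrence merge across
# per-risk-gene drug lists, and the FDA/CNS annotation filter.

#' Filter a drug list by significance
#'
#' Retains entries with \eqn{p < \alpha} (strict, matching the screen's
#' inclusion rule "p below 1e-2"), preserving order.
#'
#' @param drugList A drug list \code{data.frame} from
#'   [rankDrugsForPathwaySet()] (needs a \code{p} column with no missing
#'   values).
#' @param alpha Significance threshold; default \code{1e-2}.
#' @return The filtered \code{data.frame} (possibly 0 rows).
#' @export
filterSignificant <- function(drugList, alpha = 1e-2) {
  if (!"p" %in% colnames(drugList) || anyNA(drugList$p))
    stop("drug list entries must carry p-values", call. = FALSE)
  alpha <- stopIfNot1(alpha, "alpha")
  drugList[drugList$p < alpha, , drop = FALSE]
}

#' Merge per-gene drug lists by co-occurrence
#'
#' Counts, for every drug, the number of distinct per-risk-gene lists
#' containing it, and keeps drugs found in at least \code{cutoff} lists.
#' Kept drugs are ordered by descending count, then ascending best
#' (minimum) p-value across lists, then drug id. Duplicate drugs within
#' one list count once; the result is invariant to list order.
#'
#' @param lists List of drug lists: \code{data.frame}s with a
#'   \code{drug_id} column (and optionally \code{p}), or plain character
#'   vectors of drug ids.
#' @param cutoff Minimum number of lists (co-occurrence cut-off); the
#'   default 4 is the median of the co-occurrence range observed on the
#'   motivating corpus.
#' @return A [MergedCandidates].
#' @export
cooccurrenceMerge <- function(lists, cutoff = 4) {
  if (!length(lists)) stop("need at least one drug list", call. = FALSE)
  cutoff <- stopIfNot1(cutoff, "cutoff")
  if (cutoff < 1) stop("cutoff must be >= 1", call. = FALSE)
  asDf <- function(x) {
    if (is.character(x))
      return(data.frame(drug_id = x, p = NA_real_, stringsAsFactors = FALSE))
    if (!"p" %in% colnames(x)) x$p <- NA_real_
    x[, c("drug_id", "p"), drop = FALSE]
  }
  dfs <- lapply(lists, asDf)
  perList <- lapply(dfs, function(d) unique(d$drug_id))
  counts <- table(unlist(perList))
  drugs <- as.character(sort(names(counts)))  # empty lists -> no drugs
  counts <- as.integer(counts[drugs])
  names(counts) <- drugs
  allP <- do.call(rbind, dfs)
  minP <- vapply(drugs, function(d) {
    p <- allP$p[allP$drug_id == d]
    if (all(is.na(p))) NA_real_ else min(p, na.rm = TRUE)
  }, numeric(1))
  keep <- counts >= cutoff
  kept <- drugs[keep]
  ord <- order(-counts[keep], minP[keep], kept)
  new("MergedCandidates", counts = counts, minP = minP,
    kept = kept[ord], cutoff = as.numeric(cutoff))
}

#' Co-occurrence histogram
#'
#' Tabulates how many drugs co-exist in how many lists (a text-format
#' Venn-style summary of the merge).
#'
#' @param candidates A [MergedCandidates].
#' @return A \code{data.frame} with columns \code{n_lists} and
#'   \code{n_drugs}, descending by \code{n_lists}.
#' @export
cooccurrenceHistogram <- function(candidates) {
  stopifnot(is(candidates, "MergedCandidates"))
  h <- table(candidates@counts)
  data.frame(n_lists = as.integer(rev(names(h))),
    n_drugs = as.integer(rev(h)), row.names = NULL)
}

#' Filter merged candidates to FDA-approved, CNS-active drugs
#'
#' The last selection step of the screen: of the kept drugs, retain those
#' annotated as FDA approved with known central-nervous-system activity
#' (the treatment notes of a PRISM-style screen). Drugs absent from the
#' annotation are treated as not approved / not CNS active. Order is
#' preserved.
#'
#' @param candidates A [MergedCandidates].
#' @param meta Treatment annotation \code{data.frame} with columns
#'   \code{treatment_id}, \code{fda_approved}, \code{cns_active} (e.g.
#'   [treatmentMeta()] of a [ViabilityExperiment]).
#' @return Character vector of drug ids, in the candidates' kept order.
#' @export
filterFdaCns <- function(candidates, meta) {
  stopifnot(is(candidates, "MergedCandidates"))
  kept <- candidates@kept
  if (!length(kept)) return(character())
  if (is(meta, "ViabilityExperiment")) meta <- treatmentMeta(meta)
  i <- match(kept, meta$treatment_id)
  ok <- !is.na(i) & meta$fda_approved[i] %in% TRUE &
    meta$cns_active[i] %in% TRUE
  kept[ok]
}

#' Write the merged-candidate summary as TSV
#'
#' One row per counted drug: co-occurrence count, best p, whether it
#' passed the cut-off, and (optionally) the FDA/CNS flag.
#'
#' @param candidates A [MergedCandidates].
#' @param path Output TSV path.
#' @param meta Optional treatment annotation (see [filterFdaCns()]).
#' @return \code{path}, invisibly.
#' @export
writeCandidateTable <- function(candidates, path, meta = NULL) {
  drugs <- names(candidates@counts)
  approved <- rep(NA, length(drugs))
  if (!is.null(meta)) {
    if (is(meta, "ViabilityExperiment")) meta <- treatmentMeta(meta)
    i <- match(drugs, meta$treatment_id)
    approved <- !is.na(i) & meta$fda_approved[i] %in% TRUE &
      meta$cns_active[i] %in% TRUE
  }
  out <- data.frame(drug_id = drugs, n_lists = candidates@counts,
    min_p = candidates@minP,
    kept_flag = drugs %in% candidates@kept,
    approved_cns_flag = approved, stringsAsFactors = FALSE)
  out <- out[order(-out$n_lists, out$min_p, out$drug_id), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}
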