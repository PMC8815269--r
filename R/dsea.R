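# Drug-set enrichment analysis: map a candidate drug set back to the
# pathways it collectively up-/down-regulates.

#' Drug-set enrichment score (E-score) for one pathway
#'
#' For a given pathway, all \eqn{D} profiled drugs are ranked by their
#' pathway enrichment score (descending, ties broken by drug id); the
#' E-score is the KS running-sum statistic of the candidate set's
#' positions inside that ranking (universe size \eqn{D}), so it lies in
#' \eqn{[-1, +1]}: positive = the pathway is up-regulated by the drug set,
#' negative = down-regulated. The empirical p-value (two-sided, +1
#' correction) compares \eqn{|E|} against random drug sets of equal size
#' drawn with a seeded generator.
#'
#' @param pep A drug-level [PathwayProfiles] covering all profiled drugs.
#' @param drugSet Character vector of candidate drug ids (non-empty,
#'   strict subset of the profiled drugs).
#' @param pathway A single pathway id present in the profiles.
#' @param nPerm Permutations for the empirical p-value.
#' @param seed Integer seed.
#' @return A one-row \code{data.frame}: \code{pathway_id},
#'   \code{e_score}, \code{p_value}, \code{set_size}.
#' @export
dseaEscore <- function(pep, drugSet, pathway, nPerm = 999, seed = 1) {
  dseaCheck(pep, drugSet)
  pathway <- stopIfNot1(as.character(pathway), "pathway")
  if (!pathway %in% rownames(pep@es))
    stop("pathway not in the profiles: ", pathway, call. = FALSE)
  D <- ncol(pep@es)
  t <- length(unique(drugSet))
  nulls <- if (nPerm > 0) ksNullTable(t, D, nPerm, seed) else NULL
  r <- dseaOne(pep, unique(drugSet), pathway, D)
  p <- if (is.null(nulls)) NA_real_ else
    empiricalP(r, nulls[[as.character(t)]])
  data.frame(pathway_id = pathway, e_score = r, p_value = p, set_size = t,
    stringsAsFactors = FALSE)
}

dseaCheck <- function(pep, drugSet) {
  stopifnot(is(pep, "PathwayProfiles"))
  if (anyDuplicated(pep@drug))
    stop("pep must be drug-level; run aggregateReplicates() first",
      call. = FALSE)
  drugSet <- unique(as.character(drugSet))
  if (!length(drugSet)) stop("drug set must be non-empty", call. = FALSE)
  miss <- setdiff(drugSet, pep@drug)
  if (length(miss)) stop("drug(s) not profiled: ",
    paste(miss, collapse = ", "), call. = FALSE)
  if (length(drugSet) >= length(pep@drug))
    stop("drug set covering all profiled drugs is degenerate",
      call. = FALSE)
  invisible(TRUE)
}

# Positions of the drug set in the pathway's drug ranking, then KS.
dseaOne <- function(pep, drugSet, pathway, D) {
  drugRank <- permutationRank(-pep@es[pathway, ], pep@drug)
  ksStatistic(drugRank[match(drugSet, pep@drug)], D)
}

#' Drug-set enrichment over all pathways
#'
#' Runs [dseaEscore()] for every pathway of the profiles and returns the
#' table sorted by ascending p-value, then descending \eqn{|E|}, then
#' pathway id — the "downstream pathways shared by the candidate drugs".
#'
#' @inheritParams dseaEscore
#' @return A \code{data.frame}: \code{pathway_id}, \code{e_score},
#'   \code{p_value}.
#' @export
dseaTable <- function(pep, drugSet, nPerm = 999, seed = 1) {
  dseaCheck(pep, drugSet)
  drugSet <- unique(as.character(drugSet))
  D <- ncol(pep@es)
  t <- length(drugSet)
  nulls <- if (nPerm > 0) ksNullTable(t, D, nPerm, seed) else NULL
  ids <- rownames(pep@es)
  e <- vapply(ids, function(pw) dseaOne(pep, drugSet, pw, D), numeric(1))
  p <- if (is.null(nulls)) rep(NA_real_, length(e)) else
    vapply(e, empiricalP, numeric(1), nullEs = nulls[[as.character(t)]])
  out <- data.frame(pathway_id = ids, e_score = e, p_value = p,
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p_value, -abs(out$e_score), out$pathway_id), , drop = FALSE]
}
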