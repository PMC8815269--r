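# Pathway expression profiles: KS enrichment of pathway members inside a
# gene ranking, replicate aggregation, and second-level drug ranking for a
# query pathway set.

# Shared core: es (and optional empirical p) for every set of a bound
# collection against one ranking vector.
pepOneProfile <- function(ranking, sets, n, nulls = NULL) {
  es <- vapply(sets, function(members)
    ksStatistic(unname(ranking[members]), n), numeric(1))
  p <- rep(NA_real_, length(es))
  if (!is.null(nulls)) {
    sizes <- vapply(sets, length, integer(1))
    p <- vapply(seq_along(es), function(i)
      empiricalP(es[i], nulls[[as.character(sizes[i])]]), numeric(1))
  }
  list(es = es, p = p)
}

#' Convert one ranked profile to a pathway expression profile
#'
#' For every pathway of a bound collection, computes the KS running-sum
#' enrichment of the pathway members' positions inside the gene ranking
#' ([ksStatistic()]), an empirical permutation p-value, and a pathway rank
#' (1 = most up-regulated pathway, descending enrichment score, ties broken
#' by pathway id). The empirical p-value compares \eqn{|es|} against
#' \eqn{n_{perm}} random same-size gene sets with the +1 correction,
#' \eqn{p = (1 + \#\{|es_{rand}| \ge |es|\}) / (n_{perm} + 1)}; with
#' \code{nPerm = 0} p-values are absent. Pathways with no in-universe
#' member are skipped with a warning (via [bindUniverse()]).
#'
#' @param ranking Named integer vector: a permutation of \code{1..n} over
#'   the gene universe (rank 1 = most up-regulated), or a single-instance
#'   [RankedProfiles].
#' @param gsc A [GeneSetCollection]; bound to the ranking's universe
#'   (binding is performed here if needed).
#' @param nPerm Number of random same-size sets for the empirical p-value.
#' @param seed Integer seed for the permutation null.
#' @return A \code{data.frame}: \code{pathway_id}, \code{es}, \code{p}
#'   (\code{NA} when \code{nPerm = 0}), \code{rank}, \code{set_size}.
#' @export
profileToPep <- function(ranking, gsc, nPerm = 0, seed = 1) {
  if (is(ranking, "RankedProfiles")) {
    if (ncol(rankMatrix(ranking)) != 1L)
      stop("use computePeps() for multi-instance profiles", call. = FALSE)
    ranking <- rankMatrix(ranking)[, 1L]
  }
  if (is.null(names(ranking))) stop("ranking must be named", call. = FALSE)
  n <- length(ranking)
  gsc <- bindUniverseQuiet(gsc, names(ranking))
  if (!length(gsc@sets)) stop("no pathway with in-universe members",
    call. = FALSE)
  sets <- gsc@sets
  sizes <- vapply(sets, length, integer(1))
  nulls <- if (nPerm > 0) ksNullTable(sizes, n, nPerm, seed) else NULL
  r <- pepOneProfile(ranking, sets, n, nulls)
  data.frame(pathway_id = names(sets), es = r$es, p = r$p,
    rank = permutationRank(-r$es, names(sets)), set_size = sizes,
    row.names = NULL, stringsAsFactors = FALSE)
}

# Bind only when needed; keep the caller's warnings meaningful.
bindUniverseQuiet <- function(gsc, universe) {
  if (identical(gsc@universe, as.character(universe))) return(gsc)
  bindUniverse(gsc, universe)
}

#' Compute pathway expression profiles for a whole corpus
#'
#' Applies [profileToPep()] to every treatment instance of a corpus and
#' assembles the result into a [PathwayProfiles] object. The permutation
#' null of a random same-size gene set depends only on the set size and the
#' universe size, so one seeded null table per size is shared across
#' instances; results are bit-identical for identical seeds and inputs.
#'
#' @param profiles A [RankedProfiles].
#' @param gsc A [GeneSetCollection] over (a superset of) the profiles'
#'   gene universe.
#' @param nPerm Permutations for empirical p-values (0 = none).
#' @param seed Integer seed.
#' @return An instance-level [PathwayProfiles].
#' @export
computePeps <- function(profiles, gsc, nPerm = 0, seed = 1) {
  stopifnot(is(profiles, "RankedProfiles"))
  rk <- rankMatrix(profiles)
  n <- nrow(rk)
  gsc <- bindUniverseQuiet(gsc, rownames(rk))
  if (!length(gsc@sets)) stop("no pathway with in-universe members",
    call. = FALSE)
  sets <- gsc@sets
  sizes <- vapply(sets, length, integer(1))
  nulls <- if (nPerm > 0) ksNullTable(sizes, n, nPerm, seed) else NULL
  P <- length(sets)
  es <- matrix(NA_real_, P, ncol(rk),
    dimnames = list(names(sets), colnames(rk)))
  pv <- es
  rks <- matrix(NA_integer_, P, ncol(rk),
    dimnames = dimnames(es))
  for (j in seq_len(ncol(rk))) {
    r <- pepOneProfile(rk[, j], sets, n, nulls)
    es[, j] <- r$es
    pv[, j] <- r$p
    rks[, j] <- permutationRank(-r$es, names(sets))
  }
  new("PathwayProfiles", es = es, pval = pv, ranks = rks,
    drug = drugIds(profiles), replicate = replicateIds(profiles))
}

#' Aggregate replicate instances into drug-level profiles
#'
#' Connectivity-Map drugs come with several treatment instances; the
#' drug-level pathway rank is the ranking of the mean per-replicate pathway
#' rank (Borda-style merge, lower mean = better rank, ties broken by
#' pathway id), and the drug-level enrichment score is the mean score.
#' Aggregated p-values are not defined and are set to \code{NA}.
#'
#' @param x An instance-level [PathwayProfiles] (all drugs aggregated at
#'   once), or a list of single-drug \code{PathwayProfiles} sharing one
#'   drug id and pathway vocabulary.
#' @param ... Unused.
#' @return A drug-level [PathwayProfiles] with one column per drug
#'   (columns ordered by drug id).
#' @export
setGeneric("aggregateReplicates",
  function(x, ...) standardGeneric("aggregateReplicates"))

#' @rdname aggregateReplicates
#' @export
setMethod("aggregateReplicates", "PathwayProfiles", function(x, ...) {
  drugs <- sort(unique(x@drug))
  P <- nrow(x@es)
  es <- matrix(NA_real_, P, length(drugs),
    dimnames = list(rownames(x@es), drugs))
  rks <- matrix(NA_integer_, P, length(drugs), dimnames = dimnames(es))
  for (d in drugs) {
    cols <- which(x@drug == d)
    es[, d] <- rowMeans(x@es[, cols, drop = FALSE])
    meanRank <- rowMeans(x@ranks[, cols, drop = FALSE])
    rks[, d] <- permutationRank(meanRank, rownames(x@es))
  }
  new("PathwayProfiles", es = es, pval = es * NA_real_, ranks = rks,
    drug = drugs, replicate = rep(NA_character_, length(drugs)))
})

#' @rdname aggregateReplicates
#' @export
setMethod("aggregateReplicates", "list", function(x, ...) {
  if (!length(x)) stop("need at least one profile", call. = FALSE)
  stopifnot(all(vapply(x, is, logical(1), "PathwayProfiles")))
  ids <- lapply(x, function(p) rownames(p@es))
  if (!all(vapply(ids, identical, logical(1), ids[[1L]])))
    stop("mismatched pathway ids across replicates", call. = FALSE)
  drugs <- unique(unlist(lapply(x, drugIds)))
  if (length(drugs) != 1L)
    stop("replicates must share a single drug id", call. = FALSE)
  combined <- new("PathwayProfiles",
    es = do.call(cbind, lapply(x, esMatrix)),
    pval = do.call(cbind, lapply(x, pvalMatrix)),
    ranks = do.call(cbind, lapply(x, rankMatrix)),
    drug = unlist(lapply(x, drugIds)),
    replicate = unlist(lapply(x, replicateIds)))
  aggregateReplicates(combined)
})

#' Rank drugs for a query pathway set
#'
#' The per-risk-gene stage of the screen: given drug-level pathway
#' profiles and the pathway annotations of one risk gene, each drug is
#' scored by a second-level KS statistic of the query pathways' positions
#' inside that drug's pathway ranking (universe size = number of
#' pathways). Empirical p-values come from random same-size pathway sets
#' (seeded, shared null); the drug list is sorted by ascending p, then
#' descending \eqn{|es|}, then drug id. A drug list per risk gene is the
#' object later merged by co-occurrence.
#'
#' @param pep A drug-level [PathwayProfiles] (one column per drug; run
#'   [aggregateReplicates()] first if needed).
#' @param query Character vector of query pathway ids (non-empty, a strict
#'   subset of the profile's pathways).
#' @param nPerm Permutations for the empirical p-value.
#' @param seed Integer seed.
#' @param geneId Optional gene id recorded in the output (the risk gene
#'   whose annotations form the query).
#' @return A \code{data.frame} ("drug list"): \code{gene_id},
#'   \code{drug_id}, \code{es}, \code{p}.
#' @export
rankDrugsForPathwaySet <- function(pep, query, nPerm = 999, seed = 1,
                                   geneId = NA_character_) {
  stopifnot(is(pep, "PathwayProfiles"))
  if (ncol(pep@es) == 0L) stop("empty profile set", call. = FALSE)
  if (anyDuplicated(pep@drug))
    stop("pep must be drug-level; run aggregateReplicates() first",
      call. = FALSE)
  query <- unique(as.character(query))
  if (!length(query)) stop("query must be non-empty", call. = FALSE)
  P <- nrow(pep@es)
  miss <- setdiff(query, rownames(pep@es))
  if (length(miss)) stop("query pathway(s) not in the profiles: ",
    paste(miss, collapse = ", "), call. = FALSE)
  if (length(query) >= P)
    stop("query covering all pathways is degenerate", call. = FALSE)
  k <- length(query)
  nulls <- if (nPerm > 0) ksNullTable(k, P, nPerm, seed) else NULL
  es <- vapply(seq_len(ncol(pep@es)), function(j)
    ksStatistic(pep@ranks[query, j], P), numeric(1))
  p <- if (is.null(nulls)) rep(NA_real_, length(es)) else
    vapply(es, empiricalP, numeric(1), nullEs = nulls[[as.character(k)]])
  out <- data.frame(gene_id = geneId, drug_id = pep@drug, es = es, p = p,
    stringsAsFactors = FALSE)
  out[order(out$p, -abs(out$es), out$drug_id), , drop = FALSE]
}

#' Write / read a PEP store (directory of per-drug TSVs plus an index)
#'
#' Each drug serialises to \code{<drug>.tsv} with columns
#' \code{pathway_id}, \code{es}, \code{p}, \code{rank}; \code{index.tsv}
#' records drug ids, replicate ids and file names.
#'
#' @param pep A [PathwayProfiles].
#' @param dir Store directory (created if missing).
#' @return \code{dir} (write) or a [PathwayProfiles] (read).
#' @export
writePepStore <- function(pep, dir) {
  stopifnot(is(pep, "PathwayProfiles"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- colnames(pep@es) %||% make.names(pep@drug, unique = TRUE)
  files <- paste0(gsub("[^A-Za-z0-9._-]", "_", cols), ".tsv")
  for (j in seq_along(cols)) {
    utils::write.table(
      data.frame(pathway_id = rownames(pep@es), es = pep@es[, j],
        p = pep@pval[, j], rank = pep@ranks[, j]),
      file.path(dir, files[j]), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  utils::write.table(
    data.frame(column = cols, drug = pep@drug, replicate = pep@replicate,
      file = files, stringsAsFactors = FALSE),
    file.path(dir, "index.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' @rdname writePepStore
#' @export
readPepStore <- function(dir) {
  idx <- utils::read.delim(file.path(dir, "index.tsv"),
    stringsAsFactors = FALSE, colClasses = "character")
  mats <- lapply(idx$file, function(f)
    utils::read.delim(file.path(dir, f), stringsAsFactors = FALSE))
  ids <- mats[[1L]]$pathway_id
  grab <- function(col, mode) {
    m <- vapply(mats, function(d) as(d[[col]], mode), vector(mode, length(ids)))
    m <- matrix(m, nrow = length(ids), dimnames = list(ids, idx$column))
    m
  }
  new("PathwayProfiles", es = grab("es", "numeric"),
    pval = grab("p", "numeric"),
    ranks = {
      r <- grab("rank", "numeric"); storage.mode(r) <- "integer"; r
    },
    drug = idx$drug,
    replicate = ifelse(idx$replicate == "NA", NA_character_, idx$replicate))
}
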