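#' Construct a gene set collection
#'
#' @param sets Named list of character vectors (set id -> member genes).
#'   Duplicate members within a set are dropped with a warning.
#' @param name Optional character vector of set descriptions (recycled
#'   from ids when absent).
#' @param source Set source annotation: \code{"GO"}, \code{"KEGG"} or
#'   \code{"other"} (scalar or per-set vector).
#' @param universe Optional gene universe to bind the collection to; see
#'   [bindUniverse()].
#' @return A [GeneSetCollection].
#' @export
geneSetCollection <- function(sets, name = NULL, source = "other",
                              universe = NULL) {
  if (is.null(names(sets)) && length(sets))
    stop("'sets' must be a named list", call. = FALSE)
  ndup <- vapply(sets, anyDuplicated, integer(1))
  if (any(ndup > 0L)) {
    warning(sprintf("dropping duplicate members in %d set(s): %s",
      sum(ndup > 0), paste(names(sets)[ndup > 0], collapse = ", ")),
      call. = FALSE)
    sets <- lapply(sets, unique)
  }
  source <- match.arg(source, c("GO", "KEGG", "other"), several.ok = TRUE)
  info <- data.frame(
    id = names(sets) %||% character(),
    name = if (is.null(name)) names(sets) %||% character() else name,
    source = if (length(sets)) rep_len(source, length(sets)) else character(),
    stringsAsFactors = FALSE)
  gsc <- new("GeneSetCollection", sets = sets, info = info,
    universe = character())
  if (!is.null(universe)) gsc <- bindUniverse(gsc, universe)
  gsc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bind a collection to a gene universe
#'
#' Restricts every set to genes present in the universe (perturbagen
#' platforms never cover a full annotation corpus). Out-of-universe members
#' are dropped with a warning; sets left empty are removed with a warning.
#'
#' @param gsc A [GeneSetCollection].
#' @param universe Character vector of gene identifiers (canonical order).
#' @return The bound collection.
#' @export
bindUniverse <- function(gsc, universe) {
  stopifnot(is(gsc, "GeneSetCollection"))
  universe <- as.character(universe)
  if (anyDuplicated(universe))
    stop("universe identifiers must be unique", call. = FALSE)
  trimmed <- lapply(gsc@sets, function(s) s[s %in% universe])
  lost <- sum(vapply(gsc@sets, length, integer(1)) -
              vapply(trimmed, length, integer(1)))
  if (lost > 0)
    warning(sprintf("%d member(s) outside the universe were dropped", lost),
      call. = FALSE)
  empty <- vapply(trimmed, length, integer(1)) == 0L
  if (any(empty)) {
    warning(sprintf("removed %d set(s) with no in-universe members: %s",
      sum(empty), paste(names(trimmed)[empty], collapse = ", ")),
      call. = FALSE)
    trimmed <- trimmed[!empty]
  }
  new("GeneSetCollection", sets = trimmed,
    info = gsc@info[!empty, , drop = FALSE], universe = universe)
}

#' Read a GMT gene-set file
#'
#' One set per line: \code{id <TAB> description <TAB> member1 <TAB> ...}.
#' Gzip-compressed files are handled transparently. Duplicate members
#' within a line are de-duplicated with a warning; an empty file yields an
#' empty collection with a warning.
#'
#' @param path Path to a GMT (or GMT.gz) file.
#' @param source Source annotation recorded for every set
#'   (\code{"GO"}, \code{"KEGG"} or \code{"other"}).
#' @param universe Optional universe to bind the result to.
#' @return A [GeneSetCollection].
#' @seealso [writeGmt()]
#' @export
readGmt <- function(path, source = "other", universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(con <- gzfile(path, "rt")); close(con)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(geneSetCollection(structure(list(), names = character()),
      source = source))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(bad))
    stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields",
      bad[1]), call. = FALSE)
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate set id(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- ids
  geneSetCollection(sets,
    name = vapply(fields, `[[`, character(1), 2L),
    source = source, universe = universe)
}

#' Write a collection to GMT
#'
#' @param gsc A [GeneSetCollection].
#' @param path Output path (".gz" suffix writes gzip).
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(gsc, path) {
  stopifnot(is(gsc, "GeneSetCollection"))
  lines <- vapply(seq_along(gsc@sets), function(i)
    paste(c(gsc@info$id[i], gsc@info$name[i], gsc@sets[[i]]),
      collapse = "\t"), character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  writeLines(lines, con); close(con)
  invisible(path)
}

#' Pathways annotated to a gene
#'
#' @param gsc A [GeneSetCollection].
#' @param gene A single gene identifier.
#' @return Character vector of ids of the sets containing the gene
#'   (possibly empty).
#' @export
pathwaysOfGene <- function(gsc, gene) {
  stopifnot(is(gsc, "GeneSetCollection"))
  gene <- stopIfNot1(as.character(gene), "gene")
  names(gsc@sets)[vapply(gsc@sets, function(s) gene %in% s, logical(1))]
}

#' Construct ranked profiles from an integer rank matrix
#'
#' @param ranks Integer matrix, genes x instances; each column a
#'   permutation of \code{1..n} (rank 1 = most up-regulated). Row names are
#'   gene ids; column names \code{"drug::replicate"} instance ids.
#' @return A [RankedProfiles].
#' @export
rankedProfiles <- function(ranks) {
  storage.mode(ranks) <- "integer"
  cn <- colnames(ranks)
  if (is.null(cn) && ncol(ranks))
    stop("instance column names are required", call. = FALSE)
  parts <- strsplit(cn %||% character(), "::", fixed = TRUE)
  drug <- vapply(parts, `[[`, character(1), 1L)
  repl <- vapply(parts, function(p)
    if (length(p) > 1L) paste(p[-1L], collapse = "::") else "1", character(1))
  new("RankedProfiles", ranks = ranks, drug = drug, replicate = repl)
}

#' Convert real-valued scores to ranks
#'
#' Highest score gets rank 1 (most up-regulated). Tied scores receive
#' average ranks which are then resolved into an integer permutation by the
#' gene order of the input (the universe order), so the conversion is
#' deterministic.
#'
#' @param scores Numeric matrix (genes x instances) or vector.
#' @return Integer matrix/vector of ranks with the same dimnames.
#' @export
scoresToRanks <- function(scores) {
  rankOne <- function(v) permutationRank(-v, seq_along(v))
  if (is.matrix(scores)) {
    out <- apply(scores, 2L, rankOne)
    dimnames(out) <- dimnames(scores)
    storage.mode(out) <- "integer"
    out
  } else as.integer(rankOne(scores))
}

#' Read a perturbagen rank or score matrix
#'
#' TSV with a header; the first column holds gene identifiers, the
#' remaining columns one treatment instance each, named
#' \code{"drugid::replicateid"}. In \code{mode = "ranks"} every column must
#' be a permutation of \code{1..n}; in \code{mode = "scores"} real-valued
#' scores are converted with [scoresToRanks()]. Gzip input is handled
#' transparently.
#'
#' @param path Path to the TSV(.gz) file.
#' @param mode \code{"ranks"} or \code{"scores"}.
#' @return A [RankedProfiles].
#' @export
readRankMatrix <- function(path, mode = c("ranks", "scores")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
    stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("rank matrix needs a gene column plus at least ",
    "one instance column", call. = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene identifiers", call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell(s) in the matrix", call. = FALSE)
  if (anyNA(m)) stop("missing cell(s) in the matrix", call. = FALSE)
  rownames(m) <- genes
  if (mode == "ranks") {
    n <- nrow(m)
    ok <- apply(m, 2L, function(col) identical(sort.int(as.integer(col)),
      seq_len(n)) && all(col == as.integer(col)))
    if (!all(ok))
      stop("column(s) not a permutation of 1..n: ",
        paste(colnames(m)[!ok], collapse = ", "), call. = FALSE)
    storage.mode(m) <- "integer"
    rankedProfiles(m)
  } else {
    rankedProfiles(scoresToRanks(m))
  }
}

#' Read a long-format viability table
#'
#' CSV with mandatory columns \code{treatment_id}, \code{name},
#' \code{cell_line}, \code{value} and \code{screen_dataset_id}; optional
#' per-treatment annotation columns \code{fda_approved} and
#' \code{cns_active}. Repeated (treatment, cell line) pairs under distinct
#' \code{screen_dataset_id}s are retained as separate replicate series.
#' Rows with non-finite values are dropped with a warning; duplicate
#' (treatment, cell line, dataset) triples are an error.
#'
#' @param path Path to the CSV(.gz) file.
#' @param value Sign convention of the \code{value} column:
#'   \code{"sensitivity"} (higher = more killing, stored as-is) or
#'   \code{"viability_lfc"} (PRISM-style log-fold-change of viability,
#'   negated at ingest so that higher stored sensitivity = more killing).
#' @param mutations Optional path to a mutation CSV with columns
#'   \code{cell_line}, \code{gene}, \code{is_mutated}.
#' @param expression Optional path to an expression CSV: first column
#'   \code{gene}, remaining columns one cell line each.
#' @return A [ViabilityExperiment].
#' @export
readViabilityTable <- function(path, value = c("sensitivity", "viability_lfc"),
                               mutations = NULL, expression = NULL) {
  value <- match.arg(value)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty viability table: ", path, call. = FALSE)
  need <- c("treatment_id", "name", "cell_line", "value", "screen_dataset_id")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("missing column(s): ",
    paste(miss, collapse = ", "), call. = FALSE)
  v <- suppressWarnings(as.numeric(df$value))
  bad <- !is.finite(v)
  if (any(bad)) {
    warning(sprintf("dropped %d row(s) with non-finite values", sum(bad)),
      call. = FALSE)
    df <- df[!bad, , drop = FALSE]; v <- v[!bad]
  }
  if (nrow(df) == 0L) stop("no finite values in viability table", call. = FALSE)
  sens <- if (value == "viability_lfc") -v else v
  meta <- unique(data.frame(
    treatment_id = as.character(df$treatment_id),
    name = as.character(df$name),
    fda_approved = if ("fda_approved" %in% colnames(df))
      as.logical(df$fda_approved) else FALSE,
    cns_active = if ("cns_active" %in% colnames(df))
      as.logical(df$cns_active) else FALSE,
    stringsAsFactors = FALSE))
  if (anyDuplicated(meta$treatment_id))
    stop("inconsistent treatment annotations across rows", call. = FALSE)
  mut <- matrix(logical(0), nrow = 0, ncol = 0)
  if (!is.null(mutations)) mut <- readMutationTable(mutations)
  expr <- matrix(numeric(0), nrow = 0, ncol = 0)
  if (!is.null(expression)) expr <- readExpressionMatrix(expression)
  viabilityExperiment(
    data.frame(treatment_id = as.character(df$treatment_id),
      cell_line = as.character(df$cell_line),
      screen_dataset_id = as.character(df$screen_dataset_id),
      sensitivity = sens, stringsAsFactors = FALSE),
    treatments = meta, mutations = mut, expression = expr)
}

#' @rdname readViabilityTable
#' @param data Long-format \code{data.frame} (see the \code{data} slot of
#'   [ViabilityExperiment]).
#' @param treatments Per-treatment annotation \code{data.frame}.
#' @export
viabilityExperiment <- function(data, treatments = NULL,
                                mutations = matrix(logical(0), 0, 0),
                                expression = matrix(numeric(0), 0, 0)) {
  if (is.null(treatments)) {
    ids <- unique(as.character(data$treatment_id))
    treatments <- data.frame(treatment_id = ids, name = ids,
      fda_approved = FALSE, cns_active = FALSE, stringsAsFactors = FALSE)
  }
  new("ViabilityExperiment", data = data, treatments = treatments,
    mutations = mutations, expression = expression)
}

#' Read a long-format mutation table into a cell-line x gene logical matrix
#' @param path CSV with columns \code{cell_line}, \code{gene},
#'   \code{is_mutated}.
#' @return Logical matrix (cell lines x genes); pairs absent from the
#'   table are recorded as wild-type.
#' @export
readMutationTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "gene", "is_mutated")
  if (!all(need %in% colnames(df)))
    stop("mutation table needs columns ", paste(need, collapse = ", "),
      call. = FALSE)
  lines <- sort(unique(df$cell_line)); genes <- sort(unique(df$gene))
  m <- matrix(FALSE, length(lines), length(genes),
    dimnames = list(lines, genes))
  m[cbind(match(df$cell_line, lines), match(df$gene, genes))] <-
    as.logical(df$is_mutated)
  m
}

#' Read a gene x cell-line expression matrix
#' @param path CSV; first column \code{gene}, one column per cell line.
#' @return Numeric matrix (genes x cell lines).
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}

#' Write a viability experiment back to the long CSV format
#' @param vm A [ViabilityExperiment].
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeViabilityTable <- function(vm, path) {
  stopifnot(is(vm, "ViabilityExperiment"))
  d <- vm@data
  meta <- vm@treatments
  i <- match(d$treatment_id, meta$treatment_id)
  out <- data.frame(treatment_id = d$treatment_id, name = meta$name[i],
    cell_line = d$cell_line, value = d$sensitivity,
    screen_dataset_id = d$screen_dataset_id,
    fda_approved = meta$fda_approved[i], cns_active = meta$cns_active[i],
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
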