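# Pooled viability-screen statistics: sensitivity computation, ranking
# against a reference treatment, the direct screening protocol, mutation
# association and sensitive-vs-non-sensitive differential expression.

#' Sensitivity from barcode abundances
#'
#' Cell viability in a pooled-barcode screen is read out as barcode
#' abundance; sensitivity compares the treatment pool against the control
#' pool, \eqn{s = -\log_2((a_T + c) / (a_C + c))} with pseudocount
#' \eqn{c}. Higher sensitivity = greater viability reduction (more
#' killing). Antisymmetric under swapping treatment and control when the
#' pseudocount is 0.
#'
#' @param treatmentAbundance,controlAbundance Non-negative barcode
#'   abundances (vectorised).
#' @param pseudocount Added to both abundances; guards the log when an
#'   abundance is 0. Must be positive unless both abundances are positive.
#' @return Numeric sensitivity value(s).
#' @export
sensitivityFromCounts <- function(treatmentAbundance, controlAbundance,
                                  pseudocount = 0.5) {
  if (any(treatmentAbundance < 0) || any(controlAbundance < 0))
    stop("abundances must be non-negative", call. = FALSE)
  if (pseudocount <= 0 &&
      (any(treatmentAbundance == 0) || any(controlAbundance == 0)))
    stop("pseudocount must be positive when an abundance is 0",
      call. = FALSE)
  -log2((treatmentAbundance + pseudocount) /
        (controlAbundance + pseudocount))
}

# Pooled sensitivities of one treatment (optionally one dataset).
sensValues <- function(vm, treatment, dataset = NULL) {
  d <- vm@data
  sel <- d$treatment_id == treatment
  if (!is.null(dataset)) sel <- sel & d$screen_dataset_id == dataset
  structure(d$sensitivity[sel], names = d$cell_line[sel])
}

# Unique (treatment, dataset) replicate series.
seriesTable <- function(vm) {
  unique(vm@data[, c("treatment_id", "screen_dataset_id"), drop = FALSE])
}

# Mann-Whitney core: exact null enumeration (via the exact distribution)
# when both samples are small and untied, else normal approximation with
# tie and continuity correction — delegated to stats::wilcox.test.
mwTest <- function(x, y, alternative = c("greater", "two_sided", "less"),
                   exactMax = 8L) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y))
    stop("both series must be non-empty", call. = FALSE)
  alt <- sub("two_sided", "two.sided", alternative, fixed = TRUE)
  ties <- anyDuplicated(c(x, y)) > 0L
  useExact <- length(x) <= exactMax && length(y) <= exactMax && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alt,
    exact = useExact, correct = TRUE))
  list(u_stat = unname(wt$statistic), p = wt$p.value)
}

#' Mann-Whitney U test of a treatment against a reference
#'
#' Unpaired rank test comparing the sensitivities of a treatment's cell
#' lines against the reference treatment (pooling replicate datasets).
#' Exact when both samples have at most 8 untied values, otherwise normal
#' approximation with tie and continuity correction.
#'
#' @param vm A [ViabilityExperiment].
#' @param treatment,reference Treatment ids.
#' @param alternative \code{"greater"} (treatment more sensitive than
#'   reference; the screen's reading) or \code{"two_sided"}.
#' @return A list with \code{u_stat} and \code{p}.
#' @export
mannWhitneyVsReference <- function(vm, treatment, reference,
                                   alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is(vm, "ViabilityExperiment"))
  mwTest(sensValues(vm, treatment), sensValues(vm, reference), alternative)
}

#' Rank treatments by mean sensitivity
#'
#' Per treatment (pooled across replicate datasets): number of cell-line
#' values, mean, standard deviation and two-sided 95% t-interval
#' \eqn{\bar x \pm t_{0.975, n-1}\, s/\sqrt n}. Treatments with fewer
#' than 2 values are excluded with a warning. If a reference is supplied,
#' a Mann-Whitney test against it is attached per treatment.
#'
#' @param vm A [ViabilityExperiment].
#' @param treatments Treatment ids to summarise (default: all).
#' @param reference Optional reference treatment id for per-treatment
#'   tests (excluded from the ranking itself unless listed).
#' @param alternative Sidedness of the reference test (see
#'   [mannWhitneyVsReference()]).
#' @return A \code{data.frame} sorted by descending mean:
#'   \code{treatment_id}, \code{n_lines}, \code{mean}, \code{sd},
#'   \code{ci_lo}, \code{ci_hi}, and, with a reference, \code{u_stat},
#'   \code{p_vs_ref}.
#' @export
meanSensitivityRanking <- function(vm, treatments = NULL, reference = NULL,
                                   alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is(vm, "ViabilityExperiment"))
  if (is.null(treatments)) treatments <- unique(vm@data$treatment_id)
  vals <- lapply(treatments, function(tr) sensValues(vm, tr))
  n <- vapply(vals, length, integer(1))
  if (any(n < 2L)) {
    warning("excluded treatment(s) with fewer than 2 values: ",
      paste(treatments[n < 2L], collapse = ", "), call. = FALSE)
    vals <- vals[n >= 2L]; treatments <- treatments[n >= 2L]; n <- n[n >= 2L]
  }
  if (!length(treatments)) stop("no treatment with >= 2 values",
    call. = FALSE)
  m <- vapply(vals, mean, numeric(1))
  s <- vapply(vals, stats::sd, numeric(1))
  half <- stats::qt(0.975, n - 1) * s / sqrt(n)
  out <- data.frame(treatment_id = treatments, n_lines = n, mean = m,
    sd = s, ci_lo = m - half, ci_hi = m + half, stringsAsFactors = FALSE)
  if (!is.null(reference)) {
    ref <- sensValues(vm, reference)
    tst <- lapply(vals, function(v) mwTest(v, ref, alternative))
    out$u_stat <- vapply(tst, `[[`, numeric(1), "u_stat")
    out$p_vs_ref <- vapply(tst, `[[`, numeric(1), "p")
  }
  out[order(-out$mean, out$treatment_id), , drop = FALSE]
}

#' Flag treatments with discordant replicate datasets
#'
#' A treatment screened in several datasets should respond consistently:
#' for every dataset pair sharing at least 3 cell lines, the Pearson
#' correlation of sensitivities over shared lines is computed; treatments
#' with any pair below \code{rMin} are excluded (the "disparate
#' responses" rule). Pairs sharing fewer than 3 lines have an undefined
#' correlation: such treatments are flagged for manual review, never
#' auto-excluded. Single-dataset treatments are never excluded.
#'
#' @param vm A [ViabilityExperiment].
#' @param rMin Minimum acceptable pairwise Pearson correlation.
#' @return A list: \code{excluded} (treatment ids), \code{review}
#'   (treatment ids with undefined correlations), \code{correlations}
#'   (\code{data.frame} of every evaluated pair).
#' @export
replicateConcordanceFilter <- function(vm, rMin = 0.3) {
  stopifnot(is(vm, "ViabilityExperiment"))
  ser <- seriesTable(vm)
  multi <- names(which(table(ser$treatment_id) >= 2L))
  excluded <- character(); review <- character()
  rows <- list()
  for (tr in multi) {
    ds <- ser$screen_dataset_id[ser$treatment_id == tr]
    prs <- utils::combn(ds, 2L, simplify = FALSE)
    bad <- FALSE; undef <- FALSE
    for (pr in prs) {
      a <- sensValues(vm, tr, pr[1L]); b <- sensValues(vm, tr, pr[2L])
      shared <- intersect(names(a), names(b))
      r <- if (length(shared) >= 3L)
        stats::cor(a[shared], b[shared]) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(treatment_id = tr,
        dataset_a = pr[1L], dataset_b = pr[2L],
        n_shared = length(shared), r = r, stringsAsFactors = FALSE)
      if (is.na(r)) undef <- TRUE else if (r < rMin) bad <- TRUE
    }
    if (bad) excluded <- c(excluded, tr)
    else if (undef) review <- c(review, tr)
  }
  list(excluded = excluded, review = review,
    correlations = if (length(rows)) do.call(rbind, rows) else
      data.frame(treatment_id = character(), dataset_a = character(),
        dataset_b = character(), n_shared = integer(), r = numeric()))
}

#' Direct screening protocol
#'
#' Ranks every treatment series directly against the reference: replicate
#' datasets of one drug are treated as separate treatments (a drug
#' screened twice contributes two series). Per non-reference series the
#' report records the number of values, mean, sd, 95% t-interval, and a
#' Mann-Whitney test against the pooled reference values; it then counts
#' how many series have a higher mean than the reference and how many of
#' those are significant at \code{alpha}. Fractions are over the
#' non-reference series.
#'
#' @param vm A [ViabilityExperiment].
#' @param reference Reference treatment id (must be present).
#' @param alpha Significance threshold (default \code{1e-3}).
#' @param alternative Test sidedness (default \code{"greater"}).
#' @return A list of class \code{"DirectScreenReport"}:
#'   \code{n_treatments} (series incl. reference), \code{n_higher_mean},
#'   \code{frac_higher}, \code{n_significant}, \code{frac_significant},
#'   \code{alpha}, and \code{summaries} (per-series \code{data.frame}
#'   sorted by descending mean).
#' @export
directScreen <- function(vm, reference, alpha = 1e-3,
                         alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is(vm, "ViabilityExperiment"))
  ref <- sensValues(vm, reference)
  if (!length(ref)) stop("reference treatment not found: ", reference,
    call. = FALSE)
  ser <- seriesTable(vm)
  ser <- ser[ser$treatment_id != reference, , drop = FALSE]
  if (!nrow(ser)) stop("no treatment besides the reference", call. = FALSE)
  refMean <- mean(ref)
  rows <- lapply(seq_len(nrow(ser)), function(i) {
    v <- sensValues(vm, ser$treatment_id[i], ser$screen_dataset_id[i])
    tst <- mwTest(v, ref, alternative)
    n <- length(v); m <- mean(v); s <- stats::sd(v)
    half <- if (n >= 2) stats::qt(0.975, n - 1) * s / sqrt(n) else NA_real_
    data.frame(treatment_id = ser$treatment_id[i],
      screen_dataset_id = ser$screen_dataset_id[i], n_lines = n,
      mean = m, sd = s, ci_lo = m - half, ci_hi = m + half,
      u_stat = tst$u_stat, p_vs_ref = tst$p, stringsAsFactors = FALSE)
  })
  sm <- do.call(rbind, rows)
  sm <- sm[order(-sm$mean, sm$treatment_id), , drop = FALSE]
  higher <- sm$mean > refMean
  signif <- higher & sm$p_vs_ref < alpha
  nSeries <- nrow(sm)
  structure(list(
    reference = reference, reference_mean = refMean,
    n_treatments = nSeries + 1L,
    n_higher_mean = sum(higher), frac_higher = sum(higher) / nSeries,
    n_significant = sum(signif), frac_significant = sum(signif) / nSeries,
    alpha = alpha, alternative = alternative, summaries = sm),
    class = "DirectScreenReport")
}

#' @export
print.DirectScreenReport <- function(x, ...) {
  cat(sprintf(paste0(
    "Direct screen vs %s: %d treatment series (incl. reference)\n",
    "  higher mean: %d (%.2f%%); significant at alpha=%g: %d (%.2f%%)\n"),
    x$reference, x$n_treatments, x$n_higher_mean, 100 * x$frac_higher,
    x$alpha, x$n_significant, 100 * x$frac_significant))
  invisible(x)
}

#' Association between drug sensitivity and a gene mutation
#'
#' Two-sided Mann-Whitney test comparing the sensitivities of
#' mutation-carrying versus wild-type cell lines for one treatment.
#'
#' @param vm A [ViabilityExperiment] with a mutation matrix.
#' @param treatment Treatment id.
#' @param gene Gene symbol (a column of the mutation matrix).
#' @return The two-sided p-value.
#' @export
mutationAssociation <- function(vm, treatment, gene) {
  stopifnot(is(vm, "ViabilityExperiment"))
  if (!gene %in% colnames(vm@mutations))
    stop("gene not in the mutation annotation: ", gene, call. = FALSE)
  v <- sensValues(vm, treatment)
  v <- v[names(v) %in% rownames(vm@mutations)]
  if (!length(v)) stop("no annotated cell line with values", call. = FALSE)
  mut <- vm@mutations[names(v), gene]
  if (!any(mut)) stop("mutated group is empty for gene ", gene,
    call. = FALSE)
  if (all(mut)) stop("wild-type group is empty for gene ", gene,
    call. = FALSE)
  mwTest(v[mut], v[!mut], "two_sided")$p
}

#' Split cell lines into sensitive / non-sensitive groups
#'
#' Median split of a treatment's sensitivities (lines above the threshold
#' are "sensitive"); the threshold quantile is exposed because screens
#' define the split differently.
#'
#' @param vm A [ViabilityExperiment].
#' @param treatment Treatment id.
#' @param probs Quantile defining the split (default 0.5 = median).
#' @return A list: \code{sensitive}, \code{nonSensitive} (cell-line ids)
#'   and \code{sensitivity} (the named value vector, descending).
#' @export
sensitivityGroups <- function(vm, treatment, probs = 0.5) {
  v <- sensValues(vm, treatment)
  thr <- stats::quantile(v, probs, names = FALSE)
  v <- sort(v, decreasing = TRUE)
  list(sensitive = names(v)[v > thr], nonSensitive = names(v)[v <= thr],
    sensitivity = v)
}

#' Differential expression between sensitive and non-sensitive lines
#'
#' Per-gene Welch two-sample t-test between the two groups; genes with
#' \eqn{p < \alpha} are reported. The returned heatmap matrix contains the
#' selected genes with columns ordered by descending sensitivity (the
#' screen's display convention) and rows ordered by hierarchical
#' clustering with correlation distance and average linkage. Genes with
#' zero variance in both groups get \eqn{p = 1} (skipped, not an error).
#'
#' @param expression Numeric gene x cell-line matrix.
#' @param groups Named logical/character grouping: \code{TRUE}/"sensitive"
#'   lines vs the rest; names are cell lines (or a list as returned by
#'   [sensitivityGroups()]).
#' @param alpha Significance threshold (default \code{1e-3}).
#' @param ordering Optional named numeric vector (e.g. sensitivities)
#'   whose descending order fixes the heatmap columns; defaults to the
#'   column order of \code{expression}.
#' @return A list: \code{genes} (selected gene ids), \code{p}
#'   (named per-gene p-values), \code{matrix} (ordered heatmap matrix).
#' @export
deGenes <- function(expression, groups, alpha = 1e-3, ordering = NULL) {
  if (is.list(groups) && !is.null(groups$sensitive)) {
    if (is.null(ordering)) ordering <- groups$sensitivity
    groups <- stats::setNames(
      colnames(expression) %in% groups$sensitive, colnames(expression))
  }
  g <- as.logical(groups[colnames(expression)])
  if (sum(g) < 2L || sum(!g) < 2L)
    stop("both groups need at least 2 cell lines", call. = FALSE)
  p <- apply(expression, 1L, function(x) {
    a <- x[g]; b <- x[!g]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
    stats::t.test(a, b)$p.value
  })
  genes <- names(p)[p < alpha]
  mat <- expression[genes, , drop = FALSE]
  if (!is.null(ordering)) {
    ord <- names(sort(ordering, decreasing = TRUE))
    mat <- mat[, intersect(ord, colnames(mat)), drop = FALSE]
  }
  if (nrow(mat) >= 3L) {
    dd <- stats::as.dist(1 - stats::cor(t(mat)))
    mat <- mat[stats::hclust(dd, method = "average")$order, , drop = FALSE]
  }
  list(genes = genes, p = p, matrix = mat)
}

#' Sensitivity matrix of an experiment
#'
#' @param vm A [ViabilityExperiment].
#' @param by \code{"treatment"} pools replicate datasets (duplicate cells
#'   averaged); \code{"series"} keeps one row per (treatment, dataset).
#' @return Numeric matrix (rows = treatments or series, columns = cell
#'   lines) with \code{NA} for missing cells.
#' @export
sensitivityMatrix <- function(vm, by = c("treatment", "series")) {
  by <- match.arg(by)
  d <- vm@data
  rowsId <- if (by == "treatment") d$treatment_id else
    paste(d$treatment_id, d$screen_dataset_id, sep = "@")
  rows <- unique(rowsId); cols <- unique(d$cell_line)
  m <- matrix(NA_real_, length(rows), length(cols),
    dimnames = list(rows, cols))
  cnt <- matrix(0L, length(rows), length(cols), dimnames = dimnames(m))
  ij <- cbind(match(rowsId, rows), match(d$cell_line, cols))
  for (k in seq_len(nrow(d))) {
    i <- ij[k, 1L]; j <- ij[k, 2L]
    m[i, j] <- if (cnt[i, j] == 0L) d$sensitivity[k] else
      (m[i, j] * cnt[i, j] + d$sensitivity[k]) / (cnt[i, j] + 1L)
    cnt[i, j] <- cnt[i, j] + 1L
  }
  m
}

#' Compare pathway-annotation similarity with sensitivity similarity
#'
#' Builds two drug-by-drug Pearson correlation matrices — one from binary
#' pathway membership rows, one from sensitivity profiles across cell
#' lines (pairwise-complete) — and a per-drug discrepancy score: the mean
#' absolute difference between the drug's two correlation vectors
#' (self-correlations excluded). Drugs with a constant profile have
#' undefined correlations, reported as \code{NA}.
#'
#' @param membership Binary drug x pathway matrix.
#' @param vm A [ViabilityExperiment] covering (a superset of) the drugs.
#' @return A list: \code{corr_go}, \code{corr_sens} (matrices over the
#'   shared drugs) and \code{discrepancy} (named numeric).
#' @export
drugCorrelationMatrices <- function(membership, vm) {
  stopifnot(is(vm, "ViabilityExperiment"))
  sens <- sensitivityMatrix(vm, by = "treatment")
  shared <- intersect(rownames(membership), rownames(sens))
  if (!length(shared)) stop("no drug shared between membership and screen",
    call. = FALSE)
  corrGo <- suppressWarnings(stats::cor(t(membership[shared, , drop = FALSE])))
  corrSens <- suppressWarnings(stats::cor(t(sens[shared, , drop = FALSE]),
    use = "pairwise.complete.obs"))
  disc <- vapply(shared, function(d) {
    dif <- abs(corrGo[d, ] - corrSens[d, ])
    dif <- dif[names(dif) != d]
    if (all(is.na(dif))) NA_real_ else mean(dif, na.rm = TRUE)
  }, numeric(1))
  list(corr_go = corrGo, corr_sens = corrSens, discrepancy = disc)
}
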