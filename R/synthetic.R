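# Seeded generators: a Connectivity-Map-like profile corpus and a
# PRISM-like viability screen, both with planted ground truth, so every
# pipeline stage is testable without external downloads.

#' Generate a perturbagen corpus with planted pathway signal
#'
#' Builds a gene universe, a pathway collection (members drawn without
#' replacement), a set of risk genes each assigned to 2-6 pathways, and a
#' profile corpus in which a subset of "active" drugs perturbs the pathway
#' annotations of 1-3 risk genes: instance scores are standard normal
#' noise plus \code{direction * delta} for genes in the perturbed
#' pathways, then converted to ranks. All draws come from the seeded
#' generator, so identical seeds give bit-identical corpora.
#'
#' @param nGenes Universe size (default 1000).
#' @param nPathways Number of pathways (default 150).
#' @param setSize Range of pathway sizes (default \code{c(10, 50)}).
#' @param nDrugs Number of drugs (default 100).
#' @param replicates Treatment instances per drug (default 3).
#' @param nRiskGenes Number of risk genes (default 9, the number of
#'   annotated risk genes the motivating screen could map to pathways).
#' @param nActiveDrugs Number of planted active drugs (default 10).
#' @param delta Planted score shift (default 2.0).
#' @param seed Integer seed.
#' @return A list: \code{collection} ([GeneSetCollection]),
#'   \code{profiles} ([RankedProfiles]) and \code{truth} (risk-gene
#'   pathway assignments and per-drug perturbation targets).
#' @export
genCorpus <- function(nGenes = 1000, nPathways = 150, setSize = c(10, 50),
                      nDrugs = 100, replicates = 3, nRiskGenes = 9,
                      nActiveDrugs = 10, delta = 2.0, seed = 1) {
  stopifnot(nGenes > 0, nPathways > 0, nDrugs > 0, replicates > 0,
    nRiskGenes > 0, nActiveDrugs >= 0, delta >= 0)
  if (max(setSize) > nGenes)
    stop("pathway sizes cannot exceed the universe size", call. = FALSE)
  withSeed(seed, {
    genes <- sprintf("g%04d", seq_len(nGenes))
    pwIds <- sprintf("P%03d", seq_len(nPathways))
    sizes <- sample(seq(setSize[1L], setSize[2L]), nPathways,
      replace = TRUE)
    sets <- lapply(sizes, function(s) sample(genes, s))
    names(sets) <- pwIds
    riskGenes <- sample(genes, nRiskGenes)
    for (g in riskGenes) {
      pws <- sample(pwIds, sample(2:6, 1L))
      for (pw in pws) sets[[pw]] <- unique(c(sets[[pw]], g))
    }
    # a risk gene's pathway set is its full membership (explicit
    # assignments plus any membership from the random pathway draw) --
    # exactly what a pathway lookup on the collection returns
    assigned <- lapply(riskGenes, function(g)
      names(sets)[vapply(sets, function(s) g %in% s, logical(1))])
    names(assigned) <- riskGenes
    drugs <- sprintf("d%03d", seq_len(nDrugs))
    active <- sort(sample(drugs, nActiveDrugs))
    truthDrugs <- lapply(active, function(d) {
      nHit <- sample(seq_len(min(3L, nRiskGenes)), 1L)
      hit <- riskGenes[sample.int(nRiskGenes, nHit)]
      list(risk_genes = hit,
        pathways = sort(unique(unlist(assigned[hit]))),
        direction = sample(c(-1, 1), 1L), delta = delta)
    })
    names(truthDrugs) <- active
    cols <- as.vector(t(outer(drugs, seq_len(replicates),
      function(d, r) paste0(d, "::r", r))))
    scores <- matrix(stats::rnorm(nGenes * length(cols)), nGenes,
      dimnames = list(genes, cols))
    for (d in active) {
      tg <- unique(unlist(sets[truthDrugs[[d]]$pathways]))
      idx <- match(tg, genes)
      j <- which(startsWith(cols, paste0(d, "::")))
      scores[idx, j] <- scores[idx, j] +
        truthDrugs[[d]]$direction * delta
    }
    collection <- suppressWarnings(
      geneSetCollection(sets, source = "GO", universe = genes))
    list(collection = collection,
      profiles = rankedProfiles(scoresToRanks(scores)),
      truth = list(active_drugs = truthDrugs, risk_genes = assigned,
        delta = delta, seed = seed))
  })
}

#' Generate a viability screen with planted potent drugs
#'
#' Emulates a pooled viability screen over glioma-like cell lines:
#' \deqn{s_{dc} = \mu_d + \gamma_c + m_{dc} + \varepsilon_{dc}}
#' with cell-line effect \eqn{\gamma_c \sim N(0, 0.25)}, noise
#' \eqn{\varepsilon \sim N(0, \sigma^2)}, \eqn{\mu_d = \mu} for planted
#' potent drugs and 0 otherwise (the reference treatment always has
#' \eqn{\mu_d = 0}), and a mutation shift \eqn{m_{dc}} for planted
#' (drug, gene) associations on mutation-carrying lines. Also generates
#' mutation calls, an expression matrix with planted differentially
#' expressed genes for one focal potent drug, and treatment annotations.
#' Default dimensions mirror a neurology-drug screen: 140 treatment
#' series (reference included) over 42 cell lines.
#'
#' @param nTreatments Total treatments including the reference.
#' @param nLines Number of cell lines (default 42).
#' @param potentFraction Fraction of non-reference treatments with a
#'   planted effect (default 0.1); ignored when \code{potent} is given.
#' @param mu Planted mean sensitivity shift (default 1.0).
#' @param sigma Noise standard deviation (default 0.5).
#' @param mutationGenes Genes with mutation calls
#'   (default \code{c("TP53", "PTEN")}).
#' @param mutationRate Per-line mutation probability (default 0.3).
#' @param mutationShift Planted sensitivity shift on mutated lines for
#'   one associated drug per mutation gene (default \code{mu}).
#' @param treatments Optional explicit treatment ids (reference added if
#'   absent); overrides \code{nTreatments}.
#' @param reference Reference treatment id (default \code{"TMZ"}).
#' @param potent Optional explicit potent treatment ids.
#' @param nExprGenes,nDeGenes Expression matrix size and number of
#'   planted DE genes (defaults 200 and 20).
#' @param deShift Planted DE mean shift in units of the expression SD
#'   (default 3).
#' @param approvedCns Logical: annotate treatments as FDA-approved and
#'   CNS-active (default \code{TRUE}, emulating a screen restricted to an
#'   approved neurology panel).
#' @param seed Integer seed.
#' @return A list: \code{vm} ([ViabilityExperiment]) and \code{truth}
#'   (\code{potent}, \code{mutation_effects}, \code{de_genes},
#'   \code{reference}).
#' @export
genViability <- function(nTreatments = 140, nLines = 42,
                         potentFraction = 0.1, mu = 1.0, sigma = 0.5,
                         mutationGenes = c("TP53", "PTEN"),
                         mutationRate = 0.3, mutationShift = mu,
                         treatments = NULL, reference = "TMZ",
                         potent = NULL, nExprGenes = 200, nDeGenes = 20,
                         deShift = 3, approvedCns = TRUE, seed = 1) {
  stopifnot(nLines > 1, potentFraction >= 0, potentFraction <= 1,
    sigma > 0)
  withSeed(seed, {
    if (is.null(treatments))
      treatments <- c(reference,
        sprintf("drug%03d", seq_len(nTreatments - 1L)))
    else if (!reference %in% treatments)
      treatments <- c(reference, treatments)
    nonRef <- setdiff(treatments, reference)
    if (is.null(potent))
      potent <- sort(sample(nonRef,
        round(potentFraction * length(nonRef))))
    else potent <- intersect(potent, nonRef)
    lines <- sprintf("line%03d", seq_len(nLines))
    gammaC <- stats::rnorm(nLines, 0, 0.5)
    muD <- stats::setNames(ifelse(treatments %in% potent, mu, 0),
      treatments)
    mut <- matrix(stats::rbinom(nLines * length(mutationGenes), 1L,
      mutationRate) == 1L, nLines,
      dimnames = list(lines, mutationGenes))
    mutEff <- NULL
    if (length(mutationGenes)) {
      pool <- if (length(potent)) potent else nonRef
      mutDrug <- sample(pool, min(length(mutationGenes), length(pool)),
        replace = length(pool) < length(mutationGenes))
      mutEff <- data.frame(treatment_id = mutDrug,
        gene = mutationGenes[seq_along(mutDrug)],
        shift = mutationShift, stringsAsFactors = FALSE)
    }
    sens <- outer(muD, gammaC, `+`) +
      matrix(stats::rnorm(length(treatments) * nLines, 0, sigma),
        length(treatments))
    dimnames(sens) <- list(treatments, lines)
    if (!is.null(mutEff)) for (k in seq_len(nrow(mutEff))) {
      carriers <- lines[mut[, mutEff$gene[k]]]
      sens[mutEff$treatment_id[k], carriers] <-
        sens[mutEff$treatment_id[k], carriers] + mutEff$shift[k]
    }
    exprGenes <- sprintf("e%04d", seq_len(nExprGenes))
    expr <- matrix(stats::rnorm(nExprGenes * nLines), nExprGenes,
      dimnames = list(exprGenes, lines))
    deTruth <- list()
    if (length(potent) && nDeGenes > 0) {
      focal <- potent[1L]
      deG <- sort(sample(exprGenes, nDeGenes))
      sensLines <- lines[sens[focal, ] >
        stats::median(sens[focal, ])]
      expr[deG, sensLines] <- expr[deG, sensLines] + deShift
      deTruth[[focal]] <- deG
    }
    long <- data.frame(
      treatment_id = rep(treatments, times = nLines),
      cell_line = rep(lines, each = length(treatments)),
      screen_dataset_id = "S1",
      sensitivity = as.vector(sens),
      stringsAsFactors = FALSE)
    meta <- data.frame(treatment_id = treatments, name = treatments,
      fda_approved = approvedCns, cns_active = approvedCns,
      stringsAsFactors = FALSE)
    vm <- viabilityExperiment(long, treatments = meta, mutations = mut,
      expression = expr)
    list(vm = vm, truth = list(potent = potent, mu = mu,
      mutation_effects = mutEff, de_genes = deTruth,
      reference = reference, seed = seed))
  })
}

#' Write a generated corpus / screen to the package's on-disk formats
#'
#' The generators emit exactly the formats the readers consume: a GMT
#' collection, a rank-matrix TSV, a long-format viability CSV, mutation
#' and expression CSVs, and the planted truth as JSON.
#'
#' @param corpus A list from [genCorpus()].
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCorpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGmt(corpus$collection, file.path(dir, "collection.gmt"))
  rk <- rankMatrix(corpus$profiles)
  utils::write.table(
    data.frame(gene = rownames(rk), rk, check.names = FALSE),
    file.path(dir, "profiles.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(corpus$truth, file.path(dir, "corpus_truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeCorpus
#' @param screen A list from [genViability()].
#' @export
writeScreen <- function(screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeViabilityTable(screen$vm, file.path(dir, "viability.csv"))
  mut <- mutationMatrix(screen$vm)
  if (length(mut)) {
    long <- data.frame(
      cell_line = rep(rownames(mut), times = ncol(mut)),
      gene = rep(colnames(mut), each = nrow(mut)),
      is_mutated = as.vector(mut), stringsAsFactors = FALSE)
    utils::write.csv(long, file.path(dir, "mutations.csv"),
      row.names = FALSE, quote = FALSE)
  }
  expr <- expressionMatrix(screen$vm)
  if (length(expr))
    utils::write.csv(
      data.frame(gene = rownames(expr), expr, check.names = FALSE),
      file.path(dir, "expression.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(screen$truth, file.path(dir, "screen_truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
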