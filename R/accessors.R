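#' @title Accessors for pepScreen classes
#' @name accessors
#' @rdname accessors
#' @param x An object of one of the pepScreen classes.
#' @description Small accessor generics so user code never touches slots.
NULL

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname accessors
#' @export
setGeneric("setIds", function(x) standardGeneric("setIds"))
#' @rdname accessors
#' @export
setMethod("setIds", "GeneSetCollection", function(x) names(x@sets))

#' @rdname accessors
#' @export
setGeneric("setInfo", function(x) standardGeneric("setInfo"))
#' @rdname accessors
#' @export
setMethod("setInfo", "GeneSetCollection", function(x) x@info)

#' @rdname accessors
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))
#' @rdname accessors
#' @export
setMethod("geneUniverse", "GeneSetCollection", function(x) x@universe)
#' @rdname accessors
#' @export
setMethod("geneUniverse", "RankedProfiles", function(x) rownames(x@ranks))

#' @rdname accessors
#' @export
setGeneric("rankMatrix", function(x) standardGeneric("rankMatrix"))
#' @rdname accessors
#' @export
setMethod("rankMatrix", "RankedProfiles", function(x) x@ranks)
#' @rdname accessors
#' @export
setMethod("rankMatrix", "PathwayProfiles", function(x) x@ranks)

#' @rdname accessors
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))
#' @rdname accessors
#' @export
setMethod("drugIds", "RankedProfiles", function(x) x@drug)
#' @rdname accessors
#' @export
setMethod("drugIds", "PathwayProfiles", function(x) x@drug)

#' @rdname accessors
#' @export
setGeneric("replicateIds", function(x) standardGeneric("replicateIds"))
#' @rdname accessors
#' @export
setMethod("replicateIds", "RankedProfiles", function(x) x@replicate)
#' @rdname accessors
#' @export
setMethod("replicateIds", "PathwayProfiles", function(x) x@replicate)

#' @rdname accessors
#' @export
setGeneric("esMatrix", function(x) standardGeneric("esMatrix"))
#' @rdname accessors
#' @export
setMethod("esMatrix", "PathwayProfiles", function(x) x@es)

#' @rdname accessors
#' @export
setGeneric("pvalMatrix", function(x) standardGeneric("pvalMatrix"))
#' @rdname accessors
#' @export
setMethod("pvalMatrix", "PathwayProfiles", function(x) x@pval)

#' @rdname accessors
#' @export
setGeneric("pathwayIds", function(x) standardGeneric("pathwayIds"))
#' @rdname accessors
#' @export
setMethod("pathwayIds", "PathwayProfiles", function(x) rownames(x@es))

#' @rdname accessors
#' @export
setGeneric("viabilityData", function(x) standardGeneric("viabilityData"))
#' @rdname accessors
#' @export
setMethod("viabilityData", "ViabilityExperiment", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("treatmentMeta", function(x) standardGeneric("treatmentMeta"))
#' @rdname accessors
#' @export
setMethod("treatmentMeta", "ViabilityExperiment", function(x) x@treatments)

#' @rdname accessors
#' @export
setGeneric("treatmentIds", function(x) standardGeneric("treatmentIds"))
#' @rdname accessors
#' @export
setMethod("treatmentIds", "ViabilityExperiment",
  function(x) unique(x@data$treatment_id))

#' @rdname accessors
#' @export
setGeneric("cellLines", function(x) standardGeneric("cellLines"))
#' @rdname accessors
#' @export
setMethod("cellLines", "ViabilityExperiment",
  function(x) unique(x@data$cell_line))

#' @rdname accessors
#' @export
setGeneric("mutationMatrix", function(x) standardGeneric("mutationMatrix"))
#' @rdname accessors
#' @export
setMethod("mutationMatrix", "ViabilityExperiment", function(x) x@mutations)

#' @rdname accessors
#' @export
setGeneric("expressionMatrix", function(x) standardGeneric("expressionMatrix"))
#' @rdname accessors
#' @export
setMethod("expressionMatrix", "ViabilityExperiment", function(x) x@expression)

#' @rdname accessors
#' @export
setGeneric("candidateCounts", function(x) standardGeneric("candidateCounts"))
#' @rdname accessors
#' @export
setMethod("candidateCounts", "MergedCandidates", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("candidateMinP", function(x) standardGeneric("candidateMinP"))
#' @rdname accessors
#' @export
setMethod("candidateMinP", "MergedCandidates", function(x) x@minP)

#' @rdname accessors
#' @export
setGeneric("keptDrugs", function(x) standardGeneric("keptDrugs"))
#' @rdname accessors
#' @export
setMethod("keptDrugs", "MergedCandidates", function(x) x@kept)

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' Extract one gene set (its member genes) by id
#' @param x A \code{GeneSetCollection}.
#' @param i A set id or index.
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCollection", function(object) {
  sizes <- vapply(object@sets, length, integer(1))
  cat(sprintf("GeneSetCollection with %d set(s)", length(object@sets)))
  if (length(sizes))
    cat(sprintf(" (sizes %d..%d)", min(sizes), max(sizes)))
  if (length(object@universe))
    cat(sprintf(", bound to a universe of %d genes", length(object@universe)))
  cat("\n")
  src <- table(object@info$source)
  if (length(src))
    cat("  sources:", paste(sprintf("%s=%d", names(src), src),
      collapse = ", "), "\n")
})

setMethod("show", "RankedProfiles", function(object) {
  cat(sprintf(
    "RankedProfiles: %d genes x %d instance(s), %d drug(s)\n",
    nrow(object@ranks), ncol(object@ranks), length(unique(object@drug))))
})

setMethod("show", "PathwayProfiles", function(object) {
  lvl <- if (all(is.na(object@replicate))) "drug-level" else "instance-level"
  cat(sprintf("PathwayProfiles (%s): %d pathway(s) x %d column(s)\n",
    lvl, nrow(object@es), ncol(object@es)))
  if (all(is.na(object@pval))) cat("  p-values: absent (no permutations)\n")
})

setMethod("show", "ViabilityExperiment", function(object) {
  cat(sprintf(paste0(
    "ViabilityExperiment: %d value(s), %d treatment(s), %d cell line(s)\n"),
    nrow(object@data), length(unique(object@data$treatment_id)),
    length(unique(object@data$cell_line))))
  nser <- nrow(unique(object@data[, c("treatment_id", "screen_dataset_id")]))
  cat(sprintf("  %d treatment series; %d mutation gene(s); %d expression gene(s)\n",
    nser, ncol(object@mutations), nrow(object@expression)))
})

setMethod("show", "MergedCandidates", function(object) {
  cat(sprintf(
    "MergedCandidates: %d drug(s) counted, %d kept at cutoff >= %g\n",
    length(object@counts), length(object@kept), object@cutoff))
  if (length(object@counts)) {
    h <- table(object@counts)
    cat("  co-occurrence histogram:",
      paste(sprintf("%s list(s): %d", names(h), as.integer(h)),
        collapse = "; "), "\n")
  }
})

setMethod("show", "ScreenConfig", function(object) {
  cat("ScreenConfig\n")
  cat(sprintf("  risk genes: %s\n", paste(object@riskGenes, collapse = ", ")))
  cat(sprintf("  reference: %s\n", object@reference))
  cat(sprintf(
    "  alphaList=%g cutoff=%g alphaScreen=%g nPerm=%d seed=%d\n",
    object@alphaList, object@cutoff, object@alphaScreen,
    as.integer(object@nPerm), as.integer(object@seed)))
})
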