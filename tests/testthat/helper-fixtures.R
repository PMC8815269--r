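# Small fixtures built in code.

# Drug-level PathwayProfiles from an es matrix (pathways x drugs).
makePep <- function(es) {
  ranks <- apply(-es, 2L, function(v) {
    r <- integer(length(v)); r[order(v, rownames(es))] <- seq_along(v); r
  })
  dimnames(ranks) <- dimnames(es)
  storage.mode(ranks) <- "integer"
  methods::new("PathwayProfiles", es = es, pval = es * NA_real_,
    ranks = ranks, drug = colnames(es),
    replicate = rep(NA_character_, ncol(es)))
}

# Instance-level PathwayProfiles directly from rank columns.
makePepFromRanks <- function(ranks, drug, replicate) {
  P <- nrow(ranks)
  es <- apply(ranks, 2L, function(r) (P + 1 - r) / P * 2 - 1)
  dimnames(es) <- dimnames(ranks)
  storage.mode(ranks) <- "integer"
  methods::new("PathwayProfiles", es = es, pval = es * NA_real_,
    ranks = ranks, drug = drug, replicate = replicate)
}

# Long viability data.frame from a treatments x lines matrix.
longFromMatrix <- function(m, dataset = "S1") {
  data.frame(
    treatment_id = rep(rownames(m), times = ncol(m)),
    cell_line = rep(colnames(m), each = nrow(m)),
    screen_dataset_id = dataset,
    sensitivity = as.vector(m),
    stringsAsFactors = FALSE)
}

tmpFile <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
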