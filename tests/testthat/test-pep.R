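# A ranking where the planted pathway's members occupy the top ranks.
plantedRanking <- function(n, members, genes) {
  ranking <- integer(n)
  names(ranking) <- genes
  others <- setdiff(genes, members)
  ranking[members] <- seq_along(members)
  ranking[others] <- length(members) + seq_along(others)
  ranking
}

test_that("profileToPep scores, ranks and skips as contracted", {
  genes <- sprintf("g%02d", 1:20)
  gsc <- geneSetCollection(list(
    TOP = genes[1:4], MID = genes[9:12], OUT = c("x1", "x2")))
  ranking <- stats::setNames(1:20, genes)

  expect_warning(expect_warning(
    pep <- profileToPep(ranking, gsc, nPerm = 0),
    "outside the universe"), "no in-universe members")
  # permutation-free mode: p absent, ranks defined
  expect_true(all(is.na(pep$p)))
  expect_identical(sort(pep$rank), seq_len(nrow(pep)))
  expect_identical(pep$pathway_id[pep$rank == 1], "TOP")
  expect_equal(pep$es[pep$pathway_id == "TOP"], ksStatistic(1:4, 20))
})

test_that("a planted top pathway attains rank 1 and the minimum p", {
  genes <- sprintf("g%02d", 1:30)
  gsc <- suppressWarnings(geneSetCollection(
    list(PLANT = genes[1:5], RAND1 = genes[c(3, 11, 20, 28)],
         RAND2 = genes[c(7, 14, 22)]), universe = genes))
  ranking <- stats::setNames(1:30, genes)
  nPerm <- 199
  pep <- profileToPep(ranking, gsc, nPerm = nPerm, seed = 5)
  row <- pep[pep$pathway_id == "PLANT", ]
  expect_identical(row$rank, 1L)
  expect_equal(row$p, 1 / (nPerm + 1))
})

test_that("identical member positions tie and resolve by pathway id", {
  genes <- sprintf("g%02d", 1:10)
  gsc <- suppressWarnings(geneSetCollection(
    list(B = genes[1:3], A = genes[1:3], C = genes[5:7]),
    universe = genes))
  pep <- profileToPep(stats::setNames(1:10, genes), gsc, nPerm = 0)
  esA <- pep$es[pep$pathway_id == "A"]
  esB <- pep$es[pep$pathway_id == "B"]
  expect_identical(esA, esB)
  expect_lt(pep$rank[pep$pathway_id == "A"],
    pep$rank[pep$pathway_id == "B"])
})

test_that("computePeps is bit-identical under a fixed seed", {
  co <- genCorpus(nGenes = 120, nPathways = 12, setSize = c(5, 10),
    nDrugs = 4, replicates = 2, nRiskGenes = 2, nActiveDrugs = 1,
    seed = 3)
  p1 <- computePeps(co$profiles, co$collection, nPerm = 99, seed = 11)
  p2 <- computePeps(co$profiles, co$collection, nPerm = 99, seed = 11)
  expect_identical(p1, p2)
  expect_true(all(pvalMatrix(p1) > 0 & pvalMatrix(p1) <= 1))
})

test_that("replicate aggregation keeps single profiles and merges ranks", {
  ranks <- matrix(c(1L, 2L, 3L), 3,
    dimnames = list(c("PA", "PB", "PC"), "d1::r1"))
  pep <- makePepFromRanks(ranks, "d1", "r1")
  agg <- aggregateReplicates(pep)
  expect_identical(unname(rankMatrix(agg)[, 1]), c(1L, 2L, 3L))
  expect_identical(esMatrix(agg)[, 1], esMatrix(pep)[, 1])

  # (1,3) and (3,1) around a constant rank-2 pathway: all means tie at 2,
  # so the merged order falls back to pathway id
  ranks2 <- matrix(c(1L, 2L, 3L, 3L, 2L, 1L), 3,
    dimnames = list(c("PA", "PB", "PC"), c("d1::r1", "d1::r2")))
  agg2 <- aggregateReplicates(makePepFromRanks(ranks2, c("d1", "d1"),
    c("r1", "r2")))
  expect_identical(rankMatrix(agg2)[, "d1"],
    c(PA = 1L, PB = 2L, PC = 3L))
  expect_true(all(is.na(pvalMatrix(agg2))))
})

test_that("aggregation refuses mixed drugs or mismatched pathways", {
  r1 <- matrix(1:3, 3, dimnames = list(c("PA", "PB", "PC"), "d1::r1"))
  r2 <- matrix(1:3, 3, dimnames = list(c("PX", "PY", "PZ"), "d1::r2"))
  p1 <- makePepFromRanks(r1, "d1", "r1")
  p2 <- makePepFromRanks(r2, "d1", "r2")
  expect_error(aggregateReplicates(list(p1, p2)), "mismatched pathway")
  p3 <- makePepFromRanks(r1, "d2", "r1")
  expect_error(aggregateReplicates(list(p1, p3)), "single drug")
  # single replicate: same ranks, columns renamed to the drug id
  agg1 <- aggregateReplicates(list(p1))
  expect_identical(unname(rankMatrix(agg1)), unname(p1@ranks))
  expect_identical(colnames(rankMatrix(agg1)), "d1")
})

test_that("a drug ranking the query pathways on top dominates the list", {
  P <- 20
  ids <- sprintf("P%02d", 1:P)
  withr::with_seed(9, {
    ranks <- cbind(
      best = 1:P,
      other1 = sample(P), other2 = sample(P), other3 = sample(P))
  })
  rownames(ranks) <- ids
  colnames(ranks) <- c("best::1", "o1::1", "o2::1", "o3::1")
  pep <- makePepFromRanks(ranks, c("best", "o1", "o2", "o3"),
    rep(NA_character_, 4))
  query <- ids[1:4]
  dl <- rankDrugsForPathwaySet(pep, query, nPerm = 199, seed = 2)
  expect_identical(dl$drug_id[1], "best")
  expect_equal(dl$es[1], max(abs(dl$es)))
  expect_equal(dl$p[1], min(dl$p))
  expect_lt(dl$p[1], 0.05)
  # sorted by ascending p
  expect_true(!is.unsorted(dl$p))
})

test_that("degenerate or foreign queries are rejected", {
  ranks <- matrix(c(1:3, 3:1), 3,
    dimnames = list(c("PA", "PB", "PC"), c("d1::1", "d2::1")))
  pep <- makePepFromRanks(ranks, c("d1", "d2"), rep(NA_character_, 2))
  expect_error(rankDrugsForPathwaySet(pep, character()), "non-empty")
  expect_error(rankDrugsForPathwaySet(pep, c("PA", "PQ")), "not in")
  expect_error(rankDrugsForPathwaySet(pep, c("PA", "PB", "PC")),
    "degenerate")
  inst <- makePepFromRanks(ranks, c("d1", "d1"), c("r1", "r2"))
  expect_error(rankDrugsForPathwaySet(inst, "PA"), "drug-level")
})

test_that("PEP stores round-trip through the TSV layout", {
  co <- genCorpus(nGenes = 80, nPathways = 8, setSize = c(4, 8),
    nDrugs = 3, replicates = 2, nRiskGenes = 2, nActiveDrugs = 1,
    seed = 21)
  pep <- computePeps(co$profiles, co$collection, nPerm = 49, seed = 1)
  dir <- file.path(tempfile(), "store")
  writePepStore(pep, dir)
  back <- readPepStore(dir)
  expect_equal(esMatrix(back), esMatrix(pep))
  expect_equal(pvalMatrix(back), pvalMatrix(pep))
  expect_identical(rankMatrix(back), rankMatrix(pep))
  expect_identical(drugIds(back), drugIds(pep))
})
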