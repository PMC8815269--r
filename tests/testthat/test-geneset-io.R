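test_that("GMT parsing handles toy files, duplicates and malformed lines", {
  f <- tmpFile(c(
    "S1\tfirst set\tg1\tg2\tg3",
    "S2\tsecond set\tg1\tg4\tg5\tg6\tg7"), ".gmt")
  gsc <- readGmt(f)
  expect_s4_class(gsc, "GeneSetCollection")
  expect_identical(setIds(gsc), c("S1", "S2"))
  expect_identical(lengths(geneSets(gsc)), c(S1 = 3L, S2 = 5L))
  expect_identical(setInfo(gsc)$name, c("first set", "second set"))

  # duplicate member within a line counts once, with a warning
  fdup <- tmpFile("S1\tdup\tg1\tg2\tg1", ".gmt")
  expect_warning(g2 <- readGmt(fdup), "duplicate")
  expect_identical(g2[["S1"]], c("g1", "g2"))

  # malformed line -> parse error naming the line number
  fbad <- tmpFile(c("S1\tok\tg1", "S2\tonly-description"), ".gmt")
  expect_error(readGmt(fbad), "line 2")

  # duplicate set id -> error
  fid <- tmpFile(c("S1\ta\tg1", "S1\tb\tg2"), ".gmt")
  expect_error(readGmt(fid), "duplicate set id")

  # empty file -> empty collection with a warning
  fempty <- tmpFile(character(), ".gmt")
  expect_warning(g0 <- readGmt(fempty), "empty")
  expect_length(g0, 0)
})

test_that("GMT round-trip reproduces ids and member sets", {
  withr::with_seed(42, {
    for (i in 1:10) {
      nset <- sample(1:8, 1)
      sets <- lapply(seq_len(nset), function(j)
        sample(sprintf("g%03d", 1:50), sample(2:10, 1)))
      names(sets) <- sprintf("SET%02d", seq_len(nset))
      gsc <- geneSetCollection(sets)
      f <- tempfile(fileext = ".gmt")
      writeGmt(gsc, f)
      back <- readGmt(f)
      expect_identical(setIds(back), setIds(gsc))
      expect_identical(geneSets(back), geneSets(gsc))
    }
  })
})

test_that("binding a universe drops foreign members and empty sets", {
  gsc <- geneSetCollection(list(A = c("g1", "g2", "gX"), B = "gY"))
  expect_warning(expect_warning(
    bound <- bindUniverse(gsc, c("g1", "g2", "g3")),
    "outside the universe"), "no in-universe members")
  expect_identical(setIds(bound), "A")
  expect_identical(bound[["A"]], c("g1", "g2"))
})

test_that("pathwaysOfGene returns exactly the containing sets", {
  gsc <- geneSetCollection(list(P1 = c("g1", "g2"), P2 = "g2"))
  expect_identical(pathwaysOfGene(gsc, "g2"), c("P1", "P2"))
  expect_identical(pathwaysOfGene(gsc, "g1"), "P1")
  expect_length(pathwaysOfGene(gsc, "absent"), 0)
})

test_that("rank matrices are validated as permutations", {
  f <- tmpFile(c("gene\td1::r1",
    paste(sprintf("g%02d", 1:10), sample(10), sep = "\t")), ".tsv")
  rp <- readRankMatrix(f, mode = "ranks")
  expect_s4_class(rp, "RankedProfiles")
  expect_identical(drugIds(rp), "d1")
  expect_identical(replicateIds(rp), "r1")

  fbad <- tmpFile(c("gene\td1::r1",
    paste(sprintf("g%02d", 1:3), c(1, 3, 3), sep = "\t")), ".tsv")
  expect_error(readRankMatrix(fbad, mode = "ranks"), "permutation")

  fnum <- tmpFile(c("gene\td1::r1", "g1\t1", "g2\tnope", "g3\t3"), ".tsv")
  expect_error(readRankMatrix(fnum, mode = "ranks"))
})

test_that("score columns convert with average-tie then identifier order", {
  f <- tmpFile(c("gene\td1::r1", "a\t2.0", "b\t2.0", "c\t-1.0"), ".tsv")
  rp <- readRankMatrix(f, mode = "scores")
  expect_identical(rankMatrix(rp)[, 1],
    c(a = 1L, b = 2L, c = 3L))
})

test_that("every accepted column satisfies the permutation invariant", {
  withr::with_seed(7, {
    for (i in 1:20) {
      n <- sample(3:30, 1)
      scores <- matrix(rnorm(n * 2), n,
        dimnames = list(sprintf("g%03d", 1:n), c("a::1", "b::1")))
      rp <- rankedProfiles(scoresToRanks(scores))
      for (j in 1:2)
        expect_identical(sort(unname(rankMatrix(rp)[, j])), seq_len(n))
    }
  })
})

test_that("viability tables keep missingness and replicate datasets", {
  # 3 long rows over 2 treatments x 2 lines: one missing cell preserved
  f <- tmpFile(c("treatment_id,name,cell_line,value,screen_dataset_id",
    "t1,T one,c1,0.5,S1", "t1,T one,c2,1.5,S1", "t2,T two,c1,-0.2,S1"),
    ".csv")
  vm <- readViabilityTable(f)
  m <- sensitivityMatrix(vm)
  expect_identical(dim(m), c(2L, 2L))
  expect_true(is.na(m["t2", "c2"]))
  expect_identical(sum(!is.na(m)), 3L)

  # same treatment under two screen datasets -> two series retained
  f2 <- tmpFile(c("treatment_id,name,cell_line,value,screen_dataset_id",
    "t1,T,c1,0.5,A", "t1,T,c1,0.6,B"), ".csv")
  vm2 <- readViabilityTable(f2)
  expect_identical(nrow(sensitivityMatrix(vm2, by = "series")), 2L)

  # duplicate triple -> error
  f3 <- tmpFile(c("treatment_id,name,cell_line,value,screen_dataset_id",
    "t1,T,c1,0.5,A", "t1,T,c1,0.6,A"), ".csv")
  expect_error(readViabilityTable(f3), "one entry per")

  # empty table -> error
  f4 <- tmpFile("treatment_id,name,cell_line,value,screen_dataset_id",
    ".csv")
  expect_error(readViabilityTable(f4), "empty")
})

test_that("non-finite values are dropped with a warning, finite count kept", {
  f <- tmpFile(c("treatment_id,name,cell_line,value,screen_dataset_id",
    "t1,T,c1,0.5,S1", "t1,T,c2,NA,S1", "t1,T,c3,Inf,S1",
    "t2,T2,c1,1.25,S1"), ".csv")
  expect_warning(vm <- readViabilityTable(f), "non-finite")
  expect_identical(nrow(viabilityData(vm)), 2L)
  expect_setequal(viabilityData(vm)$sensitivity, c(0.5, 1.25))
})

test_that("the viability-lfc convention is negated at ingest", {
  f <- tmpFile(c("treatment_id,name,cell_line,value,screen_dataset_id",
    "t1,T,c1,-2,S1"), ".csv")
  vm <- readViabilityTable(f, value = "viability_lfc")
  expect_identical(viabilityData(vm)$sensitivity, 2)
})
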