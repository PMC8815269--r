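test_that("sensitivity from barcode counts follows the -log2 ratio", {
  expect_equal(sensitivityFromCounts(100, 100), 0)
  expect_equal(sensitivityFromCounts(50, 200, pseudocount = 0), 2)
  # pseudocount guards a zero treatment pool
  s <- sensitivityFromCounts(0, 100, pseudocount = 0.5)
  expect_true(is.finite(s) && s > 0)
  expect_error(sensitivityFromCounts(-1, 10), "non-negative")
  expect_error(sensitivityFromCounts(0, 10, pseudocount = 0), "positive")
})

test_that("sensitivity is antisymmetric under swapping pools (pc = 0)", {
  withr::with_seed(1, {
    a <- runif(50, 1, 1000); b <- runif(50, 1, 1000)
  })
  expect_equal(sensitivityFromCounts(a, b, 0),
    -sensitivityFromCounts(b, a, 0))
})

test_that("mean sensitivity ranking computes t-intervals", {
  m <- rbind(t1 = c(1, 2, 3), t2 = c(5, 5, 5))
  colnames(m) <- paste0("c", 1:3)
  vm <- viabilityExperiment(longFromMatrix(m))
  rk <- meanSensitivityRanking(vm)
  expect_identical(rk$treatment_id, c("t2", "t1"))
  r1 <- rk[rk$treatment_id == "t1", ]
  expect_equal(r1$mean, 2)
  expect_equal(r1$sd, 1)
  # t(0.975, 2) = 4.3027: CI = 2 -+ 4.3027/sqrt(3)
  expect_equal(r1$ci_lo, -0.48414, tolerance = 1e-4)
  expect_equal(r1$ci_hi, 4.48414, tolerance = 1e-4)
  # constant values: zero dispersion, zero-width interval
  r2 <- rk[rk$treatment_id == "t2", ]
  expect_equal(r2$sd, 0)
  expect_equal(r2$ci_lo, r2$ci_hi)
})

test_that("treatments with a single value are excluded with a warning", {
  d <- data.frame(treatment_id = c("a", "a", "b"),
    cell_line = c("c1", "c2", "c1"), screen_dataset_id = "S1",
    sensitivity = c(1, 2, 5))
  vm <- viabilityExperiment(d)
  expect_warning(rk <- meanSensitivityRanking(vm), "fewer than 2")
  expect_identical(rk$treatment_id, "a")
})

test_that("Mann-Whitney against a reference matches hand enumeration", {
  m <- rbind(trt = c(3, 4, 5, NA, NA), ref = c(1, 2, NA, NA, NA))
  colnames(m) <- paste0("c", 1:5)
  d <- longFromMatrix(m); d <- d[is.finite(d$sensitivity), ]
  vm <- viabilityExperiment(d)
  # complete separation: exact one-sided p = 1 / C(5,2) = 0.1
  r <- mannWhitneyVsReference(vm, "trt", "ref", alternative = "greater")
  expect_equal(r$p, 0.1)
  expect_equal(r$u_stat, 6)
  # identical series: two-sided p ~ 1
  m2 <- rbind(a = 1:6, b = 1:6); colnames(m2) <- paste0("c", 1:6)
  vm2 <- viabilityExperiment(longFromMatrix(m2))
  r2 <- mannWhitneyVsReference(vm2, "a", "b", alternative = "two_sided")
  expect_gte(r2$p, 0.9)
})

test_that("Mann-Whitney agrees exactly with the labeling oracle", {
  withr::with_seed(77, {
    for (i in 1:25) {
      n <- sample(2:6, 1); m <- sample(2:6, 1)
      x <- rnorm(n); y <- rnorm(m)
      for (alt in c("greater", "two_sided")) {
        got <- pepScreen:::mwTest(x, y, alt)$p
        expect_equal(got, mwOracle(x, y, alt), tolerance = 1e-12)
      }
    }
  })
})

test_that("discordant replicate datasets are flagged or excluded", {
  base <- c(0.1, 0.9, 0.4, 0.7, 0.2)
  m <- rbind(good = base, bad = base, lone = base)
  colnames(m) <- paste0("c", 1:5)
  m2 <- rbind(good = base + 0.01, bad = -base)
  colnames(m2) <- paste0("c", 1:5)
  d <- rbind(longFromMatrix(m, "S1"), longFromMatrix(m2, "S2"))
  vm <- viabilityExperiment(d)
  res <- replicateConcordanceFilter(vm, rMin = 0.3)
  expect_identical(res$excluded, "bad")
  expect_false("good" %in% res$excluded)
  expect_false("lone" %in% res$excluded)

  # fewer than 3 shared lines: flagged for review, not excluded
  mS2 <- rbind(good = c(1, 2), bad = c(2, 1))
  colnames(mS2) <- c("c8", "c9")
  vm2 <- viabilityExperiment(rbind(
    longFromMatrix(m[1:2, , drop = FALSE], "S1"),
    longFromMatrix(mS2, "S2")))
  res2 <- replicateConcordanceFilter(vm2, rMin = 0.3)
  expect_length(res2$excluded, 0)
  expect_setequal(res2$review, c("good", "bad"))
})

test_that("direct screen counts higher-mean and significant series", {
  withr::with_seed(5, {
    lines <- paste0("c", 1:12)
    ref <- rnorm(12, 0, 0.3)
    potent <- ref + 2 + rnorm(12, 0, 0.1)
    flat <- rnorm(12, 0, 0.3)
    m <- rbind(REF = ref, strong = potent, idle = flat)
    colnames(m) <- lines
  })
  vm <- viabilityExperiment(longFromMatrix(m))
  rep <- directScreen(vm, "REF", alpha = 1e-3)
  expect_s3_class(rep, "DirectScreenReport")
  expect_identical(rep$n_treatments, 3L)
  expect_true(rep$n_significant <= rep$n_higher_mean)
  expect_identical(rep$summaries$treatment_id[1], "strong")
  expect_lt(rep$summaries$p_vs_ref[1], 1e-3)
  expect_equal(rep$frac_higher,
    rep$n_higher_mean / (rep$n_treatments - 1))

  # a single treatment identical to the reference: nothing is higher
  m2 <- rbind(REF = 1:5, same = 1:5); colnames(m2) <- paste0("c", 1:5)
  vm2 <- viabilityExperiment(longFromMatrix(m2))
  rep2 <- directScreen(vm2, "REF")
  expect_identical(rep2$n_higher_mean, 0L)
  expect_error(directScreen(viabilityExperiment(
    longFromMatrix(m2[1, , drop = FALSE])), "REF"), "no treatment")
})

test_that("replicate datasets count as separate treatments in the screen", {
  m <- rbind(REF = c(1, 2, 3, 4), t1 = c(2, 3, 4, 5))
  colnames(m) <- paste0("c", 1:4)
  d <- rbind(longFromMatrix(m), longFromMatrix(m[2, , drop = FALSE], "S2"))
  vm <- viabilityExperiment(d)
  rep <- directScreen(vm, "REF")
  expect_identical(rep$n_treatments, 3L)  # REF + t1@S1 + t1@S2
})

test_that("mutation association is a two-sided exact test on toy data", {
  m <- rbind(trt = c(3, 4, 5, 1, 2)); colnames(m) <- paste0("c", 1:5)
  mut <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE), 5,
    dimnames = list(paste0("c", 1:5), "TP53"))
  vm <- viabilityExperiment(longFromMatrix(m), mutations = mut)
  expect_equal(mutationAssociation(vm, "trt", "TP53"), 0.2)
  mutAll <- mut; mutAll[] <- TRUE
  vmAll <- viabilityExperiment(longFromMatrix(m), mutations = mutAll)
  expect_error(mutationAssociation(vmAll, "trt", "TP53"), "wild-type")
  expect_error(mutationAssociation(vm, "trt", "EGFR"), "not in the")
})

test_that("differential expression recovers planted genes and orders output", {
  withr::with_seed(66, {
    G <- 100; n <- 20
    expr <- matrix(rnorm(G * n), G,
      dimnames = list(sprintf("gene%03d", 1:G), sprintf("c%02d", 1:n)))
    sens <- setNames(sort(rnorm(n), decreasing = TRUE), colnames(expr))
    groups <- setNames(seq_len(n) <= 10, names(sens))  # top half sensitive
    planted <- sprintf("gene%03d", 1:5)
    expr[planted, names(groups)[groups]] <-
      expr[planted, names(groups)[groups]] + 3
  })
  de <- deGenes(expr, groups, alpha = 1e-3, ordering = sens)
  expect_setequal(de$genes, planted)
  # columns follow descending sensitivity
  expect_identical(colnames(de$matrix), names(sens))
  expect_identical(nrow(de$matrix), 5L)
})

test_that("on label permutations the DE rate stays near alpha", {
  withr::with_seed(99, {
    G <- 400; n <- 20
    expr <- matrix(rnorm(G * n), G,
      dimnames = list(sprintf("g%03d", 1:G), sprintf("c%02d", 1:n)))
    hits <- replicate(5, {
      groups <- setNames(sample(c(rep(TRUE, 10), rep(FALSE, 10))),
        colnames(expr))
      length(deGenes(expr, groups, alpha = 0.05)$genes)
    })
  })
  expect_lt(mean(hits) / G, 0.05 + 0.03)
})

test_that("zero-variance genes yield p = 1, not an error", {
  expr <- rbind(flat = rep(1, 8), var = rnorm(8))
  colnames(expr) <- paste0("c", 1:8)
  groups <- setNames(rep(c(TRUE, FALSE), each = 4), colnames(expr))
  de <- deGenes(expr, groups, alpha = 0.9999)
  expect_equal(unname(de$p["flat"]), 1)
})

test_that("annotation and sensitivity correlation matrices match by hand", {
  mem <- rbind(d1 = c(1, 0, 1, 0), d2 = c(1, 0, 1, 0), d3 = c(0, 1, 0, 1))
  m <- rbind(d1 = c(1, 2, 3), d2 = c(3, 2, 1), d3 = c(1, 2, 3))
  colnames(m) <- paste0("c", 1:3)
  vm <- viabilityExperiment(longFromMatrix(m))
  res <- drugCorrelationMatrices(mem, vm)
  expect_equal(res$corr_go["d1", "d2"], 1)
  expect_equal(res$corr_go["d1", "d3"], -1)
  expect_equal(res$corr_sens["d1", "d2"], -1)
  expect_equal(res$corr_sens["d1", "d3"], 1)
  # discrepancy for d1: mean(|1 - (-1)|, |-1 - 1|) = 2
  expect_equal(unname(res$discrepancy["d1"]), 2)
  # constant sensitivity profile -> undefined correlations reported NA
  m2 <- rbind(d1 = c(1, 1, 1), d2 = c(1, 2, 3), d3 = c(2, 1, 3))
  colnames(m2) <- paste0("c", 1:3)
  res2 <- drugCorrelationMatrices(mem,
    viabilityExperiment(longFromMatrix(m2)))
  expect_true(all(is.na(res2$corr_sens["d1", ])))
})
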