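# Uridylation summaries, binned correlations and the two hypothesis tests.

callsFromFixture <- function(id, seed = 1) {
  comp <- builtinComposition(id)
  anchor <- builtinAnchors()[[compositionGene(comp)]]
  reads <- simulateTailReads(comp, anchor, seed = seed)
  callFastq(reads, TailCallerParam(builtinAnchors()))
}

test_that("fixture summaries reproduce the printed uridylation frequencies", {
  cs <- callsFromFixture("zc_wt_lps")
  sm <- summarizeUridylation(cs, "zc_wt_lps")
  expect_identical(totalCalled(sm), 1067L)
  rf <- roundedFrequencies(sm)
  expect_identical(unname(rf["mono_U"]), 14)
  expect_identical(unname(rf["oligo_U"]), 24)
  expect_identical(unname(summaryCounts(sm)["C_add"]), 144L)
  expect_identical(unname(summaryCounts(sm)["G_add"]), 40L)
})

test_that("summary frequencies recompute exactly from counts", {
  cs <- callsFromFixture("zc_ko", seed = 4)
  sm <- summarizeUridylation(cs, "zc_ko")
  expect_equal(unname(classFrequencies(sm)),
               unname(100 * summaryCounts(sm) / totalCalled(sm)),
               tolerance = 1e-12)
  expect_identical(unname(summaryCounts(sm)["any_U"]),
                   unname(summaryCounts(sm)["mono_U"] +
                            summaryCounts(sm)["oligo_U"]))
  base <- setdiff(names(summaryCounts(sm)), "any_U")
  expect_identical(sum(summaryCounts(sm)[base]), totalCalled(sm))
})

test_that("summarize is permutation-invariant", {
  calls <- simulateCallProfiles(400, 0.12, 0.2, seed = 8)
  perm <- calls[sample(nrow(calls)), ]
  expect_identical(summaryCounts(summarizeUridylation(calls)),
                   summaryCounts(summarizeUridylation(perm)))
})

test_that("degenerate summaries are flagged rather than failing", {
  one <- S4Vectors::DataFrame(read_id = "r", gene = "Zc3h12a",
                              status = "called", orientation = "sense",
                              polyA_len = 5L, additions = "",
                              addition_class = "none")
  sm <- summarizeUridylation(one)
  expect_identical(unname(classFrequencies(sm)["none"]), 100)
  expect_true(all(classFrequencies(sm)[c("mono_U", "oligo_U")] == 0))

  none <- one[integer(0), ]
  sm0 <- summarizeUridylation(none)
  expect_false(sm0@defined)
  expect_true(all(is.na(classFrequencies(sm0))))
})

test_that("mixed tails count toward any_U only when requested", {
  calls <- S4Vectors::DataFrame(
    read_id = sprintf("r%d", 1:4), gene = "Zc3h12a", status = "called",
    orientation = "sense", polyA_len = c(5L, 6L, 7L, 8L),
    additions = c("U", "UC", "GC", ""),
    addition_class = c("mono_U", "mixed", "mixed", "none"))
  expect_identical(unname(summaryCounts(summarizeUridylation(calls))["any_U"]),
                   1L)
  expect_identical(
    unname(summaryCounts(summarizeUridylation(calls,
                                              countMixedAsU = TRUE))["any_U"]),
    2L)
})

test_that("pearsonTest matches trivial and oracle cases", {
  expect_equal(pearsonTest(c(1, 2, 3), c(2, 4, 6))$r, 1, tolerance = 1e-12)
  expect_equal(pearsonTest(c(1, 2, 3), c(6, 4, 2))$r, -1, tolerance = 1e-12)
  got <- pearsonTest(c(1, 2, 3, 4), c(1, 3, 2, 5))
  want <- oraclePearson(c(1, 2, 3, 4), c(1, 3, 2, 5))
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_error(pearsonTest(rep(1, 5), 1:5), "degenerate")
  expect_error(pearsonTest(1:2, 1:2), "length")
})

test_that("studentTTest matches trivial and oracle cases", {
  same <- studentTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  shift <- studentTTest(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shift$p, 0.01)
  want <- oracleStudentT(c(1, 2, 3), c(11, 12, 13))
  expect_equal(shift$t, want$t, tolerance = 1e-12)
  expect_equal(shift$p, want$p, tolerance = 1e-12)
  expect_error(studentTTest(c(0, 0), c(0, 0)), "degenerate")
  expect_error(studentTTest(1, c(1, 2)), "at least 2")
})

test_that("binByPolyA detects a length-dependent oligo-U probability", {
  calls <- simulateCallProfiles(2000, probMono = 0.1,
                                probOligo = function(L) 0.4 - 0.0035 * L,
                                polyARange = c(0L, 100L), seed = 11)
  bn <- binByPolyA(calls, binWidth = 10, maxEdge = 75, minReads = 10)
  expect_true(corOligo(bn)$defined)
  expect_lt(corOligo(bn)$r, 0)
  expect_lt(corOligo(bn)$p, 0.05)
  # per-read point-biserial mode agrees on the sign
  pr <- binByPolyA(calls, perRead = TRUE)
  expect_lt(corOligo(pr)$r, 0)
})

test_that("binByPolyA flags too few qualifying bins instead of erroring", {
  calls <- simulateCallProfiles(60, 0.1, 0.2, polyARange = c(0L, 15L),
                                seed = 2)
  bn <- binByPolyA(calls, binWidth = 10, maxEdge = 75, minReads = 10)
  expect_false(corOligo(bn)$defined)
  expect_true(is.na(corOligo(bn)$r))
})

test_that("bin bookkeeping partitions the called reads", {
  calls <- simulateCallProfiles(500, 0.1, 0.15, polyARange = c(0L, 150L),
                                seed = 3)
  bn <- binByPolyA(calls, binWidth = 10, maxEdge = 75)
  tb <- binTable(bn)
  expect_identical(sum(tb$n_reads), 500L)
  expect_true(all(tb$bin_lo == seq(0, 75, by = 10)))
  expect_true(is.infinite(tb$bin_hi[nrow(tb)]))
  freqs <- c(tb$mono_U_pct, tb$oligo_U_pct)
  expect_true(all(is.na(freqs) | (freqs >= 0 & freqs <= 100)))
})

test_that("compareConditions contrasts fixture summaries", {
  smA <- summarizeUridylation(callsFromFixture("zc_wt_lps"), "zc_wt_lps")
  smB <- summarizeUridylation(callsFromFixture("zc_ko_lps"), "zc_ko_lps")
  cmp <- compareConditions(list(smA, smB))
  tab <- cmp$table
  oligo <- tab[tab$class == "oligo_U", ]
  expect_identical(floor(oligo$frequency_pct + 0.5), c(24, 14))
  expect_error(compareConditions(list(smA)), "at least two")
  il6 <- summarizeUridylation(callsFromFixture("il6_wt_lps"), "il6_wt_lps")
  expect_error(compareConditions(list(smA, il6)), "mix genes")

  # identical summaries give zero frequency differences
  cmp2 <- compareConditions(list(smA, smA))
  wide <- split(cmp2$table$frequency_pct, cmp2$table$class)
  expect_true(all(vapply(wide, function(v) diff(v) == 0, logical(1))))
})

test_that("replicate summaries yield per-class t tests", {
  mk <- function(label, seed) {
    calls <- simulateCallProfiles(300, 0.1, 0.2, seed = seed)
    summarizeUridylation(calls, label)
  }
  sums <- list(mk("a", 1), mk("a", 2), mk("a", 3),
               mk("b", 4), mk("b", 5), mk("b", 6))
  cmp <- compareConditions(sums)
  expect_false(is.null(cmp$tests))
  expect_true(all(c("class", "t", "p") %in% colnames(cmp$tests)))
  expect_true(all(is.na(cmp$tests$p) | (cmp$tests$p >= 0 & cmp$tests$p <= 1)))
})
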