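# Per-read tail calling: anchor/linker location, segmentation, classification.

test_that("findAnchor locates the leftmost tolerant match", {
  a <- zcAnchor()
  seq <- paste0(anchorSeq(a), "AAA")
  hit <- findAnchor(seq, a, 0)
  expect_identical(hit$end0, 28L)
  expect_identical(hit$start0, 0L)

  # one substitution inside the anchor still matches at maxMismatch = 1
  mut <- seq
  substr(mut, 5, 5) <- if (substr(mut, 5, 5) == "A") "C" else "A"
  expect_identical(findAnchor(mut, a, 1)$end0, 28L)

  # two substitutions exceed maxMismatch = 1 (cross-checked by brute force)
  mut2 <- mut
  substr(mut2, 9, 9) <- if (substr(mut2, 9, 9) == "G") "T" else "G"
  expect_null(findAnchor(mut2, a, 1))
  expect_null(naiveHammingSearch(mut2, anchorSeq(a), 1))
})

test_that("findLinker finds full matches and read-end prefixes", {
  lk <- defaultLinker()
  expect_identical(findLinker(paste0("AAAATT", lk), 0)$start0, 6L)
  # read truncated to a 10 nt linker prefix at position 6
  trunc <- paste0("AAAATT", substr(lk, 1, 10))
  hit <- findLinker(trunc, 0, minPrefix = 10)
  expect_identical(hit$start0, 6L)
  expect_identical(hit$matchLen, 10L)
  # absent linker
  expect_null(findLinker(strrep("A", 60), 0))
  # a prefix shorter than minPrefix does not count
  expect_null(findLinker(paste0("AAAATT", substr(lk, 1, 8)), 0,
                         minPrefix = 10))
})

test_that("segmentTail splits poly(A) from the terminal non-A block", {
  expect_identical(segmentTail("AAAAAATT"),
                   list(polyALen = 6L, additions = "UU", impure = FALSE))
  expect_identical(segmentTail("AAAAC"),
                   list(polyALen = 4L, additions = "C", impure = FALSE))
  expect_identical(segmentTail(""),
                   list(polyALen = 0L, additions = "", impure = FALSE))
  expect_identical(segmentTail("AATC"),
                   list(polyALen = 2L, additions = "UC", impure = FALSE))
  # impure poly(A) in strict mode is flagged, not thrown
  expect_true(segmentTail("ATAAAA")$impure)
  # tolerant mode absorbs one interruption per 20 nt into the length
  tol <- segmentTail(paste0(strrep("A", 10), "G", strrep("A", 10), "TT"),
                     strict = FALSE)
  expect_false(tol$impure)
  expect_identical(tol$polyALen, 21L)
  expect_identical(tol$additions, "UU")
})

test_that("classifyAddition implements the class definitions", {
  expect_identical(classifyAddition(""), "none")
  expect_identical(classifyAddition("U"), "mono_U")
  expect_identical(classifyAddition("UU"), "oligo_U")
  expect_identical(classifyAddition("UUU"), "oligo_U")
  expect_identical(classifyAddition("CC"), "C_add")
  expect_identical(classifyAddition("G"), "G_add")
  expect_identical(classifyAddition("UG"), "mixed")
  expect_identical(classifyAddition("T"), "mono_U")  # read-space input
})

test_that("orientRead restores the anchor-bearing strand", {
  param <- bothParam()
  sense <- paste0(anchorSeq(zcAnchor()), "AAAA", defaultLinker())
  o <- orientRead(sense, param)
  expect_identical(o$orientation, "sense")
  expect_identical(o$seq, sense)

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sense)))
  o2 <- orientRead(rc, param)
  expect_identical(o2$orientation, "antisense")
  expect_identical(o2$seq, sense)

  # random reads without the anchor orient nowhere (brute-force verified)
  set.seed(99)
  for (i in 1:10) {
    r <- randomDna(150)
    rrc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
    nearest <- min(naiveBestMismatch(r, anchorSeq(zcAnchor())),
                   naiveBestMismatch(rrc, anchorSeq(zcAnchor())),
                   naiveBestMismatch(r, anchorSeq(il6Anchor())),
                   naiveBestMismatch(rrc, anchorSeq(il6Anchor())))
    if (nearest > 2) expect_null(orientRead(r, param))
  }
})

test_that("callRead composes the stages and sets statuses", {
  param <- bothParam()
  read <- paste0(anchorSeq(zcAnchor()), strrep("A", 12), "TTT",
                 defaultLinker(), "GTCAGT")
  call <- callRead(read, param, "r1")
  expect_identical(call$status, "called")
  expect_identical(call$gene, "Zc3h12a")
  expect_identical(call$polyA_len, 12L)
  expect_identical(call$addition_class, "oligo_U")

  # anchor present but no linker downstream
  noLinker <- paste0(anchorSeq(zcAnchor()), strrep("A", 40), randomDna(40))
  expect_identical(callRead(noLinker, param)$status, "no_linker")

  # Il6 read against a Zc3h12a-only configuration
  il6Read <- paste0(anchorSeq(il6Anchor()), strrep("A", 10), defaultLinker())
  expect_identical(callRead(il6Read, zcOnlyParam())$status, "no_anchor")

  # impure poly(A) segment in strict mode
  impure <- paste0(anchorSeq(zcAnchor()), "AAAGAAAA", "TT", defaultLinker())
  expect_identical(callRead(impure, param)$status, "ambiguous")
})

test_that("callFastq round trips a fixture and counts statuses", {
  comp <- builtinComposition("zc_wt")
  reads <- simulateTailReads(comp, zcAnchor(), seed = 3)
  fq <- tempfile(fileext = ".fastq")
  writeFastq(reads, fq)
  cs <- callFastq(fq, zcOnlyParam())
  expect_identical(length(cs), 466L)
  expect_identical(unname(statusCounts(cs)["called"]), 466L)
  truth <- parseReadTruth(names(reads))
  df <- as.data.frame(tailCalls(cs))
  expect_identical(df$polyA_len, truth$polyA_len)
  expect_identical(df$additions, truth$additions)
  expect_identical(df$addition_class, truth$class)
})

test_that("callFastq handles empty input and reports malformed records", {
  empty <- callFastq(Biostrings::DNAStringSet(), bothParam())
  expect_identical(length(empty), 0L)
  expect_true(all(statusCounts(empty) == 0L))

  emptyFile <- tempfile(fileext = ".fastq")
  file.create(emptyFile)
  expect_identical(length(callFastq(emptyFile, bothParam())), 0L)

  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), bad)
  expect_error(callFastq(bad, bothParam()), "record 2")

  bad2 <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "III"), bad2)
  expect_error(callFastq(bad2, bothParam()), "record 1")
})

test_that("reverse-complementing every read only flips the orientation field", {
  comp <- TailComposition("toy", "Zc3h12a",
                          c(none = 8, mono_U = 6, oligo_U = 6, C_add = 3,
                            G_add = 3))
  reads <- simulateTailReads(comp, zcAnchor(), seed = 21)
  flipped <- Biostrings::reverseComplement(reads)
  names(flipped) <- names(reads)
  a <- as.data.frame(tailCalls(callFastq(reads, zcOnlyParam())))
  b <- as.data.frame(tailCalls(callFastq(flipped, zcOnlyParam())))
  expect_identical(a$status, b$status)
  expect_identical(a$polyA_len, b$polyA_len)
  expect_identical(a$additions, b$additions)
  expect_identical(a$addition_class, b$addition_class)
  expect_true(all(a$orientation == "sense"))
  expect_true(all(b$orientation == "antisense"))
})

test_that("raising the anchor mismatch allowance never loses matched reads", {
  comp <- TailComposition("toy", "Zc3h12a",
                          c(none = 15, mono_U = 10, oligo_U = 10))
  reads <- simulateTailReads(comp, zcAnchor(), seed = 13, errorRate = 0.03)
  matchedAt <- function(mm) {
    param <- TailCallerParam(builtinAnchors()["Zc3h12a"],
                             maxAnchorMismatch = mm)
    df <- as.data.frame(tailCalls(callFastq(reads, param)))
    df$read_id[df$status != "no_anchor"]
  }
  prev <- matchedAt(0)
  for (mm in 1:3) {
    cur <- matchedAt(mm)
    expect_true(all(prev %in% cur), info = paste("mm =", mm))
    prev <- cur
  }
})

test_that("gene assignment breaks ties by mismatch count", {
  # a read carrying the Il6 anchor exactly and the Zc3h12a anchor with two
  # mismatches is assigned to Il6
  zmut <- anchorSeq(zcAnchor())
  substr(zmut, 3, 3) <- "C"; substr(zmut, 7, 7) <- "C"
  read <- paste0(zmut, "AAAA", anchorSeq(il6Anchor()), strrep("A", 8),
                 defaultLinker())
  call <- callRead(read, bothParam())
  expect_identical(call$gene, "Il6")
  expect_identical(call$status, "called")
})
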