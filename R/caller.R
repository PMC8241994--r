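## Per-read tail calling: locate the gene anchor, locate the 3' linker,
## segment the intervening tail into poly(A) and terminal non-templated
## additions, and classify the addition block. This anchor-based filter
## stands in for genome alignment: the anchor is the gene-assignment
## criterion and the linker delimits the RNA 3' terminus.

#' Construct caller parameters
#'
#' Defaults tolerate typical Illumina substitution error without admitting
#' spurious matches: 2 mismatches over a >= 27 nt anchor, 1 over the 17 nt
#' linker, and a 10 nt minimum linker prefix at the read end.
#'
#' @param anchors list of [GeneAnchor-class] objects (or a single one).
#' @param linker linker DNA string.
#' @param maxAnchorMismatch,maxLinkerMismatch Hamming mismatch allowances.
#' @param minLinkerPrefix minimum matched linker prefix (nt, >= 8) when the
#'   read ends inside the linker.
#' @param searchBothStrands also try the reverse complement of each read.
#' @param strictTail strict poly(A) segmentation (see
#'   [TailCallerParam-class]).
#' @return a [TailCallerParam-class].
#' @examples
#' TailCallerParam(builtinAnchors())
#' @export
TailCallerParam <- function(anchors = builtinAnchors(),
                            linker = defaultLinker(),
                            maxAnchorMismatch = 2L, maxLinkerMismatch = 1L,
                            minLinkerPrefix = 10L, searchBothStrands = TRUE,
                            strictTail = TRUE) {
  if (is(anchors, "GeneAnchor")) anchors <- list(anchors)
  if (is.null(names(anchors)))
    names(anchors) <- vapply(anchors, anchorGene, character(1))
  new("TailCallerParam", anchors = anchors, linker = toupper(linker),
      maxAnchorMismatch = as.integer(maxAnchorMismatch),
      maxLinkerMismatch = as.integer(maxLinkerMismatch),
      minLinkerPrefix = as.integer(minLinkerPrefix),
      searchBothStrands = isTRUE(searchBothStrands),
      strictTail = isTRUE(strictTail))
}

setMethod("show", "TailCallerParam", function(object) {
  cat(sprintf(
    "TailCallerParam: %d anchor(s) [%s], linker %s\n  mismatches: anchor <= %d, linker <= %d; min linker prefix %d nt\n  both strands: %s; strict tail: %s\n",
    length(object@anchors),
    paste(vapply(object@anchors, anchorGene, character(1)), collapse = ", "),
    object@linker, object@maxAnchorMismatch, object@maxLinkerMismatch,
    object@minLinkerPrefix, object@searchBothStrands, object@strictTail))
})

#' Locate a gene anchor in a read
#'
#' Leftmost occurrence of the anchor with Hamming distance at most
#' `maxMismatch` (N counts as a mismatch).
#'
#' @param seq read sequence (character, \{A,C,G,T,N\}).
#' @param anchor a [GeneAnchor-class] or plain DNA string.
#' @param maxMismatch mismatch allowance.
#' @return `NULL` when absent, else a list with `start0` and `end0`
#'   (0-based, half-open match coordinates) and `mismatches`.
#' @examples
#' a <- builtinAnchors()$Zc3h12a
#' findAnchor(paste0(anchorSeq(a), "AAA"), a, 0)$end0  # 28
#' @export
findAnchor <- function(seq, anchor, maxMismatch = 2L) {
  pat <- if (is(anchor, "GeneAnchor")) anchorSeq(anchor) else anchor
  prof <- mismatchProfile(seq, pat)
  hit <- which(prof <= maxMismatch)
  if (length(hit) == 0L) return(NULL)
  start0 <- hit[1L] - 1L
  list(start0 = start0, end0 = start0 + nchar(pat),
       mismatches = as.integer(prof[hit[1L]]))
}

#' Locate the 3' linker downstream of an offset
#'
#' Leftmost position at or after `from0` where either the full linker, or —
#' when the read ends before the full linker fits — a linker prefix of at
#' least `minPrefix` nt, matches with at most `maxMismatch` mismatches.
#'
#' @param seq read sequence.
#' @param from0 0-based offset from which to search (anchor end).
#' @param linker linker DNA string.
#' @param minPrefix minimum prefix length at the read end.
#' @param maxMismatch mismatch allowance.
#' @return `NULL` when absent, else a list with `start0`, `matchLen` and
#'   `mismatches`.
#' @examples
#' findLinker(paste0("AAAATT", defaultLinker()), 0)$start0  # 6
#' @export
findLinker <- function(seq, from0 = 0L, linker = defaultLinker(),
                       minPrefix = 10L, maxMismatch = 1L) {
  n <- nchar(seq); m <- nchar(linker)
  if (from0 > n) stop("from0 exceeds the read length")
  prof <- mismatchProfile(seq, linker)
  hit <- which(prof <= maxMismatch)
  hit <- hit[hit - 1L >= from0]
  if (length(hit))
    return(list(start0 = hit[1L] - 1L, matchLen = m,
                mismatches = as.integer(prof[hit[1L]])))
  ## read ends inside the linker: try prefixes of decreasing length
  first <- max(from0 + 1L, n - m + 2L)         # 1-based starts with len < m
  last <- n - minPrefix + 1L
  if (first <= last) {
    for (s in first:last) {
      len <- n - s + 1L
      d <- hammingDistance(substr(seq, s, n), substr(linker, 1L, len))
      if (d <= maxMismatch)
        return(list(start0 = s - 1L, matchLen = len, mismatches = as.integer(d)))
    }
  }
  NULL
}

## Minimum anchor mismatch count over all positions (Inf when the anchor
## does not fit); used for strand and gene selection.
.bestAnchorMismatch <- function(seq, pat) {
  prof <- mismatchProfile(seq, pat)
  if (length(prof) == 0L) Inf else min(prof)
}

#' Orient a read onto the anchor-bearing strand
#'
#' Tries every configured anchor on the read and (when enabled) its reverse
#' complement; returns the strand on which some anchor matches within the
#' mismatch tolerance. When both strands match, the strand with the fewer
#' mismatches wins; ties go to sense.
#'
#' @param seq read sequence.
#' @param param a [TailCallerParam-class].
#' @return `NULL` when no anchor matches either strand, else a list with
#'   `seq` (sense-restored sequence) and `orientation`
#'   (`"sense"`/`"antisense"`).
#' @export
orientRead <- function(seq, param) {
  pats <- vapply(param@anchors, anchorSeq, character(1))
  senseBest <- min(vapply(pats, .bestAnchorMismatch, numeric(1), seq = seq))
  antiBest <- Inf
  rc <- NULL
  if (param@searchBothStrands) {
    rc <- revComp(seq)
    antiBest <- min(vapply(pats, .bestAnchorMismatch, numeric(1), seq = rc))
  }
  tol <- param@maxAnchorMismatch
  if (senseBest > tol && antiBest > tol) return(NULL)
  if (senseBest <= antiBest)
    list(seq = seq, orientation = "sense")
  else
    list(seq = rc, orientation = "antisense")
}

#' Segment a tail sequence into poly(A) and terminal additions
#'
#' The additions are the maximal 3'-terminal run of non-A bases (reported in
#' the RNA alphabet, read T as U); the remaining 5' part is the poly(A) tail.
#' In strict mode the 5' part must be pure A, otherwise the read is flagged
#' impure; in tolerant mode up to one non-A interruption per 20 nt is
#' permitted and counted toward the poly(A) length.
#'
#' @param tailSeq read-space sequence strictly between anchor end and linker
#'   start (\{A,C,G,T\}).
#' @param strict strict (default) or tolerant segmentation.
#' @return list with `polyALen`, `additions` (RNA alphabet, 5'->3') and
#'   `impure` (logical).
#' @examples
#' segmentTail("AAAAAATT")  # polyA 6, additions "UU"
#' @export
segmentTail <- function(tailSeq, strict = TRUE) {
  if (nchar(tailSeq) == 0L)
    return(list(polyALen = 0L, additions = "", impure = FALSE))
  chars <- strsplit(tailSeq, "", fixed = TRUE)[[1L]]
  nonA <- chars != "A"
  lastA <- if (all(nonA)) 0L else max(which(!nonA))
  additions <- if (lastA == nchar(tailSeq)) "" else
    substr(tailSeq, lastA + 1L, nchar(tailSeq))
  head <- chars[seq_len(lastA)]
  interruptions <- sum(head != "A")
  impure <- if (strict) interruptions > 0L
            else interruptions > ceiling(length(head) / 20)
  polyALen <- if (strict && impure) sum(head == "A") else length(head)
  list(polyALen = as.integer(polyALen),
       additions = chartr("T", "U", additions),
       impure = impure)
}

#' Classify a terminal addition block
#'
#' `""` is `none`; a single U is `mono_U`; two or more U's are `oligo_U`
#' (oligo-uridylation means at least 2 U); all-C and all-G blocks are `C_add`
#' and `G_add`; any other non-empty block is `mixed`.
#'
#' @param additions addition block, RNA alphabet (T accepted as U).
#' @return one of `"none"`, `"mono_U"`, `"oligo_U"`, `"C_add"`, `"G_add"`,
#'   `"mixed"`.
#' @examples
#' classifyAddition("UU")
#' @export
classifyAddition <- function(additions) {
  x <- chartr("T", "U", additions)
  n <- nchar(x)
  if (n == 0L) return("none")
  if (x == strrep("U", n)) return(if (n == 1L) "mono_U" else "oligo_U")
  if (x == strrep("C", n)) return("C_add")
  if (x == strrep("G", n)) return("G_add")
  "mixed"
}

.emptyCall <- function(read_id, status, orientation = NA_character_,
                       gene = NA_character_) {
  list(read_id = read_id, gene = gene, status = status,
       orientation = orientation, polyA_len = NA_integer_,
       additions = NA_character_, addition_class = NA_character_)
}

#' Call one read
#'
#' Composes [orientRead()], [findAnchor()], [findLinker()], [segmentTail()]
#' and [classifyAddition()]. When several anchors match, the fewest-mismatch
#' gene wins; an exact tie across genes is `ambiguous`, as is an impure
#' poly(A) segment in strict mode.
#'
#' @param seq read sequence (character).
#' @param param a [TailCallerParam-class].
#' @param read_id read identifier carried into the result.
#' @return a list with fields `read_id`, `gene`, `status`, `orientation`,
#'   `polyA_len`, `additions`, `addition_class`; tail fields are `NA` unless
#'   `status == "called"`.
#' @export
callRead <- function(seq, param, read_id = "") {
  ori <- orientRead(seq, param)
  if (is.null(ori)) return(.emptyCall(read_id, "no_anchor"))
  oseq <- ori$seq

  pats <- vapply(param@anchors, anchorSeq, character(1))
  best <- vapply(pats, .bestAnchorMismatch, numeric(1), seq = oseq)
  inTol <- which(best <= param@maxAnchorMismatch)
  if (length(inTol) == 0L) return(.emptyCall(read_id, "no_anchor"))
  winners <- inTol[best[inTol] == min(best[inTol])]
  if (length(winners) > 1L)
    return(.emptyCall(read_id, "ambiguous", ori$orientation))
  gene <- anchorGene(param@anchors[[winners]])

  am <- findAnchor(oseq, pats[winners], param@maxAnchorMismatch)
  lm <- findLinker(oseq, am$end0, param@linker,
                   param@minLinkerPrefix, param@maxLinkerMismatch)
  if (is.null(lm))
    return(.emptyCall(read_id, "no_linker", ori$orientation, gene))

  tail <- substr(oseq, am$end0 + 1L, lm$start0)
  seg <- segmentTail(tail, strict = param@strictTail)
  if (seg$impure)
    return(.emptyCall(read_id, "ambiguous", ori$orientation, gene))

  list(read_id = read_id, gene = gene, status = "called",
       orientation = ori$orientation, polyA_len = seg$polyALen,
       additions = seg$additions,
       addition_class = classifyAddition(seg$additions))
}

## Structural check of a 4-line FASTQ before parsing: truncated or malformed
## records are reported with their record index.
.validateFastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(invisible(TRUE))
  if (length(lines) %% 4L != 0L)
    stop("failed to read FASTQ '", path, "': truncated record ",
         length(lines) %/% 4L + 1L, call. = FALSE)
  rec <- matrix(lines, nrow = 4L)
  bad <- which(!startsWith(rec[1L, ], "@") | !startsWith(rec[3L, ], "+") |
                 nchar(rec[2L, ]) != nchar(rec[4L, ]))
  if (length(bad))
    stop("failed to read FASTQ '", path, "': malformed record ", bad[1L],
         call. = FALSE)
  invisible(TRUE)
}

#' Call every read of a FASTQ file or read set
#'
#' @param input FASTQ path or a [Biostrings::DNAStringSet].
#' @param param a [TailCallerParam-class].
#' @return a [TailCallSet-class] with one call per record and per-status run
#'   counters.
#' @examples
#' reads <- simulateTailReads(builtinComposition("zc_wt"),
#'                            builtinAnchors()$Zc3h12a, seed = 1)
#' callFastq(reads, TailCallerParam(builtinAnchors()["Zc3h12a"]))
#' @export
callFastq <- function(input, param = TailCallerParam()) {
  if (is.character(input)) {
    .validateFastq(input)
    reads <- tryCatch(
      Biostrings::readDNAStringSet(input, format = "fastq"),
      error = function(e) stop("failed to read FASTQ '", input, "': ",
                               conditionMessage(e), call. = FALSE))
  } else {
    reads <- input
  }
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  seqs <- as.character(reads)

  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) rows[[i]] <- callRead(seqs[i], param, ids[i])

  pull <- function(f, how) vapply(rows, `[[`, how, f)
  calls <- S4Vectors::DataFrame(
    read_id = pull("read_id", character(1)),
    gene = pull("gene", character(1)),
    status = pull("status", character(1)),
    orientation = pull("orientation", character(1)),
    polyA_len = pull("polyA_len", integer(1)),
    additions = pull("additions", character(1)),
    addition_class = pull("addition_class", character(1)))
  counters <- stats::setNames(integer(length(CALL_STATUSES)), CALL_STATUSES)
  tab <- table(calls$status)
  counters[names(tab)] <- as.integer(tab)
  new("TailCallSet", calls = calls, counters = counters)
}

#' @describeIn callFastq per-read calls accessor
#'   ([S4Vectors::DataFrame]).
#' @param x a `TailCallSet`.
#' @export
tailCalls <- function(x) x@calls

#' @describeIn callFastq per-status run counters.
#' @export
statusCounts <- function(x) x@counters

setMethod("show", "TailCallSet", function(object) {
  cat(sprintf("TailCallSet: %d reads (%s)\n", nrow(object@calls),
              paste(sprintf("%s=%d", names(object@counters), object@counters),
                    collapse = ", ")))
  if (nrow(object@calls))
    print(utils::head(as.data.frame(object@calls), 5L))
})

setMethod("length", "TailCallSet", function(x) nrow(x@calls))
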