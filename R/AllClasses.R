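#' @import methods
NULL

## Addition classes assigned by the caller. The generator only emits the
## first five; "mixed" arises when a terminal block contains several base
## identities (e.g. "UC").
ADDITION_CLASSES <- c("none", "mono_U", "oligo_U", "C_add", "G_add")
CALL_CLASSES <- c(ADDITION_CLASSES, "mixed")
CALL_STATUSES <- c("called", "no_anchor", "no_linker", "ambiguous")

## 3'-adaptor ligated to mRNA ends before sequencing; in read space it
## delimits the 3' terminus of the tail.
LINKER1 <- "CTGTAGGCACCATCAAT"

#' Gene-specific 3'-UTR anchor
#'
#' The sense-strand sequence of the annotated 3'-UTR terminus of a transcript,
#' ending immediately before the poly(A) tail. A read is assigned to the gene
#' when this anchor occurs in it within a mismatch tolerance; everything
#' between the anchor and the 3' linker is the tail.
#'
#' @slot gene single gene symbol.
#' @slot anchor DNA string over \{A,C,G,T\}, at least 15 nt.
#' @seealso [GeneAnchor()], [builtinAnchors()]
#' @export
setClass("GeneAnchor",
  representation(gene = "character", anchor = "character"))

setValidity("GeneAnchor", function(object) {
  msg <- character(0)
  if (length(object@gene) != 1L || !nzchar(object@gene))
    msg <- c(msg, "'gene' must be a single non-empty string")
  ok <- tryCatch({
    .checkDnaString(object@anchor, "anchor")
    TRUE
  }, error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) msg <- c(msg, ok)
  else if (nchar(object@anchor) < 15L)
    msg <- c(msg, "anchor must be at least 15 nt")
  if (length(msg)) msg else TRUE
})

#' Per-condition tail composition
#'
#' Exact per-class read counts for one sequencing condition, together with the
#' length models used to realise poly(A) tails and oligo-U blocks. This is
#' both the input to the read simulator and the aggregate a correct caller
#' must recover (generator and caller share nothing but the read bytes).
#'
#' @slot condition condition label, e.g. `"zc_wt_lps"`.
#' @slot gene gene symbol the reads belong to.
#' @slot totalReads total read count; equals `sum(classCounts)`.
#' @slot classCounts named integer vector over
#'   `c("none","mono_U","oligo_U","C_add","G_add")`.
#' @slot oligoURange integer length-2: inclusive range of U's per oligo-U read
#'   (oligo-uridylation means >= 2 U).
#' @slot polyARanges named list over the five classes; each element is either
#'   a single integer (fixed poly(A) length) or an inclusive `c(min, max)`
#'   range sampled uniformly.
#' @seealso [TailComposition()], [builtinComposition()]
#' @export
setClass("TailComposition",
  representation(condition = "character", gene = "character",
                 totalReads = "integer", classCounts = "integer",
                 oligoURange = "integer", polyARanges = "list"))

setValidity("TailComposition", function(object) {
  msg <- character(0)
  if (!identical(sort(names(object@classCounts)), sort(ADDITION_CLASSES)))
    msg <- c(msg, sprintf("classCounts must be named exactly: %s",
                          paste(ADDITION_CLASSES, collapse = ", ")))
  if (any(object@classCounts < 0L))
    msg <- c(msg, "all class counts must be >= 0")
  if (length(object@totalReads) != 1L ||
      sum(object@classCounts) != object@totalReads)
    msg <- c(msg, "sum(classCounts) must equal totalReads")
  if (length(object@oligoURange) != 2L || any(object@oligoURange < 2L) ||
      object@oligoURange[1] > object@oligoURange[2])
    msg <- c(msg, "oligoURange must be an increasing pair of integers >= 2")
  if (!all(ADDITION_CLASSES %in% names(object@polyARanges)))
    msg <- c(msg, "polyARanges must cover every addition class")
  for (cls in intersect(ADDITION_CLASSES, names(object@polyARanges))) {
    r <- object@polyARanges[[cls]]
    if (!is.numeric(r) || !(length(r) %in% 1:2) || any(r < 0) ||
        (length(r) == 2L && r[1] > r[2]))
      msg <- c(msg, sprintf("polyARanges$%s must be a length or [min,max] range", cls))
  }
  if (length(msg)) msg else TRUE
})

#' Caller configuration
#'
#' Tolerances for anchor and linker matching and the tail-segmentation mode.
#'
#' @slot anchors list of [GeneAnchor-class] objects (one per gene searched).
#' @slot linker linker DNA string (sense orientation, 3' of the tail).
#' @slot maxAnchorMismatch maximum Hamming mismatches for an anchor hit.
#' @slot maxLinkerMismatch maximum Hamming mismatches for a linker hit.
#' @slot minLinkerPrefix minimum matched linker prefix length (nt) when the
#'   read ends before the full linker.
#' @slot searchBothStrands whether to try the reverse complement of a read.
#' @slot strictTail strict segmentation requires the pre-addition segment to
#'   be pure A; tolerant mode permits one non-A interruption per 20 nt,
#'   counted toward the poly(A) length.
#' @seealso [TailCallerParam()]
#' @export
setClass("TailCallerParam",
  representation(anchors = "list", linker = "character",
                 maxAnchorMismatch = "integer", maxLinkerMismatch = "integer",
                 minLinkerPrefix = "integer", searchBothStrands = "logical",
                 strictTail = "logical"))

setValidity("TailCallerParam", function(object) {
  msg <- character(0)
  if (length(object@anchors) < 1L ||
      !all(vapply(object@anchors, is, logical(1), "GeneAnchor")))
    msg <- c(msg, "anchors must be a non-empty list of GeneAnchor objects")
  ok <- tryCatch({
    .checkDnaString(object@linker, "linker")
    TRUE
  }, error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) msg <- c(msg, ok)
  if (object@maxAnchorMismatch < 0L || object@maxLinkerMismatch < 0L)
    msg <- c(msg, "mismatch allowances must be >= 0")
  if (object@minLinkerPrefix < 8L)
    msg <- c(msg, "minLinkerPrefix must be >= 8 nt")
  if (length(msg)) msg else TRUE
})

#' Per-read tail calls for a read set
#'
#' Result container for [callFastq()]: one row per input read with the
#' assigned gene, call status, orientation, poly(A) length, terminal addition
#' block (RNA alphabet) and addition class, plus run counters per status.
#'
#' @slot calls a [S4Vectors::DataFrame] with columns `read_id`, `gene`,
#'   `status`, `orientation`, `polyA_len`, `additions`, `addition_class`.
#'   Tail fields are `NA` unless `status == "called"`.
#' @slot counters named integer vector over the four statuses.
#' @seealso [callFastq()], [tailCalls()], [statusCounts()]
#' @export
setClass("TailCallSet",
  representation(calls = "DataFrame", counters = "integer"))

setValidity("TailCallSet", function(object) {
  msg <- character(0)
  need <- c("read_id", "gene", "status", "orientation",
            "polyA_len", "additions", "addition_class")
  if (!all(need %in% colnames(object@calls)))
    msg <- c(msg, paste("calls must have columns:", paste(need, collapse = ", ")))
  if (!identical(sort(names(object@counters)), sort(CALL_STATUSES)))
    msg <- c(msg, "counters must be named by the four call statuses")
  else if (sum(object@counters) != nrow(object@calls))
    msg <- c(msg, "counters must sum to the number of calls")
  if (length(msg)) msg else TRUE
})

#' Per-condition uridylation summary
#'
#' Counts and percentage frequencies of terminal-addition classes over the
#' called reads of one condition. The frequency denominator is the number of
#' called reads (anchor and linker both found, unambiguous tail).
#'
#' @slot condition condition label.
#' @slot gene gene symbol.
#' @slot totalCalled denominator: number of called reads.
#' @slot counts named integer over
#'   `c("mono_U","oligo_U","any_U","C_add","G_add","none","mixed")`;
#'   `any_U = mono_U + oligo_U` (optionally plus mixed, see
#'   [summarizeUridylation()]).
#' @slot frequencies matching percentages (`100 * count / totalCalled`);
#'   `NA` when no reads were called.
#' @slot defined `FALSE` when `totalCalled == 0` and frequencies are undefined.
#' @seealso [summarizeUridylation()], [roundedFrequencies()]
#' @export
setClass("UridylationSummary",
  representation(condition = "character", gene = "character",
                 totalCalled = "integer", counts = "integer",
                 frequencies = "numeric", defined = "logical"))

SUMMARY_CLASSES <- c("mono_U", "oligo_U", "any_U", "C_add", "G_add",
                     "none", "mixed")

setValidity("UridylationSummary", function(object) {
  msg <- character(0)
  if (!identical(names(object@counts), SUMMARY_CLASSES) ||
      !identical(names(object@frequencies), SUMMARY_CLASSES))
    msg <- c(msg, "counts/frequencies must be named by the summary classes")
  base <- setdiff(SUMMARY_CLASSES, "any_U")
  if (length(msg) == 0L && sum(object@counts[base]) != object@totalCalled)
    msg <- c(msg, "class counts must sum to totalCalled")
  if (object@defined && length(msg) == 0L &&
      any(object@frequencies < 0 | object@frequencies > 100))
    msg <- c(msg, "frequencies must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Poly(A)-length-binned uridylation frequencies
#'
#' Reads are binned by poly(A) length into half-open `[lo, hi)` bins with a
#' final open-ended bin, and per-bin mono-U and oligo-U frequencies are
#' correlated (Pearson) against the bin midpoints.
#'
#' @slot binEdges numeric vector of left edges (last bin is open-ended).
#' @slot binMid bin midpoints used as the correlation abscissa.
#' @slot binCounts reads per bin.
#' @slot monoFreq,oligoFreq per-bin percentages among the bin's reads.
#' @slot minReads minimum reads for a bin to enter the correlation.
#' @slot corMono,corOligo lists with elements `r`, `p`, `nBins`, `defined`.
#' @seealso [binByPolyA()]
#' @export
setClass("BinnedUridylation",
  representation(binEdges = "numeric", binMid = "numeric",
                 binCounts = "integer", monoFreq = "numeric",
                 oligoFreq = "numeric", minReads = "integer",
                 corMono = "list", corOligo = "list"))

#' Transcription-shutoff decay time course
#'
#' Relative transcript abundance over time after actinomycin-D transcription
#' arrest, normalised so that the expected abundance at time 0 is 1.
#'
#' @slot time minutes, non-negative, strictly increasing, starting at 0.
#' @slot abundance strictly positive relative abundance.
#' @seealso [simulateDecay()], [fitHalfLife()]
#' @export
setClass("DecayCurve",
  representation(time = "numeric", abundance = "numeric"))

setValidity("DecayCurve", function(object) {
  msg <- character(0)
  if (length(object@time) < 3L)
    msg <- c(msg, "at least 3 time points are required")
  if (length(object@time) != length(object@abundance))
    msg <- c(msg, "time and abundance must have equal length")
  if (any(object@time < 0) || is.unsorted(object@time, strictly = TRUE))
    msg <- c(msg, "time must be non-negative and strictly increasing")
  if (length(object@time) && object@time[1] != 0)
    msg <- c(msg, "time must include 0 as the first point")
  if (any(object@abundance <= 0))
    msg <- c(msg, "abundance must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' First-order decay fit
#'
#' Log-linear least-squares fit of `log(abundance) = -k * t + c`;
#' the half-life is `log(2) / k`.
#'
#' @slot decayRate first-order rate constant k, per minute.
#' @slot halfLife minutes (`Inf` when no decay is detected, k <= 0).
#' @slot intercept fitted intercept on the log scale.
#' @slot rSquared coefficient of determination of the log-linear fit.
#' @slot nPoints number of time points used.
#' @seealso [fitHalfLife()]
#' @export
setClass("HalfLifeFit",
  representation(decayRate = "numeric", halfLife = "numeric",
                 intercept = "numeric", rSquared = "numeric",
                 nPoints = "integer"))
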