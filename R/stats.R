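## Aggregation of per-read tail calls into per-condition uridylation
## statistics, poly(A)-length-binned frequencies, and the two hypothesis
## tests used downstream (Pearson correlation, two-sample Student's t).

.callsTable <- function(calls) {
  if (is(calls, "TailCallSet")) return(calls@calls)
  if (is(calls, "DataFrame") || is.data.frame(calls)) return(calls)
  stop("calls must be a TailCallSet, DataFrame or data.frame")
}

#' Summarise uridylation over called reads
#'
#' Counts each addition class over reads with `status == "called"` and
#' reports frequencies as percentages of the called-read total. The
#' denominator deliberately excludes `no_anchor`/`no_linker`/`ambiguous`
#' reads: a tail is undefined without both boundaries.
#'
#' @param calls a [TailCallSet-class], [S4Vectors::DataFrame] or
#'   `data.frame` of calls.
#' @param condition condition label recorded in the summary.
#' @param countMixedAsU when `TRUE`, `mixed` blocks containing at least one U
#'   also count toward `any_U` (pure-U tails only by default).
#' @return a [UridylationSummary-class]. When no reads are called the
#'   frequencies are `NA` and the summary is flagged undefined rather than
#'   raising a division error.
#' @examples
#' calls <- simulateCallProfiles(500, 0.1, 0.2, seed = 1)
#' summarizeUridylation(calls, "toy")
#' @export
summarizeUridylation <- function(calls, condition = "",
                                 countMixedAsU = FALSE) {
  df <- .callsTable(calls)
  called <- df[df$status == "called", , drop = FALSE]
  gene <- unique(called$gene)
  if (length(gene) > 1L)
    stop("calls span several genes (", paste(gene, collapse = ", "),
         "); summarise one gene at a time")
  if (length(gene) == 0L) gene <- NA_character_

  counts <- stats::setNames(integer(length(SUMMARY_CLASSES)), SUMMARY_CLASSES)
  tab <- table(called$addition_class)
  keep <- intersect(names(tab), SUMMARY_CLASSES)
  counts[keep] <- as.integer(tab[keep])
  counts["any_U"] <- counts["mono_U"] + counts["oligo_U"]
  if (countMixedAsU && counts["mixed"] > 0L) {
    mixedU <- sum(grepl("U", called$additions[called$addition_class == "mixed"],
                        fixed = TRUE))
    counts["any_U"] <- counts["any_U"] + mixedU
  }
  total <- nrow(called)
  defined <- total > 0L
  freqs <- if (defined) 100 * counts / total
           else stats::setNames(rep(NA_real_, length(counts)), names(counts))
  new("UridylationSummary", condition = as.character(condition), gene = gene,
      totalCalled = as.integer(total), counts = counts,
      frequencies = stats::setNames(as.numeric(freqs), SUMMARY_CLASSES),
      defined = defined)
}

#' @describeIn summarizeUridylation exact percentage frequencies.
#' @param x a `UridylationSummary`.
#' @export
classFrequencies <- function(x) x@frequencies

#' @describeIn summarizeUridylation frequencies rounded half-up to integers,
#'   the convention of printed uridylation percentages.
#' @export
roundedFrequencies <- function(x) roundHalfUp(x@frequencies)

#' @describeIn summarizeUridylation per-class counts (including `any_U`).
#' @export
summaryCounts <- function(x) x@counts

#' @describeIn summarizeUridylation called-read denominator.
#' @export
totalCalled <- function(x) x@totalCalled

#' Summary as a one-row data.frame
#'
#' @param x a [UridylationSummary-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @export
as.data.frame.UridylationSummary <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  out <- data.frame(condition = x@condition, gene = x@gene,
                    total_called = x@totalCalled)
  for (cls in SUMMARY_CLASSES) {
    out[[paste0(cls, "_count")]] <- x@counts[[cls]]
    out[[paste0(cls, "_pct")]] <- x@frequencies[[cls]]
  }
  out
}

setMethod("show", "UridylationSummary", function(object) {
  cat(sprintf("UridylationSummary '%s' (%s): %d called reads\n",
              object@condition, object@gene, object@totalCalled))
  if (object@defined) {
    df <- data.frame(count = object@counts,
                     pct = signif(object@frequencies, 4),
                     pct_rounded = roundHalfUp(object@frequencies))
    print(df)
  } else {
    cat("  no called reads; frequencies undefined\n")
  }
})

#' Pearson correlation with two-sided p value
#'
#' Product-moment correlation; the p value comes from the t transform with
#' n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return list with `r`, `p` and `n`.
#' @examples
#' pearsonTest(1:4, c(1, 3, 2, 5))
#' @export
pearsonTest <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("degenerate input: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-sample Student's t test
#'
#' Pooled-variance two-tailed t test by default; Welch's unequal-variance
#' variant behind `welch = TRUE`.
#'
#' @param groupA,groupB numeric vectors, each of length >= 2.
#' @param welch use the Welch variant.
#' @return list with `t`, `p` and `df`.
#' @examples
#' studentTTest(c(1, 2, 3), c(11, 12, 13))
#' @export
studentTTest <- function(groupA, groupB, welch = FALSE) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 observations")
  if (stats::var(groupA) == 0 && stats::var(groupB) == 0) {
    if (identical(mean(groupA), mean(groupB)))
      stop("degenerate input: both groups constant and equal")
    stop("degenerate input: zero variance in both groups")
  }
  tt <- stats::t.test(groupA, groupB, var.equal = !welch,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Bin calls by poly(A) length and correlate uridylation with length
#'
#' Called reads are assigned to half-open poly(A)-length bins
#' `[0,w), [w,2w), ..., [maxEdge, Inf)`; per-bin mono-U and oligo-U
#' frequencies (percent of the bin's reads) are then correlated against bin
#' midpoints over bins holding at least `minReads` reads. With fewer than 3
#' qualifying bins the correlation is flagged undefined instead of erroring.
#'
#' @param calls a [TailCallSet-class], [S4Vectors::DataFrame] or
#'   `data.frame` of calls.
#' @param binWidth bin width, nt (>= 1).
#' @param maxEdge left edge of the final, open-ended bin.
#' @param minReads minimum reads for a bin to enter the correlation.
#' @param perRead when `TRUE`, additionally computes the per-read
#'   point-biserial correlation (class indicator vs poly(A) length) instead
#'   of the per-bin frequency correlation.
#' @return a [BinnedUridylation-class].
#' @examples
#' calls <- simulateCallProfiles(2000, 0.1,
#'                               function(L) 0.4 - 0.003 * L, seed = 1)
#' binByPolyA(calls)
#' @export
binByPolyA <- function(calls, binWidth = 10L, maxEdge = 75L, minReads = 10L,
                       perRead = FALSE) {
  if (binWidth < 1L) stop("binWidth must be >= 1")
  df <- .callsTable(calls)
  called <- df[df$status == "called", , drop = FALSE]
  edges <- seq(0L, maxEdge, by = binWidth)
  mids <- edges + binWidth / 2
  bin <- pmin(called$polyA_len %/% binWidth + 1L, length(edges))

  nBins <- length(edges)
  counts <- integer(nBins); mono <- numeric(nBins); oligo <- numeric(nBins)
  for (b in seq_len(nBins)) {
    inBin <- which(bin == b)
    counts[b] <- length(inBin)
    if (counts[b] > 0L) {
      mono[b] <- 100 * sum(called$addition_class[inBin] == "mono_U") / counts[b]
      oligo[b] <- 100 * sum(called$addition_class[inBin] == "oligo_U") / counts[b]
    } else {
      mono[b] <- NA_real_; oligo[b] <- NA_real_
    }
  }

  corOf <- function(freq) {
    if (perRead) {
      ind <- as.numeric(called$addition_class ==
                          if (identical(freq, mono)) "mono_U" else "oligo_U")
      if (length(ind) < 3L || stats::var(ind) == 0 ||
          stats::var(called$polyA_len) == 0)
        return(list(r = NA_real_, p = NA_real_, nBins = NA_integer_,
                    defined = FALSE))
      pt <- pearsonTest(as.numeric(called$polyA_len), ind)
      return(list(r = pt$r, p = pt$p, nBins = pt$n, defined = TRUE))
    }
    keep <- which(counts >= minReads & !is.na(freq))
    if (length(keep) < 3L || stats::var(freq[keep]) == 0)
      return(list(r = NA_real_, p = NA_real_,
                  nBins = length(keep), defined = FALSE))
    pt <- pearsonTest(mids[keep], freq[keep])
    list(r = pt$r, p = pt$p, nBins = length(keep), defined = TRUE)
  }

  new("BinnedUridylation", binEdges = as.numeric(edges), binMid = mids,
      binCounts = counts, monoFreq = mono, oligoFreq = oligo,
      minReads = as.integer(minReads),
      corMono = corOf(mono), corOligo = corOf(oligo))
}

#' @describeIn binByPolyA per-bin table (`data.frame` of edges, midpoints,
#'   counts and frequencies).
#' @param x a `BinnedUridylation`.
#' @export
binTable <- function(x) {
  data.frame(bin_lo = x@binEdges,
             bin_hi = c(x@binEdges[-1], Inf),
             bin_mid = x@binMid, n_reads = x@binCounts,
             mono_U_pct = x@monoFreq, oligo_U_pct = x@oligoFreq)
}

#' @describeIn binByPolyA mono-U correlation (`list(r, p, nBins, defined)`).
#' @export
corMono <- function(x) x@corMono

#' @describeIn binByPolyA oligo-U correlation.
#' @export
corOligo <- function(x) x@corOligo

setMethod("show", "BinnedUridylation", function(object) {
  cat(sprintf("BinnedUridylation: %d bins (width %g nt), min %d reads/bin\n",
              length(object@binEdges), diff(object@binEdges[1:2]),
              object@minReads))
  fmt <- function(cr, lab) {
    if (isTRUE(cr$defined))
      cat(sprintf("  %s: r = %.3f, p = %.3g (%d bins)\n",
                  lab, cr$r, cr$p, cr$nBins))
    else cat(sprintf("  %s: undefined (< 3 qualifying bins)\n", lab))
  }
  fmt(object@corMono, "mono-U vs length")
  fmt(object@corOligo, "oligo-U vs length")
})

#' Compare uridylation summaries across conditions
#'
#' Long-format condition-by-class table of counts and frequencies. When
#' several summaries share a condition label they are treated as replicates,
#' and for exactly two distinct conditions with >= 2 replicates each a
#' two-tailed Student's t test on replicate frequencies is added per class.
#'
#' @param summaries list of [UridylationSummary-class] objects (>= 2) for the
#'   same gene.
#' @param welch use Welch's t variant for replicate tests.
#' @return list with `table` (a `data.frame`) and `tests` (a `data.frame` of
#'   per-class t tests, or `NULL` when replicates are unavailable).
#' @export
compareConditions <- function(summaries, welch = FALSE) {
  if (length(summaries) < 2L)
    stop("at least two summaries are required")
  genes <- unique(vapply(summaries, function(s) s@gene, character(1)))
  if (length(genes) > 1L)
    stop("summaries mix genes: ", paste(genes, collapse = ", "))
  tab <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(condition = s@condition, gene = s@gene,
               class = SUMMARY_CLASSES,
               count = as.integer(s@counts),
               frequency_pct = as.numeric(s@frequencies))
  }))
  rownames(tab) <- NULL

  tests <- NULL
  conds <- vapply(summaries, function(s) s@condition, character(1))
  uc <- unique(conds)
  if (length(uc) == 2L && all(table(conds) >= 2L)) {
    tests <- do.call(rbind, lapply(SUMMARY_CLASSES, function(cls) {
      fa <- vapply(summaries[conds == uc[1]],
                   function(s) s@frequencies[[cls]], numeric(1))
      fb <- vapply(summaries[conds == uc[2]],
                   function(s) s@frequencies[[cls]], numeric(1))
      res <- tryCatch(studentTTest(fa, fb, welch = welch),
                      error = function(e) list(t = NA_real_, p = NA_real_,
                                               df = NA_real_))
      data.frame(class = cls, condition_a = uc[1], condition_b = uc[2],
                 t = res$t, p = res$p, df = res$df)
    }))
    rownames(tests) <- NULL
  }
  list(table = tab, tests = tests)
}
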