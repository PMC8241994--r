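.DEFAULT_POLYA_RANGES <- list(
  ## Uridylated tails are biased short (deadenylation precedes uridylation);
  ## unmodified and C/G-extended tails span the usual mRNA range.
  none    = c(10L, 120L),
  mono_U  = c(5L, 60L),
  oligo_U = c(5L, 60L),
  C_add   = c(10L, 120L),
  G_add   = c(10L, 120L)
)

#' Construct a tail composition
#'
#' @param condition condition label.
#' @param gene gene symbol.
#' @param classCounts named integer vector over
#'   `c("none","mono_U","oligo_U","C_add","G_add")`; missing classes count 0.
#' @param oligoURange inclusive range of U's per oligo-U read (>= 2).
#' @param polyARanges optional named list overriding the per-class poly(A)
#'   length models (single integer = fixed length; pair = uniform range).
#' @return a [TailComposition-class] object.
#' @examples
#' TailComposition("toy", "Zc3h12a", c(none = 5, mono_U = 2, oligo_U = 3))
#' @export
TailComposition <- function(condition, gene, classCounts,
                            oligoURange = c(2L, 5L), polyARanges = list()) {
  counts <- stats::setNames(integer(length(ADDITION_CLASSES)), ADDITION_CLASSES)
  if (is.null(names(classCounts)) ||
      !all(names(classCounts) %in% ADDITION_CLASSES))
    stop("classCounts must be named with classes among: ",
         paste(ADDITION_CLASSES, collapse = ", "))
  counts[names(classCounts)] <- as.integer(classCounts)
  ranges <- .DEFAULT_POLYA_RANGES
  for (cls in names(polyARanges)) {
    if (!cls %in% ADDITION_CLASSES)
      stop("unknown class in polyARanges: ", cls)
    ranges[[cls]] <- as.integer(polyARanges[[cls]])
  }
  new("TailComposition", condition = as.character(condition),
      gene = as.character(gene), totalReads = sum(counts),
      classCounts = counts, oligoURange = as.integer(oligoURange),
      polyARanges = ranges)
}

#' @describeIn TailComposition total read count.
#' @param x a `TailComposition`.
#' @export
totalReads <- function(x) x@totalReads

#' @describeIn TailComposition named per-class read counts.
#' @export
classCounts <- function(x) x@classCounts

#' @describeIn TailComposition condition label.
#' @export
conditionLabel <- function(x) x@condition

#' @describeIn TailComposition gene symbol.
#' @export
compositionGene <- function(x) x@gene

setMethod("show", "TailComposition", function(object) {
  cat(sprintf("TailComposition '%s' (%s): %d reads\n",
              object@condition, object@gene, object@totalReads))
  print(object@classCounts)
})

## Published per-condition compositions. Uridylation percentages and C/G
## addition counts for the LPS conditions are the printed values; the
## remainder is absorbed by class "none". Mono/oligo-U baselines for the
## unstimulated Zc3h12a conditions and C/G counts for Il6 are not printed
## anywhere and are synthetic stand-ins (see the methods vignette).
.BUILTIN_FIXTURES <- list(
  zc_wt      = list(gene = "Zc3h12a", total = 466L,  monoPct = 8,  oligoPct = 10,
                    C = 75L,  G = 22L),
  zc_wt_lps  = list(gene = "Zc3h12a", total = 1067L, monoPct = 14, oligoPct = 24,
                    C = 144L, G = 40L),
  zc_ko      = list(gene = "Zc3h12a", total = 311L,  monoPct = 8,  oligoPct = 10,
                    C = 65L,  G = 12L),
  zc_ko_lps  = list(gene = "Zc3h12a", total = 1714L, monoPct = 12, oligoPct = 14,
                    C = 174L, G = 60L),
  il6_wt_lps = list(gene = "Il6",     total = 1756L, monoPct = 9,  oligoPct = 6,
                    C = 0L,   G = 0L),
  il6_ko_lps = list(gene = "Il6",     total = 1730L, monoPct = 9,  oligoPct = 5,
                    C = 0L,   G = 0L)
)

#' Identifiers of the built-in composition fixtures
#'
#' Six conditions: *Zc3h12a* in Tut7+/+ and Tut7-/- macrophages with and
#' without LPS stimulation, and *Il6* in both genotypes after LPS.
#'
#' @return character vector of fixture ids.
#' @export
compositionIds <- function() names(.BUILTIN_FIXTURES)

#' Built-in composition fixtures
#'
#' Per-condition tail compositions reconstructed from the published read
#' totals, integer-rounded mono-/oligo-uridylation percentages and cytosine/
#' guanine addition counts of the gene-specific TAIL-Seq experiment.
#' Percentages are converted to counts as `floor(pct/100 * total + 0.5)` and
#' the remainder is assigned to class `"none"`, so totals are conserved.
#'
#' @param id one of [compositionIds()]: `"zc_wt"`, `"zc_wt_lps"`, `"zc_ko"`,
#'   `"zc_ko_lps"`, `"il6_wt_lps"`, `"il6_ko_lps"`.
#' @return a [TailComposition-class] object.
#' @examples
#' builtinComposition("zc_wt_lps")
#' @export
builtinComposition <- function(id) {
  if (!is.character(id) || length(id) != 1L || !id %in% names(.BUILTIN_FIXTURES))
    stop("unknown condition id '", paste(id, collapse = ","),
         "'; valid ids: ", paste(names(.BUILTIN_FIXTURES), collapse = ", "))
  fx <- .BUILTIN_FIXTURES[[id]]
  mono <- pctToCount(fx$monoPct, fx$total)
  oligo <- pctToCount(fx$oligoPct, fx$total)
  none <- fx$total - mono - oligo - fx$C - fx$G
  stopifnot(none >= 0L)
  TailComposition(id, fx$gene,
                  c(none = none, mono_U = mono, oligo_U = oligo,
                    C_add = fx$C, G_add = fx$G))
}

#' Write / read a composition as TSV
#'
#' Two-column long format (`class`, `count`) with a comment-free header;
#' condition and gene are carried in extra columns so a single file round
#' trips one composition.
#'
#' @param x a [TailComposition-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeCompositionTsv <- function(x, path) {
  df <- data.frame(condition = x@condition, gene = x@gene,
                   class = names(x@classCounts),
                   count = as.integer(x@classCounts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCompositionTsv
#' @export
readCompositionTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  TailComposition(df$condition[1], df$gene[1],
                  stats::setNames(df$count, df$class))
}

#' @rdname writeCompositionTsv
#' @export
writeCompositionJson <- function(x, path) {
  jsonlite::write_json(
    list(condition = x@condition, gene = x@gene,
         total_reads = x@totalReads,
         class_counts = as.list(x@classCounts),
         oligo_U_range = x@oligoURange,
         polyA_ranges = x@polyARanges),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
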