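## Read simulator emulating the gene-specific 3'-end library structure:
## [gene anchor][poly(A) tail][non-templated additions][3' linker][filler].
## Reads are emitted as cDNA, so uridines appear as T.

.additionString <- function(cls, oligoURange) {
  switch(cls,
    none    = "",
    mono_U  = "T",
    oligo_U = strrep("T", sample(oligoURange[1]:oligoURange[2], 1L)),
    C_add   = strrep("C", sample(1:2, 1L)),
    G_add   = strrep("G", sample(1:2, 1L)),
    stop("unknown addition class: ", cls))
}

.drawPolyALen <- function(cls, ranges) {
  r <- ranges[[cls]]
  if (length(r) == 1L) as.integer(r) else sample(r[1]:r[2], 1L)
}

#' Simulate gene-specific 3'-end reads
#'
#' Emits exactly `totalReads(composition)` reads. Class assignment is an
#' exact partition of the composition counts (not sampling), so the aggregate
#' composition of the read set is deterministic; per-read poly(A) lengths,
#' oligo-U block lengths, filler bases, strand assignment and sequencing
#' errors are drawn from a single seeded RNG stream. Read names encode the
#' true class, poly(A) length and addition block for round-trip testing (see
#' [parseReadTruth()]).
#'
#' @param composition a [TailComposition-class].
#' @param anchor a [GeneAnchor-class]; the read 5' context.
#' @param linker linker DNA string appended 3' of the additions.
#' @param readLength fixed emitted read length (nt); must be at least
#'   `nchar(anchor) + nchar(linker) + 2`. Reads shorter than this are padded
#'   with random filler bases, longer constructs are truncated (the linker
#'   then appears as a 3' prefix).
#' @param seed integer seed.
#' @param errorRate per-base substitution probability (i.i.d.).
#' @param antisenseFraction fraction of reads emitted reverse-complemented;
#'   `floor(n * fraction + 0.5)` reads are flipped.
#' @return a [Biostrings::DNAStringSet] with truth-encoding names.
#' @examples
#' reads <- simulateTailReads(builtinComposition("zc_wt"),
#'                            builtinAnchors()$Zc3h12a, seed = 1)
#' length(reads)
#' @seealso [writeFastq()], [callFastq()]
#' @export
simulateTailReads <- function(composition, anchor, linker = defaultLinker(),
                              readLength = 200L, seed = 1L,
                              errorRate = 0, antisenseFraction = 0) {
  methods::validObject(composition)
  methods::validObject(anchor)
  .checkDnaString(linker, "linker")
  readLength <- as.integer(readLength)
  if (readLength < nchar(anchorSeq(anchor)) + nchar(linker) + 2L)
    stop("readLength must be >= anchor + linker length + 2")
  if (errorRate < 0 || errorRate > 1 || antisenseFraction < 0 ||
      antisenseFraction > 1)
    stop("errorRate and antisenseFraction must lie in [0, 1]")

  counts <- classCounts(composition)
  n <- totalReads(composition)
  aseq <- anchorSeq(anchor)

  withSeed(seed, {
    cls <- rep(names(counts), counts)
    if (n > 1L) cls <- sample(cls)                    # interleave classes
    polyA <- vapply(cls, .drawPolyALen, integer(1),
                    ranges = composition@polyARanges)
    adds <- vapply(cls, .additionString, character(1),
                   oligoURange = composition@oligoURange)

    core <- paste0(aseq, strrep("A", polyA), adds, linker)
    pad <- pmax(0L, readLength - nchar(core))
    filler <- vapply(pad, function(k)
      if (k == 0L) "" else paste(sample(.DNA_ALPHABET, k, replace = TRUE),
                                 collapse = ""), character(1))
    reads <- substr(paste0(core, filler), 1L, readLength)

    orientation <- rep("sense", n)
    nAnti <- as.integer(floor(n * antisenseFraction + 0.5))
    if (nAnti > 0L) {
      anti <- sample(n, nAnti)
      orientation[anti] <- "antisense"
      reads[anti] <- revComp(reads[anti])
    }

    if (errorRate > 0) reads <- .injectErrors(reads, errorRate)

    ids <- sprintf("%s:%06d|gene=%s|class=%s|L=%d|add=%s|strand=%s",
                   conditionLabel(composition), seq_len(n),
                   compositionGene(composition), cls, polyA,
                   chartr("T", "U", adds), orientation)
    out <- Biostrings::DNAStringSet(reads)
    names(out) <- ids
    out
  })
}

## i.i.d. per-base substitutions; each hit base is replaced by one of the
## other three nucleotides, uniformly.
.injectErrors <- function(reads, rate) {
  mat <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
                nrow = nchar(reads[1]))
  hit <- which(stats::runif(length(mat)) < rate)
  if (length(hit)) {
    repl <- vapply(mat[hit], function(b)
      sample(setdiff(.DNA_ALPHABET, b), 1L), character(1))
    mat[hit] <- repl
  }
  apply(mat, 2L, paste, collapse = "")
}

#' Decode simulated-read truth from read names
#'
#' @param ids character vector of read names produced by
#'   [simulateTailReads()].
#' @return a `data.frame` with columns `read_id`, `gene`, `class`,
#'   `polyA_len`, `additions`, `strand`.
#' @export
parseReadTruth <- function(ids) {
  field <- function(key) sub(sprintf(".*\\|%s=([^|]*)(\\|.*)?$", key), "\\1", ids)
  data.frame(read_id = ids,
             gene = field("gene"),
             class = field("class"),
             polyA_len = as.integer(field("L")),
             additions = field("add"),
             strand = field("strand"),
             stringsAsFactors = FALSE)
}

#' Write reads as 4-line FASTQ (Phred+33)
#'
#' Quality strings are constant 'I' (Q40); the caller ignores qualities.
#'
#' @param reads a named [Biostrings::DNAStringSet].
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path) {
  seqs <- as.character(reads)
  lines <- as.vector(rbind(paste0("@", names(reads)), seqs, "+",
                           strrep("I", nchar(seqs))))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate an actinomycin-D decay time course
#'
#' First-order decay `exp(-log(2) * t / halfLife)` with optional
#' multiplicative log-normal noise of relative standard deviation `noiseSd`
#' (mean-one parameterisation, so the noise is unbiased on the natural
#' scale). With `noiseSd = 0` the exact exponential is returned.
#'
#' @param halfLife true half-life in minutes (> 0).
#' @param timePoints minutes; non-negative, strictly increasing, starting
#'   at 0; at least three points.
#' @param noiseSd relative standard deviation of the multiplicative noise.
#' @param seed integer seed (ignored when `noiseSd = 0`).
#' @return a [DecayCurve-class].
#' @examples
#' simulateDecay(30, c(0, 30, 60), 0)
#' @export
simulateDecay <- function(halfLife, timePoints = c(0, 30, 60, 90),
                          noiseSd = 0, seed = NULL) {
  if (!is.numeric(halfLife) || length(halfLife) != 1L || halfLife <= 0)
    stop("halfLife must be a positive number of minutes")
  ab <- exp(-log(2) * timePoints / halfLife)
  if (noiseSd > 0) {
    sdlog <- sqrt(log(1 + noiseSd^2))
    ab <- withSeed(seed,
      ab * stats::rlnorm(length(ab), meanlog = -sdlog^2 / 2, sdlog = sdlog))
  }
  new("DecayCurve", time = as.numeric(timePoints), abundance = ab)
}

#' @describeIn simulateDecay time accessor.
#' @param x a `DecayCurve`.
#' @export
decayTime <- function(x) x@time

#' @describeIn simulateDecay abundance accessor.
#' @export
decayAbundance <- function(x) x@abundance

setMethod("show", "DecayCurve", function(object) {
  cat(sprintf("DecayCurve: %d time points over %g min\n",
              length(object@time), max(object@time)))
  print(data.frame(time = object@time, abundance = signif(object@abundance, 4)))
})

#' Simulate per-read calls with a length-dependent uridylation model
#'
#' Generates a table shaped like caller output directly from a model in which
#' the probability of mono-/oligo-uridylation may depend on the poly(A)
#' length, for testing length-frequency correlation analyses where the
#' composition-table simulator (exact per-class counts, independent lengths)
#' cannot express `P(class | length)`.
#'
#' @param n number of reads.
#' @param probMono,probOligo either a single probability or a
#'   `function(L)` returning per-read probabilities given poly(A) length.
#' @param polyARange inclusive uniform range of poly(A) lengths.
#' @param gene gene symbol recorded in the table.
#' @param seed integer seed.
#' @return a [S4Vectors::DataFrame] with the caller's call columns, all
#'   `status == "called"`.
#' @seealso [binByPolyA()]
#' @export
simulateCallProfiles <- function(n, probMono = 0.1, probOligo = 0.15,
                                 polyARange = c(0L, 100L), gene = "Zc3h12a",
                                 seed = 1L) {
  pm <- if (is.function(probMono)) probMono else function(L) rep(probMono, length(L))
  po <- if (is.function(probOligo)) probOligo else function(L) rep(probOligo, length(L))
  withSeed(seed, {
    L <- sample(polyARange[1]:polyARange[2], n, replace = TRUE)
    p1 <- pmin(pmax(pm(L), 0), 1)
    p2 <- pmin(pmax(po(L), 0), 1)
    if (any(p1 + p2 > 1)) stop("probMono + probOligo must not exceed 1")
    u <- stats::runif(n)
    cls <- ifelse(u < p1, "mono_U", ifelse(u < p1 + p2, "oligo_U", "none"))
    adds <- c(none = "", mono_U = "U", oligo_U = "UU")[cls]
    S4Vectors::DataFrame(
      read_id = sprintf("sim:%06d", seq_len(n)),
      gene = gene, status = "called", orientation = "sense",
      polyA_len = as.integer(L), additions = unname(adds),
      addition_class = unname(cls))
  })
}
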