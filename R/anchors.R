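#' Construct a gene anchor
#'
#' @param gene gene symbol.
#' @param anchor sense-strand DNA sequence of the 3'-UTR terminus (>= 15 nt),
#'   ending immediately before the poly(A) tail.
#' @return a [GeneAnchor-class] object.
#' @examples
#' GeneAnchor("Zc3h12a", "TTTAAATGAAAAAGGTTGACAAAATAAA")
#' @export
GeneAnchor <- function(gene, anchor) {
  new("GeneAnchor", gene = as.character(gene),
      anchor = toupper(as.character(anchor)))
}

#' @describeIn GeneAnchor gene symbol accessor.
#' @param x a `GeneAnchor`.
#' @export
anchorGene <- function(x) x@gene

#' @describeIn GeneAnchor anchor sequence accessor (character).
#' @export
anchorSeq <- function(x) x@anchor

setMethod("show", "GeneAnchor", function(object) {
  cat(sprintf("GeneAnchor: %s (%d nt) %s\n",
              object@gene, nchar(object@anchor), object@anchor))
})

#' Built-in gene anchors
#'
#' The anchor (criteria) sequences used to filter gene-specific 3'-end reads
#' for the Regnase-1 transcript (*Zc3h12a*) and the *Il6* control transcript.
#'
#' @return named list of [GeneAnchor-class] objects.
#' @examples
#' builtinAnchors()$Zc3h12a
#' @export
builtinAnchors <- function() {
  list(
    Zc3h12a = GeneAnchor("Zc3h12a", "TTTAAATGAAAAAGGTTGACAAAATAAA"),
    Il6     = GeneAnchor("Il6",     "TGTTTAGACTGTCTTCAAACAAATAAA")
  )
}

#' Default 3' linker (linker-1)
#'
#' The synthetic oligonucleotide ligated to RNA 3' ends before reverse
#' transcription; its reverse complement is the linker-complementary part of
#' the RT primer.
#'
#' @return linker DNA string.
#' @examples
#' defaultLinker()
#' @export
defaultLinker <- function() LINKER1

#' Read gene anchors from a two-column TSV
#'
#' Expects a header line and columns `gene` and `anchor`.
#'
#' @param path TSV file path.
#' @return named list of [GeneAnchor-class] objects.
#' @export
readAnchorsTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "anchor") %in% colnames(df)))
    stop("anchor TSV must have columns 'gene' and 'anchor'")
  if (nrow(df) == 0L) stop("anchor TSV contains no genes")
  out <- lapply(seq_len(nrow(df)), function(i)
    GeneAnchor(df$gene[i], df$anchor[i]))
  names(out) <- df$gene
  out
}

#' Read gene anchors from a FASTA file
#'
#' Convenience loader when anchors are kept as short FASTA records (e.g.
#' extracted 3'-UTR termini); record names become gene symbols.
#'
#' @param path FASTA file path.
#' @return named list of [GeneAnchor-class] objects.
#' @export
readAnchorsFasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("anchor FASTA contains no records")
  genes <- sub("\\s.*$", "", names(ss))
  out <- Map(GeneAnchor, genes, as.character(ss))
  names(out) <- genes
  out
}
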