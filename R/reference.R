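#' Bundled rCRS-numbered resources
#'
#' `rcrs_reference()` returns the packaged 16,569 bp reference sequence used to
#' anchor all coordinates. The bundled sequence is a clearly labelled synthetic
#' stand-in for NC_012920: its base identities are exact at the documented
#' variant sites of the N-SNV catalogue, at their codons, at gene start codons
#' and at the 3107 placeholder (an `N` in the real rCRS); elsewhere bases are
#' random with rCRS-like composition. All coordinate arithmetic, gene placement
#' and codon-frame logic is independent of which bases fill the unconstrained
#' positions. A genuine NC_012920 sequence can be passed to every function that
#' accepts a `reference` argument.
#'
#' `rcrs_gene_map()` returns the standard mitochondrial gene map keyed to rCRS
#' numbering: one row per feature with 1-based inclusive `start`/`end`, strand
#' (`H` heavy, `L` light) and `kind` (`PROTEIN`, `TRNA`, `RRNA`, `CONTROL`).
#' The control region (D-loop) wraps the origin and is stored as two rows
#' sharing one name.
#'
#' `nsnv_catalog()` returns the bundled catalogue of 66 published
#' Neanderthal-shared mitochondrial variants (rCRS position, ref/alt alleles,
#' and the published annotation columns: rs number, mutation type, codon change,
#' protein effect, gene, codon position, frequencies). rs numbers and
#' frequencies are carried as metadata, never computed.
#'
#' @param path Optional path to an alternative TSV/FASTA with the same layout.
#' @return `rcrs_reference()`: a single upper-case character string of length
#'   16,569 (as `nchar`); the others: a `data.frame`.
#' @examples
#' nchar(rcrs_reference())
#' head(rcrs_gene_map())
#' @export
rcrs_reference <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rcrs_synthetic.fasta", package = "mitosig")
  x <- Biostrings::readDNAStringSet(path)
  as.character(toupper(x[[1]]))
}

#' @rdname rcrs_reference
#' @export
rcrs_gene_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rcrs_gene_map.tsv", package = "mitosig")
  gm <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "start", "end", "strand", "kind") %in% names(gm)))
  gm
}

#' @rdname rcrs_reference
#' @export
nsnv_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "nsnv_catalog.tsv", package = "mitosig")
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(position = "integer"))
}

# reverse-complement helpers on plain character vectors of single bases
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")

complement_base <- function(b) {
  out <- .COMP[b]
  if (anyNA(out)) stop("cannot complement base(s): ",
                       paste(unique(b[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Vertebrate mitochondrial genetic code
#'
#' Translation table 2: differs from the standard code in that `TGA` encodes
#' Trp, `ATA` encodes Met, and `AGA`/`AGG` are stop codons.
#'
#' @param codon Character vector of upper-case trinucleotides.
#' @return One-letter amino-acid codes (`*` = stop); `NA` for codons containing
#'   ambiguous bases.
#' @examples
#' translate_mito(c("TGA", "ATA", "AGA"))
#' @export
translate_mito <- function(codon) {
  stopifnot(all(nchar(codon) == 3L))
  out <- unname(.MITO_CODE[toupper(codon)])
  out
}

.MITO_CODE <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  # amino acids in TCAG-major order for translation table 2
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CCWW",   # TTT..TGG (TGA = W)
    "LLLLPPPPHHQQRRRR",
    "IIMMTTTTNNKKSS**",   # ATA = M, AGA/AGG = *
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
})
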