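#' Read an aligned mitogenome FASTA
#'
#' Reads a multi-FASTA of (typically aligned) mitogenome sequences, upper-cases
#' them, maps RNA `U` to `T` and validates the alphabet `{A,C,G,T,N,-}`.
#' Validation failures name the offending sample and position.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names = sample ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop("cannot parse FASTA '", path, "': ",
                                         conditionMessage(e)))
  if (length(x) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- chartr("u", "t", toupper(as.character(x)))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN-]", seqs[[i]])
    if (bad > 0L)
      stop("illegal character '", substr(seqs[[i]], bad, bad),
           "' in sample '", ids[i], "' at position ", bad)
  }
  seqs
}

#' Assemble a mitogenome set from sequences and clade metadata
#'
#' Binds aligned sequences to a sample-metadata table assigning each sequence a
#' clade (`NEANDERTHAL`, `ARCHAIC_AMH`, `MODERN`, or `REFERENCE` for the rCRS
#' row) and a subclade label (haplogroup name or Neanderthal subgroup).
#'
#' @param sequences Named character vector as returned by [read_fasta()], all
#'   of equal (aligned) length.
#' @param metadata `data.frame` with columns `sample_id`, `clade`,
#'   `subclade_label`, or a path to such a TSV. If `NULL`, all samples get
#'   clade `MODERN` and empty subclade labels.
#' @return An object of class `mitogenome_set`.
#' @export
mitogenome_set <- function(sequences, metadata = NULL) {
  stopifnot(is.character(sequences), length(sequences) >= 1L,
            !is.null(names(sequences)))
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L)
    stop("aligned lengths differ: ",
         paste(names(sequences)[widths != widths[1]], collapse = ", "))
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = names(sequences), clade = "MODERN",
                           subclade_label = "", stringsAsFactors = FALSE)
  } else if (is.character(metadata) && length(metadata) == 1L) {
    metadata <- utils::read.delim(metadata, stringsAsFactors = FALSE)
  }
  need <- c("sample_id", "clade", "subclade_label")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  ok_clades <- c("NEANDERTHAL", "ARCHAIC_AMH", "MODERN", "REFERENCE")
  bad <- setdiff(unique(metadata$clade), ok_clades)
  if (length(bad)) stop("unknown clade(s): ", paste(bad, collapse = ", "))
  missing_meta <- setdiff(names(sequences), metadata$sample_id)
  if (length(missing_meta))
    stop("samples without metadata: ", paste(missing_meta, collapse = ", "))
  metadata <- metadata[match(names(sequences), metadata$sample_id), ]
  rownames(metadata) <- NULL
  structure(list(sequences = sequences, metadata = metadata),
            class = "mitogenome_set")
}

#' @export
print.mitogenome_set <- function(x, ...) {
  cat("<mitogenome_set> ", length(x$sequences), " samples, aligned length ",
      nchar(x$sequences[[1]]), "\n", sep = "")
  print(table(x$metadata$clade))
  invisible(x)
}

# character matrix (samples x columns) view of the alignment
seq_matrix <- function(mset) {
  m <- do.call(rbind, strsplit(unname(mset$sequences), ""))
  rownames(m) <- names(mset$sequences)
  m
}

#' Anchor an alignment to the rCRS reference
#'
#' Maps every alignment column to an rCRS position using the gap pattern of
#' the reference row. Columns where the reference holds a gap are flagged as
#' insertions (mapped to `NA`) and never yield variant rows; all other columns
#' map 1:1, monotonically, to rCRS positions, so every downstream coordinate is
#' in rCRS numbering.
#'
#' @param mset A [mitogenome_set()].
#' @param reference Sample id of the reference row (default `"rCRS"`), or a
#'   bare (ungapped) reference sequence that must match one row of the
#'   alignment after gap removal.
#' @return An object of class `reference_anchor`: list with `reference_id`,
#'   `rcrs_sequence` (ungapped), `column_to_position` (integer, `NA` for
#'   insertion columns) and `n_positions`.
#' @export
anchor_to_reference <- function(mset, reference = "rCRS") {
  stopifnot(inherits(mset, "mitogenome_set"))
  if (reference[[1]] %in% names(mset$sequences)) {
    ref_id <- reference[[1]]
  } else if (grepl("^[ACGTNacgtn]+$", reference[[1]]) &&
             nchar(reference[[1]]) > 50L) {
    degap <- gsub("-", "", mset$sequences, fixed = TRUE)
    hit <- which(degap == toupper(reference))
    if (!length(hit))
      stop("reference sequence not found in the set; supply it as a row ",
           "or pass the id of an existing row")
    ref_id <- names(mset$sequences)[hit[1]]
  } else {
    stop("reference row '", reference[[1]], "' absent from the alignment")
  }
  ref_row <- strsplit(mset$sequences[[ref_id]], "")[[1]]
  is_ins <- ref_row == "-"
  col2pos <- rep(NA_integer_, length(ref_row))
  col2pos[!is_ins] <- seq_len(sum(!is_ins))
  structure(list(reference_id = ref_id,
                 rcrs_sequence = paste(ref_row[!is_ins], collapse = ""),
                 column_to_position = col2pos,
                 n_positions = sum(!is_ins)),
            class = "reference_anchor")
}

#' Map unaligned sequences onto the reference by pairwise alignment
#'
#' Emulates a map-to-reference assembly of complete mitogenomes: each sample is
#' globally aligned to the reference (affine gap penalties; defaults documented
#' below) and the alignments are merged on reference coordinates. Insertions
#' relative to the reference are recorded in the `insertions` attribute of the
#' result and excluded from the merged alignment, which therefore has exactly
#' one column per reference position.
#'
#' Alignment scoring defaults: match +2, mismatch -1, gap opening 10, gap
#' extension 0.5 (Biostrings conventions).
#'
#' @param sequences Named character vector of ungapped sequences.
#' @param reference Reference sequence string (default [rcrs_reference()]).
#' @param metadata Optional metadata as in [mitogenome_set()].
#' @return A [mitogenome_set()] whose columns are reference positions, with the
#'   reference included as first row (id `"rCRS"`), and an `insertions`
#'   attribute (`data.frame`: sample_id, after_position, inserted sequence).
#' @export
map_to_reference <- function(sequences, reference = rcrs_reference(),
                             metadata = NULL) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  L <- nchar(reference)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                  baseOnly = FALSE)
  rows <- character(length(sequences))
  ins <- list()
  for (i in seq_along(sequences)) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = sequences[[i]], subject = reference, type = "global",
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5)
    p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    out <- rep("-", L)
    pos <- 0L
    j <- 1L
    while (j <= length(s)) {
      if (s[j] != "-") {
        pos <- pos + 1L
        out[pos] <- p[j]
        j <- j + 1L
      } else {
        k <- j
        while (k <= length(s) && s[k] == "-") k <- k + 1L
        ins[[length(ins) + 1L]] <- data.frame(
          sample_id = names(sequences)[i], after_position = pos,
          insertion = paste(p[j:(k - 1L)], collapse = ""),
          stringsAsFactors = FALSE)
        j <- k
      }
    }
    rows[i] <- paste(out, collapse = "")
  }
  names(rows) <- names(sequences)
  all_seqs <- c(rCRS = reference, rows)
  if (!is.null(metadata) && !"rCRS" %in% metadata$sample_id) {
    metadata <- rbind(data.frame(sample_id = "rCRS", clade = "REFERENCE",
                                 subclade_label = "H2a2a1",
                                 stringsAsFactors = FALSE),
                      metadata[, c("sample_id", "clade", "subclade_label")])
  }
  out <- mitogenome_set(all_seqs, metadata)
  attr(out, "insertions") <- if (length(ins)) do.call(rbind, ins) else
    data.frame(sample_id = character(), after_position = integer(),
               insertion = character(), stringsAsFactors = FALSE)
  out
}

#' Call the polymorphic-site table from an anchored alignment
#'
#' Scans every reference-mapped column and emits one row per column carrying at
#' least two distinct alleles among `{A,C,G,T}`. `N` is treated as missing data
#' and ignored when deciding polymorphism; alignment gaps (`-`) do not count as
#' alleles but set `has_gap = TRUE` on the row, so downstream stages that must
#' exclude gapped positions (PCA, bootscan tree building) can do so while the
#' descriptive SNV census retains them. Insertion columns never yield rows.
#' Columns with more than two alleles are kept as single multiallelic rows.
#'
#' @param mset A [mitogenome_set()].
#' @param anchor A [anchor_to_reference()] result for `mset`.
#' @param include_reference Should the reference row count as a sample when
#'   determining polymorphism? Default `TRUE` (the rCRS is itself a modern
#'   haplogroup H2a2a1 genome).
#' @return An object of class `variant_table`: list with `sites` (`data.frame`:
#'   `position`, `ref`, `alt` (comma-separated for multiallelic), `has_gap`,
#'   `n_alleles`) and `calls` (character matrix, samples x sites; colnames are
#'   rCRS positions).
#' @export
call_variants <- function(mset, anchor, include_reference = TRUE) {
  stopifnot(inherits(mset, "mitogenome_set"),
            inherits(anchor, "reference_anchor"))
  m <- seq_matrix(mset)
  if (!include_reference && anchor$reference_id %in% rownames(m))
    m <- m[setdiff(rownames(m), anchor$reference_id), , drop = FALSE]
  refchars <- strsplit(anchor$rcrs_sequence, "")[[1]]
  keep <- which(!is.na(anchor$column_to_position))
  pos <- integer(0); ref <- character(0); alt <- character(0)
  has_gap <- logical(0); n_alleles <- integer(0); cols <- integer(0)
  for (j in keep) {
    col <- m[, j]
    acgt <- unique(col[col %in% c("A", "C", "G", "T")])
    if (length(acgt) < 2L) next
    p <- anchor$column_to_position[j]
    r <- refchars[p]
    a <- sort(setdiff(acgt, r))
    pos <- c(pos, p); ref <- c(ref, r)
    alt <- c(alt, paste(a, collapse = ","))
    has_gap <- c(has_gap, any(col == "-"))
    n_alleles <- c(n_alleles, length(acgt))
    cols <- c(cols, j)
  }
  calls <- m[, cols, drop = FALSE]
  colnames(calls) <- as.character(pos)
  structure(list(
    sites = data.frame(position = pos, ref = ref, alt = alt,
                       has_gap = has_gap, n_alleles = n_alleles,
                       stringsAsFactors = FALSE),
    calls = calls,
    reference_id = anchor$reference_id),
    class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("<variant_table> ", nrow(x$sites), " polymorphic sites, ",
      nrow(x$calls), " samples (", sum(x$sites$has_gap),
      " sites overlap a gap)\n", sep = "")
  invisible(x)
}

#' Reconstruct aligned sequences from a reference and a variant table
#'
#' Inverse of [call_variants()] for gap-free tables: every sample sequence is
#' the reference with its called alleles substituted. Used mainly for
#' round-trip validation.
#'
#' @param vt A [call_variants()] result.
#' @param reference Reference sequence string.
#' @return Named character vector of sequences.
#' @export
reconstruct_sequences <- function(vt, reference) {
  stopifnot(inherits(vt, "variant_table"))
  refchars <- strsplit(reference, "")[[1]]
  out <- vapply(rownames(vt$calls), function(s) {
    chars <- refchars
    chars[vt$sites$position] <- vt$calls[s, ]
    paste(chars, collapse = "")
  }, "")
  out
}

#' Write a variant table as haploid VCF 4.2
#'
#' One data line per site, `CHROM` fixed to `chrM`, `POS` in rCRS numbering,
#' comma-separated `ALT` for multiallelic rows, and a single haploid `GT` field
#' per sample (`0`, `1`, ... by allele index; `.` for missing `N` or gap).
#' Rows overlapping an alignment gap carry the `HG` INFO flag.
#'
#' @param vt A [call_variants()] result.
#' @param path Output file path.
#' @param contig_length Reference length written in the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path, contig_length = 16569L) {
  stopifnot(inherits(vt, "variant_table"))
  samples <- rownames(vt$calls)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write VCF to ", path)
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chrM,length=%d>", contig_length),
    "##INFO=<ID=HG,Number=0,Type=Flag,Description=\"Site overlaps an alignment gap in at least one sample\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  if (nrow(vt$sites)) {
    for (i in seq_len(nrow(vt$sites))) {
      alleles <- c(vt$sites$ref[i], strsplit(vt$sites$alt[i], ",")[[1]])
      gt <- as.character(match(vt$calls[, i], alleles) - 1L)
      gt[is.na(gt)] <- "."
      writeLines(paste(c("chrM", vt$sites$position[i], ".", vt$sites$ref[i],
                         vt$sites$alt[i], ".", "PASS",
                         if (vt$sites$has_gap[i]) "HG" else ".",
                         "GT", gt), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Write a variant table as TSV
#'
#' @param vt A [call_variants()] result.
#' @param path Output file path.
#' @param calls Include one column per sample with the raw allele calls?
#' @return `path`, invisibly.
#' @export
write_variant_tsv <- function(vt, path, calls = FALSE) {
  stopifnot(inherits(vt, "variant_table"))
  df <- vt$sites
  if (calls) df <- cbind(df, as.data.frame(t(vt$calls)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
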