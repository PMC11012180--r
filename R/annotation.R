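#' Locate an rCRS position on the mitochondrial gene map
#'
#' Returns the feature containing a position. In annotated gene overlaps
#' (ATP8/ATP6 and ND4L/ND4) the downstream-reading-frame gene (the one whose
#' frame continues past the overlap) is reported as primary and the alternative
#' is listed in `overlap`.
#'
#' @param position Integer rCRS position in `[1, 16569]`.
#' @param gene_map Gene map `data.frame` (default [rcrs_gene_map()]).
#' @return A list with `name`, `start`, `end`, `strand`, `kind`, `overlap`
#'   (character vector of co-located feature names, possibly empty), or `NULL`
#'   for positions in intergenic spacers.
#' @examples
#' classify_site(2706)$name   # 16S rRNA
#' classify_site(5821)$name   # tRNA-Cys
#' classify_site(146)$kind    # CONTROL (D-loop)
#' @export
classify_site <- function(position, gene_map = rcrs_gene_map()) {
  stopifnot(length(position) == 1L, !is.na(position))
  position <- as.integer(position)
  if (position < 1L || position > 16569L)
    stop("position ", position, " outside [1, 16569]")
  hits <- gene_map[gene_map$start <= position & gene_map$end >= position, ]
  if (!nrow(hits)) return(NULL)
  if (nrow(hits) > 1L && any(hits$kind == "PROTEIN")) {
    prot <- hits[hits$kind == "PROTEIN", ]
    primary <- prot[which.max(prot$start), ]
  } else {
    primary <- hits[1L, ]
  }
  list(name = primary$name, start = primary$start, end = primary$end,
       strand = primary$strand, kind = primary$kind,
       overlap = setdiff(hits$name, primary$name))
}

#' Transition or transversion
#'
#' @param ref,alt Distinct single bases in `{A,C,G,T}`.
#' @return `"TRANSITION"` (purine-purine or pyrimidine-pyrimidine) or
#'   `"TRANSVERSION"`. Vectorised over `ref`/`alt`.
#' @examples
#' ts_tv("T", "A")  # TRANSVERSION
#' ts_tv("A", "G")  # TRANSITION
#' @export
ts_tv <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  ok <- c("A", "C", "G", "T")
  if (!all(ref %in% ok) || !all(alt %in% ok))
    stop("ref and alt must be bases in {A,C,G,T}")
  if (any(ref == alt)) stop("ref and alt must differ")
  purine <- c("A", "G")
  ifelse((ref %in% purine) == (alt %in% purine), "TRANSITION", "TRANSVERSION")
}

#' Codon-level effect of a substitution in a protein-coding gene
#'
#' Computes the codon index and within-codon position from the CDS start (or,
#' for light-strand genes such as ND6, from the CDS 3' genomic end reading
#' downward), extracts the reference codon on the coding strand
#' (reverse-complementing light-strand codons and alleles), substitutes the
#' alternate allele and translates both codons with the vertebrate
#' mitochondrial genetic code (`TGA`=Trp, `ATA`=Met, `AGA`/`AGG`=stop).
#' Codons truncated by the gene boundary (incomplete, polyadenylation-completed
#' stop codons) get a codon position but no effect call.
#'
#' @param position rCRS position inside a protein-coding feature.
#' @param ref,alt Heavy-strand (reference-strand) alleles.
#' @param reference Reference sequence string (default [rcrs_reference()]).
#' @param gene_map Gene map (default [rcrs_gene_map()]).
#' @return List with `gene`, `strand`, `codon_position` (1|2|3), `ref_codon`,
#'   `alt_codon` (coding strand), `ref_aa`, `alt_aa`, and `effect`
#'   (`"SYNONYMOUS"` or `"NONSYNONYMOUS"`; `NA` for incomplete codons).
#' @examples
#' ref <- rcrs_reference()
#' codon_effect(5460, "G", "A", ref)$effect  # NONSYNONYMOUS (Ala -> Thr)
#' codon_effect(3594, "C", "T", ref)$effect  # SYNONYMOUS
#' @export
codon_effect <- function(position, ref, alt, reference = rcrs_reference(),
                         gene_map = rcrs_gene_map()) {
  feat <- classify_site(position, gene_map)
  if (is.null(feat) || feat$kind != "PROTEIN")
    stop("position ", position, " is not inside a protein-coding feature")
  refchars <- strsplit(reference, "")[[1]]
  if (!identical(refchars[position], ref))
    stop("ref allele ", ref, " does not match the reference base '",
         refchars[position], "' at position ", position)
  if (feat$strand == "H") {
    off <- position - feat$start
    cpos <- off %% 3L + 1L
    cstart <- feat$start + 3L * (off %/% 3L)
    span <- cstart + 0:2
    complete <- span[3] <= feat$end
    ref_codon <- refchars[span[span <= feat$end]]
    alt_codon <- ref_codon
    alt_codon[cpos] <- alt
  } else {
    off <- feat$end - position
    cpos <- off %% 3L + 1L
    ctop <- feat$end - 3L * (off %/% 3L)
    span <- ctop - 0:2
    complete <- span[3] >= feat$start
    ref_codon <- complement_base(refchars[span[span >= feat$start]])
    alt_codon <- ref_codon
    alt_codon[cpos] <- complement_base(alt)
  }
  ref_codon <- paste(ref_codon, collapse = "")
  alt_codon <- paste(alt_codon, collapse = "")
  if (complete && !grepl("N", ref_codon, fixed = TRUE)) {
    ref_aa <- translate_mito(ref_codon)
    alt_aa <- translate_mito(alt_codon)
    effect <- if (identical(ref_aa, alt_aa)) "SYNONYMOUS" else "NONSYNONYMOUS"
  } else {
    ref_aa <- alt_aa <- effect <- NA_character_
  }
  list(gene = feat$name, strand = feat$strand, codon_position = cpos,
       ref_codon = ref_codon, alt_codon = alt_codon,
       ref_aa = ref_aa, alt_aa = alt_aa, effect = effect)
}

#' Annotate a variant table against the mitochondrial gene map
#'
#' Produces one annotation per (position, alt allele) pair: genomic region,
#' transition/transversion class, and - for protein-coding positions - codon
#' change and protein effect under the vertebrate mitochondrial code.
#'
#' @param x A [call_variants()] result, or a `data.frame` with columns
#'   `position`, `ref`, `alt` (`alt` may be comma-separated).
#' @param reference Reference sequence string (default [rcrs_reference()]).
#' @param gene_map Gene map (default [rcrs_gene_map()]).
#' @return `data.frame` with columns `position`, `ref`, `alt`,
#'   `mutation_class`, `region` (feature name or `"intergenic"`), `kind`,
#'   `overlap`, `codon_position`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `effect` (`NONCODING`, `RNA_GENE`, `SYNONYMOUS`, `NONSYNONYMOUS`).
#' @export
annotate_variants <- function(x, reference = rcrs_reference(),
                              gene_map = rcrs_gene_map()) {
  df <- if (inherits(x, "variant_table")) x$sites else x
  stopifnot(all(c("position", "ref", "alt") %in% names(df)))
  alts <- strsplit(df$alt, ",", fixed = TRUE)
  n <- lengths(alts)
  out <- data.frame(position = rep(df$position, n), ref = rep(df$ref, n),
                    alt = unlist(alts), stringsAsFactors = FALSE)
  if (!nrow(out)) {
    empty <- out
    for (cn in c("mutation_class", "region", "kind", "overlap", "ref_codon",
                 "alt_codon", "ref_aa", "alt_aa", "effect"))
      empty[[cn]] <- character(0)
    empty$codon_position <- integer(0)
    return(empty)
  }
  out$mutation_class <- ts_tv(out$ref, out$alt)
  feats <- lapply(out$position, classify_site, gene_map = gene_map)
  out$region <- vapply(feats, function(f) if (is.null(f)) "intergenic" else f$name, "")
  out$kind <- vapply(feats, function(f) if (is.null(f)) "INTERGENIC" else f$kind, "")
  out$overlap <- vapply(feats, function(f)
    if (is.null(f) || !length(f$overlap)) "" else
      paste(f$overlap, collapse = ","), "")
  out$codon_position <- NA_integer_
  out$ref_codon <- out$alt_codon <- out$ref_aa <- out$alt_aa <- NA_character_
  out$effect <- ifelse(out$kind %in% c("TRNA", "RRNA"), "RNA_GENE", "NONCODING")
  prot <- which(out$kind == "PROTEIN")
  for (i in prot) {
    ce <- codon_effect(out$position[i], out$ref[i], out$alt[i],
                       reference = reference, gene_map = gene_map)
    out$codon_position[i] <- ce$codon_position
    out$ref_codon[i] <- ce$ref_codon
    out$alt_codon[i] <- ce$alt_codon
    out$ref_aa[i] <- ce$ref_aa
    out$alt_aa[i] <- ce$alt_aa
    out$effect[i] <- if (is.na(ce$effect)) NA_character_ else ce$effect
  }
  out
}

#' Export the gene map as BED
#'
#' Writes the bundled (1-based inclusive) gene map in 0-based half-open BED
#' coordinates. The wrapped control region stays split in two records.
#'
#' @param path Output path.
#' @param gene_map Gene map (default [rcrs_gene_map()]).
#' @return `path`, invisibly.
#' @export
write_gene_map_bed <- function(path, gene_map = rcrs_gene_map()) {
  bed <- data.frame(chrom = "chrM", start = gene_map$start - 1L,
                    end = gene_map$end, name = gene_map$name, score = 0L,
                    strand = ifelse(gene_map$strand == "H", "+", "-"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
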