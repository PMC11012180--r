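#' Partition samples into the five analysis clades
#'
#' The pattern analysis distinguishes five clades: two Neanderthal subgroups
#' (an H-like group of late European genomes and an L-like group containing the
#' oldest genomes, e.g. Altai and Mezmaiskaya), archaic anatomically modern
#' humans (AMHs), present-day haplogroup L (African) carriers and present-day
#' Eurasian haplogroup carriers. Subgroup assignment is driven by the editable
#' subclade labels in the metadata, not hard-coded: Neanderthals whose label
#' matches `neanderthal_L_regex` go to the L-like subgroup, modern samples
#' whose label matches `modern_L_regex` to modern L. Reference rows (clade
#' `REFERENCE`) are excluded.
#'
#' @param metadata Metadata `data.frame` (`sample_id`, `clade`,
#'   `subclade_label`) or a [mitogenome_set()].
#' @param neanderthal_L_regex,modern_L_regex Regexes applied to
#'   `subclade_label`.
#' @return Object of class `clade_partition`: list of five disjoint sample-id
#'   vectors `neanderthal_H`, `neanderthal_L`, `archaic_amh`, `modern_L`,
#'   `modern_eurasian`.
#' @export
make_clade_partition <- function(metadata, neanderthal_L_regex = "^L",
                                 modern_L_regex = "^L") {
  if (inherits(metadata, "mitogenome_set")) metadata <- metadata$metadata
  md <- metadata[metadata$clade != "REFERENCE", ]
  nea <- md[md$clade == "NEANDERTHAL", ]
  nea_L <- grepl(neanderthal_L_regex, nea$subclade_label)
  mod <- md[md$clade == "MODERN", ]
  mod_L <- grepl(modern_L_regex, mod$subclade_label)
  structure(list(
    neanderthal_H = nea$sample_id[!nea_L],
    neanderthal_L = nea$sample_id[nea_L],
    archaic_amh = md$sample_id[md$clade == "ARCHAIC_AMH"],
    modern_L = mod$sample_id[mod_L],
    modern_eurasian = mod$sample_id[!mod_L]),
    class = "clade_partition")
}

#' Assign a clade-presence pattern
#'
#' Maps derived-allele presence across the analysis clades to one of five
#' patterns. The two Neanderthal subgroups are collapsed with OR (presence in
#' either counts as Neanderthal presence).
#'
#' * Pattern 1 - present in Neanderthals, archaic AMHs and both modern clades;
#' * Pattern 2 - Neanderthals and archaic AMHs only;
#' * Pattern 3 - Neanderthals and both modern clades, absent in archaic AMHs;
#' * Pattern 4 - Neanderthals and modern haplogroup L only;
#' * Pattern 5 - Neanderthals and modern Eurasian haplogroups only;
#' * `NA` otherwise (including any allele absent from all Neanderthals).
#'
#' @param nea,archaic,modern_L,modern_eurasian Logical vectors of
#'   derived-allele presence per clade.
#' @return Integer vector of pattern ids (1-5) or `NA`.
#' @export
assign_pattern <- function(nea, archaic, modern_L, modern_eurasian) {
  n <- length(nea)
  stopifnot(length(archaic) == n, length(modern_L) == n,
            length(modern_eurasian) == n)
  out <- rep(NA_integer_, n)
  out[nea & archaic & modern_L & modern_eurasian] <- 1L
  out[nea & archaic & !modern_L & !modern_eurasian] <- 2L
  out[nea & !archaic & modern_L & modern_eurasian] <- 3L
  out[nea & !archaic & modern_L & !modern_eurasian] <- 4L
  out[nea & !archaic & !modern_L & modern_eurasian] <- 5L
  out
}

#' Call Neanderthal-shared variants (N-SNVs) and their presence patterns
#'
#' For every polymorphic position, finds the Neanderthal-shared allele(s) (the
#' non-reference alleles carried by at least one Neanderthal), evaluates
#' derived-allele presence per clade (missing data, `N` or gap, counts as
#' absence), and flags the site as an N-SNV when the allele is present in at
#' least one Neanderthal and at least one modern sample but in no archaic AMH.
#' Sites whose only archaic evidence is missing data can still be N-SNVs but
#' are flagged `low_confidence`. Alleles carried by Neanderthals only are
#' flagged `nea_exclusive` (candidates for the Neanderthal-specific class).
#'
#' @param vt A [call_variants()] result.
#' @param partition A [make_clade_partition()].
#' @return `data.frame` of class `pattern_calls`: one row per (position,
#'   Neanderthal-carried allele), plus one row with `allele = NA` for
#'   polymorphic positions without any Neanderthal-carried alternate allele.
#'   Columns: `position`, `allele`, the five presence flags, `pattern`,
#'   `is_nsnv`, `nea_exclusive`, `low_confidence`.
#' @export
call_nsnv <- function(vt, partition) {
  stopifnot(inherits(vt, "variant_table"), inherits(partition, "clade_partition"))
  samples <- rownames(vt$calls)
  missing_part <- setdiff(
    samples[samples != vt$reference_id], unlist(partition))
  if (length(missing_part))
    stop("samples absent from the clade partition: ",
         paste(missing_part, collapse = ", "))
  idx <- lapply(unclass(partition), function(s) match(s, samples))
  rows <- vector("list", nrow(vt$sites))
  for (i in seq_len(nrow(vt$sites))) {
    col <- vt$calls[, i]
    alts <- strsplit(vt$sites$alt[i], ",", fixed = TRUE)[[1]]
    nea_calls <- col[c(idx$neanderthal_H, idx$neanderthal_L)]
    arch_calls <- col[idx$archaic_amh]
    nea_alts <- alts[alts %in% nea_calls]
    low_conf <- any(!arch_calls %in% c("A", "C", "G", "T"))
    if (!length(nea_alts)) {
      rows[[i]] <- data.frame(
        position = vt$sites$position[i], allele = NA_character_,
        in_neanderthal_H = FALSE, in_neanderthal_L = FALSE,
        in_archaic = FALSE, in_modern_L = FALSE, in_modern_eurasian = FALSE,
        pattern = NA_integer_, is_nsnv = FALSE, nea_exclusive = FALSE,
        low_confidence = low_conf, stringsAsFactors = FALSE)
      next
    }
    rows[[i]] <- do.call(rbind, lapply(nea_alts, function(a) {
      pres <- vapply(idx, function(j) any(col[j] == a), TRUE)
      nea <- pres[["neanderthal_H"]] || pres[["neanderthal_L"]]
      pat <- assign_pattern(nea, pres[["archaic_amh"]], pres[["modern_L"]],
                            pres[["modern_eurasian"]])
      data.frame(
        position = vt$sites$position[i], allele = a,
        in_neanderthal_H = pres[["neanderthal_H"]],
        in_neanderthal_L = pres[["neanderthal_L"]],
        in_archaic = pres[["archaic_amh"]],
        in_modern_L = pres[["modern_L"]],
        in_modern_eurasian = pres[["modern_eurasian"]],
        pattern = pat,
        is_nsnv = nea && !pres[["archaic_amh"]] &&
          (pres[["modern_L"]] || pres[["modern_eurasian"]]),
        nea_exclusive = nea && !pres[["archaic_amh"]] &&
          !pres[["modern_L"]] && !pres[["modern_eurasian"]],
        low_confidence = low_conf, stringsAsFactors = FALSE)
    }))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), allele = character(),
               in_neanderthal_H = logical(), in_neanderthal_L = logical(),
               in_archaic = logical(), in_modern_L = logical(),
               in_modern_eurasian = logical(), pattern = integer(),
               is_nsnv = logical(), nea_exclusive = logical(),
               low_confidence = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pattern_calls", "data.frame")
  out
}

#' Census of patterns and of N-SNV placement per haplogroup and region
#'
#' Summarises [call_nsnv()] output: counts per pattern, the N-SNV total, and a
#' haplogroup-by-region count matrix (rows = modern subclade labels, columns =
#' gene-map regions) where cell (h, r) counts the N-SNVs in region r whose
#' derived allele is carried by at least one sample of haplogroup h.
#'
#' @param calls A [call_nsnv()] result.
#' @param vt The [call_variants()] result the calls were made from.
#' @param mset The [mitogenome_set()] providing subclade labels.
#' @param gene_map Gene map used for region binning.
#' @return List with `pattern_counts` (named integer vector `P1`-`P5` and
#'   `NONE`), `n_nsnv`, and `region_matrix`.
#' @export
pattern_census <- function(calls, vt, mset, gene_map = rcrs_gene_map()) {
  stopifnot(inherits(calls, "pattern_calls"))
  pat <- factor(ifelse(is.na(calls$pattern), "NONE",
                       paste0("P", calls$pattern)),
                levels = c(paste0("P", 1:5), "NONE"))
  pattern_counts <- table(pat)
  nsnv <- calls[calls$is_nsnv, , drop = FALSE]
  md <- mset$metadata
  modern <- md[md$clade == "MODERN", ]
  regions <- unique(gene_map$name)
  m <- matrix(0L, nrow = length(unique(modern$subclade_label)),
              ncol = length(regions),
              dimnames = list(sort(unique(modern$subclade_label)), regions))
  if (nrow(nsnv)) {
    for (i in seq_len(nrow(nsnv))) {
      feat <- classify_site(nsnv$position[i], gene_map)
      region <- if (is.null(feat)) NA_character_ else feat$name
      if (is.na(region)) next
      colcalls <- vt$calls[, as.character(nsnv$position[i])]
      carriers <- modern$subclade_label[
        colcalls[match(modern$sample_id, rownames(vt$calls))] == nsnv$allele[i]]
      for (h in unique(carriers[!is.na(carriers)]))
        m[h, region] <- m[h, region] + 1L
    }
  }
  list(pattern_counts = c(pattern_counts), n_nsnv = sum(calls$is_nsnv),
       region_matrix = m)
}

#' Allele-sharing bipartition at a site
#'
#' For each alternate allele at a position, splits the samples into carriers
#' and non-carriers, labelled with their clade memberships. This is the
#' informative content of a per-site cladogram: which clades share the derived
#' state.
#'
#' @param position rCRS position present in the variant table.
#' @param vt A [call_variants()] result.
#' @param partition A [make_clade_partition()].
#' @return List with one element per alternate allele: list(`allele`,
#'   `carriers`, `non_carriers`, `carrier_clades`).
#' @export
allele_sharing_partition <- function(position, vt, partition) {
  i <- match(position, vt$sites$position)
  if (is.na(i)) stop("position ", position, " not in the variant table")
  col <- vt$calls[, i]
  alts <- strsplit(vt$sites$alt[i], ",", fixed = TRUE)[[1]]
  clade_of <- rep(names(unclass(partition)), lengths(unclass(partition)))
  names(clade_of) <- unlist(partition)
  lapply(alts, function(a) {
    carriers <- names(col)[col == a]
    list(allele = a, carriers = carriers,
         non_carriers = setdiff(names(col), carriers),
         carrier_clades = sort(unique(unname(clade_of[carriers]))))
  })
}
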