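# Sliding-window bootstrap recombination scan (bootscan) and its building
# blocks: K80/JC69 distances, neighbor joining, per-window bootstrap support.

.encode_bases <- function(m) {
  stopifnot(is.matrix(m))
  out <- matrix(-1L, nrow(m), ncol(m), dimnames = dimnames(m))
  out[m == "A"] <- 0L; out[m == "C"] <- 1L
  out[m == "G"] <- 2L; out[m == "T"] <- 3L
  out
}

.as_char_matrix <- function(x) {
  if (inherits(x, "mitogenome_set")) return(seq_matrix(x))
  if (is.matrix(x) && is.character(x)) return(x)
  if (is.character(x) && !is.null(names(x)))
    return(do.call(rbind, strsplit(x, "")))
  stop("expected a mitogenome_set, a character matrix, ",
       "or a named character vector of aligned sequences")
}

#' Bootscan configuration
#'
#' Defaults follow the standard manual-bootscan parameterisation for
#' mitogenome screens: 200-column windows advanced by 20 columns, 1000
#' bootstrap replicates per window, a 70% support cutoff, and Kimura
#' two-parameter distances.
#'
#' @param window_size Window width in alignment columns.
#' @param step_size Step between window starts (columns);
#'   `0 < step_size < window_size`.
#' @param replicates Bootstrap replicates per window.
#' @param cutoff_percent Support cutoff in `(0, 100]` used to flag windows.
#' @param distance_model `"K80"` or `"JC69"` (F81 is not provided).
#' @param seed Integer seed; per-window substreams are derived from
#'   `(seed, window index)` so serial and window-parallel runs agree.
#' @param saturation_ceiling Distance assigned when the distance formula
#'   leaves its log domain (saturation) or no sites are comparable.
#' @param min_run Minimum number of consecutive flagged windows for a
#'   flagged segment (1 reports single-window signals as segments too).
#' @return Object of class `bootscan_config`.
#' @export
bootscan_config <- function(window_size = 200L, step_size = 20L,
                            replicates = 1000L, cutoff_percent = 70,
                            distance_model = c("K80", "JC69"), seed = 1L,
                            saturation_ceiling = 5, min_run = 1L) {
  distance_model <- match.arg(distance_model)
  if (!(window_size > step_size && step_size > 0))
    stop("need window_size > step_size > 0")
  if (replicates < 1) stop("replicates must be >= 1")
  if (!(cutoff_percent > 0 && cutoff_percent <= 100))
    stop("cutoff_percent must be in (0, 100]")
  structure(list(window_size = as.integer(window_size),
                 step_size = as.integer(step_size),
                 replicates = as.integer(replicates),
                 cutoff_percent = cutoff_percent,
                 distance_model = distance_model,
                 seed = as.integer(seed),
                 saturation_ceiling = saturation_ceiling,
                 min_run = as.integer(min_run)),
            class = "bootscan_config")
}

.model_code <- function(model) if (model == "JC69") 1L else 0L

#' Kimura two-parameter distance between two aligned sequences
#'
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` with `P` and `Q` the
#' transition and transversion proportions over pairwise-comparable sites
#' (positions with a gap or `N` in either sequence are excluded). When the
#' argument of a logarithm is non-positive (saturation) the distance is set to
#' `saturation_ceiling` with a warning rather than failing.
#'
#' @param seq_a,seq_b Aligned sequences (strings or character vectors of equal
#'   length).
#' @param saturation_ceiling Value returned on saturation.
#' @return List with `distance`, `comparable` (site count), `P`, `Q`.
#' @examples
#' k80_distance("AAAA", "AAAA")$distance  # 0
#' @export
k80_distance <- function(seq_a, seq_b, saturation_ceiling = 5) {
  a <- if (length(seq_a) == 1L) strsplit(seq_a, "")[[1]] else seq_a
  b <- if (length(seq_b) == 1L) strsplit(seq_b, "")[[1]] else seq_b
  if (length(a) != length(b)) stop("sequences must have equal aligned length")
  enc <- function(x) {
    e <- rep(-1L, length(x))
    e[x == "A"] <- 0L; e[x == "C"] <- 1L; e[x == "G"] <- 2L; e[x == "T"] <- 3L
    e
  }
  out <- cpp_k80_pair(enc(a), enc(b), saturation_ceiling)
  if (out$comparable == 0)
    stop("no pairwise-comparable sites between the two sequences")
  if (1 - 2 * out$P - out$Q <= 0 || 1 - 2 * out$Q <= 0)
    warning("K80 distance saturated; returning ceiling ", saturation_ceiling)
  out
}

#' Pairwise distance matrix for an alignment
#'
#' @param x Alignment (see [bootscan()] for accepted forms).
#' @param model `"K80"` or `"JC69"`.
#' @param saturation_ceiling Distance on saturation.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(x, model = c("K80", "JC69"),
                            saturation_ceiling = 5) {
  model <- match.arg(model)
  m <- .encode_bases(.as_char_matrix(x))
  d <- cpp_k80_matrix(m, saturation_ceiling, .model_code(model))
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration with deterministic tie-breaking (smallest
#' index pair) and negative branch lengths clamped to zero. An all-zero
#' distance matrix yields a star tree.
#'
#' @param d Symmetric distance matrix (or `dist`) with taxon labels.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (max(d) == 0) {
    tr <- ape::stree(n, type = "star", tip.label = labels)
    tr$edge.length <- rep(0, nrow(tr$edge))
    return(tr)
  }
  res <- cpp_nj(d)
  edge <- res$edge
  # renumber internal nodes so the final 3-way center becomes n + 1
  remap <- function(x) ifelse(x <= n, x, 3L * n - 1L - x)
  edge <- cbind(remap(edge[, 1]), remap(edge[, 2]))
  tr <- structure(list(edge = edge, edge.length = as.numeric(res$edge_length),
                       tip.label = labels, Nnode = n - 2L),
                  class = "phylo", order = NULL)
  ape::reorder.phylo(tr, "cladewise")
}

#' Bootstrap support for query-parental grouping in one window
#'
#' For each bootstrap replicate, the window's columns are resampled with
#' replacement (within the window only), a neighbor-joining tree of query,
#' parentals and background taxa is built on the configured distance, and the
#' replicate votes for the parental contained in the smallest clade holding
#' the query and at least one parental (ties split equally; replicates whose
#' resample has no variable site, or whose minimal clade is uninformative,
#' count as unresolved).
#'
#' @param x Alignment (a [mitogenome_set()], character matrix, or named
#'   character vector of aligned sequences).
#' @param query Sample id of the query.
#' @param parentals Sample ids of candidate parentals (>= 2 for a meaningful
#'   scan; >= 1 accepted).
#' @param window Integer `c(start, end)` in alignment columns (1-based,
#'   inclusive); default the whole alignment.
#' @param config A [bootscan_config()]. The RNG is taken from the current R
#'   random state; [bootscan()] seeds it per window.
#' @param others Background sample ids (default: all remaining samples).
#' @return Named numeric vector of percentages: one entry per parental plus
#'   `"unresolved"`.
#' @export
window_support <- function(x, query, parentals, window = NULL,
                           config = bootscan_config(), others = NULL) {
  m <- .as_char_matrix(x)
  if (is.null(others)) others <- setdiff(rownames(m), c(query, parentals))
  taxa <- c(query, parentals, others)
  if (!all(taxa %in% rownames(m)))
    stop("unknown sample id(s): ",
         paste(setdiff(taxa, rownames(m)), collapse = ", "))
  if (is.null(window)) window <- c(1L, ncol(m))
  stopifnot(window[1] >= 1, window[2] <= ncol(m), window[1] <= window[2])
  sub <- m[taxa, window[1]:window[2], drop = FALSE]
  enc <- .encode_bases(sub)
  sup <- cpp_window_support(enc, 0L, seq_along(parentals),
                            config$replicates, config$saturation_ceiling,
                            .model_code(config$distance_model))
  names(sup) <- c(parentals, "unresolved")
  sup
}

#' Sliding-window bootstrap recombination scan
#'
#' Slides windows of `window_size` alignment columns at `step_size` along the
#' alignment, computes [window_support()] in each, and extracts maximal runs
#' of consecutive windows in which one parental's support reaches
#' `cutoff_percent` as flagged segments. Columns containing a gap in any used
#' sequence are excluded from resampling (they shrink windows rather than
#' shifting them); when an anchor is supplied, window coordinates are reported
#' as rCRS positions of the window's mapped columns.
#'
#' @inheritParams window_support
#' @param anchor Optional [anchor_to_reference()] result used to report rCRS
#'   coordinates and to drop insertion columns.
#' @return Object of class `bootscan_profile`: list with `windows`
#'   (`data.frame`: start, end, midpoint, n_sites), `support` (windows x
#'   parentals percentage matrix), `unresolved`, `flagged_windows`,
#'   `flagged_segments` (`data.frame`: parental, start, end, n_windows,
#'   max_support, p_value), `genomewide_proportion` (per parental: fraction
#'   of windows at or above the cutoff) and `config`.
#' @export
bootscan <- function(x, query, parentals, config = bootscan_config(),
                     others = NULL, anchor = NULL) {
  m <- .as_char_matrix(x)
  if (is.null(others)) others <- setdiff(rownames(m), c(query, parentals))
  taxa <- c(query, parentals, others)
  if (!all(taxa %in% rownames(m)))
    stop("unknown sample id(s): ",
         paste(setdiff(taxa, rownames(m)), collapse = ", "))
  if (length(parentals) < 1) stop("need at least one parental")
  m <- m[taxa, , drop = FALSE]
  col_pos <- seq_len(ncol(m))
  if (!is.null(anchor)) {
    keep <- !is.na(anchor$column_to_position)
    col_pos <- anchor$column_to_position
  } else keep <- rep(TRUE, ncol(m))
  keep <- keep & !apply(m == "-", 2, any)
  if (ncol(m) < config$window_size)
    stop("alignment (", ncol(m), " columns) shorter than one window (",
         config$window_size, ")")
  starts <- seq(1L, ncol(m) - config$window_size + 1L, by = config$step_size)
  nw <- length(starts)
  support <- matrix(0, nw, length(parentals),
                    dimnames = list(NULL, parentals))
  unresolved <- numeric(nw)
  win <- data.frame(start = integer(nw), end = integer(nw),
                    midpoint = integer(nw), n_sites = integer(nw))
  enc_all <- .encode_bases(m)
  for (w in seq_len(nw)) {
    cols <- starts[w]:(starts[w] + config$window_size - 1L)
    use <- cols[keep[cols]]
    pos <- col_pos[cols]
    pos <- pos[!is.na(pos)]
    win$start[w] <- if (length(pos)) min(pos) else NA_integer_
    win$end[w] <- if (length(pos)) max(pos) else NA_integer_
    win$midpoint[w] <- if (length(pos)) pos[ceiling(length(pos) / 2)] else
      NA_integer_
    win$n_sites[w] <- length(use)
    if (!length(use)) {
      unresolved[w] <- 100
      next
    }
    set.seed((config$seed * 1000003L + w * 7919L) %% 2147483647L)
    sup <- cpp_window_support(enc_all[, use, drop = FALSE], 0L,
                              seq_along(parentals), config$replicates,
                              config$saturation_ceiling,
                              .model_code(config$distance_model))
    support[w, ] <- sup[seq_along(parentals)]
    unresolved[w] <- sup[length(parentals) + 1L]
  }
  flagged <- support >= config$cutoff_percent
  genomewide <- colMeans(flagged)
  segs <- list()
  for (p in seq_along(parentals)) {
    r <- rle(flagged[, p])
    ends <- cumsum(r$lengths)
    starts_r <- ends - r$lengths + 1L
    for (i in which(r$values & r$lengths >= config$min_run)) {
      wset <- starts_r[i]:ends[i]
      segs[[length(segs) + 1L]] <- data.frame(
        parental = parentals[p], start = win$start[wset[1]],
        end = win$end[wset[length(wset)]], n_windows = length(wset),
        max_support = max(support[wset, p]),
        p_value = binomial_pvalue(length(wset), length(wset), genomewide[p]),
        stringsAsFactors = FALSE)
    }
  }
  flagged_segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(parental = character(), start = integer(), end = integer(),
               n_windows = integer(), max_support = numeric(),
               p_value = numeric(), stringsAsFactors = FALSE)
  structure(list(windows = win, support = support, unresolved = unresolved,
                 flagged_windows = flagged,
                 flagged_segments = flagged_segments,
                 genomewide_proportion = genomewide,
                 query = query, parentals = parentals, config = config),
            class = "bootscan_profile")
}

#' @export
print.bootscan_profile <- function(x, ...) {
  cat("<bootscan_profile> query ", x$query, ": ", nrow(x$windows),
      " windows x ", length(x$parentals), " parentals; ",
      nrow(x$flagged_segments), " flagged segment(s) at cutoff ",
      x$config$cutoff_percent, "%\n", sep = "")
  invisible(x)
}

#' Candidate recombination tracts from a bootscan profile
#'
#' Because windows overlap, a single misleading alignment column (for example
#' one convergent mutation shared between query and a parental) lifts support
#' in up to `window_size / step_size` consecutive windows. A run of flagged
#' windows is therefore only evidence for a recombination *tract* - rather
#' than a point signal - when it is longer than one column's window
#' footprint. This function filters [bootscan()]'s flagged segments down to
#' runs of more than `min_windows` consecutive windows (default:
#' `window_size / step_size`, the single-column footprint; null simulations
#' calibrate this as separating point homoplasy from multi-window tracts).
#' Both views are reported: the unfiltered single-window flags stay in the
#' profile.
#'
#' @param profile A [bootscan()] result.
#' @param min_windows Runs must exceed this many windows; default
#'   `window_size / step_size`.
#' @return The `flagged_segments` rows with `n_windows > min_windows`.
#' @export
recombination_tracts <- function(profile, min_windows = NULL) {
  stopifnot(inherits(profile, "bootscan_profile"))
  if (is.null(min_windows))
    min_windows <- profile$config$window_size / profile$config$step_size
  segs <- profile$flagged_segments
  segs[segs$n_windows > min_windows, , drop = FALSE]
}

#' Binomial tail probability for a supported segment
#'
#' Probability of observing at least `k` supporting windows out of `n` when
#' each window independently supports the donor with the genome-wide
#' proportion `p0`. This is an approximation (windows overlap, and the
#' original manual-bootscan formulation is tool-internal); with `k = n` it
#' reduces to `p0^n`.
#'
#' @param k Supporting windows in the segment.
#' @param n Windows in the segment.
#' @param p0 Genome-wide per-window support proportion in `[0, 1]`.
#' @return The tail probability.
#' @export
binomial_pvalue <- function(k, n, p0) {
  if (n < 1) stop("empty segment")
  stopifnot(k >= 0, k <= n, p0 >= 0, p0 <= 1)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Write a bootscan profile as TSV
#'
#' @param profile A [bootscan()] result.
#' @param path Output path for the per-window table; flagged segments go to
#'   `paste0(path, ".segments.tsv")` when any exist.
#' @return `path`, invisibly.
#' @export
write_bootscan_tsv <- function(profile, path) {
  df <- cbind(profile$windows, as.data.frame(profile$support),
              unresolved = profile$unresolved)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(profile$flagged_segments))
    utils::write.table(profile$flagged_segments,
                       paste0(path, ".segments.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
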