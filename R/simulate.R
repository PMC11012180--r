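# Mitogenome-evolution simulator: three clades on a dated tree, K80
# substitution with gamma rate heterogeneity and mutational hotspots,
# optionally planted convergent mutations and recombination tracts, with a
# full per-event ground-truth record.

#' Simulation configuration
#'
#' The default tree is a five-tip caricature of the study design: two
#' Neanderthals (one H-like, one L-like), one archaic AMH and two moderns (one
#' haplogroup L, one Eurasian), with a Neanderthal-modern split depth around
#' 0.01 substitutions/site - the order of magnitude behind a ~5% polymorphic
#' alignment. Branch lengths are in expected substitutions per site at
#' relative rate 1.
#'
#' @param tree Newick string with branch lengths.
#' @param genome_length Sites to simulate (default 16,569).
#' @param kappa Transition/transversion rate ratio of the K80 process
#'   (default 2).
#' @param gamma_alpha Shape of the gamma rate-heterogeneity distribution
#'   (mean 1); 1 = moderate variation, 0.05 = the extreme-variation scenario
#'   under which recombination tests are expected to false-positive on
#'   homoplasy. `Inf` disables heterogeneity.
#' @param hotspot_fraction,hotspot_multiplier Fraction of sites designated
#'   mutational hotspots and their rate multiplier (>= 1).
#' @param recombination_events `data.frame` with columns `donor`, `recipient`
#'   (tip labels), `start`, `end` (1-based inclusive sites): donor tract
#'   copied into the recipient after substitution.
#' @param base_composition Named frequencies for A, C, G, T (root sequence
#'   draw); default approximates the human mitogenome heavy strand.
#' @param planted `data.frame` with columns `site`, `tip`, `to` (`NA` = use
#'   the transition partner of the root base, so independently planted tips
#'   converge on one derived state). Normally produced by
#'   [plant_convergence()].
#' @param planted_mutable If `FALSE` (default) planted sites are masked from
#'   the random substitution process so the planted design is exact.
#' @param clade_of Function mapping tip labels to clades; the default sends
#'   `NEA*` to `NEANDERTHAL`, `AMH*` to `ARCHAIC_AMH`, the rest to `MODERN`.
#' @param subclade_of Function mapping tip labels to subclade labels (used by
#'   [make_clade_partition()]; default gives `NEA2` and `MOD1` L-type labels).
#' @param seed Integer seed; (config, seed) fully determines the output.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(
    tree = "((NEA1:0.002,NEA2:0.002):0.008,(AMH1:0.007,(MOD1:0.004,MOD2:0.004):0.003):0.003);",
    genome_length = 16569L, kappa = 2, gamma_alpha = 1,
    hotspot_fraction = 0.01, hotspot_multiplier = 10,
    recombination_events = NULL, base_composition = c(A = 0.309, C = 0.313,
                                                      G = 0.131, T = 0.247),
    planted = NULL, planted_mutable = FALSE,
    clade_of = NULL, subclade_of = NULL, seed = 1L) {
  stopifnot(abs(sum(base_composition) - 1) < 1e-6, hotspot_multiplier >= 1,
            kappa > 0, gamma_alpha > 0, genome_length >= 1)
  if (!is.null(recombination_events)) {
    re <- recombination_events
    stopifnot(all(c("donor", "recipient", "start", "end") %in% names(re)),
              all(re$start >= 1), all(re$end <= genome_length),
              all(re$start <= re$end))
    for (r in unique(re$recipient)) {
      iv <- re[re$recipient == r, , drop = FALSE]
      iv <- iv[order(iv$start), ]
      if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)]))
        stop("overlapping recombination events on recipient ", r)
    }
  }
  if (is.null(clade_of))
    clade_of <- function(tip) ifelse(grepl("^NEA", tip), "NEANDERTHAL",
                                     ifelse(grepl("^AMH", tip),
                                            "ARCHAIC_AMH", "MODERN"))
  if (is.null(subclade_of))
    subclade_of <- function(tip) c(NEA1 = "H1e", NEA2 = "L1'2'3'4'5'6",
                                   AMH1 = "U5", MOD1 = "L0a",
                                   MOD2 = "H2a")[tip]
  structure(list(tree = tree, genome_length = as.integer(genome_length),
                 kappa = kappa, gamma_alpha = gamma_alpha,
                 hotspot_fraction = hotspot_fraction,
                 hotspot_multiplier = hotspot_multiplier,
                 recombination_events = recombination_events,
                 base_composition = base_composition, planted = planted,
                 planted_mutable = planted_mutable, clade_of = clade_of,
                 subclade_of = subclade_of, seed = as.integer(seed)),
            class = "sim_config")
}

.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
.TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))

#' Schedule convergent mutations on Neanderthal and modern branches
#'
#' Deterministically plants identical derived mutations on the terminal
#' branches of the given tips (by design one Neanderthal and one or more
#' modern tips, never an archaic AMH unless explicitly requested) at
#' `n_sites` positions spread evenly along the genome. With the default
#' non-mutable planting, the expected N-SNV set of the simulated alignment is
#' exactly the planted site set (when no archaic tip is included).
#'
#' @param config A [sim_config()].
#' @param n_sites Number of convergent sites to plant.
#' @param target_tips Tips receiving the identical derived mutation.
#' @return The modified `sim_config` (existing planted rows are kept).
#' @export
plant_convergence <- function(config, n_sites,
                              target_tips = c("NEA1", "MOD1")) {
  stopifnot(inherits(config, "sim_config"), n_sites >= 0,
            n_sites <= config$genome_length)
  tips <- ape::read.tree(text = config$tree)$tip.label
  missing_tips <- setdiff(target_tips, tips)
  if (length(missing_tips))
    stop("tip(s) not in the tree: ", paste(missing_tips, collapse = ", "))
  if (n_sites == 0) return(config)
  L <- config$genome_length
  sites <- unique(round(seq(L / (n_sites + 1), L * n_sites / (n_sites + 1),
                            length.out = n_sites)))
  new <- expand.grid(site = as.integer(sites), tip = target_tips,
                     stringsAsFactors = FALSE)
  new$to <- NA_character_
  config$planted <- rbind(config$planted, new)
  config
}

#' Simulate a mitogenome alignment with ground truth
#'
#' Draws a root sequence from the configured base composition, then applies a
#' K80 substitution process independently per site along each branch: the
#' number of events on a branch of length `b` at site `i` is Poisson with
#' mean `m_i * b`, where `m_i` is the site's gamma rate multiplier (times the
#' hotspot multiplier for hotspot sites), and each event is a transition with
#' probability `kappa / (kappa + 2)`, otherwise one of the two transversions
#' with equal probability. Planted mutations are applied at the end of their
#' tip's terminal branch; recombination tracts are copied donor to recipient
#' after substitution. Tips are emitted as an ungapped alignment and every
#' mutation event is recorded.
#'
#' @param config A [sim_config()].
#' @return List with `mset` (a [mitogenome_set()]) and `truth` (class
#'   `sim_truth`): `events` (`data.frame`: branch, site, from, to, planted,
#'   in order of application), `convergent_sites` (sites where two or more
#'   branches end at the same derived state), `recombination`,
#'   `expected_nsnv` (planted design), `root_sequence` and `config`.
#' @export
simulate_mitogenomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- tryCatch(ape::read.tree(text = config$tree),
                   error = function(e) NULL)
  if (is.null(tree) || is.null(tree$edge.length))
    stop("unparseable tree or missing branch lengths")
  tree <- ape::reorder.phylo(tree, "cladewise")
  L <- config$genome_length
  ntip <- length(tree$tip.label)

  rates <- if (is.finite(config$gamma_alpha))
    stats::rgamma(L, shape = config$gamma_alpha, rate = config$gamma_alpha)
  else rep(1, L)
  n_hot <- round(config$hotspot_fraction * L)
  hot <- if (n_hot > 0) sample.int(L, n_hot) else integer(0)
  rates[hot] <- rates[hot] * config$hotspot_multiplier

  planted <- config$planted
  if (!is.null(planted) && nrow(planted) && !config$planted_mutable)
    rates[unique(planted$site)] <- 0

  root <- sample(names(config$base_composition), L, replace = TRUE,
                 prob = config$base_composition)
  node_seq <- vector("list", ntip + tree$Nnode)
  root_node <- ntip + 1L
  node_seq[[root_node]] <- root
  branch_name <- function(node) if (node <= ntip) tree$tip.label[node] else
    paste0("node", node)

  ev_branch <- character(0); ev_site <- integer(0)
  ev_from <- character(0); ev_to <- character(0); ev_planted <- logical(0)
  p_ts <- config$kappa / (config$kappa + 2)

  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    b <- tree$edge.length[e]
    seqv <- node_seq[[parent]]
    if (b > 0) {
      nev <- stats::rpois(L, rates * b)
      for (site in which(nev > 0)) {
        for (k in seq_len(nev[site])) {
          from <- seqv[site]
          to <- if (stats::runif(1) < p_ts) .TRANSITION[[from]] else
            sample(.TRANSVERSIONS[[from]], 1)
          seqv[site] <- to
          ev_branch <- c(ev_branch, branch_name(child))
          ev_site <- c(ev_site, site)
          ev_from <- c(ev_from, from); ev_to <- c(ev_to, to)
          ev_planted <- c(ev_planted, FALSE)
        }
      }
    }
    if (child <= ntip && !is.null(planted) && nrow(planted)) {
      rows <- planted[planted$tip == tree$tip.label[child], , drop = FALSE]
      for (i in seq_len(nrow(rows))) {
        site <- rows$site[i]
        to <- rows$to[i]
        if (is.na(to)) to <- .TRANSITION[[root[site]]]
        if (seqv[site] != to) {
          ev_branch <- c(ev_branch, branch_name(child))
          ev_site <- c(ev_site, site)
          ev_from <- c(ev_from, seqv[site]); ev_to <- c(ev_to, to)
          ev_planted <- c(ev_planted, TRUE)
          seqv[site] <- to
        }
      }
    }
    node_seq[[child]] <- seqv
  }

  tips <- lapply(seq_len(ntip), function(i) node_seq[[i]])
  names(tips) <- tree$tip.label

  rec <- config$recombination_events
  if (!is.null(rec) && nrow(rec)) {
    for (i in seq_len(nrow(rec))) {
      if (!all(c(rec$donor[i], rec$recipient[i]) %in% tree$tip.label))
        stop("recombination event references unknown tip")
      span <- rec$start[i]:rec$end[i]
      tips[[rec$recipient[i]]][span] <- tips[[rec$donor[i]]][span]
    }
  }

  events <- data.frame(branch = ev_branch, site = ev_site, from = ev_from,
                       to = ev_to, planted = ev_planted,
                       stringsAsFactors = FALSE)
  convergent_sites <- .convergent_from_events(events)

  expected_nsnv <- integer(0)
  if (!is.null(planted) && nrow(planted)) {
    clades <- config$clade_of(planted$tip)
    by_site <- split(clades, planted$site)
    expected_nsnv <- sort(as.integer(names(by_site)[vapply(by_site,
      function(cl) any(cl == "NEANDERTHAL") && any(cl == "MODERN") &&
        !any(cl == "ARCHAIC_AMH"), TRUE)]))
  }

  md <- data.frame(sample_id = tree$tip.label,
                   clade = config$clade_of(tree$tip.label),
                   subclade_label = unname(config$subclade_of(tree$tip.label)),
                   stringsAsFactors = FALSE)
  md$subclade_label[is.na(md$subclade_label)] <- ""
  mset <- mitogenome_set(vapply(tips, paste, "", collapse = ""), md)
  truth <- structure(list(events = events,
                          convergent_sites = convergent_sites,
                          recombination = rec, expected_nsnv = expected_nsnv,
                          root_sequence = paste(root, collapse = ""),
                          tree = config$tree, seed = config$seed),
                     class = "sim_truth")
  list(mset = mset, truth = truth)
}

.convergent_from_events <- function(events) {
  if (!nrow(events)) return(integer(0))
  final <- events[!duplicated(events[, c("site", "branch")],
                              fromLast = TRUE), ]
  tab <- split(final$to, final$site)
  sort(as.integer(names(tab)[vapply(tab, function(x) any(table(x) >= 2),
                                    TRUE)]))
}

#' Replay recorded mutation events against the root sequence
#'
#' Applies the truth's per-branch event lists down the tree and re-applies
#' recombination tracts; the reconstructed tips must equal the simulated
#' alignment (determinism/consistency check).
#'
#' @param truth A `sim_truth` object.
#' @return Named character vector of reconstructed tip sequences.
#' @export
replay_truth <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  tree <- ape::reorder.phylo(ape::read.tree(text = truth$tree), "cladewise")
  ntip <- length(tree$tip.label)
  root <- strsplit(truth$root_sequence, "")[[1]]
  node_seq <- vector("list", ntip + tree$Nnode)
  node_seq[[ntip + 1L]] <- root
  branch_name <- function(node) if (node <= ntip) tree$tip.label[node] else
    paste0("node", node)
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    seqv <- node_seq[[parent]]
    ev <- truth$events[truth$events$branch == branch_name(child), ,
                       drop = FALSE]
    for (i in seq_len(nrow(ev))) seqv[ev$site[i]] <- ev$to[i]
    node_seq[[child]] <- seqv
  }
  tips <- lapply(seq_len(ntip), function(i) node_seq[[i]])
  names(tips) <- tree$tip.label
  rec <- truth$recombination
  if (!is.null(rec) && nrow(rec)) {
    for (i in seq_len(nrow(rec))) {
      span <- rec$start[i]:rec$end[i]
      tips[[rec$recipient[i]]][span] <- tips[[rec$donor[i]]][span]
    }
  }
  vapply(tips, paste, "", collapse = "")
}

#' Write a simulated data set as plain-text fixture files
#'
#' Writes `alignment.fasta`, `metadata.tsv` and `truth.json` into `dir`;
#' the FASTA/TSV pair round-trips through [read_fasta()] and
#' [mitogenome_set()].
#'
#' @param sim A [simulate_mitogenomes()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- Biostrings::DNAStringSet(sim$mset$sequences)
  Biostrings::writeXStringSet(fa, file.path(dir, "alignment.fasta"))
  utils::write.table(sim$mset$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  json <- list(events = truth$events,
               convergent_sites = truth$convergent_sites,
               recombination = truth$recombination,
               expected_nsnv = truth$expected_nsnv,
               root_sequence = truth$root_sequence, tree = truth$tree,
               seed = truth$seed)
  jsonlite::write_json(json, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
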