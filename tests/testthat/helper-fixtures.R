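# Shared fixture builders and independent oracles, all generated in code.

# A small hand-built anchored alignment: 20 bp reference, 5 samples.
# Engineered: SNVs at positions 3 (C>T), 7 (G>A), 12 (A>G, with one gap in
# the column), 18 (T>C); an N-only "polymorphism" at position 9 (must not be
# called); reference row included.
toy_alignment <- function() {
  ref <- "ACCGTTGCAGTACGATCTGA"
  seqs <- c(
    rCRS = ref,
    S1 = "ACTGTTGCAGTACGATCTGA",  # 3 C>T
    S2 = "ACCGTTACAGTACGATCCGA",  # 7 G>A, 18 T>C
    S3 = "ACCGTTGCNGT-CGATCTGA",  # N at 9, gap at 12
    S4 = "ACTGTTGCAGTGCGATCTGA")  # 3 C>T, 12 A>G
  md <- data.frame(
    sample_id = names(seqs),
    clade = c("REFERENCE", "NEANDERTHAL", "NEANDERTHAL", "ARCHAIC_AMH",
              "MODERN"),
    subclade_label = c("H2a2a1", "H1e", "L1'2'3'4'5'6", "U5", "L0a"),
    stringsAsFactors = FALSE)
  mitogenome_set(seqs, md)
}

# independent per-column scan (oracle for call_variants)
brute_force_variants <- function(mset, ref_id = "rCRS") {
  m <- do.call(rbind, strsplit(unname(mset$sequences), ""))
  rownames(m) <- names(mset$sequences)
  refchars <- m[ref_id, ]
  keep <- refchars != "-"
  pos <- cumsum(keep)
  out <- list()
  for (j in which(keep)) {
    col <- m[, j]
    acgt <- unique(col[col %in% c("A", "C", "G", "T")])
    if (length(acgt) < 2) next
    out[[length(out) + 1]] <- data.frame(
      position = pos[j], ref = refchars[j],
      alt = paste(sort(setdiff(acgt, refchars[j])), collapse = ","),
      has_gap = any(col == "-"), stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# independent per-site incidence enumeration (oracle for call_nsnv)
brute_force_nsnv <- function(vt, partition) {
  hits <- integer(0)
  for (i in seq_len(nrow(vt$sites))) {
    col <- vt$calls[, i]
    alts <- strsplit(vt$sites$alt[i], ",")[[1]]
    for (a in alts) {
      in_nea <- any(col[c(partition$neanderthal_H,
                          partition$neanderthal_L)] == a)
      in_arch <- any(col[partition$archaic_amh] == a)
      in_mod <- any(col[c(partition$modern_L, partition$modern_eurasian)] == a)
      if (in_nea && !in_arch && in_mod)
        hits <- c(hits, vt$sites$position[i])
    }
  }
  sort(unique(hits))
}

# random ungapped alignment with a designated reference row
random_mset <- function(n_samples, n_sites, seed, p_mut = 0.05,
                        clades = NULL) {
  set.seed(seed)
  ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  seqs <- vapply(seq_len(n_samples), function(i) {
    s <- ref
    k <- rbinom(1, n_sites, p_mut)
    if (k > 0) {
      at <- sample(n_sites, k)
      s[at] <- vapply(s[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    }
    paste(s, collapse = "")
  }, "")
  names(seqs) <- paste0("S", seq_len(n_samples))
  if (is.null(clades))
    clades <- rep_len(c("NEANDERTHAL", "ARCHAIC_AMH", "MODERN"), n_samples)
  md <- data.frame(sample_id = names(seqs), clade = clades,
                   subclade_label = rep_len(c("H1", "L0", "U5", "X2"),
                                            n_samples),
                   stringsAsFactors = FALSE)
  all <- c(structure(paste(ref, collapse = ""), names = "rCRS"), seqs)
  md <- rbind(data.frame(sample_id = "rCRS", clade = "REFERENCE",
                         subclade_label = "H2a2a1", stringsAsFactors = FALSE),
              md)
  mitogenome_set(all, md)
}

# least-squares fit of a distance matrix on a fixed topology (oracle for NJ):
# residual sum of squares after unconstrained edge-length fitting
topology_lsq_resid <- function(topo, d) {
  topo <- ape::unroot(topo)
  n <- length(topo$tip.label)
  ne <- nrow(topo$edge)
  pairs <- t(combn(n, 2))
  A <- matrix(0, nrow(pairs), ne)
  b <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    pth <- ape::nodepath(topo, i, j)
    for (k in seq_len(length(pth) - 1)) {
      e <- which((topo$edge[, 1] == pth[k] & topo$edge[, 2] == pth[k + 1]) |
                 (topo$edge[, 2] == pth[k] & topo$edge[, 1] == pth[k + 1]))
      A[r, e] <- 1
    }
    b[r] <- d[topo$tip.label[i], topo$tip.label[j]]
  }
  fit <- qr.solve(crossprod(A) + diag(1e-10, ne), crossprod(A, b))
  sum((A %*% fit - b)^2)
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
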