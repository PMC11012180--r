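test_that("K80 distance matches the closed form and handles missing data", {
  expect_equal(k80_distance("ACGTACGT", "ACGTACGT")$distance, 0)

  # engineered P = 0.1, Q = 0.05 over 200 comparable sites
  a <- rep("A", 200)
  b <- a
  b[1:20] <- "G"            # transitions
  b[21:30] <- "C"           # transversions
  res <- k80_distance(a, b)
  expect_equal(res$comparable, 200)
  expect_equal(res$P, 0.1)
  expect_equal(res$Q, 0.05)
  oracle <- -0.5 * log((1 - 2 * 0.1 - 0.05) * sqrt(1 - 2 * 0.05))
  expect_lt(abs(res$distance - oracle), 1e-10)

  # P = 0.3, Q = 0.2: 1 - 2P - Q = 0.2 > 0, still finite
  b2 <- a
  b2[1:60] <- "G"
  b2[61:100] <- "T"
  res2 <- k80_distance(a, b2)
  oracle2 <- -0.5 * log((1 - 0.6 - 0.2) * sqrt(1 - 0.4))
  expect_lt(abs(res2$distance - oracle2), 1e-10)

  # pairwise deletion of gaps and Ns (positions 5 and 6 are incomparable)
  res3 <- k80_distance("ACGTN-GT", "ACCT-AGT")
  expect_equal(res3$comparable, 6)

  expect_error(k80_distance("NNNN", "ACGT"), "comparable")
  expect_warning(k80_distance(paste(rep("A", 10), collapse = ""),
                              paste(rep("G", 10), collapse = "")),
                 "saturated")
})

test_that("K80 agrees with an independent implementation on random pairs", {
  set.seed(42)
  for (i in 1:5) {
    n <- 400
    a <- sample(c("A", "C", "G", "T"), n, TRUE)
    b <- a
    idx <- sample(n, 50)
    b[idx] <- vapply(b[idx], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    d_ape <- ape::dist.dna(ape::as.DNAbin(tolower(rbind(a, b))),
                           model = "K80", pairwise.deletion = TRUE)
    expect_lt(abs(k80_distance(a, b)$distance - as.numeric(d_ape)), 1e-10)
  }
})

test_that("K80 equals JC69 closed forms in the equal-rate regime", {
  # with transition share = 1/3 of differences, K80 reduces towards JC69
  a <- rep("A", 300)
  b <- a
  b[1:10] <- "G"; b[11:20] <- "C"; b[21:30] <- "T"   # P = 1/30, Q = 2/30
  P <- 10 / 300; Q <- 20 / 300
  k80 <- -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
  jc <- -0.75 * log(1 - 4 / 3 * (P + Q))
  expect_lt(abs(k80_distance(a, b)$distance - k80), 1e-12)
  m <- rbind(q = paste(a, collapse = ""), s = paste(b, collapse = ""))
  dj <- distance_matrix(c(q = paste(a, collapse = ""),
                          s = paste(b, collapse = "")), model = "JC69")
  expect_lt(abs(dj["q", "s"] - jc), 1e-12)
  expect_lt(abs(k80 - jc), 2e-3)  # near-equal when P/Q matches 1:2
})

test_that("neighbor joining recovers additive trees exactly", {
  skip_if_not_installed("phangorn")
  set.seed(101)
  for (n in 4:6) {
    for (rep in 1:3) {
      tr <- ape::rtree(n)
      tr$edge.length <- stats::runif(nrow(tr$edge), 0.3, 1.5)
      d <- ape::cophenetic.phylo(tr)
      mine <- nj_tree(d)
      expect_true(same_topology(mine, tr))
      # enumeration oracle: the generating topology is the unique topology
      # with (near-)zero least-squares residual, and NJ finds it
      if (n <= 5) {
        cands <- phangorn::allTrees(n, tip.label = tr$tip.label)
        resids <- vapply(cands, topology_lsq_resid, 0, d = d)
        best <- cands[[which.min(resids)]]
        expect_lt(min(resids), 1e-12)
        expect_true(same_topology(mine, best))
      }
    }
  }
})

test_that("neighbor joining handles small and degenerate inputs", {
  # n = 3: closed three-point formulas
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_equal(ape::Ntip(tr), 3)
  la <- 0.5 * (3 + 4 - 5); lb <- 0.5 * (3 + 5 - 4); lc <- 0.5 * (4 + 5 - 3)
  expect_setequal(round(tr$edge.length, 10), round(c(la, lb, lc), 10))

  # all-zero matrix: star tree
  d0 <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  star <- nj_tree(d0)
  expect_equal(star$Nnode, 1)
  expect_true(all(star$edge.length == 0))

  # 4-taxon additive matrix from ((A,B),(C,D)) with unit branches
  tr4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  d4 <- ape::cophenetic.phylo(tr4)
  expect_true(same_topology(nj_tree(d4), tr4))

  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining matches the reference implementation", {
  set.seed(7)
  for (i in 1:4) {
    n <- sample(5:10, 1)
    d <- as.matrix(stats::dist(matrix(stats::rnorm(n * 3), n)))
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    expect_true(same_topology(nj_tree(d), ape::nj(d)))
  }
})

test_that("window support behaves at the degenerate extremes", {
  set.seed(5)
  base <- sample(c("A", "C", "G", "T"), 300, TRUE)
  p2 <- vapply(base, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")  # maximally distant
  other <- base
  other[seq(1, 300, 10)] <- vapply(other[seq(1, 300, 10)], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  aln <- c(Q = paste(base, collapse = ""), P1 = paste(base, collapse = ""),
           P2 = paste(p2, collapse = ""), O1 = paste(other, collapse = ""))
  set.seed(1)
  sup <- window_support(aln, "Q", c("P1", "P2"),
                        config = bootscan_config(replicates = 100,
                                                 window_size = 200,
                                                 step_size = 20))
  expect_equal(unname(sup["P1"]), 100)  # query identical to P1

  # constant window: unresolved, no parental reaches any support
  aln0 <- c(Q = strrep("A", 250), P1 = strrep("A", 250),
            P2 = strrep("A", 250), O1 = strrep("A", 250))
  sup0 <- window_support(aln0, "Q", c("P1", "P2"),
                         config = bootscan_config(replicates = 50))
  expect_equal(unname(sup0["unresolved"]), 100)
  expect_equal(unname(sup0["P1"]), 0)
})

test_that("scan flags a planted recombinant tract at the right place", {
  cfg <- sim_config(seed = 3, genome_length = 3000, hotspot_fraction = 0,
                    recombination_events = data.frame(
                      donor = "NEA1", recipient = "MOD2",
                      start = 1000, end = 2000))
  sim <- simulate_mitogenomes(cfg)
  prof <- bootscan(sim$mset, query = "MOD2", parentals = c("NEA1", "AMH1"),
                   config = bootscan_config(window_size = 200,
                                            step_size = 20,
                                            replicates = 300, seed = 5))
  tracts <- recombination_tracts(prof)
  nea <- tracts[tracts$parental == "NEA1", ]
  expect_gte(nrow(nea), 1)
  expect_true(any(nea$start <= 2000 & nea$end >= 1000))
  expect_gte(max(nea$max_support), 70)
  expect_true(all(tracts$p_value < 0.05))
})

test_that("a query equal to a parental is flagged genome-wide", {
  cfg <- sim_config(seed = 9, genome_length = 2000, hotspot_fraction = 0)
  sim <- simulate_mitogenomes(cfg)
  seqs <- sim$mset$sequences
  seqs[["Q"]] <- seqs[["NEA1"]]   # exact copy of a parental
  prof <- bootscan(seqs, query = "Q", parentals = c("NEA1", "AMH1"),
                   config = bootscan_config(window_size = 200,
                                            step_size = 50,
                                            replicates = 100, seed = 2))
  expect_true(all(prof$support[, "NEA1"] >= 70))
  tracts <- recombination_tracts(prof)
  expect_equal(tracts$parental, "NEA1")
  expect_equal(tracts$n_windows, nrow(prof$windows))
})

test_that("bootscan profiles are bit-identical across runs with one seed", {
  cfg <- sim_config(seed = 13, genome_length = 1500, hotspot_fraction = 0)
  sim <- simulate_mitogenomes(cfg)
  conf <- bootscan_config(window_size = 200, step_size = 40,
                          replicates = 150, seed = 21)
  p1 <- bootscan(sim$mset, "MOD2", c("NEA1", "AMH1"), config = conf)
  p2 <- bootscan(sim$mset, "MOD2", c("NEA1", "AMH1"), config = conf)
  expect_identical(p1$support, p2$support)
  expect_identical(p1$flagged_segments, p2$flagged_segments)
  expect_identical(p1$unresolved, p2$unresolved)
})

test_that("support sums to at most 100 percent per window", {
  cfg <- sim_config(seed = 17, genome_length = 1500)
  sim <- simulate_mitogenomes(cfg)
  prof <- bootscan(sim$mset, "MOD1", c("NEA2", "AMH1"),
                   config = bootscan_config(window_size = 200,
                                            step_size = 40,
                                            replicates = 100, seed = 4))
  expect_true(all(prof$support >= 0 & prof$support <= 100))
  expect_true(all(rowSums(prof$support) + prof$unresolved <= 100 + 1e-9))
})

test_that("donor support inside the tract is monotone in background divergence", {
  # making the non-donor parental more divergent must not pull support away
  # from the donor inside the donor's tract (checked on seed averages)
  mean_in_tract <- function(stretch) {
    vals <- numeric(6)
    for (s in 1:6) {
      tree <- sprintf(
        "((NEA1:0.002,NEA2:0.002):0.008,(AMH1:%f,(MOD1:0.004,MOD2:0.004):0.003):0.003);",
        0.007 * stretch)
      cfg <- sim_config(seed = 400 + s, tree = tree, genome_length = 2000,
                        hotspot_fraction = 0,
                        recombination_events = data.frame(
                          donor = "NEA1", recipient = "MOD2",
                          start = 600, end = 1400))
      sim <- simulate_mitogenomes(cfg)
      prof <- bootscan(sim$mset, "MOD2", c("NEA1", "AMH1"),
                       config = bootscan_config(window_size = 200,
                                                step_size = 40,
                                                replicates = 100, seed = s))
      inside <- prof$windows$start >= 600 & prof$windows$end <= 1400
      vals[s] <- mean(prof$support[inside, "NEA1"])
    }
    mean(vals)
  }
  expect_gte(mean_in_tract(3) + 2, mean_in_tract(1))
})

test_that("binomial p-values follow the closed form", {
  expect_gte(binomial_pvalue(5, 10, 0.5), 0.5)     # null case
  expect_equal(binomial_pvalue(4, 4, 0.2), 0.2^4)  # k = n
  expect_equal(binomial_pvalue(0, 4, 0.2), 1)
  expect_error(binomial_pvalue(1, 0, 0.5), "empty")
})

test_that("bootscan validates its inputs", {
  aln <- c(Q = strrep("ACGT", 30), P = strrep("ACGT", 30))
  expect_error(bootscan(aln, "Q", "P",
                        config = bootscan_config(window_size = 200,
                                                 step_size = 20)),
               "shorter than one window")
  expect_error(bootscan_config(window_size = 10, step_size = 20), "window_size")
  expect_error(bootscan_config(cutoff_percent = 150), "cutoff")
  expect_error(bootscan_config(replicates = 0), "replicates")
})
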