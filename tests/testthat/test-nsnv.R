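test_that("assign_pattern implements the five presence patterns", {
  expect_equal(assign_pattern(TRUE, TRUE, TRUE, TRUE), 1L)
  expect_equal(assign_pattern(TRUE, TRUE, FALSE, FALSE), 2L)
  expect_equal(assign_pattern(TRUE, FALSE, TRUE, TRUE), 3L)
  expect_equal(assign_pattern(TRUE, FALSE, TRUE, FALSE), 4L)
  expect_equal(assign_pattern(TRUE, FALSE, FALSE, TRUE), 5L)
  # Neanderthal absence excludes all patterns
  expect_true(is.na(assign_pattern(FALSE, TRUE, TRUE, TRUE)))
  # partial combinations outside the five patterns
  expect_true(is.na(assign_pattern(TRUE, TRUE, TRUE, FALSE)))
})

test_that("the N-SNV criterion is evaluated per clade incidence", {
  mset <- toy_alignment()
  vt <- call_variants(mset, anchor_to_reference(mset, "rCRS"))
  part <- make_clade_partition(mset)
  expect_setequal(part$neanderthal_H, "S1")
  expect_setequal(part$neanderthal_L, "S2")
  expect_setequal(part$archaic_amh, "S3")
  expect_setequal(part$modern_L, "S4")
  calls <- call_nsnv(vt, part)

  # position 3: T in Neanderthal S1 and modern S4, absent in archaic -> N-SNV
  c3 <- calls[calls$position == 3, ]
  expect_true(c3$is_nsnv)
  expect_equal(c3$pattern, 4L)  # modern carrier is haplogroup L only
  # position 7: allele only in Neanderthal S2 -> exclusive, not an N-SNV
  c7 <- calls[calls$position == 7, ]
  expect_false(c7$is_nsnv)
  expect_true(c7$nea_exclusive)
  # position 12: derived G only in modern S4 -> no Neanderthal-shared allele
  c12 <- calls[calls$position == 12, ]
  expect_false(c12$is_nsnv)
  expect_true(is.na(c12$allele))
})

test_that("archaic carriers disqualify a site; archaic missing data flags it", {
  seqs <- c(rCRS = "AAAA",
            N1 = "GAAA", N2 = "AAAA",
            AR1 = "GAAA",                 # archaic carries the allele
            M1 = "GAAA", M2 = "GAAA")
  md <- data.frame(sample_id = names(seqs),
                   clade = c("REFERENCE", "NEANDERTHAL", "NEANDERTHAL",
                             "ARCHAIC_AMH", "MODERN", "MODERN"),
                   subclade_label = c("H2a2a1", "H1", "L1", "U5", "L0", "H3"))
  mset <- mitogenome_set(seqs, md)
  vt <- call_variants(mset, anchor_to_reference(mset, "rCRS"))
  calls <- call_nsnv(vt, make_clade_partition(mset))
  expect_false(calls$is_nsnv[calls$position == 1])
  expect_equal(calls$pattern[calls$position == 1], 1L)  # all five clades

  # same design but archaic call is missing (N): N-SNV, low confidence
  seqs["AR1"] <- "NAAA"
  mset2 <- mitogenome_set(seqs, md)
  vt2 <- call_variants(mset2, anchor_to_reference(mset2, "rCRS"))
  calls2 <- call_nsnv(vt2, make_clade_partition(mset2))
  expect_true(calls2$is_nsnv[calls2$position == 1])
  expect_true(calls2$low_confidence[calls2$position == 1])
})

test_that("call_nsnv agrees with brute-force incidence enumeration", {
  for (seed in c(3, 14, 27, 55)) {
    n <- sample(4:8, 1)
    mset <- random_mset(n, 50, seed, p_mut = 0.08)
    vt <- call_variants(mset, anchor_to_reference(mset, "rCRS"))
    part <- make_clade_partition(mset)
    calls <- call_nsnv(vt, part)
    expect_setequal(calls$position[calls$is_nsnv], brute_force_nsnv(vt, part))
  }
})

test_that("call_nsnv requires every sample in the partition", {
  mset <- toy_alignment()
  vt <- call_variants(mset, anchor_to_reference(mset, "rCRS"))
  part <- make_clade_partition(mset)
  part$modern_L <- character(0)
  expect_error(call_nsnv(vt, part), "absent from the clade partition")
})

test_that("pattern census counts patterns and bins N-SNVs by region", {
  # planted convergent sites on an otherwise mutation-free tree must come
  # back as N-SNVs exactly (random homoplasy is tested separately)
  quiet <- "((NEA1:0,NEA2:0):0,(AMH1:0,(MOD1:0,MOD2:0):0):0);"
  cfg <- plant_convergence(sim_config(seed = 77, tree = quiet,
                                      genome_length = 2000,
                                      hotspot_fraction = 0), 6)
  sim <- simulate_mitogenomes(cfg)
  aug <- mitogenome_set(
    c(sim$mset$sequences, rCRS = sim$truth$root_sequence),
    rbind(sim$mset$metadata,
          data.frame(sample_id = "rCRS", clade = "REFERENCE",
                     subclade_label = "root")))
  vt <- call_variants(aug, anchor_to_reference(aug, "rCRS"))
  calls <- call_nsnv(vt, make_clade_partition(aug))
  census <- pattern_census(calls, vt, aug)
  expect_equal(census$n_nsnv, 6)
  expect_equal(unname(census$pattern_counts["P4"]), 6L)  # planted on MOD1 (L)
  expect_equal(sum(census$pattern_counts[c("P3", "P4", "P5")]),
               census$n_nsnv)

  # region matrix: carriers appear in the carrying haplogroup's row
  expect_equal(sum(census$region_matrix["L0a", ]), 6)
  expect_equal(sum(census$region_matrix), 6)

  # no N-SNVs -> zero matrix
  cfg0 <- sim_config(seed = 78, genome_length = 500, hotspot_fraction = 0,
                     tree = "((NEA1:0,NEA2:0):0,(AMH1:0,(MOD1:0,MOD2:0):0):0);")
  sim0 <- simulate_mitogenomes(cfg0)
  aug0 <- mitogenome_set(
    c(sim0$mset$sequences, rCRS = sim0$truth$root_sequence),
    rbind(sim0$mset$metadata,
          data.frame(sample_id = "rCRS", clade = "REFERENCE",
                     subclade_label = "root")))
  vt0 <- call_variants(aug0, anchor_to_reference(aug0, "rCRS"))
  calls0 <- call_nsnv(vt0, make_clade_partition(aug0))
  census0 <- pattern_census(calls0, vt0, aug0)
  expect_equal(census0$n_nsnv, 0)
  expect_true(all(census0$region_matrix == 0))
})

test_that("allele sharing partitions split carriers from non-carriers", {
  mset <- toy_alignment()
  vt <- call_variants(mset, anchor_to_reference(mset, "rCRS"))
  part <- make_clade_partition(mset)
  p3 <- allele_sharing_partition(3, vt, part)
  expect_length(p3, 1)
  expect_setequal(p3[[1]]$carriers, c("S1", "S4"))
  expect_setequal(p3[[1]]$carrier_clades, c("neanderthal_H", "modern_L"))
  # singleton allele
  p7 <- allele_sharing_partition(7, vt, part)
  expect_equal(p7[[1]]$carriers, "S2")
  expect_equal(length(p7[[1]]$non_carriers), nrow(vt$calls) - 1)
  expect_error(allele_sharing_partition(999, vt, part), "not in")
})

test_that("planted convergence is recovered with perfect sensitivity", {
  cfg <- plant_convergence(sim_config(seed = 11, genome_length = 3000,
                                      hotspot_fraction = 0), 10)
  sim <- simulate_mitogenomes(cfg)
  aug <- mitogenome_set(
    c(sim$mset$sequences, rCRS = sim$truth$root_sequence),
    rbind(sim$mset$metadata,
          data.frame(sample_id = "rCRS", clade = "REFERENCE",
                     subclade_label = "root")))
  vt <- call_variants(aug, anchor_to_reference(aug, "rCRS"))
  calls <- call_nsnv(vt, make_clade_partition(aug))
  expect_setequal(calls$position[calls$is_nsnv], sim$truth$expected_nsnv)

  # planting on the archaic branch too removes sites from the expected set
  cfg2 <- plant_convergence(sim_config(seed = 11, genome_length = 3000),
                            5, target_tips = c("NEA1", "MOD1", "AMH1"))
  expect_length(simulate_mitogenomes(cfg2)$truth$expected_nsnv, 0)
})
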