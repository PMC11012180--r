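test_that("read_fasta normalises sequences and rejects malformed input", {
  tmp <- tempfile(fileext = ".fasta")
  writeLines(c(">a desc", "acgu", ">b", "ACGT"), tmp)
  seqs <- read_fasta(tmp)
  expect_named(seqs, c("a", "b"))
  expect_identical(unname(seqs[["a"]]), "ACGT")   # uppercased, U -> T

  writeLines(c(">a", "ACGT", ">a", "ACGT"), tmp)
  expect_error(read_fasta(tmp), "duplicate")

  writeLines(c(">s1", "ACXT"), tmp)
  expect_error(read_fasta(tmp), "illegal character 'X'.*s1.*position 3")

  writeLines(character(0), tmp)
  expect_error(read_fasta(tmp), "empty|parse")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("mitogenome_set validates lengths, clades and metadata coverage", {
  expect_error(mitogenome_set(c(a = "ACGT", b = "ACG")), "lengths differ")
  md <- data.frame(sample_id = "a", clade = "MARTIAN", subclade_label = "")
  expect_error(mitogenome_set(c(a = "ACGT"), md), "unknown clade")
  md2 <- data.frame(sample_id = "a", clade = "MODERN", subclade_label = "")
  expect_error(mitogenome_set(c(a = "ACGT", b = "ACGT"), md2),
               "without metadata: b")
})

test_that("anchoring maps columns to reference positions", {
  # identity: no gaps anywhere
  mset <- mitogenome_set(c(rCRS = "ACGTACGT", S1 = "ACGTACGA"))
  an <- anchor_to_reference(mset, "rCRS")
  expect_identical(an$column_to_position, 1:8)
  expect_identical(an$n_positions, 8L)

  # a 2-column insertion after reference position 4: those columns are
  # INSERTION (NA) and the next column maps to 5
  mset2 <- mitogenome_set(c(rCRS = "ACGT--ACGT", S1 = "ACGTTTACGT"))
  an2 <- anchor_to_reference(mset2, "rCRS")
  expect_identical(an2$column_to_position,
                   c(1:4, NA_integer_, NA_integer_, 5:8))
  expect_true(all(diff(stats::na.omit(an2$column_to_position)) == 1))

  # deletion in a sample: column still maps; sample allele recorded as gap
  mset3 <- mitogenome_set(c(rCRS = "ACGT", S1 = "A-GT"))
  an3 <- anchor_to_reference(mset3, "rCRS")
  expect_identical(an3$column_to_position, 1:4)
  vt3 <- call_variants(mset3, an3)
  expect_equal(nrow(vt3$sites), 0)  # gap is not an allele

  expect_error(anchor_to_reference(mset, "nope"), "absent")
})

test_that("call_variants applies the polymorphism, N and gap rules", {
  # four identical sequences: no polymorphism
  mset0 <- mitogenome_set(structure(rep("ACGTACGT", 4),
                                    names = paste0("s", 1:4)))
  an0 <- anchor_to_reference(mset0, "s1")
  expect_equal(nrow(call_variants(mset0, an0)$sites), 0)

  mset <- toy_alignment()
  an <- anchor_to_reference(mset, "rCRS")
  vt <- call_variants(mset, an)
  oracle <- brute_force_variants(mset)
  expect_equal(nrow(vt$sites), 4)          # engineered SNVs only
  expect_equal(vt$sites$position, oracle$position)
  expect_equal(vt$sites$ref, oracle$ref)
  expect_equal(vt$sites$alt, oracle$alt)
  expect_equal(vt$sites$has_gap, oracle$has_gap)
  expect_equal(sum(vt$sites$has_gap), 1)   # only the gapped column
  expect_false(9 %in% vt$sites$position)   # N-only column yields no row
  # ref allele equals the reference base at each called position
  refchars <- strsplit(an$rcrs_sequence, "")[[1]]
  expect_identical(vt$sites$ref, refchars[vt$sites$position])
})

test_that("insertion columns never yield variant rows", {
  mset <- mitogenome_set(c(rCRS = "ACGT--ACGT",
                           S1   = "ACGTTTACGT",
                           S2   = "ACGTTAACGA"))
  an <- anchor_to_reference(mset, "rCRS")
  vt <- call_variants(mset, an)
  # inserted columns 5-6 are polymorphic (T/T vs T/A) but unmapped
  expect_equal(vt$sites$position, 8)  # only the final-column SNV maps
})

test_that("variant calling round-trips through sequence reconstruction", {
  for (seed in c(2, 9, 31)) {
    mset <- random_mset(6, 60, seed)
    an <- anchor_to_reference(mset, "rCRS")
    vt <- call_variants(mset, an)
    rebuilt <- reconstruct_sequences(vt, an$rcrs_sequence)
    # non-variant positions are reference; variant positions are the calls
    expect_identical(unname(rebuilt[names(mset$sequences)]),
                     unname(mset$sequences))
    vt2 <- call_variants(mitogenome_set(rebuilt, mset$metadata),
                         anchor_to_reference(
                           mitogenome_set(rebuilt, mset$metadata), "rCRS"))
    expect_identical(vt$sites, vt2$sites)
    expect_identical(vt$calls, vt2$calls)
  }
})

test_that("haploid VCF output round-trips through a standard parser", {
  skip_if_not_installed("vcfR")
  mset <- toy_alignment()
  vt <- call_variants(mset, anchor_to_reference(mset, "rCRS"))
  tmp <- tempfile(fileext = ".vcf")
  write_vcf(vt, tmp)
  v <- vcfR::read.vcfR(tmp, verbose = FALSE)
  expect_equal(as.integer(v@fix[, "POS"]), vt$sites$position)
  expect_equal(unname(v@fix[, "REF"]), vt$sites$ref)
  expect_equal(unname(v@fix[, "ALT"]), vt$sites$alt)
  gt <- vcfR::extract.gt(v)
  # sample S4 carries the alt at positions 3 and 12, ref elsewhere
  expect_equal(unname(gt[, "S4"]), as.character(c(1, 0, 1, 0)))
  # S3's alignment gap at position 12 becomes a missing genotype
  i12 <- which(vt$sites$position == 12)
  expect_true(is.na(gt[i12, "S3"]) || gt[i12, "S3"] == ".")
})

test_that("multiallelic rows become single comma-separated VCF lines", {
  mset <- mitogenome_set(c(rCRS = "AAAA", S1 = "CAAA", S2 = "TAAA"))
  vt <- call_variants(mset, anchor_to_reference(mset, "rCRS"))
  expect_equal(vt$sites$alt, "C,T")
  tmp <- tempfile(fileext = ".vcf")
  write_vcf(vt, tmp)
  lines <- grep("^[^#]", readLines(tmp), value = TRUE)
  expect_length(lines, 1)
  expect_match(lines, "\tC,T\t")

  # empty table: header-only VCF
  mset0 <- mitogenome_set(c(rCRS = "AAAA", S1 = "AAAA"))
  vt0 <- call_variants(mset0, anchor_to_reference(mset0, "rCRS"))
  write_vcf(vt0, tmp)
  expect_length(grep("^[^#]", readLines(tmp)), 0)
})

test_that("map_to_reference merges pairwise alignments on rCRS coordinates", {
  ref <- paste(rep(c("ACGTGCTTAC"), 6), collapse = "")  # 60 bp
  refchars <- strsplit(ref, "")[[1]]
  del <- paste(refchars[-(21:23)], collapse = "")         # 3 bp deletion
  sub <- refchars; sub[40] <- "A"
  ins <- paste(c(refchars[1:30], "TTT", refchars[31:60]), collapse = "")
  mset <- map_to_reference(c(D = del, M = paste(sub, collapse = ""),
                             I = ins), reference = ref)
  expect_equal(nchar(mset$sequences[["D"]]), 60)
  expect_identical(substr(mset$sequences[["D"]], 21, 23), "---")
  expect_identical(substr(mset$sequences[["M"]], 40, 40), "A")
  # the insertion is recorded, not kept as columns
  expect_equal(nchar(mset$sequences[["I"]]), 60)
  insrec <- attr(mset, "insertions")
  expect_equal(insrec$sample_id, "I")
  expect_equal(insrec$insertion, "TTT")
  expect_equal(insrec$after_position, 30)
})

test_that("column-mapping conservation holds for full-span samples", {
  mset <- random_mset(4, 80, 5)
  an <- anchor_to_reference(mset, "rCRS")
  expect_equal(sum(!is.na(an$column_to_position)), 80)
  expect_equal(an$n_positions, nchar(an$rcrs_sequence))
})
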