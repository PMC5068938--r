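test_that("flank unit primers split the repeat symmetrically and extend to the product", {
  set.seed(61)
  left <- random_dna(37); right <- random_dna(37); rep24 <- random_dna(24)
  unit <- design_flank_unit(left, rep24, right, overlap = 12)
  expect_equal(nchar(unit$fw_primer$seq), 55L)  # 37 + 18
  expect_equal(nchar(unit$rv_primer$seq), 55L)  # 18 + 37
  expect_equal(nchar(unit$product), 98L)        # 37 + 24 + 37
  expect_equal(unit$product, paste0(left, rep24, right))
  # independent extension oracle: fw + rv template overlap reconstruction
  top_rv <- oracle_revcomp_dna(unit$rv_primer$seq)
  overlap_len <- nchar(unit$fw_primer$seq) + nchar(top_rv) - nchar(unit$product)
  expect_equal(overlap_len, 12L)
  expect_equal(paste0(unit$fw_primer$seq,
                      substr(top_rv, overlap_len + 1, nchar(top_rv))),
               unit$product)
  expect_error(design_flank_unit(left, rep24, right, overlap = 30),
               class = "minicr_primer_error")
})

test_that("MOE primers are 50 nt with the anchor arm, and M primers are their prefixes", {
  bb <- toy_backbone()
  sp <- random_spacers(2)
  moe <- design_moe_primers(bb, sp[[1]], sp[[2]])
  expect_equal(nchar(moe$moe_fw$seq), 50L)
  expect_equal(nchar(moe$moe_rv$seq), 50L)
  expect_equal(moe$arm_length, 26L)  # 50 - 24-nt repeat
  d1 <- bb$spacers[["D1"]]; d5 <- bb$spacers[["D5"]]
  expect_equal(substr(moe$moe_fw$seq, 1, 26),
               substr(d1, nchar(d1) - 25, nchar(d1)))
  # moe_rv 5' end is the reverse complement of the D5 arm
  expect_equal(substr(moe$moe_rv$seq, 1, 26),
               oracle_revcomp_dna(substr(d5, 1, 26)))
  m <- design_m_primers(moe$moe_fw, moe$moe_rv, moe$arm_length)
  expect_true(startsWith(moe$moe_fw$seq, m$m_fw$seq))
  expect_true(startsWith(moe$moe_rv$seq, m$m_rv$seq))
  expect_error(design_moe_primers(bb, sp[[1]], sp[[2]], total_length = 10),
               class = "minicr_primer_error")
})

test_that("fusion joins flanks on shared spacers into the arm-flanked fragment", {
  bb <- toy_backbone()
  sp <- random_spacers(2)
  set <- design_oe_set(bb, sp)
  frag <- simulate_oe_fusion(set$units, set$m)
  # 26 + 24 + 37 + 24 + 37 + 24 + 26 for two 37-nt spacers
  expect_equal(nchar(frag$seq), 198L)
  expect_length(frag$unit_trace, 3L)
  expect_true(startsWith(frag$seq, set$m$m_fw$seq))
  expect_true(endsWith(frag$seq, oracle_revcomp_dna(set$m$m_rv$seq)))
  # independent concatenation oracle
  rep24 <- bb$repeat_seq
  d1 <- bb$spacers[["D1"]]; d5 <- bb$spacers[["D5"]]
  expected <- paste0(substr(d1, nchar(d1) - 25, nchar(d1)), rep24,
                     sp[[1]], rep24, sp[[2]], rep24, substr(d5, 1, 26))
  expect_equal(frag$seq, expected)
})

test_that("fusion is order-independent when joins are unambiguous", {
  bb <- toy_backbone()
  sp <- random_spacers(4)
  set <- design_oe_set(bb, sp)
  frag <- simulate_oe_fusion(set$units, set$m)
  set.seed(62)
  for (i in 1:5) {
    shuffled <- set$units[sample(seq_along(set$units))]
    expect_equal(simulate_oe_fusion(shuffled, set$m)$seq, frag$seq)
  }
})

test_that("duplicate inner spacers make fusion ambiguous; broken sets give no amplicon", {
  bb <- toy_backbone()
  s <- random_spacers(1)[[1]]
  dup <- c(S1 = s, S2 = s)
  set_dup <- design_oe_set(bb, dup)
  expect_error(simulate_oe_fusion(set_dup$units, set_dup$m),
               class = "minicr_ambiguous_fusion_error")
  sp <- random_spacers(3)
  set3 <- design_oe_set(bb, sp)
  # drop an inner unit: chain cannot reach the reverse arm
  expect_error(simulate_oe_fusion(set3$units[-2], set3$m),
               class = "minicr_no_amplicon_error")
  # drop the forward terminal unit: nothing carries the forward M arm
  expect_error(simulate_oe_fusion(set3$units[-1], set3$m),
               class = "minicr_no_amplicon_error")
})

test_that("megaprimer insertion reproduces direct assembly inside the template context", {
  bb <- toy_backbone()
  sp <- random_spacers(3)
  set <- design_oe_set(bb, sp)
  frag <- simulate_oe_fusion(set$units, set$m)
  set.seed(63)
  vec <- random_dna(200)
  template_locus <- paste0(bb$leader_seq, bb$repeat_seq,
                           paste0(vapply(bb$spacers, paste0, "",
                                         bb$repeat_seq), collapse = ""))
  template <- nuc_seq("plasmid", paste0(vec, template_locus),
                      alphabet = "DNA", topology = "circular")
  product <- simulate_megaprimer_insertion(frag, template)
  expect_equal(product$topology, "circular")
  # independent surgery oracle: replace the D2..D4 block in the template
  direct <- assemble_minicr(bb, sp)
  expected_linear <- paste0(vec, direct$full_seq)
  expect_equal(nchar(product$seq), nchar(expected_linear))
  expect_true(grepl(product$seq, paste0(expected_linear, expected_linear),
                    fixed = TRUE))
  # arm errors
  no_d1 <- nuc_seq("broken", paste0(vec, bb$repeat_seq), alphabet = "DNA",
                   topology = "circular")
  expect_error(simulate_megaprimer_insertion(frag, no_d1),
               class = "minicr_arm_error")
})

test_that("verify_oe_route round-trips random backbone/spacer sets", {
  set.seed(64)
  for (i in 1:10) {
    bb <- toy_backbone(seed = 6000 + i,
                       spacer_length = sample(35:40, 1),
                       repeat_length = sample(22:28, 1))
    k <- sample(1:5, 1)
    sp <- random_spacers(k, length = sample(35:40, 1))
    rep_route <- verify_oe_route(bb, sp)
    expect_true(rep_route$round_trip_ok,
                info = sprintf("set %d (k=%d)", i, k))
  }
})

test_that("the dosage route multiplies a spacer in place, matching direct assembly", {
  bb <- toy_backbone()
  s <- random_spacers(1, length = 37)
  single <- assemble_minicr(bb, c(AA2 = s[[1]]), name = "miniCR-A2")
  route <- design_dosage_route(single, s[[1]], copies = 3)
  expect_equal(nchar(route$over_fw$seq), 80L)  # 19 + 24 + 37
  expect_equal(sum(route$product$spacers == s[[1]]), 3L)
  expect_equal(names(route$product$spacers),
               c("D1", "AA2_c1", "AA2_c2", "AA2_c3", "D5", "D6"))
  direct <- assemble_minicr(bb, setNames(rep(s[[1]], 3), paste0("AA2_c", 1:3)))
  expect_equal(route$product$full_seq, direct$full_seq)
  # identity for a single copy
  expect_identical(design_dosage_route(single, s[[1]], 1)$product, single)
  # spacer must be present exactly once
  expect_error(design_dosage_route(single, random_dna(37), 3),
               class = "minicr_spacer_error")
  dup <- assemble_minicr(bb, setNames(rep(s[[1]], 2), c("a", "b")))
  expect_error(design_dosage_route(dup, s[[1]], 3),
               class = "minicr_spacer_error")
})

test_that("primer sheets flatten nested sets with protocol metadata", {
  bb <- toy_backbone()
  set <- design_oe_set(bb, random_spacers(2))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fasta")
  sheet <- write_primer_sheet(list(set$units[[2]]$fw_primer, set$moe, set$m),
                              tsv, fa,
                              protocol = list(ratio = "200:1"))
  expect_equal(nrow(sheet), 5L)
  expect_true(all(sheet$length >= 15L))
  expect_match(readLines(tsv)[1], "ratio: 200:1")
  expect_length(read_fasta(fa), 5L)
})
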