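test_that("default assembly replaces the second to fourth backbone spacers", {
  bb <- toy_backbone()
  new3 <- random_spacers(3)
  cons <- assemble_minicr(bb, new3)
  expect_equal(names(cons$spacers), c("D1", "S1", "S2", "S3", "D5", "D6"))
  expect_equal(unname(cons$provenance),
               c("backbone", "artificial", "artificial", "artificial",
                 "backbone", "backbone"))
  # n spacers, n+1 repeats
  n_rep <- lengths(regmatches(cons$full_seq,
                              gregexpr(bb$repeat_seq, cons$full_seq,
                                       fixed = TRUE)))
  expect_equal(unname(n_rep), length(cons$spacers) + 1L)
  # full_seq is exactly leader + (repeat+spacer)* + terminal repeat
  expect_equal(cons$full_seq,
               paste0(bb$leader_seq, bb$repeat_seq,
                      paste0(vapply(cons$spacers, paste0, "",
                                    bb$repeat_seq), collapse = "")))
  # default-mode arithmetic: |backbone| - 3 + |new|
  expect_equal(length(cons$spacers), length(bb$spacers) - 3L + 3L)
})

test_that("single insertion and identical dosage spacers are accepted", {
  bb <- toy_backbone()
  one <- assemble_minicr(bb, random_spacers(1))
  expect_equal(names(one$spacers), c("D1", "S1", "D5", "D6"))
  s <- random_spacers(1)[[1]]
  dosage <- assemble_minicr(bb, setNames(rep(s, 3), paste0("A_c", 1:3)))
  expect_equal(sum(dosage$spacers == s), 3L)
  expect_equal(sum(dosage$provenance == "artificial"), 3L)
})

test_that("assembly rejects corrupting spacers", {
  bb <- toy_backbone()
  expect_error(assemble_minicr(bb, c(S1 = paste0("AA", bb$repeat_seq, "TT"))),
               class = "minicr_spacer_error")
  expect_error(assemble_minicr(bb, c(S1 = "")), class = "minicr_spacer_error")
  expect_error(assemble_minicr(bb, character(0)), class = "minicr_input_error")
})

test_that("the locus transcript covers the array only and regenerates spacer RNA", {
  bb <- toy_backbone()
  new2 <- random_spacers(2)
  cons <- assemble_minicr(bb, new2)
  tx <- locus_transcript(cons)
  expect_equal(tx$alphabet, "RNA")
  expect_false(grepl("T", tx$seq, fixed = TRUE))
  expect_equal(nchar(tx$seq), nchar(cons$full_seq) - nchar(bb$leader_seq))
  # spacer RNA at its expected offset within the transcript
  rl <- nchar(bb$repeat_seq)
  pos <- rl  # after first repeat
  for (i in seq_along(cons$spacers)) {
    sl <- nchar(cons$spacers[[i]])
    expect_equal(substr(tx$seq, pos + 1, pos + sl),
                 transcribe(cons$spacers[[i]]))
    pos <- pos + sl + rl
  }
})

test_that("maturation yields one 8-nt-handled crRNA per spacer in array order", {
  bb <- toy_backbone()
  cons <- assemble_minicr(bb, random_spacers(3))
  cr <- mature_crrnas(cons)
  expect_length(cr, length(cons$spacers))
  handles <- vapply(cr, `[[`, "", "handle_rna")
  expect_equal(unique(handles),
               transcribe(substr(bb$repeat_seq, nchar(bb$repeat_seq) - 7,
                                 nchar(bb$repeat_seq))))
  expect_true(all(nchar(handles) == 8L))
  expect_equal(vapply(cr, `[[`, 0L, "array_index"),
               seq_along(cons$spacers))
  short_rep <- minicr_backbone(bb$leader_seq, "ACGTACGT", bb$spacers)
  expect_error(mc <- minicr_backbone(bb$leader_seq, "ACGT", bb$spacers),
               class = "minicr_repeat_error")
})

test_that("a crRNA derived from a scanned candidate base-pairs its protospacer", {
  h <- handle_spec("AUUGAAAG")
  fx <- synth_target_transcript(length = 800, k_sites = 1, handle = h,
                                seed = 51)
  cand <- scan_transcript(fx$transcript, h)[1, ]
  bb <- toy_backbone()
  spacer_dna <- make_spacer(cand$protospacer)$spacer_dna
  cons <- assemble_minicr(bb, c(AA1 = spacer_dna))
  cr <- mature_crrnas(cons)[[2]]  # D1 first, AA1 second
  expect_equal(cr$spacer_name, "AA1")
  # crRNA spacer is complementary to the protospacer: revcomp round trip
  expect_equal(revcomp(cr$spacer_rna), cand$protospacer)
})

test_that("validate_construct reports length, repeat and duplication issues", {
  bb <- toy_backbone()
  clean <- assemble_minicr(bb, random_spacers(2))
  expect_equal(nrow(validate_construct(clean)), 0L)
  short <- assemble_minicr(bb, c(S1 = "ACGTACGTACGT"))
  rep_short <- validate_construct(short)
  expect_true(any(rep_short$check == "spacer_length" &
                    rep_short$level == "violation"))
  s <- random_spacers(1)[[1]]
  dosage <- assemble_minicr(bb, setNames(rep(s, 2), c("A_c1", "A_c2")))
  rep_dup <- validate_construct(dosage)
  dup_rows <- rep_dup[rep_dup$check == "duplicate_spacer", ]
  expect_equal(unique(dup_rows$level), "warning")
  expect_match(dup_rows$message[1], "dosage")
})

test_that("GenBank output of a construct annotates the array and round-trips the sequence", {
  bb <- toy_backbone()
  cons <- assemble_minicr(bb, random_spacers(2), name = "miniCR_test")
  gb <- withr::local_tempfile(fileext = ".gb")
  write_construct_genbank(cons, gb)
  lines <- readLines(gb)
  expect_true(any(grepl("repeat_region", lines)))
  expect_true(any(grepl("/provenance=\"artificial\"", lines)))
  ori <- grep("^ORIGIN", lines)
  seq <- toupper(gsub("[^a-z]", "",
                      paste(lines[(ori + 1):(length(lines) - 1)],
                            collapse = "")))
  expect_equal(seq, cons$full_seq)
})
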