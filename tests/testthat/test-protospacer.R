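test_that("scan_transcript equals naive enumeration on random transcripts in both modes", {
  set.seed(31)
  for (i in 1:6) {
    n <- sample(300:2000, 1)
    seq <- random_rna(n)
    handle <- handle_spec(random_rna(8))
    for (wob in c(TRUE, FALSE)) {
      cfg_full <- scan_config(criterion_mode = "full",
                              pas_config = pas_config(wobble_counts_as_paired = wob))
      got <- scan_transcript(seq, handle, cfg_full)
      expect_equal(sort(got$start),
                   oracle_scan_starts(seq, handle$handle_rna, wobble = wob,
                                      mode = "full"))
      cfg_min <- scan_config(criterion_mode = "minimal",
                             pas_config = pas_config(wobble_counts_as_paired = wob))
      got_min <- scan_transcript(seq, handle, cfg_min)
      expect_equal(sort(got_min$start),
                   oracle_scan_starts(seq, handle$handle_rna, wobble = wob,
                                      mode = "minimal"))
    }
  }
})

test_that("scan candidates carry consistent pairing detail and ranking", {
  h <- handle_spec("AUUGAAAG")
  fx <- synth_target_transcript(length = 1200, k_sites = 3, handle = h,
                                seed = 32)
  cands <- scan_transcript(fx$transcript, h)
  expect_equal(sort(cands$start), fx$truth$planted_protospacers$start)
  expect_true(all(cands$paired_count >= 6L))
  expect_true(all(nchar(cands$protospacer) == 37L))
  expect_true(all(nchar(cands$pas) == 8L))
  # ranking: paired desc, then WC desc, then start asc
  key <- order(-cands$paired_count, -cands$wc_count, cands$start)
  expect_equal(key, seq_len(nrow(cands)))
  # spacer is the reverse complement of the protospacer
  for (r in seq_len(nrow(cands))) {
    expect_equal(cands$spacer_rna[r],
                 make_spacer(cands$protospacer[r])$spacer_rna)
  }
})

test_that("short transcripts warn and return an empty table", {
  h <- toy_handle()
  expect_warning(res <- scan_transcript(random_rna(30), h),
                 class = "minicr_short_transcript_warning")
  expect_equal(nrow(res), 0L)
})

test_that("poly-A transcripts admit no minimal-motif candidate for a C-requiring handle", {
  h <- toy_handle()  # minimal motif needs G at the +5-equivalent position
  seq <- paste(rep("A", 200), collapse = "")
  res <- scan_transcript(seq, h, scan_config(criterion_mode = "minimal"))
  expect_equal(nrow(res), 0L)
})

test_that("tightening the criterion never adds candidates", {
  set.seed(33)
  for (i in 1:4) {
    seq <- random_rna(900)
    handle <- handle_spec(random_rna(8))
    loose <- scan_transcript(seq, handle, scan_config(
      pas_config = pas_config(min_paired = 5)))
    tight <- scan_transcript(seq, handle, scan_config(
      pas_config = pas_config(min_paired = 6)))
    no_wob <- scan_transcript(seq, handle, scan_config(
      pas_config = pas_config(min_paired = 5,
                              wobble_counts_as_paired = FALSE)))
    expect_true(all(tight$start %in% loose$start))
    expect_true(all(no_wob$start %in% loose$start))
  }
})

test_that("make_spacer round-trips through the array top strand", {
  set.seed(34)
  ps <- random_rna(37)
  sp <- make_spacer(ps)
  expect_equal(nchar(sp$spacer_rna), 37L)
  expect_equal(sp$spacer_rna, revcomp(ps))
  # transcribing the inserted DNA spacer regenerates the crRNA spacer,
  # whose reverse complement is the protospacer again
  expect_equal(revcomp(transcribe(sp$spacer_dna)), ps)
})

test_that("select_multiplex respects separation, rank order, and infeasibility reporting", {
  cands <- data.frame(
    transcript_id = "tx",
    start = seq(1, 901, by = 100),
    end = seq(1, 901, by = 100) + 36L,
    paired_count = c(8, 7, 7, 6, 6, 6, 6, 6, 6, 6),
    wc_count = c(8, 7, 6, 6, 6, 6, 6, 6, 6, 6),
    stringsAsFactors = FALSE)
  cands <- cands[order(-cands$paired_count, -cands$wc_count, cands$start), ]
  picks <- select_multiplex(cands, 5, min_separation = 150)
  expect_equal(nrow(picks), 5L)
  expect_true(all(diff(picks$start) >= 150))
  top1 <- select_multiplex(cands, 1, min_separation = 150)
  expect_equal(top1$start, 1L)  # top-ranked candidate
  err <- expect_error(select_multiplex(cands, 11, min_separation = 150),
                      class = "minicr_infeasible_error")
  # starts 1,101,...,901 with >=150 nt separation admit at most 1,201,401,601,801
  expect_match(conditionMessage(err), "maximum feasible k is 5")
})

test_that("min_mismatches equals exhaustive offset enumeration", {
  h <- toy_handle()
  set.seed(35)
  tx <- random_rna(500)
  # perfect target: spacer built from a window
  window <- substr(tx, 101, 137)
  expect_equal(min_mismatches(revcomp(window), tx), 0L)
  # single planted mismatch
  mut <- window
  substr(mut, 15, 15) <- setdiff(c("A", "C", "G", "U"),
                                 substr(mut, 15, 15))[1]
  sp1 <- revcomp(mut)
  expect_equal(min_mismatches(sp1, tx), 1L)
  for (i in 1:5) {
    sp <- random_rna(37)
    expect_equal(min_mismatches(sp, tx), oracle_min_mismatches(sp, tx))
  }
  expect_error(min_mismatches(random_rna(50), random_rna(40)),
               class = "minicr_input_error")
})

test_that("nonsense spacers exceed the mismatch threshold and are seed-deterministic", {
  set.seed(36)
  target <- nuc_seq("amylase_like", random_rna(2709), alphabet = "RNA")
  sp <- generate_nonsense_spacer(39, list(target), threshold = 20, seed = 99)
  expect_equal(nchar(sp), 39L)
  expect_gt(oracle_min_mismatches(as.character(sp), target$seq), 20L)
  sp2 <- generate_nonsense_spacer(39, list(target), threshold = 20, seed = 99)
  expect_equal(as.character(sp), as.character(sp2))
  expect_error(generate_nonsense_spacer(39, list(target), threshold = 39),
               class = "minicr_input_error")
  expect_error(generate_nonsense_spacer(10, list(target), threshold = 9,
                                        seed = 1, max_attempts = 3),
               class = "minicr_sampling_error")
})

test_that("offtarget_scan finds planted hits and agrees with min_mismatches", {
  set.seed(37)
  txs <- lapply(1:3, function(i) nuc_seq(paste0("tx", i), random_rna(400),
                                         alphabet = "RNA"))
  window <- substr(txs[[2]]$seq, 200, 236)
  sp <- revcomp(window)
  hits <- offtarget_scan(sp, txs, max_mismatches = 0)
  expect_equal(hits$transcript_id, "tx2")
  expect_equal(hits$start, 200L)
  expect_equal(hits$mismatches, 0L)
  none <- offtarget_scan(random_rna(37), txs, max_mismatches = 0)
  expect_equal(nrow(none), 0L)
  # cross-operation consistency: best hit per transcript == min_mismatches
  all_hits <- offtarget_scan(sp, txs, max_mismatches = 37)
  for (tx in txs) {
    best <- min(all_hits$mismatches[all_hits$transcript_id == tx$id])
    expect_equal(best, min_mismatches(sp, tx))
  }
})
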