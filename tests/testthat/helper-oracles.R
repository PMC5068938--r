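# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive expectations with naive loops and lookup tables,
# not via the package's own code paths.

ORACLE_PAIR <- local({
  wc <- c("A U", "U A", "G C", "C G")
  wob <- c("G U", "U G")
  function(target, handle) {
    key <- paste(target, handle)
    if (key %in% wc) "WATSON_CRICK" else if (key %in% wob) "WOBBLE" else "MISMATCH"
  }
})

# naive double-loop scan: every window, every PAS position classified one
# by one with the lookup table above
oracle_scan_starts <- function(seq, handle_str, L = 37L, min_paired = 6L,
                               wobble = TRUE, mode = "full",
                               minimal = c(3L, 4L, 5L)) {
  n <- nchar(seq)
  if (n < L + 8L) return(integer(0))
  hits <- integer(0)
  for (s in 1:(n - L - 7L)) {
    paired <- logical(8)
    for (i in 1:8) {
      t <- substr(seq, s + L + i - 1L, s + L + i - 1L)
      h <- substr(handle_str, 9L - i, 9L - i)
      cls <- ORACLE_PAIR(t, h)
      paired[i] <- cls == "WATSON_CRICK" || (wobble && cls == "WOBBLE")
    }
    ok <- if (mode == "full") sum(paired) >= min_paired else all(paired[minimal])
    if (ok) hits <- c(hits, s)
  }
  hits
}

# exhaustive offset enumeration of the ungapped mismatch minimum
oracle_min_mismatches <- function(spacer_rna, transcript_seq) {
  target <- chartr("ACGU", "UGCA", spacer_rna)
  target <- paste(rev(strsplit(target, "")[[1]]), collapse = "")
  tc <- strsplit(transcript_seq, "")[[1]]
  pc <- strsplit(target, "")[[1]]
  L <- length(pc)
  best <- L + 1L
  for (s in 1:(length(tc) - L + 1L)) {
    mm <- sum(tc[s:(s + L - 1L)] != pc)
    if (mm < best) best <- mm
  }
  best
}

# naive sliding count of motif trinucleotides
oracle_motif_count <- function(seq, patterns, min_pos = 1L) {
  n <- nchar(seq)
  if (n < 3L) return(0L)
  cnt <- 0L
  for (p in max(1L, min_pos):(n - 2L)) {
    if (substr(seq, p, p + 2L) %in% patterns) cnt <- cnt + 1L
  }
  cnt
}

# independent reverse complement for involution checks
oracle_revcomp_dna <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

toy_handle <- function() handle_spec("CCCCUUUU")

# compact backbone for assembly/OE tests (short leader keeps sequences small)
toy_backbone <- function(seed = 101L, spacer_length = 37L,
                         repeat_length = 24L, n_spacers = 6L) {
  synth_backbone(seed = seed, n_spacers = n_spacers,
                 spacer_length = spacer_length,
                 repeat_length = repeat_length, leader_length = 60L)
}

random_spacers <- function(k, length = 37L) {
  sp <- vapply(seq_len(k), function(i) random_dna(length), "")
  names(sp) <- paste0("S", seq_len(k))
  sp
}
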