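# Protospacer enumeration, filtering, ranking and selection on a target
# transcript, plus mismatch-based off-target screening and nonsense-spacer
# generation for control constructs.

#' Scan configuration
#'
#' @param protospacer_length protospacer window length in nt (default 37).
#' @param criterion_mode `"full"` (keep windows whose PAS pairs at least
#'   `min_paired` handle positions) or `"minimal"` (keep windows whose PAS
#'   pairs all of the minimal positions, default -3/-4/-5).
#' @param pas_config a [pas_config()].
#' @param min_separation default minimum distance between selected
#'   protospacer starts in [select_multiplex()]; defaults to twice the
#'   protospacer length so multiplexed spacers hit well-separated positions.
#' @param energy_threshold optional kcal/mol cutoff, applied only when an
#'   energy scorer is plugged into [scan_transcript()]; candidates with
#'   interaction energy above (weaker than) the threshold are dropped.
#' @return object of class `scan_config`.
#' @export
scan_config <- function(protospacer_length = 37L,
                        criterion_mode = c("full", "minimal"),
                        pas_config = minicrdesign::pas_config(),
                        min_separation = 2L * protospacer_length,
                        energy_threshold = NULL) {
  protospacer_length <- as.integer(protospacer_length)
  if (is.na(protospacer_length) || protospacer_length < 1L) {
    mc_error("protospacer_length must be >= 1", "minicr_input_error")
  }
  structure(list(protospacer_length = protospacer_length,
                 criterion_mode = match.arg(criterion_mode),
                 pas_config = pas_config,
                 min_separation = as.integer(min_separation),
                 energy_threshold = energy_threshold),
            class = "scan_config")
}

# vectorised per-window pairing profile: returns a list with matrices of
# pair classes for all windows at once (rows = windows, cols = +1..+8)
scan_profiles <- function(chars, n, L, handle) {
  nw <- n - L - 7L
  cls <- matrix("", nrow = nw, ncol = 8L)
  for (i in 1:8) {
    tb <- chars[(L + i):(L + i + nw - 1L)]
    hb <- handle_base(handle, i)
    wc <- WC_PARTNER[tb] == hb
    wo <- !is.na(WOBBLE_PARTNER[tb]) & WOBBLE_PARTNER[tb] == hb
    cls[, i] <- ifelse(wc, "WATSON_CRICK", ifelse(wo, "WOBBLE", "MISMATCH"))
  }
  cls
}

#' Scan a transcript for PAS-compliant protospacers
#'
#' Slides a window of `protospacer_length` over the mRNA, reads the 8 nt
#' immediately 3' of each window as the PAS, matches it against the handle,
#' and returns every window passing the active criterion. Candidates are
#' ranked by paired count (descending), then Watson-Crick-only count
#' (descending), then start (ascending).
#'
#' @param transcript RNA [nuc_seq()] or string (mRNA, sense orientation).
#' @param handle a [handle_spec()].
#' @param config a [scan_config()].
#' @param energy_scorer optional `function(spacer_rna, protospacer_rna)`
#'   returning an interaction energy in kcal/mol (plug in an external
#'   folding tool or a lookup table); when absent the `energy` column is
#'   `NA` and no energy filtering occurs.
#' @return data.frame of candidates: `transcript_id`, `start`, `end`
#'   (1-based inclusive), `protospacer`, `spacer_rna`, `pas`,
#'   `paired_count`, `wc_count`, `minimal_ok`, `pairing` (in PAS order
#'   +1..+8), `energy`.
#' @export
scan_transcript <- function(transcript, handle, config = scan_config(),
                            energy_scorer = NULL) {
  id <- if (inherits(transcript, "nuc_seq")) transcript$id else "transcript"
  seq <- toupper(seq_chr(transcript))
  if (inherits(transcript, "nuc_seq") && transcript$alphabet != "RNA") {
    mc_error(sprintf("transcript '%s' must be RNA", id),
             "minicr_alphabet_error")
  }
  check_alphabet(seq, "RNA", id)
  L <- config$protospacer_length
  n <- nchar(seq)
  empty <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), protospacer = character(),
                      spacer_rna = character(), pas = character(),
                      paired_count = integer(), wc_count = integer(),
                      minimal_ok = logical(), pairing = character(),
                      energy = numeric(), stringsAsFactors = FALSE)
  if (n < L + 8L) {
    mc_warn(sprintf(
      "transcript '%s' (%d nt) too short for a %d-nt protospacer plus 8-nt PAS",
      id, n, L), "minicr_short_transcript_warning")
    return(empty)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  cls <- scan_profiles(chars, n, L, handle)
  pc <- config$pas_config
  paired <- cls == "WATSON_CRICK" |
    (pc$wobble_counts_as_paired & cls == "WOBBLE")
  paired_count <- rowSums(paired)
  wc_count <- rowSums(cls == "WATSON_CRICK")
  minimal_ok <- rowSums(paired[, -pc$minimal_positions, drop = FALSE]) ==
    length(pc$minimal_positions)
  keep <- if (config$criterion_mode == "full") {
    paired_count >= pc$min_paired
  } else {
    minimal_ok
  }
  starts <- which(keep)
  if (length(starts) == 0L) return(empty)
  glyph <- c("WATSON_CRICK" = "|", "WOBBLE" = ":", "MISMATCH" = ".")
  res <- data.frame(
    transcript_id = id,
    start = starts,
    end = starts + L - 1L,
    protospacer = substring(seq, starts, starts + L - 1L),
    spacer_rna = vapply(substring(seq, starts, starts + L - 1L),
                        revcomp_chr, "", alphabet = "RNA",
                        USE.NAMES = FALSE),
    pas = substring(seq, starts + L, starts + L + 7L),
    paired_count = paired_count[starts],
    wc_count = wc_count[starts],
    minimal_ok = minimal_ok[starts],
    pairing = apply(cls[starts, , drop = FALSE], 1L,
                    function(r) paste(glyph[r], collapse = "")),
    energy = NA_real_,
    stringsAsFactors = FALSE)
  if (!is.null(energy_scorer)) {
    res$energy <- mapply(energy_scorer, res$spacer_rna, res$protospacer)
    if (!is.null(config$energy_threshold)) {
      res <- res[!is.na(res$energy) & res$energy < config$energy_threshold, ,
                 drop = FALSE]
    }
  }
  res <- res[order(-res$paired_count, -res$wc_count, res$start), ,
             drop = FALSE]
  rownames(res) <- NULL
  attr(res, "scan_config") <- config
  attr(res, "handle") <- handle
  res
}

#' Derive the spacer from a protospacer
#'
#' The crRNA spacer is the reverse complement of the protospacer (the crRNA
#' base-pairs the mRNA). `spacer_dna` is the same sequence in DNA alphabet,
#' as inserted into the array top strand, so that transcription of the locus
#' regenerates `spacer_rna`.
#'
#' @param protospacer RNA string (or a candidate row's `protospacer`).
#' @return list with `spacer_rna` and `spacer_dna`.
#' @export
make_spacer <- function(protospacer) {
  ps <- toupper(seq_chr(protospacer))
  check_alphabet(ps, "RNA", "protospacer")
  spacer_rna <- revcomp_chr(ps, "RNA")
  list(spacer_rna = spacer_rna, spacer_dna = rna_to_dna(spacer_rna))
}

#' Select spacers for a multiplex construct
#'
#' Greedy selection in rank order subject to a minimum pairwise separation
#' between protospacer starts, so the construct targets well-separated
#' positions on the mRNA.
#'
#' @param candidates data.frame from [scan_transcript()] (already ranked).
#' @param k number of spacers wanted.
#' @param min_separation minimum distance between any two selected starts
#'   (nt); defaults to the scan config's value when attached, else 74.
#' @return the `k` selected rows, in transcript order.
#' @export
select_multiplex <- function(candidates, k, min_separation = NULL) {
  if (is.null(min_separation)) {
    cfg <- attr(candidates, "scan_config")
    min_separation <- if (!is.null(cfg)) cfg$min_separation else 74L
  }
  k <- as.integer(k)
  if (k < 1L) mc_error("k must be >= 1", "minicr_input_error")
  picked <- integer(0)
  for (i in seq_len(nrow(candidates))) {
    s <- candidates$start[i]
    if (all(abs(s - candidates$start[picked]) >= min_separation)) {
      picked <- c(picked, i)
      if (length(picked) == k) break
    }
  }
  if (length(picked) < k) {
    # true maximum feasible k: greedy over starts in increasing order
    starts <- sort(candidates$start)
    feas <- 0L; last <- -Inf
    for (s in starts) {
      if (s - last >= min_separation) { feas <- feas + 1L; last <- s }
    }
    mc_error(sprintf(
      "cannot select %d candidates with separation >= %d nt; maximum feasible k is %d",
      k, min_separation, feas), "minicr_infeasible_error")
  }
  out <- candidates[picked, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Hamming distances between `pattern` and every equal-length window of
# `chars`; vectorised over windows.
window_mismatches <- function(chars, pattern_chars) {
  L <- length(pattern_chars)
  nw <- length(chars) - L + 1L
  mm <- integer(nw)
  for (j in seq_len(L)) {
    mm <- mm + (chars[j:(j + nw - 1L)] != pattern_chars[j])
  }
  mm
}

#' Minimum mismatch count of a spacer against a transcript
#'
#' The spacer targets the reverse complement of transcript windows, so the
#' reverse complement of the spacer is compared (ungapped Hamming distance)
#' against every equal-length window of the transcript; the minimum over all
#' offsets is returned.
#'
#' @param spacer_rna RNA spacer.
#' @param transcript RNA [nuc_seq()] or string.
#' @return integer minimum mismatch count.
#' @export
min_mismatches <- function(spacer_rna, transcript) {
  sp <- toupper(seq_chr(spacer_rna))
  tr <- toupper(seq_chr(transcript))
  check_alphabet(sp, "RNA", "spacer")
  check_alphabet(tr, "RNA", "transcript")
  if (nchar(sp) > nchar(tr)) {
    mc_error("spacer longer than transcript", "minicr_input_error")
  }
  pattern <- strsplit(revcomp_chr(sp, "RNA"), "", fixed = TRUE)[[1]]
  chars <- strsplit(tr, "", fixed = TRUE)[[1]]
  min(window_mismatches(chars, pattern))
}

#' Scan a transcriptome for off-target hits of a spacer
#'
#' Ungapped sliding-window comparison of the spacer's target sequence
#' (reverse complement of the spacer) against every transcript.
#'
#' @param spacer_rna RNA spacer.
#' @param transcriptome list of RNA [nuc_seq()] records.
#' @param max_mismatches report hits with at most this many mismatches.
#' @return data.frame `transcript_id`, `start`, `mismatches`, sorted by
#'   mismatches then transcript then position.
#' @export
offtarget_scan <- function(spacer_rna, transcriptome, max_mismatches) {
  sp <- toupper(seq_chr(spacer_rna))
  check_alphabet(sp, "RNA", "spacer")
  pattern <- strsplit(revcomp_chr(sp, "RNA"), "", fixed = TRUE)[[1]]
  hits <- lapply(transcriptome, function(tx) {
    tr <- toupper(seq_chr(tx))
    if (nchar(tr) < length(pattern)) return(NULL)
    mm <- window_mismatches(strsplit(tr, "", fixed = TRUE)[[1]], pattern)
    idx <- which(mm <= max_mismatches)
    if (length(idx) == 0L) return(NULL)
    data.frame(transcript_id = if (inherits(tx, "nuc_seq")) tx$id else "tx",
               start = idx, mismatches = mm[idx],
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    return(data.frame(transcript_id = character(), start = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$mismatches, hits$transcript_id, hits$start), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Generate a nonsense (non-targeting) control spacer
#'
#' Rejection-samples random RNA spacers until one exceeds the mismatch
#' threshold against every excluded target at every ungapped offset —
#' the criterion used for the Z1/Z2 control spacers (39 nt, more than 20
#' mismatches anywhere on the target gene). Deterministic for a fixed seed.
#'
#' @param length spacer length in nt (default 39).
#' @param excluded_targets list of RNA [nuc_seq()]/strings the spacer must
#'   not match.
#' @param threshold required `min_mismatches` strictly exceeded against every
#'   excluded target (default 20). Must be below `length`.
#' @param seed integer RNG seed (optional; the caller's RNG state is
#'   restored afterwards).
#' @param max_attempts rejection-sampling budget.
#' @return RNA spacer string with attributes `min_mismatches` (per target)
#'   and `attempts`.
#' @export
generate_nonsense_spacer <- function(length = 39L, excluded_targets,
                                     threshold = 20L, seed = NULL,
                                     max_attempts = 10000L) {
  length <- as.integer(length); threshold <- as.integer(threshold)
  if (threshold >= length) {
    mc_error("threshold must be smaller than the spacer length",
             "minicr_input_error")
  }
  if (!is.list(excluded_targets)) excluded_targets <- list(excluded_targets)
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      sp <- paste(sample(RNA_BASES, length, replace = TRUE), collapse = "")
      mm <- vapply(excluded_targets, function(t) min_mismatches(sp, t), 0L)
      if (all(mm > threshold)) {
        return(structure(sp, min_mismatches = mm, attempts = attempt))
      }
    }
    mc_error(sprintf(
      "no spacer with > %d mismatches found in %d attempts; lower the threshold",
      threshold, max_attempts), "minicr_sampling_error")
  })
}

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write scan candidates as TSV
#'
#' @param candidates data.frame from [scan_transcript()].
#' @param path output file.
#' @param provenance optional named list written as `#`-prefixed header
#'   lines (e.g. config hash, seed).
#' @export
write_candidates_tsv <- function(candidates, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    for (nm in names(provenance)) {
      writeLines(sprintf("# %s: %s", nm, provenance[[nm]]), con)
    }
  }
  utils::write.table(candidates, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
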