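# crRNA 5'-handle vs target-RNA PAS base-pairing rules.
#
# Position convention: the mature crRNA handle is 8 nt, numbered -8..-1 with
# -1 adjacent to the spacer. The PAS is the 8 nt immediately 3' of the
# protospacer on the target mRNA, numbered +1..+8. Pairing is antiparallel:
# target position +i is read against handle position -i.

WC_PARTNER <- c(A = "U", U = "A", G = "C", C = "G")
WOBBLE_PARTNER <- c(G = "U", U = "G")  # G:U wobble, symmetric

#' Define a crRNA 5' handle
#'
#' The 8-nt repeat-derived handle of a mature crRNA, written 5' to 3' so the
#' first character is position -8 and the last is position -1 (adjacent to
#' the spacer). When the source DNA repeat is supplied, the handle must equal
#' the transcription of its final 8 nt — that is how processing generates it.
#'
#' @param handle_rna 8-nt RNA string, 5' to 3'.
#' @param source_repeat optional DNA repeat whose last 8 nt transcribe to
#'   `handle_rna`.
#' @return object of class `handle_spec`.
#' @export
handle_spec <- function(handle_rna, source_repeat = NULL) {
  handle_rna <- toupper(handle_rna)
  if (nchar(handle_rna) != 8L) {
    mc_error("handle_rna must be exactly 8 nt", "minicr_input_error")
  }
  check_alphabet(handle_rna, "RNA", "handle")
  if (!is.null(source_repeat)) {
    source_repeat <- toupper(source_repeat)
    check_alphabet(source_repeat, "DNA", "repeat")
    if (nchar(source_repeat) < 8L) {
      mc_error("source_repeat shorter than 8 nt", "minicr_input_error")
    }
    tail8 <- substr(source_repeat, nchar(source_repeat) - 7L,
                    nchar(source_repeat))
    if (transcribe_chr(tail8) != handle_rna) {
      mc_error(sprintf(
        "handle %s does not match transcription of repeat tail %s",
        handle_rna, tail8), "minicr_input_error")
    }
  }
  structure(list(handle_rna = handle_rna, source_repeat = source_repeat),
            class = "handle_spec")
}

#' Derive the handle from a DNA repeat
#'
#' @param repeat_seq DNA repeat (at least 8 nt).
#' @return [handle_spec()] whose handle is the transcribed 8-nt repeat tail.
#' @export
handle_from_repeat <- function(repeat_seq) {
  repeat_seq <- toupper(repeat_seq)
  check_alphabet(repeat_seq, "DNA", "repeat")
  if (nchar(repeat_seq) < 8L) {
    mc_error("repeat shorter than 8 nt", "minicr_repeat_error")
  }
  tail8 <- substr(repeat_seq, nchar(repeat_seq) - 7L, nchar(repeat_seq))
  handle_spec(transcribe_chr(tail8), source_repeat = repeat_seq)
}

#' @export
print.handle_spec <- function(x, ...) {
  cat(sprintf("<handle_spec> 5'-%s-3' (positions -8..-1)\n", x$handle_rna))
  invisible(x)
}

# base at handle position -i (i in 1..8)
handle_base <- function(handle, i) {
  substr(handle$handle_rna, 9L - i, 9L - i)
}

#' PAS-matching configuration
#'
#' @param min_paired minimum number of paired handle positions for the full
#'   acceptance criterion (default 6 of 8).
#' @param wobble_counts_as_paired whether G:U wobble positions count as
#'   paired (default `TRUE`; accepted designs display G:U pairing).
#' @param minimal_positions handle positions whose pairing alone suffices to
#'   suppress DNA interference (default `c(-3, -4, -5)`).
#' @return object of class `pas_config`.
#' @export
pas_config <- function(min_paired = 6L, wobble_counts_as_paired = TRUE,
                       minimal_positions = c(-3L, -4L, -5L)) {
  min_paired <- as.integer(min_paired)
  if (is.na(min_paired) || min_paired < 0L || min_paired > 8L) {
    mc_error("min_paired must be in 0..8", "minicr_input_error")
  }
  minimal_positions <- sort(as.integer(minimal_positions), decreasing = TRUE)
  if (!all(minimal_positions %in% -8:-1)) {
    mc_error("minimal_positions must lie in -8..-1", "minicr_input_error")
  }
  structure(list(min_paired = min_paired,
                 wobble_counts_as_paired = isTRUE(wobble_counts_as_paired),
                 minimal_positions = minimal_positions),
            class = "pas_config")
}

#' Classify one target/handle base pair
#'
#' Watson-Crick (`A:U`, `U:A`, `G:C`, `C:G`), G:U wobble (`G:U`, `U:G`), or
#' mismatch. Symmetric in its arguments. Bases must be RNA; DNA input is an
#' error so callers transcribe first. With `strict = FALSE`, IUPAC ambiguity
#' codes are classified as `MISMATCH` (never-pairing) instead of erroring.
#'
#' @param target_base,handle_base single RNA bases.
#' @param strict error on ambiguity codes (default) rather than treating
#'   them as mismatches.
#' @return `"WATSON_CRICK"`, `"WOBBLE"` or `"MISMATCH"`.
#' @export
classify_pair <- function(target_base, handle_base, strict = TRUE) {
  tb <- toupper(target_base); hb <- toupper(handle_base)
  for (b in c(tb, hb)) {
    if (b %in% RNA_BASES) next
    if (b == "T") {
      mc_error("DNA base 'T' supplied: transcribe to RNA first",
               "minicr_alphabet_error")
    }
    if (!strict && b %in% IUPAC_AMBIGUITY) return("MISMATCH")
    mc_error(sprintf("invalid RNA base '%s'", b), "minicr_alphabet_error")
  }
  if (WC_PARTNER[[tb]] == hb) return("WATSON_CRICK")
  if (!is.na(WOBBLE_PARTNER[tb]) && WOBBLE_PARTNER[[tb]] == hb) return("WOBBLE")
  "MISMATCH"
}

pair_counts_as_paired <- function(cls, config) {
  cls == "WATSON_CRICK" | (config$wobble_counts_as_paired & cls == "WOBBLE")
}

#' Match a PAS against a crRNA handle
#'
#' Classifies each of the 8 PAS positions against the corresponding handle
#' position in antiparallel register (+i against -i) and summarises the
#' profile.
#'
#' @param pas 8-nt RNA, 5' to 3', at target positions +1..+8 immediately
#'   downstream of the protospacer.
#' @param handle a [handle_spec()].
#' @param config a [pas_config()].
#' @param strict passed to [classify_pair()].
#' @return object of class `pas_match` with `per_position` (named by handle
#'   position "-1".."-8"), `paired_count`, `wc_count`, `minimal_ok` and a
#'   compact `pairing_string` (`|` Watson-Crick, `:` wobble, `.` mismatch,
#'   written in PAS order +1..+8).
#' @export
match_pas <- function(pas, handle, config = pas_config(), strict = TRUE) {
  pas <- toupper(seq_chr(pas))
  if (nchar(pas) != 8L) {
    mc_error("PAS must be exactly 8 nt", "minicr_input_error")
  }
  cls <- vapply(1:8, function(i) {
    classify_pair(substr(pas, i, i), handle_base(handle, i), strict = strict)
  }, "")
  names(cls) <- as.character(-(1:8))
  paired <- pair_counts_as_paired(cls, config)
  minimal_idx <- as.character(config$minimal_positions)
  structure(list(
    per_position = cls,
    paired_count = sum(paired),
    wc_count = sum(cls == "WATSON_CRICK"),
    minimal_ok = all(paired[minimal_idx]),
    pairing_string = paste(c("WATSON_CRICK" = "|", "WOBBLE" = ":",
                             "MISMATCH" = ".")[cls], collapse = "")
  ), class = "pas_match")
}

#' @export
print.pas_match <- function(x, ...) {
  cat(sprintf("<pas_match> paired %d/8 (WC %d) minimal_ok=%s  [+1..+8] %s\n",
              x$paired_count, x$wc_count, x$minimal_ok, x$pairing_string))
  invisible(x)
}

# target bases pairing a given handle base under the config
paired_target_bases <- function(hb, config) {
  out <- names(WC_PARTNER)[WC_PARTNER == hb]
  if (config$wobble_counts_as_paired) {
    out <- c(out, names(WOBBLE_PARTNER)[!is.na(WOBBLE_PARTNER) &
                                          WOBBLE_PARTNER == hb])
  }
  unique(out)
}

#' Enumerate the minimal PAS motif trinucleotides
#'
#' Returns every target-side trinucleotide (read 5' to 3' at the + positions
#' mirroring `minimal_positions`) for which the minimal criterion holds —
#' the fast path used by the genome survey. The minimal set must be three
#' contiguous handle positions (the motif is defined as a contiguous 3-mer).
#'
#' @param handle a [handle_spec()].
#' @param config a [pas_config()].
#' @return sorted character vector of RNA 3-mers.
#' @export
minimal_motif_patterns <- function(handle, config = pas_config()) {
  pos <- sort(-config$minimal_positions)  # e.g. 3 4 5 on the target side
  if (length(pos) != 3L || !all(diff(pos) == 1L)) {
    mc_error("minimal_positions must be 3 contiguous handle positions",
             "minicr_input_error")
  }
  choices <- lapply(pos, function(i) {
    b <- paired_target_bases(handle_base(handle, i), config)
    if (length(b) == 0L) character(0) else b
  })
  if (any(lengths(choices) == 0L)) return(character(0))
  grid <- expand.grid(choices, stringsAsFactors = FALSE)
  sort(unique(apply(grid, 1L, paste, collapse = "")))
}
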