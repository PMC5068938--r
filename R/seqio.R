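DNA_BASES <- c("A", "C", "G", "T")
RNA_BASES <- c("A", "C", "G", "U")
IUPAC_AMBIGUITY <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

# classed error helper so callers (and the CLI) can branch on failure type
mc_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "minicr_error", "error")))
}

mc_warn <- function(msg, class = "minicr_warning") {
  warning(warningCondition(msg, class = c(class, "warning")))
}

#' Guess whether a sequence is DNA or RNA
#'
#' A sequence containing `U` is RNA, one containing `T` is DNA; a sequence
#' with neither (e.g. `ACG`) falls back to `default`.
#'
#' @param seq character scalar, nucleotide sequence.
#' @param default alphabet assumed when the sequence is ambiguous.
#' @return `"DNA"` or `"RNA"`.
#' @export
guess_alphabet <- function(seq, default = "DNA") {
  seq <- toupper(seq)
  has_u <- grepl("U", seq, fixed = TRUE)
  has_t <- grepl("T", seq, fixed = TRUE)
  if (has_u && has_t) {
    mc_error("sequence mixes T and U; not a valid single-alphabet sequence",
             "minicr_alphabet_error")
  }
  if (has_u) return("RNA")
  if (has_t) return("DNA")
  default
}

check_alphabet <- function(seq, alphabet, id = "<unnamed>",
                           allow_ambiguity = FALSE) {
  bases <- if (alphabet == "RNA") RNA_BASES else DNA_BASES
  allowed <- if (allow_ambiguity) c(bases, IUPAC_AMBIGUITY) else bases
  pat <- sprintf("[^%s]", paste(allowed, collapse = ""))
  bad <- regexpr(pat, seq)
  if (bad > 0) {
    mc_error(sprintf(
      "record '%s': invalid %s character '%s' at position %d",
      id, alphabet, substr(seq, bad, bad), bad), "minicr_alphabet_error")
  }
  invisible(TRUE)
}

#' Create a nucleotide sequence record
#'
#' The basic container used throughout the toolkit: an id, an uppercased
#' sequence over a declared alphabet, and a topology. Ambiguity codes are
#' rejected by default; with `allow_ambiguity = TRUE` they are accepted and
#' later treated as never-pairing by the PAS matcher.
#'
#' @param id character label.
#' @param seq nucleotide string (DNA `ACGT` or RNA `ACGU`).
#' @param alphabet `"DNA"`, `"RNA"`, or `NULL` to autodetect.
#' @param topology `"linear"` or `"circular"` (circular is reserved for
#'   plasmid/template records).
#' @param allow_ambiguity accept IUPAC ambiguity codes.
#' @return an object of class `nuc_seq`.
#' @export
nuc_seq <- function(id, seq, alphabet = NULL, topology = "linear",
                    allow_ambiguity = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    mc_error("id must be a non-empty character scalar", "minicr_input_error")
  }
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || !nzchar(seq)) {
    mc_error(sprintf("record '%s': sequence must be non-empty", id),
             "minicr_input_error")
  }
  if (is.null(alphabet)) alphabet <- guess_alphabet(seq)
  alphabet <- match.arg(alphabet, c("DNA", "RNA"))
  topology <- match.arg(topology, c("linear", "circular"))
  check_alphabet(seq, alphabet, id, allow_ambiguity)
  structure(list(id = id, seq = seq, alphabet = alphabet,
                 topology = topology),
            class = "nuc_seq")
}

#' @export
print.nuc_seq <- function(x, ...) {
  n <- nchar(x$seq)
  shown <- if (n > 60) paste0(substr(x$seq, 1, 57), "...") else x$seq
  cat(sprintf("<nuc_seq> %s (%s, %s, %d nt)\n  %s\n",
              x$id, x$alphabet, x$topology, n, shown))
  invisible(x)
}

#' @export
as.character.nuc_seq <- function(x, ...) x$seq

seq_chr <- function(x) if (inherits(x, "nuc_seq")) x$seq else toupper(x)

#' Reverse complement
#'
#' Standard antiparallel complement; the alphabet is preserved (DNA in,
#' DNA out; RNA in, RNA out). Ambiguity codes are rejected unless
#' `allow_ambiguity = TRUE` (they then complement per IUPAC).
#'
#' @param x character sequence or [nuc_seq()].
#' @param allow_ambiguity accept IUPAC ambiguity codes.
#' @return same type as the input.
#' @export
revcomp <- function(x, allow_ambiguity = FALSE) {
  if (inherits(x, "nuc_seq")) {
    x$seq <- revcomp_chr(x$seq, x$alphabet, x$id, allow_ambiguity)
    return(x)
  }
  s <- toupper(x)
  revcomp_chr(s, guess_alphabet(s), "<unnamed>", allow_ambiguity)
}

revcomp_chr <- function(s, alphabet, id = "<unnamed>",
                        allow_ambiguity = FALSE) {
  check_alphabet(s, alphabet, id, allow_ambiguity)
  if (alphabet == "RNA") {
    as.character(Biostrings::reverseComplement(Biostrings::RNAString(s)))
  } else {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
}

#' Transcribe a sense-strand DNA sequence to RNA
#'
#' Replaces T with U; nothing else changes. RNA input is refused (it is
#' already transcribed), which catches accidental double transcription.
#'
#' @param x character DNA sequence or a DNA [nuc_seq()].
#' @return RNA string, or an RNA `nuc_seq` when given a record.
#' @export
transcribe <- function(x) {
  if (inherits(x, "nuc_seq")) {
    if (x$alphabet == "RNA") {
      mc_error(sprintf("record '%s' is already RNA", x$id),
               "minicr_alphabet_error")
    }
    x$seq <- transcribe_chr(x$seq, x$id)
    x$alphabet <- "RNA"
    return(x)
  }
  transcribe_chr(toupper(x))
}

transcribe_chr <- function(s, id = "<unnamed>") {
  if (grepl("U", s, fixed = TRUE)) {
    mc_error(sprintf("record '%s' contains U: already RNA", id),
             "minicr_alphabet_error")
  }
  chartr("T", "U", s)
}

#' Back-transcribe an RNA sequence to its coding-strand DNA
#'
#' @param x character RNA sequence.
#' @return DNA string (U replaced by T).
#' @export
rna_to_dna <- function(x) {
  s <- toupper(seq_chr(x))
  if (grepl("T", s, fixed = TRUE)) {
    mc_error("sequence contains T: already DNA", "minicr_alphabet_error")
  }
  chartr("U", "T", s)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @param alphabet force `"DNA"`/`"RNA"`, or `NULL` to autodetect per record.
#' @param allow_ambiguity accept IUPAC ambiguity codes.
#' @param topology topology assigned to every record.
#' @return list of [nuc_seq()] records, in file order; the header token
#'   before the first whitespace becomes the id and sequences are uppercased.
#' @export
read_fasta <- function(path, alphabet = NULL, allow_ambiguity = FALSE,
                       topology = "linear") {
  if (!file.exists(path)) {
    mc_error(sprintf("file not found: %s", path), "minicr_io_error")
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    mc_error(sprintf("cannot parse FASTA '%s': %s",
                                     path, conditionMessage(e)),
                             "minicr_io_error")
                  })
  if (length(set) == 0L) {
    mc_error(sprintf("empty FASTA file: %s", path), "minicr_empty_error")
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    mc_error(sprintf("duplicate FASTA ids: %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "minicr_duplicate_id_error")
  }
  lapply(seq_along(set), function(i) {
    nuc_seq(ids[[i]], as.character(set[[i]]), alphabet = alphabet,
            topology = topology, allow_ambiguity = allow_ambiguity)
  })
}

#' Write sequences as FASTA
#'
#' @param seqs a [nuc_seq()], a list of them, or a named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "nuc_seq")) seqs <- list(seqs)
  if (is.character(seqs)) {
    stopifnot(!is.null(names(seqs)))
    seqs <- mapply(nuc_seq, names(seqs), seqs, SIMPLIFY = FALSE)
  }
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, "", "seq"))
  names(set) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

validate_annotation <- function(annotation) {
  need <- c("locus_tag", "start", "end", "strand")
  if (!is.data.frame(annotation) || !all(need %in% names(annotation))) {
    mc_error(paste("annotation must be a data.frame with columns",
                   paste(need, collapse = ", ")), "minicr_input_error")
  }
  annotation
}

#' Extract CDS records (sense mRNA) from a genome
#'
#' For each feature the genomic segment is taken, reverse-complemented when
#' the feature is on the minus strand, and transcribed (T to U), yielding the
#' mRNA in sense orientation. Multi-segment CDS (several rows sharing a
#' `locus_tag`) are concatenated in transcription order, with a warning
#' (rare in archaea).
#'
#' @param genome a [nuc_seq()] (DNA).
#' @param annotation data.frame with columns `locus_tag`, `start`, `end`
#'   (1-based inclusive), `strand` (`+`/`-`), e.g. from [read_gff3_cds()].
#' @return list of `cds_record` objects with fields `locus_tag`,
#'   `parent_genome`, `start`, `end`, `strand`, `mrna_seq`.
#' @export
extract_cds <- function(genome, annotation) {
  stopifnot(inherits(genome, "nuc_seq"))
  annotation <- validate_annotation(annotation)
  glen <- nchar(genome$seq)
  tags <- unique(annotation$locus_tag)
  lapply(tags, function(tag) {
    feat <- annotation[annotation$locus_tag == tag, , drop = FALSE]
    for (i in seq_len(nrow(feat))) {
      st <- feat$start[i]; en <- feat$end[i]; sd <- feat$strand[i]
      if (!sd %in% c("+", "-")) {
        mc_error(sprintf("feature '%s': unknown strand symbol '%s'", tag, sd),
                 "minicr_strand_error")
      }
      if (is.na(st) || is.na(en) || st < 1 || en > glen || st > en) {
        mc_error(sprintf(
          "feature '%s': coordinates %s..%s out of range for genome '%s' (%d nt)",
          tag, st, en, genome$id, glen), "minicr_coordinate_error")
      }
    }
    if (nrow(feat) > 1L) {
      mc_warn(sprintf("feature '%s': multi-segment CDS (%d segments) joined",
                      tag, nrow(feat)), "minicr_multisegment_warning")
    }
    feat <- feat[order(feat$start), , drop = FALSE]
    dna <- paste(substring(genome$seq, feat$start, feat$end), collapse = "")
    strand <- feat$strand[1]
    if (strand == "-") dna <- revcomp_chr(dna, "DNA", tag)
    structure(list(locus_tag = tag,
                   parent_genome = genome$id,
                   start = min(feat$start), end = max(feat$end),
                   strand = strand,
                   mrna_seq = transcribe_chr(dna, tag)),
              class = "cds_record")
  })
}

#' @export
print.cds_record <- function(x, ...) {
  cat(sprintf("<cds_record> %s %s:%d-%d(%s) mRNA %d nt\n",
              x$locus_tag, x$parent_genome, x$start, x$end, x$strand,
              nchar(x$mrna_seq)))
  invisible(x)
}

#' Read CDS features from a GFF3 file
#'
#' Thin wrapper over [rtracklayer::import()]; only `CDS` features are kept.
#' The locus tag is taken from the `locus_tag` attribute, falling back to
#' `ID`, then `Parent`.
#'
#' @param path GFF3 file.
#' @return annotation data.frame (`locus_tag`, `seqid`, `start`, `end`,
#'   `strand`) suitable for [extract_cds()].
#' @export
read_gff3_cds <- function(path) {
  if (!file.exists(path)) {
    mc_error(sprintf("file not found: %s", path), "minicr_io_error")
  }
  gr <- rtracklayer::import(path)
  gr <- gr[as.character(gr$type) == "CDS"]
  if (length(gr) == 0L) {
    mc_error(sprintf("no CDS features in %s", path), "minicr_empty_error")
  }
  mc <- GenomicRanges::mcols(gr)
  pick <- function(col) if (col %in% names(mc)) as.character(mc[[col]]) else NULL
  tag <- pick("locus_tag")
  if (is.null(tag) || all(is.na(tag))) tag <- pick("ID")
  if (is.null(tag) || all(is.na(tag))) {
    par <- mc[["Parent"]]
    if (!is.null(par)) tag <- vapply(as.list(par), function(p)
      if (length(p)) as.character(p[[1]]) else NA_character_, "")
  }
  if (is.null(tag)) {
    mc_error("CDS features carry no locus_tag/ID/Parent attribute",
             "minicr_input_error")
  }
  data.frame(locus_tag = tag,
             seqid = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write a CDS annotation table as GFF3
#'
#' @param annotation data.frame (`locus_tag`, `start`, `end`, `strand`).
#' @param seqid sequence id the features live on.
#' @param path output file.
#' @export
write_gff3_cds <- function(annotation, seqid, path) {
  annotation <- validate_annotation(annotation)
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand)
  gr$type <- "CDS"
  gr$source <- "minicrdesign"
  gr$phase <- 0L
  gr$ID <- annotation$locus_tag
  gr$locus_tag <- annotation$locus_tag
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Write intervals as BED6 (0-based half-open)
#'
#' @param df data.frame with `chrom`, `start` (1-based), `end` (1-based
#'   inclusive), `name`, `score`, `strand`.
#' @param path output file.
#' @export
write_bed6 <- function(df, path) {
  out <- data.frame(chrom = df$chrom,
                    start = df$start - 1L,
                    end = df$end,
                    name = df$name,
                    score = df$score,
                    strand = df$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
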