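test_that("read_fasta parses records, preserves order, and trims headers", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x some description", "ACGT", ">y", "ggga", "cc"), fa)
  recs <- read_fasta(fa)
  expect_length(recs, 2L)
  expect_equal(vapply(recs, `[[`, "", "id"), c("x", "y"))
  expect_equal(recs[[1]]$seq, "ACGT")
  expect_equal(recs[[2]]$seq, "GGGACC")
})

test_that("read_fasta raises distinct errors for empty files, duplicate ids and ambiguity codes", {
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), class = "minicr_empty_error")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), dup)
  expect_error(read_fasta(dup), class = "minicr_duplicate_id_error")

  amb <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">z", "ACNT"), amb)
  err <- expect_error(read_fasta(amb), class = "minicr_alphabet_error")
  expect_match(conditionMessage(err), "z")
  expect_match(conditionMessage(err), "position 3")
  # override accepts the record
  expect_silent(read_fasta(amb, allow_ambiguity = TRUE))
})

test_that("revcomp complements antiparallel, preserves alphabet, and is an involution", {
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("AAAA"), "TTTT")
  expect_equal(revcomp("ACCT"), "AGGT")
  expect_equal(revcomp("ACGU"), "ACGU")
  expect_equal(revcomp("AAAU"), "AUUU")
  expect_error(revcomp("ACNT"), class = "minicr_alphabet_error")
  set.seed(11)
  for (i in 1:20) {
    s <- random_dna(sample(5:80, 1))
    expect_equal(revcomp(revcomp(s)), s)
    expect_equal(revcomp(s), oracle_revcomp_dna(s))
  }
})

test_that("transcribe replaces T with U only, and refuses RNA input", {
  expect_equal(transcribe("ACGT"), "ACGU")
  expect_equal(transcribe("TTTT"), "UUUU")
  expect_error(transcribe("ACGU"), class = "minicr_alphabet_error")
  set.seed(12)
  s <- random_dna(200)
  expect_equal(nchar(transcribe(s)), 200L)
  expect_false(grepl("T", transcribe(s), fixed = TRUE))
})

test_that("extract_cds produces sense mRNA on both strands and checks coordinates", {
  g <- nuc_seq("g1", "ACCTGGGT")
  plus <- extract_cds(g, data.frame(locus_tag = "p", start = 1, end = 4,
                                    strand = "+"))[[1]]
  expect_equal(plus$mrna_seq, "ACCU")
  minus <- extract_cds(g, data.frame(locus_tag = "m", start = 1, end = 4,
                                     strand = "-"))[[1]]
  expect_equal(minus$mrna_seq, "AGGU")  # revcomp(ACCT) = AGGT, transcribed
  expect_error(
    extract_cds(g, data.frame(locus_tag = "x", start = 2, end = 9,
                              strand = "+")),
    class = "minicr_coordinate_error")
  expect_error(
    extract_cds(g, data.frame(locus_tag = "x", start = 1, end = 4,
                              strand = "*")),
    class = "minicr_strand_error")
  expect_warning(
    extract_cds(g, data.frame(locus_tag = "j", start = c(1, 6),
                              end = c(3, 8), strand = "+")),
    class = "minicr_multisegment_warning")
})

test_that("GFF3 write/read round trip preserves the CDS annotation", {
  h <- handle_spec("AUUGAAAG")
  fx <- synth_cds_set(4, planted_counts = c(1, 0, 2, 3), seed = 5,
                      handle = h)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3_cds(fx$annotation, fx$genome$id, gff)
  back <- read_gff3_cds(gff)
  expect_equal(back$locus_tag, fx$annotation$locus_tag)
  expect_equal(back$start, fx$annotation$start)
  expect_equal(back$end, fx$annotation$end)
  expect_equal(back$strand, fx$annotation$strand)
  cds <- extract_cds(fx$genome, back)
  expect_equal(vapply(cds, `[[`, "", "mrna_seq"),
               vapply(fx$cds, `[[`, "", "mrna_seq"))
})

test_that("GenBank flat files round-trip CDS features including complement locations", {
  gb <- withr::local_tempfile(fileext = ".gb")
  genome <- "ATGAAACCCGGGTTTTAGCATCATGGCCATTAA"
  writeLines(c(
    sprintf("LOCUS       synth_plasmid %d bp DNA linear 01-JAN-2026",
            nchar(genome)),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(genome)),
    "     CDS             1..18",
    "                     /locus_tag=\"GENE_A\"",
    "     CDS             complement(22..33)",
    "                     /locus_tag=\"GENE_B\"",
    "ORIGIN",
    paste("        1", tolower(genome)),
    "//"), gb)
  parsed <- read_genbank_cds(gb)
  expect_equal(parsed$genome$seq, genome)
  expect_equal(parsed$annotation$locus_tag, c("GENE_A", "GENE_B"))
  cds <- extract_cds(parsed$genome, parsed$annotation)
  expect_equal(cds[[1]]$mrna_seq, transcribe(substr(genome, 1, 18)))
  expect_equal(cds[[2]]$mrna_seq,
               transcribe(oracle_revcomp_dna(substr(genome, 22, 33))))
})

test_that("BED6 output is 0-based half-open", {
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed6(data.frame(chrom = "tx", start = 10L, end = 46L, name = "ps",
                        score = 8L, strand = "+"), bed)
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(as.integer(fields[2:3]), c(9L, 46L))
})
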