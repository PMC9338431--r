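test_that("FASTA round trip preserves ids and sequences, errors on duplicates", {
  recs <- list(seq_record("a", "ACGTACGT"),
               seq_record("b", "TTTTCCCCGGGG"),
               seq_record("c", paste(rep("ACGTN", 40), collapse = "")))
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, path, width = 17)
  back <- read_fasta(path)
  expect_identical(names(back), c("a", "b", "c"))
  expect_identical(vapply(back, `[[`, "", "seq"),
                   vapply(recs, `[[`, "", "seq") |> setNames(c("a", "b", "c")))
  # minimal record
  p2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT"), p2)
  expect_identical(read_fasta(p2)[["a"]]$seq, "ACGT")
  # duplicate ids named in the error
  p3 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "AAAA", ">x", "CCCC"), p3)
  expect_error(read_fasta(p3), "x")
})

test_that("translation follows the selected genetic code", {
  expect_identical(translate_dna("ATA", "vertebrate_mito"), "M")
  expect_identical(translate_dna("ATA", "standard"), "I")
  expect_identical(translate_dna("TGA", "vertebrate_mito"), "W")
  expect_identical(translate_dna("TGA", "standard"), "*")
  expect_identical(translate_dna("AGAAGG", "vertebrate_mito"), "**")
  expect_identical(translate_dna("AGAAGG", "standard"), "RR")
  # frames, N handling, trailing incomplete codon
  expect_identical(translate_dna("AATGGCT", "standard", frame = 1), "MA")
  expect_identical(translate_dna("ATNGGG", "standard"), "XG")
  expect_identical(translate_dna("ATGCC", "standard"), "M")
})

test_that("the two code tables differ at exactly AGA, AGG, ATA, TGA", {
  std <- genetic_code("standard")
  mito <- genetic_code("vertebrate_mito")
  diff <- names(std$table)[std$table != mito$table]
  expect_setequal(diff, c("AGA", "AGG", "ATA", "TGA"))
  expect_setequal(std$stops, c("TAA", "TAG", "TGA"))
  expect_setequal(mito$stops, c("TAA", "TAG", "AGA", "AGG"))
})

test_that("translation is strand sensitive", {
  s <- "ATGGCTAAGGCTTGGCAT"
  expect_false(translate_dna(s, "standard") ==
               translate_dna(reverse_complement(s), "standard"))
})

test_that("reading-frame classification flags premature mitochondrial stops", {
  mito <- simulate_mitogenome(seed = 42)
  g <- mito_gene_seq(mito, "ND3")
  # identity: intact
  r <- classify_reading_frame(g, g, "ND3")
  expect_true(r$gap_free)
  expect_identical(r$mito_internal_stops, 0L)
  expect_true(r$intact_mito_frame)
  # a mid-gene codon replaced by TAA: one premature stop, not intact
  g_taa <- g
  substr(g_taa, 100, 102) <- "TAA"
  r2 <- classify_reading_frame(g_taa, g, "mutant")
  expect_identical(r2$mito_internal_stops, 1L)
  expect_false(r2$intact_mito_frame)
  # internal AGA: stop under the mito code only
  g_aga <- g
  substr(g_aga, 100, 102) <- "AGA"
  r3 <- classify_reading_frame(g_aga, g, "aga")
  expect_gte(r3$mito_internal_stops, 1L)
  expect_false(r3$intact_mito_frame)
  expect_identical(translate_dna("AGA", "standard"), "R")
})

test_that("classification is invariant to non-homologous flanking sequence", {
  mito <- simulate_mitogenome(seed = 7)
  g <- mito_gene_seq(mito, "COX2")
  flank5 <- random_dna(400, seed = 11)
  flank3 <- random_dna(350, seed = 12)
  r_bare <- classify_reading_frame(g, g)
  r_flank <- classify_reading_frame(paste0(flank5, g, flank3), g)
  expect_identical(r_flank$intact_mito_frame, r_bare$intact_mito_frame)
  expect_identical(r_flank$mito_internal_stops, r_bare$mito_internal_stops)
  expect_identical(r_flank$n_codons, r_bare$n_codons)
})

test_that("unrelated sequence is reported as no homology", {
  mito <- simulate_mitogenome(seed = 9)
  g <- mito_gene_seq(mito, "ND4L")
  r <- classify_reading_frame(random_dna(500, seed = 99), g)
  expect_true(r$no_homology)
  expect_false(r$intact_mito_frame)
  expect_false(r$gap_free)
})

test_that("interval writers follow the BED and GFF3 coordinate conventions", {
  df <- data.frame(id = c("n2", "n1"), scaffold = c("s1", "s1"),
                   start = c(5000L, 100L), end = c(5400L, 200L),
                   strand = c("-", "+"))
  bed <- withr::local_tempfile(fileext = ".bed")
  gff <- withr::local_tempfile(fileext = ".gff3")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_intervals(df, bed, "BED")
  write_intervals(df, gff, "GFF3")
  write_intervals(df, tsv, "TSV")
  bl <- readLines(bed)
  expect_identical(strsplit(bl[1], "\t")[[1]][1:3], c("s1", "99", "200"))
  gl <- readLines(gff)
  expect_identical(gl[1], "##gff-version 3")
  f1 <- strsplit(gl[2], "\t")[[1]]
  expect_identical(f1[4], "100"); expect_identical(f1[5], "200")
  tl <- readLines(tsv)
  expect_length(tl, 3L)  # header + 2 rows
  expect_match(tl[1], "^numt_id\tscaffold\tstart\tend\tchromosome")
  expect_error(write_intervals(df, tsv, "VCF"), "BED, GFF3, TSV")
})

test_that("BED and GFF3 coordinates round-trip through an independent reader", {
  skip_if_not_installed("rtracklayer")
  df <- data.frame(id = paste0("n", 1:3), scaffold = "s1",
                   start = c(1L, 250L, 10000L), end = c(100L, 300L, 10100L),
                   strand = "+")
  bed <- withr::local_tempfile(fileext = ".bed")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_intervals(df, bed, "BED")
  write_intervals(df, gff, "GFF3")
  gb <- rtracklayer::import(bed)
  gg <- rtracklayer::import(gff)
  expect_identical(GenomicRanges::start(gb), df$start)
  expect_identical(GenomicRanges::end(gb), df$end)
  expect_identical(GenomicRanges::start(gg), df$start)
  expect_identical(GenomicRanges::end(gg), df$end)
})
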