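mito <- simulate_mitogenome(seed = 101)

test_that("an exact planted copy is recovered at full length and identity", {
  ins <- substr(mito$record$seq, 1000, 1499)  # 500 bp
  nuc <- plant_copy(50000, ins, at = 20000, seed = 5)
  hits <- scan_numts(mito$record, c(chr1 = nuc))
  expect_gte(nrow(hits), 1L)
  top <- hits[1, ]
  expect_identical(top$nuclear_scaffold, "chr1")
  expect_gte(top$percent_identity, 99.5)
  # the aligner may extend a few coincidentally matching flank bases
  expect_gte(top$aligned_length, 500L); expect_lte(top$aligned_length, 516L)
  expect_lte(abs(top$nuclear_start - 20000L), 8L)
  expect_lte(abs(top$nuclear_end - 20499L), 8L)
  expect_lte(abs(top$mito_start - 1000L), 8L)
  expect_lte(abs(top$mito_end - 1499L), 8L)
})

test_that("a 5% diverged copy is found with identity in the expected band", {
  ins <- mutate_fraction(substr(mito$record$seq, 3000, 4999), 0.05, seed = 8)
  nuc <- plant_copy(50000, ins, at = 10000, seed = 6)
  hits <- scan_numts(mito$record, c(chr1 = nuc))
  expect_gte(nrow(hits), 1L)
  expect_gte(hits$percent_identity[1], 93)
  expect_lte(hits$percent_identity[1], 97)
})

test_that("a reverse-complemented copy reports minus strand and correct mito interval", {
  ins <- reverse_complement(substr(mito$record$seq, 5000, 5799))
  nuc <- plant_copy(40000, ins, at = 15000, seed = 7)
  hits <- scan_numts(mito$record, c(chr1 = nuc))
  expect_identical(hits$strand[1], "-")
  expect_equal(hits$mito_start[1], 5000L)
  expect_equal(hits$mito_end[1], 5799L)
})

test_that("origin-spanning hits on a circular mitogenome are split at position 1", {
  L <- nchar(mito$record$seq)
  ins <- paste0(substr(mito$record$seq, L - 199, L),
                substr(mito$record$seq, 1, 300))
  nuc <- plant_copy(40000, ins, at = 12000, seed = 9)
  hits <- scan_numts(mito$record, c(chr1 = nuc))
  expect_gte(nrow(hits), 2L)
  expect_true(any(hits$mito_end == L))
  expect_true(any(hits$mito_start == 1L))
  expect_true(all(hits$mito_end <= L))
})

test_that("length filtering is strict at the threshold", {
  h <- empty <- scan_numts(mito$record, list())
  h <- rbind(empty, data.frame(
    nuclear_scaffold = "s", nuclear_start = 1L, nuclear_end = 10L,
    strand = "+", mito_start = 1L, mito_end = 10L, percent_identity = 100,
    aligned_length = c(150L, 200L, 201L, 569L), bit_score = 1, e_value = 0))
  kept <- filter_hits(h, 200L)
  expect_identical(sort(kept$aligned_length), c(201L, 569L))
  expect_identical(nrow(filter_hits(empty)), 0L)
  all10k <- h; all10k$aligned_length <- 10000L
  expect_identical(nrow(filter_hits(all10k)), 4L)
})

test_that("fragment clustering honours the 10 kb gap rule and is order independent", {
  mk <- function(starts, ends, sc = "s1") data.frame(
    nuclear_scaffold = sc, nuclear_start = starts, nuclear_end = ends,
    strand = "+", mito_start = 100L, mito_end = 100L + (ends - starts),
    percent_identity = 99, aligned_length = ends - starts + 1L,
    bit_score = 50, e_value = 0)
  near <- mk(c(1000L, 12000L), c(2000L, 13000L))   # gap 9,999
  far <- mk(c(1000L, 12002L), c(2000L, 13000L))    # gap 10,001
  expect_length(cluster_fragments(near), 1L)
  expect_identical(cluster_fragments(near)[[1]]$n_fragments, 2L)
  expect_length(cluster_fragments(far), 2L)
  # four fragments within gaps: one numt with 4 fragments
  four <- mk(c(1000L, 4000L, 15000L, 26000L), c(2000L, 6000L, 16000L, 27000L))
  cl <- cluster_fragments(four)
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$n_fragments, 4L)
  expect_identical(cl[[1]]$total_length, sum(four$nuclear_end - four$nuclear_start + 1L))
  # permuting input rows yields the identical clustering
  perm <- four[c(3, 1, 4, 2), ]
  expect_identical(as.data.frame(cluster_fragments(perm)),
                   as.data.frame(cluster_fragments(four)))
})

test_that("scan agrees with a Smith-Waterman oracle on small fixtures", {
  ins <- mutate_fraction(substr(mito$record$seq, 7000, 7399), 0.05, seed = 3)
  nuc <- plant_copy(2000, ins, at = 800, seed = 44)
  # oracle: optimal local alignment of the mitogenome region vs the fixture
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(mito$record$seq), Biostrings::DNAString(nuc),
    type = "local")
  o_len <- Biostrings::nchar(pa)
  o_pid <- Biostrings::pid(pa)
  expect_gte(o_pid, 90); expect_gt(o_len, 200)  # oracle finds the planted copy
  hits <- scan_numts(mito$record, c(fix = nuc))
  expect_gte(nrow(hits), 1L)
  expect_lt(abs(hits$nuclear_start[1] - Biostrings::start(Biostrings::subject(pa))), 15)
  expect_lt(abs(hits$aligned_length[1] - o_len), 25)
})

test_that("a self-scan of the mitogenome returns the full-length self-hit first", {
  hits <- scan_numts(mito$record,
                     list(self = seq_record("self", mito$record$seq)))
  expect_gte(hits$aligned_length[1], nchar(mito$record$seq))
  expect_equal(hits$percent_identity[1], 100)
})

test_that("conservation profiles report query cover and top-hit identity", {
  numt <- substr(mito$record$seq, 2000, 3999)
  # exact full copy
  pr <- profile_conservation(seq_record("q", numt),
                             c(g1 = plant_copy(30000, numt, 9000, seed = 21)))
  expect_equal(pr$query_cover, 100)
  expect_equal(pr$top_hit_identity, 100)
  # half the numt present
  half <- substr(numt, 1, 1000)
  pr2 <- profile_conservation(seq_record("q", numt),
                              c(g1 = plant_copy(30000, half, 9000, seed = 22)))
  expect_gt(pr2$query_cover, 40); expect_lt(pr2$query_cover, 60)
  # unrelated genome
  pr3 <- profile_conservation(seq_record("q", numt),
                              c(g1 = random_dna(30000, seed = 23)))
  expect_equal(pr3$query_cover, 0)
  expect_equal(pr3$top_hit_identity, 0)
})

test_that("word_size below the minimum and empty genomes are handled", {
  expect_error(scan_numts(mito$record, c(a = "ACGT"), word_size = 3), "word_size")
  expect_identical(nrow(scan_numts(mito$record, list())), 0L)
})
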