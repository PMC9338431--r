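test_that("simulated mitogenomes have 13 stop-free ORFs and are reproducible", {
  m1 <- simulate_mitogenome(seed = 5)
  m2 <- simulate_mitogenome(seed = 5)
  m3 <- simulate_mitogenome(seed = 6)
  expect_identical(m1$record$seq, m2$record$seq)
  expect_false(identical(m1$record$seq, m3$record$seq))
  expect_identical(nrow(m1$genes), 13L)
  expect_identical(nchar(m1$record$seq), 16500L)
  expect_true(m1$record$circular)
  for (g in m1$genes$gene) {
    prot <- translate_dna(mito_gene_seq(m1, g), "vertebrate_mito")
    body <- substr(prot, 1, nchar(prot) - 1)
    expect_false(grepl("*", body, fixed = TRUE))
    expect_identical(substr(prot, nchar(prot), nchar(prot)), "*")
  }
  expect_error(simulate_mitogenome(list(total_length = 12000L), seed = 1),
               "exceed")
})

test_that("a canonical age-0 insertion plants an exact mitochondrial copy", {
  m <- simulate_mitogenome(seed = 11)
  ev <- insertion_event("scaffold_1", 5000, 2000, 2999)
  ls <- simulate_numt_landscape(m, list(ev),
                               nuclear_config = list(n_scaffolds = 1L,
                                                     scaffold_length = 20000L),
                               seed = 11)
  tr <- ls$truth
  expect_identical(nrow(tr), 1L)
  planted <- substr(ls$nuclear[[tr$scaffold]]$seq, tr$start, tr$end)
  expect_identical(planted, substr(m$record$seq, 2000, 2999))
})

test_that("hybrid donors diverge as requested while keeping ORFs intact", {
  m <- simulate_mitogenome(seed = 21)
  # fragment covering ND1..ND3 (genes fully inside 2500..9300)
  ev <- insertion_event("scaffold_1", 8000, 2500, 9300, source = "hybrid",
                        donor_divergence = 0.05, age = 0)
  ls <- simulate_numt_landscape(m, list(ev),
                               nuclear_config = list(n_scaffolds = 1L,
                                                     scaffold_length = 30000L),
                               seed = 21)
  tr <- ls$truth
  planted <- substr(ls$nuclear[[tr$scaffold]]$seq, tr$start, tr$end)
  ref <- substr(m$record$seq, 2500, 9300)
  p <- mean(strsplit(planted, "")[[1]] != strsplit(ref, "")[[1]])
  # realized divergence within a generous binomial band around 0.05
  n <- nchar(ref)
  expect_gt(p, 0.05 - 4 * sqrt(0.05 * 0.95 / n))
  expect_lt(p, 0.05 + 4 * sqrt(0.05 * 0.95 / n))
  # ORFs of fully-contained genes remain intact under the mito code
  inside <- m$genes[m$genes$start >= 2500 & m$genes$end <= 9300, ]
  expect_gte(nrow(inside), 3L)
  for (k in seq_len(nrow(inside))) {
    gs <- inside$start[k] - 2500 + 1
    gcopy <- substr(planted, gs, gs + (inside$end[k] - inside$start[k]))
    prot <- translate_dna(gcopy, "vertebrate_mito")
    expect_false(grepl("*", substr(prot, 1, nchar(prot) - 1), fixed = TRUE))
  }
})

test_that("old insertions with indels lose their reading frames", {
  broken <- 0L; total <- 0L
  for (s in 1:10) {
    m <- simulate_mitogenome(seed = 500 + s)
    ev <- insertion_event("scaffold_1", 2000, 1, 16500, age = 0.3)
    ls <- simulate_numt_landscape(m, list(ev),
                                 nuclear_config = list(n_scaffolds = 1L,
                                                       scaffold_length = 25000L),
                                 seed = 500 + s, indels = TRUE)
    tr <- ls$truth
    planted <- substr(ls$nuclear[[tr$scaffold]]$seq, tr$start, tr$end)
    for (g in m$genes$gene) {
      rep <- classify_reading_frame(planted, mito_gene_seq(m, g))
      total <- total + 1L
      if (!rep$intact_mito_frame) broken <- broken + 1L
    }
  }
  expect_gte(broken / total, 0.9)
})

test_that("insertions overlapping on a scaffold are rejected", {
  m <- simulate_mitogenome(seed = 31)
  evs <- list(insertion_event("scaffold_1", 5000, 1000, 1999),
              insertion_event("scaffold_1", 5000, 3000, 3999))
  expect_error(simulate_numt_landscape(m, evs,
    nuclear_config = list(n_scaffolds = 1L, scaffold_length = 20000L),
    seed = 1), "overlap")
  expect_error(insertion_event("s", 1, 10, 20, source = "canonical",
                               donor_divergence = 0.1), "canonical")
  expect_error(insertion_event("s", 1, 10, 20, age = -1), "rates")
})

test_that("codon alignments simulated with omega 0 show no amino-acid change", {
  tr <- ape::read.tree(text = "((a:0.4,b:0.4):0.2,c:0.6,d:0.6);")
  cl <- data.frame(proportion = 1, omega_background = 0, omega_numt = 0)
  seqs <- simulate_codon_alignment(tr, cl, kappa = 2, n_codons = 150, seed = 8,
                                   codon_freqs = NULL)
  prots <- vapply(seqs, translate_dna, "", code = "vertebrate_mito")
  expect_length(unique(unname(prots)), 1L)
})

test_that("long-branch neutral simulation approaches the stationary distribution", {
  tr <- ape::read.tree(text = "(a:30,b:30);")
  cl <- data.frame(proportion = 1, omega_background = 1, omega_numt = 1)
  seqs <- simulate_codon_alignment(tr, cl, kappa = 1, n_codons = 2000, seed = 15,
                                   codon_freqs = NULL)
  g <- numtforge:::get_codon_graph(genetic_code("vertebrate_mito"))
  obs <- table(factor(numtforge:::split_codons(seqs[["a"]]), g$codons))
  gof <- stats::chisq.test(as.vector(obs), p = rep(1 / g$n, g$n))
  expect_gt(gof$p.value, 0.001)
})

test_that("recovered omega precision improves with alignment length", {
  # NG86 omega on a two-taxon pair as a cheap consistent estimator
  tr <- ape::read.tree(text = "(a:0.3,b:0.3);")
  cl <- data.frame(proportion = 1, omega_background = 0.5, omega_numt = 0.5)
  est <- function(n_codons, seed) {
    seqs <- simulate_codon_alignment(tr, cl, kappa = 2, n_codons = n_codons,
                                     seed = seed, codon_freqs = NULL)
    s <- pairwise_dnds(codon_alignment(seqs[["a"]], seqs[["b"]],
                                       "vertebrate_mito"))
    s$omega
  }
  small <- vapply(1:40, function(r) est(150L, 9000 + r), 0)
  large <- vapply(1:40, function(r) est(600L, 9500 + r), 0)
  ratio <- stats::sd(small) / stats::sd(large)
  # quadrupling the length should halve the standard error (ratio ~ 2)
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.6)
})

test_that("generators are pure functions of (config, seed)", {
  l1 <- default_numt_landscape(seed = 4)
  l2 <- default_numt_landscape(seed = 4)
  expect_identical(l1$truth, l2$truth)
  expect_identical(vapply(l1$nuclear, `[[`, "", "seq"),
                   vapply(l2$nuclear, `[[`, "", "seq"))
  tr <- ape::read.tree(text = "(a:0.2,b:0.2);")
  cl <- data.frame(proportion = 1, omega_background = 0.4, omega_numt = 0.4)
  s1 <- simulate_codon_alignment(tr, cl, n_codons = 50, seed = 2)
  s2 <- simulate_codon_alignment(tr, cl, n_codons = 50, seed = 2)
  expect_identical(unname(s1), unname(s2))
})
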