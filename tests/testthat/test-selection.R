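mito_code <- genetic_code("vertebrate_mito")

test_that("the codon rate matrix has the GY94 structure and unit scaling", {
  g <- length(numtforge:::sense_codons(mito_code))
  pi_eq <- rep(1 / g, g)
  # omega = 0 removes all nonsynonymous flux
  Q0 <- codon_rate_matrix(2, 0, NULL, mito_code)
  std <- mito_code$table
  for (k in 1:50) {
    set.seed(k)
    idx <- sample(g, 2)
    i <- rownames(Q0)[idx[1]]; j <- rownames(Q0)[idx[2]]
    if (std[i] != std[j]) expect_equal(Q0[i, j], 0)
  }
  # rows sum to zero; expected rate is one
  Q <- codon_rate_matrix(3, 0.4, NULL, mito_code)
  expect_lt(max(abs(rowSums(Q))), 1e-10)
  expect_equal(-sum(pi_eq * diag(Q)), 1, tolerance = 1e-10)
  # detailed balance with non-uniform frequencies
  set.seed(2)
  pif <- stats::runif(g); pif <- pif / sum(pif)
  Qr <- codon_rate_matrix(2.5, 0.7, pif, mito_code)
  pif2 <- pmax(pif, 1e-8); pif2 <- pif2 / sum(pif2)
  expect_lt(max(abs(pif2 * Qr - t(pif2 * Qr))), 1e-12)
  # kappa = 1, omega = 1, equal freqs: all single-nt neighbour rates equal
  Q1 <- codon_rate_matrix(1, 1, NULL, mito_code)
  off <- Q1[Q1 > 0]
  expect_lt(diff(range(off)), 1e-12)
  expect_error(codon_rate_matrix(-1, 0.5), "kappa")
})

test_that("pruning equals the closed-form two-sequence likelihood", {
  skip_if_not_installed("Matrix")
  tr <- ape::read.tree(text = "(a:0.25,b:0.35);")
  cl <- data.frame(proportion = 1, omega_background = 0.3, omega_numt = 0.3)
  seqs <- simulate_codon_alignment(tr, cl, kappa = 2, n_codons = 40, seed = 7,
                                   codon_freqs = NULL)
  ll <- codon_log_likelihood(tr, seqs, cl, kappa = 2, codon_freqs = NULL)
  g <- numtforge:::get_codon_graph(mito_code)
  Q <- codon_rate_matrix(2, 0.3, NULL, mito_code)
  P <- as.matrix(Matrix::expm(Q * 0.6))  # both branches traversed
  ia <- match(numtforge:::split_codons(seqs[["a"]]), g$codons)
  ib <- match(numtforge:::split_codons(seqs[["b"]]), g$codons)
  oracle <- sum(log(P[cbind(ia, ib)] / g$n))
  expect_equal(ll, oracle, tolerance = 1e-8)
})

test_that("pruning equals brute-force state summation on a 4-leaf tree", {
  skip_if_not_installed("Matrix")
  tr <- ape::read.tree(text = "((a:0.2,b:0.3):0.15,c:0.25,d:0.4);")
  cl <- data.frame(proportion = 1, omega_background = 0.5, omega_numt = 0.5)
  seqs <- simulate_codon_alignment(tr, cl, kappa = 2, n_codons = 10, seed = 21,
                                   codon_freqs = NULL)
  ll <- codon_log_likelihood(tr, seqs, cl, kappa = 2, codon_freqs = NULL)
  oracle <- oracle_loglik_4leaf(tr, as.list(seqs), omega = 0.5, kappa = 2)
  expect_equal(ll, oracle, tolerance = 1e-8)
})

test_that("site independence: duplicating every column doubles the log-likelihood", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.1,c:0.3,d:0.2);")
  cl <- data.frame(proportion = 1, omega_background = 0.4, omega_numt = 0.4)
  seqs <- simulate_codon_alignment(tr, cl, kappa = 2, n_codons = 30, seed = 3,
                                   codon_freqs = NULL)
  ll1 <- codon_log_likelihood(tr, seqs, cl, kappa = 2, codon_freqs = NULL)
  doubled <- vapply(seqs, function(s) paste0(s, s), "")
  ll2 <- codon_log_likelihood(tr, doubled, cl, kappa = 2, codon_freqs = NULL)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-9)
})

test_that("likelihood is invariant to rerooting (reversibility)", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.15,(c:0.3,d:0.1):0.05,e:0.25);")
  cl <- data.frame(proportion = 1, omega_background = 0.3, omega_numt = 0.3)
  seqs <- simulate_codon_alignment(tr, cl, kappa = 2, n_codons = 40, seed = 9,
                                   codon_freqs = NULL)
  ll0 <- codon_log_likelihood(tr, seqs, cl, kappa = 2, codon_freqs = NULL)
  for (og in c("a", "c", "e")) {
    rr <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    llr <- codon_log_likelihood(rr, seqs, cl, kappa = 2, codon_freqs = NULL)
    expect_equal(llr, ll0, tolerance = 1e-8)
  }
})

two_ratio_tree <- function() {
  tr <- ape::read.tree(text = "((n1:0.1,n2:0.1):0.15,m1:0.4,m2:0.4);")
  label_numt_clade(tr, c("n1", "n2"))
}

test_that("two-ratio fits recover a shared omega and nest the one-ratio model", {
  tr <- two_ratio_tree()
  cl <- data.frame(proportion = 1, omega_background = 0.2, omega_numt = 0.2)
  seqs <- simulate_codon_alignment(tr, cl, kappa = 2, n_codons = 500, seed = 33,
                                   codon_freqs = NULL)
  f2 <- fit_codon_model(tr, seqs, "two_ratio", n_restarts = 1, seed = 1)
  expect_lt(abs(f2$omegas[["omega_background"]] - 0.2), 0.05)
  expect_lt(abs(f2$omegas[["omega_numt"]] - 0.2), 0.05)
  f1 <- fit_codon_model(tr, seqs, "one_ratio", n_restarts = 1, seed = 1)
  # nesting: the richer model can only improve the likelihood
  expect_gte(f2$logL, f1$logL - 1e-6)
  # constraining the two omegas to the one-ratio MLE reproduces its logL
  tr_hat <- f1$tree
  cl_eq <- data.frame(proportion = 1, omega_background = f1$omegas[["omega"]],
                      omega_numt = f1$omegas[["omega"]])
  ll_eq <- codon_log_likelihood(tr_hat, seqs, cl_eq, kappa = f1$kappa,
                                codon_freqs = f1$codon_freqs)
  expect_equal(ll_eq, f1$logL, tolerance = 1e-6)
  # default df from the model specs
  lr <- lrt_codon(f1, f2)
  expect_identical(lr$df, 1L)
  expect_gte(lr$statistic, 0)
})

test_that("likelihood-ratio tests reproduce known chi-square outcomes", {
  # near-identical likelihoods: p rounds to 0.99
  r1 <- lrt_codon(-1811.746326, -1811.746294, df = 1)
  expect_equal(round(r1$p_value, 2), 0.99)
  # moderate difference: p rounds to 0.15
  r2 <- lrt_codon(-1803.236605, -1802.187057, df = 1)
  expect_equal(round(r2$p_value, 2), 0.15)
  # identical values: statistic 0, p = 1
  r3 <- lrt_codon(-100, -100, df = 1)
  expect_equal(r3$statistic, 0); expect_equal(r3$p_value, 1)
  # nesting violation is an error
  expect_error(lrt_codon(-100, -110, df = 1), "nesting")
  expect_error(lrt_codon(-100, -99, df = 0), "df")
})

test_that("clade model C recovers the omega ordering numt > 1 > background", {
  tr <- two_ratio_tree()
  cl_true <- data.frame(proportion = c(0.55, 0.05, 0.40),
                        omega_background = c(0.05, 1, 0.03),
                        omega_numt = c(0.05, 1, 2.8))
  ok <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    seqs <- simulate_codon_alignment(tr, cl_true, kappa = 2, n_codons = 300,
                                     seed = 4000 + r, codon_freqs = NULL)
    f <- fit_codon_model(tr, seqs, "cladeC", n_restarts = 1, seed = r)
    w_bg <- f$classes$omega_background[3]
    w_nu <- f$classes$omega_numt[3]
    if (w_nu > 1 && w_bg < 1) ok <- ok + 1L
  }
  expect_gte(ok, ceiling(0.9 * n_rep))
})
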