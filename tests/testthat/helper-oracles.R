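# Shared fixtures and independent oracles used across the suite.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

# plant `insert` into a random host sequence at `at`; returns host string
plant_copy <- function(host_len, insert, at, seed) {
  host <- random_dna(host_len, seed)
  paste0(substr(host, 1, at - 1), insert, substr(host, at, host_len))
}

mutate_fraction <- function(seq, fraction, seed) {
  set.seed(seed)
  s <- strsplit(seq, "")[[1]]
  n <- max(1L, round(fraction * length(s)))
  pos <- sample.int(length(s), n)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}

# independent NG86 site-count oracle: direct enumeration using the
# Biostrings code tables, no shared code with count_sites()
oracle_sites <- function(codon, code_id) {
  tab <- Biostrings::getGeneticCode(code_id)
  aa <- tab[[codon]]
  bases <- c("A", "C", "G", "T")
  syn <- 0
  for (pos in 1:3) {
    muts <- vapply(setdiff(bases, substr(codon, pos, pos)), function(b) {
      m <- codon; substr(m, pos, pos) <- b; m
    }, "")
    aas <- tab[muts]
    valid <- aas != "*"
    if (sum(valid) > 0) syn <- syn + sum(aas[valid] == aa) / sum(valid)
  }
  c(syn = syn, nonsyn = 3 - syn)
}

# brute-force codon-tree likelihood for a 4-leaf unrooted tree by explicit
# summation over all internal-state pairs, with transition matrices from
# Matrix::expm (independent of the package's eigendecomposition propagator)
oracle_loglik_4leaf <- function(tree, seqs, omega, kappa, code_name = "vertebrate_mito") {
  code <- genetic_code(code_name)
  Q <- codon_rate_matrix(kappa, omega, NULL, code)
  cods <- colnames(Q)
  n <- length(cods)
  pi <- rep(1 / n, n)
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  root <- tr$edge[nrow(tr$edge), 1]
  internal <- setdiff(unique(as.vector(tr$edge)), seq_len(n_tip))
  stopifnot(length(internal) == 2L)
  other <- setdiff(internal, root)
  P <- lapply(seq_len(nrow(tr$edge)), function(e)
    as.matrix(Matrix::expm(Q * tr$edge.length[e])))
  states <- lapply(tr$tip.label, function(tx) {
    m <- match(substring(seqs[[tx]], seq(1, nchar(seqs[[tx]]), 3),
                         seq(3, nchar(seqs[[tx]]), 3)), cods)
    m
  })
  names(states) <- tr$tip.label
  nsites <- length(states[[1]])
  ll <- 0
  for (site in seq_len(nsites)) {
    tot <- 0
    for (s1 in seq_len(n)) for (s2 in seq_len(n)) {
      assign_state <- function(v) {
        if (v == root) s1 else if (v == other) s2
        else states[[tr$tip.label[v]]][site]
      }
      pr <- pi[s1]
      for (e in seq_len(nrow(tr$edge))) {
        pr <- pr * P[[e]][assign_state(tr$edge[e, 1]), assign_state(tr$edge[e, 2])]
      }
      tot <- tot + pr
    }
    ll <- ll + log(tot)
  }
  ll
}

# random additive (tree-metric) distance matrix from a random topology
random_additive <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  list(tree = tr, D = stats::cophenetic(tr))
}

# small two-fragment landscape used for the clustering boundary checks
two_fragment_genome <- function(mito, spacer, seed) {
  frag1 <- substr(mito$record$seq, 3000, 3999)
  frag2 <- substr(mito$record$seq, 8000, 8999)
  host <- random_dna(30000 + spacer, seed)
  at1 <- 5000
  paste0(substr(host, 1, at1 - 1), frag1,
         substr(host, at1, at1 + spacer - 1), frag2,
         substr(host, at1 + spacer, nchar(host)))
}
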