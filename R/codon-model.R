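# Goldman-Yang style codon substitution machinery: 60/61-state Markov chain
# over the sense codons of a genetic code, with transition/transversion ratio
# kappa, nonsynonymous/synonymous ratio omega, and codon frequencies pi.

sense_codons <- function(code) {
  code <- as_genetic_code(code)
  sort(names(code$table)[code$table != "*"])
}

# single-nucleotide neighbour structure of the sense-codon space
codon_graph <- function(code) {
  code <- as_genetic_code(code)
  cods <- sense_codons(code)
  n <- length(cods)
  mat <- do.call(rbind, strsplit(cods, ""))
  ii <- integer(); jj <- integer(); ts <- logical(); syn <- logical()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    diff <- which(mat[i, ] != mat[j, ])
    if (length(diff) != 1L) next
    pair <- sort(c(mat[i, diff], mat[j, diff]))
    is_ts <- identical(pair, c("A", "G")) || identical(pair, c("C", "T"))
    is_syn <- code$table[cods[i]] == code$table[cods[j]]
    ii <- c(ii, i); jj <- c(jj, j); ts <- c(ts, is_ts); syn <- c(syn, is_syn)
  }
  list(codons = cods, n = n, i = ii, j = jj, transition = ts, synonymous = syn)
}

.graph_cache <- new.env(parent = emptyenv())
get_codon_graph <- function(code) {
  code <- as_genetic_code(code)
  key <- code$name
  if (is.null(.graph_cache[[key]])) .graph_cache[[key]] <- codon_graph(code)
  .graph_cache[[key]]
}

#' Codon substitution rate matrix
#'
#' Builds the generator of a GY94-family codon model: entries are zero for
#' multi-nucleotide changes and proportional to the target codon frequency
#' times kappa for transitions and omega for nonsynonymous changes. Rows sum
#' to zero and the matrix is scaled so the expected rate at stationarity is
#' one substitution per codon per unit branch length. The chain is
#' time-reversible by construction.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param codon_freqs Numeric vector of sense-codon frequencies (named or in
#'   the order of `sense_codons(code)`), or `NULL` for equal frequencies.
#' @param code Genetic code (default vertebrate mitochondrial).
#' @return The scaled generator matrix with codon dimnames.
#' @export
codon_rate_matrix <- function(kappa, omega, codon_freqs = NULL,
                              code = genetic_code("vertebrate_mito")) {
  if (kappa <= 0) stop("kappa must be > 0")
  if (omega < 0) stop("omega must be >= 0")
  g <- get_codon_graph(code)
  pi <- normalise_freqs(codon_freqs, g)
  Q <- matrix(0, g$n, g$n, dimnames = list(g$codons, g$codons))
  rate <- ifelse(g$transition, kappa, 1) * ifelse(g$synonymous, 1, omega)
  Q[cbind(g$i, g$j)] <- pi[g$j] * rate
  Q[cbind(g$j, g$i)] <- pi[g$i] * rate
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix (zero total rate)")
  Q / mu
}

normalise_freqs <- function(codon_freqs, g) {
  if (is.null(codon_freqs)) return(rep(1 / g$n, g$n))
  if (!is.null(names(codon_freqs))) {
    if (!all(g$codons %in% names(codon_freqs)))
      stop("codon_freqs must cover all sense codons (stop codons have no state)")
    codon_freqs <- codon_freqs[g$codons]
  }
  if (length(codon_freqs) != g$n) stop("codon_freqs must have length ", g$n)
  pi <- pmax(as.numeric(codon_freqs), 1e-8)
  pi / sum(pi)
}

# eigen-decomposition of a reversible generator; returns closure t -> P(t)
propagator <- function(Q, pi) {
  sq <- sqrt(pi)
  B <- Q * outer(sq, 1 / sq)
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  U <- eg$vectors * (1 / sq)    # diag(1/sq) %*% V
  V <- t(eg$vectors * sq)       # t(V) %*% diag(sq)
  lam <- eg$values
  function(t) {
    P <- U %*% (exp(lam * t) * V)
    P[P < 0] <- 0
    P
  }
}

#' Empirical codon frequencies of an alignment
#'
#' @param seqs In-frame aligned sequences (named character vector or list of
#'   [seq_record()]s).
#' @param scheme `"F3x4"` (position-specific nucleotide frequencies),
#'   `"F1x4"` (pooled nucleotide frequencies) or `"equal"`.
#' @param code Genetic code.
#' @return Named frequency vector over the sense codons, summing to 1.
#' @export
codon_frequencies <- function(seqs, scheme = c("F3x4", "F1x4", "equal"),
                              code = genetic_code("vertebrate_mito")) {
  scheme <- match.arg(scheme)
  g <- get_codon_graph(code)
  if (scheme == "equal")
    return(stats::setNames(rep(1 / g$n, g$n), g$codons))
  recs <- as_seq_records(seqs)
  chars <- lapply(recs, function(r) strsplit(r$seq, "")[[1]])
  len <- unique(vapply(chars, length, 0L))
  if (length(len) != 1L || len %% 3L != 0L) stop("sequences must be aligned and in frame")
  bases <- c("A", "C", "G", "T")
  pos_of <- rep(1:3, length.out = len)
  counts <- matrix(1, 3, 4, dimnames = list(NULL, bases))  # +1 pseudocount
  for (ch in chars) {
    keep <- ch %in% bases
    tb <- table(factor(pos_of[keep], 1:3), factor(ch[keep], bases))
    counts <- counts + as.matrix(tb)
  }
  fr <- counts / rowSums(counts)
  if (scheme == "F1x4") {
    pooled <- colSums(counts) / sum(counts)
    fr <- matrix(pooled, 3, 4, byrow = TRUE, dimnames = list(NULL, bases))
  }
  cm <- do.call(rbind, strsplit(g$codons, ""))
  pi <- fr[1, cm[, 1]] * fr[2, cm[, 2]] * fr[3, cm[, 3]]
  pi <- pi / sum(pi)
  stats::setNames(pi, g$codons)
}

# convert aligned sequences to a codon-state matrix (taxa x sites), NA for
# untranslatable codons (treated as missing data in the likelihood)
codon_state_matrix <- function(seqs, code) {
  g <- get_codon_graph(code)
  recs <- as_seq_records(seqs)
  mats <- lapply(recs, function(r) {
    cods <- split_codons(r$seq)
    match(cods, g$codons)
  })
  len <- unique(vapply(mats, length, 0L))
  if (length(len) != 1L) stop("sequences must have equal length")
  out <- do.call(rbind, mats)
  rownames(out) <- names(recs)
  out
}

# site-pattern compression: unique columns + multiplicities
compress_patterns <- function(states) {
  key <- apply(states, 2, paste, collapse = ",")
  first <- !duplicated(key)
  pat <- states[, first, drop = FALSE]
  w <- as.vector(table(factor(key, levels = key[first])))
  list(patterns = pat, weights = w)
}

# postorder traversal info for an ape tree; branch.class is realigned to the
# postorder edge permutation (reorder.phylo does not permute custom fields)
tree_info <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  bc <- if (is.null(tree$branch.class)) rep("background", nrow(tr$edge)) else {
    perm <- match(paste(tr$edge[, 1], tr$edge[, 2]),
                  paste(tree$edge[, 1], tree$edge[, 2]))
    tree$branch.class[perm]
  }
  list(edge = tr$edge, edge.length = tr$edge.length, branch.class = bc,
       n_tip = length(tr$tip.label), tip.label = tr$tip.label,
       root = tr$edge[nrow(tr$edge), 1])
}

# core pruning likelihood for one site class: returns per-pattern log-lik
prune_class <- function(info, tipstates, Pmats, pi) {
  n <- length(pi)
  npat <- ncol(tipstates)
  nnode <- info$n_tip + max(info$edge[, 1]) - info$n_tip
  partial <- vector("list", max(info$edge))
  logscale <- numeric(npat)
  get_tip <- function(k) {
    L <- matrix(0, n, npat)
    st <- tipstates[k, ]
    miss <- is.na(st)
    if (any(!miss)) L[cbind(st[!miss], which(!miss))] <- 1
    if (any(miss)) L[, miss] <- 1
    L
  }
  for (e in seq_len(nrow(info$edge))) {
    parent <- info$edge[e, 1]; child <- info$edge[e, 2]
    Lc <- if (child <= info$n_tip) get_tip(child) else partial[[child]]
    contrib <- Pmats[[e]] %*% Lc
    if (is.null(partial[[parent]])) partial[[parent]] <- contrib
    else partial[[parent]] <- partial[[parent]] * contrib
    # per-pattern rescaling against underflow
    cm <- apply(partial[[parent]], 2, max)
    small <- cm < 1e-100 & cm > 0
    if (any(small)) {
      partial[[parent]][, small] <- sweep(
        partial[[parent]][, small, drop = FALSE], 2, cm[small], "/")
      logscale[small] <- logscale[small] + log(cm[small])
    }
  }
  L <- partial[[info$root]]
  mx <- apply(L, 2, max)
  lik <- colSums(pi * sweep(L, 2, mx, "/"))
  log(lik) + log(mx) + logscale
}

#' Log-likelihood of a codon alignment on a tree
#'
#' Felsenstein pruning over the sense-codon state space, with a mixture over
#' site classes. Each site class specifies a proportion and an omega for the
#' background branches and one for the numt branches (equal for models
#' without branch structure). Branch classes are taken from
#' `tree$branch.class` (see [label_numt_clade()]); if the class omegas
#' differ and the tree carries no labels, an error is raised. Alignment
#' columns containing untranslatable codons (N, stop) in a taxon are treated
#' as missing data for that taxon.
#'
#' @param tree `ape::phylo` with edge lengths (expected substitutions per
#'   codon), optionally with `branch.class`.
#' @param seqs Aligned in-frame sequences; names must match tip labels.
#' @param classes Data frame with columns `proportion`, `omega_background`,
#'   `omega_numt` (one row per site class; proportions sum to 1).
#' @param kappa Transition/transversion ratio.
#' @param code Genetic code (default vertebrate mitochondrial).
#' @param codon_freqs Frequency vector over sense codons, a scheme name
#'   (`"F3x4"`, `"F1x4"`, `"equal"`) to estimate from the alignment, or
#'   `NULL` for equal.
#' @return The log-likelihood (numeric scalar).
#' @export
codon_log_likelihood <- function(tree, seqs, classes, kappa = 2,
                                 code = genetic_code("vertebrate_mito"),
                                 codon_freqs = "F3x4") {
  code <- as_genetic_code(code)
  recs <- as_seq_records(seqs)
  pi <- resolve_freqs(codon_freqs, recs, code)
  states <- codon_state_matrix(recs, code)
  info <- tree_info(tree)
  if (!setequal(rownames(states), info$tip.label))
    stop("alignment taxa do not match tree tip labels")
  states <- states[info$tip.label, , drop = FALSE]
  cp <- compress_patterns(states)
  classes <- validate_classes(classes)
  needs_partition <- any(abs(classes$omega_background - classes$omega_numt) > 1e-12)
  if (needs_partition && all(info$branch.class == "background") &&
      is.null(tree$branch.class))
    stop("model distinguishes numt branches but the tree has no branch labels")
  ll <- loglik_engine(info, cp, classes, kappa, pi, code)
  sum(ll * cp$weights)
}

resolve_freqs <- function(codon_freqs, recs, code) {
  g <- get_codon_graph(code)
  if (is.null(codon_freqs)) return(rep(1 / g$n, g$n))
  if (is.character(codon_freqs) && length(codon_freqs) == 1L)
    return(unname(codon_frequencies(recs, codon_freqs, code)))
  normalise_freqs(codon_freqs, g)
}

validate_classes <- function(classes) {
  classes <- as.data.frame(classes)
  need <- c("proportion", "omega_background", "omega_numt")
  if (!all(need %in% names(classes)))
    stop("classes needs columns: ", paste(need, collapse = ", "))
  if (any(classes$proportion < -1e-9)) stop("negative class proportion")
  s <- sum(classes$proportion)
  if (abs(s - 1) > 1e-6) stop("class proportions must sum to 1")
  classes$proportion <- pmax(classes$proportion, 0) / s
  classes
}

# per-pattern mixture log-likelihood (vector over patterns)
loglik_engine <- function(info, cp, classes, kappa, pi, code) {
  ncls <- nrow(classes)
  per_class <- matrix(NA_real_, ncls, ncol(cp$patterns))
  # cache propagators by omega value (shared between partitions when equal)
  prop_cache <- list()
  get_prop <- function(omega) {
    key <- sprintf("%.12g", omega)
    if (is.null(prop_cache[[key]]))
      prop_cache[[key]] <<- propagator(
        codon_rate_matrix(kappa, omega, pi, code), pi)
    prop_cache[[key]]
  }
  for (c_i in seq_len(ncls)) {
    w_bg <- classes$omega_background[c_i]
    w_nu <- classes$omega_numt[c_i]
    Pmats <- vector("list", nrow(info$edge))
    for (e in seq_len(nrow(info$edge))) {
      w <- if (info$branch.class[e] == "numt") w_nu else w_bg
      Pmats[[e]] <- get_prop(w)(info$edge.length[e])
    }
    per_class[c_i, ] <- prune_class(info, cp$patterns, Pmats, pi)
  }
  p <- classes$proportion
  if (ncls == 1L) return(per_class[1L, ])
  keep <- p > 0
  M <- per_class[keep, , drop = FALSE]
  m <- apply(M, 2, max)
  log(colSums(p[keep] * exp(sweep(M, 2, m, "-")))) + m
}
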