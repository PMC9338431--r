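#' Tajima-Nei (1984) pairwise distance
#'
#' Nucleotide distance correcting for unequal base composition and multiple
#' hits: d = -b log(1 - p/b), with b = (1 - sum(g_i^2) + p^2/h)/2 where g_i
#' are mean base frequencies over the two sequences, p the proportion of
#' differing sites and h = sum over unordered base pairs (i, j) of
#' x_ij^2 / (2 g_i g_j) with x_ij the relative frequency of mismatch pair
#' (i, j). With equal base frequencies and balanced mismatch types this
#' reduces to the Jukes-Cantor distance -(3/4) log(1 - 4p/3). Alignment
#' columns containing a gap or N in either sequence are dropped (pairwise
#' deletion).
#'
#' @param seq_a,seq_b Equal-length aligned DNA strings.
#' @return The distance (0 for identical sequences).
#' @export
tajima_nei <- function(seq_a, seq_b) {
  a <- strsplit(toupper(as.character(seq_a)), "")[[1]]
  b <- strsplit(toupper(as.character(seq_b)), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L) stop("no comparable sites after pairwise deletion")
  p <- mean(a != b)
  if (p == 0) return(0)
  bases <- c("A", "C", "G", "T")
  g <- (table(factor(a, bases)) + table(factor(b, bases))) / (2 * n)
  g <- as.numeric(g)
  h <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    xij <- (sum(a == bases[i] & b == bases[j]) +
            sum(a == bases[j] & b == bases[i])) / n
    if (xij > 0) h <- h + xij^2 / (2 * g[i] * g[j])
  }
  bcoef <- (1 - sum(g^2) + p^2 / h) / 2
  if (p >= bcoef)
    stop(sprintf("Tajima-Nei distance saturated (p = %.3f >= b = %.3f)", p, bcoef))
  -bcoef * log(1 - p / bcoef)
}

#' Tajima-Nei distance matrix for a set of aligned sequences
#'
#' @param seqs Named character vector or list of [seq_record()]s, all the
#'   same length (an alignment).
#' @return A symmetric matrix with zero diagonal, taxa as dimnames.
#' @export
tajima_nei_matrix <- function(seqs) {
  recs <- as_seq_records(seqs)
  taxa <- names(recs)
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- tryCatch(
      tajima_nei(recs[[i]]$seq, recs[[j]]$seq),
      error = function(e) stop("pair (", taxa[i], ", ", taxa[j], "): ",
                               conditionMessage(e)))
  }
  d
}

#' Neighbour-joining tree
#'
#' Saitou-Nei neighbour joining on a symmetric distance matrix. Ties in the
#' rate-corrected criterion are broken deterministically by the lowest index
#' pair. Negative branch-length estimates are clamped to zero with the
#' deficit moved to the sister branch, so all edge lengths are non-negative.
#' For an additive (tree-metric) matrix the generating topology and branch
#' lengths are recovered exactly.
#'
#' @param D Symmetric numeric matrix with taxon dimnames (>= 3 taxa), zero
#'   diagonal.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  taxa <- rownames(D)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(D)))
  n_tip <- nrow(D)
  # node ids: 1..n_tip tips, internal nodes numbered from n_tip+1 (ape style)
  active_id <- seq_len(n_tip)
  next_internal <- n_tip + 1L
  edges <- matrix(integer(), 0, 2)
  elen <- numeric()
  d <- D
  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    # lowest-index tie break: scan column-major over i<j
    best <- c(1L, 2L); bq <- Inf
    for (j in 2:m) for (i in 1:(j - 1)) {
      if (Q[i, j] < bq - 1e-12) { bq <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    ll <- clamp_pair(li, lj)
    new_id <- next_internal; next_internal <- next_internal + 1L
    edges <- rbind(edges, c(new_id, active_id[i]), c(new_id, active_id[j]))
    elen <- c(elen, ll[1L], ll[2L])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    du <- du[-c(i, j)]
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    d <- rbind(cbind(d, du), c(du, 0))
    active_id <- c(active_id[-c(i, j)], new_id)
  }
  # resolve final three lineages around one internal node
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  center <- next_internal
  edges <- rbind(edges, c(center, active_id[1L]), c(center, active_id[2L]),
                 c(center, active_id[3L]))
  elen <- c(elen, max(v1, 0), max(v2, 0), max(v3, 0))
  n_internal <- center - n_tip
  # renumber internal nodes so the last-created (root of traversal) is n_tip+1
  map <- integer(center)
  map[seq_len(n_tip)] <- seq_len(n_tip)
  map[(n_tip + 1L):center] <- n_tip + rev(seq_len(n_internal))
  edges[] <- map[edges]
  tr <- list(edge = edges, edge.length = elen, tip.label = taxa,
             Nnode = n_internal)
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  ape::reorder.phylo(tr, "cladewise")
}

#' Label the numt clade on a tree
#'
#' Partitions the branches of a tree into the clade formed by the numt
#' sequences (including its stem branch) and the rest of the tree, the
#' branch classification used by the two-ratio and clade selection models.
#' The numt taxa must form a clade in the unrooted sense; otherwise an
#' error is raised.
#'
#' @param tree An `ape::phylo` tree.
#' @param numt_taxa Character vector of tip labels (non-empty subset of the
#'   leaves; may be all leaves).
#' @return The tree with an added element `branch.class`, a character vector
#'   aligned with `tree$edge` rows taking values `"numt"` or `"background"`.
#' @export
label_numt_clade <- function(tree, numt_taxa) {
  stopifnot(inherits(tree, "phylo"))
  # work on the unrooted form so the stem of the clade is a single branch
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  tips <- tree$tip.label
  if (!length(numt_taxa)) stop("numt_taxa must be non-empty")
  if (!all(numt_taxa %in% tips))
    stop("unknown taxa: ", paste(setdiff(numt_taxa, tips), collapse = ", "))
  n_tip <- length(tips)
  if (length(numt_taxa) == n_tip) {
    tree$branch.class <- rep("numt", nrow(tree$edge))
    return(tree)
  }
  # root at a background tip so rooted monophyly = unrooted clade
  out <- setdiff(tips, numt_taxa)[1L]
  rt <- ape::root(tree, outgroup = out, resolve.root = TRUE)
  if (!ape::is.monophyletic(rt, numt_taxa))
    stop("numt taxa are not monophyletic: ", paste(numt_taxa, collapse = ", "))
  target <- match(numt_taxa, tips)
  cls <- rep("background", nrow(tree$edge))
  # an edge is in the numt partition if the tip set below it (on the side away
  # from the background root) is a non-empty subset of numt_taxa
  for (e in seq_len(nrow(tree$edge))) {
    for (side in 1:2) {
      below <- tips_below(tree, tree$edge[e, side], exclude_edge = e)
      if (length(below) && all(below %in% target) &&
          !all(seq_len(n_tip) %in% below)) {
        cls[e] <- "numt"
        break
      }
    }
  }
  tree$branch.class <- cls
  tree
}

# tip indices reachable from `node` without traversing edge `exclude_edge`
tips_below <- function(tree, node, exclude_edge) {
  n_tip <- length(tree$tip.label)
  seen <- integer(); stack <- node
  visited <- logical(max(tree$edge))
  tipset <- integer()
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (visited[v]) next
    visited[v] <- TRUE
    if (v <= n_tip) tipset <- c(tipset, v)
    inc <- which((tree$edge[, 1] == v | tree$edge[, 2] == v))
    inc <- setdiff(inc, exclude_edge)
    for (e in inc) {
      w <- if (tree$edge[e, 1] == v) tree$edge[e, 2] else tree$edge[e, 1]
      if (!visited[w]) stack <- c(stack, w)
    }
  }
  sort(tipset)
}

#' Read and write Newick trees
#'
#' Thin wrappers over `ape::read.tree` / `ape::write.tree` so the package's
#' tree I/O is explicit; branch lengths round-trip at full precision.
#'
#' @param tree An `ape::phylo` object.
#' @param path File path.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
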