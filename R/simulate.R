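# Synthetic mitonuclear data with known ground truth: simulated mitogenomes,
# nuclear genomes with planted numts of controlled age/source, and codon
# alignments evolved under the selection models.

#' Simulate a mitogenome with protein-coding gene annotation
#'
#' Generates a circular mitogenome emulating the vertebrate layout: a
#' leading rRNA/tRNA block, 13 protein-coding genes (ND1..CYTB) separated by
#' short spacers, and a trailing D-loop. Every gene is a stop-free ORF under
#' the vertebrate mitochondrial code (ATG start, body of sense codons,
#' terminal stop), so reading-frame classification has exact ground truth.
#'
#' @param config Optional list overriding `gene_lengths` (named, bp,
#'   multiples of 3 including the stop), `total_length` (default 16500),
#'   `leading_spacer` (default 2600), `intergenic` (default 60) and
#'   `gc` content of non-coding sequence (default 0.4).
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return A list of class `mito_sim`: `record` (a circular [seq_record()]),
#'   `genes` (data frame gene/start/end/strand, 1-based inclusive) and
#'   `seed`.
#' @export
simulate_mitogenome <- function(config = list(), seed = 1L) {
  defaults <- list(
    gene_lengths = c(ND1 = 957, ND2 = 1044, COX1 = 1545, COX2 = 684,
                     ATP8 = 204, ATP6 = 681, COX3 = 786, ND3 = 348,
                     ND4L = 297, ND4 = 1380, ND5 = 1821, ND6 = 528,
                     CYTB = 1140),
    total_length = 16500L, leading_spacer = 2600L, intergenic = 60L, gc = 0.4)
  cfg <- utils::modifyList(defaults, config)
  gl <- cfg$gene_lengths
  if (any(gl %% 3L != 0L)) stop("gene lengths must be multiples of 3")
  coding <- sum(gl) + cfg$leading_spacer + cfg$intergenic * (length(gl) - 1L)
  if (coding >= cfg$total_length)
    stop("gene lengths plus spacers exceed total genome length")
  set.seed(as.integer(seed))
  code <- genetic_code("vertebrate_mito")
  sense <- setdiff(names(code$table), code$stops)
  body_pool <- setdiff(sense, "ATG")
  random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE,
    prob = c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)),
    collapse = "")
  make_gene <- function(len) {
    n_body <- len / 3L - 2L
    paste0("ATG", paste(sample(body_pool, n_body, TRUE), collapse = ""),
           sample(c("TAA", "TAG", "AGA", "AGG"), 1L))
  }
  parts <- character(); genes <- list(); pos <- 1L
  parts <- c(parts, random_dna(cfg$leading_spacer))
  pos <- pos + cfg$leading_spacer
  for (k in seq_along(gl)) {
    gseq <- make_gene(gl[[k]])
    genes[[k]] <- data.frame(gene = names(gl)[k], start = pos,
                             end = pos + gl[[k]] - 1L, strand = "+",
                             stringsAsFactors = FALSE)
    parts <- c(parts, gseq)
    pos <- pos + gl[[k]]
    if (k < length(gl)) {
      parts <- c(parts, random_dna(cfg$intergenic))
      pos <- pos + cfg$intergenic
    }
  }
  dloop <- cfg$total_length - (pos - 1L)
  parts <- c(parts, random_dna(dloop))
  rec <- seq_record("mito_sim", paste(parts, collapse = ""), circular = TRUE)
  structure(list(record = rec, genes = do.call(rbind, genes), seed = seed,
                 config = cfg), class = "mito_sim")
}

#' @export
print.mito_sim <- function(x, ...) {
  cat("<mito_sim>", nchar(x$record$seq), "bp,", nrow(x$genes),
      "protein-coding genes, seed", x$seed, "\n")
  invisible(x)
}

#' Extract a gene sequence from a simulated mitogenome
#'
#' @param mito A `mito_sim` object.
#' @param gene Gene name (e.g. `"ND3"`).
#' @return The coding sequence as a character string.
#' @export
mito_gene_seq <- function(mito, gene) {
  g <- mito$genes[mito$genes$gene == gene, ]
  if (nrow(g) != 1L) stop("unknown gene: ", gene)
  substr(mito$record$seq, g$start, g$end)
}

#' Write the gene annotation of a simulated mitogenome as GFF3
#'
#' @param mito A `mito_sim` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mito_gff <- function(mito, path) {
  g <- mito$genes
  lines <- c("##gff-version 3",
             sprintf("%s\tnumtforge\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     mito$record$id, g$start, g$end, g$strand, g$gene))
  writeLines(lines, path)
  invisible(path)
}

#' Describe a planted numt insertion
#'
#' An insertion event records where a (possibly evolved) copy of the
#' mitogenome lands in the nuclear genome. `source` distinguishes the donor
#' lineage: `"canonical"` (the reference mitogenome itself),
#' `"heteroplasmic"` or `"hybrid"` (a donor evolved away from the reference
#' by `donor_divergence` substitutions/site under functional constraint --
#' stop-creating changes in genes rejected, nonsynonymous changes strongly
#' disfavoured -- emulating a divergent but still-expressed mtDNA). `age` is
#' the neutral nuclear divergence (substitutions/site) accumulated after
#' insertion, applied uniformly with no coding constraint.
#'
#' @param scaffold Target scaffold id.
#' @param position 1-based insertion point in the original scaffold.
#' @param mito_start,mito_end Mitochondrial interval copied (used when
#'   `fragments` is NULL).
#' @param source `"canonical"`, `"heteroplasmic"` or `"hybrid"`.
#' @param age Post-insertion substitutions/site (>= 0).
#' @param donor_divergence Donor-lineage substitutions/site (>= 0; must be 0
#'   for `"canonical"`).
#' @param strand `"+"` or `"-"`.
#' @param fragments Optional data frame `mito_start`, `mito_end`,
#'   `spacer_after` (nuclear bases retained between this fragment and the
#'   next; last value ignored) describing a fragmented insertion.
#' @return An object of class `insertion_event`.
#' @export
insertion_event <- function(scaffold, position, mito_start = NULL,
                            mito_end = NULL,
                            source = c("canonical", "heteroplasmic", "hybrid"),
                            age = 0, donor_divergence = 0, strand = "+",
                            fragments = NULL) {
  source <- match.arg(source)
  if (age < 0 || donor_divergence < 0) stop("rates must be >= 0")
  if (source == "canonical" && donor_divergence > 0)
    stop("canonical insertions have donor_divergence 0")
  if (is.null(fragments)) {
    if (is.null(mito_start) || is.null(mito_end))
      stop("give mito_start/mito_end or a fragments table")
    fragments <- data.frame(mito_start = mito_start, mito_end = mito_end,
                            spacer_after = 0L)
  }
  fragments <- as.data.frame(fragments)
  if (is.null(fragments$spacer_after)) fragments$spacer_after <- 0L
  stopifnot(all(fragments$mito_start <= fragments$mito_end))
  structure(list(scaffold = as.character(scaffold),
                 position = as.integer(position), source = source,
                 age = age, donor_divergence = donor_divergence,
                 strand = strand, fragments = fragments),
            class = "insertion_event")
}

# evolve a functional donor to the target divergence: the expected number of
# substitutions is placed at distinct sites, separately for gene and non-gene
# regions (so divergence is uniform along the molecule); inside genes,
# stop-creating changes are rejected and nonsynonymous ones accepted with
# prob `nonsyn_accept` (the site is re-drawn within the region on rejection)
evolve_donor <- function(seq, genes, divergence, nonsyn_accept = 0.2) {
  if (divergence <= 0) return(seq)
  s <- strsplit(seq, "")[[1]]
  len <- length(s)
  code <- genetic_code("vertebrate_mito")
  in_gene <- integer(len)
  for (k in seq_len(nrow(genes))) in_gene[genes$start[k]:genes$end[k]] <- k
  bases <- c("A", "C", "G", "T")
  try_substitute <- function(pos) {
    new <- sample(setdiff(bases, s[pos]), 1L)
    gi <- in_gene[pos]
    if (gi > 0L) {
      gs <- genes$start[gi]; ge <- genes$end[gi]
      off <- pos - gs
      c0 <- gs + (off %/% 3L) * 3L
      codon <- paste(s[c0:(c0 + 2L)], collapse = "")
      newcodon <- codon
      substr(newcodon, off %% 3L + 1L, off %% 3L + 1L) <- new
      aa_old <- code$table[codon]; aa_new <- code$table[newcodon]
      is_terminal <- (c0 + 2L) == ge
      if (!is_terminal && identical(unname(aa_new), "*")) return(FALSE)
      if (is_terminal && !identical(unname(aa_new), "*")) return(FALSE)
      if (!is.na(aa_old) && !is.na(aa_new) && aa_old != aa_new &&
          stats::runif(1L) > nonsyn_accept) return(FALSE)
    }
    s[pos] <<- new
    TRUE
  }
  for (region in list(which(in_gene > 0L), which(in_gene == 0L))) {
    if (!length(region)) next
    n_target <- stats::rbinom(1L, length(region), divergence)
    if (n_target == 0L) next
    pool <- sample(region)  # distinct candidate sites in random order
    accepted <- 0L
    for (pos in pool) {
      if (accepted >= n_target) break
      if (try_substitute(pos)) accepted <- accepted + 1L
    }
  }
  paste(s, collapse = "")
}

# neutral post-insertion evolution: per-site substitution prob `rate`,
# optional indels (geometric length, mean 2, at 5% of the substitution rate)
evolve_neutral <- function(seq, rate, indels = FALSE) {
  s <- strsplit(seq, "")[[1]]
  len <- length(s)
  bases <- c("A", "C", "G", "T")
  hit <- stats::runif(len) < rate
  if (any(hit)) {
    s[hit] <- vapply(s[hit], function(b) sample(setdiff(bases, b), 1L), "")
  }
  if (indels && rate > 0) {
    n_indel <- stats::rpois(1L, 0.05 * rate * len)
    for (k in seq_len(n_indel)) {
      ilen <- stats::rgeom(1L, 0.5) + 1L
      pos <- sample.int(max(length(s) - ilen, 1L), 1L)
      if (stats::runif(1L) < 0.5) {
        s <- s[-(pos:min(pos + ilen - 1L, length(s)))]
      } else {
        ins <- sample(bases, ilen, TRUE)
        s <- append(s, ins, after = pos)
      }
    }
  }
  paste(s, collapse = "")
}

#' Plant numt insertions into a simulated nuclear genome
#'
#' Builds nuclear scaffolds of random sequence and plants the given
#' insertion events: for each event a donor mitogenome is chosen (the
#' reference, or a copy evolved under functional constraint for
#' heteroplasmic/hybrid donors), the specified mitochondrial fragments are
#' excised, inserted at the target position separated by the retained
#' nuclear spacers, and then evolved neutrally for `age` substitutions/site.
#' The returned truth table records the realized nuclear coordinates of
#' every fragment, accounting for the length shifts caused by earlier
#' insertions on the same scaffold.
#'
#' @param mito A `mito_sim` object (from [simulate_mitogenome()]).
#' @param events List of [insertion_event()]s; insertions overlapping on the
#'   original scaffold coordinates are an error.
#' @param nuclear_config List: `n_scaffolds` (default 4), `scaffold_length`
#'   (default 250000), `gc` (default 0.42). Scaffolds are named
#'   `scaffold_1..n`.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param indels Enable post-insertion indels (default FALSE, keeping frame
#'   analyses exact).
#' @return A list of class `numt_landscape`: `nuclear` (list of
#'   [seq_record()]s), `mito`, `truth` (per-fragment data frame with realized
#'   coordinates), `events`, `seed`.
#' @export
simulate_numt_landscape <- function(mito, events, nuclear_config = list(),
                                    seed = 1L, indels = FALSE) {
  cfg <- utils::modifyList(list(n_scaffolds = 4L, scaffold_length = 250000L,
                                gc = 0.42), nuclear_config)
  # decorrelate from the mitogenome generator's stream so that passing the
  # same seed to both cannot replicate random mitogenome regions in scaffolds
  set.seed((as.integer(seed) + 104729L) %% .Machine$integer.max)
  bases <- c("A", "C", "G", "T")
  prob <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
  scaffolds <- stats::setNames(
    vapply(seq_len(cfg$n_scaffolds), function(i)
      paste(sample(bases, cfg$scaffold_length, TRUE, prob), collapse = ""), ""),
    paste0("scaffold_", seq_len(cfg$n_scaffolds)))

  # validate: events on one scaffold must not overlap in original coordinates
  by_sc <- split(events, vapply(events, `[[`, "", "scaffold"))
  for (sc in names(by_sc)) {
    evs <- by_sc[[sc]]
    iv <- t(vapply(evs, function(e) {
      span <- e$position + sum(e$fragments$spacer_after)
      c(e$position, span)
    }, numeric(2)))
    o <- order(iv[, 1])
    iv <- iv[o, , drop = FALSE]
    if (nrow(iv) > 1L && any(iv[-1L, 1] <= iv[-nrow(iv), 2]))
      stop("overlapping planted insertions on ", sc)
  }

  truth <- list()
  for (sc in names(scaffolds)) {
    evs <- by_sc[[sc]]
    if (is.null(evs)) next
    evs <- evs[order(vapply(evs, `[[`, 0L, "position"))]
    shift <- 0L
    for (ei in seq_along(evs)) {
      ev <- evs[[ei]]
      donor <- if (ev$source == "canonical") mito$record$seq else
        evolve_donor(mito$record$seq, mito$genes, ev$donor_divergence)
      cursor <- ev$position + shift  # insertion point in current scaffold
      for (fi in seq_len(nrow(ev$fragments))) {
        fr <- ev$fragments[fi, ]
        fseq <- substr(donor, fr$mito_start, fr$mito_end)
        if (ev$strand == "-") fseq <- reverse_complement(fseq)
        fseq <- evolve_neutral(fseq, ev$age, indels = indels)
        flen <- nchar(fseq)
        cur <- scaffolds[[sc]]
        scaffolds[[sc]] <- paste0(substr(cur, 1L, cursor - 1L), fseq,
                                  substr(cur, cursor, nchar(cur)))
        truth[[length(truth) + 1L]] <- data.frame(
          event = ev$id %||% NA_integer_, scaffold = sc,
          start = cursor, end = cursor + flen - 1L, strand = ev$strand,
          mito_start = fr$mito_start, mito_end = fr$mito_end,
          source = ev$source, age = ev$age,
          donor_divergence = ev$donor_divergence,
          fragment = fi, n_fragments = nrow(ev$fragments),
          stringsAsFactors = FALSE)
        shift <- shift + flen
        cursor <- cursor + flen + fr$spacer_after
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(event = integer(), scaffold = character(), start = integer(),
               end = integer(), stringsAsFactors = FALSE)
  nuclear <- lapply(names(scaffolds), function(n) seq_record(n, scaffolds[[n]]))
  names(nuclear) <- names(scaffolds)
  structure(list(nuclear = nuclear, mito = mito, truth = truth,
                 events = events, seed = seed), class = "numt_landscape")
}

#' @export
print.numt_landscape <- function(x, ...) {
  cat("<numt_landscape>", length(x$nuclear), "scaffolds,",
      nrow(x$truth), "planted fragments, seed", x$seed, "\n")
  invisible(x)
}

#' The default synthetic numt landscape
#'
#' Twelve insertion events spanning the conditions the pipeline is meant to
#' resolve: total lengths 250-14,000 bp, post-insertion divergences 0-0.12,
#' one to four fragments per event (inter-fragment spacers all below the
#' 10 kb clustering gap, so each event is one numt), plus and minus strands,
#' and canonical, heteroplasmic and hybrid donor lineages.
#'
#' @param seed Integer seed.
#' @return A `numt_landscape` (see [simulate_numt_landscape()]).
#' @export
default_numt_landscape <- function(seed = 1L) {
  mito <- simulate_mitogenome(seed = seed)
  fr <- function(ms, me, sp) data.frame(mito_start = ms, mito_end = me,
                                        spacer_after = sp)
  events <- list(
    insertion_event("scaffold_1",  20000, 1000, 1999),
    insertion_event("scaffold_1",  90000, age = 0.02,
                    fragments = fr(c(2100, 7700), c(5099, 9699), c(5000, 0))),
    insertion_event("scaffold_1", 170000, 9500, 10099, age = 0.05, strand = "-"),
    insertion_event("scaffold_2",  30000, 3000, 4999, source = "hybrid",
                    age = 0.01, donor_divergence = 0.05),
    insertion_event("scaffold_2", 100000, age = 0.08,
                    fragments = fr(c(100, 5400, 11600, 14300),
                                   c(2599, 6899, 12599, 15099),
                                   c(3000, 8000, 2000, 0))),
    insertion_event("scaffold_2", 180000, 6300, 7799, age = 0.12),
    insertion_event("scaffold_3",  25000, 9800, 10599, source = "heteroplasmic",
                    age = 0.02, donor_divergence = 0.03),
    insertion_event("scaffold_3",  95000, age = 0.10, strand = "-",
                    fragments = fr(c(1, 9400), c(7000, 16399), c(9000, 0))),
    insertion_event("scaffold_3", 190000, 12000, 12249),
    insertion_event("scaffold_4",  40000, age = 0.03,
                    fragments = fr(c(3900, 2300, 10100),
                                   c(5099, 3199, 10799), c(4000, 6000, 0))),
    insertion_event("scaffold_4", 120000, 8000, 12999, source = "hybrid",
                    donor_divergence = 0.08),
    insertion_event("scaffold_4", 200000, 15000, 15299, age = 0.06))
  for (i in seq_along(events)) events[[i]]$id <- i
  simulate_numt_landscape(mito, events, seed = seed)
}

#' Reference tree for codon-model simulation studies
#'
#' A six-taxon unrooted tree with a three-taxon numt clade (total numt
#' branch length 0.9 expected substitutions per codon) and three
#' mitochondrial background taxa, branch classes already labelled. This is
#' the design used by the package's parameter-recovery simulations: enough
#' numt branch length that the clade's omega is estimated with a standard
#' error of roughly 0.1 at 500 codons, mirroring a multi-species study
#' rather than a minimal quartet.
#'
#' @return An `ape::phylo` with `branch.class`.
#' @export
numt_demo_tree <- function() {
  tr <- ape::read.tree(
    text = "(((n1:0.2,n2:0.2):0.1,n3:0.25):0.15,(m1:0.3,m2:0.3):0.1,m3:0.5);")
  label_numt_clade(tr, c("n1", "n2", "n3"))
}

#' Simulate a codon alignment along a tree
#'
#' Evolves codon sites along a fixed tree under the GY94-family model used
#' by [fit_codon_model()]: sites are assigned to classes by the class
#' proportions, the root state is drawn from the stationary distribution,
#' and each branch applies the transition matrix of its (site class, branch
#' class) rate matrix. Deterministic given the seed.
#'
#' @param tree `ape::phylo` with edge lengths; must carry `branch.class`
#'   (see [label_numt_clade()]) if any class distinguishes the partitions.
#' @param classes Data frame `proportion`, `omega_background`, `omega_numt`.
#' @param kappa Transition/transversion ratio.
#' @param n_codons Number of codon sites.
#' @param seed Integer seed.
#' @param code Genetic code (default vertebrate mitochondrial).
#' @param codon_freqs Frequencies over sense codons, or NULL for equal.
#' @return Named character vector of tip sequences (in-frame, no stops);
#'   attribute `site_class` gives the true class of each site.
#' @export
simulate_codon_alignment <- function(tree, classes, kappa = 2, n_codons = 300L,
                                     seed = 1L,
                                     code = genetic_code("vertebrate_mito"),
                                     codon_freqs = NULL) {
  code <- as_genetic_code(code)
  classes <- validate_classes(classes)
  needs_partition <- any(abs(classes$omega_background - classes$omega_numt) > 1e-12)
  if (needs_partition && is.null(tree$branch.class))
    stop("classes distinguish numt branches but the tree has no branch labels")
  info <- tree_info(tree)
  g <- get_codon_graph(code)
  pi <- normalise_freqs(codon_freqs, g)
  set.seed(as.integer(seed))
  site_class <- sample.int(nrow(classes), n_codons, TRUE,
                           prob = classes$proportion)
  # preorder = reverse postorder edge order
  states <- matrix(NA_integer_, max(info$edge), n_codons)
  states[info$root, ] <- sample.int(g$n, n_codons, TRUE, prob = pi)
  props <- list()
  get_P <- function(omega, t) {
    key <- sprintf("%.12g", omega)
    if (is.null(props[[key]]))
      props[[key]] <<- propagator(codon_rate_matrix(kappa, omega, pi, code), pi)
    props[[key]](t)
  }
  for (e in rev(seq_len(nrow(info$edge)))) {
    parent <- info$edge[e, 1]; child <- info$edge[e, 2]
    for (ci in seq_len(nrow(classes))) {
      idx <- which(site_class == ci)
      if (!length(idx)) next
      w <- if (info$branch.class[e] == "numt") classes$omega_numt[ci] else
        classes$omega_background[ci]
      P <- get_P(w, info$edge.length[e])
      ps <- states[parent, idx]
      for (s in unique(ps)) {
        sel <- idx[ps == s]
        states[child, sel] <- sample.int(g$n, length(sel), TRUE, prob = P[s, ])
      }
    }
  }
  out <- vapply(seq_len(info$n_tip), function(k)
    paste(g$codons[states[k, ]], collapse = ""), "")
  names(out) <- info$tip.label
  attr(out, "site_class") <- site_class
  out
}
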