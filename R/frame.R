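#' Classify the reading frame of a numt-resident gene
#'
#' Aligns a numt fragment to a complete mitochondrial coding sequence and
#' asks whether the fragment still carries an intact mitochondrial reading
#' frame: a gap-free alignment with no premature stop codon under the
#' vertebrate mitochondrial code. The fragment is also translated under the
#' standard nuclear code, where mitochondrial genes typically show premature
#' stops (AGA/AGG read as Arg in the nucleus but stop in the mitochondrion,
#' TGA the reverse) -- the signature that a numt is not translatable as a
#' nuclear gene even when its mitochondrial frame is intact.
#'
#' The alignment is local on both sequences by default (`mode = "overlap"`):
#' only the overlapping homologous segment must be gap-free. With
#' `mode = "full"` the entire gene must align (global on the gene, local on
#' the fragment). Both strands of the fragment are tried and the better
#' scoring one used. Scoring: match +1, mismatch -1, gap open -5, extend -2.
#' The gene's own terminal stop codon is not counted as premature, and
#' incomplete stops completed by polyadenylation are not treated as stops --
#' only full 3-nt stop codons count.
#'
#' @param fragment_seq Numt fragment DNA (character or [seq_record()]).
#' @param mito_gene_seq Complete mitochondrial CDS starting in frame 0,
#'   length a multiple of 3.
#' @param gene_id Label carried into the report.
#' @param mode `"overlap"` (default) or `"full"`; see Details.
#' @param min_identity Percent identity below which the fragment is declared
#'   non-homologous to the gene (default 60).
#' @param min_overlap Minimum aligned length in bp (default 30).
#' @return A list of class `intactness_report` with fields `gene_id`, `frame`
#'   (0/1/2, frame of the gene's codons within the fragment segment),
#'   `mito_internal_stops`, `nuclear_internal_stops`, `gap_free`,
#'   `intact_mito_frame`, `no_homology`, `strand`, `percent_identity`,
#'   `gene_span` (1-based gene interval covered) and `n_codons` examined.
#' @export
classify_reading_frame <- function(fragment_seq, mito_gene_seq, gene_id = "gene",
                                   mode = c("overlap", "full"),
                                   min_identity = 60, min_overlap = 30L) {
  mode <- match.arg(mode)
  frag <- if (inherits(fragment_seq, "seq_record")) fragment_seq$seq else
    toupper(as.character(fragment_seq))
  gene <- if (inherits(mito_gene_seq, "seq_record")) mito_gene_seq$seq else
    toupper(as.character(mito_gene_seq))
  if (!nzchar(frag) || !nzchar(gene)) stop("empty sequence")
  if (nchar(gene) %% 3L != 0L)
    stop("mito_gene_seq length must be a multiple of 3 (complete CDS)")

  type <- if (mode == "overlap") "local" else "global-local"
  align_one <- function(fr) {
    # pattern = gene so that "full" mode is global on the gene
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(gene), Biostrings::DNAString(fr),
      type = type, substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE),
      gapOpening = 5, gapExtension = 2)
  }
  pa_f <- align_one(frag)
  pa_r <- align_one(reverse_complement(frag))
  use_rev <- Biostrings::score(pa_r) > Biostrings::score(pa_f)
  pa <- if (use_rev) pa_r else pa_f

  gal <- as.character(Biostrings::alignedPattern(pa))
  fal <- as.character(Biostrings::alignedSubject(pa))
  cols_g <- strsplit(gal, "")[[1]]
  cols_f <- strsplit(fal, "")[[1]]
  n_match <- sum(cols_g == cols_f & cols_g != "-")
  n_aln <- sum(cols_g != "-" & cols_f != "-")
  pid <- if (n_aln > 0) 100 * n_match / n_aln else 0

  g1 <- Biostrings::start(Biostrings::pattern(pa))
  g2 <- Biostrings::end(Biostrings::pattern(pa))
  f1 <- Biostrings::start(Biostrings::subject(pa))

  base <- list(gene_id = gene_id, frame = NA_integer_,
               mito_internal_stops = NA_integer_, nuclear_internal_stops = NA_integer_,
               gap_free = FALSE, intact_mito_frame = FALSE, no_homology = TRUE,
               strand = if (use_rev) "-" else "+", percent_identity = pid,
               gene_span = c(NA_integer_, NA_integer_), n_codons = 0L)
  class(base) <- "intactness_report"
  if (n_aln < min_overlap || pid < min_identity || Biostrings::score(pa) <= 0)
    return(base)

  gap_free <- !any(cols_g == "-") && !any(cols_f == "-")

  # walk alignment columns; group by gene codon index, collect fragment bases
  gene_pos <- cumsum(cols_g != "-") + g1 - 1L
  gene_pos[cols_g == "-"] <- NA_integer_
  L <- nchar(gene)
  terminal_codon <- (L %/% 3L)  # codon index of the gene's own stop
  codon_idx <- ifelse(is.na(gene_pos), NA_integer_, (gene_pos - 1L) %/% 3L + 1L)

  mito <- genetic_code("vertebrate_mito")
  std <- genetic_code("standard")
  m_stops <- 0L; n_stops <- 0L; n_codons <- 0L
  for (ci in unique(codon_idx[!is.na(codon_idx)])) {
    cols <- which(!is.na(codon_idx) & codon_idx == ci)
    gbases <- cols_g[cols]
    if (sum(gbases != "-") != 3L) next  # codon only partially covered
    # fragment bases in those columns, plus any fragment insertions inside
    span <- min(cols):max(cols)
    fb <- cols_f[span]
    fb <- fb[fb != "-"]
    if (length(fb) != 3L) next  # indel disrupts this codon
    n_codons <- n_codons + 1L
    codon <- paste(fb, collapse = "")
    if (ci != terminal_codon) {
      aam <- mito$table[codon]; aas <- std$table[codon]
      if (!is.na(aam) && aam == "*") m_stops <- m_stops + 1L
      if (!is.na(aas) && aas == "*") n_stops <- n_stops + 1L
    }
  }

  delta <- f1 - g1
  first_codon_start_gene <- g1 + ((3L - ((g1 - 1L) %% 3L)) %% 3L)
  frame <- ((first_codon_start_gene + delta - 1L) %% 3L)

  out <- base
  out$frame <- as.integer(frame)
  out$mito_internal_stops <- m_stops
  out$nuclear_internal_stops <- n_stops
  out$gap_free <- gap_free
  out$intact_mito_frame <- gap_free && m_stops == 0L
  out$no_homology <- FALSE
  out$gene_span <- c(g1, g2)
  out$n_codons <- n_codons
  out
}

#' @export
print.intactness_report <- function(x, ...) {
  cat("<intactness_report>", x$gene_id, "\n")
  if (x$no_homology) {
    cat("  no homology to gene above threshold\n")
  } else {
    cat(sprintf("  strand %s, identity %.1f%%, gene span %d-%d (%d codons)\n",
                x$strand, x$percent_identity, x$gene_span[1], x$gene_span[2],
                x$n_codons))
    cat(sprintf("  gap-free: %s | internal stops (mito code): %d | (nuclear code): %d\n",
                x$gap_free, x$mito_internal_stops, x$nuclear_internal_stops))
    cat("  intact mitochondrial reading frame:", x$intact_mito_frame, "\n")
  }
  invisible(x)
}
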