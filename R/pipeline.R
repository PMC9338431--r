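#' Pipeline configuration
#'
#' Collects inputs and thresholds for [run_pipeline()]. Thresholds default
#' to the canonical numt-discovery settings: seed length 20, fragment length
#' filter 200 bp (strict), clustering gap 10 kb, E-value cutoff 0.01, and a
#' follow-up trigger of more than five nucleotide substitutions between a
#' numt-resident gene and its mitochondrial homolog.
#'
#' @param mito Mitogenome: `mito_sim`, [seq_record()] or FASTA path.
#' @param nuclear Nuclear assembly: list of records, named vector, FASTA
#'   path, or `numt_landscape`.
#' @param genes Optional gene annotation data frame (`gene`, `start`, `end`,
#'   `strand`) on the mitogenome; taken from a `mito_sim` automatically.
#' @param comparison_genomes Optional named list of genomes for
#'   cross-genome conservation profiling.
#' @param out_dir Output directory for reports.
#' @param word_size,min_len,cluster_gap,e_cutoff Discovery thresholds.
#' @param subs_trigger Substitution count above which (strictly) a gene is
#'   flagged for phylogenetic/selection follow-up (default 5).
#' @param dS_low,dS_high Age-classification thresholds on dS (defaults 0.1
#'   and 1.0).
#' @param models Codon model kinds to fit on flagged genes with enough taxa
#'   (default none; model fitting is opt-in as it dominates runtime).
#' @param seed Integer seed for stochastic stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mito, nuclear, genes = NULL,
                            comparison_genomes = NULL,
                            out_dir = tempfile("numtforge_run"),
                            word_size = 20L, min_len = 200L,
                            cluster_gap = 10000L, e_cutoff = 0.01,
                            subs_trigger = 5L, dS_low = 0.1, dS_high = 1.0,
                            models = character(), seed = 1L) {
  if (any(c(word_size, min_len, cluster_gap, e_cutoff) <= 0))
    stop("thresholds must be positive")
  known <- c("one_ratio", "two_ratio", "two_ratio_fixed", "M1a", "M2a",
             "cladeC", "cladeC_fixed")
  if (length(models) && !all(models %in% known))
    stop("unknown models: ", paste(setdiff(models, known), collapse = ", "))
  structure(list(mito = mito, nuclear = nuclear, genes = genes,
                 comparison_genomes = comparison_genomes, out_dir = out_dir,
                 word_size = word_size, min_len = min_len,
                 cluster_gap = cluster_gap, e_cutoff = e_cutoff,
                 subs_trigger = subs_trigger, dS_low = dS_low,
                 dS_high = dS_high, models = models, seed = seed),
            class = "pipeline_config")
}

#' Run the full numt analysis pipeline
#'
#' Orchestrates scan, length filter, fragment clustering, per-gene
#' reading-frame classification, pairwise dN/dS on intact-frame genes,
#' neighbour-joining trees for genes exceeding the substitution trigger,
#' optional codon-model fits with LRTs, and age classification. Reports are
#' written as TSV (numt summary, per-gene dN/dS, model/LRT tables), trees
#' as Newick, and a JSON manifest with per-stage counts and output
#' checksums. The run is deterministic given the inputs and seed.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `numts`, `frame_reports`,
#'   `dnds`, `flagged`, `trees`, `model_fits`, `age`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  mito <- config$mito
  genes <- config$genes
  if (inherits(mito, "mito_sim")) {
    genes <- genes %||% mito$genes
    mito <- mito$record
  } else {
    mito <- as_single_record(mito, circular_default = TRUE)
  }
  nuclear <- config$nuclear
  if (inherits(nuclear, "numt_landscape")) nuclear <- nuclear$nuclear
  nuclear <- if (is.character(nuclear) && length(nuclear) == 1L)
    read_fasta(nuclear) else as_seq_records(nuclear)

  # stage 1-3: scan, filter, cluster
  hits <- scan_numts(mito, nuclear, word_size = config$word_size,
                     e_cutoff = config$e_cutoff)
  counts$hits <- nrow(hits)
  kept <- filter_hits(hits, config$min_len)
  counts$hits_after_length_filter <- nrow(kept)
  numts <- cluster_fragments(kept, config$cluster_gap)
  counts$numts <- length(numts)
  counts$fragments <- if (length(numts))
    sum(vapply(numts, `[[`, 0L, "n_fragments")) else 0L
  numt_tsv <- file.path(config$out_dir, "numts.tsv")
  write_intervals(numts, numt_tsv, "TSV")
  write_intervals(numts, file.path(config$out_dir, "numts.bed"), "BED")

  # stage 4: reading-frame classification per fragment x overlapping gene
  frame_reports <- list(); dnds_rows <- list(); flagged <- list()
  if (!is.null(genes) && length(numts)) {
    for (nu in numts) {
      for (fi in seq_len(nrow(nu$fragments))) {
        fr <- nu$fragments[fi, ]
        frag_seq <- substr(nuclear[[fr$nuclear_scaffold]]$seq,
                           fr$nuclear_start, fr$nuclear_end)
        overl <- genes[genes$start <= fr$mito_end & genes$end >= fr$mito_start, ]
        for (gi in seq_len(nrow(overl))) {
          g <- overl[gi, ]
          # only genes fully contained in the fragment's mito interval can be
          # intact full-length copies
          if (g$start < fr$mito_start || g$end > fr$mito_end) next
          gseq <- substr(mito$seq, g$start, g$end)
          rep <- classify_reading_frame(frag_seq, gseq,
                                        gene_id = sprintf("numt%d.f%d.%s",
                                                          nu$id, fi, g$gene))
          rep$numt <- nu$id; rep$fragment <- fi; rep$gene <- g$gene
          frame_reports[[length(frame_reports) + 1L]] <- rep
          if (!rep$intact_mito_frame) next
          pair <- extract_gene_pair(frag_seq, gseq)
          if (is.null(pair)) next
          nsub <- sum(strsplit(pair$a, "")[[1]] != strsplit(pair$b, "")[[1]])
          summ <- tryCatch(
            pairwise_dnds(codon_alignment(pair$a, pair$b,
                                          gene_id = rep$gene_id)),
            error = function(e) NULL)
          if (is.null(summ)) next
          dnds_rows[[length(dnds_rows) + 1L]] <- cbind(
            data.frame(numt = nu$id, fragment = fi, n_substitutions = nsub),
            dnds_table(list(summ)))
          if (nsub > config$subs_trigger)
            flagged[[length(flagged) + 1L]] <- list(
              numt = nu$id, fragment = fi, gene = g$gene,
              numt_seq = pair$b, mito_seq = pair$a, n_substitutions = nsub)
        }
      }
    }
  }
  counts$intact_frame_genes <- sum(vapply(frame_reports, function(r)
    isTRUE(r$intact_mito_frame), TRUE))
  counts$genes_flagged <- length(flagged)
  dnds_df <- if (length(dnds_rows)) do.call(rbind, dnds_rows) else
    data.frame(numt = integer(), fragment = integer(),
               n_substitutions = integer(), gene = character(),
               syn_substitutions = integer(), nonsyn_substitutions = integer(),
               dN = numeric(), dS = numeric(), dN_dS = numeric(),
               p_value = numeric(), saturated = logical(),
               stringsAsFactors = FALSE)
  dnds_tsv <- file.path(config$out_dir, "dnds.tsv")
  utils::write.table(dnds_df, dnds_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # stage 5: trees for flagged genes (all copies of the gene + mito homolog)
  trees <- list(); model_fits <- list()
  if (length(flagged)) {
    by_gene <- split(flagged, vapply(flagged, `[[`, "", "gene"))
    for (gname in names(by_gene)) {
      fl <- by_gene[[gname]]
      seqs <- c(stats::setNames(fl[[1L]]$mito_seq, "mito_reference"),
                stats::setNames(vapply(fl, `[[`, "", "numt_seq"),
                                vapply(fl, function(x)
                                  sprintf("numt%d_%s", x$numt, gname), "")))
      if (length(seqs) < 3L) next
      D <- tryCatch(tajima_nei_matrix(seqs), error = function(e) NULL)
      if (is.null(D)) next
      tr <- neighbor_joining(D)
      numt_tips <- setdiff(names(seqs), "mito_reference")
      tr <- tryCatch(label_numt_clade(tr, numt_tips), error = function(e) tr)
      trees[[gname]] <- tr
      write_newick(tr, file.path(config$out_dir,
                                 paste0("tree_", gname, ".nwk")))
      if (length(config$models) && !is.null(tr$branch.class) &&
          length(seqs) >= 4L) {
        suite <- fit_codon_model_suite(tr, seqs, models = config$models,
                                       seed = config$seed)
        model_fits[[gname]] <- suite
        utils::write.table(suite$table,
                           file.path(config$out_dir,
                                     paste0("models_", gname, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  counts$trees <- length(trees)

  # stage 6: age classification per numt
  age <- list()
  if (length(numts)) {
    for (nu in numts) {
      ds_vals <- dnds_df$dS[dnds_df$numt == nu$id]
      ds <- if (length(ds_vals) && any(!is.na(ds_vals)))
        max(ds_vals, na.rm = TRUE) else NA_real_
      profiles <- NULL
      if (!is.null(config$comparison_genomes)) {
        nseq <- substr(nuclear[[nu$scaffold]]$seq, nu$span_start, nu$span_end)
        profiles <- do.call(rbind, lapply(names(config$comparison_genomes),
          function(gid) {
            pr <- profile_conservation(seq_record(paste0("numt_", nu$id), nseq),
                                       config$comparison_genomes[[gid]],
                                       e_cutoff = config$e_cutoff)
            data.frame(subject_genome_id = gid, query_cover = pr$query_cover,
                       top_hit_identity = pr$top_hit_identity,
                       stringsAsFactors = FALSE)
          }))
      }
      age[[as.character(nu$id)]] <- classify_numt_age(
        ds, profiles, dS_low = config$dS_low, dS_high = config$dS_high)
    }
  }

  outputs <- list.files(config$out_dir, full.names = TRUE)
  manifest <- list(
    tool = "numtforge", version = as.character(utils::packageVersion("numtforge")),
    seed = config$seed,
    thresholds = list(word_size = config$word_size, min_len = config$min_len,
                      cluster_gap = config$cluster_gap,
                      e_cutoff = config$e_cutoff,
                      subs_trigger = config$subs_trigger),
    counts = counts,
    checksums = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(list(numts = numts, frame_reports = frame_reports, dnds = dnds_df,
                 flagged = flagged, trees = trees, model_fits = model_fits,
                 age = age, manifest = manifest, out_dir = config$out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (n in names(x$manifest$counts))
    cat(sprintf("  %-28s %s\n", n, x$manifest$counts[[n]]))
  cat("  reports in:", x$out_dir, "\n")
  invisible(x)
}

# align a fragment to a full gene and, when the alignment is gap-free and
# covers the whole gene, return the in-frame pair (gene, fragment copy)
extract_gene_pair <- function(frag_seq, gene_seq) {
  rep <- classify_reading_frame(frag_seq, gene_seq, mode = "full")
  if (rep$no_homology || !rep$gap_free) return(NULL)
  pa_f <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(gene_seq), Biostrings::DNAString(frag_seq),
    type = "global-local", substitutionMatrix =
      Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  pa_r <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(gene_seq),
    Biostrings::DNAString(reverse_complement(frag_seq)),
    type = "global-local", substitutionMatrix =
      Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  pa <- if (Biostrings::score(pa_r) > Biostrings::score(pa_f)) pa_r else pa_f
  a <- as.character(Biostrings::alignedPattern(pa))
  b <- as.character(Biostrings::alignedSubject(pa))
  if (grepl("-", a, fixed = TRUE) || grepl("-", b, fixed = TRUE)) return(NULL)
  if (nchar(a) != nchar(gene_seq)) return(NULL)
  list(a = a, b = b)
}

#' Classify the age of a numt
#'
#' Rule-based age label from synonymous divergence and cross-genome
#' conservation, with dS taking precedence: `ancient` if dS exceeds
#' `dS_high` or the numt is present at high query cover in every comparison
#' genome; `recent` if dS is below `dS_low` or the numt is absent (low
#' cover) from all comparison genomes; otherwise `intermediate`. With no
#' evidence at all the label is `unclassified`. The rationale names the rule
#' that fired.
#'
#' @param dS Synonymous divergence of the numt's best-characterised gene
#'   (NA if unavailable).
#' @param profiles Optional data frame with columns `subject_genome_id`,
#'   `query_cover`, `top_hit_identity` from [profile_conservation()].
#' @param dS_low,dS_high Thresholds (defaults 0.1, 1.0).
#' @param cover_high Query cover regarded as presence (default 80).
#' @return List with `label` and `rationale`.
#' @export
classify_numt_age <- function(dS, profiles = NULL, dS_low = 0.1, dS_high = 1.0,
                              cover_high = 80) {
  has_ds <- !is.null(dS) && length(dS) == 1L && !is.na(dS)
  has_prof <- !is.null(profiles) && nrow(profiles) > 0L
  if (!has_ds && !has_prof)
    return(list(label = "unclassified", rationale = "no dS and no conservation evidence"))
  if (has_ds && dS > dS_high)
    return(list(label = "ancient",
                rationale = sprintf("dS = %.4f > %.2f", dS, dS_high)))
  if (has_prof && all(profiles$query_cover >= cover_high))
    return(list(label = "ancient",
                rationale = "present at high query cover in all comparison genomes"))
  if (has_ds && dS < dS_low)
    return(list(label = "recent",
                rationale = sprintf("dS = %.4f < %.2f", dS, dS_low)))
  if (has_prof && all(profiles$query_cover < cover_high) && !has_ds)
    return(list(label = "recent",
                rationale = "absent from all comparison genomes"))
  list(label = "intermediate",
       rationale = if (has_ds)
         sprintf("dS = %.4f within [%.2f, %.2f] band", dS, dS_low, dS_high)
       else "mixed conservation profile")
}
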