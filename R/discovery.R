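#' Homology scan of a mitogenome against a nuclear assembly
#'
#' Runs a seed-and-extend local-alignment search of the mitochondrial genome
#' (query) against the scaffolds of a nuclear assembly (subject), the first
#' step of numt discovery. The search is delegated to the `blastn` executable
#' (task `blastn`, exact-match seeds of `word_size`, both strands, gapped
#' extension) and parsed into the package's homology-hit table. A circular
#' mitogenome is handled by appending its first `word_size - 1` bases to the
#' query; hits spanning the origin are split at position 1 and reported as
#' two mitochondrial intervals.
#'
#' @param mito A [seq_record()] for the mitogenome (set `circular = TRUE` to
#'   enable origin-spanning hits) or a single-record FASTA path.
#' @param nuclear A list of [seq_record()]s, a named character vector, or a
#'   FASTA path for the nuclear assembly.
#' @param word_size Exact-match seed length (default 20).
#' @param e_cutoff E-value cutoff (default 0.01).
#' @param task `"blastn"` (word_size honoured, sensitive) or `"megablast"`
#'   (the blastn executable's default mode, used for cross-genome profiling).
#' @return A data frame of class `numt_hits` with columns `nuclear_scaffold`,
#'   `nuclear_start`, `nuclear_end` (1-based inclusive), `strand`,
#'   `mito_start`, `mito_end`, `percent_identity`, `aligned_length`,
#'   `bit_score`, `e_value`, sorted by descending bit score. A self-scan of
#'   the mitogenome therefore returns the full-length self-hit first.
#' @export
scan_numts <- function(mito, nuclear, word_size = 20L, e_cutoff = 0.01,
                       task = c("blastn", "megablast")) {
  task <- match.arg(task)
  if (word_size < 4L) stop("word_size must be >= 4")
  mito <- as_single_record(mito, circular_default = TRUE)
  nuclear <- if (is.character(nuclear) && length(nuclear) == 1L &&
                 file.exists(nuclear)) read_fasta(nuclear) else as_seq_records(nuclear)
  if (length(nuclear) == 0L) return(empty_hits())

  L <- nchar(mito$seq)
  qseq <- mito$seq
  if (isTRUE(mito$circular) && L > word_size)
    qseq <- paste0(qseq, substr(mito$seq, 1L, word_size - 1L))

  raw <- run_blastn(query = stats::setNames(qseq, mito$id), subject = nuclear,
                    word_size = word_size, evalue = e_cutoff, task = task)
  if (nrow(raw) == 0L) return(empty_hits())
  hits <- normalise_hits(raw, mito_len = L, circular = isTRUE(mito$circular))
  hits <- hits[order(-hits$bit_score, hits$nuclear_scaffold, hits$nuclear_start), ,
               drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("numt_hits", "data.frame")
  hits
}

as_single_record <- function(x, circular_default = FALSE) {
  if (inherits(x, "seq_record")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    recs <- read_fasta(x, circular = circular_default)
    if (length(recs) != 1L) stop("expected a single-record FASTA: ", x)
    return(recs[[1L]])
  }
  if (is.character(x) && length(x) == 1L) return(seq_record("query", x, circular_default))
  stop("cannot interpret input as a single sequence record")
}

empty_hits <- function() {
  out <- data.frame(nuclear_scaffold = character(), nuclear_start = integer(),
                    nuclear_end = integer(), strand = character(),
                    mito_start = integer(), mito_end = integer(),
                    percent_identity = numeric(), aligned_length = integer(),
                    bit_score = numeric(), e_value = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("numt_hits", "data.frame")
  out
}

run_blastn <- function(query, subject, word_size, evalue, task) {
  bl <- Sys.which("blastn"); mk <- Sys.which("makeblastdb")
  if (!nzchar(bl) || !nzchar(mk))
    stop("blastn/makeblastdb not found on PATH; the homology scan requires BLAST+")
  dir <- tempfile("numtscan"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  qfa <- file.path(dir, "query.fa"); sfa <- file.path(dir, "subject.fa")
  write_fasta(query, qfa)
  write_fasta(subject, sfa)
  db <- file.path(dir, "db")
  out <- file.path(dir, "hits.tsv")
  system2(mk, c("-in", sfa, "-dbtype", "nucl", "-out", db),
          stdout = FALSE, stderr = FALSE)
  args <- c("-query", qfa, "-db", db, "-evalue", format(evalue, scientific = FALSE),
            "-task", task, "-dust", "no", "-soft_masking", "false",
            "-outfmt", shQuote("6 sseqid sstart send qstart qend pident length bitscore evalue"),
            "-out", out)
  if (task == "blastn") args <- c(args, "-word_size", as.character(word_size))
  status <- system2(bl, args, stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L)) stop("blastn failed with status ", status)
  if (!file.size(out)) return(data.frame())
  utils::read.table(out, sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("sseqid", "sstart", "send", "qstart", "qend",
                                  "pident", "length", "bitscore", "evalue"))
}

normalise_hits <- function(raw, mito_len, circular) {
  minus <- raw$sstart > raw$send
  hits <- data.frame(
    nuclear_scaffold = as.character(raw$sseqid),
    nuclear_start = as.integer(pmin(raw$sstart, raw$send)),
    nuclear_end = as.integer(pmax(raw$sstart, raw$send)),
    strand = ifelse(minus, "-", "+"),
    mito_start = as.integer(raw$qstart),
    mito_end = as.integer(raw$qend),
    percent_identity = raw$pident,
    aligned_length = as.integer(raw$length),
    bit_score = raw$bitscore,
    e_value = raw$evalue,
    stringsAsFactors = FALSE)
  if (!circular) return(hits)
  # drop hits living entirely in the wrap-around extension (re-found at origin)
  keep <- hits$mito_start <= mito_len
  hits <- hits[keep, , drop = FALSE]
  spans <- which(hits$mito_end > mito_len)
  if (!length(spans)) return(hits)
  extra <- vector("list", length(spans))
  for (k in seq_along(spans)) {
    i <- spans[k]
    h <- hits[i, , drop = FALSE]
    len1 <- mito_len - h$mito_start + 1L
    # split nuclear interval at the matching offset (collinear approximation)
    h1 <- h; h2 <- h
    h1$mito_end <- mito_len
    h2$mito_start <- 1L; h2$mito_end <- h$mito_end - mito_len
    if (h$strand == "+") {
      h1$nuclear_end <- h$nuclear_start + len1 - 1L
      h2$nuclear_start <- h$nuclear_start + len1
    } else {
      h1$nuclear_start <- h$nuclear_end - len1 + 1L
      h2$nuclear_end <- h$nuclear_end - len1
    }
    h1$aligned_length <- len1
    h2$aligned_length <- h$aligned_length - len1
    hits[i, ] <- h1
    extra[[k]] <- h2
  }
  rbind(hits, do.call(rbind, extra))
}

#' Filter homology hits by aligned length
#'
#' Retains hits strictly longer than `min_length` aligned bases (the numt
#' definition threshold: matches longer than 200 bp count as putative numts).
#'
#' @param hits A `numt_hits` data frame from [scan_numts()].
#' @param min_length Length threshold in bp; the comparison is strict (>).
#' @return The filtered `numt_hits` data frame.
#' @export
filter_hits <- function(hits, min_length = 200L) {
  out <- hits[hits$aligned_length > min_length, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("numt_hits", "data.frame")
  out
}

#' Cluster numt fragments into numts
#'
#' Single-linkage clustering of homology hits on each nuclear scaffold:
#' fragments whose nuclear intervals lie within `max_gap` bases of one
#' another (gap counted as intervening bases between nearest fragment ends)
#' belong to one numt, irrespective of strand or mitochondrial origin.
#' Numts are numbered in genome order (scaffold, then start); fragments
#' within a numt are ordered by nuclear start.
#'
#' @param hits A `numt_hits` data frame.
#' @param max_gap Maximum intervening gap in bp (default 10000).
#' @return An object of class `numt_set`: a list of numts, each with `id`,
#'   `scaffold`, `span_start`, `span_end`, `n_fragments`, `total_length`
#'   (sum of fragment lengths), `mito_coords` and a `fragments` data frame.
#' @export
cluster_fragments <- function(hits, max_gap = 10000L) {
  if (nrow(hits) == 0L) {
    out <- structure(list(), class = "numt_set")
    return(out)
  }
  hits <- hits[order(hits$nuclear_scaffold, hits$nuclear_start, hits$nuclear_end,
                     hits$mito_start), , drop = FALSE]
  numts <- list()
  for (sc in sort(unique(hits$nuclear_scaffold))) {
    h <- hits[hits$nuclear_scaffold == sc, , drop = FALSE]
    grp <- integer(nrow(h)); g <- 1L; grp[1L] <- 1L
    cur_end <- h$nuclear_end[1L]
    if (nrow(h) > 1L) for (i in 2L:nrow(h)) {
      gap <- h$nuclear_start[i] - cur_end - 1L
      if (gap > max_gap) { g <- g + 1L; cur_end <- h$nuclear_end[i] }
      else cur_end <- max(cur_end, h$nuclear_end[i])
      grp[i] <- g
    }
    for (gi in seq_len(max(grp))) {
      fr <- h[grp == gi, , drop = FALSE]
      rownames(fr) <- NULL
      numts[[length(numts) + 1L]] <- list(
        scaffold = sc,
        span_start = min(fr$nuclear_start), span_end = max(fr$nuclear_end),
        n_fragments = nrow(fr),
        total_length = sum(fr$nuclear_end - fr$nuclear_start + 1L),
        mito_coords = paste(sprintf("%d-%d", fr$mito_start, fr$mito_end),
                            collapse = "; "),
        strand = if (all(fr$strand == "+")) "+" else if (all(fr$strand == "-")) "-" else ".",
        fragments = fr)
    }
  }
  ord <- order(vapply(numts, `[[`, "", "scaffold"),
               vapply(numts, `[[`, 0, "span_start"))
  numts <- numts[ord]
  for (i in seq_along(numts)) numts[[i]]$id <- i
  structure(numts, class = "numt_set")
}

#' @export
print.numt_set <- function(x, ...) {
  cat("<numt_set>", length(x), "numts,",
      sum(vapply(x, `[[`, 0L, "n_fragments")), "fragments\n")
  if (length(x)) print(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' @export
as.data.frame.numt_set <- function(x, ...) {
  if (!length(x)) {
    return(data.frame(id = integer(), scaffold = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_fragments = integer(), length = integer(),
                      total_length = integer(), mito_coords = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    id = vapply(x, `[[`, 0L, "id"),
    scaffold = vapply(x, `[[`, "", "scaffold"),
    start = vapply(x, function(n) as.integer(n$span_start), 0L),
    end = vapply(x, function(n) as.integer(n$span_end), 0L),
    strand = vapply(x, `[[`, "", "strand"),
    n_fragments = vapply(x, `[[`, 0L, "n_fragments"),
    length = vapply(x, function(n) as.integer(n$span_end - n$span_start + 1L), 0L),
    total_length = vapply(x, function(n) as.integer(n$total_length), 0L),
    mito_coords = vapply(x, `[[`, "", "mito_coords"),
    stringsAsFactors = FALSE)
}

#' Cross-genome conservation profile of a numt
#'
#' Searches a numt sequence against another genome (blastn defaults,
#' E-value cutoff 0.01) and summarises the result as the percentage of the
#' query covered by retained hits and the percent identity of the top
#' (highest bit score) hit. No hit gives (0, 0). High query cover indicates
#' a homologous region in the subject genome; its identity dates the
#' insertion relative to the species split.
#'
#' @param numt_seq The numt sequence (character or [seq_record()]).
#' @param subject_genome Subject genome: list of [seq_record()]s, named
#'   character vector, or FASTA path.
#' @param e_cutoff E-value cutoff (default 0.01).
#' @param task blastn task; `"megablast"` is the executable's default.
#' @return A list with `query_cover` and `top_hit_identity`, both in [0, 100].
#' @export
profile_conservation <- function(numt_seq, subject_genome, e_cutoff = 0.01,
                                 task = c("megablast", "blastn")) {
  task <- match.arg(task)
  q <- as_single_record(numt_seq)
  hits <- scan_numts(seq_record(q$id, q$seq, circular = FALSE), subject_genome,
                     word_size = if (task == "blastn") 11L else 28L,
                     e_cutoff = e_cutoff, task = task)
  if (nrow(hits) == 0L)
    return(list(query_cover = 0, top_hit_identity = 0))
  iv <- IRanges::reduce(IRanges::IRanges(hits$mito_start, hits$mito_end))
  cover <- 100 * sum(IRanges::width(iv)) / nchar(q$seq)
  list(query_cover = min(cover, 100),
       top_hit_identity = hits$percent_identity[which.max(hits$bit_score)])
}
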