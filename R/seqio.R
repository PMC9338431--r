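#' Sequence records
#'
#' The package passes sequences around as `seq_record` objects: a record id,
#' an uppercase DNA string over A/C/G/T/N, and a circularity flag (relevant
#' for mitogenomes, where homology hits may span the origin).
#'
#' @param id Record identifier (non-empty string, no whitespace-only).
#' @param seq DNA string; uppercased on construction.
#' @param circular Logical; is the molecule circular?
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, seq, circular = FALSE) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (!nzchar(id)) stop("seq_record: empty id")
  if (!nzchar(seq)) stop("seq_record: empty sequence for record '", id, "'")
  if (grepl("[^ACGTN]", seq)) stop("seq_record '", id, "': characters outside {A,C,G,T,N}")
  structure(list(id = id, seq = seq, circular = isTRUE(circular)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat("<seq_record>", x$id, paste0("(", nchar(x$seq), " bp",
      if (x$circular) ", circular", ")"), "\n")
  invisible(x)
}

#' Read a FASTA file
#'
#' Parses a (wrapped or unwrapped) multi-record FASTA file into a list of
#' [seq_record()]s. Record ids are the first whitespace-delimited token of
#' each header. Duplicate ids and empty sequences are errors naming the
#' offending record.
#'
#' @param path Path to a FASTA file.
#' @param circular Logical, recycled over records; marks molecules circular.
#' @return A named list of `seq_record` objects.
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate FASTA ids in '", path, "': ",
                        paste(dup, collapse = ", "))
  circular <- rep_len(circular, length(set))
  recs <- lapply(seq_along(set), function(i) {
    s <- as.character(set[[i]])
    if (!nzchar(s)) stop("empty sequence for record '", ids[i], "' in '", path, "'")
    seq_record(ids[i], s, circular[i])
  })
  names(recs) <- ids
  recs
}

#' Write records to FASTA
#'
#' @param records A list of [seq_record()]s (or a named character vector).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  records <- as_seq_records(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$id), con)
    s <- r$seq
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

as_seq_records <- function(x) {
  if (inherits(x, "seq_record")) return(stats::setNames(list(x), x$id))
  if (is.character(x)) {
    if (is.null(names(x))) stop("character sequences must be named")
    return(stats::setNames(
      lapply(names(x), function(n) seq_record(n, x[[n]])), names(x)))
  }
  if (is.list(x)) {
    stopifnot(all(vapply(x, inherits, TRUE, "seq_record")))
    return(stats::setNames(x, vapply(x, `[[`, "", "id")))
  }
  stop("cannot interpret input as sequence records")
}

#' Write numt intervals to BED, GFF3 or TSV
#'
#' Nuclear coordinates are held 1-based inclusive throughout the package
#' (BLAST convention). BED output converts to 0-based half-open; GFF3 and the
#' TSV report stay 1-based inclusive. The TSV mirrors the standard numt
#' summary table: scaffold, start, end, chromosome label, fragment count,
#' total numt length and the mitochondrial coordinates of each fragment.
#' Writers are deterministic: rows sorted by scaffold then start.
#'
#' @param numts A `numt_set` from [cluster_fragments()], or a data frame with
#'   columns `scaffold`, `start`, `end` and optionally `id`, `strand`,
#'   `n_fragments`, `length`, `mito_coords`, `chromosome`.
#' @param path Output path.
#' @param format One of `"BED"`, `"GFF3"`, `"TSV"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(numts, path, format = c("BED", "GFF3", "TSV")) {
  if (length(format) == 1L && !toupper(format) %in% c("BED", "GFF3", "TSV"))
    stop("unknown format '", format, "'; supported: BED, GFF3, TSV")
  format <- toupper(match.arg(format))
  df <- as_interval_df(numts)
  df <- df[order(df$scaffold, df$start, df$end), , drop = FALSE]
  lines <- switch(format,
    BED = sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                  df$scaffold, df$start - 1L, df$end, df$id, 0L, df$strand),
    GFF3 = c("##gff-version 3",
             sprintf("%s\tnumtforge\tnumt\t%d\t%d\t.\t%s\t.\tID=%s",
                     df$scaffold, df$start, df$end, df$strand, df$id)),
    TSV = c(paste(c("numt_id", "scaffold", "start", "end", "chromosome",
                    "n_fragments", "numt_length", "mito_coordinates"),
                  collapse = "\t"),
            sprintf("%s\t%s\t%d\t%d\t%s\t%d\t%d\t%s",
                    df$id, df$scaffold, df$start, df$end, df$chromosome,
                    df$n_fragments, df$length, df$mito_coords)))
  writeLines(lines, path)
  invisible(path)
}

as_interval_df <- function(numts) {
  df <- if (inherits(numts, "numt_set")) as.data.frame(numts) else as.data.frame(numts)
  need <- c("scaffold", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("interval table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(df$id)) df$id <- paste0("numt_", seq_len(nrow(df)))
  if (is.null(df$strand)) df$strand <- "+"
  if (is.null(df$n_fragments)) df$n_fragments <- 1L
  if (is.null(df$length)) df$length <- df$end - df$start + 1L
  if (is.null(df$mito_coords)) df$mito_coords <- "."
  if (is.null(df$chromosome)) df$chromosome <- df$scaffold
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  stopifnot(all(df$start <= df$end))
  df
}
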