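#' Genetic-code tables
#'
#' Returns a genetic code as used throughout the package: a full 64-codon
#' translation table plus its stop-codon set. Two codes are provided, the
#' standard nuclear code and the vertebrate mitochondrial code. They differ at
#' exactly four codons: ATA (Ile vs Met), TGA (stop vs Trp) and AGA/AGG
#' (Arg vs stop). These differences are what create premature stop codons when
#' a mitochondrial gene is read under the nuclear code after insertion into
#' the nuclear genome.
#'
#' @param name `"standard"` or `"vertebrate_mito"` (aliases: `"nuclear"`,
#'   `"mito"`).
#' @return An object of class `genetic_code`: a list with elements `name`,
#'   `table` (named character vector of 64 codons to one-letter amino acids,
#'   stops as `"*"`) and `stops` (character vector of stop codons).
#' @examples
#' gc <- genetic_code("vertebrate_mito")
#' gc$table[["TGA"]]   # "W"
#' gc$stops            # TAA TAG AGA AGG
#' @export
genetic_code <- function(name = c("standard", "vertebrate_mito", "nuclear", "mito")) {
  name <- match.arg(name)
  canonical <- switch(name,
    standard = "standard", nuclear = "standard",
    vertebrate_mito = "vertebrate_mito", mito = "vertebrate_mito")
  id <- if (canonical == "standard") "1" else "2"
  tab <- Biostrings::getGeneticCode(id)
  tab <- stats::setNames(as.character(tab), names(tab))
  stopifnot(length(tab) == 64L)
  out <- structure(
    list(name = canonical, table = tab, stops = names(tab)[tab == "*"]),
    class = "genetic_code")
  out
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code>", x$name, "\n")
  cat("  stop codons:", paste(x$stops, collapse = " "), "\n")
  invisible(x)
}

is_genetic_code <- function(x) inherits(x, "genetic_code")

as_genetic_code <- function(code) {
  if (is_genetic_code(code)) return(code)
  if (is.character(code) && length(code) == 1L) return(genetic_code(code))
  stop("`code` must be a genetic_code object or a code name")
}

#' Translate a DNA sequence
#'
#' Translates `seq` in the given reading frame under a genetic code. Stop
#' codons are rendered as `"*"`; any codon containing a character outside
#' A/C/G/T (e.g. N) becomes `"X"`; a trailing incomplete codon is dropped.
#'
#' @param seq A DNA string (character scalar, case-insensitive).
#' @param code A [genetic_code()] object or code name.
#' @param frame Offset 0, 1 or 2: translation starts at position `frame + 1`.
#' @return The protein as a single character string.
#' @examples
#' translate_dna("ATA", "vertebrate_mito")  # "M"
#' translate_dna("ATA", "standard")         # "I"
#' translate_dna("AGAAGG", "vertebrate_mito")  # "**"
#' @export
translate_dna <- function(seq, code = genetic_code("standard"), frame = 0L) {
  code <- as_genetic_code(code)
  if (!frame %in% 0:2) stop("`frame` must be 0, 1 or 2")
  s <- toupper(as.character(seq))
  s <- substr(s, frame + 1L, nchar(s))
  n_codons <- nchar(s) %/% 3L
  if (n_codons == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n_codons)
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(code$table[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Split a DNA string into codons
#'
#' @param seq DNA string whose length is a multiple of 3.
#' @return Character vector of codons.
#' @keywords internal
split_codons <- function(seq) {
  s <- toupper(as.character(seq))
  if (nchar(s) %% 3L != 0L) stop("sequence length is not a multiple of 3")
  starts <- seq.int(1L, nchar(s), by = 3L)
  substring(s, starts, starts + 2L)
}

#' Reverse complement
#'
#' @param seq DNA string.
#' @return The reverse complement as a character string.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}
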