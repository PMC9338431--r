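#' In-frame pairwise codon alignment
#'
#' Container for a gap-free, equal-length, in-frame pair of coding sequences
#' to be compared by [pairwise_dnds()]. Sequence `a` is the reference (a
#' functional mitochondrial gene) and must contain no internal stop codon
#' under `code`; a terminal stop is allowed and is dropped from the
#' comparison.
#'
#' @param seq_a,seq_b Equal-length gap-free DNA strings, length a multiple
#'   of 3.
#' @param code Genetic code ([genetic_code()] object or name); default
#'   vertebrate mitochondrial.
#' @param gene_id Label.
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(seq_a, seq_b, code = genetic_code("vertebrate_mito"),
                            gene_id = "gene") {
  code <- as_genetic_code(code)
  a <- toupper(as.character(seq_a)); b <- toupper(as.character(seq_b))
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  if (nchar(a) %% 3L != 0L) stop("alignment length must be a multiple of 3")
  if (grepl("-", a, fixed = TRUE) || grepl("-", b, fixed = TRUE))
    stop("codon_alignment must be gap-free")
  ca <- split_codons(a); cb <- split_codons(b)
  # drop a shared terminal stop codon (reference's own stop is not data)
  n <- length(ca)
  if (n > 0L && code$table[ca[n]] == "*") { ca <- ca[-n]; cb <- cb[-n] }
  internal <- which(code$table[ca] == "*")
  if (length(internal))
    stop("reference sequence has internal stop codon(s) at codon ",
         paste(internal, collapse = ", "))
  structure(list(gene_id = gene_id, codons_a = ca, codons_b = cb, code = code),
            class = "codon_alignment")
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Nei-Gojobori (1986) style site counting: each codon position contributes
#' the fraction of its possible single-nucleotide changes that are
#' synonymous. Changes producing a stop codon are excluded from the
#' denominator at that position, so the three positions always sum to 3
#' sites (syn + nonsyn).
#'
#' @param codon A sense codon (3-letter string).
#' @param code Genetic code.
#' @return Named numeric vector `c(syn, nonsyn)`.
#' @examples
#' count_sites("TTT", genetic_code("standard"))  # syn 1/3, nonsyn 8/3
#' @export
count_sites <- function(codon, code = genetic_code("standard")) {
  code <- as_genetic_code(code)
  codon <- toupper(codon)
  aa <- code$table[codon]
  if (is.na(aa)) stop("invalid codon: ", codon)
  if (aa == "*") stop("count_sites: stop codon input (", codon, ")")
  bases <- c("A", "C", "G", "T")
  syn <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    n_syn <- 0L; n_valid <- 0L
    for (bb in setdiff(bases, ref)) {
      mut <- codon
      substr(mut, pos, pos) <- bb
      maa <- code$table[mut]
      if (maa == "*") next
      n_valid <- n_valid + 1L
      if (maa == aa) n_syn <- n_syn + 1L
    }
    if (n_valid > 0L) syn <- syn + n_syn / n_valid
  }
  c(syn = syn, nonsyn = 3 - syn)
}

# all stop-free single-step paths between two codons; returns per-path
# (syn, nonsyn) step counts. Endpoints are assumed sense codons.
codon_paths <- function(ca, cb, code) {
  diffpos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  k <- length(diffpos)
  if (k == 0L) return(matrix(0, 1, 2, dimnames = list(NULL, c("syn", "nonsyn"))))
  perms <- if (k == 1L) list(diffpos) else {
    idx <- permutations_of(k)
    lapply(seq_len(nrow(idx)), function(i) diffpos[idx[i, ]])
  }
  out <- list()
  for (ord in perms) {
    cur <- ca; syn <- 0L; nonsyn <- 0L; ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(cb, pos, pos)
      aa1 <- code$table[cur]; aa2 <- code$table[nxt]
      if (aa2 == "*" && nxt != cb) { ok <- FALSE; break }  # stop intermediate
      if (aa2 == "*") { ok <- FALSE; break }               # stop endpoint guarded upstream
      if (aa1 == aa2) syn <- syn + 1L else nonsyn <- nonsyn + 1L
      cur <- nxt
    }
    if (ok) out[[length(out) + 1L]] <- c(syn = syn, nonsyn = nonsyn)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L))
  sub <- permutations_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Count synonymous and nonsynonymous substitutions in a codon alignment
#'
#' Codon pairs differing at one position are classified directly. Pairs
#' differing at 2-3 positions are averaged over all orderings of single
#' steps that avoid stop codons (NG86 pathway averaging). Alongside the
#' fractional averaged counts, integer "minimal-path" counts are reported
#' (the stop-free path maximising the number of synonymous steps), the form
#' in which substitution counts are conventionally tabulated. Codon pairs
#' where every path passes through a stop, or where either codon is itself
#' a stop, are excluded and counted in `n_excluded`.
#'
#' @param aln A [codon_alignment()].
#' @return A list with `syn_subs`, `nonsyn_subs` (pathway-averaged),
#'   `syn_subs_int`, `nonsyn_subs_int` (max-synonymous path), `n_codons`
#'   (codons used) and `n_excluded`.
#' @export
count_substitutions <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  code <- aln$code
  Sd <- 0; Nd <- 0; Sdi <- 0L; Ndi <- 0L; used <- 0L; excluded <- 0L
  for (i in seq_along(aln$codons_a)) {
    ca <- aln$codons_a[i]; cb <- aln$codons_b[i]
    if (is.na(code$table[ca]) || is.na(code$table[cb]) ||
        code$table[ca] == "*" || code$table[cb] == "*") { excluded <- excluded + 1L; next }
    paths <- codon_paths(ca, cb, code)
    if (is.null(paths)) { excluded <- excluded + 1L; next }
    used <- used + 1L
    Sd <- Sd + mean(paths[, "syn"]); Nd <- Nd + mean(paths[, "nonsyn"])
    best <- which.max(paths[, "syn"])
    Sdi <- Sdi + paths[best, "syn"]; Ndi <- Ndi + paths[best, "nonsyn"]
  }
  list(syn_subs = Sd, nonsyn_subs = Nd,
       syn_subs_int = as.integer(Sdi), nonsyn_subs_int = as.integer(Ndi),
       n_codons = used, n_excluded = excluded)
}

#' Pairwise dN/dS by Nei-Gojobori counting
#'
#' Computes synonymous and nonsynonymous site counts (averaged over the two
#' sequences), pathway-averaged substitution counts, Jukes-Cantor-corrected
#' rates dS and dN, their ratio omega, and a Fisher exact test of the 2x2
#' substitutions-vs-sites table. omega < 1 indicates purifying selection,
#' omega about 1 neutral fixation, omega > 1 positive selection. When the
#' proportion of differences at synonymous or nonsynonymous sites reaches
#' 3/4 the correction diverges; the corresponding rate is returned as `NA`
#' with `saturated = TRUE` rather than infinity. With zero observed
#' substitutions, dN = dS = 0, omega is undefined (`NA`) and p = 1.
#'
#' @param aln A [codon_alignment()] (at least 10 codons).
#' @return An object of class `substitution_summary`.
#' @export
pairwise_dnds <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (length(aln$codons_a) < 10L) stop("need at least 10 codons")
  code <- aln$code
  subs <- count_substitutions(aln)
  S <- 0; N <- 0
  for (i in seq_along(aln$codons_a)) {
    ca <- aln$codons_a[i]; cb <- aln$codons_b[i]
    if (code$table[ca] == "*" || code$table[cb] == "*" ||
        is.na(code$table[ca]) || is.na(code$table[cb])) next
    if (is.null(codon_paths(ca, cb, code))) next
    sa <- count_sites(ca, code); sb <- count_sites(cb, code)
    S <- S + (sa["syn"] + sb["syn"]) / 2
    N <- N + (sa["nonsyn"] + sb["nonsyn"]) / 2
  }
  S <- unname(S); N <- unname(N)
  pS <- if (S > 0) subs$syn_subs / S else 0
  pN <- if (N > 0) subs$nonsyn_subs / N else 0
  jc <- function(p) {
    if (p == 0) return(0)
    if (p < 3 / 4) -3 / 4 * log(1 - 4 * p / 3) else NA_real_
  }
  dS <- jc(pS); dN <- jc(pN)
  saturated <- is.na(dS) || is.na(dN)
  no_subs <- subs$syn_subs + subs$nonsyn_subs == 0
  omega <- if (no_subs || saturated || is.na(dS) || dS <= 0) NA_real_ else dN / dS
  p_value <- if (no_subs) 1 else {
    tab <- rbind(c(round(subs$syn_subs), round(max(S - subs$syn_subs, 0))),
                 c(round(subs$nonsyn_subs), round(max(N - subs$nonsyn_subs, 0))))
    stats::fisher.test(tab)$p.value
  }
  structure(list(
    gene_id = aln$gene_id, syn_sites = unname(S), nonsyn_sites = unname(N),
    syn_subs = subs$syn_subs, nonsyn_subs = subs$nonsyn_subs,
    syn_subs_int = subs$syn_subs_int, nonsyn_subs_int = subs$nonsyn_subs_int,
    dN = dN, dS = dS, omega = omega, p_value = p_value,
    n_codons = subs$n_codons, n_excluded = subs$n_excluded,
    saturated = saturated), class = "substitution_summary")
}

#' @export
print.substitution_summary <- function(x, ...) {
  cat("<substitution_summary>", x$gene_id, "\n")
  cat(sprintf("  sites: S = %.2f, N = %.2f over %d codons (%d excluded)\n",
              x$syn_sites, x$nonsyn_sites, x$n_codons, x$n_excluded))
  cat(sprintf("  substitutions: syn %.2f (int %d), nonsyn %.2f (int %d)\n",
              x$syn_subs, x$syn_subs_int, x$nonsyn_subs, x$nonsyn_subs_int))
  fmt <- function(v) if (is.na(v)) "-" else sprintf("%.4f", v)
  cat(sprintf("  dN = %s, dS = %s, dN/dS = %s, P = %s%s\n",
              fmt(x$dN), fmt(x$dS), fmt(x$omega), fmt(x$p_value),
              if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Table of pairwise dN/dS summaries
#'
#' @param summaries A list of `substitution_summary` objects.
#' @return A data frame with one row per gene, mirroring the standard
#'   per-gene dN/dS report (integer substitution counts, dN, dS, omega, P).
#' @export
dnds_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(x) {
    data.frame(gene = x$gene_id,
               syn_substitutions = x$syn_subs_int,
               nonsyn_substitutions = x$nonsyn_subs_int,
               dN = x$dN, dS = x$dS, dN_dS = x$omega, p_value = x$p_value,
               saturated = x$saturated, stringsAsFactors = FALSE)
  }))
}
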