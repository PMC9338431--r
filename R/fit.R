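#' Codon model specifications
#'
#' Constructs a model specification for [fit_codon_model()]. Supported
#' kinds, following the standard branch/site/clade codon-model families:
#'
#' * `one_ratio`: a single omega over the whole tree.
#' * `two_ratio`: separate omegas for the numt clade and the background.
#' * `two_ratio_fixed`: background omega free, numt omega fixed at 1
#'   (neutral evolution of the numt clade).
#' * `M1a`: two site classes, purifying (0 < omega0 < 1) and neutral
#'   (omega = 1), no branch structure.
#' * `M2a`: M1a plus a third, unrestricted site class (also known as the
#'   three-class positive-selection site model).
#' * `cladeC`: three site classes; classes 1 (purifying, shared) and 2
#'   (neutral, shared) are common to both branch partitions, class 3 has
#'   independent omegas for background and numt branches.
#' * `cladeC_fixed`: clade model C with the numt omega of class 3 fixed at 1.
#'
#' @param kind Model kind (see above).
#' @param frequencies Codon frequency scheme: `"F3x4"` (default), `"F1x4"`
#'   or `"equal"`.
#' @param code Genetic code name or object (default vertebrate
#'   mitochondrial).
#' @return An object of class `codon_model_spec`.
#' @export
codon_model <- function(kind = c("one_ratio", "two_ratio", "two_ratio_fixed",
                                 "M1a", "M2a", "cladeC", "cladeC_fixed"),
                        frequencies = c("F3x4", "F1x4", "equal"),
                        code = "vertebrate_mito") {
  kind <- match.arg(kind)
  frequencies <- match.arg(frequencies)
  structure(list(kind = kind, frequencies = frequencies,
                 code = as_genetic_code(code)),
            class = "codon_model_spec")
}

#' @export
print.codon_model_spec <- function(x, ...) {
  cat("<codon_model_spec>", x$kind, "| frequencies:", x$frequencies,
      "| code:", x$code$name, "\n")
  invisible(x)
}

# per-kind parameter layout: omega parameters (with bounds) and number of
# free mixture proportions; builders map a named parameter list to the
# `classes` data frame consumed by codon_log_likelihood()
model_layout <- function(kind) {
  cls <- function(p, wb, wn) data.frame(proportion = p, omega_background = wb,
                                        omega_numt = wn)
  switch(kind,
    one_ratio = list(
      omega_names = "omega", omega_upper = 50, n_prop = 0L, partition = FALSE,
      build = function(w, p) cls(1, w[["omega"]], w[["omega"]])),
    two_ratio = list(
      omega_names = c("omega_background", "omega_numt"), omega_upper = c(50, 50),
      n_prop = 0L, partition = TRUE,
      build = function(w, p) cls(1, w[["omega_background"]], w[["omega_numt"]])),
    two_ratio_fixed = list(
      omega_names = "omega_background", omega_upper = 50, n_prop = 0L,
      partition = TRUE,
      build = function(w, p) cls(1, w[["omega_background"]], 1)),
    M1a = list(
      omega_names = "omega0", omega_upper = 1, n_prop = 1L, partition = FALSE,
      build = function(w, p) cls(c(p[1], 1 - p[1]), c(w[["omega0"]], 1),
                                 c(w[["omega0"]], 1))),
    M2a = list(
      omega_names = c("omega0", "omega2"), omega_upper = c(1, 50), n_prop = 2L,
      partition = FALSE,
      build = function(w, p) cls(p, c(w[["omega0"]], 1, w[["omega2"]]),
                                 c(w[["omega0"]], 1, w[["omega2"]]))),
    cladeC = list(
      omega_names = c("omega0", "omega3_background", "omega3_numt"),
      omega_upper = c(1, 50, 50), n_prop = 2L, partition = TRUE,
      build = function(w, p) cls(p, c(w[["omega0"]], 1, w[["omega3_background"]]),
                                 c(w[["omega0"]], 1, w[["omega3_numt"]]))),
    cladeC_fixed = list(
      omega_names = c("omega0", "omega3_background"), omega_upper = c(1, 50),
      n_prop = 2L, partition = TRUE,
      build = function(w, p) cls(p, c(w[["omega0"]], 1, w[["omega3_background"]]),
                                 c(w[["omega0"]], 1, 1))),
    stop("unknown model kind: ", kind))
}

# number of free parameters excluding branch lengths (kappa + omegas + props)
n_free_params <- function(kind) {
  lay <- model_layout(kind)
  1L + length(lay$omega_names) + lay$n_prop
}

softmax_props <- function(a) {
  z <- exp(c(a, 0) - max(c(a, 0)))
  z / sum(z)
}

#' Fit a codon substitution model by maximum likelihood
#'
#' Fits a GY94-family codon model on a fixed tree topology, maximising the
#' pruning log-likelihood over kappa, the model's omega parameters, site
#' class proportions (via a softmax reparameterisation) and all branch
#' lengths (free per branch, which absorbs rate differences between the
#' nuclear and mitochondrial partitions). Optimisation is bounded
#' quasi-Newton (L-BFGS-B on log-transformed parameters; omega in
#' [1e-6, 50], kappa in [0.05, 100], branch lengths in [1e-8, 20]) with
#' seeded multi-start; the best of `n_restarts` starts is returned.
#'
#' @param tree `ape::phylo` with starting edge lengths; for partition models
#'   either carrying `branch.class` or supplied with `numt_taxa`.
#' @param seqs Aligned in-frame sequences named by tip label.
#' @param model A kind string or [codon_model()] spec.
#' @param numt_taxa Optional tip labels of the numt clade (used to label
#'   branches via [label_numt_clade()] when the tree is unlabelled).
#' @param n_restarts Number of optimisation starts (>= 1; default 3).
#' @param seed Integer seed controlling the restart jitter.
#' @param control List: `factr` (L-BFGS-B tolerance, default 1e7) and
#'   `maxit` (default 500).
#' @return An object of class `codon_fit` with the fitted parameters, the
#'   log-likelihood, the tree with fitted branch lengths, and convergence
#'   diagnostics. Methods: `print`, `summary`, `coef`, `logLik`.
#' @export
fit_codon_model <- function(tree, seqs, model = "one_ratio", numt_taxa = NULL,
                            n_restarts = 3L, seed = 1L, control = list()) {
  spec <- if (inherits(model, "codon_model_spec")) model else codon_model(model)
  lay <- model_layout(spec$kind)
  if (lay$partition && is.null(tree$branch.class)) {
    if (is.null(numt_taxa))
      stop("model '", spec$kind, "' needs branch labels: supply numt_taxa ",
           "or a tree from label_numt_clade()")
    tree <- label_numt_clade(tree, numt_taxa)
  }
  recs <- as_seq_records(seqs)
  code <- spec$code
  pi <- unname(codon_frequencies(recs, spec$frequencies, code))
  states <- codon_state_matrix(recs, code)
  info <- tree_info(tree)
  if (!setequal(rownames(states), info$tip.label))
    stop("alignment taxa do not match tree tip labels")
  states <- states[info$tip.label, , drop = FALSE]
  cp <- compress_patterns(states)
  n_edge <- nrow(info$edge)
  n_omega <- length(lay$omega_names)

  # parameter vector: log kappa | log omegas | prop logits | log branch lens
  idx_kappa <- 1L
  idx_omega <- if (n_omega) 1L + seq_len(n_omega) else integer()
  idx_prop <- if (lay$n_prop) 1L + n_omega + seq_len(lay$n_prop) else integer()
  idx_bl <- 1L + n_omega + lay$n_prop + seq_len(n_edge)
  lower <- c(log(0.05), rep(log(1e-6), n_omega), rep(-12, lay$n_prop),
             rep(log(1e-8), n_edge))
  upper <- c(log(100), log(lay$omega_upper), rep(12, lay$n_prop),
             rep(log(20), n_edge))

  unpack <- function(par) {
    w <- stats::setNames(exp(par[idx_omega]), lay$omega_names)
    p <- if (lay$n_prop) softmax_props(par[idx_prop]) else 1
    list(kappa = exp(par[idx_kappa]), omegas = w,
         proportions = p, classes = lay$build(as.list(w), p),
         bl = exp(par[idx_bl]))
  }
  nll <- function(par) {
    pr <- unpack(par)
    inf2 <- info
    inf2$edge.length <- pr$bl
    ll <- tryCatch(
      sum(loglik_engine(inf2, cp, validate_classes(pr$classes), pr$kappa, pi,
                        code) * cp$weights),
      error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  bl0 <- pmin(pmax(info$edge.length, 1e-4), 5)
  if (all(is.na(bl0)) || is.null(info$edge.length)) bl0 <- rep(0.1, n_edge)
  start0 <- c(log(2), log(pmin(rep(0.2, n_omega), lay$omega_upper * 0.9)),
              rep(0, lay$n_prop), log(bl0))
  ctrl <- list(factr = control$factr %||% 1e7, maxit = control$maxit %||% 500L)

  set.seed(as.integer(seed) %% .Machine$integer.max)
  best <- NULL
  n_conv <- 0L
  for (r in seq_len(max(1L, n_restarts))) {
    st <- if (r == 1L) start0 else
      pmin(pmax(start0 + stats::rnorm(length(start0), 0, 0.5), lower), upper)
    opt <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = ctrl$factr, maxit = ctrl$maxit)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (opt$convergence == 0L) n_conv <- n_conv + 1L
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("optimisation failed in all restarts")

  pr <- unpack(best$par)
  fitted_tree <- tree
  # map fitted lengths (postorder) back onto the input tree's edge order
  post <- ape::reorder.phylo(tree, "postorder")
  key_in <- paste(tree$edge[, 1], tree$edge[, 2])
  key_post <- paste(post$edge[, 1], post$edge[, 2])
  fitted_tree$edge.length <- pr$bl[match(key_in, key_post)]

  structure(list(
    spec = spec, kind = spec$kind, logL = -best$value,
    kappa = pr$kappa, omegas = pr$omegas, proportions = pr$proportions,
    classes = pr$classes, tree = fitted_tree, codon_freqs = pi,
    n_params = n_free_params(spec$kind) + n_edge,
    n_sites = sum(cp$weights), n_taxa = length(info$tip.label),
    converged = n_conv > 0L, n_restarts = max(1L, n_restarts),
    n_converged = n_conv), class = "codon_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.codon_fit <- function(x, ...) {
  cat("<codon_fit>", x$kind, sprintf("| logL = %.6f", x$logL), "\n")
  cat(sprintf("  kappa = %.3f | %d taxa, %d codons | %s\n", x$kappa,
              x$n_taxa, x$n_sites,
              if (x$converged) "converged" else "NOT converged"))
  cl <- x$classes
  for (i in seq_len(nrow(cl)))
    cat(sprintf("  class %d: proportion %.4f | omega bg %.4f | omega numt %.4f\n",
                i, cl$proportion[i], cl$omega_background[i], cl$omega_numt[i]))
  invisible(x)
}

#' @export
summary.codon_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.codon_fit <- function(object, ...) {
  c(kappa = object$kappa, object$omegas,
    if (length(object$proportions) > 1)
      stats::setNames(object$proportions,
                      paste0("p", seq_along(object$proportions) - 1L)))
}

#' @export
logLik.codon_fit <- function(object, ...) {
  structure(object$logL, df = object$n_params, class = "logLik")
}

#' Likelihood-ratio test between nested codon models
#'
#' Computes 2 * (logL_alt - logL_null) and the chi-square upper-tail
#' p-value. Accepts fitted `codon_fit` objects or bare log-likelihood
#' values (e.g. published values being re-examined). For fits, the default
#' df is the difference in free non-branch parameter counts; it can always
#' be overridden. A small negative statistic (optimisation noise) is clamped
#' to zero; a violation beyond `tolerance` is an error since it contradicts
#' the nesting.
#'
#' @param null,alt `codon_fit` objects or numeric log-likelihoods.
#' @param df Degrees of freedom; required when bare numerics are given.
#' @param tolerance Permitted nesting violation in log-units (default 0.01).
#' @return An object of class `codon_lrt`: list with `statistic`, `df`,
#'   `p_value`, `logL_null`, `logL_alt`.
#' @examples
#' lrt_codon(-1811.746326, -1811.746294, df = 1)  # p ~ 0.99
#' @export
lrt_codon <- function(null, alt, df = NULL, tolerance = 0.01) {
  ll0 <- if (inherits(null, "codon_fit")) null$logL else as.numeric(null)
  ll1 <- if (inherits(alt, "codon_fit")) alt$logL else as.numeric(alt)
  if (is.null(df)) {
    if (!inherits(null, "codon_fit") || !inherits(alt, "codon_fit"))
      stop("df must be given when bare log-likelihoods are supplied")
    df <- n_free_params(alt$kind) - n_free_params(null$kind)
  }
  if (df < 1L) stop("df must be >= 1")
  stat <- 2 * (ll1 - ll0)
  if (stat < -tolerance)
    stop(sprintf("nesting violated: alt logL (%.6f) below null (%.6f)", ll1, ll0))
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = as.integer(df),
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 logL_null = ll0, logL_alt = ll1),
            class = "codon_lrt")
}

#' @export
print.codon_lrt <- function(x, ...) {
  cat(sprintf("<codon_lrt> 2*dlogL = %.4f, df = %d, P = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Fit a set of codon models and tabulate them
#'
#' Convenience wrapper fitting several model kinds on the same data and
#' returning a long-format table (model, site class, proportion, omega per
#' partition, logL), the shape in which codon-model suites are reported.
#'
#' @param tree,seqs,numt_taxa As in [fit_codon_model()].
#' @param models Character vector of model kinds.
#' @param ... Passed to [fit_codon_model()].
#' @return A list with `fits` (named list of `codon_fit`) and `table`
#'   (data frame).
#' @export
fit_codon_model_suite <- function(tree, seqs, numt_taxa = NULL,
                                  models = c("one_ratio", "two_ratio",
                                             "two_ratio_fixed"), ...) {
  fits <- lapply(models, function(m)
    fit_codon_model(tree, seqs, model = m, numt_taxa = numt_taxa, ...))
  names(fits) <- models
  tab <- do.call(rbind, lapply(models, function(m) {
    f <- fits[[m]]
    cl <- f$classes
    data.frame(model = m, site_class = seq_len(nrow(cl)),
               proportion = cl$proportion,
               omega_background = cl$omega_background,
               omega_numt = cl$omega_numt,
               logL = c(f$logL, rep(NA_real_, nrow(cl) - 1L)),
               stringsAsFactors = FALSE)
  }))
  list(fits = fits, table = tab)
}
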