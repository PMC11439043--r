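## ---- pruning data preparation ------------------------------------------

## Compress alignment columns into unique site patterns.
site_patterns <- function(aln) {
  key <- apply(aln$codons, 2, paste, collapse = "\r")
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(columns = which(u), weights = as.numeric(tabulate(idx, nbins = sum(u))),
       site_to_pattern = idx)
}

## Per-tip partial likelihood matrices (sense codons x patterns).
## Ambiguous codons are marginalized: partial mass 1 on every compatible
## sense codon; gaps give a flat vector of ones.
tip_partials <- function(aln, pattern_cols) {
  code <- aln$code
  sense <- code$sense
  s <- length(sense)
  compat_cache <- new.env(parent = emptyenv())
  lapply(aln$taxa, function(tx) {
    m <- matrix(0, s, length(pattern_cols))
    cods <- aln$codons[tx, pattern_cols]
    for (j in seq_along(cods)) {
      cod <- cods[j]
      hit <- compat_cache[[cod]]
      if (is.null(hit)) {
        hit <- match(compatible_codons(cod, code), sense)
        if (length(hit) == 0L) {
          stopf("codon '%s' (taxon %s) is compatible only with stop codons", cod, tx)
        }
        compat_cache[[cod]] <- hit
      }
      m[hit, j] <- 1
    }
    m
  })
}

## Postorder edge matrix and per-edge lengths for a phylo tree.
postorder_edges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ord <- match(
    paste(tr$edge[, 1], tr$edge[, 2]),
    paste(tree$edge[, 1], tree$edge[, 2])
  )
  list(edges = tr$edge, lengths = tr$edge.length,
       orig_index = ord, ntip = ape::Ntip(tree),
       nnode = ape::Ntip(tree) + tree$Nnode)
}

## Site-class layout of branch-site Model A:
##   class 0: background omega0, foreground omega0   (weight p0)
##   class 1: background 1,      foreground 1        (weight p1)
##   class 2a: background omega0, foreground omega2  (weight p2 * p0/(p0+p1))
##   class 2b: background 1,      foreground omega2  (weight p2 * p1/(p0+p1))
model_a_classes <- function(p0, p1, omega0, omega2) {
  p2 <- 1 - p0 - p1
  list(
    weights = c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1)),
    bg = c(omega0, 1, omega0, 1),
    fg = c(omega0, 1, omega2, omega2)
  )
}

## Evaluate the mixture log-likelihood. `omegas` are matched by value so each
## distinct omega gets a single generator/eigendecomposition; generators share
## kappa/pi and are jointly scaled by the class-weighted background rate so
## branch lengths are expected substitutions per codon site.
bs_lnl_engine <- function(prep, kappa, pi, classes, brlen,
                          return_site_matrix = FALSE, code) {
  omegas <- sort(unique(c(classes$bg, classes$fg)))
  bg_idx <- match(classes$bg, omegas)
  ## the eigensystems depend only on (kappa, omegas, class weights), not on
  ## branch lengths, so gradient steps along branch lengths reuse them
  key <- paste(c(kappa, omegas, classes$weights), collapse = " ")
  cache <- prep$cache
  if (!is.null(cache) && identical(cache$key, key)) {
    eigs <- cache$eigs
  } else {
    Qs <- lapply(omegas, function(w) {
      build_generator(codon_model(kappa, w, pi, code), scale = FALSE)
    })
    rates <- vapply(Qs, attr, numeric(1), "rate")
    scale <- sum(classes$weights * rates[bg_idx])
    if (!is.finite(scale) || scale <= 0) return(list(lnl = -Inf))
    eigs <- lapply(Qs, function(Q) generator_eigen(Q / scale, pi))
    if (!is.null(cache)) {
      cache$key <- key
      cache$eigs <- eigs
    }
  }
  res <- cpp_bs_lnl(
    edges = prep$post$edges, nnode = prep$post$nnode, ntip = prep$post$ntip,
    tip_partials = prep$tips,
    eigA = lapply(eigs, `[[`, "A"), eigB = lapply(eigs, `[[`, "B"),
    eigLambda = lapply(eigs, `[[`, "lambda"),
    brlen = brlen,
    class_bg = bg_idx, class_fg = match(classes$fg, omegas),
    fg_edge = prep$fg_edge_post,
    class_weights = classes$weights, pat_weights = prep$patterns$weights,
    pi = unname(pi), return_site_matrix = return_site_matrix
  )
  res
}

## One-time preparation shared across likelihood evaluations.
prepare_pruning <- function(aln, tree) {
  validate_tree_alignment(tree, aln)
  if (any(grepl("-", aln$codons))) {
    stopf("alignment contains gaps; run excise_gaps() before model fitting")
  }
  ## order alignment rows to tree tip numbering
  aln$codons <- aln$codons[tree$tip.label, , drop = FALSE]
  aln$taxa <- tree$tip.label
  pat <- site_patterns(aln)
  post <- postorder_edges(tree)
  fg <- foreground_edge(tree)
  fg_post <- if (fg > 0L) which(post$orig_index == fg) else 0L
  list(aln = aln, patterns = pat, tips = tip_partials(aln, pat$columns),
       post = post, fg_edge_post = as.integer(fg_post),
       cache = new.env(parent = emptyenv()))
}

#' Branch-site Model A log-likelihood
#'
#' Evaluates the pruning log-likelihood of a codon alignment on a tree under
#' the four-class branch-site mixture, at given parameter values. Used
#' internally by [fit_branch_site()]; exposed for direct evaluation and for
#' verification against enumeration oracles.
#'
#' @param aln Gap-free [codon_alignment()].
#' @param tree `phylo` with branch lengths and (optionally) a foreground mark
#'   (see [mark_foreground()]); without a mark all classes use background rates.
#' @param kappa,omega0,omega2 Model parameters.
#' @param p0,p1 Site-class proportions (p2 = 1 - p0 - p1 split
#'   proportionally between classes 2a/2b).
#' @param codon_freqs Equilibrium frequencies; default F3x4 from the data.
#' @return Log-likelihood (scalar).
#' @export
bs_loglik <- function(aln, tree, kappa = 2, omega0 = 0.1, omega2 = 1,
                      p0 = 0.7, p1 = 0.2, codon_freqs = NULL) {
  if (is.null(codon_freqs)) codon_freqs <- codon_frequencies(aln)
  prep <- prepare_pruning(aln, tree)
  classes <- model_a_classes(p0, p1, omega0, omega2)
  res <- bs_lnl_engine(prep, kappa, codon_freqs, classes,
                       brlen = prep$post$lengths, code = aln$code)
  res$lnl
}

#' Log-likelihood of an alignment under a fitted model
#'
#' @param aln Gap-free [codon_alignment()].
#' @param tree Tree with branch lengths (defaults to the fitted tree).
#' @param fit A [fit_branch_site()] result.
#' @return Log-likelihood (scalar).
#' @export
log_likelihood <- function(aln, tree = NULL, fit) {
  stopifnot(inherits(fit, "bs_fit"))
  tree <- tree %||% fit$tree
  bs_loglik(aln, tree,
            kappa = fit$kappa, omega0 = fit$omega0, omega2 = fit$omega2,
            p0 = fit$p["p0"], p1 = fit$p["p1"], codon_freqs = fit$codon_freqs)
}
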