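#' Naive Empirical Bayes site-class posteriors
#'
#' At the maximum-likelihood estimates of a fitted alternative branch-site
#' model, computes per-site posterior probabilities of the four site classes
#' (posterior proportional to class prior times class-conditional site
#' likelihood) and reports the sites whose combined posterior for the
#' positively selected classes (2a + 2b) reaches the threshold.
#'
#' @param aln Gap-free [codon_alignment()] (the data the model was fitted to).
#' @param tree Tree with foreground mark; defaults to the fitted tree.
#' @param fit Alternative-model [fit_branch_site()] result.
#' @param threshold Posterior probability cutoff in (0, 1); default 0.95, the
#'   5% significance convention.
#' @return Object of class `site_posterior`: `posterior` (sites x 4 matrix,
#'   rows sum to 1), `p_selected` (posterior of class 2a or 2b per site),
#'   `selected_sites` (1-based codon site indices) and `threshold`.
#' @export
neb_sites <- function(aln, tree = NULL, fit, threshold = 0.95) {
  stopifnot(inherits(fit, "bs_fit"))
  assert_probability(threshold, "threshold")
  if (fit$fix_omega2) {
    msg("NEB on a null fit (omega2 = 1); class 2 has no selective meaning")
  }
  tree <- tree %||% fit$tree
  prep <- prepare_pruning(aln, tree)
  classes <- model_a_classes(fit$p["p0"], fit$p["p1"], fit$omega0, fit$omega2)
  res <- bs_lnl_engine(prep, fit$kappa, fit$codon_freqs, classes,
                       brlen = tree$edge.length[prep$post$orig_index],
                       return_site_matrix = TRUE, code = aln$code)
  lw <- log(classes$weights)
  logpost <- res$site_log + lw            # nclass x npat, column-recycled
  post_pat <- apply(logpost, 2, function(v) {
    m <- max(v)
    e <- exp(v - m)
    e / sum(e)
  })
  post <- t(post_pat)[prep$patterns$site_to_pattern, , drop = FALSE]
  colnames(post) <- c("class0", "class1", "class2a", "class2b")
  rownames(post) <- seq_len(nrow(post))
  p_sel <- post[, "class2a"] + post[, "class2b"]
  structure(
    list(posterior = post, p_selected = p_sel,
         selected_sites = which(p_sel >= threshold),
         threshold = threshold, lnL = res$lnl),
    class = "site_posterior"
  )
}

#' @export
print.site_posterior <- function(x, ...) {
  cat(sprintf("NEB site posteriors: %d sites, %d selected at P >= %.2f\n",
              nrow(x$posterior), length(x$selected_sites), x$threshold))
  if (length(x$selected_sites)) {
    cat("  sites:", paste(x$selected_sites, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.site_posterior <- function(x, ...) {
  graphics::barplot(x$p_selected, names.arg = seq_along(x$p_selected),
                    ylim = c(0, 1), ylab = "P(class 2a or 2b)",
                    xlab = "codon site", border = NA, ...)
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}
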