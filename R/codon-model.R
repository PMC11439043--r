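## Cache of codon-pair classifications per translation table.
.pair_cache <- new.env(parent = emptyenv())

## For the sense codons of `code`, a list with:
##   type: s x s integer matrix, 0 = multi-nucleotide change (rate 0),
##         1 = synonymous transversion, 2 = synonymous transition,
##         3 = nonsynonymous transversion, 4 = nonsynonymous transition
codon_pair_types <- function(code) {
  key <- as.character(code$table_id)
  if (!is.null(.pair_cache[[key]])) return(.pair_cache[[key]])
  sense <- code$sense
  s <- length(sense)
  mat <- do.call(rbind, strsplit(sense, ""))
  aa <- unname(code$codon_to_aa[sense])
  type <- matrix(0L, s, s, dimnames = list(sense, sense))
  is_transition <- function(a, b) {
    (a %in% c("A", "G") && b %in% c("A", "G")) ||
      (a %in% c("C", "T") && b %in% c("C", "T"))
  }
  for (i in seq_len(s)) {
    for (j in seq_len(s)) {
      if (i == j) next
      diff <- which(mat[i, ] != mat[j, ])
      if (length(diff) != 1L) next
      ts <- is_transition(mat[i, diff], mat[j, diff])
      syn <- aa[i] == aa[j]
      type[i, j] <- if (syn && !ts) 1L else if (syn && ts) 2L else
        if (!syn && !ts) 3L else 4L
    }
  }
  res <- list(type = type, aa = aa)
  .pair_cache[[key]] <- res
  res
}

#' Codon substitution model (Goldman-Yang)
#'
#' Parameterises instantaneous substitution between sense codons: only
#' single-nucleotide changes have nonzero rate, scaled by the
#' transition/transversion ratio `kappa`, the nonsynonymous/synonymous ratio
#' `omega`, and the target codon's equilibrium frequency.
#'
#' @param kappa Transition/transversion rate ratio, >= 0.
#' @param omega Nonsynonymous/synonymous rate ratio, >= 0.
#' @param codon_freqs Equilibrium frequencies over the sense codons of `code`
#'   (named or in `code$sense` order), summing to 1. Default uniform.
#' @param code A [genetic_code()] or table id.
#' @return Object of class `codon_model`.
#' @export
codon_model <- function(kappa = 2, omega = 0.5, codon_freqs = NULL,
                        code = genetic_code(5L)) {
  code <- as_genetic_code(code)
  s <- length(code$sense)
  if (is.null(codon_freqs)) codon_freqs <- rep(1 / s, s)
  if (!is.null(names(codon_freqs))) codon_freqs <- codon_freqs[code$sense]
  if (length(codon_freqs) != s || anyNA(codon_freqs) || any(codon_freqs < 0)) {
    stopf("codon_freqs must be %d non-negative values over the sense codons", s)
  }
  if (abs(sum(codon_freqs) - 1) > 1e-8) stopf("codon_freqs must sum to 1")
  if (kappa < 0 || omega < 0) stopf("kappa and omega must be >= 0")
  structure(
    list(kappa = kappa, omega = omega,
         codon_freqs = setNames(as.numeric(codon_freqs), code$sense),
         code = code),
    class = "codon_model"
  )
}

#' @export
print.codon_model <- function(x, ...) {
  cat(sprintf("GY94 codon model: kappa = %.4g, omega = %.4g, table %d (%d sense codons)\n",
              x$kappa, x$omega, x$code$table_id, length(x$code$sense)))
  invisible(x)
}

#' Equilibrium codon frequencies from an alignment
#'
#' @param aln A [codon_alignment()] (ambiguous codons and gaps are skipped in
#'   the counts).
#' @param scheme `"F3x4"` (position-specific nucleotide frequencies, default),
#'   `"F1x4"` (pooled nucleotide frequencies) or `"F61"` (observed codon
#'   frequencies with a small floor).
#' @return Named frequency vector over the sense codons, summing to 1.
#' @export
codon_frequencies <- function(aln, scheme = c("F3x4", "F1x4", "F61")) {
  scheme <- match.arg(scheme)
  code <- aln$code
  sense <- code$sense
  obs <- as.vector(aln$codons)
  obs <- obs[vapply(obs, is_unambiguous_codon, logical(1))]
  if (scheme == "F61") {
    cnt <- table(factor(obs, levels = sense)) + 0.5
    f <- as.numeric(cnt) / sum(cnt)
    return(setNames(f, sense))
  }
  chars <- do.call(rbind, strsplit(obs, ""))
  pos_freq <- if (scheme == "F3x4") {
    lapply(1:3, function(p) {
      f <- table(factor(chars[, p], levels = NUC))
      pmax(as.numeric(f) / sum(f), 1e-10)
    })
  } else {
    f <- table(factor(as.vector(chars), levels = NUC))
    rep(list(pmax(as.numeric(f) / sum(f), 1e-10)), 3)
  }
  names(pos_freq[[1]]) <- names(pos_freq[[2]]) <- names(pos_freq[[3]]) <- NUC
  sm <- do.call(rbind, strsplit(sense, ""))
  f <- pos_freq[[1]][sm[, 1]] * pos_freq[[2]][sm[, 2]] * pos_freq[[3]][sm[, 3]]
  setNames(as.numeric(f / sum(f)), sense)
}

#' Instantaneous rate generator of a codon model
#'
#' Off-diagonal rate for a single-nucleotide codon pair is
#' `pi_target * {1, kappa, omega, omega*kappa}` for synonymous transversions,
#' synonymous transitions, nonsynonymous transversions and nonsynonymous
#' transitions respectively; multi-nucleotide changes have rate zero; rows sum
#' to zero. With `scale = TRUE` the generator is scaled so the expected number
#' of substitutions per codon site at equilibrium is 1.
#'
#' @param model A [codon_model()].
#' @param scale Scale to one expected substitution per site?
#' @return Rate matrix over sense codons, with attribute `rate` holding the
#'   pre-scaling equilibrium rate.
#' @export
build_generator <- function(model, scale = TRUE) {
  stopifnot(inherits(model, "codon_model"))
  pt <- codon_pair_types(model$code)
  pi <- model$codon_freqs
  if (abs(sum(pi) - 1) > 1e-8) stopf("codon frequencies must sum to 1")
  mult <- c(1, model$kappa, model$omega, model$omega * model$kappa)
  Q <- matrix(0, length(pi), length(pi), dimnames = dimnames(pt$type))
  nz <- pt$type > 0L
  Q[nz] <- mult[pt$type[nz]]
  Q <- sweep(Q, 2, pi, `*`)
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  if (scale && rate > 0) Q <- Q / rate
  attr(Q, "rate") <- rate
  Q
}

## Symmetrized eigendecomposition of a reversible generator.
## Q = A diag(lambda) B with A = D^{-1/2} U, B = U' D^{1/2}.
generator_eigen <- function(Q, pi) {
  d <- sqrt(pi)
  S <- Q * (d %o% (1 / d))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(A = e$vectors / d, B = t(e$vectors) * rep(d, each = length(d)),
       lambda = e$values)
}

#' Transition probability matrix exp(Qt)
#'
#' Computed by eigendecomposition of the (reversible) generator.
#'
#' @param model A [codon_model()] (or a list with `Q` and `pi`).
#' @param t Branch length in expected substitutions per codon site.
#' @param scale Passed to [build_generator()].
#' @return Stochastic matrix over sense codons.
#' @export
transition_matrix <- function(model, t, scale = TRUE) {
  Q <- build_generator(model, scale = scale)
  eig <- generator_eigen(Q, model$codon_freqs)
  P <- eig$A %*% (exp(eig$lambda * t) * eig$B)
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}
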