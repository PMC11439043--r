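## ---- Nei-Gojobori (1986) counting machinery --------------------------------

ng86_tables <- function(code) {
  key <- paste0("ng86_", code$table_id)
  if (!is.null(.pair_cache[[key]])) return(.pair_cache[[key]])
  sense <- code$sense
  aa <- unname(code$codon_to_aa[sense])
  names(aa) <- sense
  ## synonymous site fraction per codon position: among the 3 possible
  ## single-nucleotide changes at a position, stop-creating changes are
  ## excluded and the position's unit weight is split syn/nonsyn
  syn_sites <- vapply(sense, function(cod) {
    chars <- strsplit(cod, "")[[1]]
    tot <- 0
    for (p in 1:3) {
      alt <- setdiff(NUC, chars[p])
      muts <- vapply(alt, function(n) {
        x <- chars; x[p] <- n; paste(x, collapse = "")
      }, character(1))
      keep <- muts %in% sense
      if (!any(keep)) next
      tot <- tot + sum(aa[muts[keep]] == aa[cod]) / sum(keep)
    }
    tot
  }, numeric(1))
  res <- list(aa = aa, syn_sites = syn_sites)
  .pair_cache[[key]] <- res
  res
}

## Average synonymous/nonsynonymous differences between two codons over all
## mutational pathways that avoid stop codons.
ng86_diffs <- function(codA, codB, tab, sense) {
  if (codA == codB) return(c(syn = 0, nonsyn = 0))
  a <- strsplit(codA, "")[[1]]
  b <- strsplit(codB, "")[[1]]
  pos <- which(a != b)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  paths <- perms(pos)
  acc <- c(syn = 0, nonsyn = 0)
  nvalid <- 0L
  for (ord in paths) {
    cur <- a
    steps <- c(syn = 0, nonsyn = 0)
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- b[p]
      c1 <- paste(cur, collapse = "")
      c2 <- paste(nxt, collapse = "")
      if (!(c2 %in% sense) || !(c1 %in% sense)) { ok <- FALSE; break }
      if (tab$aa[c1] == tab$aa[c2]) steps["syn"] <- steps["syn"] + 1
      else steps["nonsyn"] <- steps["nonsyn"] + 1
      cur <- nxt
    }
    if (ok) { acc <- acc + steps; nvalid <- nvalid + 1L }
  }
  if (nvalid == 0L) {
    ## all pathways pass through stops: count every change as nonsynonymous
    return(c(syn = 0, nonsyn = length(pos)))
  }
  acc / nvalid
}

pairwise_ng86 <- function(codA, codB, code) {
  tab <- ng86_tables(code)
  sense <- code$sense
  S <- (sum(tab$syn_sites[codA]) + sum(tab$syn_sites[codB])) / 2
  N <- 3 * length(codA) - S
  d <- c(syn = 0, nonsyn = 0)
  for (i in seq_along(codA)) d <- d + ng86_diffs(codA[i], codB[i], tab, sense)
  pS <- if (S > 0) d[["syn"]] / S else 0
  pN <- if (N > 0) d[["nonsyn"]] / N else 0
  jc <- function(p) {
    if (p >= 0.749) return(NA_real_)  # beyond Jukes-Cantor saturation
    -3 / 4 * log(1 - 4 * p / 3)
  }
  list(dN = jc(pN), dS = jc(pS), S = S, N = N, Sd = d[["syn"]], Nd = d[["nonsyn"]])
}

## ---- ML pairwise ------------------------------------------------------------

pairwise_ml <- function(codA, codB, code) {
  aln <- codon_alignment(rbind(A = codA, B = codB), code = code,
                         strip_terminal_stop = FALSE)
  pi <- codon_frequencies(aln, "F3x4")
  sense <- code$sense
  key <- paste(codA, codB)
  u <- !duplicated(key)
  w <- tabulate(match(key, key[u]), nbins = sum(u))
  ia <- match(codA[u], sense)
  ib <- match(codB[u], sense)
  if (anyNA(ia) || anyNA(ib)) {
    stopf("pairwise ML requires unambiguous, gap-free codons")
  }
  nll <- function(theta) {
    t <- exp(theta[1]); kappa <- exp(theta[2]); omega <- exp(theta[3])
    Q <- build_generator(codon_model(kappa, omega, pi, code), scale = TRUE)
    eig <- generator_eigen(Q, pi)
    P <- eig$A %*% (exp(eig$lambda * t) * eig$B)
    lik <- pi[ia] * pmax(P[cbind(ia, ib)], 1e-300)
    -sum(w * log(lik))
  }
  opt <- optim(c(log(0.3), log(2), log(0.5)), nll, method = "L-BFGS-B",
               lower = c(log(1e-6), log(0.01), log(1e-4)),
               upper = c(log(20), log(100), log(50)),
               control = list(maxit = 200, factr = 1e9))
  t <- exp(opt$par[1]); kappa <- exp(opt$par[2]); omega <- exp(opt$par[3])
  ## decompose the per-codon rate into synonymous/nonsynonymous flux and the
  ## site proportions implied by the neutral (omega = 1) opportunity
  pt <- codon_pair_types(code)
  pim <- pi %o% pi
  kmult <- matrix(1, length(pi), length(pi))
  kmult[pt$type %in% c(2L, 4L)] <- kappa
  base <- pim * kmult
  A <- sum(base[pt$type %in% c(3L, 4L)])   # nonsynonymous opportunity
  B <- sum(base[pt$type %in% c(1L, 2L)])   # synonymous opportunity
  rhoN <- omega * A / (omega * A + B)
  rhoS <- B / (omega * A + B)
  pN <- A / (A + B)
  pS <- B / (A + B)
  list(dN = t * rhoN / (3 * pN), dS = t * rhoS / (3 * pS),
       t = t, kappa = kappa, omega_hat = omega, lnL = -opt$value)
}

#' Pairwise synonymous and nonsynonymous substitution rates
#'
#' Estimates dN and dS between two in-frame codon sequences, either by
#' maximizing the two-sequence codon-model likelihood over branch length,
#' kappa and omega (`method = "ML"`), or by the Nei-Gojobori (1986) counting
#' estimator with pathway averaging and Jukes-Cantor correction
#' (`method = "NG86"`), which serves as an independent cross-check.
#'
#' @param seqA,seqB Nucleotide strings (equal length, divisible by 3, gap-free,
#'   unambiguous) or character vectors of codons.
#' @param code A [genetic_code()] or table id.
#' @param method `"ML"` or `"NG86"`.
#' @return Object of class `pairwise_rates`: `dN`, `dS`, `omega`
#'   (`NA` with `omega_undefined = TRUE` when `dS = 0`), `method`, and
#'   method-specific details.
#' @examples
#' pairwise_rates("TTT", "TTC", method = "NG86")
#' @export
pairwise_rates <- function(seqA, seqB, code = genetic_code(5L),
                           method = c("ML", "NG86")) {
  method <- match.arg(method)
  code <- as_genetic_code(code)
  to_codons <- function(s) {
    if (length(s) > 1L) return(toupper(s))
    s <- toupper(gsub("\\s", "", s))
    if (nchar(s) %% 3L != 0L) stopf("sequence length not divisible by 3")
    substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  }
  codA <- to_codons(seqA)
  codB <- to_codons(seqB)
  if (length(codA) != length(codB)) stopf("sequences have different codon counts")
  if (any(grepl("-", c(codA, codB)))) stopf("gaps must be excised first")

  if (identical(codA, codB)) {
    out <- list(dN = 0, dS = 0)
  } else if (method == "NG86") {
    out <- pairwise_ng86(codA, codB, code)
  } else {
    out <- pairwise_ml(codA, codB, code)
  }
  undefined <- !is.na(out$dS) && out$dS == 0
  structure(
    c(list(omega = if (undefined || is.na(out$dS)) NA_real_ else out$dN / out$dS,
           omega_undefined = undefined, method = method, n_codons = length(codA)),
      out),
    class = "pairwise_rates"
  )
}

#' @export
print.pairwise_rates <- function(x, ...) {
  cat(sprintf("Pairwise rates (%s, %d codons): dN = %.4f, dS = %.4f, dN/dS = %s\n",
              x$method, x$n_codons, x$dN, x$dS,
              if (isTRUE(x$omega_undefined) || is.na(x$omega)) "undefined (dS = 0)"
              else sprintf("%.4f", x$omega)))
  invisible(x)
}
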