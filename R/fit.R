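## ---- parameter transforms -------------------------------------------------
## kappa, omega0 and branch lengths are optimized on the log scale; omega2 on
## log scale bounded below at 1; the class proportions (p0, p1, p2) through a
## softmax over (x1, x2, 0).

BS_BOUNDS <- list(
  log_kappa = log(c(0.01, 100)),
  log_omega0 = log(c(1e-4, 0.999)),
  log_omega2 = c(0, log(999)),
  x = c(-12, 12),
  log_brlen = log(c(1e-6, 12))
)

softmax3 <- function(x1, x2) {
  e <- exp(c(x1, x2, 0) - max(x1, x2, 0))
  e / sum(e)
}

pack_params <- function(kappa, omega0, omega2, p0, p1, brlen, fix_omega2) {
  p2 <- max(1 - p0 - p1, 1e-6)
  x1 <- log(p0 / p2)
  x2 <- log(p1 / p2)
  c(log(kappa), log(omega0),
    if (!fix_omega2) log(max(omega2, 1 + 1e-8)),
    x1, x2, log(pmax(brlen, 1.1e-6)))
}

unpack_params <- function(theta, nedge, fix_omega2) {
  i <- 1L
  kappa <- exp(theta[i]); i <- i + 1L
  omega0 <- exp(theta[i]); i <- i + 1L
  omega2 <- if (fix_omega2) 1 else { v <- exp(theta[i]); i <- i + 1L; v }
  p <- softmax3(theta[i], theta[i + 1L]); i <- i + 2L
  brlen <- exp(theta[i:(i + nedge - 1L)])
  list(kappa = kappa, omega0 = omega0, omega2 = omega2,
       p0 = p[1], p1 = p[2], brlen = brlen)
}

param_bounds <- function(nedge, fix_omega2) {
  lower <- c(BS_BOUNDS$log_kappa[1], BS_BOUNDS$log_omega0[1],
             if (!fix_omega2) BS_BOUNDS$log_omega2[1],
             rep(BS_BOUNDS$x[1], 2), rep(BS_BOUNDS$log_brlen[1], nedge))
  upper <- c(BS_BOUNDS$log_kappa[2], BS_BOUNDS$log_omega0[2],
             if (!fix_omega2) BS_BOUNDS$log_omega2[2],
             rep(BS_BOUNDS$x[2], 2), rep(BS_BOUNDS$log_brlen[2], nedge))
  list(lower = lower, upper = upper)
}

## ---- M0 pre-fit ------------------------------------------------------------
## Single-omega fit used as a deterministic warm start for the mixture models.
fit_m0 <- function(prep, pi, code, control = list()) {
  nedge <- nrow(prep$post$edges)
  obj <- function(theta) {
    kappa <- exp(theta[1]); omega <- exp(theta[2])
    brlen <- exp(theta[3:(2 + nedge)])
    classes <- list(weights = 1, bg = omega, fg = omega)
    res <- bs_lnl_engine(prep, kappa, pi, classes, brlen, code = code)
    if (!is.finite(res$lnl)) return(1e10)
    -res$lnl
  }
  start <- c(log(2), log(0.3), rep(log(0.15), nedge))
  lower <- c(BS_BOUNDS$log_kappa[1], log(1e-4), rep(BS_BOUNDS$log_brlen[1], nedge))
  upper <- c(BS_BOUNDS$log_kappa[2], log(10), rep(BS_BOUNDS$log_brlen[2], nedge))
  opt <- optim(start, obj, method = "L-BFGS-B", lower = lower, upper = upper,
               control = modifyList(list(maxit = 150, factr = 1e10), control))
  list(kappa = exp(opt$par[1]), omega = exp(opt$par[2]),
       brlen = exp(opt$par[3:(2 + nedge)]), lnl = -opt$value)
}

## ---- Model A fit -----------------------------------------------------------

#' Fit branch-site Model A by maximum likelihood
#'
#' Fits the four-class branch-site codon mixture (site classes with
#' `0 < omega0 < 1`, `omega1 = 1`, and a foreground-only `omega2`) to a
#' gap-free codon alignment on a tree with one marked foreground branch. The
#' alternative model estimates `omega2 >= 1`; the null fixes `omega2 = 1`.
#' Optimization is bounded quasi-Newton (L-BFGS-B) from several deterministic
#' starts (the first warm-started from a single-omega pre-fit); branch lengths
#' are re-optimized under each model.
#'
#' @param aln Gap-free [codon_alignment()].
#' @param tree `phylo` carrying a foreground mark ([mark_foreground()] or a
#'   `#1` Newick label).
#' @param fix_omega2 `TRUE` fits the null model (omega2 fixed at 1).
#' @param freq Codon frequency scheme (see [codon_frequencies()]).
#' @param starts Number of optimization starts (>= 1). Starts beyond the
#'   three deterministic ones are seeded jitters.
#' @param seed Seed for any randomized extra starts (deterministic defaults
#'   are unaffected).
#' @param start Optional warm start: a `bs_fit` or a named list with elements
#'   `kappa`, `omega0`, `omega2`, `p0`, `p1`, `brlen`.
#' @param control Passed to [stats::optim()] (`maxit`, `factr`, ...).
#' @return Object of class `bs_fit` with maximum-likelihood estimates
#'   (`kappa`, `omega0`, `omega2`, proportions `p`), `lnL`, the tree with
#'   fitted branch lengths, convergence information and the data summary.
#' @seealso [lrt()], [neb_sites()], [simulate.bs_fit()]
#' @export
fit_branch_site <- function(aln, tree, fix_omega2 = FALSE,
                            freq = c("F3x4", "F1x4", "F61"),
                            starts = 3L, seed = 1L, start = NULL,
                            control = list()) {
  freq <- match.arg(freq)
  if (foreground_edge(tree) == 0L) {
    stopf("tree has no foreground mark; use mark_foreground()")
  }
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  pi <- codon_frequencies(aln, freq)
  prep <- prepare_pruning(aln, tree)
  nedge <- nrow(prep$post$edges)
  bounds <- param_bounds(nedge, fix_omega2)
  ctl <- modifyList(list(maxit = 200, factr = 1e9), control)

  obj <- function(theta) {
    pr <- unpack_params(theta, nedge, fix_omega2)
    classes <- model_a_classes(pr$p0, pr$p1, pr$omega0, pr$omega2)
    res <- bs_lnl_engine(prep, pr$kappa, pi, classes, pr$brlen, code = aln$code)
    if (!is.finite(res$lnl)) return(1e10)
    -res$lnl
  }

  starts <- max(1L, as.integer(starts))
  start_list <- list()
  if (is.null(start) || starts > 1L) {
    ## deterministic default starts, the first warm-started from a
    ## single-omega pre-fit (skipped entirely when a warm start is supplied
    ## and only one start is requested)
    m0 <- fit_m0(prep, pi, aln$code, control = list(factr = 1e10))
    start_list <- list(
      m0 = pack_params(m0$kappa, min(m0$omega, 0.9), 2, 0.7, 0.2, m0$brlen,
                       fix_omega2),
      selected = pack_params(m0$kappa, min(m0$omega, 0.5), 50, 0.85, 0.1,
                             m0$brlen, fix_omega2),
      broad = pack_params(2, 0.2, 3, 0.6, 0.3, rep(0.1, nedge), fix_omega2)
    )
  }
  if (!is.null(start)) {
    ws <- if (inherits(start, "bs_fit")) {
      list(kappa = start$kappa, omega0 = start$omega0,
           omega2 = if (fix_omega2) 1 else max(start$omega2, 1.001),
           p0 = unname(start$p["p0"]), p1 = unname(start$p["p1"]),
           brlen = start$brlen_post)
    } else start
    start_list <- c(list(warm = pack_params(ws$kappa, ws$omega0, ws$omega2,
                                            ws$p0, ws$p1, ws$brlen,
                                            fix_omega2)),
                    start_list)
  }
  if (starts > length(start_list)) {
    extra <- with_seed(seed, lapply(seq_len(starts - length(start_list)),
                                    function(i) {
      base <- start_list[[1 + (i %% length(start_list))]]
      base + rnorm(length(base), sd = 0.3)
    }))
    names(extra) <- paste0("jitter", seq_along(extra))
    start_list <- c(start_list, extra)
  }
  start_list <- start_list[seq_len(min(starts, length(start_list)))]

  best <- NULL
  status <- character(0)
  for (nm in names(start_list)) {
    theta0 <- pmin(pmax(start_list[[nm]], bounds$lower), bounds$upper)
    opt <- tryCatch(
      optim(theta0, obj, method = "L-BFGS-B",
            lower = bounds$lower, upper = bounds$upper, control = ctl),
      error = function(e) NULL
    )
    if (is.null(opt)) { status <- c(status, paste0(nm, ":error")); next }
    status <- c(status, paste0(nm, ":", opt$convergence))
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      best$start_used <- nm
    }
  }
  if (is.null(best)) stopf("all optimization starts failed")

  pr <- unpack_params(best$par, nedge, fix_omega2)
  p2 <- 1 - pr$p0 - pr$p1
  fitted_tree <- tree
  fitted_tree$edge.length[prep$post$orig_index] <- pr$brlen
  attr(fitted_tree, "foreground_node") <- attr(tree, "foreground_node")

  structure(
    list(
      kappa = pr$kappa, omega0 = pr$omega0, omega2 = pr$omega2,
      p = c(p0 = pr$p0, p1 = pr$p1,
            p2a = p2 * pr$p0 / (pr$p0 + pr$p1),
            p2b = p2 * pr$p1 / (pr$p0 + pr$p1)),
      lnL = -best$value,
      fix_omega2 = fix_omega2,
      tree = fitted_tree,
      brlen_post = pr$brlen,
      codon_freqs = pi,
      freq_scheme = freq,
      n_sites = ncol(aln$codons),
      n_patterns = length(prep$patterns$weights),
      n_taxa = length(aln$taxa),
      foreground = foreground_taxa(tree),
      convergence = best$convergence,
      start_used = best$start_used,
      start_status = status,
      seed = seed,
      code_table = aln$code$table_id,
      call = match.call()
    ),
    class = "bs_fit"
  )
}

## ---- methods ---------------------------------------------------------------

#' @export
print.bs_fit <- function(x, ...) {
  cat(sprintf("Branch-site Model A (%s): lnL = %.4f\n",
              if (x$fix_omega2) "null, omega2 = 1" else "alternative",
              x$lnL))
  cat(sprintf("  kappa = %.3f, omega0 = %.4f, omega2 = %.3f\n",
              x$kappa, x$omega0, x$omega2))
  cat(sprintf("  class proportions: p0 = %.3f p1 = %.3f p2a = %.3f p2b = %.3f\n",
              x$p["p0"], x$p["p1"], x$p["p2a"], x$p["p2b"]))
  cat(sprintf("  foreground: %s\n", paste(x$foreground, collapse = ", ")))
  invisible(x)
}

#' @export
summary.bs_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  data: %d taxa, %d codon sites (%d patterns), table %d, %s frequencies\n",
              object$n_taxa, object$n_sites, object$n_patterns,
              object$code_table, object$freq_scheme))
  cat(sprintf("  optimizer: start '%s' (convergence %d); starts tried: %s\n",
              object$start_used, object$convergence,
              paste(object$start_status, collapse = " ")))
  invisible(object)
}

#' @export
coef.bs_fit <- function(object, ...) {
  c(kappa = object$kappa, omega0 = object$omega0, omega2 = object$omega2,
    object$p)
}

#' @export
logLik.bs_fit <- function(object, ...) {
  val <- object$lnL
  df <- 4 + length(object$brlen_post) - object$fix_omega2
  structure(val, df = df, nobs = object$n_sites, class = "logLik")
}

#' Likelihood ratio test between null and alternative branch-site fits
#'
#' Computes `2 * (lnL_alt - lnL_null)`, the chi-square upper-tail p value (two
#' degrees of freedom by default), and a Bonferroni-adjusted p value
#' (`min(1, p_raw * n_tests)`), flagging significance at the 5% and 1% levels
#' (chi-square(2) critical values 5.991 and 9.210).
#'
#' @param null,alt `bs_fit` objects fitted to the same data, with
#'   `fix_omega2 = TRUE` and `FALSE` respectively.
#' @param df Degrees of freedom of the chi-square reference (default 2; the
#'   canonical alternative `df = 1` or the 50:50 mixture reference are
#'   available via `df = 1`, `mixture = TRUE`).
#' @param n_tests Bonferroni multiplier (number of branches tested per gene
#'   tree).
#' @param mixture Use the 50:50 mixture of a point mass at 0 and
#'   chi-square(df)?
#' @param tol Negative statistics larger than `-tol` are clamped to 0; below
#'   that an error signals a model/optimizer inconsistency.
#' @return Object of class `bs_lrt`.
#' @export
lrt <- function(null, alt, df = 2, n_tests = 1, mixture = FALSE, tol = 1e-4) {
  stopifnot(inherits(null, "bs_fit"), inherits(alt, "bs_fit"))
  if (!null$fix_omega2 || alt$fix_omega2) {
    stopf("lrt(null, alt): null must fix omega2 = 1, alt must estimate it")
  }
  if (null$n_sites != alt$n_sites || null$n_taxa != alt$n_taxa) {
    stopf("null and alternative were fitted to different data")
  }
  stat <- 2 * (alt$lnL - null$lnL)
  if (stat < -tol) {
    stopf("2*dlnL = %.6g < 0: alternative fit worse than null (optimizer inconsistency)", stat)
  }
  stat <- max(stat, 0)
  p_raw <- pchisq(stat, df = df, lower.tail = FALSE)
  if (mixture) p_raw <- if (stat == 0) 1 else 0.5 * p_raw
  p_adj <- min(1, p_raw * n_tests)
  structure(
    list(statistic = stat, df = df, p_raw = p_raw, p_adjusted = p_adj,
         n_tests = n_tests, mixture = mixture,
         significant_05 = p_adj < 0.05, significant_01 = p_adj < 0.01,
         lnL_null = null$lnL, lnL_alt = alt$lnL),
    class = "bs_lrt"
  )
}

#' @export
print.bs_lrt <- function(x, ...) {
  cat(sprintf("LRT: 2*dlnL = %.4f, df = %d%s, p_raw = %.4g, p_adj = %.4g (x%d)%s\n",
              x$statistic, x$df, if (x$mixture) " (50:50 mixture)" else "",
              x$p_raw, x$p_adjusted, x$n_tests,
              if (x$significant_01) " **" else if (x$significant_05) " *" else ""))
  invisible(x)
}

#' @export
anova.bs_fit <- function(object, ..., df = 2, n_tests = 1) {
  fits <- c(list(object), list(...))
  fits <- Filter(function(f) inherits(f, "bs_fit"), fits)
  if (length(fits) != 2L) stopf("anova.bs_fit needs exactly two bs_fit objects")
  nulls <- vapply(fits, `[[`, logical(1), "fix_omega2")
  if (sum(nulls) != 1L) stopf("need one null (fix_omega2) and one alternative fit")
  lrt(fits[[which(nulls)]], fits[[which(!nulls)]], df = df, n_tests = n_tests)
}

#' Chi-square upper-tail critical value
#'
#' @param alpha Significance level.
#' @param df Degrees of freedom (default 2, for which the closed form is
#'   `-2 log(alpha)`).
#' @export
chisq_critical <- function(alpha, df = 2) qchisq(alpha, df = df, lower.tail = FALSE)

#' Run the branch-site positive-selection test on one foreground branch
#'
#' Convenience wrapper fitting the null (`omega2 = 1`) and alternative models
#' and returning the likelihood ratio test. The alternative is warm-started
#' from the null fit, which guarantees a non-negative statistic.
#'
#' @inheritParams fit_branch_site
#' @inheritParams lrt
#' @param ... Passed to [fit_branch_site()].
#' @return List with `null`, `alt` (`bs_fit`) and `test` (`bs_lrt`).
#' @export
branch_site_test <- function(aln, tree, df = 2, n_tests = 1, ...) {
  null <- fit_branch_site(aln, tree, fix_omega2 = TRUE, ...)
  alt <- fit_branch_site(aln, tree, fix_omega2 = FALSE, start = null, ...)
  if (alt$lnL < null$lnL) {
    ## the null optimum (omega2 = 1) is a feasible point of the alternative;
    ## if the optimizer stalled short of it, take it as the alternative fit
    for (f in c("kappa", "omega0", "p", "lnL", "tree", "brlen_post")) {
      alt[[f]] <- null[[f]]
    }
    alt$omega2 <- 1
    alt$start_used <- "null-optimum"
  }
  list(null = null, alt = alt, test = lrt(null, alt, df = df, n_tests = n_tests))
}

#' Simulate alignments from a fitted branch-site model
#'
#' Parametric simulation at the maximum-likelihood estimates, on the fitted
#' tree (useful for parametric-bootstrap calibration of the LRT).
#'
#' @param object A `bs_fit`.
#' @param nsim Number of alignments.
#' @param seed Simulation seed (consecutive seeds `seed + 0:(nsim-1)` are
#'   used per replicate).
#' @param n_sites Sites per alignment (default: as fitted).
#' @param ... Unused.
#' @return List of [simulate_codon_alignment()] results (length `nsim`).
#' @export
simulate.bs_fit <- function(object, nsim = 1, seed = 1L, n_sites = NULL, ...) {
  lapply(seq_len(nsim) - 1L, function(i) {
    simulate_codon_alignment(
      tree = object$tree, n_sites = n_sites %||% object$n_sites,
      kappa = object$kappa, omega0 = object$omega0, omega2 = object$omega2,
      p0 = unname(object$p["p0"]), p1 = unname(object$p["p1"]),
      codon_freqs = object$codon_freqs, code = genetic_code(object$code_table),
      seed = seed + i
    )
  })
}
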