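## Independent oracles. These deliberately avoid the package's pruning and
## eigendecomposition code paths: transition matrices come from Matrix::expm
## (scaling-and-squaring) and site likelihoods from literal enumeration of all
## internal-node codon assignments.

## All assignments of s states to k internal nodes (cached: the grid is the
## same for every instance of a given tree size).
.oracle_grids <- new.env(parent = emptyenv())
oracle_state_grid <- function(k, s) {
  key <- paste(k, s)
  if (is.null(.oracle_grids[[key]])) {
    .oracle_grids[[key]] <- as.matrix(expand.grid(rep(list(seq_len(s)), k)))
  }
  .oracle_grids[[key]]
}

## Exhaustive-enumeration mixture log-likelihood for small trees.
oracle_bs_lnl <- function(aln, tree, kappa, omega0, omega2, p0, p1, pi) {
  code <- aln$code
  sense <- code$sense
  s <- length(sense)
  classes <- mitosel:::model_a_classes(p0, p1, omega0, omega2)
  omegas <- sort(unique(c(classes$bg, classes$fg)))
  Qs <- lapply(omegas, function(w) {
    build_generator(codon_model(kappa, w, pi, code), scale = FALSE)
  })
  rates <- vapply(Qs, attr, numeric(1), "rate")
  scale <- sum(classes$weights * rates[match(classes$bg, omegas)])
  fg <- mitosel:::foreground_edge(tree)
  P <- lapply(seq_len(nrow(tree$edge)), function(e) {
    lapply(seq_along(omegas), function(k) {
      as.matrix(Matrix::expm((Qs[[k]] / scale) * tree$edge.length[e]))
    })
  })
  ntip <- ape::Ntip(tree)
  internals <- (ntip + 1L):(ntip + tree$Nnode)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  grid <- oracle_state_grid(length(internals), s)
  tip_idx <- matrix(match(aln$codons[tree$tip.label, , drop = FALSE], sense),
                    nrow = ntip)
  total <- 0
  for (j in seq_len(ncol(aln$codons))) {
    class_lik <- numeric(length(classes$weights))
    for (k in seq_along(classes$weights)) {
      lik <- pi[grid[, match(root, internals)]]
      for (e in seq_len(nrow(tree$edge))) {
        pa <- tree$edge[e, 1]
        ch <- tree$edge[e, 2]
        w <- if (e == fg) classes$fg[k] else classes$bg[k]
        Pm <- P[[e]][[match(w, omegas)]]
        pstate <- grid[, match(pa, internals)]
        cstate <- if (ch <= ntip) rep(tip_idx[ch, j], nrow(grid)) else
          grid[, match(ch, internals)]
        lik <- lik * Pm[cbind(pstate, cstate)]
      }
      class_lik[k] <- sum(lik)
    }
    total <- total + log(sum(classes$weights * class_lik))
  }
  total
}

## Exhaustive parsimony oracle: minimum-change labelings of a rooted tree with
## given tip states; returns the set of root states achieving the minimum.
oracle_fitch_root_set <- function(tree, tip_states) {
  ntip <- ape::Ntip(tree)
  internals <- (ntip + 1L):(ntip + tree$Nnode)
  states <- sort(unique(tip_states))
  grid <- as.matrix(expand.grid(rep(list(states), length(internals)),
                                stringsAsFactors = FALSE))
  label_of <- function(row, node) {
    if (node <= ntip) tip_states[tree$tip.label[node]] else
      row[match(node, internals)]
  }
  changes <- apply(grid, 1, function(row) {
    sum(vapply(seq_len(nrow(tree$edge)), function(e) {
      label_of(row, tree$edge[e, 1]) != label_of(row, tree$edge[e, 2])
    }, logical(1)))
  })
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  sort(unique(grid[changes == min(changes), match(root, internals)]))
}

## Naive per-column re-check of the FdNs fixation predicate.
oracle_fdns_predicate <- function(aln, foreground, outgroup, col,
                                  reported_anc, reported_der) {
  aa <- aa_matrix(aln)
  fg <- aa[foreground, col]
  og <- aa[outgroup, col]
  all(fg == reported_der) &&
    !any(fg %in% c("-", "X")) &&
    reported_anc != reported_der &&
    reported_anc %in% og
}
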