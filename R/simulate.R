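## ---- codon alignment simulation ---------------------------------------------

#' Simulate a codon alignment under branch-site Model A
#'
#' Evolves codon sites along a tree under the same GY94 generator used for
#' inference: root codons are drawn from the equilibrium frequencies, each
#' site belongs to one of the four Model A classes (drawn from the class
#' proportions or supplied), and transitions along each branch follow
#' `exp(Qt)` with the class's background omega everywhere except the marked
#' foreground branch, which uses the class's foreground omega.
#'
#' @param tree `phylo` with branch lengths (expected substitutions per codon
#'   site) and a foreground mark for branch-site regimes.
#' @param n_sites Number of codon sites.
#' @param kappa,omega0,omega2,p0,p1 Model parameters (see
#'   [fit_branch_site()]).
#' @param codon_freqs Equilibrium frequencies over sense codons (default
#'   uniform).
#' @param code A [genetic_code()] or table id.
#' @param seed Mandatory seed; identical seed and configuration give
#'   byte-identical output.
#' @param site_classes Optional integer vector in 1:4 (classes 0, 1, 2a, 2b)
#'   overriding the random class assignment.
#' @return List with `alignment` (a gap-free, stop-free [codon_alignment()]),
#'   `site_classes` (true class per site) and `tree`.
#' @export
simulate_codon_alignment <- function(tree, n_sites, kappa = 2, omega0 = 0.1,
                                     omega2 = 1, p0 = 0.7, p1 = 0.2,
                                     codon_freqs = NULL,
                                     code = genetic_code(5L), seed,
                                     site_classes = NULL) {
  if (missing(seed)) stopf("seed is mandatory for simulation")
  code <- as_genetic_code(code)
  s <- length(code$sense)
  pi <- codon_freqs %||% rep(1 / s, s)
  if (!is.null(names(pi))) pi <- pi[code$sense]
  if (p0 < 0 || p1 < 0 || p0 + p1 > 1) stopf("invalid class proportions")
  classes <- model_a_classes(p0, p1, omega0, omega2)
  fg <- foreground_edge(tree)

  ## same generator code as inference, jointly scaled by the background rate
  omegas <- sort(unique(c(classes$bg, classes$fg)))
  Qs <- lapply(omegas, function(w) {
    build_generator(codon_model(kappa, w, pi, code), scale = FALSE)
  })
  rates <- vapply(Qs, attr, numeric(1), "rate")
  scale <- sum(classes$weights * rates[match(classes$bg, omegas)])
  eigs <- lapply(Qs, function(Q) generator_eigen(Q / scale, pi))
  pmat <- function(widx, t) {
    P <- eigs[[widx]]$A %*% (exp(eigs[[widx]]$lambda * t) * eigs[[widx]]$B)
    P[P < 0] <- 0
    P / rowSums(P)
  }

  post <- postorder_edges(tree)
  edges <- post$edges[rev(seq_len(nrow(post$edges))), , drop = FALSE] # preorder
  lens <- rev(post$lengths)
  fg_post <- if (fg > 0L) which(post$orig_index == fg) else 0L
  fg_pre <- if (fg_post > 0L) nrow(edges) + 1L - fg_post else 0L

  with_seed(seed, {
    cls <- site_classes %||% sample.int(4L, n_sites, replace = TRUE,
                                        prob = classes$weights)
    stopifnot(all(cls %in% 1:4), length(cls) == n_sites)
    nodes <- matrix(NA_integer_, post$nnode, n_sites)
    root <- edges[1, 1]
    nodes[root, ] <- sample.int(s, n_sites, replace = TRUE, prob = pi)
    for (e in seq_len(nrow(edges))) {
      parent <- edges[e, 1]; child <- edges[e, 2]
      for (k in sort(unique(cls))) {
        w <- if (e == fg_pre) classes$fg[k] else classes$bg[k]
        P <- pmat(match(w, omegas), lens[e])
        sites_k <- which(cls == k)
        par_states <- nodes[parent, sites_k]
        for (st in unique(par_states)) {
          sel <- sites_k[par_states == st]
          nodes[child, sel] <- sample.int(s, length(sel), replace = TRUE,
                                          prob = P[st, ])
        }
      }
    }
    codons <- matrix(code$sense[nodes[seq_len(post$ntip), ]],
                     nrow = post$ntip,
                     dimnames = list(tree$tip.label, NULL))
    list(alignment = codon_alignment(codons, code = code,
                                     strip_terminal_stop = FALSE),
         site_classes = cls, tree = tree)
  })
}

#' Plant clade-fixed derived nonsynonymous substitutions
#'
#' Overwrites scheduled alignment columns with a known FdNs configuration:
#' every foreground taxon receives the derived codon (optionally with seeded
#' synonymous scatter preserving the derived amino acid) and every outgroup
#' taxon the ancestral codon. The schedule is returned as a truth table for
#' recall checks against [detect_fdns()].
#'
#' @param aln A [codon_alignment()].
#' @param clade A [clade_spec()] naming the foreground taxa.
#' @param schedule Data frame with columns `site`, `ancestral_codon`,
#'   `derived_codon` and optional `syn_scatter` (logical).
#' @param seed Seed for the synonymous scatter.
#' @return List with `alignment` and `truth` (schedule plus the derived and
#'   ancestral amino acids).
#' @export
plant_fdns <- function(aln, clade, schedule, seed = 1L) {
  if (nrow(schedule) == 0L) return(list(alignment = aln, truth = schedule))
  code <- aln$code
  if (is.null(schedule$syn_scatter)) schedule$syn_scatter <- FALSE
  ham <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  with_seed(seed, {
    for (i in seq_len(nrow(schedule))) {
      anc <- toupper(schedule$ancestral_codon[i])
      der <- toupper(schedule$derived_codon[i])
      site <- schedule$site[i]
      if (site < 1L || site > ncol(aln$codons)) stopf("scheduled site %d out of range", site)
      if (anc == der) stopf("derived codon equals ancestral at site %d", site)
      if (!all(c(anc, der) %in% code$sense)) stopf("scheduled codons must be sense codons")
      if (ham(anc, der) != 1L) stopf("derived codon must be one nucleotide from ancestral")
      if (code$codon_to_aa[anc] == code$codon_to_aa[der]) {
        stopf("scheduled substitution at site %d is synonymous", site)
      }
      aln$codons[clade$outgroup, site] <- anc
      aln$codons[clade$foreground, site] <- der
      if (isTRUE(schedule$syn_scatter[i])) {
        syn <- setdiff(code$sense[code$codon_to_aa[code$sense] ==
                                    code$codon_to_aa[der]], der)
        if (length(syn) && length(clade$foreground) > 1L) {
          tx <- sample(clade$foreground, 1L)
          aln$codons[tx, site] <- sample(syn, 1L)
        }
      }
    }
    truth <- schedule
    truth$ancestral_aa <- unname(code$codon_to_aa[toupper(schedule$ancestral_codon)])
    truth$derived_aa <- unname(code$codon_to_aa[toupper(schedule$derived_codon)])
    truth$branch <- clade$label
    list(alignment = aln, truth = truth)
  })
}

## ---- toy structures -----------------------------------------------------------

#' Generate a toy protein structure with channel annotations
#'
#' Builds a small synthetic structure (ideal alpha-helix backbone trace or a
#' seeded self-avoiding random coil, one CA and one CB-like atom per residue),
#' designates a channel residue set, and returns the true minimum
#' residue-to-channel distances computed by exhaustive pairwise search for use
#' as ground truth.
#'
#' @param n_residues Number of residues (>= 3).
#' @param geometry `"helix"` or `"coil"`.
#' @param channel_residues Residue numbers forming the channel (default: every
#'   5th residue).
#' @param pathway Channel name.
#' @param seed Seed (used by the coil geometry and CB placement).
#' @return List with `structure` ([structure_model()]), `channel`
#'   ([channel_annotation()], query frame) and `true_distances` (per residue).
#' @export
toy_structure <- function(n_residues, geometry = c("helix", "coil"),
                          channel_residues = NULL, pathway = "H", seed = 1L) {
  stopifnot(n_residues >= 3L)
  geometry <- match.arg(geometry)
  channel_residues <- channel_residues %||% seq(1L, n_residues, by = 5L)
  with_seed(seed, {
    ca <- if (geometry == "helix") {
      th <- (seq_len(n_residues) - 1L) * 100 * pi / 180
      cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * (seq_len(n_residues) - 1L))
    } else {
      steps <- matrix(rnorm(3L * (n_residues - 1L)), ncol = 3)
      steps <- 3.8 * steps / sqrt(rowSums(steps^2))
      apply(rbind(0, steps), 2, cumsum)
    }
    cb <- ca + matrix(rnorm(3L * n_residues, sd = 0.5), ncol = 3) + 1
    atoms <- data.frame(
      chain = "A",
      resno = rep(seq_len(n_residues), each = 2L),
      resid = "ALA",
      elety = rep(c("CA", "CB"), n_residues),
      x = as.vector(rbind(ca[, 1], cb[, 1])),
      y = as.vector(rbind(ca[, 2], cb[, 2])),
      z = as.vector(rbind(ca[, 3], cb[, 3])),
      stringsAsFactors = FALSE
    )
    struct <- structure_model(atoms)
    channel <- channel_annotation(
      data.frame(pathway = pathway, chain = "A", resno = channel_residues,
                 stringsAsFactors = FALSE),
      frame = "query"
    )
    ## exhaustive ground truth from the full atom-pair distance matrix
    D <- as.matrix(stats::dist(atoms[, c("x", "y", "z")]))
    ch_atoms <- which(atoms$resno %in% channel_residues)
    true_d <- vapply(seq_len(n_residues), function(r) {
      min(D[atoms$resno == r, ch_atoms])
    }, numeric(1))
    list(structure = struct, channel = channel,
         true_distances = data.frame(resno = seq_len(n_residues),
                                     distance = true_d))
  })
}

## ---- OCR plates ----------------------------------------------------------------

#' Simulate an OCR plate with known ground truth
#'
#' Generates the standard 32-cycle plate layout: an untreated plateau (cycles
#' 1 to inj1-1), a post-injection-1 plateau (FCCP or DMSO level), a
#' post-azide plateau, background wells at a constant baseline, and Gaussian
#' measurement noise. True derived metrics are computed directly from the
#' configured levels.
#'
#' @param untreated,dmso_level,fccp_level,azide_level Plateau OCR levels
#'   (pmol O2/min) for sample wells; `dmso_level`/`fccp_level` apply after
#'   injection 1 to the respective group.
#' @param background Background-well level.
#' @param sigma Gaussian noise standard deviation (0 = noiseless).
#' @param n_wells Sample wells per treatment group.
#' @param n_background Background wells.
#' @param worms Worms per sample well.
#' @param n_cycles,injections Run layout.
#' @param seed Mandatory seed.
#' @return List with `plate` ([ocr_plate()]) and `truth` (per-worm basal,
#'   maximal, spare, untreated).
#' @export
simulate_ocr_plate <- function(untreated = 20, dmso_level = 18,
                               fccp_level = 45, azide_level = 4,
                               background = 2, sigma = 1,
                               n_wells = 3L, n_background = 2L, worms = 70,
                               n_cycles = 32L, injections = c(9L, 29L), seed) {
  if (missing(seed)) stopf("seed is mandatory for simulation")
  stopifnot(untreated >= 0, dmso_level >= 0, fccp_level >= 0, azide_level >= 0)
  phase <- function(level1) {
    c(rep(untreated, injections[1] - 1L),
      rep(level1, injections[2] - injections[1]),
      rep(azide_level, n_cycles - injections[2] + 1L))
  }
  wells <- data.frame(
    well = sprintf("W%02d", seq_len(2L * n_wells + n_background)),
    group = c(rep("DMSO", n_wells), rep("FCCP", n_wells),
              rep("BG", n_background)),
    worms = c(rep(worms, 2L * n_wells), rep(NA, n_background)),
    role = c(rep("sample", 2L * n_wells), rep("background", n_background)),
    stringsAsFactors = FALSE
  )
  base <- rbind(
    matrix(rep(phase(dmso_level) + background, n_wells), n_wells, byrow = TRUE),
    matrix(rep(phase(fccp_level) + background, n_wells), n_wells, byrow = TRUE),
    matrix(background, n_background, n_cycles)
  )
  rownames(base) <- wells$well
  with_seed(seed, {
    noisy <- base + if (sigma > 0) {
      matrix(rnorm(length(base), sd = sigma), nrow(base))
    } else 0
    plate <- ocr_plate(wells, noisy, injections = injections)
    truth <- list(
      basal = (dmso_level - azide_level) / worms,
      maximal = (fccp_level - azide_level) / worms,
      spare = (fccp_level - dmso_level) / worms,
      untreated = untreated / worms
    )
    list(plate = plate, truth = truth)
  })
}
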