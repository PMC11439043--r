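#' Protein structure model
#'
#' Minimal heavy-atom coordinate container: one row per atom with chain,
#' author residue number, residue name, atom name and coordinates in Angstrom.
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z` (and optionally `occ`).
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stopf("atoms need columns: %s", paste(need, collapse = ", "))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stopf("non-finite atom coordinates")
  }
  if (is.null(atoms$occ)) atoms$occ <- 1
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues, chains %s\n",
              nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resno")])),
              paste(unique(x$atoms$chain), collapse = ", ")))
  invisible(x)
}

#' Read a PDB coordinate file
#'
#' Keeps the first model only, the highest-occupancy alternate location of
#' each atom, and heavy atoms only (hydrogens excluded).
#'
#' @param path PDB file.
#' @return A [structure_model()].
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  atom_lines <- grep("^ATOM", lines)
  if (!length(atom_lines)) stopf("no ATOM records in %s", path)
  for (i in atom_lines) {
    coords <- suppressWarnings(as.numeric(c(
      substr(lines[i], 31, 38), substr(lines[i], 39, 46), substr(lines[i], 47, 54)
    )))
    if (anyNA(coords)) stopf("malformed coordinate field at line %d of %s", i, path)
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  ## drop hydrogens
  elesy <- at$elesy
  elesy[is.na(elesy) | elesy == ""] <- sub("^[0-9]*([A-Za-z]).*$", "\\1",
                                           at$elety[is.na(elesy) | elesy == ""])
  at <- at[toupper(elesy) != "H", , drop = FALSE]
  ## highest-occupancy altloc per atom
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  ord <- order(key, -at$o)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), , drop = FALSE]
  at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  at$chain[is.na(at$chain)] <- "A"
  structure_model(data.frame(
    chain = at$chain, resno = at$resno, resid = at$resid, elety = at$elety,
    x = at$x, y = at$y, z = at$z, occ = at$o, stringsAsFactors = FALSE
  ))
}

#' Write a structure model as a minimal PDB file
#'
#' @param struct A [structure_model()].
#' @param path Output file.
#' @export
write_structure <- function(struct, path) {
  a <- struct$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
    seq_len(nrow(a)), substr(a$elety, 1, 4), substr(a$resid, 1, 3),
    substr(a$chain, 1, 1), a$resno, a$x, a$y, a$z, a$occ, 0
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a channel-residue annotation table
#'
#' Tab-separated file with header columns `pathway`, `chain`, `resno` and an
#' optional `frame` column (or a single `frame` value for the whole file)
#' declaring whether residue numbers are in template or query numbering.
#'
#' @param path TSV file.
#' @param frame Numbering frame if not given in the file.
#' @return Object of class `channel_annotation` (data frame).
#' @export
read_channel_annotation <- function(path, frame = "template") {
  d <- read.delim(path, stringsAsFactors = FALSE)
  channel_annotation(d, frame = if ("frame" %in% names(d)) d$frame[1] else frame)
}

#' @rdname read_channel_annotation
#' @param x Data frame with columns `pathway`, `chain`, `resno`.
#' @export
channel_annotation <- function(x, frame = "query") {
  need <- c("pathway", "chain", "resno")
  if (!all(need %in% names(x)) || nrow(x) == 0L) {
    stopf("channel annotation needs a non-empty table with columns: %s",
          paste(need, collapse = ", "))
  }
  attr(x, "frame") <- frame
  class(x) <- c("channel_annotation", class(x))
  x
}

## ---- residue numbering transfer ---------------------------------------------

#' Residue mapping between two protein sequences
#'
#' Global pairwise alignment (Needleman-Wunsch, BLOSUM62, affine gaps) whose
#' aligned columns induce a strictly increasing, injective map between
#' positions of the two sequences; gap-aligned positions are unmapped.
#'
#' @param seqA,seqB Amino-acid strings.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @param substitution_matrix Name of the substitution matrix.
#' @return Object of class `residue_mapping` with `ab` (length `nchar(seqA)`,
#'   `NA` = unmapped) and `ba` (inverse).
#' @export
residue_mapping <- function(seqA, seqB, gap_opening = 10, gap_extension = 0.5,
                            substitution_matrix = "BLOSUM62") {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  alnA <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  alnB <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ab <- rep(NA_integer_, nchar(seqA))
  ba <- rep(NA_integer_, nchar(seqB))
  ia <- 0L; ib <- 0L
  for (k in seq_along(alnA)) {
    if (alnA[k] != "-") ia <- ia + 1L
    if (alnB[k] != "-") ib <- ib + 1L
    if (alnA[k] != "-" && alnB[k] != "-") {
      ab[ia] <- ib
      ba[ib] <- ia
    }
  }
  structure(list(ab = ab, ba = ba, score = Biostrings::score(pa),
                 params = list(gap_opening = gap_opening,
                               gap_extension = gap_extension,
                               substitution_matrix = substitution_matrix)),
            class = "residue_mapping")
}

#' Map a residue position from one sequence into another
#'
#' @inheritParams residue_mapping
#' @param posA 1-based position(s) in `seqA`.
#' @param mapping Optional precomputed [residue_mapping()] (avoids realigning).
#' @return Integer position(s) in `seqB`; `NA` where `posA` aligns to a gap.
#' @export
map_residue_coordinates <- function(seqA, seqB, posA, mapping = NULL, ...) {
  mapping <- mapping %||% residue_mapping(seqA, seqB, ...)
  if (any(posA < 1L | posA > length(mapping$ab))) {
    stopf("posA out of range [1, %d]", length(mapping$ab))
  }
  mapping$ab[posA]
}

## ---- distances and proximity -------------------------------------------------

#' Minimum heavy-atom distance from a residue to a channel residue set
#'
#' @param struct A [structure_model()].
#' @param residue Length-2 vector or list `(chain, resno)`.
#' @param channel A [channel_annotation()] (one or more pathways) already in
#'   the structure's numbering frame.
#' @return Data frame with one row per pathway: `pathway`, `distance`
#'   (Angstrom), `nearest_chain`, `nearest_resno`.
#' @export
min_channel_distance <- function(struct, residue, channel) {
  a <- struct$atoms
  ra <- a[a$chain == residue[[1]] & a$resno == as.integer(residue[[2]]), , drop = FALSE]
  if (!nrow(ra)) stopf("residue %s:%s not in structure", residue[[1]], residue[[2]])
  out <- lapply(split(as.data.frame(channel), channel$pathway), function(ch) {
    found <- logical(nrow(ch))
    best <- Inf
    nearest <- c(NA_character_, NA_integer_)
    for (i in seq_len(nrow(ch))) {
      ma <- a[a$chain == ch$chain[i] & a$resno == ch$resno[i], , drop = FALSE]
      if (!nrow(ma)) next
      found[i] <- TRUE
      d2 <- outer(ra$x, ma$x, `-`)^2 + outer(ra$y, ma$y, `-`)^2 +
        outer(ra$z, ma$z, `-`)^2
      m <- sqrt(min(d2))
      if (m < best) {
        best <- m
        nearest <- c(ch$chain[i], ch$resno[i])
      }
    }
    if (!any(found)) {
      stopf("no channel member of pathway '%s' resolvable in structure: %s",
            ch$pathway[1],
            paste(ch$chain, ch$resno, sep = ":", collapse = ", "))
    }
    data.frame(pathway = ch$pathway[1], distance = best,
               nearest_chain = nearest[1],
               nearest_resno = as.integer(nearest[2]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Classify residue-to-channel proximity
#'
#' `within4` when the minimum distance is at or below the contact threshold
#' (4 Angstrom, inclusive), else `within13` at or below the proximity
#' threshold (13 Angstrom, inclusive), else `distal`.
#'
#' @param distances Numeric vector of minimum distances (Angstrom).
#' @param thresholds Length-2 vector `(contact, proximal)`.
#' @return Factor with levels `within4`, `within13`, `distal`.
#' @export
classify_proximity <- function(distances, thresholds = c(4, 13)) {
  if (any(distances < 0, na.rm = TRUE)) stopf("negative distance")
  stopifnot(length(thresholds) == 2L, thresholds[1] <= thresholds[2])
  cls <- ifelse(distances <= thresholds[1], "within4",
                ifelse(distances <= thresholds[2], "within13", "distal"))
  factor(cls, levels = c("within4", "within13", "distal"))
}

#' Proximity of residues to annotated channels
#'
#' Computes, for each query residue, the minimum heavy-atom distance to every
#' annotated pathway and the proximity class of the overall minimum.
#'
#' @param struct A [structure_model()].
#' @param residues Data frame with columns `chain`, `resno` (extra columns are
#'   carried through).
#' @inheritParams min_channel_distance
#' @inheritParams classify_proximity
#' @return Data frame of class `proximity_records`: inputs plus one distance
#'   column per pathway, `min_distance`, `nearest_pathway`, `class`.
#' @export
proximity_map <- function(struct, residues, channel, thresholds = c(4, 13)) {
  rows <- lapply(seq_len(nrow(residues)), function(i) {
    d <- min_channel_distance(struct, list(residues$chain[i], residues$resno[i]),
                              channel)
    wide <- setNames(as.list(d$distance), paste0("dist_", d$pathway))
    j <- which.min(d$distance)
    cbind(residues[i, , drop = FALSE],
          as.data.frame(wide),
          data.frame(min_distance = d$distance[j],
                     nearest_pathway = d$pathway[j],
                     nearest_resno = d$nearest_resno[j]))
  })
  out <- do.call(rbind, rows)
  out$class <- classify_proximity(out$min_distance, thresholds)
  rownames(out) <- NULL
  class(out) <- c("proximity_records", class(out))
  out
}

## ---- superposition -----------------------------------------------------------

#' RMSD after optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of two matched coordinate sets by the Kabsch
#' algorithm; reflections are disallowed (proper rotations only).
#'
#' @param coordsA,coordsB Numeric n x 3 matrices of matched points (n >= 3).
#' @return Single RMSD value in the input units, with the rotation matrix and
#'   translation in attributes `rotation` and `translation`.
#' @export
superpose_rmsd <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA)
  coordsB <- as.matrix(coordsB)
  if (!all(dim(coordsA) == dim(coordsB)) || ncol(coordsA) != 3L) {
    stopf("coordinate sets must be matched n x 3 matrices")
  }
  if (nrow(coordsA) < 3L) stopf("need at least 3 points")
  ca <- colMeans(coordsA)
  cb <- colMeans(coordsB)
  A0 <- sweep(coordsA, 2, ca)
  B0 <- sweep(coordsB, 2, cb)
  s <- svd(t(B0) %*% A0)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Bfit <- B0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((A0 - Bfit)^2)))
  attr(rmsd, "rotation") <- R
  attr(rmsd, "translation") <- ca - as.vector(R %*% cb)
  rmsd
}
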