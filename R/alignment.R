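#' In-frame codon alignment
#'
#' Container for an aligned set of protein-coding nucleotide sequences kept in
#' reading frame, bound to a genetic code. Gaps must be representable as
#' whole-codon triplets; complete non-terminal stop codons are rejected.
#'
#' @param x Named character vector of aligned nucleotide sequences (equal
#'   lengths, divisible by 3), or a taxa x sites character matrix of codon
#'   triplets with row names.
#' @param code A [genetic_code()] or table id (default 5, invertebrate
#'   mitochondrial).
#' @param strip_terminal_stop Drop a final codon column consisting only of
#'   stop codons and/or gaps (logged via `message`)?
#' @return Object of class `codon_alignment`: list with `taxa`, `codons`
#'   (character matrix, taxa x codon sites), `code` and optional `gene_ranges`.
#' @examples
#' aln <- codon_alignment(c(a = "ATGTTT", b = "ATGTTC"))
#' @export
codon_alignment <- function(x, code = genetic_code(5L),
                            strip_terminal_stop = TRUE) {
  code <- as_genetic_code(code)
  if (is.matrix(x)) {
    codons <- toupper(x)
    if (is.null(rownames(codons))) stopf("codon matrix needs taxon row names")
  } else {
    if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
      stopf("sequences must be named by taxon")
    }
    if (length(x) == 0L) stopf("alignment is empty")
    x <- toupper(gsub("\\s", "", x))
    len <- nchar(x)
    if (length(unique(len)) != 1L) {
      stopf("aligned sequences have unequal lengths: %s",
            paste(unique(len), collapse = ", "))
    }
    if (len[1] %% 3L != 0L) {
      stopf("alignment length %d is not divisible by 3 (frame error)", len[1])
    }
    nsite <- len[1] %/% 3L
    codons <- matrix("", nrow = length(x), ncol = nsite,
                     dimnames = list(names(x), NULL))
    for (i in seq_along(x)) {
      codons[i, ] <- substring(x[i], 3L * seq_len(nsite) - 2L,
                               3L * seq_len(nsite))
    }
  }
  if (anyDuplicated(rownames(codons))) stopf("duplicated taxon labels")

  ## gaps must fill whole codons
  partial <- grepl("-", codons) & codons != "---"
  if (any(partial)) {
    w <- which(partial, arr.ind = TRUE)[1, ]
    stopf("gap not aligned to codon boundary (taxon %s, codon site %d)",
          rownames(codons)[w[1]], w[2])
  }

  aln <- structure(
    list(taxa = rownames(codons), codons = codons, code = code,
         gene_ranges = NULL),
    class = "codon_alignment"
  )

  if (strip_terminal_stop && ncol(codons) > 0L) {
    last <- codons[, ncol(codons)]
    complete <- vapply(last, is_unambiguous_codon, logical(1))
    if (all(last[complete] %in% code$stops) && any(complete)) {
      msg("stripping terminal stop codon column ", ncol(codons))
      aln$codons <- codons[, -ncol(codons), drop = FALSE]
    }
  }

  check_internal_stops(aln)
  aln
}

check_internal_stops <- function(aln) {
  codons <- aln$codons
  complete <- matrix(vapply(codons, is_unambiguous_codon, logical(1)),
                     nrow = nrow(codons))
  stops <- matrix(FALSE, nrow(codons), ncol(codons))
  stops[complete] <- codons[complete] %in% aln$code$stops
  if (any(stops)) {
    w <- which(stops, arr.ind = TRUE)[1, ]
    stopf("in-frame stop codon %s (taxon %s, codon site %d)",
          codons[w[1], w[2]], rownames(codons)[w[1]], w[2])
  }
  invisible(aln)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("Codon alignment: %d taxa x %d codon sites (NCBI table %d)\n",
              length(x$taxa), ncol(x$codons), x$code$table_id))
  if (!is.null(x$gene_ranges)) {
    cat("  genes:", paste(sprintf("%s[%d-%d]", names(x$gene_ranges),
                                  vapply(x$gene_ranges, `[`, 1, 1),
                                  vapply(x$gene_ranges, `[`, 1, 2)),
                          collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
dim.codon_alignment <- function(x) dim(x$codons)

#' Number of codon sites
#' @param aln A `codon_alignment`.
#' @export
n_sites <- function(aln) ncol(aln$codons)

#' Read an in-frame codon alignment from FASTA
#'
#' @param path FASTA file of aligned coding sequences.
#' @inheritParams codon_alignment
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path, code = genetic_code(5L),
                                 strip_terminal_stop = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stopf("no FASTA records in %s", path)
  x <- setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  codon_alignment(x, code = code, strip_terminal_stop = strip_terminal_stop)
}

#' Write a codon alignment to FASTA
#'
#' @param aln A [codon_alignment()].
#' @param path Output file.
#' @export
write_codon_alignment <- function(aln, path) {
  seqs <- apply(aln$codons, 1, paste, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

#' Remove all codon columns containing a gap
#'
#' Excises every codon site at which any taxon carries a gap, preserving the
#' reading frame and the relative order of the remaining sites, as done before
#' codon-model fitting.
#'
#' @param aln A [codon_alignment()].
#' @return A gap-free `codon_alignment`; removed column indices are kept in
#'   attribute `removed_sites`.
#' @export
excise_gaps <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  has_gap <- apply(aln$codons == "---" | grepl("-", aln$codons), 2, any)
  out <- aln
  out$codons <- aln$codons[, !has_gap, drop = FALSE]
  if (!is.null(aln$gene_ranges)) {
    keep <- which(!has_gap)
    out$gene_ranges <- lapply(aln$gene_ranges, function(r) {
      inside <- keep >= r[1] & keep <= r[2]
      if (!any(inside)) return(NULL)
      range(match(keep[inside], keep))
    })
    out$gene_ranges <- Filter(Negate(is.null), out$gene_ranges)
  }
  attr(out, "removed_sites") <- which(has_gap)
  out
}

#' Concatenate per-gene codon alignments
#'
#' Joins alignments over an identical taxon set, in the given order, keeping a
#' per-gene site-range index. Row order follows the first alignment.
#'
#' @param alignments Named list of [codon_alignment()] objects.
#' @return A `codon_alignment` with `gene_ranges` set.
#' @export
concatenate_genes <- function(alignments) {
  stopifnot(is.list(alignments), length(alignments) > 0L)
  if (is.null(names(alignments))) {
    names(alignments) <- paste0("gene", seq_along(alignments))
  }
  taxa <- alignments[[1]]$taxa
  for (i in seq_along(alignments)) {
    missing <- setdiff(taxa, alignments[[i]]$taxa)
    extra <- setdiff(alignments[[i]]$taxa, taxa)
    if (length(missing) || length(extra)) {
      stopf("taxon set mismatch in '%s': missing [%s], unexpected [%s]",
            names(alignments)[i], paste(missing, collapse = ", "),
            paste(extra, collapse = ", "))
    }
  }
  mats <- lapply(alignments, function(a) a$codons[taxa, , drop = FALSE])
  joined <- do.call(cbind, mats)
  rownames(joined) <- taxa
  ends <- cumsum(vapply(mats, ncol, integer(1)))
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- codon_alignment(joined, code = alignments[[1]]$code,
                         strip_terminal_stop = FALSE)
  out$gene_ranges <- Map(function(s, e) c(s, e), starts, ends)
  names(out$gene_ranges) <- names(alignments)
  out
}

#' Amino-acid matrix of a codon alignment
#'
#' @param aln A [codon_alignment()].
#' @param allow_terminal_stop Passed to [translate_codons()].
#' @return Character matrix (taxa x sites) of one-letter amino acids.
#' @export
aa_matrix <- function(aln, allow_terminal_stop = TRUE) {
  m <- matrix("", nrow = nrow(aln$codons), ncol = ncol(aln$codons),
              dimnames = dimnames(aln$codons))
  for (i in seq_len(nrow(m))) {
    m[i, ] <- strsplit(
      translate_codons(aln$codons[i, ], aln$code,
                       allow_terminal_stop = allow_terminal_stop), "")[[1]]
  }
  m
}

#' Back-translate an amino-acid matrix into a codon alignment
#'
#' Each amino acid is encoded by a fixed canonical codon (the first codon for
#' that amino acid in TCAG order under the chosen code). Useful for encoding
#' published per-site amino-acid state patterns as alignment input; codon-level
#' attributes (single-nucleotide attributability, synonymous variation) of the
#' result reflect the canonical encoding, not the original data.
#'
#' @param aa Character matrix (taxa x sites) of one-letter amino acids, `-`
#'   for gaps.
#' @param code A [genetic_code()] or table id.
#' @return A [codon_alignment()].
#' @export
back_translate_aa <- function(aa, code = genetic_code(5L)) {
  code <- as_genetic_code(code)
  canon <- vapply(
    unique(unname(code$codon_to_aa[code$sense])),
    function(a) code$sense[code$codon_to_aa[code$sense] == a][1],
    character(1)
  )
  names(canon) <- unique(unname(code$codon_to_aa[code$sense]))
  bad <- setdiff(unique(as.vector(aa)), c(names(canon), "-"))
  if (length(bad)) stopf("cannot back-translate symbol(s): %s",
                         paste(bad, collapse = ", "))
  codons <- matrix("---", nrow = nrow(aa), ncol = ncol(aa),
                   dimnames = dimnames(aa))
  notgap <- aa != "-"
  codons[notgap] <- canon[aa[notgap]]
  codon_alignment(codons, code = code, strip_terminal_stop = FALSE)
}
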