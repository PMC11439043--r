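#' Genome record with feature annotations
#'
#' @param sequence Single nucleotide string.
#' @param features Optional data frame with columns `name`, `start`, `end`
#'   (1-based inclusive), `strand`, `type`.
#' @return Object of class `genome_record`.
#' @export
genome_record <- function(sequence, features = NULL) {
  sequence <- toupper(gsub("\\s", "", sequence))
  if (!is.null(features)) {
    need <- c("name", "start", "end", "strand", "type")
    if (!all(need %in% names(features))) {
      stopf("features need columns: %s", paste(need, collapse = ", "))
    }
    if (any(features$start < 1 | features$end > nchar(sequence) |
              features$start > features$end)) {
      stopf("feature coordinates out of sequence bounds [1, %d]",
            nchar(sequence))
    }
  }
  structure(list(sequence = sequence, features = features),
            class = "genome_record")
}

#' Read a genome record from FASTA (+ optional TSV feature table)
#'
#' @param fasta Single-record FASTA file.
#' @param features_tsv Optional tab-separated feature table with header
#'   `name start end strand type`.
#' @export
read_genome <- function(fasta, features_tsv = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) stopf("no FASTA record in %s", fasta)
  if (length(seqs) > 1L) msg("using first of ", length(seqs), " records")
  feats <- if (!is.null(features_tsv)) {
    read.delim(features_tsv, stringsAsFactors = FALSE)
  } else NULL
  genome_record(as.character(seqs[[1]]), feats)
}

#' Nucleotide composition statistics
#'
#' AT and GC percentages of a genome or of one named annotated region, as used
#' to characterise AT-rich mitochondrial genomes and control regions.
#'
#' @param rec A [genome_record()].
#' @param region Optional feature name restricting the computation.
#' @return Object of class `composition_stats`: `length`, `at_pct`, `gc_pct`,
#'   `ambiguous` (count of non-ACGT characters, excluded from percentages),
#'   `region`. Percentages are full precision; `print` shows one decimal.
#' @examples
#' composition_stats(genome_record("ATAT"))
#' @export
composition_stats <- function(rec, region = NULL) {
  stopifnot(inherits(rec, "genome_record"))
  seq <- rec$sequence
  if (!is.null(region)) {
    if (is.null(rec$features) || !region %in% rec$features$name) {
      stopf("unknown region name: %s", region)
    }
    f <- rec$features[rec$features$name == region, ][1, ]
    seq <- substr(seq, f$start, f$end)
  }
  n <- nchar(seq)
  counts <- table(factor(strsplit(seq, "")[[1]],
                         levels = c("A", "C", "G", "T")))
  known <- sum(counts)
  structure(
    list(
      length = n,
      at_pct = if (known > 0) 100 * (counts[["A"]] + counts[["T"]]) / known else NA_real_,
      gc_pct = if (known > 0) 100 * (counts[["G"]] + counts[["C"]]) / known else NA_real_,
      ambiguous = n - known,
      region = region %||% "full sequence"
    ),
    class = "composition_stats"
  )
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf("%s: %d bp, AT %.1f%%, GC %.1f%%",
              x$region, x$length, x$at_pct, x$gc_pct))
  if (x$ambiguous > 0) cat(sprintf(" (%d ambiguous excluded)", x$ambiguous))
  cat("\n")
  invisible(x)
}
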