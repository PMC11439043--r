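NUC <- c("T", "C", "A", "G")

IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  "-" = c("A", "C", "G", "T"), "?" = c("A", "C", "G", "T")
)

ALL_CODONS <- as.vector(t(outer(
  as.vector(t(outer(NUC, NUC, paste0))), NUC, paste0
)))

#' Genetic code tables
#'
#' Builds a genetic code object from an NCBI translation table identifier.
#' The default, table 5, is the invertebrate mitochondrial code used for
#' nematode mitochondrial genes: ATA encodes Met, AGA/AGG encode Ser and TGA
#' encodes Trp, leaving TAA/TAG as the only stop codons.
#'
#' @param table_id NCBI translation table number (e.g. 1 standard,
#'   2 vertebrate mitochondrial, 5 invertebrate mitochondrial).
#' @return An object of class `genetic_code` with elements `table_id`,
#'   `codon_to_aa` (named character over all 64 codons, `*` marks stops),
#'   `sense` (sense codons in fixed order) and `stops`.
#' @examples
#' code <- genetic_code(5)
#' code$codon_to_aa[c("ATA", "AGA", "TGA")]
#' @export
genetic_code <- function(table_id = 5L) {
  table_id <- as.integer(table_id)
  map <- tryCatch(
    Biostrings::getGeneticCode(as.character(table_id)),
    error = function(e) stopf("unknown NCBI translation table: %d", table_id)
  )
  map <- map[ALL_CODONS]
  stopifnot(length(map) == 64L, !anyNA(map))
  structure(
    list(
      table_id = table_id,
      codon_to_aa = map,
      sense = names(map)[map != "*"],
      stops = names(map)[map == "*"]
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf(
    "Genetic code (NCBI table %d): %d sense codons, stops: %s\n",
    x$table_id, length(x$sense), paste(x$stops, collapse = ", ")
  ))
  invisible(x)
}

as_genetic_code <- function(code) {
  if (inherits(code, "genetic_code")) return(code)
  genetic_code(code)
}

## Sense-codon indices (1..64) compatible with an observed triplet under the
## IUPAC alphabet. Gaps and fully ambiguous codons are compatible with all
## sense codons; a triplet only compatible with stops is an error upstream.
compatible_codons <- function(triplet, code) {
  chars <- strsplit(toupper(triplet), "")[[1]]
  if (length(chars) != 3L) stopf("not a triplet: '%s'", triplet)
  sets <- lapply(chars, function(ch) {
    s <- IUPAC[[ch]]
    if (is.null(s)) stopf("unknown nucleotide symbol '%s'", ch)
    s
  })
  cods <- as.vector(outer(
    as.vector(outer(sets[[1]], sets[[2]], paste0)), sets[[3]], paste0
  ))
  intersect(cods, code$sense)
}

is_unambiguous_codon <- function(triplet) {
  grepl("^[ACGTU]{3}$", toupper(triplet))
}

#' Translate codons to amino acids
#'
#' @param codons Character vector of triplets, or one in-frame nucleotide
#'   string whose length is divisible by 3.
#' @param code A [genetic_code()] or a table id.
#' @param allow_terminal_stop Keep a final stop codon (translated as `*`)?
#' @return Single amino-acid string. Ambiguous codons translate to their
#'   unique amino acid when all compatible codons agree, otherwise `X`;
#'   all-gap codons translate to `-`.
#' @examples
#' translate_codons(c("ATA", "AGA", "TGA"), genetic_code(5))
#' @export
translate_codons <- function(codons, code = genetic_code(5L),
                             allow_terminal_stop = TRUE) {
  code <- as_genetic_code(code)
  if (length(codons) == 1L && nchar(codons) > 3L) {
    if (nchar(codons) %% 3L != 0L) {
      stopf("sequence length %d is not divisible by 3", nchar(codons))
    }
    codons <- substring(codons, seq(1L, nchar(codons), 3L),
                        seq(3L, nchar(codons), 3L))
  }
  codons <- toupper(codons)
  aa <- character(length(codons))
  for (i in seq_along(codons)) {
    cod <- codons[i]
    if (cod %in% c("---", "...")) {
      aa[i] <- "-"
    } else if (is_unambiguous_codon(cod)) {
      a <- unname(code$codon_to_aa[gsub("U", "T", cod)])
      if (a == "*" && !(allow_terminal_stop && i == length(codons))) {
        stopf("internal stop codon %s at codon site %d", cod, i)
      }
      aa[i] <- a
    } else {
      compat <- compatible_codons(cod, code)
      hits <- unique(unname(code$codon_to_aa[compat]))
      aa[i] <- if (length(hits) == 1L) hits else "X"
    }
  }
  paste(aa, collapse = "")
}

## Amino-acid chemistry partition used to label substitutions.
AA_CHEM <- c(
  G = "nonpolar", A = "nonpolar", V = "nonpolar", L = "nonpolar",
  I = "nonpolar", P = "nonpolar", F = "nonpolar", M = "nonpolar",
  W = "nonpolar",
  S = "polar", T = "polar", C = "polar", Y = "polar", N = "polar",
  Q = "polar",
  K = "positive", R = "positive", H = "positive",
  D = "negative", E = "negative"
)

#' Chemical class of an amino acid
#'
#' Partition used for substitution labelling: nonpolar (G A V L I P F M W),
#' polar (S T C Y N Q), positively charged (K R H), negatively charged (D E).
#'
#' @param aa One-letter amino-acid codes.
#' @return Character vector of classes.
#' @export
aa_chem_class <- function(aa) {
  aa <- toupper(aa)
  bad <- setdiff(aa, names(AA_CHEM))
  if (length(bad)) stopf("nonstandard amino acid symbol: %s",
                         paste(bad, collapse = ", "))
  unname(AA_CHEM[aa])
}

#' Classify the chemical nature of an amino-acid substitution
#'
#' @param ancestral_aa,derived_aa One-letter amino-acid codes.
#' @return List with `from`, `to` (chemical classes), `label`
#'   ("from-to") and `polarity_crossing` (`TRUE` when exactly one side of the
#'   substitution is nonpolar).
#' @examples
#' classify_chemistry("F", "Y") # nonpolar-polar, crossing
#' @export
classify_chemistry <- function(ancestral_aa, derived_aa) {
  cls <- aa_chem_class(c(ancestral_aa, derived_aa))
  list(
    from = cls[1], to = cls[2],
    label = paste(cls[1], cls[2], sep = "-"),
    polarity_crossing = xor(cls[1] == "nonpolar", cls[2] == "nonpolar")
  )
}
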