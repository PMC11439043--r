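#' Packaged COX substitution patterns and reference tree
#'
#' `cox_substitution_patterns()` returns the packaged table of clade-fixed
#' amino-acid replacement sites in nematode cytochrome c oxidase subunits
#' (per-site states for ten taxa, with bovine-template and H. mephisto
#' numbering, proximity flags and chemical-change labels).
#' `nematode_tree()` returns the matching ten-taxon reference topology.
#'
#' @return A data frame / `phylo` object.
#' @export
cox_substitution_patterns <- function() {
  read.delim(system.file("extdata", "cox_fdns_patterns.tsv",
                         package = "mitosel"),
             stringsAsFactors = FALSE)
}

#' @rdname cox_substitution_patterns
#' @export
nematode_tree <- function() {
  read_marked_tree(system.file("extdata", "nematode10.nwk",
                               package = "mitosel"))
}

#' Taxon order of the packaged substitution patterns
#' @export
cox_pattern_taxa <- function() {
  c("Btaurus", "Hsapiens", "Celegans", "Dpachys", "Dcoronatus",
    "Bxylophilus", "Predivivus", "Hmephisto", "Hgingivalis", "Hconsperatus")
}

#' Foreground clade definitions on the packaged tree
#'
#' Branch B = the Halicephalobus genus; branch C adds P. redivivus
#' (Panagrolaimidae); branch D adds B. xylophilus (Tylenchina).
#'
#' @param tree The ten-taxon reference tree.
#' @return Named list of [clade_spec()] objects.
#' @export
cox_clades <- function(tree = nematode_tree()) {
  hali <- c("Hmephisto", "Hgingivalis", "Hconsperatus")
  list(
    B = clade_spec(hali, tree, "B"),
    C = clade_spec(c("Predivivus", hali), tree, "C"),
    D = clade_spec(c("Bxylophilus", "Predivivus", hali), tree, "D")
  )
}

#' Rerun the FdNs scan on the packaged substitution patterns
#'
#' Encodes each packaged pattern row as a ten-taxon alignment column
#' (back-translated to codons under the invertebrate mitochondrial code), runs
#' [detect_fdns()] for each foreground clade (B, C, D) on each gene, and
#' summarizes the detected records by branch and gene.
#'
#' @param patterns Pattern table (default: the packaged one).
#' @param tree Reference tree.
#' @return List with `records` (all detected FdNs, with the template site of
#'   each source column attached), `summary` ([summarize_fdns()]), and
#'   `patterns`.
#' @export
fdns_reference_analysis <- function(patterns = cox_substitution_patterns(),
                                    tree = nematode_tree()) {
  taxa <- cox_pattern_taxa()
  clades <- cox_clades(tree)
  all_rec <- list()
  for (gene in unique(patterns$gene)) {
    rows <- patterns[patterns$gene == gene, , drop = FALSE]
    aa <- do.call(cbind, lapply(rows$states, function(s) strsplit(s, "")[[1]]))
    rownames(aa) <- taxa
    aln <- back_translate_aa(aa)
    aln$gene_ranges <- setNames(list(c(1L, ncol(aa))), gene)
    for (cl in clades) {
      rec <- detect_fdns(aln, tree, cl)
      if (nrow(rec)) {
        rec$template_site <- rows$template_site[rec$site]
        rec$query_site <- rows$query_site[rec$site]
        all_rec[[paste(gene, cl$label)]] <- rec
      }
    }
  }
  records <- do.call(rbind, all_rec)
  rownames(records) <- NULL
  list(records = records, summary = summarize_fdns(records),
       patterns = patterns)
}
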