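#' Clade specification for FdNs scanning
#'
#' Designates a foreground clade (by tip labels) on a tree; all remaining taxa
#' form the outgroup. The foreground must be monophyletic.
#'
#' @param foreground Tip labels of the foreground clade.
#' @param tree `phylo` containing all taxa.
#' @param label Branch label used in reports (e.g. "B", "C", "D").
#' @return Object of class `clade_spec`.
#' @export
clade_spec <- function(foreground, tree, label = "fg") {
  missing <- setdiff(foreground, tree$tip.label)
  if (length(missing)) stopf("foreground taxa not in tree: %s",
                             paste(missing, collapse = ", "))
  outgroup <- setdiff(tree$tip.label, foreground)
  if (!length(outgroup)) stopf("foreground cannot contain every taxon")
  mrca <- if (length(foreground) == 1L) {
    match(foreground, tree$tip.label)
  } else {
    ape::getMRCA(tree, foreground)
  }
  under <- tree$tip.label[clade_tips(tree, mrca)]
  if (!setequal(under, foreground)) {
    stopf("clade '%s' is not monophyletic: MRCA also spans %s", label,
          paste(setdiff(under, foreground), collapse = ", "))
  }
  structure(list(label = label, foreground = foreground, outgroup = outgroup,
                 mrca = mrca),
            class = "clade_spec")
}

## Structural context reused across alignment columns: attachment node,
## neighbor subtrees seen from it (excluding the clade), patristic-nearest
## lineage and per-lineage taxon ordering.
fdns_context <- function(tree, clade) {
  ntip <- ape::Ntip(tree)
  adj <- vector("list", ntip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    adj[[p]] <- c(adj[[p]], c)
    adj[[c]] <- c(adj[[c]], p)
  }
  parent <- rep(NA_integer_, ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  n0 <- parent[clade$mrca]
  if (is.na(n0)) stopf("foreground clade has no outgroup attachment (is it the whole tree?)")

  tips_from <- function(v, from) {
    out <- integer(0)
    stack <- list(c(v, from))
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      v <- cur[1]; fr <- cur[2]
      if (v <= ntip) out <- c(out, v)
      else for (u in adj[[v]]) if (u != fr) stack[[length(stack) + 1L]] <- c(u, v)
    }
    out
  }
  neighbors <- setdiff(adj[[n0]], clade$mrca)
  nb_tips <- lapply(neighbors, tips_from, from = n0)

  D <- ape::dist.nodes(tree)
  og_idx <- match(clade$outgroup, tree$tip.label)
  nb_dist <- vapply(nb_tips, function(tt) {
    tt <- intersect(tt, og_idx)
    if (!length(tt)) return(Inf)
    min(D[clade$mrca, tt])
  }, numeric(1))
  nearest_nb <- which.min(nb_dist)
  ## outgroup taxa inside each neighbor lineage, nearest first
  nb_taxa_ord <- lapply(nb_tips, function(tt) {
    tt <- intersect(tt, og_idx)
    tt[order(D[clade$mrca, tt])]
  })
  list(tree = tree, ntip = ntip, adj = adj, n0 = n0,
       neighbors = neighbors, nearest_nb = nearest_nb,
       nb_taxa_ord = nb_taxa_ord, og_idx = og_idx)
}

combine_fitch <- function(sets) {
  sets <- Filter(Negate(is.null), sets)
  if (!length(sets)) return(NULL)
  s <- sets[[1]]
  for (t in sets[-1]) {
    i <- intersect(s, t)
    s <- if (length(i)) i else union(s, t)
  }
  s
}

## Fitch state set of the subtree hanging from `v` when entered from `from`,
## over outgroup states only (NULL = uninformative).
fitch_from <- function(v, from, ctx, states) {
  if (v <= ctx$ntip) {
    st <- states[[v]]
    return(if (is.null(st) || is.na(st) || st %in% c("-", "X")) NULL else st)
  }
  combine_fitch(lapply(setdiff(ctx$adj[[v]], from),
                       fitch_from, from = v, ctx = ctx, states = states))
}

#' Ancestral amino acid of a clade from its outgroups
#'
#' Fitch parsimony over the outgroup states, evaluated on the outgroup subtree
#' rooted at the clade's attachment point. Ties are broken by the Fitch state
#' of the phylogenetically nearest outgroup lineage (smallest patristic
#' distance from the clade), then by the state of the nearest taxon within
#' that lineage; remaining ties are reported as ambiguous.
#'
#' @param column Named character vector of per-taxon amino acids (one-letter;
#'   `-`/`X` treated as missing). Must cover all outgroup taxa of `clade`.
#' @param clade A [clade_spec()].
#' @param tree The tree used to build `clade`.
#' @return List with `state` (character or `NA`), `candidates`, `ambiguous`,
#'   `tie_break` (`"none"`, `"lineage"`, `"taxon"` or `"unresolved"`).
#' @export
infer_ancestral_aa <- function(column, clade, tree) {
  ctx <- fdns_context(tree, clade)
  infer_ancestral_aa_ctx(column, ctx, tree)
}

infer_ancestral_aa_ctx <- function(column, ctx, tree) {
  states <- vector("list", ctx$ntip)
  for (tx in intersect(names(column), tree$tip.label)) {
    i <- match(tx, tree$tip.label)
    if (i %in% ctx$og_idx) states[[i]] <- toupper(column[[tx]])
  }
  nb_sets <- lapply(ctx$neighbors, function(u) {
    fitch_from(u, ctx$n0, ctx, states)
  })
  cand <- combine_fitch(nb_sets)
  if (is.null(cand)) stopf("no ancestral information: all outgroups are gapped")
  if (length(cand) == 1L) {
    return(list(state = cand, candidates = cand, ambiguous = FALSE,
                tie_break = "none"))
  }
  s1 <- nb_sets[[ctx$nearest_nb]]
  c2 <- intersect(cand, s1 %||% character(0))
  if (length(c2) == 1L) {
    return(list(state = c2, candidates = cand, ambiguous = FALSE,
                tie_break = "lineage"))
  }
  c3 <- if (length(c2)) c2 else cand
  for (i in ctx$nb_taxa_ord[[ctx$nearest_nb]]) {
    st <- states[[i]]
    if (is.null(st)) next
    if (st %in% c3) {
      return(list(state = st, candidates = cand, ambiguous = FALSE,
                  tie_break = "taxon"))
    }
    break
  }
  list(state = NA_character_, candidates = cand, ambiguous = TRUE,
       tie_break = "unresolved")
}

## 1-based position of alignment codon column `col` in taxon `tx`'s ungapped
## coordinate system; NA when the taxon is gapped at that column.
position_in_taxon <- function(aln, tx, col) {
  row <- aln$codons[tx, ]
  notgap <- row != "---"
  if (!notgap[col]) return(NA_integer_)
  sum(notgap[seq_len(col)])
}

#' Detect fixed derived nonsynonymous substitutions (FdNs)
#'
#' Scans a codon alignment for sites at which every foreground taxon shares an
#' amino acid that differs from the ancestral state reconstructed from the
#' outgroups ([infer_ancestral_aa()]). For each reported site the scanner
#' records whether the change is attributable to a single nucleotide
#' substitution (some observed outgroup codon encoding the ancestral amino
#' acid lies one nucleotide from some foreground codon), whether the
#' foreground shows synonymous codon variation preserving the derived amino
#' acid, and the chemical nature of the change ([classify_chemistry()]).
#'
#' Columns with a gap or ambiguity in any foreground taxon are disqualified
#' (fixation cannot be asserted); outgroup gaps are tolerated while at least
#' two ungapped outgroups remain. Sites whose ancestral state is ambiguous
#' after tie-breaking are skipped and listed in attribute `ambiguous_sites`.
#'
#' @param aln A [codon_alignment()].
#' @param tree `phylo` covering the alignment taxa.
#' @param clade A [clade_spec()] (or foreground tip labels).
#' @param strict_outgroup_absence Additionally require that no outgroup taxon
#'   carries the derived amino acid (a stricter fixation rule that discards
#'   sites with homoplasy in distant outgroups; default `FALSE`).
#' @param reference_taxon Taxon whose ungapped coordinates are reported as
#'   `ref_site` (default: first foreground taxon).
#' @param comparator_taxon Optional second taxon for dual numbering
#'   (`cmp_site`), e.g. a structural template species.
#' @return Data frame of class `fdns_records`; one row per substitution with
#'   site numbering, ancestral/derived states, flags and chemistry. Gene
#'   labels are filled in from `aln$gene_ranges` when present.
#' @export
detect_fdns <- function(aln, tree, clade, strict_outgroup_absence = FALSE,
                        reference_taxon = NULL, comparator_taxon = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (!inherits(clade, "clade_spec")) clade <- clade_spec(clade, tree)
  validate_tree_alignment(tree, aln)
  ctx <- fdns_context(tree, clade)
  aa <- aa_matrix(aln)
  fg <- clade$foreground
  og <- clade$outgroup
  reference_taxon <- reference_taxon %||% fg[1]

  gene_of <- function(col) {
    if (is.null(aln$gene_ranges)) return(NA_character_)
    for (g in names(aln$gene_ranges)) {
      r <- aln$gene_ranges[[g]]
      if (col >= r[1] && col <= r[2]) return(g)
    }
    NA_character_
  }

  rows <- list()
  ambiguous_sites <- integer(0)
  for (col in seq_len(ncol(aa))) {
    fg_aa <- aa[fg, col]
    if (any(fg_aa %in% c("-", "X"))) next
    a_f <- fg_aa[1]
    if (!all(fg_aa == a_f)) next
    og_aa <- aa[og, col]
    informative <- !(og_aa %in% c("-", "X"))
    if (sum(informative) < 2L) next
    anc <- infer_ancestral_aa_ctx(setNames(og_aa, og), ctx, tree)
    if (anc$ambiguous) {
      ambiguous_sites <- c(ambiguous_sites, col)
      next
    }
    if (anc$state == a_f) next
    if (strict_outgroup_absence && a_f %in% og_aa[informative]) next

    fg_codons <- unique(aln$codons[fg, col])
    anc_codons <- unique(aln$codons[og, col][og_aa == anc$state])
    anc_codons <- anc_codons[vapply(anc_codons, is_unambiguous_codon, logical(1))]
    hamming <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    min_ham <- if (length(anc_codons)) {
      min(outer(anc_codons, fg_codons, Vectorize(hamming)))
    } else NA_integer_
    chem <- classify_chemistry(anc$state, a_f)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = gene_of(col),
      site = col,
      ref_taxon = reference_taxon,
      ref_site = position_in_taxon(aln, reference_taxon, col),
      cmp_taxon = comparator_taxon %||% NA_character_,
      cmp_site = if (is.null(comparator_taxon)) NA_integer_ else
        position_in_taxon(aln, comparator_taxon, col),
      branch = clade$label,
      ancestral_aa = anc$state,
      derived_aa = a_f,
      single_snp = !is.na(min_ham) && min_ham == 1L,
      syn_variation = length(fg_codons) > 1L,
      chem_from = chem$from,
      chem_to = chem$to,
      chem_label = chem$label,
      polarity_crossing = chem$polarity_crossing,
      tie_break = anc$tie_break,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    gene = character(0), site = integer(0), ref_taxon = character(0),
    ref_site = integer(0), cmp_taxon = character(0), cmp_site = integer(0),
    branch = character(0), ancestral_aa = character(0),
    derived_aa = character(0), single_snp = logical(0),
    syn_variation = logical(0), chem_from = character(0),
    chem_to = character(0), chem_label = character(0),
    polarity_crossing = logical(0), tie_break = character(0),
    stringsAsFactors = FALSE
  )
  attr(out, "ambiguous_sites") <- ambiguous_sites
  class(out) <- c("fdns_records", class(out))
  out
}

#' Summarize FdNs records by branch and gene
#'
#' @param records One or more `fdns_records` data frames (concatenated with
#'   `rbind` if a list is given).
#' @return Data frame with one row per (branch, gene): `n`,
#'   `n_polarity_crossing`, `n_syn_variation`; total count in attribute
#'   `total` and printed by the method.
#' @export
summarize_fdns <- function(records) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, records)
  }
  if (is.null(records) || nrow(records) == 0L) {
    out <- data.frame(branch = character(0), gene = character(0),
                      n = integer(0), n_polarity_crossing = integer(0),
                      n_syn_variation = integer(0))
    attr(out, "total") <- 0L
    class(out) <- c("fdns_summary", class(out))
    return(out)
  }
  gene_key <- ifelse(is.na(records$gene), "(unassigned)", records$gene)
  key <- interaction(records$branch, gene_key, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(d) {
    data.frame(branch = d$branch[1], gene = d$gene[1], n = nrow(d),
               n_polarity_crossing = sum(d$polarity_crossing),
               n_syn_variation = sum(d$syn_variation),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$branch, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- nrow(records)
  class(out) <- c("fdns_summary", class(out))
  out
}

#' @export
print.fdns_summary <- function(x, ...) {
  cat(sprintf("FdNs summary: %d substitutions\n", attr(x, "total")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
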