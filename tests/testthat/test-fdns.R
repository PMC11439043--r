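ten_taxa <- cox_pattern_taxa()

aa_column_alignment <- function(states, taxa = ten_taxa) {
  aa <- matrix(strsplit(states, "")[[1]], ncol = 1)
  rownames(aa) <- taxa
  back_translate_aa(aa)
}

test_that("ancestral inference follows outgroup parsimony with documented tie-breaks", {
  tree <- nematode_tree()
  clades <- cox_clades(tree)
  ## all outgroups identical
  colA <- setNames(rep("A", 6), clades$C$outgroup)
  expect_identical(infer_ancestral_aa(colA, clades$C, tree)$state, "A")
  ## the branch-D column with outgroup states (T,N,F,F,F) resolves to F
  colD <- setNames(c("T", "N", "F", "F", "F"), clades$D$outgroup)
  resD <- infer_ancestral_aa(colD, clades$D, tree)
  expect_identical(resD$state, "F")
  expect_false(resD$ambiguous)
  ## gapped outgroups are uninformative; all gapped is an error
  expect_error(
    infer_ancestral_aa(setNames(rep("-", 6), clades$C$outgroup), clades$C, tree),
    "no ancestral information")
})

test_that("ancestral candidate sets match an exhaustive parsimony oracle", {
  ## Fitch on the outgroup subtree rooted at the attachment point equals the
  ## minimal-change root states found by enumerating all internal labelings
  tree <- read_marked_tree("(((f1:0.1,f2:0.1):0.3,(o1:0.2,o2:0.2):0.15):0.1,(o3:0.3,o4:0.3):0.2,o5:0.45);")
  clade <- clade_spec(c("f1", "f2"), tree, "X")
  ## outgroup subtree as seen from the attachment point
  og_tree <- ape::read.tree(text = "((o1:0.2,o2:0.2):0.15,((o3:0.3,o4:0.3):0.2,o5:0.45):0.1);")
  withr::with_seed(12, {
    for (i in 1:25) {
      sts <- setNames(sample(c("A", "S", "T", "V"), 5, replace = TRUE),
                      paste0("o", 1:5))
      res <- infer_ancestral_aa(sts, clade, tree)
      oracle <- oracle_fitch_root_set(og_tree, sts)
      expect_setequal(res$candidates, oracle)
      if (!res$ambiguous) expect_true(res$state %in% oracle)
    }
  })
})

test_that("detector reproduces canonical fixed-derived patterns", {
  tree <- nematode_tree()
  clades <- cox_clades(tree)
  ## clade C gains S from an all-A background
  rec <- detect_fdns(aa_column_alignment("AAAAAASSSS"), tree, clades$C)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$ancestral_aa, "A")
  expect_identical(rec$derived_aa, "S")
  expect_identical(rec$chem_label, "nonpolar-polar")
  ## clade B gains M; foreground synonymous recoding flips only syn_variation
  alnB <- aa_column_alignment("FFFFFFFMMM")
  recB <- detect_fdns(alnB, tree, clades$B)
  expect_identical(recB$derived_aa, "M")
  expect_false(recB$syn_variation)
  ## invariant column and broken fixation yield nothing
  expect_identical(nrow(detect_fdns(aa_column_alignment("LLLLLLLLLL"),
                                    tree, clades$C)), 0L)
  expect_identical(nrow(detect_fdns(aa_column_alignment("AAAAAASSSA"),
                                    tree, clades$C)), 0L)
  ## foreground gap disqualifies the column
  gapped <- aa_column_alignment("AAAAAASS-S")
  expect_identical(nrow(detect_fdns(gapped, tree, clades$C)), 0L)
})

test_that("detector is invariant to taxon order and synonymous recoding", {
  tree <- nematode_tree()
  clades <- cox_clades(tree)
  aln <- aa_column_alignment("AAAAAASSSS")
  rec0 <- detect_fdns(aln, tree, clades$C)
  perm <- sample(seq_len(10))
  aln2 <- aln
  aln2$codons <- aln$codons[perm, , drop = FALSE]
  aln2$taxa <- aln$taxa[perm]
  rec1 <- detect_fdns(aln2, tree, clades$C)
  expect_identical(rec1$ancestral_aa, rec0$ancestral_aa)
  expect_identical(rec1$derived_aa, rec0$derived_aa)
  ## recode one foreground serine synonymously: same call, syn_variation on
  aln3 <- aln
  stopifnot(aln3$codons["Hmephisto", 1] != "AGT")
  aln3$codons["Hmephisto", 1] <- "AGT"
  rec2 <- detect_fdns(aln3, tree, clades$C)
  expect_identical(rec2$derived_aa, rec0$derived_aa)
  expect_true(rec2$syn_variation)
})

test_that("single-nucleotide attributability is computed from observed codons", {
  tree <- nematode_tree()
  clades <- cox_clades(tree)
  base <- matrix("GCT", nrow = 10, ncol = 1, dimnames = list(ten_taxa, NULL))
  base[clades$C$foreground, 1] <- "TCT"  # Ala GCT -> Ser TCT, one change
  rec <- detect_fdns(codon_alignment(base, strip_terminal_stop = FALSE),
                     tree, clades$C)
  expect_true(rec$single_snp)
  base2 <- base
  base2[clades$C$foreground, 1] <- "AGT"  # Ser via a 2-nucleotide route
  rec2 <- detect_fdns(codon_alignment(base2, strip_terminal_stop = FALSE),
                      tree, clades$C)
  expect_identical(rec2$derived_aa, "S")
  expect_false(rec2$single_snp)
})

test_that("strict outgroup absence discards distant homoplasy", {
  tree <- nematode_tree()
  clades <- cox_clades(tree)
  ## branch-D column where one distant outgroup already carries the derived state
  aln <- aa_column_alignment("VLVVVLLLLL")
  expect_identical(nrow(detect_fdns(aln, tree, clades$D)), 1L)
  expect_identical(nrow(detect_fdns(aln, tree, clades$D,
                                    strict_outgroup_absence = TRUE)), 0L)
})

test_that("planted substitutions are recovered exactly, with no spurious records", {
  tree <- nematode_tree()
  clades <- cox_clades(tree)
  for (seed in 1:50) {
    ## constant background alignment; plant one substitution for clade C
    m <- matrix("ATG", nrow = 10, ncol = 12, dimnames = list(ten_taxa, NULL))
    aln <- codon_alignment(m, strip_terminal_stop = FALSE)
    planted <- plant_fdns(aln, clades$C,
                          data.frame(site = 5L + (seed %% 3L),
                                     ancestral_codon = "GCA",
                                     derived_codon = "TCA"),
                          seed = seed)
    rec <- detect_fdns(planted$alignment, tree, clades$C)
    expect_identical(nrow(rec), 1L)
    expect_identical(rec$site, planted$truth$site)
    expect_identical(rec$ancestral_aa, "A")
    expect_identical(rec$derived_aa, "S")
    expect_true(rec$single_snp)
    ## every reported record satisfies the naive per-column predicate
    expect_true(oracle_fdns_predicate(planted$alignment, clades$C$foreground,
                                      clades$C$outgroup, rec$site,
                                      rec$ancestral_aa, rec$derived_aa))
  }
})

test_that("branch summaries count totals, crossings and synonymous variation", {
  empty <- summarize_fdns(list())
  expect_identical(attr(empty, "total"), 0L)
  expect_identical(nrow(empty), 0L)
  res <- fdns_reference_analysis()
  s <- res$summary
  expect_identical(attr(s, "total"), 20L)
  expect_identical(s$n[s$branch == "D" & s$gene == "COX1"], 8L)
})

test_that("dual numbering reports positions in reference and comparator taxa", {
  tree <- nematode_tree()
  clades <- cox_clades(tree)
  m <- matrix("ATG", nrow = 10, ncol = 6, dimnames = list(ten_taxa, NULL))
  m["Btaurus", 1:2] <- "---"           # comparator offset by two codons
  m[clades$C$foreground, 4] <- "TCA"
  m[clades$C$outgroup, 4] <- "GCA"
  m["Btaurus", 4] <- "GCA"
  aln <- codon_alignment(m, strip_terminal_stop = FALSE)
  rec <- detect_fdns(aln, tree, clades$C, reference_taxon = "Hmephisto",
                     comparator_taxon = "Btaurus")
  expect_identical(rec$ref_site, 4L)
  expect_identical(rec$cmp_site, 2L)
})

test_that("non-monophyletic foreground is rejected", {
  tree <- nematode_tree()
  expect_error(clade_spec(c("Hmephisto", "Celegans"), tree, "bad"),
               "not monophyletic")
})
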