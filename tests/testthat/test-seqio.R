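test_that("codon alignments parse, validate frame and reject stops", {
  aln <- codon_alignment(c(a = "ATGTTT", b = "ATGTTC"))
  expect_identical(dim(aln), c(2L, 2L))
  expect_error(codon_alignment(c(a = "ATGTT", b = "ATGTT")), "divisible by 3")
  expect_error(codon_alignment(c(a = "ATGTTT", b = "ATGTTTTTT")), "unequal")
  expect_error(codon_alignment(c(a = "ATGTAATTT", b = "ATGAAATTT")),
               "stop codon")
  expect_error(codon_alignment(c(a = "AT-GTT", b = "ATGGTT")),
               "codon boundary")
})

test_that("terminal stop columns are stripped with a message", {
  expect_message(
    aln <- codon_alignment(c(a = "ATGTAA", b = "ATG---")),
    "terminal stop"
  )
  expect_identical(n_sites(aln), 1L)
})

test_that("FASTA round trip is lossless", {
  sim <- simulate_codon_alignment(tree6(), 40, seed = 11)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_codon_alignment(sim$alignment, f)
  back <- read_codon_alignment(f)
  expect_identical(back$codons, sim$alignment$codons)
  expect_identical(back$taxa, sim$alignment$taxa)
  ## byte-level: rewrite of the reread alignment is identical
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_codon_alignment(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("gap excision removes exactly the gap-containing codon columns", {
  m <- rbind(a = c("ATG", "TTT", "GGA"), b = c("ATG", "---", "GGA"))
  aln <- codon_alignment(m, strip_terminal_stop = FALSE)
  out <- excise_gaps(aln)
  expect_identical(n_sites(out), 2L)
  expect_identical(attr(out, "removed_sites"), 2L)
  ## no gaps → identity
  expect_identical(excise_gaps(out)$codons, out$codons)
  ## random gap patterns match a brute-force column scan
  for (seed in 1:5) {
    aln <- random_alignment(5, 30, seed = seed)
    withr::with_seed(seed, {
      gaps <- matrix(runif(5 * 30) < 0.1, 5, 30)
    })
    aln$codons[gaps] <- "---"
    out <- excise_gaps(aln)
    expect_identical(ncol(out$codons), sum(colSums(gaps) == 0))
    expect_false(any(grepl("-", out$codons)))
    ## surviving columns are a subsequence of the input columns
    kept <- setdiff(seq_len(30), attr(out, "removed_sites"))
    expect_identical(out$codons, aln$codons[, kept, drop = FALSE])
  }
})

test_that("gene concatenation keeps ranges and row order of the first gene", {
  g1 <- random_alignment(4, 5, seed = 1)
  g2 <- random_alignment(4, 7, seed = 2)
  cat12 <- concatenate_genes(list(one = g1, two = g2))
  expect_identical(n_sites(cat12), 12L)
  expect_identical(cat12$gene_ranges, list(one = c(1L, 5L), two = c(6L, 12L)))
  ## single gene → identity
  expect_identical(concatenate_genes(list(g = g1))$codons, g1$codons)
  ## shuffled taxon order in the second gene follows the first alignment
  g2shuf <- g2
  perm <- c(3, 1, 4, 2)
  g2shuf$codons <- g2$codons[perm, ]
  g2shuf$taxa <- g2$taxa[perm]
  expect_identical(concatenate_genes(list(g1, g2shuf))$codons,
                   cbind(g1$codons, g2$codons))
  ## taxon mismatch errors name the missing taxon
  g3 <- g2
  rownames(g3$codons)[1] <- "zz"
  g3$taxa[1] <- "zz"
  expect_error(concatenate_genes(list(g1, bad = g3)), "t1")
})

test_that("marked Newick trees round-trip labels, lengths and the mark", {
  tr <- tree6()
  expect_identical(foreground_taxa(tr), c("t1", "t2"))
  txt <- write_marked_tree(tr)
  tr2 <- read_marked_tree(txt)
  expect_identical(tr2$tip.label, tr$tip.label)
  expect_equal(tr2$edge.length, tr$edge.length, tolerance = 1e-10)
  expect_identical(foreground_taxa(tr2), foreground_taxa(tr))
  expect_error(read_marked_tree("((a#1:1,b:1):1,c#1:2);"), "more than one")
  expect_error(mark_foreground(ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1);"),
                               c("a", "b")),
               "not monophyletic")
})

test_that("composition statistics match character counting", {
  st <- composition_stats(genome_record("ATAT"))
  expect_identical(st$length, 4L)
  expect_equal(st$at_pct, 100)
  for (seed in 1:5) {
    withr::with_seed(seed, {
      s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE,
                        prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    })
    st <- composition_stats(genome_record(s))
    cnt <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
    expect_equal(st$at_pct, 100 * (cnt[["A"]] + cnt[["T"]]) / 500)
    expect_equal(st$at_pct + st$gc_pct, 100, tolerance = 1e-9)
  }
})

test_that("composition honors annotated regions and ambiguity", {
  rec <- genome_record("AAAAGGGGCC", features = data.frame(
    name = "ctrl", start = 1, end = 4, strand = "+", type = "misc"))
  expect_equal(composition_stats(rec, "ctrl")$at_pct, 100)
  expect_equal(composition_stats(rec)$at_pct, 40)
  expect_error(composition_stats(rec, "nope"), "unknown region")
  stn <- composition_stats(genome_record("AANN"))
  expect_identical(stn$ambiguous, 2L)
  expect_equal(stn$at_pct, 100)
  expect_error(genome_record("ACGT", features = data.frame(
    name = "x", start = 0, end = 2, strand = "+", type = "misc")), "bounds")
})
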