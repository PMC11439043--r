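test_that("simulation is byte-deterministic given seed and configuration", {
  a <- simulate_codon_alignment(tree6(), 50, 2, 0.1, 2, 0.7, 0.2, seed = 123)
  b <- simulate_codon_alignment(tree6(), 50, 2, 0.1, 2, 0.7, 0.2, seed = 123)
  expect_identical(a$alignment$codons, b$alignment$codons)
  expect_identical(a$site_classes, b$site_classes)
  c <- simulate_codon_alignment(tree6(), 50, 2, 0.1, 2, 0.7, 0.2, seed = 124)
  expect_false(identical(a$alignment$codons, c$alignment$codons))
  ## seeding does not disturb the caller's RNG stream
  set.seed(1); x <- runif(1)
  set.seed(1); invisible(simulate_codon_alignment(tree6(), 5, seed = 9))
  expect_identical(runif(1), x)
})

test_that("zero branch lengths copy the root to every tip", {
  tr <- read_marked_tree("((a:0,b:0)#1:0,(c:0,d:0):0);")
  sim <- simulate_codon_alignment(tr, 30, seed = 6)
  for (i in 2:4) {
    expect_identical(sim$alignment$codons[i, ], sim$alignment$codons[1, ])
  }
})

test_that("simulated alignments contain neither stops nor gaps", {
  sim <- simulate_codon_alignment(tree6(), 400, 2, 0.2, 5, 0.5, 0.3, seed = 18)
  expect_true(all(sim$alignment$codons %in% CODE5$sense))
  expect_identical(sort(unique(sim$site_classes)), c(1L, 2L, 3L, 4L))
})

test_that("empirical codon frequencies converge to the equilibrium", {
  pi <- uniform_freqs()
  sim <- simulate_codon_alignment(tree6(), 10000, 2, 0.5, 1, 0.8, 0.1,
                                  codon_freqs = pi, seed = 99)
  emp <- table(factor(sim$alignment$codons, levels = CODE5$sense))
  emp <- as.numeric(emp) / sum(emp)
  expect_lt(sum(abs(emp - pi)) / 2, 0.05)  # total variation
})

test_that("fitted omega2 concentrates near 1 under the null regime", {
  sim <- simulate_codon_alignment(tree6(), 600, 2, 0.1, 1, 0.75, 0.2, seed = 55)
  fit <- fit_branch_site(sim$alignment, tree6(), fix_omega2 = FALSE,
                         starts = 2, control = list(factr = 1e10))
  ## either omega2 stays near 1 or the selected-class mass vanishes
  expect_true(fit$omega2 < 2.5 || sum(fit$p[c("p2a", "p2b")]) < 0.02)
})

test_that("planting validates its schedule", {
  tree <- nematode_tree()
  clades <- cox_clades(tree)
  aln <- codon_alignment(matrix("ATG", 10, 4,
                                dimnames = list(cox_pattern_taxa(), NULL)),
                         strip_terminal_stop = FALSE)
  expect_identical(plant_fdns(aln, clades$B, data.frame())$alignment$codons,
                   aln$codons)
  expect_error(plant_fdns(aln, clades$B, data.frame(
    site = 1, ancestral_codon = "GCA", derived_codon = "GCA")), "equals")
  expect_error(plant_fdns(aln, clades$B, data.frame(
    site = 1, ancestral_codon = "GCA", derived_codon = "TCT")), "one nucleotide")
  expect_error(plant_fdns(aln, clades$B, data.frame(
    site = 1, ancestral_codon = "GCA", derived_codon = "GCC")), "synonymous")
  expect_error(plant_fdns(aln, clades$B, data.frame(
    site = 9, ancestral_codon = "GCA", derived_codon = "TCA")), "out of range")
  ## synonymous scatter sets the flag by construction
  res <- plant_fdns(aln, clades$C, data.frame(
    site = 2, ancestral_codon = "GCA", derived_codon = "TCA",
    syn_scatter = TRUE), seed = 4)
  rec <- detect_fdns(res$alignment, tree, clades$C)
  expect_true(rec$syn_variation)
})

test_that("toy structures classify exactly as their returned ground truth", {
  ## channel covering every residue puts everything within4 (distance 0)
  all_ch <- toy_structure(8, "helix", channel_residues = 1:8, seed = 1)
  expect_true(all(all_ch$true_distances$distance == 0))
  expect_true(all(classify_proximity(all_ch$true_distances$distance) == "within4"))
  ## a pair exactly 13.0 apart sits on the within13 boundary
  at <- data.frame(chain = "A", resno = 1:2, resid = "GLY", elety = "CA",
                   x = c(0, 13), y = 0, z = 0)
  s <- structure_model(at)
  ch <- channel_annotation(data.frame(pathway = "H", chain = "A", resno = 2))
  d <- min_channel_distance(s, list("A", 1), ch)$distance
  expect_identical(d, 13)
  expect_identical(as.character(classify_proximity(d)), "within13")
  ## random structures match the returned truth across seeds
  for (seed in 1:100) {
    toy <- toy_structure(12, "coil", channel_residues = c(2, 9), seed = seed)
    res <- proximity_map(toy$structure, data.frame(chain = "A", resno = 1:12),
                         toy$channel)
    expect_equal(res$min_distance, toy$true_distances$distance,
                 tolerance = 1e-9)
  }
})

test_that("noiseless OCR plates return configured differences exactly", {
  sim <- simulate_ocr_plate(untreated = 20, dmso_level = 18, fccp_level = 45,
                            azide_level = 4, background = 2, sigma = 0,
                            worms = 1, seed = 1)
  m <- derive_ocr_metrics(sim$plate)
  expect_identical(m$basal, sim$truth$basal)
  expect_identical(m$maximal, sim$truth$maximal)
  expect_identical(m$spare, sim$truth$spare)
  ## sample wells indistinguishable from background zero all metrics
  sim0 <- simulate_ocr_plate(untreated = 0, dmso_level = 0, fccp_level = 0,
                             azide_level = 0, background = 5, sigma = 0,
                             worms = 1, seed = 1)
  m0 <- derive_ocr_metrics(sim0$plate)
  expect_identical(c(m0$basal, m0$maximal, m0$spare, m0$untreated),
                   c(0, 0, 0, 0))
})
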