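test_that("PDB reading enforces coordinate records and filtering rules", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER junk", "END"), f)
  expect_error(read_structure(f), "no ATOM records")
  ## malformed coordinate field reports the line number
  writeLines(c(pdb_atom_line(1, "CA", "ALA", "A", 1, 1, 2, 3),
               sub("   1.000", "  x1.000", pdb_atom_line(2, "CB", "ALA", "A", 1, 1, 2, 3), fixed = TRUE),
               "END"), f)
  expect_error(read_structure(f), "line 2")
  ## synthetic 3-residue structure round-trips through write/read
  toy <- toy_structure(3, "helix", seed = 2)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy$structure, f2)
  back <- read_structure(f2)
  expect_identical(nrow(back$atoms), nrow(toy$structure$atoms))
  expect_equal(back$atoms[, c("x", "y", "z")],
               toy$structure$atoms[, c("x", "y", "z")], tolerance = 1e-3)
  ## altloc: the higher-occupancy conformer wins; hydrogens are dropped
  writeLines(c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.6, alt = "A"),
               pdb_atom_line(2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.4, alt = "B"),
               pdb_atom_line(3, "H", "ALA", "A", 1, 5, 5, 5),
               "END"), f)
  s <- read_structure(f)
  expect_identical(nrow(s$atoms), 1L)
  expect_identical(s$atoms$x, 0)
})

test_that("residue mapping is induced by a global alignment", {
  sq <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  expect_identical(map_residue_coordinates(sq, sq, 7L), 7L)
  ## two inserted residues upstream shift positions by two
  ins <- paste0(substr(sq, 1, 4), "GG", substr(sq, 5, nchar(sq)))
  expect_identical(map_residue_coordinates(sq, ins, 10L), 12L)
  expect_identical(map_residue_coordinates(ins, sq, 12L), 10L)
  ## composition: A -> B -> A returns the original position for mapped sites
  mp <- residue_mapping(sq, ins)
  inv <- residue_mapping(ins, sq)
  for (p in seq_len(nchar(sq))) {
    q <- mp$ab[p]
    if (!is.na(q)) expect_identical(inv$ab[q], p)
  }
  ## strictly increasing and injective
  mapped <- mp$ab[!is.na(mp$ab)]
  expect_true(all(diff(mapped) > 0))
  expect_error(map_residue_coordinates(sq, ins, 99L), "out of range")
})

test_that("minimum channel distances match exhaustive search and rigid motion", {
  toy <- toy_structure(20, "coil", channel_residues = c(3, 11, 17), seed = 5)
  for (r in c(1, 5, 11, 20)) {
    d <- min_channel_distance(toy$structure, list("A", r), toy$channel)
    expect_equal(d$distance, toy$true_distances$distance[r], tolerance = 1e-9)
  }
  ## a channel member has distance zero to its own pathway
  d0 <- min_channel_distance(toy$structure, list("A", 11), toy$channel)
  expect_identical(d0$distance, 0)
  ## simple Euclidean identity
  at <- data.frame(chain = "A", resno = c(1, 2), resid = "GLY", elety = "CA",
                   x = c(0, 3), y = c(0, 4), z = c(0, 0))
  s <- structure_model(at)
  ch <- channel_annotation(data.frame(pathway = "H", chain = "A", resno = 2))
  expect_identical(min_channel_distance(s, list("A", 1), ch)$distance, 5)
  ## invariance under rigid motion of the whole structure
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  moved <- toy$structure
  xyz <- as.matrix(moved$atoms[, c("x", "y", "z")]) %*% t(R)
  moved$atoms$x <- xyz[, 1] + 11; moved$atoms$y <- xyz[, 2] - 3
  moved$atoms$z <- xyz[, 3] + 2
  d1 <- min_channel_distance(toy$structure, list("A", 7), toy$channel)
  d2 <- min_channel_distance(moved, list("A", 7), toy$channel)
  expect_equal(d1$distance, d2$distance, tolerance = 1e-9)
  ## unresolvable members are reported
  expect_error(min_channel_distance(s, list("A", 1),
                                    channel_annotation(data.frame(
                                      pathway = "K", chain = "A", resno = 99))),
               "K")
})

test_that("proximity classes use inclusive 4/13 Angstrom thresholds", {
  cls <- classify_proximity(c(3.9, 4.0, 4.1, 12.9, 13.0, 13.1))
  expect_identical(as.character(cls),
                   c("within4", "within4", "within13", "within13", "within13",
                     "distal"))
  expect_error(classify_proximity(-1), "negative")
  ## nesting: within4 implies within13 on random batches
  withr::with_seed(8, {
    d <- runif(200, 0, 25)
    cls <- classify_proximity(d)
    expect_true(all(d[cls == "within4"] <= 13))
  })
})

test_that("proximity mapping matches simulator ground truth", {
  toy <- toy_structure(25, "helix", channel_residues = c(4, 12), seed = 9)
  res <- proximity_map(toy$structure,
                       data.frame(chain = "A", resno = 1:25), toy$channel)
  expect_equal(res$min_distance, toy$true_distances$distance, tolerance = 1e-9)
  expect_identical(as.character(classify_proximity(toy$true_distances$distance)),
                   as.character(res$class))
})

test_that("Kabsch superposition is exact, symmetric and reflection-free", {
  withr::with_seed(3, {
    A <- matrix(rnorm(30), ncol = 3)
  })
  expect_equal(as.numeric(superpose_rmsd(A, A)), 0, tolerance = 1e-12)
  ## rigid rotation + translation recovers zero RMSD
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  B <- A %*% t(R) + matrix(rep(c(4, -2, 7), each = 10), ncol = 3)
  expect_lt(as.numeric(superpose_rmsd(A, B)), 1e-9)
  ## symmetry
  withr::with_seed(4, {
    B2 <- A + matrix(rnorm(30, sd = 0.3), ncol = 3)
  })
  expect_equal(as.numeric(superpose_rmsd(A, B2)),
               as.numeric(superpose_rmsd(B2, A)), tolerance = 1e-9)
  ## agrees with an independent least-squares superposition
  skip_if_not_installed("bio3d")
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(A)), mobile = as.vector(t(B2)),
                           fixed.inds = 1:30, mobile.inds = 1:30)
  ref <- sqrt(mean(colSums(matrix((as.vector(t(A)) - fitted)^2, nrow = 3))))
  expect_equal(as.numeric(superpose_rmsd(A, B2)), ref, tolerance = 1e-3)
  ## mirrored coordinates cannot be superposed by a proper rotation
  M <- A %*% diag(c(-1, 1, 1))
  expect_gt(as.numeric(superpose_rmsd(A, M)), 0.1)
  expect_error(superpose_rmsd(A, A[1:5, ]), "matched")
  expect_error(superpose_rmsd(A[1:2, ], A[1:2, ]), "3 points")
})

test_that("channel annotations validate and load from TSV", {
  f <- system.file("extdata", "synthetic_channels.tsv", package = "mitosel")
  ch <- read_channel_annotation(f)
  expect_s3_class(ch, "channel_annotation")
  expect_identical(attr(ch, "frame"), "template")
  expect_setequal(unique(ch$pathway), c("H", "K"))
  expect_error(channel_annotation(data.frame(pathway = character(0),
                                             chain = character(0),
                                             resno = integer(0))),
               "non-empty")
})
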