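flat_plate <- function(dmso = 10, fccp = 30, azide = 2, untreated = 12,
                       bg = 0, worms = 1, sigma = 0, seed = 1) {
  simulate_ocr_plate(untreated = untreated, dmso_level = dmso,
                     fccp_level = fccp, azide_level = azide, background = bg,
                     sigma = sigma, worms = worms, seed = seed)
}

test_that("normalization subtracts background and divides by worm count", {
  sim <- flat_plate(dmso = 50, fccp = 50, azide = 50, untreated = 50,
                    bg = 0, worms = 10)
  norm <- normalize_ocr(sim$plate)
  expect_true(all(norm == 5))
  ## wells holding no worms measure only background: zero everywhere
  sim2 <- flat_plate(dmso = 0, fccp = 0, azide = 0, untreated = 0, bg = 7)
  expect_true(all(normalize_ocr(sim2$plate) == 0))
  ## random plate matches per-cycle arithmetic
  sim3 <- flat_plate(sigma = 2, worms = 4, seed = 42)
  p <- sim3$plate
  bgw <- p$wells$role == "background"
  manual <- sweep(p$ocr[!bgw, ], 2, colMeans(p$ocr[bgw, , drop = FALSE])) /
    p$wells$worms[!bgw]
  expect_equal(normalize_ocr(p), manual, tolerance = 1e-12)
})

test_that("derived metrics follow the flux-assay formulas bit-exactly at sigma 0", {
  sim <- flat_plate()
  m <- derive_ocr_metrics(sim$plate, species = "mephisto")
  expect_identical(m$basal, 8)
  expect_identical(m$maximal, 28)
  expect_identical(m$spare, 20)
  expect_identical(m$untreated, 12)
  expect_identical(m$spare, m$maximal - m$basal)
  ## FCCP trace identical to DMSO trace -> spare 0
  m0 <- derive_ocr_metrics(flat_plate(dmso = 30, fccp = 30)$plate)
  expect_identical(m0$spare, 0)
})

test_that("spare equals maximal minus basal on noisy plates (algebraic identity)", {
  for (seed in 1:10) {
    sim <- flat_plate(sigma = 3, worms = 70, seed = seed)
    m <- derive_ocr_metrics(sim$plate)
    expect_equal(m$spare, m$maximal - m$basal, tolerance = 1e-9)
    expect_true(all(c(m$window, m$azide_window, m$untreated_window) %in% 1:32))
  }
})

test_that("noisy plates recover configured metrics within 3 sigma of a window mean", {
  sigma <- 2
  for (seed in 1:5) {
    sim <- flat_plate(dmso = 18, fccp = 45, azide = 4, untreated = 20,
                      worms = 1, sigma = sigma, seed = seed)
    m <- derive_ocr_metrics(sim$plate)
    tol <- 3 * sigma / sqrt(4)
    expect_lt(abs(m$basal - sim$truth$basal), tol)
    expect_lt(abs(m$maximal - sim$truth$maximal), tol)
    expect_lt(abs(m$spare - sim$truth$spare), tol)
  }
})

test_that("metric estimates are unbiased over Monte-Carlo replicates", {
  sigma <- 2
  err <- sapply(1:100, function(seed) {
    sim <- flat_plate(dmso = 18, fccp = 45, azide = 4, worms = 1,
                      sigma = sigma, seed = seed)
    m <- derive_ocr_metrics(sim$plate)
    c(m$basal - sim$truth$basal, m$maximal - sim$truth$maximal)
  })
  expect_lt(max(abs(rowMeans(err))), sigma / 5)
})

test_that("metrics are invariant to well order and duplicated background", {
  sim <- simulate_ocr_plate(sigma = 1.5, worms = 3, n_background = 1L, seed = 7)
  p <- sim$plate
  m0 <- derive_ocr_metrics(p)
  perm <- rev(seq_len(nrow(p$wells)))
  p2 <- ocr_plate(p$wells[perm, ], p$ocr[perm, ], injections = p$injections)
  m1 <- derive_ocr_metrics(p2)
  expect_equal(m0$basal, m1$basal, tolerance = 1e-12)
  expect_equal(m0$spare, m1$spare, tolerance = 1e-12)
  ## duplicate background well with an identical trace
  wells3 <- rbind(p$wells, data.frame(well = "W99", group = "BG", worms = NA,
                                      role = "background"))
  bgrow <- p$ocr[p$wells$role == "background", , drop = FALSE][1, , drop = FALSE]
  rownames(bgrow) <- "W99"
  p3 <- ocr_plate(wells3, rbind(p$ocr, bgrow), injections = p$injections)
  m2 <- derive_ocr_metrics(p3)
  expect_equal(m0$basal, m2$basal, tolerance = 1e-12)
})

test_that("plate validation and species windows behave as documented", {
  expect_identical(species_window("mephisto"), 10:13)
  expect_identical(species_window("elegans"), 13:16)
  sim <- flat_plate()
  expect_error(derive_ocr_metrics(sim$plate, window = 30:35), "outside recorded")
  wells <- sim$plate$wells
  wells$group[wells$group == "FCCP"] <- "DMSO"
  p <- ocr_plate(wells, sim$plate$ocr, injections = sim$plate$injections)
  expect_error(derive_ocr_metrics(p), "FCCP")
  wells2 <- sim$plate$wells
  wells2$worms[1] <- 0
  expect_error(ocr_plate(wells2, sim$plate$ocr), "worm count")
  ## negative metrics warn but are not clipped
  simn <- flat_plate(dmso = 1, fccp = 30, azide = 5)
  expect_warning(mn <- derive_ocr_metrics(simn$plate), "negative")
  expect_identical(mn$basal, -4)
})

test_that("plates round-trip through the long CSV format", {
  sim <- flat_plate(sigma = 1, worms = 5, seed = 3)
  p <- sim$plate
  long <- do.call(rbind, lapply(seq_len(nrow(p$wells)), function(i) {
    data.frame(well = p$wells$well[i], group = p$wells$group[i],
               worms = p$wells$worms[i], role = p$wells$role[i],
               cycle = seq_len(p$n_cycles), ocr = p$ocr[i, ])
  }))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(long, f, row.names = FALSE)
  p2 <- read_ocr_plate(f)
  expect_equal(unname(p2$ocr), unname(p$ocr), tolerance = 1e-12)
  expect_equal(derive_ocr_metrics(p2)$spare, derive_ocr_metrics(p)$spare,
               tolerance = 1e-12)
})

test_that("fold changes divide with a zero guard", {
  expect_equal(fold_change(46, 10)$ratio, 4.6)
  expect_identical(fold_change(5, 5)$ratio, 1)
  z <- fold_change(3, 0)
  expect_true(z$undefined)
  expect_true(is.na(z$ratio))
  withr::with_seed(2, {
    for (i in 1:10) {
      a <- rnorm(1); b <- rnorm(1)
      expect_identical(fold_change(a, b)$ratio, a / b)
    }
  })
})
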