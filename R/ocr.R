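#' Extracellular-flux (OCR) plate
#'
#' Container for a plate run of oxygen consumption rate measurements: a well
#' table (treatment group, worm count, sample/background role), a wells x
#' cycles OCR matrix, and the injection schedule. The standard nematode run is
#' 32 measurement cycles: 8 untreated, injection 1 (FCCP or DMSO vehicle)
#' before cycle 9, injection 2 (sodium azide) before cycle 29.
#'
#' @param wells Data frame with columns `well`, `group`, `worms`, `role`
#'   (`"sample"` or `"background"`).
#' @param ocr Numeric matrix (wells x cycles), rows named by well, of OCR in
#'   pmol O2/min.
#' @param injections Integer vector `(inj1, inj2)`: first cycle measured after
#'   each injection.
#' @param times Optional cycle time stamps (minutes).
#' @return Object of class `ocr_plate`.
#' @export
ocr_plate <- function(wells, ocr, injections = c(9L, 29L), times = NULL) {
  need <- c("well", "group", "worms", "role")
  if (!all(need %in% names(wells))) {
    stopf("wells needs columns: %s", paste(need, collapse = ", "))
  }
  ocr <- as.matrix(ocr)
  if (is.null(rownames(ocr))) rownames(ocr) <- wells$well
  if (!setequal(rownames(ocr), wells$well)) {
    stopf("OCR matrix rows and well table disagree")
  }
  ocr <- ocr[wells$well, , drop = FALSE]
  if (!all(wells$role %in% c("sample", "background"))) {
    stopf("role must be 'sample' or 'background'")
  }
  if (!any(wells$role == "background")) stopf("at least one background well required")
  smp <- wells$role == "sample"
  if (any(is.na(wells$worms[smp]) | wells$worms[smp] <= 0)) {
    stopf("sample wells need worm count > 0")
  }
  injections <- as.integer(injections)
  if (length(injections) != 2L || any(diff(c(1L, injections, ncol(ocr) + 1L)) <= 0)) {
    stopf("injections must be increasing cycle indices within the run")
  }
  structure(list(wells = wells, ocr = ocr, injections = injections,
                 times = times, n_cycles = ncol(ocr)),
            class = "ocr_plate")
}

#' @export
print.ocr_plate <- function(x, ...) {
  cat(sprintf("OCR plate: %d wells (%d background), %d cycles, injections at %d and %d\n",
              nrow(x$wells), sum(x$wells$role == "background"), x$n_cycles,
              x$injections[1], x$injections[2]))
  invisible(x)
}

#' Read an OCR plate from a long-format CSV
#'
#' Expected columns: `well`, `group`, `worms`, `role`, `cycle`, `ocr`
#' (optionally `time`).
#'
#' @param path CSV file.
#' @param injections Injection schedule as in [ocr_plate()].
#' @export
read_ocr_plate <- function(path, injections = c(9L, 29L)) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  wells <- unique(d[, c("well", "group", "worms", "role")])
  cycles <- sort(unique(d$cycle))
  m <- matrix(NA_real_, nrow(wells), length(cycles),
              dimnames = list(wells$well, cycles))
  m[cbind(match(d$well, wells$well), match(d$cycle, cycles))] <- d$ocr
  if (anyNA(m)) stopf("missing (well, cycle) measurements in %s", path)
  ocr_plate(wells, m, injections = injections,
            times = if ("time" %in% names(d)) tapply(d$time, d$cycle, mean) else NULL)
}

#' Background-subtracted, per-worm OCR
#'
#' Subtracts the mean background-well OCR from each sample well at each cycle
#' and divides by the well's worm count, yielding pmol O2/min/worm.
#'
#' @param plate An [ocr_plate()].
#' @return Matrix (sample wells x cycles).
#' @export
normalize_ocr <- function(plate) {
  stopifnot(inherits(plate, "ocr_plate"))
  bg <- plate$wells$role == "background"
  bg_mean <- colMeans(plate$ocr[bg, , drop = FALSE])
  smp <- plate$wells[!bg, , drop = FALSE]
  out <- sweep(plate$ocr[!bg, , drop = FALSE], 2, bg_mean)
  sweep(out, 1, smp$worms, `/`)
}

#' Species measurement-window presets
#'
#' Post-injection-1 window used for the basal (DMSO) and maximal (FCCP)
#' plateau means: cycles 10-13 for *H. mephisto* (which peaks and declines
#' quickly) and 13-16 for *C. elegans*.
#'
#' @param species `"mephisto"` or `"elegans"`.
#' @return Integer cycle window.
#' @export
species_window <- function(species = c("mephisto", "elegans")) {
  switch(match.arg(species), mephisto = 10:13, elegans = 13:16)
}

#' Derived respiration metrics from an OCR plate
#'
#' Implements the standard flux-assay arithmetic on per-worm,
#' background-subtracted traces: basal = mean DMSO-well OCR over the
#' measurement window minus the non-mitochondrial OCR (pooled mean over all
#' sample wells across the azide window); maximal = mean FCCP-well OCR over
#' the window minus the same azide term; spare = FCCP minus DMSO window means,
#' so that spare = maximal - basal holds as an algebraic identity. The
#' untreated mean over cycles 5-8 (before any injection) is reported as well.
#'
#' @param plate An [ocr_plate()].
#' @param species Window preset (see [species_window()]); ignored when
#'   `window` is given.
#' @param window Integer cycles of the post-injection-1 measurement window.
#' @param azide_window Cycles averaged for non-mitochondrial OCR; default all
#'   cycles from the second injection to the end of the run.
#' @param untreated_window Cycles averaged for the untreated baseline.
#' @param basal_group,maximal_group Group labels of the vehicle-control and
#'   uncoupler wells.
#' @return Object of class `ocr_metrics`: `basal`, `maximal`, `spare`,
#'   `untreated` (pmol O2/min/worm), per-well window means, and the windows
#'   used. Negative metrics are reported as-is with a warning.
#' @export
derive_ocr_metrics <- function(plate, species = c("mephisto", "elegans"),
                               window = NULL, azide_window = NULL,
                               untreated_window = 5:8,
                               basal_group = "DMSO", maximal_group = "FCCP") {
  stopifnot(inherits(plate, "ocr_plate"))
  window <- window %||% species_window(species)
  azide_window <- azide_window %||% seq(plate$injections[2], plate$n_cycles)
  for (w in list(window, azide_window, untreated_window)) {
    if (any(w < 1L | w > plate$n_cycles)) {
      stopf("measurement window outside recorded cycles [1, %d]", plate$n_cycles)
    }
  }
  norm <- normalize_ocr(plate)
  smp <- plate$wells[plate$wells$role == "sample", , drop = FALSE]
  for (g in c(basal_group, maximal_group)) {
    if (!g %in% smp$group) stopf("missing treatment group: %s", g)
  }
  group_mean <- function(g, cyc) {
    mean(rowMeans(norm[smp$group == g, cyc, drop = FALSE]))
  }
  azide <- mean(rowMeans(norm[, azide_window, drop = FALSE]))
  dmso <- group_mean(basal_group, window)
  fccp <- group_mean(maximal_group, window)
  res <- structure(
    list(basal = dmso - azide, maximal = fccp - azide, spare = fccp - dmso,
         untreated = mean(rowMeans(norm[, untreated_window, drop = FALSE])),
         azide = azide,
         window = window, azide_window = azide_window,
         untreated_window = untreated_window,
         per_well = data.frame(
           well = smp$well, group = smp$group,
           window_mean = rowMeans(norm[, window, drop = FALSE]),
           azide_mean = rowMeans(norm[, azide_window, drop = FALSE])
         )),
    class = "ocr_metrics"
  )
  if (res$basal < 0 || res$maximal < 0) {
    warning("negative derived respiration metric; check assay quality",
            call. = FALSE)
  }
  res
}

#' @export
print.ocr_metrics <- function(x, ...) {
  cat(sprintf(
    "OCR metrics (pmol O2/min/worm): basal %.4g, maximal %.4g, spare %.4g, untreated %.4g\n",
    x$basal, x$maximal, x$spare, x$untreated))
  cat(sprintf("  windows: measurement %s, azide %s, untreated %s\n",
              paste(range(x$window), collapse = "-"),
              paste(range(x$azide_window), collapse = "-"),
              paste(range(x$untreated_window), collapse = "-")))
  invisible(x)
}

#' Fold change between two metrics
#'
#' @param a,b Numeric values (e.g. maximal-temperature vs minimal-temperature
#'   respiration).
#' @return List with `ratio` (`NA` with `undefined = TRUE` when `b = 0`), `a`,
#'   `b`.
#' @export
fold_change <- function(a, b) {
  if (b == 0) return(list(ratio = NA_real_, undefined = TRUE, a = a, b = b))
  list(ratio = a / b, undefined = FALSE, a = a, b = b)
}
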