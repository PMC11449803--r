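#' @include AllClasses.R
NULL

LABEL_CLASSES <- c("double", "excl_htr1a", "excl_htr2a", "negative")
POSITIVE_CLASSES <- c("double", "excl_htr1a", "excl_htr2a")

#' Classify cells by Htr1a/Htr2a co-expression
#'
#' A cell is positive for a transcript iff its puncta count is at least
#' `minPuncta` (default 1, i.e. any detected punctum). The
#' (htr1a±, htr2a±) truth table assigns each cell exactly one class:
#' `double`, `excl_htr1a`, `excl_htr2a` or `negative`. Negative cells are
#' excluded from every Htr1/2a+ denominator downstream.
#'
#' @param cells validated cell table (see [readCellTable()]), or any
#'   data.frame with `htr1a_count` and `htr2a_count` columns.
#' @param minPuncta positivity threshold in puncta (default 1).
#' @return Factor of length `nrow(cells)` with levels
#'   `double, excl_htr1a, excl_htr2a, negative`.
#' @examples
#' classifyCell(data.frame(htr1a_count = c(3, 2, 0, 0),
#'                         htr2a_count = c(0, 5, 4, 0)))
#' @export
classifyCell <- function(cells, minPuncta = 1L) {
  if (minPuncta < 1L) stopf("minPuncta must be >= 1")
  p1 <- cells$htr1a_count >= minPuncta
  p2 <- cells$htr2a_count >= minPuncta
  cls <- ifelse(p1 & p2, "double",
         ifelse(p1, "excl_htr1a",
         ifelse(p2, "excl_htr2a", "negative")))
  factor(cls, levels = LABEL_CLASSES)
}

.sectionProportions <- function(cells, minPuncta) {
  cls <- classifyCell(cells, minPuncta)
  pos <- cls != "negative"
  n <- sum(pos)
  if (n == 0L) return(NULL)
  counts <- as.integer(table(factor(cls[pos], levels = POSITIVE_CLASSES)))
  p <- counts / n
  # the last positive class takes the exact complement so the proportions
  # sum to 1 to the last bit, not merely to rounding error
  j <- max(which(counts > 0L))
  p[j] <- 1 - sum(p[seq_len(j - 1L)])
  p
}

#' Per-animal co-expression class proportions
#'
#' Computes, for each animal, the proportion of Htr1/2a+ cells (cells
#' positive for either transcript) in each class. Proportions are computed
#' per section first — where they sum to 1 across the three positive
#' classes exactly — and then averaged, unweighted, over the animal's
#' sections (4 per individual region, 8 for the combined-region analysis).
#' Sections with no positive cell are excluded with a warning. Cell
#' pooling across sections is available as an explicitly non-default
#' diagnostic.
#'
#' @param cells validated cell table.
#' @param level `"region"` (per animal and region) or `"combined"`
#'   (all of an animal's sections together, the mPFC analysis).
#' @param minPuncta positivity threshold (default 1).
#' @param pooled if `TRUE`, pool cells across sections instead of
#'   averaging section proportions (diagnostic mode; default `FALSE`).
#' @return data.frame with columns `animal_id` (, `region`), `n_sections`,
#'   `double`, `excl_htr1a`, `excl_htr2a`.
#' @export
proportionsByAnimal <- function(cells, level = c("region", "combined"),
                                minPuncta = 1L, pooled = FALSE) {
  level <- match.arg(level)
  cells <- validateCellTable(cells)
  keys <- if (level == "region")
    unique(cells[, c("animal_id", "region")])
  else unique(cells[, "animal_id", drop = FALSE])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- cells$animal_id == keys$animal_id[i]
    if (level == "region") sel <- sel & cells$region == keys$region[i]
    sub <- cells[sel, , drop = FALSE]
    secs <- split(sub, sub$section_id)
    if (pooled) {
      props <- .sectionProportions(sub, minPuncta)
      nSec <- length(secs)
    } else {
      per <- lapply(secs, .sectionProportions, minPuncta = minPuncta)
      empty <- vapply(per, is.null, logical(1))
      if (any(empty))
        warning(sprintf("animal %s: %d section(s) with no Htr1/2a+ cell excluded",
                        keys$animal_id[i], sum(empty)), call. = FALSE)
      per <- per[!empty]
      if (!length(per)) return(NULL)
      props <- colMeans(do.call(rbind, per))
      nSec <- length(per)
    }
    out <- data.frame(animal_id = keys$animal_id[i],
                      n_sections = nSec, stringsAsFactors = FALSE)
    if (level == "region") out$region <- keys$region[i]
    out$double <- props[1]; out$excl_htr1a <- props[2]
    out$excl_htr2a <- props[3]
    out
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

# Trapezoid with linear bridging of interior NA bins; leading/trailing NA
# bins are dropped. x: bin centres, y: proportions (may contain NA).
.bridgedTrapz <- function(x, y) {
  ok <- !is.na(y)
  if (sum(ok) < 2L) return(0)
  first <- which(ok)[1]; last <- tail(which(ok), 1)
  x <- x[first:last]; y <- y[first:last]
  if (anyNA(y)) {
    interior <- which(is.na(y))
    y[interior] <- approx(x[!is.na(y)], y[!is.na(y)],
                          xout = x[interior])$y
  }
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Cortical-depth spatial profile with AUC
#'
#' Bins Htr1/2a+ cells by distance from the Layer I midline into `nBins`
#' half-open bins `[edge_i, edge_{i+1})` of width `extentUm/nBins` (the
#' last bin closed), computes per-bin class proportions over the positive
#' cells in the bin, and the trapezoidal area under each class's
#' proportion curve evaluated at bin centres. Empty bins carry absent
#' proportions; for the AUC, interior empty bins are linearly bridged
#' between their occupied neighbours and leading/trailing empty bins are
#' dropped.
#'
#' The defaults — 2000 µm extent in 50 bins of 40 µm — place deep-layer
#' (Layer V, roughly 900–1200 µm) signal well inside interior bins; both
#' knobs are exposed.
#'
#' @param cells validated cell table (typically one region).
#' @param extentUm profile extent in micrometres (default 2000); all cell
#'   distances must be within it.
#' @param nBins number of distance bins (default 50).
#' @param minPuncta positivity threshold (default 1).
#' @return A [SpatialProfile-class].
#' @export
spatialProfile <- function(cells, extentUm = 2000, nBins = 50L,
                           minPuncta = 1L) {
  cells <- validateCellTable(cells)
  nBins <- as.integer(nBins)
  if (nBins < 2L) stopf("nBins must be >= 2")
  if (any(cells$distance_um > extentUm))
    stopf("cell distances exceed extentUm = %g", extentUm)
  edges <- seq(0, extentUm, length.out = nBins + 1L)
  centres <- (head(edges, -1) + tail(edges, -1)) / 2
  cls <- classifyCell(cells, minPuncta)
  pos <- cls != "negative"
  d <- cells$distance_um[pos]
  cl <- factor(as.character(cls[pos]), levels = POSITIVE_CLASSES)
  bin <- pmin(nBins, as.integer(floor(d / (extentUm / nBins))) + 1L)
  counts <- matrix(0L, nBins, 3,
                   dimnames = list(NULL, POSITIVE_CLASSES))
  if (length(bin)) {
    tab <- table(factor(bin, levels = seq_len(nBins)), cl)
    counts[] <- as.integer(tab)
  }
  tot <- rowSums(counts)
  props <- counts / ifelse(tot > 0, tot, NA_real_)
  auc <- vapply(POSITIVE_CLASSES,
                function(k) .bridgedTrapz(centres, props[, k]), numeric(1))
  new("SpatialProfile", nBins = nBins, binEdges = edges,
      binCentres = centres, counts = counts, proportions = props,
      auc = auc)
}

#' Htr2a transcript abundance over Htr1/2a+ cells
#'
#' Total Htr2a puncta summed over Htr1/2a+ cells and the mean per positive
#' cell, computed per section and then averaged unweighted over each
#' animal's sections (matching the aggregation of
#' [proportionsByAnimal()]). Per-cell abundance is absent for sections
#' with no positive cell.
#'
#' @param cells validated cell table.
#' @param minPuncta positivity threshold (default 1).
#' @return data.frame per animal with `total_htr2a` (mean section total),
#'   `htr2a_per_cell` (mean of section per-cell means), `n_sections`.
#' @export
htr2aAbundance <- function(cells, minPuncta = 1L) {
  cells <- validateCellTable(cells)
  rows <- lapply(unique(cells$animal_id), function(a) {
    sub <- cells[cells$animal_id == a, , drop = FALSE]
    secs <- split(sub, sub$section_id)
    per <- lapply(secs, function(s) {
      cls <- classifyCell(s, minPuncta)
      pos <- cls != "negative"
      n <- sum(pos)
      tot <- sum(s$htr2a_count[pos])
      c(total = tot, perCell = if (n > 0) tot / n else NA_real_)
    })
    m <- do.call(rbind, per)
    perCell <- if (all(is.na(m[, "perCell"]))) NA_real_
               else mean(m[, "perCell"], na.rm = TRUE)
    data.frame(animal_id = a,
               total_htr2a = mean(m[, "total"]),
               htr2a_per_cell = perCell,
               n_sections = nrow(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a synthetic per-cell transcript-count table
#'
#' Draws a cell table emulating CellProfiler/Imaris exports: per animal,
#' region and section, cells receive a class from the supplied positive /
#' co-expression probabilities, distances from a depth distribution
#' peaking in deep layers for Htr2a-expressing cells, and puncta counts
#' from per-class negative-binomial mixtures scaled by a treatment
#' multiplier. Entirely synthetic; intended to exercise the quantification
#' layer, not to reproduce any real tissue.
#'
#' @param nAnimals animals per group.
#' @param sectionsPerRegion sections per animal and region (default 4, so
#'   8 combined).
#' @param cellsPerSection cells per section (default 150).
#' @param pDouble,pExcl1a,pExcl2a,pNegative class probabilities (must sum
#'   to 1).
#' @param mu1a,mu2a negative-binomial mean puncta for expressed
#'   transcripts.
#' @param sizeNb negative-binomial size (dispersion) parameter.
#' @param htr2aMult multiplier on Htr2a puncta means (treatment effect).
#' @param extentUm depth extent (default 2000 µm).
#' @param seed integer seed.
#' @param groupLabel prefix for animal ids.
#' @return Validated cell table data.frame.
#' @export
simulateCellTable <- function(nAnimals = 5, sectionsPerRegion = 4,
                              cellsPerSection = 150, pDouble = 0.25,
                              pExcl1a = 0.30, pExcl2a = 0.20,
                              pNegative = 0.25, mu1a = 6, mu2a = 8,
                              sizeNb = 4, htr2aMult = 1, extentUm = 2000,
                              seed = 1, groupLabel = "an") {
  probs <- c(pDouble, pExcl1a, pExcl2a, pNegative)
  if (abs(sum(probs) - 1) > 1e-9) stopf("class probabilities must sum to 1")
  withSeed(seed, {
    rows <- list()
    for (a in seq_len(nAnimals)) for (rg in REGIONS)
      for (s in seq_len(sectionsPerRegion)) {
        n <- cellsPerSection
        cls <- sample(LABEL_CLASSES, n, replace = TRUE, prob = probs)
        # Htr2a-expressing cells concentrate in deep layers (~900-1200 um)
        deep <- cls %in% c("double", "excl_htr2a")
        dist <- ifelse(deep,
                       pmin(extentUm, pmax(0, rnorm(n, 1050, 250))),
                       runif(n, 0, extentUm))
        pos1 <- cls %in% c("double", "excl_htr1a")
        pos2 <- cls %in% c("double", "excl_htr2a")
        c1 <- ifelse(pos1, 1L + rnbinom(n, size = sizeNb, mu = mu1a), 0L)
        c2 <- ifelse(pos2,
                     1L + rnbinom(n, size = sizeNb, mu = mu2a * htr2aMult),
                     0L)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = sprintf("%s%02d", groupLabel, a), region = rg,
          section_id = sprintf("%s%02d_%s_s%d", groupLabel, a, rg, s),
          distance_um = round(dist, 1), htr1a_count = as.integer(c1),
          htr2a_count = as.integer(c2), stringsAsFactors = FALSE)
      }
    validateCellTable(do.call(rbind, rows))
  })
}
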