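test_that("cells classify by the co-expression truth table", {
  d <- data.frame(htr1a_count = c(3L, 2L, 0L, 0L),
                  htr2a_count = c(0L, 5L, 4L, 0L))
  expect_identical(as.character(classifyCell(d)),
                   c("excl_htr1a", "double", "excl_htr2a", "negative"))
  # monotone in the positivity threshold: raising it never resurrects a cell
  withr::with_seed(3, {
    tab <- data.frame(htr1a_count = rpois(200, 2),
                      htr2a_count = rpois(200, 2))
    for (m in 1:4) {
      lo <- classifyCell(tab, m) == "negative"
      hi <- classifyCell(tab, m + 1L) == "negative"
      expect_true(all(hi >= lo))
    }
  })
})

test_that("class proportions are per-section then animal-averaged", {
  one <- mkCellSection(10, 5, 5)
  pr <- proportionsByAnimal(one, "region")
  expect_equal(unlist(pr[, c("double", "excl_htr1a", "excl_htr2a")]),
               c(double = 0.5, excl_htr1a = 0.25, excl_htr2a = 0.25))

  # two sections with proportions p and q: animal value (p + q) / 2, not
  # the cell-pooled value
  two <- rbind(mkCellSection(8, 1, 1, section = "s1"),
               mkCellSection(10, 50, 40, section = "s2"))
  pr <- proportionsByAnimal(two, "region")
  pSec <- c(8, 1, 1) / 10
  qSec <- c(10, 50, 40) / 100
  expect_equal(unname(unlist(pr[, c("double", "excl_htr1a",
                                    "excl_htr2a")])),
               (pSec + qSec) / 2)
  pooled <- proportionsByAnimal(two, "region", pooled = TRUE)
  pooledOracle <- c(18, 51, 41) / 110
  expect_equal(unname(unlist(pooled[, c("double", "excl_htr1a",
                                        "excl_htr2a")])),
               pooledOracle)
  expect_false(isTRUE(all.equal(unname(unlist(pr[, 4:6])), pooledOracle)))

  # sections sum to 1 across positive classes on random tables, exactly
  ct <- simulateCellTable(nAnimals = 3, seed = 5)
  for (s in split(ct, ct$section_id)) {
    pr <- proportionsByAnimal(s, "region")
    expect_identical(pr$double + pr$excl_htr1a + pr$excl_htr2a, 1)
  }

  # a section with no positive cell is excluded with a warning
  withNeg <- rbind(mkCellSection(5, 3, 2, section = "s1"),
                   mkCellSection(0, 0, 0, nNeg = 10, section = "s2"))
  expect_warning(pr <- proportionsByAnimal(withNeg, "region"),
                 "no Htr1/2a")
  expect_identical(pr$n_sections, 1L)
})

test_that("spatial profiles bin, conserve and integrate correctly", {
  # constant 0.5/0.25/0.25 composition in every bin
  cells <- do.call(rbind, lapply(1:50, function(b)
    mkCellSection(2, 1, 1, distance = (b - 0.5) * 40,
                  section = sprintf("s%d", b))))
  prof <- spatialProfile(cells, extentUm = 2000, nBins = 50)
  expect_identical(sum(prof@counts), 200L)  # conservation
  centres <- prof@binCentres
  expect_equal(prof@auc[["double"]],
               0.5 * (centres[50] - centres[1]))

  # all cells in one bin: only that bin has defined proportions
  onebin <- mkCellSection(4, 2, 2, distance = 1015)
  prof <- spatialProfile(onebin, extentUm = 2000, nBins = 50)
  occ <- !is.na(prof@proportions[, 1])
  expect_identical(which(occ), 26L)  # 1015 um falls in bin [1000, 1040)
  expect_equal(prof@proportions[26, ], c(double = 0.5, excl_htr1a = 0.25,
                                         excl_htr2a = 0.25))

  # AUC against an independent trapezoid oracle (with bridging applied to
  # the same occupied support)
  skip_if_not_installed("pracma")
  withr::with_seed(11, {
    for (rep in 1:5) {
      ct <- simulateCellTable(nAnimals = 1, cellsPerSection = 60,
                              seed = 200 + rep)
      sub <- ct[ct$region == "IL", ]
      prof <- spatialProfile(sub, extentUm = 2000, nBins = 50)
      for (k in colnames(prof@proportions)) {
        y <- prof@proportions[, k]
        okb <- which(!is.na(y))
        if (length(okb) < 2) next
        rng <- okb[1]:okb[length(okb)]
        x <- prof@binCentres[rng]
        yy <- approx(prof@binCentres[okb], y[okb], xout = x)$y
        expect_equal(prof@auc[[k]], pracma::trapz(x, yy),
                     tolerance = 1e-12)
      }
    }
  })

  expect_error(spatialProfile(mkCellSection(1, 0, 0, distance = 2500),
                              extentUm = 2000), "exceed")
})

test_that("Htr2a abundance sums over positive cells and averages sections", {
  d <- data.frame(animal_id = "a1", region = "IL", section_id = "s1",
                  distance_um = 1,
                  htr1a_count = c(2L, 1L, 3L, 0L),
                  htr2a_count = c(0L, 2L, 4L, 0L))
  ab <- htr2aAbundance(d)
  expect_equal(ab$total_htr2a, 6)
  expect_equal(ab$htr2a_per_cell, 2)

  allNeg <- data.frame(animal_id = "a1", region = "IL", section_id = "s1",
                       distance_um = 1, htr1a_count = 0L, htr2a_count = 0L)
  ab <- htr2aAbundance(allNeg)
  expect_equal(ab$total_htr2a, 0)
  expect_identical(ab$htr2a_per_cell, NA_real_)

  # two sections: animal value is the unweighted mean of section values
  d2 <- rbind(d, within(d, {section_id <- "s2"; htr2a_count <-
                              htr2a_count * 2L}))
  ab <- htr2aAbundance(d2)
  expect_equal(ab$total_htr2a, (6 + 12) / 2)

  # treatment multiplier lowers per-cell abundance (direction check)
  hi <- htr2aAbundance(simulateCellTable(nAnimals = 3, seed = 31,
                                         htr2aMult = 1))
  lo <- htr2aAbundance(simulateCellTable(nAnimals = 3, seed = 31,
                                         htr2aMult = 0.5))
  expect_lt(mean(lo$htr2a_per_cell), mean(hi$htr2a_per_cell))
})
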