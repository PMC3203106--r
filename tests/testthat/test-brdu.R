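test_that("colour thresholding is pixel-exact on a noise-free phantom", {
  ph <- fixture("bud9clean")
  img <- sectionImage(ph, centralSection(ph))
  m <- thresholdNuclei(img)
  brown <- c(70, 45, 30) / 255
  blue <- c(80, 110, 170) / 255
  isCol <- function(colr) abs(img[, , 1] - colr[1]) < 1e-9 &
    abs(img[, , 2] - colr[2]) < 1e-9 & abs(img[, , 3] - colr[3]) < 1e-9
  expect_identical(m$brdu, isCol(brown))
  expect_identical(m$nuclei, isCol(brown) | isCol(blue))
  expect_true(all(m$nuclei[m$brdu]))           # brdu subset of nuclei
  expect_error(thresholdNuclei(img[, , 1]), "RGB")
})

test_that("a BrdU-free phantom gives an empty BrdU mask", {
  s <- phantomSpec(nSections = 3, noiseSd = 0,
                   brduFraction = c(ectoderm = 0, core = 0, periphery = 0,
                                    mesenchyme = 0))
  ph <- generateStack(s)
  for (img in ph$images) expect_equal(sum(thresholdNuclei(img)$brdu), 0)
})

test_that("equal-size nuclei give the expected mask-area fraction", {
  # 150 identical discs, 50 of them BrdU-positive: area fraction exactly 1/3
  pos <- as.matrix(expand.grid(row = seq(10, 150, by = 10),
                               col = seq(10, 100, by = 10)))[1:150, ]
  brownIdx <- 1:50
  brown <- c(70, 45, 30) / 255; blue <- c(80, 110, 170) / 255
  img <- array(rep(c(222, 180, 190) / 255, each = 160 * 110),
               c(160, 110, 3))
  for (j in seq_len(nrow(pos))) {
    m <- matrix(FALSE, 160, 110)
    m <- BudQuant:::fillEllipse(m, pos[j, 1], pos[j, 2], 3, 3)
    colr <- if (j %in% brownIdx) brown else blue
    for (k in 1:3) { ch <- img[, , k]; ch[m] <- colr[k]; img[, , k] <- ch }
  }
  m <- thresholdNuclei(img)
  expect_equal(sum(m$brdu) / sum(m$nuclei), 1 / 3, tolerance = 0.02)
})

test_that("tabulation counts, additivity and undefined fractions", {
  map <- matrix(0L, 20, 30)
  map[2:6, ] <- match("core", compartmentNames()) - 1L
  map[8:12, ] <- match("periphery", compartmentNames()) - 1L
  map[14:16, ] <- match("neck", compartmentNames()) - 1L
  lb <- new("CompartmentLabeling", map = map, pixelSize = 1)
  nuc <- map > 0
  brd <- matrix(FALSE, 20, 30)
  brd[2:6, ] <- TRUE                            # core fully labelled
  brd[8, ] <- TRUE                              # 1/5 of periphery
  tab <- tabulateCompartments(lb, brd, nuc)
  g <- function(cp) tab[tab$compartment == cp, ]
  expect_equal(g("core")$fraction, 1)           # all-positive compartment
  expect_equal(g("periphery")$fraction, 0.2)
  expect_equal(g("neck")$fraction, 0)
  # MR total is the exact sum of its parts
  expect_identical(g("MR")$nuclear_pixels,
                   g("core")$nuclear_pixels + g("periphery")$nuclear_pixels +
                     g("neck")$nuclear_pixels + g("mr")$nuclear_pixels)
  # whole-MR fraction is the pixel-weighted mean of the parts
  parts <- tab[tab$compartment %in% c("core", "periphery", "neck"), ]
  expect_equal(g("MR")$fraction,
               sum(parts$fraction * parts$nuclear_pixels) /
                 sum(parts$nuclear_pixels))
  # empty compartment: undefined fraction, not zero
  expect_true(is.na(g("d.ect")$fraction))
  # masks must be nested and conformable
  expect_error(tabulateCompartments(lb, nuc, brd), "subset")
  expect_error(tabulateCompartments(lb, brd[1:5, 1:5], nuc[1:5, 1:5]),
               "shape")
})

test_that("phantom fractions are recovered within binomial error", {
  ph <- fixture("bud15")
  truth <- ph$truth
  i <- centralSection(ph)
  img <- sectionImage(ph, i)
  cnt <- quantifySection(img, truth@labelings[[i]])
  nuc <- truth@nuclei[truth@nuclei$section == i, ]
  ectN <- sum(nuc$compartment %in% c("d.ect", "v.ect"), na.rm = TRUE)
  fEct <- cnt$fraction[cnt$compartment == "ectoderm"]
  expect_lt(abs(fEct - 0.22), 3 * sqrt(0.22 * 0.78 / ectN))
  mrN <- sum(nuc$compartment %in% c("core", "periphery", "mr"), na.rm = TRUE)
  fMr <- cnt$fraction[cnt$compartment == "MR"]
  expect_lt(abs(fMr - 0.045), 3 * sqrt(0.045 * 0.955 / mrN))
})

test_that("dorso-ventral difference is a signed antisymmetric statistic", {
  expect_equal(dvDifference(0.2, 0.2), 0)
  expect_equal(dvDifference(0.25, 0.20), 0.05)
  expect_equal(dvDifference(0.20, 0.25), -dvDifference(0.25, 0.20))
  expect_true(is.na(dvDifference(NA, 0.2)))
})

test_that("ectoderm/rudiment ratios reproduce the published means", {
  expect_equal(ectodermMrRatio(0.22, 0.04), 5.5)
  # published per-rudiment fold differences and their printed means
  e115 <- c(3.5, 1.3, 5.6, 2.5)
  e125 <- c(4.5, 5.9, 4.0, 8.9, 4.2)
  e135 <- c(5.5, 24.8, 6.5, 8.1, 8.5)
  expect_equal(BudQuant:::roundHalfUp(mean(e115), 1), 3.2)
  expect_equal(BudQuant:::roundHalfUp(mean(e125), 1), 5.5)
  expect_equal(BudQuant:::roundHalfUp(mean(e135), 1), 10.7)
  expect_warning(r0 <- ectodermMrRatio(0.2, 0), "zero")
  expect_true(is.infinite(r0))
})
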