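test_that("active-contour ectoderm refinement recovers the true band", {
  ph <- fixture("bud15")
  i <- centralSection(ph)
  img <- sectionImage(ph, i)
  ann <- ph$truth@annotations[[i]]
  gt <- ph$truth@labelings[[i]]
  ectArms <- compartmentMask(gt, "d.ect") | compartmentMask(gt, "v.ect")
  rows <- range(which(rowSums(ectArms) > 0))
  fullBand <- matrix(FALSE, nrow(ectArms), ncol(ectArms))
  fullBand[rows[1]:rows[2], ] <- TRUE
  ect <- refineEctoderm(img, ann@basementMembrane, bandPrior = 15,
                        pixelSize = 1)
  expect_gte(jaccardIndex(ect, fullBand), 0.9)
})

test_that("ectoderm refinement error paths and fixed point", {
  blank <- array(0.97, c(60, 80, 3))
  mb <- cbind(rep(20, 10), seq(1, 80, length.out = 10))
  expect_error(refineEctoderm(blank, mb), "contrast|empty")
  expect_error(refineEctoderm(blank, cbind(c(999, 999), c(1, 80))),
               "outside image")
  # zero iterations return the initialisation band unchanged
  ph <- fixture("bud15")
  i <- centralSection(ph)
  img <- sectionImage(ph, i)
  ann <- ph$truth@annotations[[i]]
  init <- refineEctoderm(img, ann@basementMembrane, bandPrior = 15,
                         pixelSize = 1, maxIter = 0)
  W <- ncol(init)
  mrows <- BudQuant:::polylineRowAt(ann@basementMembrane, seq_len(W))
  d <- matrix(mrows, nrow(init), W, byrow = TRUE) -
    matrix(seq_len(nrow(init)), nrow(init), W)
  expect_identical(init, !is.na(d) & d > 0 & d <= 15)
})

test_that("mammary-mesenchyme band is an annulus of the right width", {
  m <- matrix(FALSE, 120, 120)
  m <- BudQuant:::fillEllipse(m, 60, 60, 30, 30)
  band <- mammaryMesenchymeBand(m, pixelSize = 1)
  expect_equal(sum(band), pi * (45^2 - 30^2), tolerance = 0.05)
  expect_equal(sum(band & m), 0)              # band never overlaps the MR
  # distance from the rudiment never exceeds 15 um + 1 px
  dmap <- as.matrix(EBImage::distmap(!m))
  expect_lte(max(dmap[band]), 16)
  # rounding rule for coarser pixels
  band2 <- mammaryMesenchymeBand(m, pixelSize = 1.5)
  dm2 <- as.matrix(EBImage::distmap(!m))
  expect_lte(max(dm2[band2]), 10 + 1)         # radius round(15/1.5) = 10
  expect_error(mammaryMesenchymeBand(m, pixelSize = 40), "coarse")
})

test_that("erosion to the 1:3 core matches the analytic disc", {
  m <- matrix(FALSE, 140, 140)
  m <- BudQuant:::fillEllipse(m, 70, 70, 60, 60)
  ec <- erodeToCore(m)
  expect_false(ec$degenerate)
  expect_lt(abs(ec$ratio - 1 / 3), 0.05)
  rEff <- sqrt(sum(ec$core) / pi)
  expect_lt(abs(rEff - 60 / sqrt(3)), 2)      # 60/sqrt(3) ~ 34.6 px
  expect_identical(ec$periphery, m & !ec$core)
  expect_error(erodeToCore(m, isCentralSection = FALSE), "central")
})

test_that("tiny masks take the degenerate empty-core path", {
  m <- matrix(FALSE, 10, 10); m[5, 5:7] <- TRUE
  expect_warning(ec <- erodeToCore(m), "empty")
  expect_true(ec$degenerate)
  expect_equal(sum(ec$core), 0)
  expect_identical(ec$periphery, m)
})

test_that("chosen erosion level is optimal under an exhaustive depth scan", {
  set.seed(3)
  for (rep in 1:3) {
    m <- matrix(FALSE, 96, 96)
    for (k in 1:4)
      m <- BudQuant:::fillEllipse(m, runif(1, 35, 60), runif(1, 35, 60),
                                  runif(1, 12, 25), runif(1, 12, 25),
                                  runif(1, 0, pi))
    ec <- erodeToCore(m)
    # oracle: re-erode exhaustively and track every achievable ratio
    A <- sum(m); cur <- m; best <- abs(1 - 1 / 3)
    repeat {
      cur <- as.matrix(EBImage::erode(cur, EBImage::makeBrush(3, "disc"))) > 0.5
      if (!any(cur)) break
      best <- min(best, abs(sum(cur) / A - 1 / 3))
    }
    expect_equal(abs(ec$ratio - 1 / 3), best, tolerance = 1e-12)
  }
})

test_that("dermal window spans 65 um below the center, parallel to the membrane", {
  mb <- cbind(rep(10, 20), seq(1, 120, length.out = 20))
  win <- dermalWindow(c(140, 120), mrCenter = c(40, 60),
                      basementMembrane = mb, pixelSize = 1)
  rows <- range(which(win, arr.ind = TRUE)[, 1])
  expect_equal(rows[1], 40)
  expect_equal(diff(rows), 65)
  # exclusions hold identically
  mr <- matrix(FALSE, 140, 120); mr <- BudQuant:::fillEllipse(mr, 50, 60, 20, 20)
  band <- mammaryMesenchymeBand(mr, 1)
  win2 <- dermalWindow(c(140, 120), c(40, 60), mb, 1,
                       exclude = list(mr, band))
  expect_equal(sum(win2 & (mr | band)), 0)
  expect_warning(dermalWindow(c(60, 120), c(40, 60), mb, 1), "clipped")
})

test_that("dermal window lies fully below the basement membrane on a phantom", {
  ph <- fixture("bud15")
  i <- centralSection(ph)
  ann <- ph$truth@annotations[[i]]
  gt <- ph$truth@labelings[[i]]
  win <- dermalWindow(dim(labelMap(gt)), ann@mrCenter,
                      ann@basementMembrane, pixelSize = 1)
  mrows <- BudQuant:::polylineRowAt(ann@basementMembrane,
                                    seq_len(ncol(labelMap(gt))))
  idx <- which(win, arr.ind = TRUE)
  expect_true(all(idx[, 1] > mrows[idx[, 2]]))
})

test_that("ectoderm splits into two arms that partition it", {
  ph <- fixture("bud15")
  i <- centralSection(ph)
  gt <- ph$truth@labelings[[i]]
  ectArms <- compartmentMask(gt, "d.ect") | compartmentMask(gt, "v.ect")
  rows <- range(which(rowSums(ectArms) > 0))
  band <- matrix(FALSE, nrow(ectArms), ncol(ectArms))
  band[rows[1]:rows[2], ] <- TRUE
  mr <- compartmentMask(gt, "core") | compartmentMask(gt, "periphery") |
    compartmentMask(gt, "mr")
  dv <- splitEctoderm(band, mr, "left")
  # symmetric phantom: arms equal within 2%
  expect_lt(abs(sum(dv$ventral) - sum(dv$dorsal)) /
              max(sum(dv$ventral), sum(dv$dorsal)), 0.02)
  # orientation flip swaps the masks exactly
  dv2 <- splitEctoderm(band, mr, "right")
  expect_identical(dv$ventral, dv2$dorsal)
  expect_identical(dv$dorsal, dv2$ventral)
  # partition identity: arms + attachment zone = ectoderm
  attachment <- band & !dv$ventral & !dv$dorsal
  expect_identical(dv$ventral | dv$dorsal | attachment, band)
  expect_equal(sum(dv$ventral & dv$dorsal), 0)
  # error when the rudiment is detached
  far <- matrix(FALSE, nrow(band), ncol(band)); far[130, 60] <- TRUE
  expect_error(splitEctoderm(band, far, "left"), "adjacent")
})

test_that("labelCompartments reproduces ground truth on a phantom", {
  ph <- fixture("bud15")
  i <- centralSection(ph)
  img <- sectionImage(ph, i)
  seg <- labelCompartments(img, ph$truth@annotations[[i]], pixelSize = 1)
  gt <- ph$truth@labelings[[i]]
  for (nm in c("d.ect", "v.ect", "core", "periphery", "mamm.mes",
               "derm.mes")) {
    expect_gte(jaccardIndex(compartmentMask(seg$labeling, nm),
                            compartmentMask(gt, nm)), 0.85)
  }
  # labels pairwise disjoint by construction of the map
  map <- labelMap(seg$labeling)
  tot <- 0
  for (nm in setdiff(compartmentNames(), "background"))
    tot <- tot + sum(compartmentMask(seg$labeling, nm))
  expect_equal(tot, sum(map > 0))
  # overlay has the image shape
  expect_identical(dim(seg$overlay), dim(img))
})

test_that("a manual line splits the mammary band into two labelled halves", {
  ph <- fixture("bud15")
  i <- centralSection(ph)
  img <- sectionImage(ph, i)
  ann <- ph$truth@annotations[[i]]
  W <- dim(img)[2]
  ann2 <- new("AnnotationSet", mrContour = ann@mrContour,
              neckContour = ann@neckContour,
              basementMembrane = ann@basementMembrane,
              mrCenter = ann@mrCenter, isCentralSection = TRUE,
              ventralSide = "left",
              mesenchymeSplitLine = cbind(rep(ann@mrCenter[1], 8),
                                          seq(1, W, length.out = 8)))
  seg <- labelCompartments(img, ann2, pixelSize = 1)
  halves <- seg$details$bandHalves
  band <- compartmentMask(seg$labeling, "mamm.mes")
  expect_identical(halves$a | halves$b, band)
  expect_equal(sum(halves$a & halves$b), 0)
  expect_gt(sum(halves$a), 0)
  expect_gt(sum(halves$b), 0)
})
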