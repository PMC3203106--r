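test_that("stack alignment recovers applied misalignments on a phantom", {
  ph <- fixture("bud9clean")
  imgs <- ph$images[1:5]
  pert <- perturbStack(imgs, maxShift = 3, maxRot = 0.05, maxScale = 0.02,
                       seed = 4)
  ref <- cbind(c(15, 15, 73.5), c(60, 240, 150))  # 2 ectoderm pts + center
  cps <- lapply(pert$transforms, function(tf) transformPoints(tf, ref))
  al <- alignStack(pert$stack, cps)
  expect_identical(al$kept, 1:5)
  for (i in 2:5) {
    rec <- al$transforms[[i]]
    tru <- invertTransform(pert$transforms[[i]])
    expect_equal(rec@s, tru@s, tolerance = 1e-9)
    expect_equal(rec@theta, tru@theta, tolerance = 1e-9)
    expect_equal(c(rec@tx, rec@ty), c(tru@tx, tru@ty), tolerance = 1e-9)
    # aligned image close to the unperturbed original
    expect_lt(mean(abs(al$stack[[i]] - imgs[[i]])), 0.08)
  }
  # alignment reduces the mean control-point residual
  resid <- function(stack_cps) mean(vapply(stack_cps, function(cp)
    mean(sqrt(rowSums((cp - ref)^2))), numeric(1)))
  aligned_cps <- lapply(seq_along(cps), function(i)
    transformPoints(al$transforms[[i]], cps[[i]]))
  expect_lt(resid(aligned_cps), resid(cps))
})

test_that("alignment edge cases: identity, single section, missing points", {
  ph <- fixture("bud9clean")
  imgs <- ph$images[1:3]
  ref <- cbind(c(15, 15, 73.5), c(60, 240, 150))
  al <- alignStack(imgs, list(ref, ref, ref))
  expect_true(all(vapply(al$transforms, isIdentityTransform, logical(1))))
  expect_identical(al$stack, imgs)
  one <- alignStack(imgs[1], list(ref))
  expect_identical(one$stack[[1]], imgs[[1]])
  expect_warning(al2 <- alignStack(imgs, list(ref, NULL, ref)), "skipped")
  expect_identical(al2$kept, c(1L, 3L))
})

test_that("label voxel extraction finds exactly the constructed nuclei", {
  # 40 well-separated BrdU-positive nuclei over 5 sections
  set.seed(9)
  grid <- as.matrix(expand.grid(row = seq(15, 85, by = 10),
                                col = seq(15, 75, by = 15)))
  pos <- cbind(grid[1:40, ], section = rep(c(1, 3, 5, 2, 4), each = 8))
  stack <- drawNucleusStack(c(100, 90), 5, pos, radius = 3)
  ns <- extractLabelVoxels(stack, spacing = c(1, 1, 5), nucleusRadiusUm = 3)
  expect_equal(nrow(nucleusTable(ns)), 40)
  # centroids in micrometres: z of section s is (s - 0.5) * 5
  tb <- nucleusTable(ns)
  expect_true(all(abs(sort(unique(tb$z_um)) -
                        (sort(unique(pos[, 3])) - 0.5) * 5) < 1e-9))
  # empty when no positive nuclei
  blank <- drawNucleusStack(c(40, 40), 2, cbind(row = 1, col = 1,
                                                section = 99)[0, ,
                                                              drop = FALSE])
  ns0 <- extractLabelVoxels(blank, spacing = c(1, 1, 5))
  expect_equal(nrow(nucleusTable(ns0)), 0)
  expect_error(extractLabelVoxels(stack, threshold = 1.2), "threshold")
})

test_that("the size window removes speckles", {
  pos <- cbind(row = 30, col = 30, section = 1)
  stack <- drawNucleusStack(c(60, 60), 2, pos, radius = 3)
  # add a 2-pixel speckle
  for (k in 1:3) stack[[2]][10, 10:11, k] <- c(70, 45, 30)[k] / 255
  ns <- extractLabelVoxels(stack, spacing = c(1, 1, 5),
                           sizeWindow = c(10, 100))
  expect_equal(nrow(nucleusTable(ns)), 1)
  expect_equal(nucleusTable(ns)$voxels, sum(
    BudQuant:::fillEllipse(matrix(FALSE, 60, 60), 30, 30, 3, 3)))
})

test_that("touching nuclei split into the true count with preserved voxels", {
  # two spheres overlapping ~20%
  a <- sphereArray(c(30, 24, 24), c(10, 12, 12), 6) |
    sphereArray(c(30, 24, 24), c(19.6, 12, 12), 6)
  ns <- BudQuant:::.nucleusSet(BudQuant:::.label3d(a), c(1, 1, 1))
  expect_equal(nrow(nucleusTable(ns)), 1)
  sp <- splitTouching(ns)
  tb <- nucleusTable(sp)
  expect_equal(nrow(tb), 2)
  # centroids within one voxel of the true centers (voxel-center coords)
  got <- sort(tb$row_um)
  expect_lt(abs(got[1] - 9.5), 1)
  expect_lt(abs(got[2] - 19.1), 1)
  # split labels exactly partition the input foreground
  expect_identical(sp@labels > 0, ns@labels > 0)
  # three in a row
  b <- sphereArray(c(42, 24, 24), c(10, 12, 12), 6) |
    sphereArray(c(42, 24, 24), c(19.6, 12, 12), 6) |
    sphereArray(c(42, 24, 24), c(29.2, 12, 12), 6)
  ns3 <- BudQuant:::.nucleusSet(BudQuant:::.label3d(b), c(1, 1, 1))
  expect_equal(nrow(nucleusTable(splitTouching(ns3))), 3)
  # a single sphere passes through unchanged
  s1 <- sphereArray(c(20, 20, 20), c(10, 10, 10), 6)
  ns1 <- BudQuant:::.nucleusSet(BudQuant:::.label3d(s1), c(1, 1, 1))
  sp1 <- splitTouching(ns1)
  expect_identical(sp1@labels, ns1@labels)
})

test_that("anisotropy-aware distance transform matches brute force", {
  set.seed(7)
  d <- c(7, 6, 5); spc <- c(1, 1.3, 2.1)
  m <- array(runif(prod(d)) > 0.4, d)
  e <- BudQuant:::.edt3d(m, spc)
  bg <- which(!m, arr.ind = TRUE)
  for (w in which(m)) {
    i <- c((w - 1) %% d[1] + 1, ((w - 1) %/% d[1]) %% d[2] + 1,
           (w - 1) %/% (d[1] * d[2]) + 1)
    bf <- min((sweep(bg, 2, i)^2) %*% (spc^2))
    expect_equal(e[w], bf, tolerance = 1e-9)
  }
})

test_that("iso-surfaces are watertight with volumes matching the voxel set", {
  sph <- sphereArray(c(45, 45, 45), c(23, 23, 23), 20)
  mesh <- isosurface(sph, spacing = c(1, 1, 1), tag = "nuclei")
  expect_gt(nrow(mesh@vertices), 0)
  expect_true(all(mesh@faces >= 1 & mesh@faces <= nrow(mesh@vertices)))
  # signed volume equals the voxel count (outward consistent winding)
  expect_equal(meshVolume(mesh), sum(sph), tolerance = 1e-9)
  # and is within 5% of the analytic sphere
  expect_lt(abs(meshVolume(mesh) / (4 / 3 * pi * 20^3) - 1), 0.05)
  # every edge is shared by exactly two faces (watertight)
  ed <- rbind(mesh@faces[, 1:2], mesh@faces[, 2:3], mesh@faces[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  expect_true(all(table(key) == 2))
  # anisotropic spacing scales the z extent
  slab <- sph[, , 20:26]
  m5 <- isosurface(slab, spacing = c(1, 1, 5))
  expect_equal(diff(range(m5@vertices[, 3])), 7 * 5)
  expect_error(isosurface(array(FALSE, c(3, 3, 3))), "empty")
})
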