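test_that("material membership follows the layered geometry", {
  fbr <- buildPhantom(collagenThickness = 100)
  ## collagen slab sits at the implant top depth, implant below it
  expect_identical(materialAt(fbr, c(0, 0, 1.55)), "collagen")
  expect_identical(materialAt(fbr, c(0, 0, 2.0)), "polystyrene")
  expect_identical(materialAt(fbr, c(0, 0, 0.5)), "skin")
  expect_identical(materialAt(fbr, c(0, 0, 1.0)), "fat")
  expect_identical(materialAt(fbr, c(0, 0, 10)), "muscle")
  ## outside the disk footprint the layers continue
  expect_identical(materialAt(fbr, c(5, 5, 1.55)), "muscle")
  expect_identical(sampleKind(fbr), "FBR")
})

test_that("zero collagen thickness yields the initial-conditions sample", {
  ic <- buildPhantom(collagenThickness = 0)
  expect_identical(sampleKind(ic), "InitialConditions")
  set.seed(7)
  pts <- cbind(runif(5000, -10, 10), runif(5000, -10, 10),
               runif(5000, 0, 20))
  expect_false(any(materialAt(ic, pts) == "collagen"))
  ## every point receives exactly one valid label
  expect_true(all(materialAt(ic, pts) %in%
                    c("skin", "fat", "muscle", "polystyrene")))
})

test_that("implant volume matches the cylinder by hit-or-miss sampling", {
  ic <- buildPhantom()
  set.seed(42)
  n <- 400000
  ## box tightly enclosing the implant
  pts <- cbind(runif(n, -4.5, 4.5), runif(n, -4.5, 4.5),
               runif(n, 1.4, 3.6))
  boxVol <- 9 * 9 * 2.2
  hit <- materialAt(ic, pts) == "polystyrene"
  mc <- mean(hit) * boxVol
  expect_lt(abs(mc - pi * 4^2 * 2) / (pi * 4^2 * 2), 0.01)
})

test_that("geometry is symmetric about the implant axis", {
  fbr <- buildPhantom(collagenThickness = 150)
  set.seed(3)
  pts <- cbind(runif(2000, -10, 10), runif(2000, -10, 10),
               runif(2000, 0, 20))
  expect_identical(materialAt(fbr, pts),
                   materialAt(fbr, cbind(-pts[, 1], -pts[, 2], pts[, 3])))
})

test_that("collagen region volume scales linearly with thickness", {
  set.seed(11)
  n <- 300000
  pts <- cbind(runif(n, -4.5, 4.5), runif(n, -4.5, 4.5),
               runif(n, 1.45, 1.75))
  hits <- vapply(c(100, 200), function(t)
    sum(materialAt(buildPhantom(collagenThickness = t), pts) == "collagen"),
    numeric(1))
  ## common random points: ratio of hit counts estimates the volume ratio
  expect_lt(abs(hits[2] / hits[1] - 2), 0.05)
})

test_that("phantom construction validates its inputs", {
  expect_error(buildPhantom(collagenThickness = -1), "nonnegative")
  expect_error(buildPhantom(skinThickness = -0.5), "positive")
  ## implant deeper than the domain
  expect_error(buildPhantom(implantTopDepth = 19.5), "below the domain")
  expect_error(buildPhantom(lateralExtent = 10), "at least 20")
})

test_that("mimicked thickness follows mass / (density * area)", {
  ## 1 g pure collagen over the 8 mm disk at 500 ug/mm^3 -> 39.79 mm
  t1 <- thicknessFromMass(1, 1, area = pi * 4^2, density = 500)
  expect_equal(t1 / 1000, 39.78874, tolerance = 1e-6)
  expect_identical(thicknessFromMass(0), 0)
  ## linear in mass
  expect_equal(thicknessFromMass(0.2, 1 / 11),
               2 * thicknessFromMass(0.1, 1 / 11))
  expect_error(thicknessFromMass(1, 1, area = 0), "positive")
  expect_error(thicknessFromMass(1, 2), "collagenFraction")
})
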