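test_that("dice matches hand counts and is a symmetric bounded overlap", {
  a <- array(0L, c(10, 10, 2))
  b <- array(0L, c(10, 10, 2))
  a[1:100] <- 1L          # |A| = 100
  b[41:100] <- 1L         # |B| = 60, overlap 50 after shifting B's support
  b[91:100] <- 0L
  b[101:110] <- 1L
  expect_equal(sum(a == 1), 100)
  expect_equal(sum(b == 1), 60)
  expect_equal(sum(a == 1 & b == 1), 50)
  expect_equal(dice(a, b), 2 * 50 / 160)
  expect_equal(dice(a, a), 1.0)
  d <- array(0L, c(10, 10, 2))
  d[150:200] <- 1L
  expect_equal(dice(a, d), 0.0)
  expect_equal(dice(array(0L, c(3, 3, 3)), array(0L, c(3, 3, 3))), 1.0)
  # symmetry + bounds on random masks
  set.seed(42)
  for (i in 1:5) {
    x <- array(rbinom(125, 1, 0.4), c(5, 5, 5))
    y <- array(rbinom(125, 1, 0.4), c(5, 5, 5))
    expect_identical(dice(x, y), dice(y, x))
    expect_true(dice(x, y) >= 0 && dice(x, y) <= 1)
  }
  expect_error(dice(a, array(0L, c(5, 5, 5))))
})

test_that("surface distances recover analytic sphere offsets", {
  s1 <- make_icosphere(1, subdivisions = 3)
  expect_equal(surface_distance(s1, s1)$rmse, 0)
  expect_equal(surface_distance(s1, s1)$hausdorff, 0)
  s2 <- make_icosphere(1.5, subdivisions = 3)
  r <- surface_distance(s1, s2)
  expect_equal(r$rmse, 0.5, tolerance = 0.02)
  expect_equal(r$hausdorff, 0.5, tolerance = 0.02)
  # symmetric HD is symmetric in its arguments
  expect_equal(surface_distance(s1, s2)$hausdorff,
               surface_distance(s2, s1)$hausdorff)
  expect_error(surface_distance(tri_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)), s1))
})

test_that("rmse <= hausdorff and symmetric HD obeys the triangle inequality", {
  set.seed(7)
  spheres <- lapply(1:4, function(i) {
    make_icosphere(runif(1, 0.5, 2), runif(3, -1, 1), subdivisions = 2)
  })
  hd <- function(a, b) surface_distance(a, b)$hausdorff
  for (i in 1:3) {
    r <- surface_distance(spheres[[i]], spheres[[i + 1]])
    expect_lte(r$rmse, r$hausdorff + 1e-12)
  }
  expect_lte(hd(spheres[[1]], spheres[[3]]),
             hd(spheres[[1]], spheres[[2]]) + hd(spheres[[2]], spheres[[3]]) + 1e-9)
  expect_lte(hd(spheres[[2]], spheres[[4]]),
             hd(spheres[[2]], spheres[[3]]) + hd(spheres[[3]], spheres[[4]]) + 1e-9)
})

test_that("contour distances recover analytic circle offsets and honor ignore zones", {
  sq <- planar_contour(cbind(c(0, 1, 2, 2, 2, 1, 0, 0), c(0, 0, 0, 1, 2, 2, 2, 1)) * 10)
  r0 <- contour_distance(sq, sq)
  expect_equal(r0$rmse, 0)
  expect_equal(r0$hausdorff, 0)
  c30 <- circle_contour(30)
  c31 <- circle_contour(31)
  r <- contour_distance(c30, c31)
  expect_equal(r$rmse, 1.0, tolerance = 0.02)
  expect_equal(r$hausdorff, 1.0, tolerance = 0.02)
  # zones excluded from the source samples
  rz <- contour_distance(c30, c31, ignore_zones = list(c(0.25, 0.75)))
  expect_equal(rz$rmse, 1.0, tolerance = 0.02)
  expect_error(contour_distance(c30, c31, ignore_zones = list(c(0, 1))),
               "empty after exclusion")
})
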