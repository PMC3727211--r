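test_that("similarity landmark fit recovers known transforms exactly", {
  # construct-and-recover over random rotations, scales and translations
  set.seed(21)
  for (i in 1:25) {
    ang <- runif(3, -pi, pi)
    Rz <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                            c(0, 0, 1))
    Rx <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)),
                            c(0, sin(a), cos(a)))
    Rm <- Rz(ang[1]) %*% Rx(ang[2]) %*% Rz(ang[3])
    tf <- similarity_transform(Rm, runif(1, 0.7, 1.4), runif(3, -20, 20))
    A <- landmark_set(matrix(runif(9, -15, 15), 3))
    fit <- fit_similarity_landmarks(A, landmark_set(apply_similarity(tf, A)))
    expect_lt(max(abs(fit$rotation - tf$rotation)), 1e-9)
    expect_lt(abs(fit$scale - tf$scale), 1e-9)
    expect_lt(max(abs(fit$translation - tf$translation)), 1e-9)
  }
})

test_that("similarity transforms invert and centroids align", {
  tf <- similarity_transform(diag(3), 1.1, c(5, -2, 1))
  pts <- matrix(rnorm(30), 10)
  back <- apply_similarity(invert_similarity(tf), apply_similarity(tf, pts))
  expect_lt(max(abs(back - pts)), 1e-12)
  A <- landmark_set(matrix(runif(9, -5, 5), 3))
  B <- landmark_set(matrix(runif(9, -5, 5), 3))
  fit <- fit_similarity_landmarks(A, B)
  expect_lt(max(abs(colMeans(apply_similarity(fit, A)) - colMeans(unclass(B)))),
            1e-9)
})

test_that("collinear landmark triplets are rejected", {
  expect_error(landmark_set(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               "collinear")
  A <- unclass(landmark_set(matrix(runif(9), 3)))
  coll <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(fit_similarity_landmarks(coll, A), "collinear")
})

test_that("FFD interpolation satisfies partition of unity", {
  lat <- ffd_lattice_covering(c(0, 0, 0), c(12, 12, 12), 4)
  g0 <- ffd_grid(lat$origin, lat$spacing, lat$dims)
  set.seed(5)
  pts <- matrix(runif(60, 0, 12), 20)
  expect_identical(max(abs(ffd_displacement(g0, pts))), 0)
  gv <- g0
  gv$coef[, , , 1] <- 1.5; gv$coef[, , , 2] <- -2; gv$coef[, , , 3] <- 0.25
  d <- ffd_displacement(gv, pts)
  expect_lt(max(abs(sweep(d, 2, c(1.5, -2, 0.25)))), 1e-12)
})

test_that("single-control-point displacement equals the direct tensor product", {
  # independent oracle: direct evaluation of the cubic B-spline polynomials
  lat <- ffd_lattice_covering(c(0, 0, 0), c(10, 10, 10), 5)
  set.seed(8)
  for (i in 1:10) {
    g <- ffd_grid(lat$origin, lat$spacing, lat$dims)
    ic <- c(sample(2:4, 1), sample(2:4, 1), sample(2:4, 1))
    g$coef[ic[1], ic[2], ic[3], 2] <- 1
    pt <- matrix(runif(3, 0, 10), 1)
    w <- 1
    for (a in 1:3) {
      t0 <- (pt[a] - lat$origin[a]) / lat$spacing
      cell <- floor(t0); u <- t0 - cell
      l <- ic[a] - cell
      w <- w * (if (l >= 0 && l <= 3) bspline_b(l, u) else 0)
    }
    expect_lt(abs(ffd_displacement(g, pt)[2] - w), 1e-9)
  }
})

test_that("points outside the lattice support are rejected by coordinate", {
  lat <- ffd_lattice_covering(c(0, 0, 0), c(10, 10, 10), 5)
  g <- ffd_grid(lat$origin, lat$spacing, lat$dims)
  expect_error(ffd_transform(g, matrix(c(50, 0, 0), 1)), "50")
})

test_that("scattered fit reproduces constants, recovers known fields, handles one point", {
  lat <- ffd_lattice_covering(c(0, 0, 0), c(15, 15, 15), 5)
  set.seed(13)
  pts <- matrix(runif(300, 0, 15), 100)
  # constant displacement reproduced
  g <- fit_ffd_scattered(pts, matrix(rep(c(2, -1, 0.5), each = 100), 100), lat)
  chk <- matrix(runif(60, 1, 14), 20)
  expect_lt(max(abs(sweep(ffd_displacement(g, chk), 2, c(2, -1, 0.5)))), 1e-6)
  # construct-and-recover from a known FFD sampled densely: the induced
  # field is recovered in the data-covered interior (control points whose
  # support the samples never touch are not identifiable)
  gt <- ffd_grid(lat$origin, lat$spacing, lat$dims,
                 array(runif(prod(lat$dims) * 3, -1, 1), c(lat$dims, 3)))
  dense <- as.matrix(expand.grid(seq(0, 15, 0.75), seq(0, 15, 0.75),
                                 seq(0, 15, 0.75)))
  fit <- fit_ffd_scattered(dense, ffd_displacement(gt, dense), lat,
                           lambda = 1e-10)
  inner <- matrix(runif(300, 1, 14), 100)
  expect_lt(max(abs(ffd_displacement(fit, inner) -
                      ffd_displacement(gt, inner))), 1e-3)
  # single point: minimum-norm-style solution matching its displacement
  one <- fit_ffd_scattered(matrix(c(7, 7, 7), 1), matrix(c(1, 0, 0), 1), lat)
  expect_lt(max(abs(ffd_displacement(one, matrix(c(7, 7, 7), 1)) -
                      c(1, 0, 0))), 1e-4)
  expect_error(fit_ffd_scattered(matrix(numeric(0), 0, 3),
                                 matrix(numeric(0), 0, 3), lat), "no points")
})

test_that("FFD refinement preserves the coarse deformation", {
  lat <- ffd_lattice_covering(c(0, 0, 0), c(20, 20, 20), 10)
  set.seed(2)
  coarse <- ffd_grid(lat$origin, lat$spacing, lat$dims,
                     array(runif(prod(lat$dims) * 3, -2, 2), c(lat$dims, 3)))
  fine <- refine_ffd(coarse, 5)
  pts <- matrix(runif(300, 2, 18), 100)
  dev <- max(abs(ffd_displacement(fine, pts) - ffd_displacement(coarse, pts)))
  expect_lt(dev, 0.1 * max(abs(coarse$coef)))
  # zero field refines to zero; translation fields refine exactly
  z <- refine_ffd(ffd_grid(lat$origin, lat$spacing, lat$dims), 5)
  expect_lt(max(abs(z$coef)), 1e-8)
  tr <- ffd_grid(lat$origin, lat$spacing, lat$dims)
  tr$coef[, , , 1] <- 3
  trf <- refine_ffd(tr, 5)
  expect_lt(max(abs(sweep(ffd_displacement(trf, pts), 2, c(3, 0, 0)))), 1e-6)
  expect_error(refine_ffd(coarse, 10), "smaller")
})

test_that("moving one control point only alters the field inside its support", {
  lat <- ffd_lattice_covering(c(0, 0, 0), c(30, 30, 30), 5)
  g <- ffd_grid(lat$origin, lat$spacing, lat$dims)
  ic <- c(4, 4, 4)
  g$coef[ic[1], ic[2], ic[3], 1] <- 2
  cpos <- lat$origin + (ic - 1) * lat$spacing
  set.seed(30)
  pts <- matrix(runif(600, 2, 28), 200)
  d <- ffd_displacement(g, pts)[, 1]
  far <- apply(abs(sweep(pts, 2, cpos)), 1, max) >= 2 * lat$spacing
  expect_identical(max(abs(d[far])), 0)
  expect_gt(max(abs(d[!far])), 0)
})

test_that("non-rigid ICP is exact on identical meshes and recovers known warps", {
  fx <- atlas_fixture()
  # identical meshes: zero RMSE, zero deformation at every level
  reg0 <- icp_nonrigid(fx$gp_target, fx$gp_target,
                       schedule_mm = c(20, 10, 5), max_iter = 5)
  expect_lt(max(reg0$rmse), 1e-9)
  expect_lt(max(abs(reg0$grids[[3]]$coef)), 1e-6)
  # the atlas fixture: large initial error, sub-0.1 mm final surface RMSE
  reg <- gp_registration()
  expect_lt(reg$rmse[length(reg$rmse)], 0.1)
  expect_true(all(diff(reg$rmse) <= 1e-9))
  # non-overlapping meshes are rejected with advice
  off <- surface_mesh(sweep(fx$gp_source$vertices, 2, c(500, 0, 0), "+"),
                      fx$gp_source$faces)
  expect_error(icp_nonrigid(off, fx$gp_target), "pre-registration")
})

test_that("registration is equivariant under rigid motions of both meshes", {
  fx <- atlas_fixture()
  reg <- gp_registration()
  th <- 0.6
  Rm <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  tr <- c(12, -4, 7)
  move <- function(m) surface_mesh(sweep(m$vertices %*% t(Rm), 2, tr, "+"),
                                   m$faces)
  reg2 <- icp_nonrigid(move(fx$gp_source), move(fx$gp_target))
  pts <- fx$gp_source$vertices[seq(1, nrow(fx$gp_source$vertices), 40), ]
  mapped1 <- sweep(predict(reg, pts) %*% t(Rm), 2, tr, "+")
  mapped2 <- predict(reg2, sweep(pts %*% t(Rm), 2, tr, "+"))
  expect_lt(max(abs(mapped1 - mapped2)), 1e-6)
})
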