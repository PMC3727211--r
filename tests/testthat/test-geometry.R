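test_that("extracted sphere surface matches the analytic area and radius", {
  vol <- sphere_volume(radius = 10, spacing = 0.5)
  m <- extract_surface(vol, 1L)
  expect_lt(abs(mesh_area(m) / (4 * pi * 100) - 1), 0.03)
  radial <- abs(sqrt(rowSums(m$vertices^2)) - 10)
  expect_lt(max(radial), 0.5 * sqrt(3))   # one voxel diagonal
})

test_that("surface extraction rejects absent and degenerate labels", {
  vol <- sphere_volume(radius = 4, spacing = 1)
  expect_error(extract_surface(vol, 7L), "absent")
  vol$data[] <- 0L
  vol$data[4, 4, 4] <- 2L
  expect_error(extract_surface(vol, 2L), "degenerate")
})

test_that("mesh RMSE equals the direct per-vertex computation", {
  vol <- sphere_volume(radius = 6, spacing = 1)
  m <- extract_surface(vol, 1L)
  expect_identical(mesh_rmse(m, m), 0)
  shifted <- surface_mesh(sweep(m$vertices, 2, c(3, 0, 0), "+"), m$faces)
  expect_equal(mesh_rmse(m, shifted), 3, tolerance = 1e-12)
  set.seed(9)
  jit <- m$vertices + matrix(rnorm(length(m$vertices), 0, 0.3),
                             ncol = 3)
  direct <- sqrt(mean(rowSums((m$vertices - jit)^2)))
  expect_equal(mesh_rmse(m, surface_mesh(jit, m$faces)), direct,
               tolerance = 1e-12)
  expect_error(mesh_rmse(m, surface_mesh(m$vertices[-1, ], m$faces[1, , drop = FALSE])),
               "vertex counts")
})

test_that("PLY and OBJ round-trips preserve the mesh", {
  vol <- sphere_volume(radius = 5, spacing = 1)
  m <- extract_surface(vol, 1L)
  fp <- tempfile(fileext = ".ply"); fo <- tempfile(fileext = ".obj")
  write_ply(m, fp); write_obj(m, fo)
  for (m2 in list(read_ply(fp), read_obj(fo))) {
    expect_equal(m2$vertices, unname(m$vertices), tolerance = 1e-6)
    expect_identical(m2$faces, unname(m$faces))
  }
})

test_that("a straight lead has arc length equal to the chord", {
  cp <- cbind(seq(0, 30, length.out = 5), seq(0, -15, length.out = 5),
              seq(0, 9, length.out = 5))
  lead <- build_lead(lead_spec(cp))
  chord <- sqrt(sum((cp[5, ] - cp[1, ])^2))
  expect_lt(abs(lead$total_length - chord), 1e-9)
})

test_that("the default lead has four ordered contacts with three gaps", {
  cp <- rbind(c(0, 0, 30), c(0, 0, 20), c(0, 0, 10), c(0, 0, 0))
  lead <- build_lead(lead_spec(cp))
  expect_identical(nrow(lead$contacts), 4L)
  expect_true(all(diff(lead$contacts[, "start"]) > 0))   # distal -> proximal
  gaps <- lead$contacts[-1, "start"] - lead$contacts[-4, "end"]
  expect_equal(unname(gaps), rep(1.5, 3), tolerance = 1e-9)
  # the contact array must fit along the lead (4x6 + 3x4 + tip > 30)
  expect_error(build_lead(lead_spec(cp, contact_length_mm = 6,
                                    contact_gap_mm = 4)), "fit")
  expect_error(lead_spec(cp, contact_gap_mm = 0), "overlap")
})

test_that("lead rasterization resolves contacts at fine spacing and merges them at coarse", {
  cp <- rbind(c(0, 0, 16), c(0, 0, 10), c(0, 0, 5), c(0, 0, 0))
  spec <- lead_spec(cp, insulation_radius_mm = 1, contact_radius_mm = 1,
                    core_radius_mm = 0.4, contact_length_mm = 0.6,
                    contact_gap_mm = 0.6, tip_offset_mm = 0.3)
  lead <- build_lead(spec)
  # brute-force oracle: classify by exact point-line distance and arc position
  oracle <- function(grid) {
    cc <- grid_centers(grid)
    n <- grid_dims(grid)
    pts <- as.matrix(expand.grid(cc$x, cc$y, cc$z))
    r <- sqrt(pts[, 1]^2 + pts[, 2]^2)          # distance to z axis
    s <- pts[, 3]                               # arc position from the tip
    contact <- rep(FALSE, nrow(pts))
    for (q in seq_len(nrow(lead$contacts)))
      contact <- contact | (s >= lead$contacts[q, 1] & s <= lead$contacts[q, 2])
    cls <- integer(nrow(pts))
    cls[r <= 1 & s >= 0 & s <= 16] <- 2L
    # the swept tube ends in a rounded cap at the tip
    cls[s < 0 & sqrt(r^2 + s^2) <= 1] <- 2L
    cls[contact & r <= 1] <- 1L
    cls[r <= 0.4 & s >= 0 & s <= 16] <- 1L
    array(cls, n)
  }
  # z offset keeps cell centres off the exact contact boundaries
  fine <- uniform_grid(c(-2, -2, -1.11), c(2, 2, 8.09), 0.2)
  ov <- unclass(rasterize_lead(lead, fine))
  exp_f <- oracle(fine)
  expect_gt(mean(ov == exp_f), 0.99)    # sub-voxel arc sampling at interfaces
  # the core makes the whole distal column conductor; probe outside it:
  # contacts only -> 4 disjoint axial conductor runs
  col <- ov[14, 11, ]                   # x = 0.7, y = 0.1
  runs <- rle(col == 1L)
  expect_identical(sum(runs$values), 4L)
  coarse <- uniform_grid(c(-2.5, -2.5, -1.5), c(2.5, 2.5, 8.5), 1)
  ovc <- unclass(rasterize_lead(lead, coarse))
  colc <- ovc[4, 3, ]                   # one cell off-axis
  expect_lt(sum(rle(colc == 1L)$values), 4L)  # staircasing merges the pattern
  tiny <- uniform_grid(c(30, 30, 30), c(40, 40, 40), 1)
  expect_error(rasterize_lead(lead, tiny), "intersect")
})

test_that("lead construction transforms covariantly under rigid motions", {
  cp <- rbind(c(0, 0, 18), c(1, 0.5, 12), c(2, 0, 6), c(2.5, -1, 0))
  lead1 <- build_lead(lead_spec(cp))
  th <- 0.7
  Rm <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- c(5, -3, 2)
  lead2 <- build_lead(lead_spec(sweep(cp %*% t(Rm), 2, tr, "+")))
  expect_equal(lead2$total_length, lead1$total_length, tolerance = 1e-8)
  expect_equal(lead2$contacts, lead1$contacts, tolerance = 1e-8)
  mapped <- sweep(lead1$centerline %*% t(Rm), 2, tr, "+")
  expect_equal(lead2$centerline, mapped, tolerance = 1e-8)
})

test_that("rasterized conductor volume converges to the analytic cylinder volume", {
  cp <- rbind(c(0, 0, 12), c(0, 0, 8), c(0, 0, 4), c(0, 0, 0))
  spec <- lead_spec(cp, insulation_radius_mm = 1, contact_radius_mm = 1,
                    core_radius_mm = 0.5, contact_length_mm = 1.5,
                    contact_gap_mm = 1.5, tip_offset_mm = 0.5)
  lead <- build_lead(spec)
  vol_of <- function(h) {
    g <- uniform_grid(c(-2, -2, -1), c(2, 2, 13), h)
    sum(unclass(rasterize_lead(lead, g)) == 1L) * h^3
  }
  # conductor = 4 contacts (r = 1) + core (r = 0.5) elsewhere along 12 mm
  analytic <- 4 * 1.5 * pi * 1^2 + (12 - 6) * pi * 0.5^2
  expect_lt(abs(vol_of(0.2) / analytic - 1), 0.10)
  expect_lt(abs(vol_of(0.2) / analytic - 1),
            abs(vol_of(0.8) / analytic - 1))
})
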