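test_that("shell-only phantom respects the outer ellipsoid", {
  spec <- head_phantom_spec(nuclei = list())
  hp <- make_head_phantom(spec, 1)
  vol <- hp$volume
  expect_setequal(sort(unique(as.vector(vol$data))), c(0L, 1L, 2L, 3L, 4L))
  idx <- which(vol$data > 0L) - 1L
  d <- dim(vol$data)
  pts <- cbind(vol$origin[1] + ((idx %% d[1]) + 0.5) * vol$spacing[1],
               vol$origin[2] + (((idx %/% d[1]) %% d[2]) + 0.5) * vol$spacing[2],
               vol$origin[3] + ((idx %/% (d[1] * d[2])) + 0.5) * vol$spacing[3])
  q <- (pts[, 1] / 16)^2 + (pts[, 2] / 20)^2 + (pts[, 3] / 16)^2
  expect_true(all(q <= 1))
})

test_that("structure volumes agree across rasterization resolutions", {
  # brute-force voxel counting at two spacings on a compact spec
  spec <- head_phantom_spec(outer_semiaxes_mm = c(9, 10, 9),
                            nuclei = list(
                              list(name = "blob", label = 10L,
                                   center = c(0, 0, 0),
                                   semiaxes = c(3, 3.5, 3), lamina = FALSE)))
  v1 <- make_head_phantom(spec, 1)$volume
  v02 <- make_head_phantom(spec, 0.2)$volume
  for (lab in c(1L, 2L, 4L, 10L)) {   # all >= 5 mm across
    vol1 <- structure_volume(v1$data == lab, v1$spacing)
    vol02 <- structure_volume(v02$data == lab, v02$spacing)
    expect_lt(abs(vol02 / vol1 - 1), 0.05)
  }
})

test_that("rasterized volume converges to the analytic one as spacing shrinks", {
  spec <- head_phantom_spec()
  gpi <- spec$primitives[[1]]
  analytic <- 4 / 3 * pi * prod(gpi$semiaxes)
  region <- list(lo = gpi$center - gpi$semiaxes - 1,
                 hi = gpi$center + gpi$semiaxes + 1)
  err <- vapply(c(1, 0.2, 0.1), function(h) {
    v <- make_head_phantom(spec, h, region = region)$volume
    abs(structure_volume(v$data == 13L, h) / analytic - 1)
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[3], 0.02)
})

test_that("sub-voxel laminae survive fine rasterization and vanish at coarse", {
  spec <- head_phantom_spec()
  crop <- list(lo = c(-5, -7, -5), hi = c(5, 3, 5))
  fine <- make_head_phantom(spec, 0.2, region = crop)$volume
  coarse <- make_head_phantom(spec, 1)$volume
  expect_gt(sum(fine$data == 21L), 0)   # internal lamina present
  expect_gt(sum(fine$data == 20L), 0)   # external lamina present
  expect_identical(sum(coarse$data == 21L), 0L)
  expect_identical(sum(coarse$data == 20L), 0L)
})

test_that("a nucleus escaping the white matter is rejected by name", {
  expect_error(
    head_phantom_spec(nuclei = list(
      list(name = "rogue", label = 10L, center = c(9, 12, 9),
           semiaxes = c(4, 4, 4), lamina = FALSE))),
    "rogue")
})

test_that("micro atlas with identity warp equals nearest-neighbour resampling", {
  spec <- head_phantom_spec()
  crop <- list(lo = c(-5, -7, -5), hi = c(5, 3, 5))
  hp <- make_head_phantom(spec, 0.4, region = crop)
  atl <- make_micro_atlas(hp$volume, warp_amplitude_mm = 0,
                          warp_spacing_mm = 10, seed = 3,
                          landmarks = hp$landmarks,
                          rotation_deg = 0, scale = 1,
                          translation_mm = c(0, 0, 0))
  expect_identical(atl$volume$data, hp$volume$data)
})

test_that("micro atlas generation is deterministic in the seed", {
  spec <- head_phantom_spec()
  crop <- list(lo = c(-4, -6, -4), hi = c(4, 2, 4))
  hp <- make_head_phantom(spec, 0.4, region = crop)
  a1 <- make_micro_atlas(hp$volume, 1.5, 8, seed = 11, landmarks = hp$landmarks)
  a2 <- make_micro_atlas(hp$volume, 1.5, 8, seed = 11, landmarks = hp$landmarks)
  expect_identical(a1$volume$data, a2$volume$data)
  expect_identical(a1$ffd$coef, a2$ffd$coef)
  a3 <- make_micro_atlas(hp$volume, 1.5, 8, seed = 12, landmarks = hp$landmarks)
  expect_false(identical(a1$ffd$coef, a3$ffd$coef))
})

test_that("atlas warp amplitude bounds the surface displacement", {
  # brute-force: evaluate the generated FFD on the GPi surface points; the
  # displacement can never exceed the control amplitude (partition of unity)
  fx <- atlas_fixture()
  gpi <- extract_surface(fx$head$volume, 13L)
  disp <- ffd_displacement(fx$atlas$ffd, gpi$vertices, clamp = TRUE)
  expect_lte(max(abs(disp)), 2)
  expect_error(make_micro_atlas(fx$head$volume, 6, 10, seed = 1), "folding")
})

test_that("probe points are reproducible and lie on their layers", {
  spec <- head_phantom_spec()
  hp <- make_head_phantom(spec, 1)
  p1 <- make_probe_points(hp$volume, 5, labels = c(S = 1L, GM = 11L), seed = 4)
  p2 <- make_probe_points(hp$volume, 5, labels = c(S = 1L, GM = 11L), seed = 4)
  expect_identical(p1, p2)
  expect_identical(rownames(p1), c(paste0("S", 1:5), paste0("GM", 1:5)))
  labs <- sample_labels(hp$volume, p1)
  expect_identical(labs, c(rep(1L, 5), rep(11L, 5)))
  expect_error(make_probe_points(hp$volume, 5, labels = c(X = 99L), seed = 1),
               "empty")
  expect_error(make_probe_points(hp$volume, 1e6, labels = c(GM = 13L), seed = 1),
               "only")
})
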