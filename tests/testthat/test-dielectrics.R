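test_that("tissue lookup resolves nuclei to grey matter and laminae to white matter", {
  tab <- load_tissue_table()
  gpi <- material_for("GPi", tab)
  expect_equal(gpi$sigma, 0.58)
  expect_equal(gpi$eps_r, 73.51)
  iml <- material_for("IML", tab)
  expect_equal(iml$sigma, 0.34)
  expect_equal(iml$eps_r, 52.53)
  air <- material_for("air", tab)
  expect_equal(air$sigma, 0)
  expect_equal(air$eps_r, 1)
  expect_equal(material_for(13L, tab)$sigma, 0.58)  # integer labels resolve too
  expect_equal(material_for("conductor", tab)$sigma, 4e6)
  expect_equal(material_for("insulation", tab)$eps_r, 3)
  expect_error(material_for("adamantium", tab), "known")
})

test_that("material assignment covers every cell exactly once", {
  hp <- make_head_phantom(head_phantom_spec(), 1)
  cp <- rbind(c(4.5, 4, 16), c(3, 2, 10), c(1.5, -0.5, 4), c(0, -2, -3.8))
  lead <- build_lead(lead_spec(cp, insulation_radius_mm = 1,
                               contact_radius_mm = 1, core_radius_mm = 0.75,
                               contact_length_mm = 0.6, contact_gap_mm = 0.6,
                               tip_offset_mm = 0.3))
  g <- uniform_grid(c(-20, -24, -20), c(20, 24, 20), 1)
  ov <- rasterize_lead(lead, g)
  mat <- assign_materials(hp$volume, ov, grid = g)
  n <- prod(grid_dims(g))
  air <- !mat$tissue & mat$implant == 0L
  expect_equal(sum(mat$tissue) + sum(mat$implant > 0) + sum(air), n)
  # implant overrides tissue
  expect_true(all(mat$sigma[mat$implant == 1L] == 4e6))
  expect_true(all(mat$pec[mat$implant == 1L]))
  expect_true(all(mat$eps_r[mat$implant == 2L] == 3))
  # air cells are vacuum-like
  expect_true(all(mat$sigma[air] == 0))
  expect_true(all(mat$eps_r[air] == 1))
  expect_error(assign_materials(hp$volume,
                                structure(array(0L, c(2, 2, 2)),
                                          class = "implant_overlay"),
                                grid = g), "match")
})

test_that("a homogeneous grey-matter phantom gives a uniform sigma field", {
  arr <- array(13L, c(6, 6, 6))   # GPi label -> grey matter everywhere
  vol <- label_volume(arr, 1)
  mat <- assign_materials(vol)
  expect_true(all(mat$sigma == 0.58))
  expect_true(all(mat$eps_r == 73.51))
  expect_true(all(mat$tissue))
})

test_that("multiscale grid covers the roi with fine cells and bounded grading", {
  dom <- list(lo = c(-20, -20, -20), hi = c(20, 20, 20))
  roi <- list(lo = c(-2, -3, -4), hi = c(2, 0, 2))
  g <- build_multiscale_grid(dom, roi, fine_mm = 0.2, coarse_mm = 1,
                             grading_ratio = 1.5)
  for (a in 1:3) {
    e <- g$edges[[a]]
    h <- diff(e)
    expect_lt(max(abs(c(e[1], e[length(e)]) - c(dom$lo[a], dom$hi[a]))), 1e-9)
    r <- h[-1] / h[-length(h)]
    expect_lte(max(pmax(r, 1 / r)), 1.5 + 1e-6)
    fine <- e >= roi$lo[a] - 1e-9 & e <= roi$hi[a] + 1e-9
    expect_lt(max(abs(diff(e[fine]) - 0.2)), 1e-9)
    expect_lte(max(h), 1 + 1e-6)
  }
  expect_equal(sum(unlist(lapply(grid_cell_sizes(g), sum))), 120,
               tolerance = 1e-9)
  # degenerate roi: uniform coarse grid
  g0 <- build_multiscale_grid(dom, list(lo = c(0, 0, 0), hi = c(0, 0, 0)),
                              coarse_mm = 1)
  expect_identical(grid_dims(g0), c(x = 40L, y = 40L, z = 40L))
  expect_error(build_multiscale_grid(dom,
                                     list(lo = c(-30, 0, 0), hi = c(0, 1, 1))),
               "outside")
  # roi spanning the whole domain: uniform fine grid
  gf <- build_multiscale_grid(list(lo = c(0, 0, 0), hi = c(4, 4, 4)),
                              list(lo = c(0, 0, 0), hi = c(4, 4, 4)),
                              fine_mm = 0.5)
  expect_true(all(abs(unlist(grid_cell_sizes(gf)) - 0.5) < 1e-9))
})

test_that("cell-interior material assignment is resolution independent", {
  hp1 <- make_head_phantom(head_phantom_spec(), 1)
  tab <- load_tissue_table()
  g1 <- uniform_grid(c(-6, -8, -6), c(6, 4, 6), 1)
  g2 <- uniform_grid(c(-6, -8, -6), c(6, 4, 6), 0.5)
  m1 <- assign_materials(hp1$volume, NULL, tab, g1)
  m2 <- assign_materials(hp1$volume, NULL, tab, g2)
  # every fine cell strictly inside a coarse cell carries its material
  expect_equal(m2$sigma[2, 2, 2], m1$sigma[1, 1, 1])
  keep <- function(a) a[seq(1, dim(a)[1], 2), seq(1, dim(a)[2], 2),
                        seq(1, dim(a)[3], 2)]
  expect_true(mean(keep(m2$sigma) == m1$sigma) > 0.95)
})

test_that("the Courant timestep follows the closed form and scales linearly", {
  g <- uniform_grid(c(0, 0, 0), c(10, 10, 10), 1)
  dt <- courant_dt(g, safety = 1)
  expect_equal(dt, 1e-3 / (299792458 * sqrt(3)), tolerance = 1e-12)
  # ~1.925 ps at 1 mm (1.9245 with the rounded c = 3e8 m/s)
  expect_equal(dt * 1e12, 1.9245, tolerance = 1e-3)
  g2 <- uniform_grid(c(0, 0, 0), c(10, 10, 10), 0.5)
  expect_equal(courant_dt(g2, 1), dt / 2, tolerance = 1e-12)
  # a graded grid is limited by its smallest cell
  gm <- build_multiscale_grid(list(lo = c(0, 0, 0), hi = c(20, 20, 20)),
                              list(lo = c(8, 8, 8), hi = c(12, 12, 12)),
                              fine_mm = 0.2, coarse_mm = 1)
  expect_lt(courant_dt(gm, 0.99), 0.99 * 0.2e-3 / (299792458 * sqrt(3)) * 1.001)
})
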