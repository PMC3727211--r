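# SAR computation against closed forms and exhaustive-search oracles on toy
# grids; full-simulation SAR behaviour is covered by the acceptance suite.

toy_field <- function(grid, mag) {
  n <- grid_dims(grid)
  stopifnot(all(dim(mag) == n))
  structure(list(grid = grid, Ex = array(complex(real = mag), n),
                 Ey = array(0i, n), Ez = array(0i, n),
                 params = NULL, converged = TRUE, periods = 1L),
            class = "field_volume")
}

uniform_tissue <- function(n = 5, h = 10, sigma = 2, rho = 1000) {
  g <- uniform_grid(c(0, 0, 0), rep(n * h, 3), h)
  m <- vacuum_materials(g)
  m$sigma[] <- sigma; m$rho[] <- rho; m$eps_r[] <- 60
  m$tissue[] <- TRUE
  m
}

test_that("raw SAR follows sigma |E|^2 / (2 rho) and masks the implant", {
  m <- uniform_tissue(5, sigma = 2, rho = 1000)
  f <- toy_field(m$grid, array(10, c(5, 5, 5)))
  s <- local_sar(f, m)
  expect_equal(max(abs(s$sar - 0.1)), 0, tolerance = 1e-12)
  # conductor cells carry no SAR
  m2 <- m; m2$implant[3, 3, 3] <- 1L; m2$tissue[3, 3, 3] <- FALSE
  s2 <- local_sar(f, m2)
  expect_identical(s2$sar[3, 3, 3], 0)
  # zero field -> zero map
  s0 <- local_sar(toy_field(m$grid, array(0, c(5, 5, 5))), m)
  expect_identical(max(s0$sar), 0)
})

test_that("cube-grown averages equal the exhaustive-search oracle on toy grids", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 5
    m <- uniform_tissue(n, h = 10, sigma = 1)
    # per-cell densities keep box masses away from exact target ties
    m$rho <- array(900 + 200 * runif(n^3), rep(n, 3))
    mag <- array(runif(n^3, 0, 20), rep(n, 3))
    m$tissue[sample(n^3, 5)] <- FALSE          # punch air holes
    f <- toy_field(m$grid, mag)
    raw <- local_sar(f, m)
    target_g <- 1000 * sum(m$rho[m$tissue]) * 1e-6 * 0.4  # 40% of total mass
    avg <- averaged_sar(raw, m, target_g)
    # oracle: for each tissue cell, enumerate cells by Chebyshev distance of
    # centres and take the smallest centred cube reaching the mass
    cc <- grid_centers(m$grid)
    ctr <- as.matrix(expand.grid(cc$x, cc$y, cc$z))
    mass <- ifelse(m$tissue, m$rho * 1e-6, 0)  # 10 mm cells -> 1e-6 m^3
    pow <- raw$sar * mass
    for (ci in which(m$tissue)) {
      d <- apply(abs(sweep(ctr, 2, ctr[ci, ])), 1, max)
      ord <- order(d)
      dm <- 0; dp <- 0; h <- 0
      for (q in seq_along(ord)) {
        h <- d[ord[q]]
        sel <- d <= h + 1e-9
        dm <- sum(mass[sel]); dp <- sum(pow[sel])
        if (dm >= target_g / 1000) break
      }
      expect_equal(avg$sar[ci], dp / dm, tolerance = 1e-9)
    }
  }
})

test_that("uniform SAR averages to itself and single hot cells obey the peak ordering", {
  m <- uniform_tissue(7, h = 10)
  s <- 3.7
  mag <- array(sqrt(2 * s * m$rho[1] / m$sigma[1]), rep(7, 3))
  raw <- local_sar(toy_field(m$grid, mag), m)
  avg <- averaged_sar(raw, m, 1000 * m$rho[1] * 1e-6 * 3)  # 3-cell mass
  expect_lt(max(abs(avg$sar[avg$valid] - s)), 1e-9)
  # hot cell: averaging can only reduce the peak
  mag[4, 4, 4] <- 10 * mag[4, 4, 4]
  raw2 <- local_sar(toy_field(m$grid, mag), m)
  a1 <- averaged_sar(raw2, m, 1000 * m$rho[1] * 1e-6 * 2)
  a10 <- averaged_sar(raw2, m, 1000 * m$rho[1] * 1e-6 * 20)
  expect_lte(a10$peak, a1$peak)
  expect_lte(a1$peak, raw2$peak)
})

test_that("whole-head SAR matches the explicit mass-weighted sum and scales quadratically", {
  set.seed(12)
  m <- uniform_tissue(6, h = 8, sigma = 0.5, rho = 1050)
  m$tissue[1:2, , ] <- FALSE
  mag <- array(runif(216, 0, 5), rep(6, 3))
  raw <- local_sar(toy_field(m$grid, mag), m)
  mass <- ifelse(m$tissue, m$rho * 8^3 * 1e-9, 0)
  expect_equal(whole_head_sar(raw, m),
               sum(raw$sar * mass) / sum(mass), tolerance = 1e-12)
  raw2 <- local_sar(toy_field(m$grid, 2 * mag), m)
  expect_equal(whole_head_sar(raw2, m), 4 * whole_head_sar(raw, m),
               tolerance = 1e-12)
  # power bookkeeping: total absorbed power equals SAR_w times tissue mass
  expect_equal(sum(raw$sar * mass),
               whole_head_sar(raw, m) * sum(mass), tolerance = 1e-12)
})

test_that("normalization drives the reference whole-head SAR to the target", {
  m <- uniform_tissue(5)
  mag <- array(runif(125, 1, 3), rep(5, 3))
  f <- toy_field(m$grid, mag)
  ref <- whole_head_sar(local_sar(f, m), m)
  nz <- normalize_to_reference(list(a = f, b = f), ref, target = 3.2)
  expect_equal(nz$scale, sqrt(3.2 / ref), tolerance = 1e-12)
  after <- whole_head_sar(local_sar(nz$fields$a, m), m)
  expect_equal(after, 3.2, tolerance = 1e-9)
  expect_equal(normalize_to_reference(list(f), 3.2)$scale, 1)
  expect_equal(normalize_to_reference(list(f), 4 * 3.2)$scale, 0.5)
  expect_error(normalize_to_reference(list(f), 0), "positive")
})

test_that("profile extrema counting matches hand-counted patterns", {
  expect_identical(count_extrema(rep(2, 10), 0.1)$n_minima, 0L)
  expect_identical(count_extrema(rep(2, 10), 0.1)$n_maxima, 0L)
  ce <- count_extrema(c(1, 0, 1, 0, 1), 0.1)
  expect_identical(ce$n_minima, 2L)
  expect_identical(ce$n_maxima, 3L)
  # minima above the zero tolerance are not counted as nulls
  ce2 <- count_extrema(c(1, 0.5, 1, 0, 1), 0.1)
  expect_identical(ce2$n_minima, 1L)
  expect_identical(ce2$n_maxima, 3L)
})

test_that("line profiles interpolate |E| and model comparison is exact on itself", {
  m <- uniform_tissue(6, h = 2)
  mag <- array(0, rep(6, 3))
  cc <- grid_centers(m$grid)
  for (k in 1:6) mag[, , k] <- cc$z[k]          # |E| = z
  f <- toy_field(m$grid, mag)
  pr <- line_profile(f, c(5, 5, 1.5), c(5, 5, 10.5), step_mm = 0.5)
  expect_equal(pr$value, pr$z, tolerance = 1e-9)  # linear field, exact interp
  expect_error(line_profile(f, c(5, 5, -50), c(5, 5, 5)), "outside")
  cmp <- compare_models(f, f, probes = rbind(c(5, 5, 5), c(3, 3, 7)))
  expect_equal(cmp$peak_shift_mm, 0)
  expect_equal(cmp$probe_mean, 0)
  expect_equal(cmp$probe_sd, 0)
  # translated localized hot spot: peak shifts by exactly one cell
  bump <- array(0, rep(6, 3))
  for (k in 1:6) bump[, , k] <- exp(-(outer((cc$x - 5)^2, (cc$y - 5)^2, "+") +
                                        (cc$z[k] - 5)^2))
  bump2 <- bump * 0; bump2[, , 2:6] <- bump[, , 1:5]
  cmp2 <- compare_models(toy_field(m$grid, bump), toy_field(m$grid, bump2))
  expect_equal(cmp2$peak_shift_mm, 2, tolerance = 1e-9)
})
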