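# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, .fixture_cache)) assign(name, expr, .fixture_cache)
  get(name, .fixture_cache)
}

# analytic sphere label volume (radius mm, spacing mm)
sphere_volume <- function(radius = 10, spacing = 0.5, pad = 2) {
  n <- ceiling(2 * (radius + pad) / spacing)
  cx <- (seq_len(n) - 0.5) * spacing - (radius + pad)
  arr <- array(0L, c(n, n, n))
  pts2 <- outer(cx^2, cx^2, "+")
  for (k in seq_len(n)) arr[, , k] <- as.integer(pts2 + cx[k]^2 <= radius^2)
  label_volume(arr, spacing, rep(-(radius + pad), 3))
}

# the registration fixture: fine phantom crop, warped atlas, similarity fit
# and the GP-complex non-rigid registration
atlas_fixture <- function() {
  memo("atlas_fixture", {
    spec <- head_phantom_spec()
    crop <- list(lo = c(-7, -9, -7), hi = c(9, 10, 8))
    hp <- make_head_phantom(spec, 0.2, region = crop)
    atl <- make_micro_atlas(hp$volume, warp_amplitude_mm = 2,
                            warp_spacing_mm = 10, seed = 7,
                            landmarks = hp$landmarks)
    sim_fit <- fit_similarity_landmarks(atl$landmarks, hp$landmarks)
    gp_t <- extract_surface(hp$volume, c(12L, 13L, 21L))
    gp_s <- extract_surface(atl$volume, c(12L, 13L, 21L))
    gp_sa <- surface_mesh(apply_similarity(sim_fit, gp_s$vertices), gp_s$faces)
    list(spec = spec, head = hp, atlas = atl, sim_fit = sim_fit,
         gp_target = gp_t, gp_source = gp_sa)
  })
}

gp_registration <- function() {
  memo("gp_registration", icp_nonrigid(atlas_fixture()$gp_source,
                                       atlas_fixture()$gp_target))
}

# the full coarse-vs-multiscale comparison experiment (expensive; shared by
# the resolution-effect and electrode-profile acceptance tests)
comparison_report <- function() {
  memo("comparison_report",
       run_pipeline(default_pipeline_config(seed = 1, profile = "full"),
                    verbose = FALSE))
}

# vacuum material grid on an arbitrary rectilinear grid
vacuum_materials <- function(grid) {
  n <- grid_dims(grid)
  structure(list(grid = grid, eps_r = array(1, n), sigma = array(0, n),
                 rho = array(1, n), pec = array(FALSE, n),
                 tissue = array(FALSE, n), implant = array(0L, n),
                 labels = array(0L, n)),
            class = "material_grid")
}

# quasi-1D plane-wave experiment grid (periodic transverse, PML in z)
plane_wave_grid <- function(cell_mm, nz, nxy = 8) {
  uniform_grid(c(0, 0, 0), c(nxy, nxy, nz) * cell_mm, cell_mm)
}
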