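test_that("overlap metrics and centroid distance match brute-force counting", {
  # independent oracle: direct voxel loops on random toy masks
  set.seed(17)
  for (i in 1:20) {
    d <- c(10, 10, 10)
    pred <- array(stats::runif(prod(d)) < 0.3, d)
    gt <- array(stats::runif(prod(d)) < 0.3, d)
    if (!any(gt)) gt[5, 5, 5] <- TRUE
    if (!any(pred)) pred[2, 2, 2] <- TRUE
    tp <- 0L; fp <- 0L; fn <- 0L
    cp <- c(0, 0, 0); cg <- c(0, 0, 0)
    for (a in 1:10) for (b in 1:10) for (cc in 1:10) {
      if (pred[a, b, cc] && gt[a, b, cc]) tp <- tp + 1L
      if (pred[a, b, cc] && !gt[a, b, cc]) fp <- fp + 1L
      if (!pred[a, b, cc] && gt[a, b, cc]) fn <- fn + 1L
      if (pred[a, b, cc]) cp <- cp + c(a, b, cc)
      if (gt[a, b, cc]) cg <- cg + c(a, b, cc)
    }
    om <- overlap_metrics(pred, gt)
    expect_identical(c(om$TP, om$FP, om$FN), c(tp, fp, fn))
    expect_equal(om$PM, 100 * tp / (tp + fn), tolerance = 1e-12)
    expect_equal(om$Pplus, 100 * tp / (tp + fp), tolerance = 1e-12)
    expect_identical(om$TP + om$FN, sum(gt))
    dc <- sqrt(sum((cp / sum(pred) - cg / sum(gt))^2)) * 0.7
    expect_equal(centroid_distance(pred, gt, 0.7), dc, tolerance = 1e-9)
  }
})

test_that("identical masks score perfectly and disjoint extras halve P+", {
  m <- array(FALSE, c(8, 8, 8)); m[2:4, 2:4, 2:4] <- TRUE
  om <- overlap_metrics(m, m)
  expect_equal(om$PM, 100)
  expect_equal(om$Pplus, 100)
  expect_equal(centroid_distance(m, m, 1), 0)
  extra <- m; extra[5:7, 5:7, 5:7] <- TRUE   # equal-size disjoint blob
  om2 <- overlap_metrics(extra, m)
  expect_equal(om2$PM, 100)
  expect_equal(om2$Pplus, 50)
})

test_that("PM and P+ swap when prediction and ground truth swap roles", {
  set.seed(4)
  pred <- array(stats::runif(512) < 0.4, c(8, 8, 8))
  gt <- array(stats::runif(512) < 0.4, c(8, 8, 8))
  a <- overlap_metrics(pred, gt); b <- overlap_metrics(gt, pred)
  expect_equal(a$PM, b$Pplus)
  expect_equal(a$Pplus, b$PM)
  expect_identical(a$FP, b$FN)
})

test_that("degenerate masks raise errors or flagged values", {
  gt <- array(FALSE, c(4, 4, 4)); gt[2, 2, 2] <- TRUE
  empty <- array(FALSE, c(4, 4, 4))
  expect_error(overlap_metrics(gt, empty), "empty")
  om <- overlap_metrics(empty, gt)
  expect_equal(om$PM, 0)
  expect_true(is.na(om$Pplus))
  expect_error(centroid_distance(empty, gt, 1), "empty")
})

test_that("centroid distance reads voxel shifts in mm", {
  m <- array(FALSE, c(12, 12, 12)); m[3:5, 3:5, 3:5] <- TRUE
  sh <- array(FALSE, c(12, 12, 12)); sh[5:7, 3:5, 3:5] <- TRUE
  expect_equal(centroid_distance(sh, m, 1), 2)
  expect_equal(centroid_distance(sh, m, c(0.5, 1, 1)), 1)
})

test_that("structure volume is count times voxel volume", {
  m <- array(FALSE, c(12, 12, 12)); m[1:10, 1:10, 1:10] <- TRUE
  expect_equal(structure_volume(m, 1), 1000)
  expect_equal(structure_volume(m, 0.5), 125)
  gpi <- head_phantom_spec()$primitives[[1]]
  region <- list(lo = gpi$center - gpi$semiaxes - 1,
                 hi = gpi$center + gpi$semiaxes + 1)
  v <- make_head_phantom(head_phantom_spec(), 0.2, region = region)$volume
  expect_lt(abs(structure_volume(v$data == 13L, 0.2) /
                  (4 / 3 * pi * prod(gpi$semiaxes)) - 1), 0.02)
})

test_that("label propagation through identity and translation is exact", {
  fx <- atlas_fixture()
  reg <- gp_registration()
  # identity: propagate the head volume onto itself through a null transform
  sub <- fx$head$volume
  region <- list(lo = c(-3, -5, -3), hi = c(3, 1, 3))
  target <- mshead:::crop_volume(sub, region)
  id_reg <- icp_nonrigid(fx$gp_target, fx$gp_target,
                         schedule_mm = c(20, 10), max_iter = 3)
  out <- propagate_labels(sub, similarity_transform(),
                          list(list(reg = id_reg, labels = c(12L, 13L, 21L))),
                          target)
  gt <- mshead:::crop_volume(sub, region)
  sel <- gt$data %in% c(12L, 13L, 21L)
  expect_gt(mean(out$data[sel] == gt$data[sel]), 0.999)
  # pure translation by one voxel: labels shift exactly one voxel
  tr <- similarity_transform(diag(3), 1, c(0.2, 0, 0))
  shifted <- propagate_labels(sub, tr,
                              list(list(reg = id_reg,
                                        labels = c(12L, 13L, 21L))), target)
  d <- dim(target$data)
  inner <- 2:(d[1])
  exp_lab <- gt$data[inner - 1L, , ]
  sel <- exp_lab %in% c(12L, 13L, 21L)
  expect_gt(mean(shifted$data[inner, , ][sel] == exp_lab[sel]), 0.999)
})

test_that("propagated atlas labels recover the ground-truth putamen", {
  fx <- atlas_fixture()
  put_t <- extract_surface(fx$head$volume, c(11L, 20L, 12L, 21L, 13L))
  put_s <- extract_surface(fx$atlas$volume, c(11L, 20L, 12L, 21L, 13L))
  put_sa <- surface_mesh(apply_similarity(fx$sim_fit, put_s$vertices),
                         put_s$faces)
  regp <- icp_nonrigid(put_sa, put_t)
  region <- list(lo = c(-6.5, -8.5, -6.5), hi = c(6.5, 4.5, 6.5))
  target <- mshead:::crop_volume(fx$head$volume, region)
  prop <- propagate_labels(fx$atlas$volume, fx$sim_fit,
                           list(list(reg = regp, labels = c(11L, 20L)),
                                list(reg = gp_registration(),
                                     labels = c(12L, 13L, 21L))),
                           target)
  gt <- mshead:::crop_volume(fx$head$volume, region)
  om <- overlap_metrics(prop$data == 11L, gt$data == 11L)
  expect_gte(om$PM, 85)
})
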