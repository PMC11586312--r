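test_that("IDIF extraction averages the VOI and recovers planted curves", {
  vol <- array(3, c(6, 6, 6, 4))
  mask <- array(FALSE, c(6, 6, 6)); mask[3:4, 3:4, 3:4] <- TRUE
  idif <- extract_idif(vol, mask)
  expect_equal(idif$activity, rep(3, 4))
  expect_error(extract_idif(vol, array(FALSE, c(6, 6, 6))), "empty")
  expect_error(extract_idif(vol, array(TRUE, c(5, 5, 5))), "dims")

  # planted blood curve in a 5-mm sphere recovered within 2%
  sched <- frame_schedule("human")
  curve <- input_curve()(sched$mid)
  dims <- c(16, 16, 16)
  vol2 <- array(0, c(dims, nrow(sched)))
  sph <- sphere_mask(dims, center = c(8, 8, 8), diameter_mm = 5,
                     voxel_size = 1)
  expect_gt(sum(sph), 0)
  for (f in seq_len(nrow(sched))) {
    frame <- array(0, dims); frame[sph] <- curve[f]
    vol2[, , , f] <- frame
  }
  rec <- extract_idif(vol2, sph, sched)
  expect_lt(max(abs(rec$activity - curve) / pmax(curve, 1e-9)), 0.02)
})

test_that("Logan transform identity: tissue = c * input gives slope c", {
  sched <- frame_schedule("mouse")
  cp <- input_curve()(sched$mid)
  fit <- logan_vt(5 * cp, cp, sched$mid)
  expect_equal(fit$vt, 5, tolerance = 1e-6)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
  expect_true(fit$tstar %in% sched$mid)
  expect_gte(fit$n_points, 3L)
  expect_lte(fit$max_rel_error_achieved, 0.10)

  # rescaling both curves by the same constant leaves VT unchanged
  fit2 <- logan_vt(5 * cp * 37, cp * 37, sched$mid)
  expect_equal(fit2$vt, fit$vt, tolerance = 1e-9)
  expect_error(logan_vt(cp, rep(0, length(cp)), sched$mid), "zero")
})

test_that("Logan VT recovers K1/k2 on noiseless 1TCM data", {
  pet <- gen_dynamic_pet(list(r = list(K1 = 0.5, k2 = 0.1)),
                         frame_schedule("mouse"))
  fit <- logan_vt(pet$tacs$activity, pet$input$activity, pet$tacs$mid,
                  max_rel_error = 0.10)
  expect_lt(abs(fit$vt - 5) / 5, 0.02)
  # the t* criterion rejects when the bound is impossibly tight
  expect_error(logan_vt(pet$tacs$activity, pet$input$activity, pet$tacs$mid,
                        max_rel_error = 1e-9), "best achieved")
})

test_that("trapezoid integrals are monotone for non-negative curves", {
  sched <- frame_schedule("human")
  for (s in 1:5) {
    set.seed(s)
    y <- runif(nrow(sched), 0, 10)
    expect_true(all(diff(taumetry:::cumtrapz0(sched$mid, y)) >= 0))
  }
})

test_that("vt_image maps regions and handles failures per voxel", {
  sched <- frame_schedule("mouse")
  lv <- array(0L, c(4, 4, 2))
  lv[1:2, , ] <- 1L; lv[3:4, 1:2, ] <- 2L
  pet <- gen_dynamic_pet(list(a = list(K1 = 0.4, k2 = 0.2),
                              b = list(K1 = 0.5, k2 = 0.1)),
                         sched, label_volume = lv)
  vt <- vt_image(pet$volume, pet$input$activity, sched$mid)
  expect_lt(abs(mean(vt[lv == 1L], na.rm = TRUE) - 2) / 2, 0.02)
  expect_lt(abs(mean(vt[lv == 2L], na.rm = TRUE) - 5) / 5, 0.02)
  expect_true(all(is.na(vt[lv == 0L])))   # empty voxels -> missing
  # all-zero volume -> all-missing map
  zero_vt <- vt_image(array(0, c(2, 2, 2, nrow(sched))), pet$input$activity,
                      sched$mid)
  expect_true(all(is.na(zero_vt)))
  # fixed t* (tissue-region convention) gives the same answer on clean data
  fit_ref <- logan_vt(pet$tacs$activity[pet$tacs$region == "b"],
                      pet$input$activity, sched$mid)
  vt_fixed <- vt_image(pet$volume, pet$input$activity, sched$mid,
                       tstar = fit_ref$tstar)
  expect_lt(abs(mean(vt_fixed[lv == 2L], na.rm = TRUE) - 5) / 5, 0.02)
  # slopes below the configured threshold are clamped to it
  cp <- input_curve()(sched$mid)
  clamped <- logan_vt(5 * cp, cp, sched$mid, vt_threshold = 10)
  expect_equal(clamped$vt, 10)
  expect_true(clamped$clamped)
})

test_that("reference normalization and static windows follow the defaults", {
  expect_equal(normalize_to_reference(3, 3), 1)
  expect_equal(normalize_to_reference(c(a = 6, b = 9), 3), c(a = 2, b = 3))
  expect_error(normalize_to_reference(1, 0), "positive")

  sched <- frame_schedule("mouse")
  # frames fully inside 20-40 min: constant TAC -> that constant
  expect_equal(static_window_mean(rep(7, nrow(sched)), sched), 7)
  sel <- which(sched$start >= 20 & sched$end <= 40)
  expect_true(length(sel) > 0)
  expect_true(all(sched$mid[sel] >= 20 & sched$mid[sel] <= 40))
  # volume mode: 3x reference phantom gives SUVR 3
  nvol <- array(rep(c(3, 1), each = 4), c(2, 2, 2, nrow(sched)))
  stat <- static_window_mean(nvol, sched)
  expect_equal(normalize_to_reference(mean(stat[, , 1]), mean(stat[, , 2])), 3)
})

test_that("cohens_d follows the pooled-SD definition", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # means 1 and 0 with pooled SD 1
  set.seed(2)
  a <- c(0, 2); b <- c(-1, 1)   # var 2 each, pooled SD sqrt(2), diff 1
  expect_equal(cohens_d(a, b), 1 / sqrt(2))
  expect_equal(cohens_d(c(2, 4), c(1, 3)), 1 / sqrt(2), tolerance = 1e-12)
  expect_error(cohens_d(1, c(1, 2)), "n >= 2")
  expect_warning(d <- cohens_d(c(1, 1), c(2, 2)), "pooled")
  expect_true(is.na(d))
})

test_that("voxelwise regression detects planted clusters and only those", {
  set.seed(42)
  dims <- c(10, 10, 10); nsub <- 12
  covariate <- rnorm(nsub)
  planted <- which(array(slice.index(array(0, dims), 1) <= 5 &
                         slice.index(array(0, dims), 2) <= 3 &
                         slice.index(array(0, dims), 3) <= 2, dims))[1:30]
  vols <- lapply(seq_len(nsub), function(i) {
    v <- array(rnorm(prod(dims), 0, 0.1), dims)
    v[planted] <- v[planted] + covariate[i]
    v
  })
  res <- voxelwise_regression(vols, covariate, p_thresh = 0.005, k_min = 20)
  expect_equal(nrow(res$clusters), 1L)
  expect_setequal(which(res$cluster_map > 0), planted)
  expect_gt(res$clusters$size, 20)
  # deterministic labeling across runs
  res2 <- voxelwise_regression(vols, covariate)
  expect_identical(res$cluster_map, res2$cluster_map)
  expect_error(voxelwise_regression(vols[1:3], covariate[1:3]), "4 subjects")
  expect_error(voxelwise_regression(vols, covariate[-1]), "length")
})
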