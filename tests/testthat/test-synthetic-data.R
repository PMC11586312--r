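test_that("gen_ihc_section handles empty, exact-count and invalid inputs", {
  blank <- gen_ihc_section(dims = c(256, 256), seed = 1)
  expect_equal(nrow(blank$truth$objects), 0L)
  expect_true(all(blank$image$pixels <= 0.05 + 1e-12))
  expect_equal(blank$truth$positive_fraction, 0)

  planted <- gen_ihc_section(dims = c(768, 768),
                             n_objects = c(NFT = 15, CB = 15, TA = 15),
                             seed = 2)
  expect_equal(nrow(planted$truth$objects), 45L)
  expect_equal(as.vector(table(planted$truth$objects$class)[c("NFT", "CB", "TA")]),
               c(15L, 15L, 15L))
  # objects inside bounds, labels restricted to the four classes
  expect_true(all(planted$truth$objects$class %in% c("NFT", "CB", "TA", "TF")))
  for (px in planted$truth$pixels) {
    expect_true(all(px[, 1L] >= 1 & px[, 1L] <= 768))
    expect_true(all(px[, 2L] >= 1 & px[, 2L] <= 768))
  }

  expect_error(gen_ihc_section(dims = c(128, 256)), "256")
  expect_error(gen_ihc_section(pixel_size = 0), "pixel_size")
  expect_error(gen_ihc_section(densities = c(NFT = -1)), "densities")
})

test_that("generators are bit-identical under a repeated seed", {
  a <- gen_ihc_section(dims = c(256, 256), n_objects = c(NFT = 5, TA = 5),
                       noise_sd = 0.01, seed = 11)
  b <- gen_ihc_section(dims = c(256, 256), n_objects = c(NFT = 5, TA = 5),
                       noise_sd = 0.01, seed = 11)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$objects, b$truth$objects)

  ca <- gen_scrad_cohort(seed = 4, noise_sd = 0.1)
  cb <- gen_scrad_cohort(seed = 4, noise_sd = 0.1)
  expect_identical(ca$pellets, cb$pellets)

  sa <- gen_cortical_slab(seed = 4, noise_sd = 0.1)
  sb <- gen_cortical_slab(seed = 4, noise_sd = 0.1)
  expect_identical(sa$volume, sb$volume)

  expect_identical(fan_seed(7, 4), fan_seed(7, 4))
  expect_length(unique(fan_seed(7, 100)), 100L)
  expect_true(all(fan_seed(123456, 1000) >= 0))
})

test_that("Poisson densities give the expected object count on average", {
  # lambda * area = 100 expected objects; mean over 50 seeds within 3 SE
  lambda <- 100 / (512 * 512)
  counts <- vapply(1:50, function(s)
    nrow(gen_ihc_section(dims = c(512, 512),
                         densities = c(TF = lambda), seed = s)$truth$objects),
    numeric(1L))
  se <- sqrt(100 / 50)  # Poisson mean = variance = 100
  expect_lt(abs(mean(counts) - 100), 3 * se)
})

test_that("planted areas are conserved and recoverable from the raster", {
  sec <- gen_ihc_section(dims = c(256, 256),
                         n_objects = c(NFT = 8, CB = 6, TA = 6, TF = 5),
                         noise_sd = 0, seed = 21)
  expect_lte(sum(sec$truth$objects$area_um2), 256 * 256)
  # noise 0: thresholding the raster recovers exactly the planted mask
  recovered <- sec$image$pixels > 0.05 + 1e-9
  expect_identical(recovered, sec$truth$positive_mask)
  expect_equal(mean(recovered), sec$truth$positive_fraction)
})

test_that("gen_autorad_section mixes class densities linearly", {
  sec <- gen_ihc_section(dims = c(256, 256),
                         n_objects = c(NFT = 10, TA = 10), seed = 31)
  flat <- gen_autorad_section(sec$truth, coupling = c("NFT/CB" = 0, "TA/TF" = 0),
                              background = 50, noise_sd = 0, seed = 1)
  expect_true(all(flat$pixels == 50))

  arg <- gen_autorad_section(sec$truth, coupling = c("NFT/CB" = 2, "TA/TF" = 0),
                             background = 10, noise_sd = 0, seed = 1)
  # subfield ARG mean minus background proportional to NFT/CB density
  roi <- roi_rect(1, 1, 128, 128, id = "q")
  m <- taumetry:::roi_mask(roi, c(256, 256))
  dens <- sum(sec$truth$channel_masks[["NFT/CB"]] & m) / sum(m)
  expect_equal(mean(arg$pixels[m]) - 10, 2 * dens, tolerance = 1e-12)

  expect_error(gen_autorad_section(sec$truth, coupling = c("NFT/CB" = -1)),
               "gains")
  expect_error(gen_autorad_section(list()), "gen_ihc_section")
})

test_that("frame schedules match the acquisition protocols", {
  mouse <- frame_schedule("mouse")
  expect_equal(nrow(mouse), 26L)
  expect_equal(mouse$duration_s,
               c(rep(10, 6), rep(30, 2), rep(60, 3), rep(120, 5),
                 rep(300, 5), rep(600, 5)))
  expect_gte(max(mouse$end), 60)
  human <- frame_schedule("human")
  expect_equal(nrow(human), 35L)
  expect_equal(max(human$end), 60)
  expect_true(all(diff(mouse$start) > 0))
  expect_equal(mouse$mid, (mouse$start + mouse$end) / 2)
  expect_error(frame_schedule(numeric(0)), "empty")
})

test_that("gen_dynamic_pet reproduces one-tissue-compartment kinetics", {
  sched <- frame_schedule("mouse")
  zero <- gen_dynamic_pet(list(r = list(K1 = 0, k2 = 0.1)), sched)
  expect_true(all(zero$tacs$activity == 0))

  # numeric convolution vs closed form for a mono-exponential input
  A <- 40; mu <- 0.25; K1 <- 0.5; k2 <- 0.1
  pet <- gen_dynamic_pet(list(r = list(K1 = K1, k2 = k2)), sched,
                         input_fun = function(t) A * exp(-mu * t))
  cf <- analytic_1tcm_monoexp(pet$tacs$mid, K1, k2, A, mu)
  expect_lt(max(abs(pet$tacs$activity - cf) / cf), 0.005)
  expect_equal(unname(pet$truth_vt), K1 / k2)

  # labelled 4-D volume carries the regional curves
  lv <- array(0L, c(4, 4, 2)); lv[1:2, , ] <- 1L
  petv <- gen_dynamic_pet(list(r = list(K1 = 0.3, k2 = 0.15)), sched,
                          label_volume = lv)
  expect_equal(dim(petv$volume), c(4, 4, 2, 26))
  expect_equal(petv$volume[1, 1, 1, ], petv$tacs$activity)
  expect_true(all(petv$volume[4, , , ] == 0))
  expect_error(gen_dynamic_pet(schedule = frame_schedule("mouse")[0, ]),
               "empty")
})

test_that("scrad cohorts satisfy the extrapolation identity and magnitudes", {
  co <- gen_scrad_cohort(n_tg = 5, n_wt = 5, noise_sd = 0, seed = 5)
  # noise 0: identity residual exactly zero per mouse
  expect_equal(co$truth$pet_increment_bq, co$truth$predicted_brain_bq)
  expect_true(all(co$truth$bq_per_neuron >= 0))
  expect_true(all(co$pellets$measured_bq >= 0))
  expect_equal(nrow(co$pellets), 20L)
  # TG per-animal cellular activity within the configured kBq range
  tg_kbq <- co$truth$cellular_kbq[co$truth$genotype == "TG"]
  expect_true(all(tg_kbq > 7.7 & tg_kbq < 36.5))

  # fold-change recovered at n = 50/50 within 3 SE of the cohort-mean ratio
  big <- gen_scrad_cohort(n_tg = 50, n_wt = 50, seed = 6)
  tg <- big$truth$genotype == "TG"
  ratio <- mean(big$truth$bq_per_neuron[tg]) /
    mean(big$truth$bq_per_neuron[!tg])
  se <- 1.89 * 0.3 * sqrt(2 / 50)
  expect_lt(abs(ratio - 1.89), 3 * se)
  expect_error(gen_scrad_cohort(n_tg = 0), "mouse")
  expect_error(gen_scrad_cohort(fold_change = 0), "fold")
})

test_that("cortical slabs encode the depth profile and parcellation", {
  slab <- gen_cortical_slab(seed = 7)
  expect_equal(sort(unique(as.integer(slab$labels))), 1:3)
  expect_equal(sort(unique(as.integer(slab$parcels))), 1:200)
  expect_true(all(slab$z_wm > slab$z_csf))

  # flat profile: identical expected value at all depths
  flat <- gen_cortical_slab(profile = function(d) rep(3, length(d)), seed = 7)
  expect_true(all(flat$volume == 3))

  # Gaussian bump at depth 0: volume maximum within 1 voxel of the boundary
  bump <- gen_cortical_slab(seed = 8)
  for (x in c(1, 20, 40)) for (y in c(1, 20, 40)) {
    k <- which.max(bump$volume[x, y, ])
    zc <- (k - 0.5) * bump$voxel_size
    expect_lte(abs(zc - bump$z_wm[x, y]), bump$voxel_size)
  }
  expect_error(gen_cortical_slab(thickness_mm = 0), "degenerate")
  expect_error(gen_cortical_slab(n_parcels = 0), "parcel")
})
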