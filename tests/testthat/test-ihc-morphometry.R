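test_that("segmentation matches an independent flood-fill oracle", {
  blank <- stain_image(matrix(0, 64, 64), 1)
  expect_identical(segment_objects(blank, intensity_threshold = 0.5), list())

  # three disjoint supra-threshold disks
  img <- matrix(0, 100, 100)
  for (ctr in list(c(20, 20), c(20, 70), c(70, 45))) {
    d <- outer(1:100, 1:100, function(i, j)
      (i - ctr[1])^2 + (j - ctr[2])^2 <= 8^2)
    img[d] <- 1
  }
  si <- stain_image(img, 1)
  objs <- segment_objects(si, intensity_threshold = 0.5)
  oracle <- flood_fill_label(img >= 0.5)
  expect_length(objs, max(oracle))
  expect_length(objs, 3L)
  # same pixel partition as the oracle
  for (o in objs) {
    labs <- oracle[o$pixels]
    expect_length(unique(labs), 1L)
    expect_equal(nrow(o$pixels), sum(oracle == labs[1L]))
  }
  # min_area drops small components
  expect_length(segment_objects(si, intensity_threshold = 0.5,
                                min_area = 1e4), 0L)
  expect_error(segment_objects(si, intensity_threshold = NaN), "finite")
})

test_that("planted exemplars are all recovered as candidates", {
  sec <- gen_ihc_section(dims = c(768, 768),
                         n_objects = c(NFT = 15, CB = 15, TA = 15), seed = 42)
  objs <- segment_objects(sec$image, intensity_threshold = 0.2)
  expect_gte(length(objs), 45L)
})

test_that("descriptors match hand-computed oracles", {
  # 10x10 solid square at 1 µm/px
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  f <- compute_features(sq, stain_image(sq * 2, 1))
  expect_equal(f[["area"]], 100)
  p_oracle <- crofton_by_hand(sq)
  expect_equal(f[["perimeter"]], p_oracle, tolerance = 1e-12)
  expect_equal(f[["circularity"]], 4 * pi * 100 / p_oracle^2, tolerance = 1e-12)
  expect_equal(f[["mean_intensity"]], 2)

  # rasterized disk r = 20: near-circle identity for the dimensionless trio
  d <- disk_mask(64, 20)
  fd <- compute_features(d, stain_image(d * 1, 1))
  expect_gt(fd[["circularity"]], 0.90); expect_lt(fd[["circularity"]], 1.02)
  expect_gt(fd[["roundness"]], 0.95); expect_lt(fd[["roundness"]], 1.05)
  expect_gt(fd[["compactness"]], 0.95); expect_lt(fd[["compactness"]], 1.05)

  # single pixel: equivalent diameter = sqrt(4/pi) * pixel_size
  sp <- matrix(FALSE, 5, 5); sp[3, 3] <- TRUE
  fp <- compute_features(sp, stain_image(sp * 1, 1), pixel_size = 2)
  expect_equal(fp[["equiv_diameter"]], sqrt(4 / pi) * 2, tolerance = 1e-9)
  expect_equal(fp[["area"]], 4)
  expect_error(compute_features(matrix(FALSE, 5, 5), stain_image(sp * 1, 1)),
               "empty")
})

test_that("features are invariant to translation, rotation and pixel scale", {
  base <- matrix(FALSE, 60, 60)
  base[10:25, 12:20] <- TRUE
  base[14:18, 21:30] <- TRUE  # L-shaped, asymmetric
  img <- function(m) stain_image(m * 1, 1)
  f0 <- compute_features(base, img(base))
  # translation: exact
  shifted <- matrix(FALSE, 60, 60)
  shifted[(10:25) + 20, (12:20) + 15] <- TRUE
  shifted[(14:18) + 20, (21:30) + 15] <- TRUE
  f1 <- compute_features(shifted, img(shifted))
  expect_equal(f1, f0, tolerance = 1e-12)
  # 90-degree rotation: within 2% discretization tolerance
  rot <- t(base)[ncol(base):1, ]
  f2 <- compute_features(rot, img(rot))
  for (nm in names(f0)) expect_equal(f2[[nm]], f0[[nm]], tolerance = 0.02)
  # pixel-size scaling: areas by s^2, lengths by s, dimensionless unchanged
  s <- 2.5
  fs <- compute_features(base, stain_image(base * 1, s))
  expect_equal(fs[["area"]], f0[["area"]] * s^2)
  for (nm in c("equiv_diameter", "major_axis", "minor_axis", "perimeter"))
    expect_equal(fs[[nm]], f0[[nm]] * s)
  for (nm in c("circularity", "roundness", "compactness", "mean_intensity"))
    expect_equal(fs[[nm]], f0[[nm]])
})

test_that("rule calibration pools classes into two channels", {
  mk <- function(cls, area, inten) {
    f <- c(area = area, equiv_diameter = sqrt(4 * area / pi),
           major_axis = 10, minor_axis = 8, perimeter = 30,
           mean_intensity = inten, circularity = 0.9, roundness = 0.9,
           compactness = 0.9)
    taumetry:::new_tau_object(cbind(1, 1), f, class = cls)
  }
  ex <- list(mk("NFT", 50, 0.8), mk("NFT", 200, 0.9), mk("CB", 120, 0.85),
             mk("TA", 400, 0.3), mk("TF", 4, 0.5))
  rules <- calibrate_rules(ex, expansion = 0.1)
  expect_named(rules$channels, c("NFT/CB", "TA/TF"))
  # area [50, 200] widened by 0.1 * 150 -> [35, 215]
  expect_equal(unname(rules$channels[["NFT/CB"]]$intervals[, "area"]),
               c(35, 215))
  # single-exemplar channel at expansion 0: degenerate interval
  r0 <- calibrate_rules(list(mk("NFT", 50, 0.8), mk("TA", 400, 0.3)),
                        expansion = 0)
  expect_equal(unname(r0$channels[["TA/TF"]]$intervals[, "area"]), c(400, 400))
  expect_error(calibrate_rules(list(mk("NFT", 50, 0.8))), "TA/TF")
  expect_error(calibrate_rules(ex, expansion = -1), "expansion")

  # JSON round trip preserves the rules
  path <- tempfile(fileext = ".json")
  write_rules_json(rules, path)
  back <- read_rules_json(path)
  expect_equal(back$channels[["NFT/CB"]]$intervals,
               rules$channels[["NFT/CB"]]$intervals)
  expect_equal(back$expansion, rules$expansion)
})

test_that("classification assigns channels with the intensity tie-break", {
  expect_identical(classify_objects(list(),
                                    calibrate_rules(list(
    taumetry:::new_tau_object(cbind(1, 1), stats::setNames(rep(1, 9),
      taumetry:::FEATURE_NAMES), class = "NFT"),
    taumetry:::new_tau_object(cbind(1, 1), stats::setNames(rep(1, 9),
      taumetry:::FEATURE_NAMES), class = "TA")))), list())

  scene <- make_classified_scene(seed = 101,
                                 n_test = c(NFT = 30, CB = 20, TA = 40, TF = 10))
  pred <- vapply(scene$objects, `[[`, "", "channel")
  expect_gte(mean(pred == scene$truth_channel), 0.95)
  # a CB-like object (compact, bright) routes to the dense NFT/CB channel
  cb_idx <- which(scene$truth_channel == "NFT/CB")
  expect_gte(mean(pred[cb_idx] == "NFT/CB"), 0.9)
})

test_that("subfield quantification counts pixels inside the polygon", {
  img <- stain_image(matrix(0.1, 50, 50), 1)
  m <- matrix(FALSE, 50, 50)
  roi <- roi_rect(10, 10, 35, 50, id = "sf1", label = "cortical")
  inroi <- which(taumetry:::roi_mask(roi, c(50, 50)))
  expect_length(inroi, 25 * 40)
  m[inroi[1:125]] <- TRUE
  rec <- quantify_subfield(img, list("NFT/CB" = m, "TA/TF" = matrix(FALSE, 50, 50)), roi)
  expect_equal(rec$NFT_CB_area_pct, 100 * 125 / 1000)
  expect_equal(rec$TA_TF_area_pct, 0)
  expect_true(is.na(rec$TA_TF_intensity))   # zero positive -> missing
  expect_equal(rec$total_area_pct, 12.5)
  expect_identical(rec$label, "cortical")
  out <- roi_rect(100, 100, 120, 120)
  expect_error(quantify_subfield(img, list(a = m), out), "outside")

  # 8-12 ROIs give 8-12 records
  recs <- lapply(1:10, function(i)
    quantify_subfield(img, list(a = m),
                      roi_rect(1, 5 * i - 4, 49, 5 * i, id = i)))
  expect_length(recs, 10L)

  # channel area-% never exceeds total area-%
  sec <- gen_ihc_section(dims = c(256, 256),
                         n_objects = c(NFT = 10, TA = 10), seed = 3)
  r <- quantify_subfield(sec$image,
                         c(sec$truth$channel_masks,
                           list(total = sec$truth$positive_mask)),
                         roi_rect(1, 1, 255, 255))
  expect_lte(r$NFT_CB_area_pct + r$TA_TF_area_pct, r$total_area_pct + 1e-12)
})

test_that("colocalization reports AT8 share of the structure mask", {
  at8 <- matrix(0, 40, 40); gfap <- matrix(0, 40, 40)
  gfap[1:20, 1:20] <- 1            # 400 px structure
  at8[1:10, 1:10] <- 1             # 100 px signal inside it
  coloc <- colocalization_area(stain_image(at8, 1),
                               stain_image(gfap, 1, stain = "GFAP"),
                               signal_threshold = 0.5, mask_threshold = 0.5)
  expect_equal(coloc, 25)
  # disjoint masks -> 0
  at8b <- matrix(0, 40, 40); at8b[30:35, 30:35] <- 1
  expect_equal(colocalization_area(stain_image(at8b, 1),
                                   stain_image(gfap, 1, stain = "GFAP"),
                                   0.5, 0.5), 0)
  # frame mode: % of the whole scanning frame
  fr <- matrix(0, 100, 100); fr[1:70, 1:10] <- 1  # 700/10000 = 7%
  expect_equal(colocalization_area(stain_image(fr, 1), mode = "frame",
                                   signal_threshold = 0.5), 7)
  expect_error(colocalization_area(stain_image(at8, 1),
                                   stain_image(matrix(0, 10, 10), 1,
                                               stain = "GFAP"),
                                   0.5, 0.5), "geometry")
})

test_that("Otsu threshold separates a bimodal histogram", {
  set.seed(1)
  v <- c(rnorm(500, 0.1, 0.02), rnorm(500, 0.8, 0.05))
  th <- otsu_threshold(v)
  expect_gt(th, 0.2); expect_lt(th, 0.7)
  expect_equal(otsu_threshold(rep(3, 10)), 3)
})
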