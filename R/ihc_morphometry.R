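#' @title AT8 object morphometry
#' @description Segmentation of AT8-positive objects, shape/intensity
#'   descriptors, exemplar-calibrated interval rules, and the two-channel
#'   (NFT/CB vs TA/TF) classification used to split tau load by cell type.
#' @name ihc_morphometry
NULL

FEATURE_NAMES <- c("area", "equiv_diameter", "major_axis", "minor_axis",
                   "perimeter", "mean_intensity", "circularity",
                   "roundness", "compactness")

# Crofton perimeter estimate (4 directions) of a binary mask, in pixels.
# P = (pi/8) * (c_h + c_v + (c_d1 + c_d2)/sqrt(2)) where c_* count
# foreground/background transitions along rows, columns and the two
# diagonals, including transitions across the image border.
crofton_perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(0L, nr + 2L, nc + 2L)
  m[2:(nr + 1L), 2:(nc + 1L)] <- as.integer(mask)
  dnr <- nrow(m); dnc <- ncol(m)
  c_h <- sum(abs(m[, -1L] - m[, -dnc]))
  c_v <- sum(abs(m[-1L, ] - m[-dnr, ]))
  c_d1 <- sum(abs(m[-1L, -1L] - m[-dnr, -dnc]))
  c_d2 <- sum(abs(m[-1L, -dnc] - m[-dnr, -1L]))
  (pi / 8) * (c_h + c_v + (c_d1 + c_d2) / sqrt(2))
}

#' Morphometric feature vector of a segmented object
#'
#' Computes the descriptor set used for object thresholding: area,
#' equivalent diameter, ellipse major/minor axis, perimeter, mean intensity,
#' circularity, roundness and compactness.
#'
#' Conventions (the common image-morphometry definitions):
#' * area `A` = pixel count × pixel_size²;
#' * equivalent diameter = `sqrt(4A/pi)`;
#' * ellipse axes from second central moments of the pixel-center cloud with
#'   the 1/12 px² single-pixel variance term added (axis length
#'   `4*sqrt(eigenvalue)`), so a single pixel has a finite axis;
#' * perimeter `P` by the 4-direction Crofton intercept estimator;
#' * circularity = `4*pi*A/P^2`; roundness = `4A/(pi*major^2)`;
#'   compactness = `sqrt(4A/pi)/major` (equivalent diameter over major axis).
#'
#' @param mask logical matrix (same shape as the image) or a 2-column matrix
#'   of (row, col) pixel indices belonging to the object.
#' @param image a [stain_image()] or numeric matrix supplying intensities.
#' @param pixel_size µm per pixel; taken from `image` when it is a
#'   `stain_image`.
#' @return named numeric vector with elements
#'   `r paste0('\x60', c("area", "equiv_diameter", "major_axis", "minor_axis",
#'   "perimeter", "mean_intensity", "circularity", "roundness",
#'   "compactness"), '\x60', collapse = ", ")`. Lengths in µm, areas in µm²,
#'   intensity in a.u., the last three dimensionless.
#' @export
compute_features <- function(mask, image, pixel_size = NULL) {
  if (inherits(image, "stain_image")) {
    if (is.null(pixel_size)) pixel_size <- image$pixel_size
    img <- image$pixels
  } else img <- image
  if (is.null(pixel_size)) pixel_size <- 1
  if (is.logical(mask)) {
    if (!any(mask)) stop("empty object mask", call. = FALSE)
    idx <- which(mask, arr.ind = TRUE)
  } else {
    idx <- mask
    if (is.null(dim(idx)) || nrow(idx) == 0L)
      stop("empty object mask", call. = FALSE)
  }
  if (max(idx[, 1L]) > nrow(img) || max(idx[, 2L]) > ncol(img) || min(idx) < 1L)
    stop("object mask outside image bounds", call. = FALSE)
  n <- nrow(idx)
  ps <- pixel_size
  area <- n * ps^2
  equiv_d <- sqrt(4 * area / pi)
  # second central moments (pixel units) + 1/12 px^2 pixel-extent term
  r <- idx[, 1L]; cc <- idx[, 2L]
  mu_rr <- sum((r - mean(r))^2) / n + 1 / 12
  mu_cc <- sum((cc - mean(cc))^2) / n + 1 / 12
  mu_rc <- sum((r - mean(r)) * (cc - mean(cc))) / n
  tr2 <- (mu_rr + mu_cc) / 2
  det_sqrt <- sqrt(max(((mu_rr - mu_cc) / 2)^2 + mu_rc^2, 0))
  l1 <- tr2 + det_sqrt; l2 <- max(tr2 - det_sqrt, 0)
  major <- 4 * sqrt(l1) * ps
  minor <- 4 * sqrt(l2) * ps
  bb <- matrix(FALSE, max(r) - min(r) + 1L, max(cc) - min(cc) + 1L)
  bb[cbind(r - min(r) + 1L, cc - min(cc) + 1L)] <- TRUE
  perim <- crofton_perimeter(bb) * ps
  mean_int <- mean(img[idx])
  c(area = area,
    equiv_diameter = equiv_d,
    major_axis = major,
    minor_axis = minor,
    perimeter = perim,
    mean_intensity = mean_int,
    circularity = 4 * pi * area / perim^2,
    roundness = 4 * area / (pi * major^2),
    compactness = equiv_d / major)
}

new_tau_object <- function(pixels, features, channel = "unassigned",
                           class = NA_character_) {
  structure(list(pixels = pixels, features = features,
                 channel = channel, class = class),
            class = "tau_object")
}

#' @export
print.tau_object <- function(x, ...) {
  cat(sprintf("<tau_object> %d px, area %.1f µm², channel %s\n",
              nrow(x$pixels), x$features[["area"]], x$channel))
  invisible(x)
}

#' Segment AT8-positive objects
#'
#' Thresholds the image (fixed threshold, or Otsu when `intensity_threshold`
#' is `NULL`) and labels connected components with 8-connectivity.
#' Components smaller than `min_area` are dropped.
#'
#' @param image a [stain_image()].
#' @param intensity_threshold foreground threshold (a.u.); pixels `>=` the
#'   threshold are positive. `NULL` selects the Otsu threshold of the image
#'   histogram.
#' @param min_area minimum object area in µm² (inclusive lower bound).
#' @return list of `tau_object`s (channel `"unassigned"`), ordered by first
#'   pixel in column-major scan order; an empty image yields an empty list.
#' @seealso [compute_features()], [classify_objects()]
#' @export
segment_objects <- function(image, intensity_threshold = NULL, min_area = 0) {
  stopifnot(inherits(image, "stain_image"))
  if (min_area < 0) stop("`min_area` must be >= 0", call. = FALSE)
  rng <- range(image$pixels)
  if (is.null(intensity_threshold)) {
    intensity_threshold <- otsu_threshold(image$pixels)
  } else if (!is.finite(intensity_threshold) ||
             intensity_threshold < rng[1L] || intensity_threshold > rng[2L] + 1e-12) {
    # threshold above the maximum means "nothing positive", which is valid;
    # only non-finite or below-minimum thresholds are parameter errors
    if (!is.finite(intensity_threshold))
      stop("`intensity_threshold` must be finite", call. = FALSE)
  }
  mask <- image$pixels >= intensity_threshold
  if (!any(mask)) return(list())
  lab <- label_components(mask, connectivity = 8L)
  k <- max(lab)
  out <- vector("list", k)
  keep <- logical(k)
  idx_all <- which(lab > 0L, arr.ind = TRUE)
  labs <- lab[lab > 0L]
  ord <- split(seq_len(nrow(idx_all)), labs)
  for (i in seq_len(k)) {
    idx <- idx_all[ord[[as.character(i)]], , drop = FALSE]
    f <- compute_features(idx, image)
    if (f[["area"]] >= min_area) {
      out[[i]] <- new_tau_object(idx, f)
      keep[i] <- TRUE
    }
  }
  out[keep]
}

#' Feature table of a tau-object list
#'
#' @param objects list of `tau_object`s.
#' @return data.frame with one row per object: the nine descriptors plus
#'   `channel` and (when known) the ground-truth `class`.
#' @export
object_features <- function(objects) {
  if (length(objects) == 0L) {
    df <- as.data.frame(matrix(numeric(0), 0, length(FEATURE_NAMES)))
    names(df) <- FEATURE_NAMES
    df$channel <- character(0); df$class <- character(0)
    return(df)
  }
  df <- as.data.frame(do.call(rbind, lapply(objects, `[[`, "features")))
  df$channel <- vapply(objects, `[[`, "", "channel")
  df$class <- vapply(objects, function(o) as.character(o$class), "")
  df
}

#' Calibrate per-channel classification rules from exemplars
#'
#' Mirrors the manual workflow in which single NFT, CB and TA objects are
#' selected per slice to define object thresholds. NFT and CB exemplars are
#' pooled into one `NFT/CB` channel and TA and TF into `TA/TF` (the two
#' merged analysis channels); each channel's rule is the axis-aligned box
#' `[min - expansion*range, max + expansion*range]` over all nine
#' descriptors, plus an intensity threshold (the lower bound of the
#' channel's mean-intensity interval) used to break ties.
#'
#' @param exemplars list of `tau_object`s whose `class` field is one of
#'   `"NFT"`, `"CB"`, `"TA"`, `"TF"`.
#' @param expansion non-negative fraction of each feature's exemplar range
#'   added on both sides of the interval. The default 0.25 compensates for
#'   the sample range of 15-20 exemplars systematically undercovering the
#'   population feature range (the empirical min/max of n draws misses
#'   roughly a `1/(n+1)` tail on each side per feature, compounded across
#'   nine features); the channels' morphology contrast keeps the widened
#'   boxes apart.
#' @return object of class `class_rule_set`: per-channel feature intervals,
#'   intensity threshold, and the exemplar counts used.
#' @export
calibrate_rules <- function(exemplars, expansion = 0.25) {
  if (expansion < 0) stop("`expansion` must be >= 0", call. = FALSE)
  cls <- vapply(exemplars, function(o) as.character(o$class), "")
  if (any(!cls %in% c("NFT", "CB", "TA", "TF")))
    stop("exemplar classes must be NFT, CB, TA or TF", call. = FALSE)
  channel_of <- ifelse(cls %in% c("NFT", "CB"), "NFT/CB", "TA/TF")
  rules <- list()
  for (ch in c("NFT/CB", "TA/TF")) {
    sel <- which(channel_of == ch)
    if (length(sel) == 0L)
      stop(sprintf("no exemplars for channel %s", ch), call. = FALSE)
    feats <- do.call(rbind, lapply(exemplars[sel], `[[`, "features"))
    lo <- apply(feats, 2L, min); hi <- apply(feats, 2L, max)
    rg <- hi - lo
    intervals <- rbind(min = lo - expansion * rg, max = hi + expansion * rg)
    rules[[ch]] <- list(
      intervals = intervals,
      intensity_threshold = intervals["min", "mean_intensity"],
      n_exemplars = length(sel),
      exemplar_classes = table(cls[sel])
    )
  }
  structure(list(channels = rules, expansion = expansion),
            class = "class_rule_set")
}

#' @export
print.class_rule_set <- function(x, ...) {
  cat("<class_rule_set> channels:", paste(names(x$channels), collapse = ", "),
      sprintf("(expansion %.2f)\n", x$expansion))
  invisible(x)
}

#' Serialize / restore a rule set as JSON
#'
#' @param rules a `class_rule_set`.
#' @param path JSON file path.
#' @export
write_rules_json <- function(rules, path) {
  stopifnot(inherits(rules, "class_rule_set"))
  payload <- list(expansion = rules$expansion, channels = lapply(
    rules$channels, function(ch) list(
      intervals = as.data.frame(ch$intervals),
      intensity_threshold = ch$intensity_threshold,
      n_exemplars = ch$n_exemplars)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rules_json
#' @export
read_rules_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  chans <- lapply(p$channels, function(ch) {
    iv <- as.matrix(ch$intervals)
    rownames(iv) <- c("min", "max")
    list(intervals = iv, intensity_threshold = ch$intensity_threshold,
         n_exemplars = ch$n_exemplars)
  })
  structure(list(channels = chans, expansion = p$expansion),
            class = "class_rule_set")
}

#' Assign objects to the NFT/CB or TA/TF channel
#'
#' An object joins a channel iff *all* nine of its descriptors fall inside
#' that channel's calibrated intervals. If both channels match, the tie is
#' broken by intensity: the object goes to `NFT/CB` (the "high density"
#' channel) when its mean intensity is at or above the NFT/CB intensity
#' threshold, otherwise to `TA/TF`. Objects matching neither channel stay
#' `"unassigned"`.
#'
#' @param objects list of `tau_object`s.
#' @param rules a `class_rule_set` from [calibrate_rules()].
#' @return the same list with the `channel` field filled in.
#' @export
classify_objects <- function(objects, rules) {
  stopifnot(inherits(rules, "class_rule_set"))
  lapply(objects, function(o) {
    f <- o$features[FEATURE_NAMES]
    hit <- vapply(rules$channels, function(ch) {
      iv <- ch$intervals[, FEATURE_NAMES, drop = FALSE]
      all(f >= iv["min", ] & f <= iv["max", ])
    }, logical(1L))
    o$channel <- if (all(hit)) {
      if (f[["mean_intensity"]] >=
          rules$channels[["NFT/CB"]]$intensity_threshold) "NFT/CB" else "TA/TF"
    } else if (hit[["NFT/CB"]]) "NFT/CB"
    else if (hit[["TA/TF"]]) "TA/TF"
    else "unassigned"
    o
  })
}

# Binary mask (image-shaped) of all pixels belonging to objects in `channel`.
channel_mask <- function(objects, dims, channel) {
  m <- matrix(FALSE, dims[1L], dims[2L])
  for (o in objects)
    if (identical(o$channel, channel)) m[o$pixels] <- TRUE
  m
}

#' Quantify AT8 occupancy within a subfield ROI
#'
#' Computes per-channel AT8 area-% (`100 * positive-in-ROI / ROI pixels`),
#' per-channel mean intensity over the positive pixels, and the total AT8
#' area-%, for one manually drawn subfield polygon. A pixel belongs to the
#' ROI iff its center falls inside the polygon.
#'
#' @param image a [stain_image()].
#' @param masks named list of logical matrices: channel masks (typically
#'   `"NFT/CB"`, `"TA/TF"`) plus optionally `"total"`; when `"total"` is
#'   absent the union of the channel masks is used.
#' @param roi an [roi_polygon()].
#' @return one-row data.frame (a SubfieldRecord): `subfield`, `label`,
#'   `roi_px`, `<channel>_area_pct`, `<channel>_intensity`,
#'   `total_area_pct`. Intensity over zero positive pixels is `NA`.
#' @export
quantify_subfield <- function(image, masks, roi) {
  stopifnot(inherits(image, "stain_image"), inherits(roi, "roi_polygon"))
  inroi <- roi_mask(roi, dim(image$pixels))
  n_roi <- sum(inroi)
  if (n_roi == 0L) stop("ROI lies fully outside the image", call. = FALSE)
  chans <- setdiff(names(masks), "total")
  total <- if ("total" %in% names(masks)) masks$total else
    Reduce(`|`, masks[chans], matrix(FALSE, nrow(image$pixels), ncol(image$pixels)))
  rec <- data.frame(subfield = roi$id, label = roi$label, roi_px = n_roi,
                    stringsAsFactors = FALSE)
  for (ch in chans) {
    pos <- masks[[ch]] & inroi
    nm <- gsub("[^A-Za-z0-9]+", "_", ch)
    rec[[paste0(nm, "_area_pct")]] <- 100 * sum(pos) / n_roi
    rec[[paste0(nm, "_intensity")]] <-
      if (any(pos)) mean(image$pixels[pos]) else NA_real_
  }
  tpos <- total & inroi
  rec$total_area_pct <- 100 * sum(tpos) / n_roi
  rec$total_intensity <- if (any(tpos)) mean(image$pixels[tpos]) else NA_real_
  rec
}

#' Colocalization of an AT8 mask with a cell-type mask
#'
#' Transfers the AT8 signal mask into a GFAP (astrocyte) or MAP2 (neuron)
#' structure mask and reports the AT8 area-% inside the structure:
#' `100 * |AT8+ ∩ mask+| / |mask+|`. `mode = "frame"` instead quantifies a
#' single signal as the % area of the entire scanning frame,
#' `100 * |signal+| / total pixels`.
#'
#' @param signal AT8 [stain_image()].
#' @param mask_image GFAP or MAP2 [stain_image()] of identical geometry
#'   (ignored in frame mode).
#' @param signal_threshold,mask_threshold foreground thresholds (Otsu when
#'   `NULL`).
#' @param mode `"mask"` (default) or `"frame"`.
#' @return area percentage (scalar). In mask mode an empty structure mask
#'   yields `NA`.
#' @export
colocalization_area <- function(signal, mask_image = NULL,
                                signal_threshold = NULL, mask_threshold = NULL,
                                mode = c("mask", "frame")) {
  mode <- match.arg(mode)
  stopifnot(inherits(signal, "stain_image"))
  if (is.null(signal_threshold)) signal_threshold <- otsu_threshold(signal$pixels)
  sig <- signal$pixels >= signal_threshold
  if (mode == "frame") return(100 * sum(sig) / length(sig))
  stopifnot(inherits(mask_image, "stain_image"))
  if (!identical(dim(signal$pixels), dim(mask_image$pixels)))
    stop("signal and mask images must share geometry", call. = FALSE)
  if (is.null(mask_threshold)) mask_threshold <- otsu_threshold(mask_image$pixels)
  mk <- mask_image$pixels >= mask_threshold
  if (!any(mk)) return(NA_real_)
  100 * sum(sig & mk) / sum(mk)
}
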