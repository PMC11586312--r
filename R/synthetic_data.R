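#' @title Seeded synthetic-data generators
#' @description Generators for every input the analysis modules consume,
#'   with ground truth attached: AT8 sections with class-specific object
#'   morphology, autoradiography sections as linear mixtures of class
#'   densities, dynamic PET with one-tissue-compartment kinetics, single-cell
#'   radiotracing cohorts obeying the extrapolation identity, and cortical
#'   slabs with a depth-dependent binding profile. All generators are
#'   deterministic given `seed`.
#' @name synthetic_data
NULL

#' Fan a global seed out to per-stage child seeds
#'
#' Splitting rule: `child_i = (seed * 1009 + 7919 * i) mod (2^31 - 1)`, `i`
#' the 1-based stage index. Documented so that multi-stage pipelines driven
#' by one global seed are reproducible stage by stage.
#'
#' @param seed integer global seed.
#' @param n number of child seeds.
#' @return integer vector of `n` child seeds, each in `[0, 2^31 - 2]`.
#' @export
fan_seed <- function(seed, n) {
  as.integer((as.numeric(seed) * 1009 + 7919 * seq_len(n)) %% 2147483647)
}

# default morphology distributions, units px / a.u. on a 0-1 intensity scale
default_morphology <- function() {
  list(
    NFT = list(radius = c(4, 7),   axis_ratio = c(1, 2),   intensity = c(0.85, 0.05)),
    CB  = list(radius = c(3, 5),   axis_ratio = c(1, 1.5), intensity = c(0.80, 0.05)),
    TA  = list(radius = c(12, 20), arms = c(5, 8),         intensity = c(0.35, 0.05)),
    TF  = list(npx = c(1, 5),                              intensity = c(0.50, 0.05))
  )
}

render_ellipse <- function(nr, nc, cy, cx, a, b, theta) {
  r0 <- max(1L, floor(cy - a)); r1 <- min(nr, ceiling(cy + a))
  c0 <- max(1L, floor(cx - a)); c1 <- min(nc, ceiling(cx + a))
  rows <- r0:r1; cols <- c0:c1
  dy <- rep(rows - 0.5 - cy, times = length(cols))
  dx <- rep(cols - 0.5 - cx, each = length(rows))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  sel <- u^2 + v^2 <= 1
  cbind(rep(rows, times = length(cols))[sel],
        rep(cols, each = length(rows))[sel])
}

# stellate (radial-arm) polygon: alternating outer/inner vertices with jitter
render_stellate <- function(nr, nc, cy, cx, r_out, n_arms, inner_frac = 0.3) {
  k <- 2L * n_arms
  ang <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)] +
    stats::runif(k, -0.15, 0.15)
  rad <- rep(c(r_out, r_out * inner_frac), n_arms) *
    stats::runif(k, 0.85, 1.15)
  poly <- list(x = cx + rad * cos(ang), y = cy + rad * sin(ang))
  r0 <- max(1L, floor(cy - r_out)); r1 <- min(nr, ceiling(cy + r_out))
  c0 <- max(1L, floor(cx - r_out)); c1 <- min(nc, ceiling(cx + r_out))
  rows <- r0:r1; cols <- c0:c1
  py <- rep(rows - 0.5, times = length(cols))
  px <- rep(cols - 0.5, each = length(rows))
  sel <- points_in_polygon(px, py, poly)
  cbind(rep(rows, times = length(cols))[sel],
        rep(cols, each = length(rows))[sel])
}

render_speck <- function(nr, nc, cy, cx, npx) {
  r <- round(cy); cc <- round(cx)
  cand <- rbind(c(0, 0), c(0, 1), c(1, 0), c(0, -1), c(-1, 0))
  take <- cand[seq_len(min(npx, 5L)), , drop = FALSE]
  px <- cbind(r + take[, 1L], cc + take[, 2L])
  px[px[, 1L] >= 1 & px[, 1L] <= nr & px[, 2L] >= 1 & px[, 2L] <= nc, ,
     drop = FALSE]
}

#' Generate a synthetic AT8 immunohistochemistry section
#'
#' Plants AT8-positive objects with class-specific morphology on a quiet
#' background: NFT and CB as compact high-intensity filled ellipses, TA as
#' large diffuse low-intensity stellate (radial-arm) shapes, TF as small
#' low-area specks. Objects are non-overlapping (rejection sampling on
#' bounding circles). Either exact per-class counts or Poisson densities can
#' be requested; exact counts support planting labelled exemplars for rule
#' calibration.
#'
#' @param dims image size in pixels, `c(rows, cols)`; each must be >= 256.
#' @param pixel_size µm per pixel (> 0).
#' @param n_objects named integer vector of exact per-class counts, e.g.
#'   `c(NFT = 15, CB = 15, TA = 15)`. Takes precedence over `densities`.
#' @param densities named numeric vector of per-class Poisson intensities in
#'   objects per µm² (expected count = density × image area); all >= 0.
#' @param morphology per-class morphology distributions; see
#'   `taumetry:::default_morphology()` for the structure and defaults.
#' @param background background intensity (a.u.).
#' @param noise_sd additive Gaussian pixel noise sd (0 disables noise).
#' @param seed integer seed; identical seed and parameters give
#'   bit-identical output.
#' @return list with `image` (a [stain_image()]) and `truth`: a list with
#'   `objects` (data.frame: `id`, `class`, `row`, `col`, `area_um2`,
#'   `intensity`), `pixels` (per-object pixel index matrices),
#'   `class_masks` (binary matrix per class), `channel_masks` (merged
#'   `NFT/CB`, `TA/TF`), `positive_mask` and `positive_fraction`.
#' @export
gen_ihc_section <- function(dims = c(768, 768), pixel_size = 1,
                            n_objects = NULL,
                            densities = c(NFT = 0, CB = 0, TA = 0, TF = 0),
                            morphology = default_morphology(),
                            background = 0.05, noise_sd = 0, seed = 1L) {
  if (length(dims) != 2L || any(dims < 256))
    stop("image dims must be at least 256 x 256 px", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  if (any(densities < 0)) stop("densities must be >= 0", call. = FALSE)
  set.seed(seed)
  nr <- dims[1L]; nc <- dims[2L]
  if (is.null(n_objects)) {
    area_um2 <- nr * nc * pixel_size^2
    n_objects <- vapply(names(densities), function(cl)
      stats::rpois(1L, densities[[cl]] * area_um2), integer(1L))
  }
  n_objects <- n_objects[n_objects > 0]
  classes <- rep(names(n_objects), times = n_objects)
  img <- matrix(background, nr, nc)
  placed <- matrix(numeric(0), 0, 3)  # cy, cx, bounding radius
  obj_px <- list(); obj_meta <- list()
  for (i in seq_along(classes)) {
    cl <- classes[i]
    mo <- morphology[[cl]]
    for (attempt in 1:200) {
      if (cl %in% c("NFT", "CB")) {
        a <- stats::runif(1, mo$radius[1], mo$radius[2])
        ratio <- stats::runif(1, mo$axis_ratio[1], mo$axis_ratio[2])
        b <- a / ratio
        rad <- a
      } else if (cl == "TA") {
        r_out <- stats::runif(1, mo$radius[1], mo$radius[2])
        rad <- 1.15 * r_out  # arms jitter up to 15% beyond the nominal radius
      } else {
        rad <- 2
      }
      cy <- stats::runif(1, rad + 2, nr - rad - 2)
      cx <- stats::runif(1, rad + 2, nc - rad - 2)
      if (nrow(placed) > 0 &&
          any(sqrt((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2) <
              placed[, 3] + rad + 2)) next
      px <- switch(cl,
        NFT = , CB = render_ellipse(nr, nc, cy, cx, a, b,
                                    stats::runif(1, 0, pi)),
        TA  = render_stellate(nr, nc, cy, cx, r_out,
                              sample(mo$arms[1]:mo$arms[2], 1L)),
        TF  = render_speck(nr, nc, cy, cx,
                           sample(mo$npx[1]:mo$npx[2], 1L)))
      if (nrow(px) == 0L) next
      # keep the largest 8-connected piece so one planted object is exactly
      # one component (thin stellate arms can otherwise detach)
      if (nrow(px) > 1L) {
        r0 <- min(px[, 1L]); c0 <- min(px[, 2L])
        bb <- matrix(FALSE, max(px[, 1L]) - r0 + 1L, max(px[, 2L]) - c0 + 1L)
        bb[cbind(px[, 1L] - r0 + 1L, px[, 2L] - c0 + 1L)] <- TRUE
        lb <- label_components(bb, 8L)
        main <- which.max(tabulate(lb[lb > 0L]))
        keep_px <- which(lb == main, arr.ind = TRUE)
        px <- cbind(keep_px[, 1L] + r0 - 1L, keep_px[, 2L] + c0 - 1L)
      }
      placed <- rbind(placed, c(cy, cx, rad))
      # keep every planted object strictly above any sensible foreground
      # threshold: pixel jitter (sd 2% of intensity) must not straddle it
      inten <- stats::rnorm(1, mo$intensity[1], mo$intensity[2])
      inten <- max(inten, background + 0.2)
      img[px] <- inten + stats::rnorm(nrow(px), 0, 0.02 * inten)
      obj_px[[length(obj_px) + 1L]] <- px
      obj_meta[[length(obj_meta) + 1L]] <- data.frame(
        class = cl, row = mean(px[, 1]) - 0.5, col = mean(px[, 2]) - 0.5,
        area_um2 = nrow(px) * pixel_size^2, intensity = inten,
        stringsAsFactors = FALSE)
      break
    }
  }
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
  img <- pmax(img, 0)
  objects <- if (length(obj_meta)) {
    cbind(id = seq_along(obj_meta), do.call(rbind, obj_meta))
  } else {
    data.frame(id = integer(0), class = character(0), row = numeric(0),
               col = numeric(0), area_um2 = numeric(0), intensity = numeric(0))
  }
  class_masks <- lapply(stats::setNames(nm = c("NFT", "CB", "TA", "TF")),
    function(cl) {
      m <- matrix(FALSE, nr, nc)
      for (k in which(objects$class == cl)) m[obj_px[[k]]] <- TRUE
      m
    })
  channel_masks <- list(
    "NFT/CB" = class_masks$NFT | class_masks$CB,
    "TA/TF"  = class_masks$TA | class_masks$TF)
  positive <- channel_masks[["NFT/CB"]] | channel_masks[["TA/TF"]]
  list(
    image = stain_image(img, pixel_size = pixel_size, stain = "AT8"),
    truth = list(objects = objects, pixels = obj_px,
                 class_masks = class_masks, channel_masks = channel_masks,
                 positive_mask = positive,
                 positive_fraction = mean(positive))
  )
}

# separable Gaussian blur, kernel normalised to sum 1 (sigma in px)
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(x) {
    n <- length(x)
    xp <- c(rep(x[1L], half), x, rep(x[n], half))
    out <- numeric(n)
    for (t in seq_along(k)) out <- out + k[t] * xp[t:(t + n - 1L)]
    out
  }
  m <- apply(m, 2L, conv1)
  t(apply(m, 1L, conv1))
}

#' Generate a matched autoradiography section
#'
#' Builds the radiotracer-binding raster implied by a planted AT8 ground
#' truth: `ARG = background + gain["NFT/CB"] * density_NFT/CB +
#' gain["TA/TF"] * density_TA/TF + noise`, where the per-channel density map
#' is the planted channel mask (optionally Gaussian-blurred to emulate the
#' coarser autoradiography resolution). The default gains make the
#' dense-tau (NFT/CB) channel couple much more strongly into the binding
#' signal than the astrocytic (TA/TF) channel, so subfield correlations
#' inherit the NFT/CB > TA/TF ordering by construction.
#'
#' @param truth the `truth` element returned by [gen_ihc_section()].
#' @param coupling named gains, a.u. per unit density,
#'   `c("NFT/CB" = ..., "TA/TF" = ...)`; both >= 0.
#' @param background mean background level (a.u.).
#' @param noise_sd additive Gaussian noise sd (>= 0).
#' @param blur_sigma Gaussian blur of the density maps in px (0 = none).
#' @param pixel_size µm per pixel of the output (same grid as the IHC
#'   raster so subfield ROIs transfer).
#' @param seed integer seed.
#' @return a [stain_image()] with stain `"ARG"`.
#' @export
gen_autorad_section <- function(truth,
                                coupling = c("NFT/CB" = 40, "TA/TF" = 8),
                                background = 100, noise_sd = 0,
                                blur_sigma = 0, pixel_size = 1, seed = 1L) {
  if (is.null(truth$channel_masks))
    stop("`truth` must come from gen_ihc_section()", call. = FALSE)
  if (any(coupling < 0)) stop("coupling gains must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise sd must be >= 0", call. = FALSE)
  dims <- dim(truth$positive_mask)
  set.seed(seed)
  arg <- matrix(background, dims[1L], dims[2L])
  for (ch in names(coupling)) {
    dmap <- truth$channel_masks[[ch]] + 0
    if (is.null(dmap)) stop(sprintf("truth lacks channel mask %s", ch),
                            call. = FALSE)
    if (blur_sigma > 0) dmap <- gaussian_blur(dmap, blur_sigma)
    arg <- arg + coupling[[ch]] * dmap
  }
  if (noise_sd > 0)
    arg <- arg + matrix(stats::rnorm(prod(dims), 0, noise_sd), dims[1L], dims[2L])
  stain_image(pmax(arg, 0), pixel_size = pixel_size, stain = "ARG")
}

#' PET frame schedules
#'
#' The two acquisition schedules used throughout: `"mouse"` (6×10, 2×30,
#' 3×60, 5×120, 5×300, 5×600 s; 26 frames) and `"human"` (12×5, 6×10, 3×20,
#' 7×60, 4×300, 3×600 s; 35 frames spanning 60 min). A custom schedule can
#' be given as a vector of frame durations in seconds.
#'
#' @param preset `"mouse"`, `"human"`, or a numeric vector of frame
#'   durations (seconds).
#' @return data.frame with `start`, `end`, `mid` (minutes) and
#'   `duration_s`.
#' @export
frame_schedule <- function(preset = "mouse") {
  durations_s <- if (is.numeric(preset)) preset
  else switch(preset,
    mouse = c(rep(10, 6), rep(30, 2), rep(60, 3), rep(120, 5),
              rep(300, 5), rep(600, 5)),
    human = c(rep(5, 12), rep(10, 6), rep(20, 3), rep(60, 7),
              rep(300, 4), rep(600, 3)),
    stop("unknown schedule preset", call. = FALSE))
  if (length(durations_s) == 0L) stop("empty frame schedule", call. = FALSE)
  end <- cumsum(durations_s) / 60
  start <- c(0, end[-length(end)])
  data.frame(start = start, end = end, mid = (start + end) / 2,
             duration_s = durations_s)
}

#' Arterial input-curve model
#'
#' `C_p(t) = A (t/tp) exp(1 - t/tp) + A_tail (1 - exp(-t/tp)) exp(-lambda t)`:
#' a fast first-pass peak of amplitude `A` at `tp` minutes plus a slow
#' washout tail. Returns a function of time (minutes) giving kBq/ml.
#'
#' @param peak_time peak time `tp` in minutes.
#' @param peak_amplitude `A` in kBq/ml.
#' @param tail_fraction tail amplitude as a fraction of `A`.
#' @param washout_rate tail washout rate `lambda`, 1/min.
#' @export
input_curve <- function(peak_time = 0.75, peak_amplitude = 100,
                        tail_fraction = 0.15, washout_rate = 0.02) {
  force(peak_time); force(peak_amplitude)
  force(tail_fraction); force(washout_rate)
  function(t) {
    t <- pmax(t, 0)
    peak_amplitude * (t / peak_time) * exp(1 - t / peak_time) +
      peak_amplitude * tail_fraction *
        (1 - exp(-t / peak_time)) * exp(-washout_rate * t)
  }
}

# C_T(t) = K1 exp(-k2 t) (*) C_p(t) on a fine grid via the exact
# exponential-decay trapezoid recursion; values returned at `times` by
# linear interpolation.
one_tissue_response <- function(times, input_fun, K1, k2, dt = 0.005) {
  if (K1 < 0) stop("K1 must be >= 0", call. = FALSE)
  if (k2 <= 0) stop("k2 must be > 0", call. = FALSE)
  tmax <- max(times)
  grid <- seq(0, tmax + dt, by = dt)
  cp <- input_fun(grid)
  n <- length(grid)
  ct <- numeric(n)
  e <- exp(-k2 * dt)
  for (i in 2:n)
    ct[i] <- ct[i - 1] * e + K1 * dt * (cp[i] + cp[i - 1] * e) / 2
  stats::approx(grid, ct, xout = times, rule = 2)$y
}

#' Generate dynamic PET time-activity data
#'
#' One-tissue-compartment tracer kinetics: each region's tissue curve is
#' `C_T(t) = K1 exp(-k2 t) ⊛ C_p(t)` evaluated at frame mid-times, with
#' `V_T = K1/k2` as regional ground truth. Optionally renders a 4-D voxel
#' volume from a 3-D region-label array.
#'
#' @param regions named list of kinetic parameter lists, each with `K1`
#'   (ml·cm⁻³·min⁻¹, >= 0) and `k2` (1/min, > 0).
#' @param schedule a [frame_schedule()] data.frame (must be non-empty).
#' @param input_fun plasma input function of time in minutes (default
#'   [input_curve()] defaults).
#' @param noise_sd Gaussian noise sd added to frame activities (kBq/ml).
#' @param seed integer seed.
#' @param label_volume optional 3-D integer array of region indices
#'   (0 = background) keyed to `seq_along(regions)`; when given, a 4-D
#'   volume `[x, y, z, frame]` is also returned (background voxels carry the
#'   input-function curve scaled by `blood_fraction`).
#' @param blood_fraction activity in label-0 voxels as a fraction of the
#'   input curve (default 0: background is empty).
#' @return list with `tacs` (data.frame: `region`, `frame`, `start`, `end`,
#'   `mid`, `activity`), `input` (data.frame with the plasma curve at frame
#'   mid-times), `schedule`, `truth_vt` (named `K1/k2`), and `volume` when
#'   `label_volume` is supplied.
#' @export
gen_dynamic_pet <- function(regions = list(cortex = list(K1 = 0.5, k2 = 0.1)),
                            schedule = frame_schedule("mouse"),
                            input_fun = input_curve(),
                            noise_sd = 0, seed = 1L,
                            label_volume = NULL, blood_fraction = 0) {
  if (nrow(schedule) == 0L) stop("empty frame schedule", call. = FALSE)
  set.seed(seed)
  mid <- schedule$mid
  cp <- input_fun(mid)
  tac_list <- lapply(names(regions), function(rg) {
    p <- regions[[rg]]
    act <- one_tissue_response(mid, input_fun, p$K1, p$k2)
    if (noise_sd > 0) act <- pmax(act + stats::rnorm(length(act), 0, noise_sd), 0)
    data.frame(region = rg, frame = seq_along(mid), start = schedule$start,
               end = schedule$end, mid = mid, activity = act,
               stringsAsFactors = FALSE)
  })
  tacs <- do.call(rbind, tac_list)
  out <- list(
    tacs = tacs,
    input = data.frame(mid = mid, activity = cp),
    schedule = schedule,
    truth_vt = vapply(regions, function(p) p$K1 / p$k2, numeric(1L))
  )
  if (!is.null(label_volume)) {
    d <- dim(label_volume)
    vol <- array(0, c(d, nrow(schedule)))
    curves <- rbind(blood_fraction * cp,
                    do.call(rbind, lapply(tac_list, function(x) x$activity)))
    for (f in seq_len(nrow(schedule))) {
      frame <- curves[label_volume + 1L, f]
      if (noise_sd > 0) frame <- frame + stats::rnorm(length(frame), 0, noise_sd)
      vol[, , , f] <- frame
    }
    out$volume <- vol
  }
  out
}

#' Generate a single-cell radiotracing cohort
#'
#' Emulates the scRadiotracing experiment: transgenic (TG) and wild-type
#' (WT) mice are injected with tracer, neurons and astrocytes are sorted,
#' and pellet radioactivity is measured hours later. Defaults are anchored
#' to the reported magnitudes: TG neurons take up `fold_change` (1.89×) more
#' tracer per cell than WT neurons, TG neuron uptake is 27× astrocyte
#' uptake (5× in WT), and per-animal cellular radioactivity lands in the
#' 7.7-36.5 kBq range. With `noise_sd = 0` each TG mouse's PET increment
#' equals `N_neuron * Bq/neuron + N_astro * Bq/astrocyte` exactly (the
#' extrapolation conservation identity).
#'
#' @param n_tg,n_wt mice per arm (>= 1).
#' @param fold_change TG/WT neuron-uptake fold change (> 0).
#' @param wt_neuron_bq mean WT neuron uptake, Bq per cell at injection time.
#' @param neuron_astro_ratio_tg,neuron_astro_ratio_wt within-genotype
#'   neuron:astrocyte uptake ratios.
#' @param between_mouse_cv lognormal coefficient of variation of per-mouse
#'   uptake around the genotype mean.
#' @param noise_sd fractional Gaussian noise applied to the PET increments
#'   (0 keeps the identity exact).
#' @param census a [brain_cell_census()].
#' @param seed integer seed.
#' @return list with `truth` (data.frame per mouse: genotype, per-cell
#'   uptakes, predicted brain Bq, PET increment Bq, cellular kBq) and
#'   `pellets` (data.frame, one row per cell pellet: `mouse`, `genotype`,
#'   `cell_type`, `cell_count`, `measured_bq`, `offset_min`,
#'   `background_bq`, `injected_dose_mbq`, `body_weight_g`, `total_cells`,
#'   `cd11b_pos`, `acsa2_pos`).
#' @export
gen_scrad_cohort <- function(n_tg = 5, n_wt = 5, fold_change = 1.89,
                             wt_neuron_bq = 1.6e-4,
                             neuron_astro_ratio_tg = 27,
                             neuron_astro_ratio_wt = 5,
                             between_mouse_cv = 0.3,
                             noise_sd = 0,
                             census = brain_cell_census(), seed = 1L) {
  if (n_tg < 1 || n_wt < 1) stop("need >= 1 mouse per arm", call. = FALSE)
  if (fold_change <= 0) stop("fold change must be > 0", call. = FALSE)
  set.seed(seed)
  n <- n_tg + n_wt
  genotype <- c(rep("TG", n_tg), rep("WT", n_wt))
  sdlog <- sqrt(log(1 + between_mouse_cv^2))
  mu_n <- ifelse(genotype == "TG", wt_neuron_bq * fold_change, wt_neuron_bq)
  u_neuron <- mu_n * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  ratio <- ifelse(genotype == "TG", neuron_astro_ratio_tg, neuron_astro_ratio_wt)
  u_astro <- mu_n / ratio * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  predicted <- census$neurons * u_neuron + census$astrocytes * u_astro
  increment <- predicted
  if (noise_sd > 0)
    increment <- predicted * (1 + stats::rnorm(n, 0, noise_sd))
  mouse <- sprintf("%s%02d", ifelse(genotype == "TG", "tg", "wt"),
                   c(seq_len(n_tg), seq_len(n_wt)))
  truth <- data.frame(
    mouse = mouse, genotype = genotype,
    bq_per_neuron = u_neuron, bq_per_astrocyte = u_astro,
    predicted_brain_bq = predicted, pet_increment_bq = increment,
    cellular_kbq = predicted / 1000,
    stringsAsFactors = FALSE)
  pellet_rows <- list()
  for (i in seq_len(n)) {
    for (ct in c("neuron", "astrocyte")) {
      count <- round(stats::runif(1, 2e5, 8e5))
      offset <- stats::runif(1, 360, 420)
      u <- if (ct == "neuron") u_neuron[i] else u_astro[i]
      measured <- u * count * 2^(-offset / 109.77)
      total <- count + round(stats::runif(1, 0.02, 0.08) * count)
      if (ct == "neuron") {
        cd11b <- round(stats::runif(1, 0.01, 0.05) * total)
        acsa2 <- round(stats::runif(1, 0.01, 0.05) * total)
      } else {
        cd11b <- round(stats::runif(1, 0.0, 0.03) * total)
        acsa2 <- round(stats::runif(1, 0.88, 0.97) * total)
      }
      pellet_rows[[length(pellet_rows) + 1L]] <- data.frame(
        mouse = mouse[i], genotype = genotype[i], cell_type = ct,
        cell_count = count, measured_bq = measured, offset_min = offset,
        background_bq = stats::runif(1, 0.05, 0.15),
        injected_dose_mbq = stats::rnorm(1, 12.7, 2.1),
        body_weight_g = stats::runif(1, 22, 32),
        total_cells = total, cd11b_pos = cd11b, acsa2_pos = acsa2,
        stringsAsFactors = FALSE)
    }
  }
  list(truth = truth, pellets = do.call(rbind, pellet_rows))
}

# grid factorisation for R parcels: divisor pair closest to square
parcel_grid_dims <- function(R) {
  divs <- which(R %% seq_len(R) == 0)
  gx <- max(divs[divs <= sqrt(R)])
  c(gx, R / gx)
}

#' Generate a cortical slab with a depth-dependent binding profile
#'
#' Builds a 3-D slab whose third axis is depth: CSF on top, cortical gray
#' matter (GM) in the middle, white matter (WM) below, with a smoothly
#' undulating GM/WM boundary. The PET volume equals
#' `profile(signed distance to the GM/WM boundary)` plus optional noise
#' (distance in mm, positive into WM), so the default Gaussian bump centred
#' at 0 puts the signal maximum on the boundary surface — the
#' oligodendroglial-tau enrichment the layered analysis is designed to
#' detect. The cortical sheet is tiled into `R` parcels.
#'
#' @param dims voxel dims `c(nx, ny, nz)`.
#' @param voxel_size mm per voxel (isotropic).
#' @param thickness_mm cortical thickness (GM depth extent).
#' @param csf_mm CSF pad above the cortex.
#' @param undulation_mm amplitude of the boundary undulation.
#' @param n_parcels number of parcels `R` (default 200, a Schaefer-like
#'   cortical parcellation resolution).
#' @param profile function of signed distance (mm) from the GM/WM boundary
#'   returning PET signal; default `1 + 0.8 * exp(-d^2 / (2 * 0.75^2))`.
#' @param noise_sd Gaussian voxel noise sd.
#' @param seed integer seed.
#' @return list with `volume` (3-D array), `labels` (1 = CSF, 2 = GM,
#'   3 = WM), `z_csf`, `z_wm` (boundary depth maps in mm, `nx x ny`),
#'   `parcels` (`nx x ny` integer map, 1..R), `profile`, `voxel_size`,
#'   `thickness_mm`.
#' @export
gen_cortical_slab <- function(dims = c(40, 40, 24), voxel_size = 0.5,
                              thickness_mm = 3, csf_mm = 2,
                              undulation_mm = 1, n_parcels = 200,
                              profile = function(d) 1 + 0.8 * exp(-d^2 / (2 * 0.75^2)),
                              noise_sd = 0, seed = 1L) {
  if (n_parcels < 1) stop("need >= 1 parcel", call. = FALSE)
  if (thickness_mm <= 0) stop("degenerate slab: no gray matter", call. = FALSE)
  depth_mm <- dims[3L] * voxel_size
  if (csf_mm + thickness_mm + undulation_mm >= depth_mm)
    stop("slab too shallow for the requested geometry", call. = FALSE)
  set.seed(seed)
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  xg <- seq_len(nx); yg <- seq_len(ny)
  ph <- stats::runif(4, 0, 2 * pi)
  z_csf <- outer(xg, yg, function(x, y)
    csf_mm + undulation_mm * 0.5 *
      (sin(2 * pi * x / nx + ph[1]) * cos(2 * pi * y / ny + ph[2]) + 1) / 2)
  z_wm <- z_csf + thickness_mm +
    undulation_mm * 0.5 *
      (outer(xg, yg, function(x, y)
        sin(2 * pi * x / nx + ph[3]) * sin(2 * pi * y / ny + ph[4])) + 1) / 2
  zc <- (seq_len(nz) - 0.5) * voxel_size  # voxel-center depth, mm
  labels <- array(0L, dims)
  volume <- array(0, dims)
  for (k in seq_len(nz)) {
    labels[, , k] <- ifelse(zc[k] < z_csf, 1L, ifelse(zc[k] < z_wm, 2L, 3L))
    volume[, , k] <- profile(zc[k] - z_wm)
  }
  if (noise_sd > 0)
    volume <- volume + array(stats::rnorm(prod(dims), 0, noise_sd), dims)
  gd <- parcel_grid_dims(n_parcels)
  px <- pmin(ceiling(xg / (nx / gd[1L])), gd[1L])
  py <- pmin(ceiling(yg / (ny / gd[2L])), gd[2L])
  parcels <- outer(px, py, function(a, b) (a - 1L) * gd[2L] + b)
  list(volume = volume, labels = labels, z_csf = z_csf, z_wm = z_wm,
       parcels = parcels, profile = profile, voxel_size = voxel_size,
       thickness_mm = thickness_mm)
}
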