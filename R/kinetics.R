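#' @title PET kinetics: Logan graphical analysis and readouts
#' @description Logan plots with image-derived input functions, voxelwise
#'   volume-of-distribution maps, reference-region normalization (VT ratio
#'   and static-window SUVR), effect sizes, and a voxelwise regression map
#'   with cluster-extent filtering.
#' @name kinetics
NULL

#' F-18 physical half-life in minutes
#' @export
F18_HALF_LIFE_MIN <- 109.77

# cumulative trapezoid with an implicit (0, 0) origin point
cumtrapz0 <- function(t, y) {
  tt <- c(0, t); yy <- c(0, y)
  c(0, cumsum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2))[-1]
}

#' Extract an image-derived input function
#'
#' Per-frame mean of the dynamic volume over a vascular VOI mask — the
#' blood activity curve used as the Logan input (left-ventricle VOI in
#' mice, 5-mm carotid spheres in humans).
#'
#' @param volume 4-D array `[x, y, z, frame]`.
#' @param mask 3-D logical array, non-empty, same spatial dims.
#' @param schedule optional [frame_schedule()] attached to the output.
#' @return data.frame with `frame`, `activity`, and schedule columns when
#'   given.
#' @export
extract_idif <- function(volume, mask, schedule = NULL) {
  d <- dim(volume)
  if (length(d) != 4L) stop("`volume` must be 4-D", call. = FALSE)
  if (!identical(dim(mask), d[1:3]))
    stop("mask and volume dims differ", call. = FALSE)
  if (!any(mask)) stop("empty VOI mask", call. = FALSE)
  idx <- which(mask)
  nvox <- prod(d[1:3])
  act <- vapply(seq_len(d[4L]), function(f)
    mean(volume[idx + (f - 1L) * nvox]), numeric(1L))
  out <- data.frame(frame = seq_len(d[4L]), activity = act)
  if (!is.null(schedule)) out <- cbind(out, schedule[, c("start", "end", "mid")])
  out
}

#' Spherical VOI mask
#'
#' @param dims 3-D voxel dims.
#' @param center voxel-center coordinates of the sphere center (1-based).
#' @param diameter_mm sphere diameter in mm (default 5.0, the carotid VOI
#'   convention).
#' @param voxel_size mm per voxel.
#' @return logical 3-D array: voxels whose centers lie inside the sphere.
#' @export
sphere_mask <- function(dims, center, diameter_mm = 5, voxel_size = 1) {
  r <- diameter_mm / 2 / voxel_size
  i <- slice.index(array(0, dims), 1L)
  j <- slice.index(array(0, dims), 2L)
  k <- slice.index(array(0, dims), 3L)
  (i - center[1L])^2 + (j - center[2L])^2 + (k - center[3L])^2 <= r^2
}

#' Logan graphical analysis of a tissue curve
#'
#' Transforms tissue and input curves to Logan coordinates
#' `x(t) = ∫₀ᵗ C_p ds / C_T(t)`, `y(t) = ∫₀ᵗ C_T ds / C_T(t)` (trapezoidal
#' integrals at frame mid-times with an implicit origin) and fits the late
#' linear segment by ordinary least squares; the slope is the total volume
#' of distribution `V_T`. The equilibration time `t*` is the earliest frame
#' mid-time such that every later point deviates from the fitted line by at
#' most `max_rel_error` relative to the fit (default 10%, the maximum-error
#' criterion). Fits with negative slope are clamped to `vt_threshold`
#' (default 0).
#'
#' @param tissue numeric vector of tissue activity at frame mid-times, or a
#'   data.frame with `mid` and `activity`.
#' @param input plasma/blood activity, same conventions.
#' @param t_mid frame mid-times in minutes (taken from `tissue` when it is
#'   a data.frame).
#' @param max_rel_error maximum relative deviation of included points from
#'   the fitted line (fraction; default 0.10).
#' @param vt_threshold lower clamp for the fitted slope (default 0).
#' @param min_points minimum points in the fitted segment (>= 3).
#' @return object of class `logan_fit`: `vt`, `intercept`, `tstar`,
#'   `max_rel_error_achieved`, `n_points`, `clamped`.
#' @export
logan_vt <- function(tissue, input, t_mid = NULL, max_rel_error = 0.10,
                     vt_threshold = 0, min_points = 3L) {
  if (is.data.frame(tissue)) { t_mid <- tissue$mid; tissue <- tissue$activity }
  if (is.data.frame(input)) input <- input$activity
  stopifnot(length(tissue) == length(input), length(tissue) == length(t_mid))
  if (all(input == 0)) stop("input function is identically zero", call. = FALSE)
  int_cp <- cumtrapz0(t_mid, input)
  int_ct <- cumtrapz0(t_mid, tissue)
  ok <- tissue > 0
  if (sum(ok) < min_points)
    stop("fewer than `min_points` frames with positive tissue activity",
         call. = FALSE)
  x <- int_cp[ok] / tissue[ok]
  y <- int_ct[ok] / tissue[ok]
  tm <- t_mid[ok]
  n <- length(x)
  best_err <- Inf
  for (k in seq_len(n - min_points + 1L)) {
    xi <- x[k:n]; yi <- y[k:n]
    fit <- stats::lm.fit(cbind(1, xi), yi)
    pred <- fit$fitted.values
    rel <- abs(yi - pred) / abs(pred)
    err <- max(rel)
    if (err <= max_rel_error) {
      slope <- fit$coefficients[2L]
      clamped <- slope < vt_threshold
      return(structure(list(
        vt = max(slope, vt_threshold),
        intercept = unname(fit$coefficients[1L]),
        tstar = tm[k],
        max_rel_error_achieved = err,
        n_points = n - k + 1L,
        clamped = clamped), class = "logan_fit"))
    }
    best_err <- min(best_err, err)
  }
  stop(sprintf(
    "no t* satisfies the maximum-error criterion (best achieved %.3f > %.3f)",
    best_err, max_rel_error), call. = FALSE)
}

#' @export
print.logan_fit <- function(x, ...) {
  cat(sprintf(
    "<logan_fit> VT = %.4g (intercept %.3g), t* = %.2f min, %d points, max rel err %.3f%s\n",
    x$vt, x$intercept, x$tstar, x$n_points, x$max_rel_error_achieved,
    if (isTRUE(x$clamped)) " [clamped]" else ""))
  invisible(x)
}

#' Voxelwise volume-of-distribution image
#'
#' Applies [logan_vt()] to every voxel of a dynamic volume. When `tstar` is
#' supplied (e.g. determined once on a designated tissue-region curve) the
#' Logan fit uses all frames from `tstar` on without re-searching; voxels
#' where the fit fails are set to `NA`.
#'
#' @param volume 4-D array `[x, y, z, frame]`.
#' @param input input function (vector or data.frame with `activity`).
#' @param t_mid frame mid-times (minutes).
#' @param tstar optional fixed equilibration time (minutes).
#' @param mask optional 3-D logical array restricting the fit.
#' @param ... passed to [logan_vt()].
#' @return 3-D array of `V_T` values (`NA` where the fit failed).
#' @export
vt_image <- function(volume, input, t_mid, tstar = NULL, mask = NULL, ...) {
  d <- dim(volume)
  if (length(d) != 4L) stop("`volume` must be 4-D", call. = FALSE)
  if (is.data.frame(input)) input <- input$activity
  out <- array(NA_real_, d[1:3])
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  nvox <- prod(d[1:3])
  frames <- seq_len(d[4L])
  sel <- if (!is.null(tstar)) which(t_mid >= tstar - 1e-9) else NULL
  for (v in which(mask)) {
    tac <- volume[v + (frames - 1L) * nvox]
    fit <- tryCatch({
      if (!is.null(sel)) {
        if (all(tac[sel] <= 0)) NULL
        else {
          xfit <- logan_fixed_segment(tac, input, t_mid, sel, ...)
          xfit
        }
      } else logan_vt(tac, input, t_mid, ...)
    }, error = function(e) NULL)
    if (!is.null(fit)) out[v] <- fit$vt
  }
  out
}

# Logan OLS on a fixed late segment (no t* search); shares the transform
# with logan_vt.
logan_fixed_segment <- function(tissue, input, t_mid, sel, vt_threshold = 0, ...) {
  int_cp <- cumtrapz0(t_mid, input)
  int_ct <- cumtrapz0(t_mid, tissue)
  ok <- sel[tissue[sel] > 0]
  if (length(ok) < 3L) stop("fewer than 3 usable frames", call. = FALSE)
  x <- int_cp[ok] / tissue[ok]
  y <- int_ct[ok] / tissue[ok]
  fit <- stats::lm.fit(cbind(1, x), y)
  pred <- fit$fitted.values
  structure(list(
    vt = max(fit$coefficients[2L], vt_threshold),
    intercept = unname(fit$coefficients[1L]),
    tstar = t_mid[ok[1L]],
    max_rel_error_achieved = max(abs(y - pred) / abs(pred)),
    n_points = length(ok),
    clamped = fit$coefficients[2L] < vt_threshold), class = "logan_fit")
}

#' Normalize a quantity to a reference region
#'
#' Target/reference ratio used for both VT ratios (striatal reference in
#' mice) and SUVR (inferior-cerebellar reference in humans).
#'
#' @param target numeric scalar, vector, or array of target values.
#' @param reference reference-region mean (must be > 0).
#' @return `target / reference`, same shape as `target`.
#' @export
normalize_to_reference <- function(target, reference) {
  if (!is.numeric(reference) || length(reference) != 1L ||
      !is.finite(reference) || reference <= 0)
    stop("reference mean must be a positive scalar", call. = FALSE)
  target / reference
}

#' Static-window mean of a dynamic acquisition
#'
#' Duration-weighted mean of frames fully contained in the window (default
#' 20-40 min, the static late-phase readout).
#'
#' @param x 4-D array or numeric TAC vector.
#' @param schedule a [frame_schedule()] data.frame.
#' @param window `c(start, end)` minutes.
#' @return 3-D array (volume input) or scalar (TAC input).
#' @export
static_window_mean <- function(x, schedule, window = c(20, 40)) {
  sel <- which(schedule$start >= window[1L] - 1e-9 &
               schedule$end <= window[2L] + 1e-9)
  if (length(sel) == 0L)
    stop("no frames fall inside the static window", call. = FALSE)
  w <- schedule$duration_s[sel] / sum(schedule$duration_s[sel])
  if (is.array(x) && length(dim(x)) == 4L) {
    out <- array(0, dim(x)[1:3])
    for (i in seq_along(sel)) out <- out + w[i] * x[, , , sel[i]]
    out
  } else {
    sum(w * x[sel])
  }
}

#' Cohen's d standardized mean difference
#'
#' `(mean(a) - mean(b)) / s_pooled` with the pooled standard deviation
#' using `n - 1` weighting.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return scalar `d`; `NA` (with a warning) when the pooled SD is zero.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs n >= 2", call. = FALSE)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) {
    if (mean(a) == mean(b)) return(0)
    warning("zero pooled SD; Cohen's d undefined")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sp
}

#' Voxelwise regression map with cluster-extent filtering
#'
#' Simple linear regression of each voxel's value on a per-subject
#' covariate (the SPM-style analysis: cellular tracer uptake as the
#' regression vector), thresholded at `p < p_thresh` uncorrected; suprathreshold
#' voxels are grouped into 6-connected 3-D clusters and clusters of size
#' `> k_min` voxels are retained (defaults `p < 0.005`, `k > 20`).
#'
#' @param volumes list of 3-D arrays (one per subject) or a 4-D array with
#'   subjects along the 4th dimension.
#' @param covariate numeric vector, one value per subject (n >= 4).
#' @param p_thresh uncorrected per-voxel p threshold.
#' @param k_min minimum cluster extent (strict: clusters must exceed it).
#' @return list with `p_volume` (3-D array of p-values), `cluster_map`
#'   (integer 3-D array, 0 = background, clusters numbered deterministically
#'   by smallest linear index), and `clusters` (data.frame: `cluster`,
#'   `size`, `peak_t`, `peak_x`, `peak_y`, `peak_z`).
#' @export
voxelwise_regression <- function(volumes, covariate, p_thresh = 0.005,
                                 k_min = 20L) {
  if (is.list(volumes)) {
    dims <- dim(volumes[[1L]])
    if (!all(vapply(volumes, function(v) identical(dim(v), dims), logical(1L))))
      stop("subject volumes must share dimensions", call. = FALSE)
    Y <- vapply(volumes, as.numeric, numeric(prod(dims)))
  } else {
    d <- dim(volumes)
    dims <- d[1:3]
    Y <- matrix(volumes, prod(dims), d[4L])
  }
  nsub <- ncol(Y)
  if (length(covariate) != nsub)
    stop("covariate length must equal the number of subjects", call. = FALSE)
  if (nsub < 4L) stop("need >= 4 subjects", call. = FALSE)
  xc <- covariate - mean(covariate)
  sx <- sqrt(sum(xc^2))
  ym <- rowMeans(Y)
  yc <- Y - ym
  sy <- sqrt(rowSums(yc^2))
  r <- as.numeric(yc %*% xc) / (sy * sx)
  r[sy == 0] <- NA
  df <- nsub - 2L
  tval <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  p_vol <- array(p, dims)
  supra <- array(!is.na(p) & p < p_thresh, dims)
  lab <- label_components_3d(supra, connectivity = 6L)
  if (max(lab) == 0L) {
    return(list(p_volume = p_vol, cluster_map = lab,
                clusters = data.frame(cluster = integer(0), size = integer(0),
                                      peak_t = numeric(0), peak_x = integer(0),
                                      peak_y = integer(0), peak_z = integer(0))))
  }
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes > k_min)
  out_map <- array(0L, dims)
  rows <- list()
  for (new_id in seq_along(keep)) {
    old <- keep[new_id]
    vox <- which(lab == old)
    out_map[vox] <- new_id
    tv <- array(tval, dims)[vox]
    pk <- vox[which.max(abs(tv))]
    coord <- arrayInd(pk, dims)
    rows[[new_id]] <- data.frame(cluster = new_id, size = sizes[old],
                                 peak_t = tv[which.max(abs(tv))],
                                 peak_x = coord[1L], peak_y = coord[2L],
                                 peak_z = coord[3L])
  }
  list(p_volume = p_vol, cluster_map = out_map,
       clusters = if (length(rows)) do.call(rbind, rows) else
         data.frame(cluster = integer(0), size = integer(0),
                    peak_t = numeric(0), peak_x = integer(0),
                    peak_y = integer(0), peak_z = integer(0)))
}
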