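#' @title Layered cortical-surface sampling of PET signal
#' @description Builds surfaces systematically shifted from the GM/CSF
#'   boundary to below the GM/WM boundary, samples parcel-wise SUVR on each,
#'   and compares layers within subjects (repeated-measures ANOVA with
#'   Tukey-adjusted pairwise contrasts) and between groups (Cohen's d per
#'   parcel and layer).
#' @name cortical_layers
NULL

LAYER_NAMES <- c("GM/CSF boundary", "GM toward CSF", "GM toward WM",
                 "GM/WM boundary", "below GM/WM")

#' Build the five sampling surfaces of a cortical slab
#'
#' Default placement: layer 1 on the GM/CSF boundary, layers 2-3 at 25% and
#' 75% fractional cortical depth, layer 4 on the GM/WM boundary, layer 5
#' shifted `below_mm` (default 1 mm, about one PET voxel) into the white
#' matter. Supplying `offsets` instead places every surface at
#' `z_wm + offset` mm (so `offsets = rep(0, 5)` yields five copies of the
#' GM/WM boundary).
#'
#' @param slab a [gen_cortical_slab()] result (needs `z_csf`, `z_wm`,
#'   `voxel_size`).
#' @param depth_fractions fractional cortical depths of layers 1-4.
#' @param below_mm WM offset of layer 5 in mm.
#' @param offsets optional 5 signed offsets (mm) from the GM/WM boundary,
#'   overriding the fraction-based placement.
#' @return object of class `layer_surfaces`: a named list of 5 depth maps
#'   (mm, `nx x ny` matrices) plus the voxel size.
#' @export
build_layer_surfaces <- function(slab, depth_fractions = c(0, 0.25, 0.75, 1),
                                 below_mm = 1, offsets = NULL) {
  z_csf <- slab$z_csf; z_wm <- slab$z_wm
  thick <- z_wm - z_csf
  if (any(thick < slab$voxel_size))
    stop("cortical thickness below voxel size somewhere in the slab",
         call. = FALSE)
  if (!is.null(offsets)) {
    if (length(offsets) != 5L) stop("`offsets` must have 5 values", call. = FALSE)
    maps <- lapply(offsets, function(o) z_wm + o)
  } else {
    stopifnot(length(depth_fractions) == 4L)
    maps <- c(lapply(depth_fractions, function(f) z_csf + f * thick),
              list(z_wm + below_mm))
  }
  names(maps) <- LAYER_NAMES
  structure(c(maps, list(voxel_size = slab$voxel_size)),
            class = "layer_surfaces")
}

#' Sample layer-wise parcel SUVR profiles
#'
#' Trilinearly interpolates the PET volume at every (x, y) column's surface
#' depth for each of the five layers and averages within parcels.
#'
#' @param volume 3-D PET (SUVR) array, same grid as the slab.
#' @param surfaces a [build_layer_surfaces()] result.
#' @param parcels `nx x ny` integer parcel map (1..R).
#' @param subject subject identifier attached to the output.
#' @return data.frame (LayerProfile set): `subject`, `parcel`, `layer`
#'   (factor with the five layer names in anatomical order), `suvr`.
#'   Parcels with no vertices yield no rows.
#' @export
sample_layer_suvr <- function(volume, surfaces, parcels, subject = "s1") {
  stopifnot(inherits(surfaces, "layer_surfaces"))
  d <- dim(volume)
  nx <- d[1L]; ny <- d[2L]
  if (!identical(dim(parcels), c(nx, ny)))
    stop("parcel map and volume grids differ", call. = FALSE)
  vs <- surfaces$voxel_size
  xi <- rep(seq_len(nx), times = ny)
  yi <- rep(seq_len(ny), each = nx)
  pid <- as.integer(parcels)
  rows <- lapply(seq_along(LAYER_NAMES), function(li) {
    zmap <- surfaces[[LAYER_NAMES[li]]]
    # depth (mm) -> continuous voxel-center coordinate along axis 3
    zc <- as.numeric(zmap) / vs + 0.5
    vals <- trilinear(volume, xi, yi, zc)
    means <- tapply(vals, pid, mean)
    data.frame(subject = subject, parcel = as.integer(names(means)),
               layer = LAYER_NAMES[li], suvr = as.numeric(means),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$layer <- factor(out$layer, levels = LAYER_NAMES)
  out[order(out$parcel, out$layer), ]
}

# subject x layer matrix of parcel-mean SUVR
profile_matrix <- function(profiles) {
  m <- tapply(profiles$suvr,
              list(as.character(profiles$subject),
                   as.character(profiles$layer)),
              mean)
  miss <- setdiff(LAYER_NAMES, colnames(m))
  if (length(miss))
    m <- cbind(m, matrix(NA_real_, nrow(m), length(miss),
                         dimnames = list(NULL, miss)))
  m[, LAYER_NAMES, drop = FALSE]
}

#' Compare layers within one group
#'
#' One-way repeated-measures ANOVA of subject-level layer means (each
#' subject's parcels are averaged first), followed by Tukey-adjusted
#' pairwise contrasts of the layer estimated marginal means using the
#' studentized-range distribution on the within-subject error term. A
#' Greenhouse-Geisser-corrected p-value is reported alongside the
#' unadjusted F test.
#'
#' @param profiles LayerProfile data.frame from [sample_layer_suvr()]
#'   (rows from >= 3 subjects; every subject must have all 5 layers).
#' @return object of class `layer_comparison`: `anova` (data.frame with F,
#'   df, p, `p_gg`, epsilon), `emmeans` (layer means), `contrasts`
#'   (data.frame of all 10 layer pairs with difference, studentized-range
#'   q and Tukey-adjusted p), `n_subjects`.
#' @export
compare_layers <- function(profiles) {
  m <- profile_matrix(profiles)
  if (any(is.na(m))) {
    bad <- rownames(m)[apply(m, 1L, anyNA)]
    stop("missing layers for subjects: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 3L) stop("need >= 3 subjects", call. = FALSE)
  grand <- mean(m)
  layer_means <- colMeans(m)
  subj_means <- rowMeans(m)
  ss_layer <- n * sum((layer_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_layer - ss_subj
  df1 <- k - 1L; df2 <- (n - 1L) * (k - 1L)
  ms_layer <- ss_layer / df1
  ms_err <- ss_err / df2
  if (ms_layer == 0 && ms_err == 0) {
    Fval <- 0; p <- 1; eps <- 1; p_gg <- 1
  } else if (ms_err == 0) {
    Fval <- Inf; p <- 0; eps <- 1; p_gg <- 0
  } else {
    Fval <- ms_layer / ms_err
    p <- stats::pf(Fval, df1, df2, lower.tail = FALSE)
    # Greenhouse-Geisser epsilon from the double-centered covariance matrix
    S <- stats::cov(m)
    Sc <- S - outer(rowMeans(S), colMeans(S), `+`) + mean(S)
    eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
    eps <- min(max(eps, 1 / (k - 1)), 1)
    p_gg <- stats::pf(Fval, df1 * eps, df2 * eps, lower.tail = FALSE)
  }
  pairs <- utils::combn(k, 2L)
  se_d <- sqrt(2 * ms_err / n)
  contrasts <- data.frame(
    layer_a = colnames(m)[pairs[1L, ]],
    layer_b = colnames(m)[pairs[2L, ]],
    difference = layer_means[pairs[1L, ]] - layer_means[pairs[2L, ]],
    stringsAsFactors = FALSE)
  if (ms_err == 0) {
    contrasts$q <- ifelse(contrasts$difference == 0, 0, Inf)
    contrasts$p_tukey <- ifelse(contrasts$difference == 0, 1, 0)
  } else {
    contrasts$q <- abs(contrasts$difference) / sqrt(ms_err / n)
    contrasts$p_tukey <- stats::ptukey(contrasts$q, k, df2, lower.tail = FALSE)
  }
  rownames(contrasts) <- NULL
  structure(list(
    anova = data.frame(F = Fval, df1 = df1, df2 = df2, p = p,
                       gg_epsilon = eps, p_gg = p_gg),
    emmeans = data.frame(layer = colnames(m), mean = unname(layer_means),
                         se = unname(apply(m, 2L, stats::sd)) / sqrt(n),
                         stringsAsFactors = FALSE),
    contrasts = contrasts,
    n_subjects = n), class = "layer_comparison")
}

#' @export
print.layer_comparison <- function(x, ...) {
  a <- x$anova
  cat(sprintf(
    "<layer_comparison> n = %d subjects; F(%d, %d) = %.2f, p = %.3g (GG p = %.3g)\n",
    x$n_subjects, a$df1, a$df2, a$F, a$p, a$p_gg))
  sig <- x$contrasts[x$contrasts$p_tukey < 0.05, , drop = FALSE]
  cat(sprintf("  %d/%d Tukey-adjusted contrasts with p < 0.05\n",
              nrow(sig), nrow(x$contrasts)))
  invisible(x)
}

#' Per-parcel, per-layer group effect sizes
#'
#' Cohen's d (patients minus controls) for each (parcel, layer) cell,
#' computed over subject-level parcel values, plus a per-layer mean-d
#' summary naming the layer with the largest mean effect size.
#'
#' @param patients,controls LayerProfile data.frames from
#'   [sample_layer_suvr()] for the two groups.
#' @return object of class `layer_effect_sizes`: `d` (data.frame: `parcel`,
#'   `layer`, `d`; `NA` where the pooled SD is zero), `by_layer` (mean d
#'   per layer), `max_layer` (name of the layer maximizing mean d).
#' @export
layer_effect_sizes <- function(patients, controls) {
  if (nrow(patients) == 0L || nrow(controls) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  cells <- unique(patients[, c("parcel", "layer")])
  d_of <- function(parcel, layer) {
    a <- patients$suvr[patients$parcel == parcel & patients$layer == layer]
    b <- controls$suvr[controls$parcel == parcel & controls$layer == layer]
    if (length(a) < 2L || length(b) < 2L) return(NA_real_)
    suppressWarnings(cohens_d(a, b))
  }
  cells$d <- mapply(d_of, cells$parcel, cells$layer)
  by_layer <- stats::aggregate(d ~ layer, data = cells, FUN = mean,
                               na.action = stats::na.omit)
  by_layer <- by_layer[match(LAYER_NAMES, by_layer$layer), ]
  structure(list(d = cells, by_layer = by_layer,
                 max_layer = as.character(
                   by_layer$layer[which.max(by_layer$d)])),
            class = "layer_effect_sizes")
}

#' @export
print.layer_effect_sizes <- function(x, ...) {
  cat("<layer_effect_sizes> mean Cohen's d by layer:\n")
  print(x$by_layer, row.names = FALSE)
  cat("  maximal at:", x$max_layer, "\n")
  invisible(x)
}
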