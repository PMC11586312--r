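#' Stain-intensity image
#'
#' Light container for a 2-D single-channel intensity raster with a physical
#' pixel size, the substrate of all histology-side operations. Pixels are
#' stored as a numeric matrix in row-major display convention: row 1 is the
#' top of the image, and the pixel at matrix position `(i, j)` has its
#' *center* at continuous coordinates `(x, y) = (j - 0.5, i - 0.5)` in pixel
#' units (0-based, origin at the top-left image corner). ROI polygons use the
#' same coordinate frame.
#'
#' @param pixels numeric matrix of non-negative, finite intensities (a.u.).
#' @param pixel_size physical pixel edge length, micrometres per pixel
#'   (must be `> 0`).
#' @param stain stain label, one of `"AT8"`, `"GFAP"`, `"MAP2"`, `"ARG"`.
#' @return An object of class `stain_image`: a list with elements `pixels`,
#'   `pixel_size` and `stain`.
#' @examples
#' img <- stain_image(matrix(0, 64, 64), pixel_size = 1)
#' dim(img)
#' @export
stain_image <- function(pixels, pixel_size, stain = c("AT8", "GFAP", "MAP2", "ARG")) {
  stain <- match.arg(stain)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (µm/px)", call. = FALSE)
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("`pixels` must be finite", call. = FALSE)
  structure(list(pixels = pixels, pixel_size = pixel_size, stain = stain),
            class = "stain_image")
}

#' @export
dim.stain_image <- function(x) dim(x$pixels)

#' @export
print.stain_image <- function(x, ...) {
  cat(sprintf("<stain_image> %s, %d x %d px @ %.3g µm/px, range [%.3g, %.3g]\n",
              x$stain, nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

as_stain_image <- function(x, pixel_size = 1, stain = "AT8") {
  if (inherits(x, "stain_image")) return(x)
  stain_image(x, pixel_size = pixel_size, stain = stain)
}

#' Write / read a stain image as plain text
#'
#' Round-trips a [stain_image()] through a tab-separated pixel table plus a
#' JSON sidecar (`<path>.json`) carrying the pixel size and stain label.
#' Plain text stands in for the usual single-channel 16-bit TIFF container,
#' which has no reader in the supported dependency set.
#'
#' @param image a `stain_image`.
#' @param path file path for the TSV pixel table.
#' @return `write_stain_image` returns `path` invisibly; `read_stain_image`
#'   returns a `stain_image`.
#' @export
write_stain_image <- function(image, path) {
  stopifnot(inherits(image, "stain_image"))
  utils::write.table(image$pixels, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(pixel_size = image$pixel_size, stain = image$stain),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stain_image
#' @export
read_stain_image <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(px) <- NULL
  stain_image(px, pixel_size = meta$pixel_size, stain = meta$stain)
}

#' Polygonal region of interest
#'
#' @param x,y polygon vertex coordinates in pixel units (image frame of
#'   [stain_image()]; the polygon is closed implicitly).
#' @param id subfield identifier.
#' @param label anatomical region label (e.g. `"cortical"` or
#'   `"GM/WM boundary"`); carried through to quantification outputs.
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(x, y, id = "roi", label = NA_character_) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("a polygon needs >= 3 vertices", call. = FALSE)
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 id = id, label = label), class = "roi_polygon")
}

#' Rectangle ROI convenience constructor
#'
#' @param x0,y0,x1,y1 rectangle corners in pixel units.
#' @inheritParams roi_polygon
#' @export
roi_rect <- function(x0, y0, x1, y1, id = "roi", label = NA_character_) {
  roi_polygon(c(x0, x1, x1, x0), c(y0, y0, y1, y1), id = id, label = label)
}

# Even-odd ray-casting point-in-polygon test, vectorised over points.
points_in_polygon <- function(px, py, poly) {
  vx <- poly$x; vy <- poly$y
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Logical membership matrix: TRUE where the pixel center falls inside `roi`.
roi_mask <- function(roi, dims) {
  nr <- dims[1L]; nc <- dims[2L]
  cx <- rep(seq_len(nc) - 0.5, each = nr)
  cy <- rep(seq_len(nr) - 0.5, times = nc)
  matrix(points_in_polygon(cx, cy, roi), nr, nc)
}

#' Otsu intensity threshold
#'
#' Maximizes the between-class variance of the intensity histogram; used as
#' the default segmentation threshold when no fixed threshold is supplied.
#'
#' @param values numeric vector (or matrix) of intensities.
#' @param nbins number of histogram bins.
#' @return threshold value on the intensity scale; pixels `>=` threshold are
#'   foreground.
#' @export
otsu_threshold <- function(values, nbins = 256L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1L])
  breaks <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1L] + breaks[-(nbins + 1L)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  # midpoint of the maximizing plateau (empty histogram gaps tie)
  ties <- which(sigma_b >= max(sigma_b) - 1e-12 * abs(max(sigma_b)))
  k <- ties[ceiling(length(ties) / 2)]
  breaks[k + 1L]
}

# --- connected components ----------------------------------------------------

# 2-D connected-component labelling by vectorised minimum-label propagation.
# connectivity: 8 (default) or 4. Returns an integer matrix; background 0,
# components labelled 1..K in order of their smallest linear index
# (deterministic).
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  mask <- mask & !is.na(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  if (!any(mask)) return(matrix(0L, nr, nc))
  lab <- matrix(Inf, nr + 2L, nc + 2L)
  core_i <- 2L:(nr + 1L); core_j <- 2L:(nc + 1L)
  m <- matrix(FALSE, nr + 2L, nc + 2L)
  m[core_i, core_j] <- mask
  idx <- which(m)
  lab[idx] <- idx
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  ir <- seq_len(nr + 2L); jc <- seq_len(nc + 2L)
  repeat {
    new <- lab
    for (s in shifts) {
      sh <- lab[pmin(pmax(ir - s[1L], 1L), nr + 2L),
                pmin(pmax(jc - s[2L], 1L), nc + 2L)]
      new <- pmin(new, sh)
    }
    new[!m] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  roots <- lab[idx]
  out <- matrix(0L, nr + 2L, nc + 2L)
  out[idx] <- match(roots, sort(unique(roots)))
  out[core_i, core_j, drop = FALSE]
}

# 3-D connected components, 6- or 26-connectivity, same propagation scheme.
label_components_3d <- function(mask, connectivity = 6L) {
  stopifnot(length(dim(mask)) == 3L)
  d <- dim(mask)
  if (!any(mask)) return(array(0L, d))
  dp <- d + 2L
  m <- array(FALSE, dp)
  m[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  lab <- array(Inf, dp)
  idx <- which(m)
  lab[idx] <- idx
  if (connectivity == 6L) {
    shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    shifts <- list()
    for (a in -1:1) for (b in -1:1) for (cc in -1:1)
      if (!(a == 0 && b == 0 && cc == 0)) shifts <- c(shifts, list(c(a, b, cc)))
  }
  i1 <- seq_len(dp[1]); i2 <- seq_len(dp[2]); i3 <- seq_len(dp[3])
  repeat {
    new <- lab
    for (s in shifts) {
      sh <- lab[pmin(pmax(i1 - s[1], 1L), dp[1]),
                pmin(pmax(i2 - s[2], 1L), dp[2]),
                pmin(pmax(i3 - s[3], 1L), dp[3]), drop = FALSE]
      new <- pmin(new, sh)
    }
    new[!m] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  roots <- lab[idx]
  out <- array(0L, dp)
  out[idx] <- match(roots, sort(unique(roots)))
  out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

# Trilinear interpolation of a 3-D array at continuous voxel-center
# coordinates (1-based, i.e. the value at integer (i,j,k) is vol[i,j,k]).
# Coordinates outside the grid are clamped to the boundary.
trilinear <- function(vol, i, j, k) {
  d <- dim(vol)
  i <- pmin(pmax(i, 1), d[1]); j <- pmin(pmax(j, 1), d[2]); k <- pmin(pmax(k, 1), d[3])
  i0 <- pmin(floor(i), d[1] - 1L); j0 <- pmin(floor(j), d[2] - 1L)
  k0 <- pmin(floor(k), d[3] - 1L)
  if (d[1] == 1L) i0 <- rep(1, length(i))
  if (d[2] == 1L) j0 <- rep(1, length(j))
  if (d[3] == 1L) k0 <- rep(1, length(k))
  fi <- i - i0; fj <- j - j0; fk <- k - k0
  at <- function(a, b, cc) vol[cbind(a, b, cc)]
  i1 <- pmin(i0 + 1L, d[1]); j1 <- pmin(j0 + 1L, d[2]); k1 <- pmin(k0 + 1L, d[3])
  c000 <- at(i0, j0, k0); c100 <- at(i1, j0, k0)
  c010 <- at(i0, j1, k0); c110 <- at(i1, j1, k0)
  c001 <- at(i0, j0, k1); c101 <- at(i1, j0, k1)
  c011 <- at(i0, j1, k1); c111 <- at(i1, j1, k1)
  c00 <- c000 * (1 - fi) + c100 * fi
  c10 <- c010 * (1 - fi) + c110 * fi
  c01 <- c001 * (1 - fi) + c101 * fi
  c11 <- c011 * (1 - fi) + c111 * fi
  c0 <- c00 * (1 - fj) + c10 * fj
  c1 <- c01 * (1 - fj) + c11 * fj
  c0 * (1 - fk) + c1 * fk
}
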