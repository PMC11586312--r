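#' @title Autoradiography binding ratios and the correlation battery
#' @description Subfield binding ratios against an AT8-negative white-matter
#'   reference, pooled and per-subject correlations between cell-type tau
#'   abundance and binding, partial correlation with region cofactors, and
#'   the two-predictor standardized regression.
#' @name autorad_quant
NULL

#' Autoradiography binding ratio of a subfield
#'
#' Ratio of ROI mean intensities between a target subfield and an
#' AT8-negative white-matter reference region on the same section. ROI
#' membership uses the shared pixel-center-in-polygon rule, so subfields
#' drawn on the adjacent AT8 section transfer directly.
#'
#' @param image an autoradiography [stain_image()].
#' @param target,reference [roi_polygon()]s intersecting the image.
#' @return one-row data.frame: `subfield`, `label` (the target ROI's region
#'   tag, e.g. cortical vs GM/WM boundary), `target_mean`,
#'   `reference_mean`, `ratio`.
#' @export
binding_ratio <- function(image, target, reference) {
  stopifnot(inherits(image, "stain_image"))
  tm <- roi_mask(target, dim(image$pixels))
  rm_ <- roi_mask(reference, dim(image$pixels))
  if (!any(tm)) stop("target ROI lies outside the image", call. = FALSE)
  if (!any(rm_)) stop("reference ROI lies outside the image", call. = FALSE)
  ref_mean <- mean(image$pixels[rm_])
  if (ref_mean <= 0)
    stop("reference mean must be positive", call. = FALSE)
  tgt_mean <- mean(image$pixels[tm])
  data.frame(subfield = target$id, label = target$label,
             target_mean = tgt_mean, reference_mean = ref_mean,
             ratio = tgt_mean / ref_mean, stringsAsFactors = FALSE)
}

new_correlation_result <- function(estimate, n, p, covariates = character(0),
                                   note = NA_character_) {
  structure(list(estimate = estimate, n = n, p = p,
                 covariates = covariates, note = note),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cov <- if (length(x$covariates)) paste0(" | ", paste(x$covariates, collapse = ", "))
         else ""
  cat(sprintf("<correlation_result> r = %.3f (n = %d, p = %.3g)%s\n",
              x$estimate, x$n, x$p, cov))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Pooled subfield correlation
#'
#' Pearson correlation between a channel's AT8 abundance and the matched
#' autoradiography binding ratio over subfields pooled across subjects (the
#' pooled n = 129 design). Residual normality is checked by a
#' Kolmogorov-Smirnov test on the simple-regression residuals and reported,
#' not enforced.
#'
#' @param abundance per-subfield AT8 area-% (or intensity) values.
#' @param ratio matched binding ratios.
#' @return a `correlation_result` (estimate, n, two-sided p) with the KS
#'   p-value in `note`; zero variance in either variable flags the estimate
#'   as undefined (`NA`).
#' @export
pooled_subfield_correlation <- function(abundance, ratio) {
  ok <- stats::complete.cases(abundance, ratio)
  x <- abundance[ok]; y <- ratio[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete subfield pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(new_correlation_result(NA_real_, n, NA_real_,
                                  note = "zero variance: correlation undefined"))
  ct <- stats::cor.test(x, y, method = "pearson")
  res <- stats::residuals(stats::lm(y ~ x))
  ks <- suppressWarnings(
    stats::ks.test(scale(res), "pnorm"))
  new_correlation_result(unname(ct$estimate), n, ct$p.value,
                         note = sprintf("KS normality of residuals p = %.3f",
                                        ks$p.value))
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after linear removal
#' of the covariates (with intercept) from both; the p-value uses the
#' t-transform with `n - 2 - k` degrees of freedom, `k` the number of
#' covariate columns. With no (or constant) covariates this reduces exactly
#' to the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates `NULL`, a numeric vector, matrix, or data.frame of
#'   covariates (e.g. a region indicator); must be full rank after adding
#'   the intercept.
#' @return a `correlation_result` with the controlled covariates listed.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates)) {
    Z <- matrix(1, n, 1L)
    k <- 0L
    cov_names <- character(0)
  } else {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    cov_names <- colnames(cv)
    # drop constant columns (they carry no information beyond the intercept)
    keep <- apply(cv, 2L, function(col) stats::sd(col) > 0)
    cv <- cv[, keep, drop = FALSE]
    Z <- cbind(1, cv)
    k <- ncol(cv)
    if (qr(Z)$rank < ncol(Z))
      stop("covariate matrix is rank deficient", call. = FALSE)
  }
  if (n < k + 4L) stop("need n >= 4 + number of covariates", call. = FALSE)
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(new_correlation_result(NA_real_, n, NA_real_, cov_names,
                                  "zero residual variance"))
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  new_correlation_result(r, n, p, cov_names)
}

#' Two-predictor standardized regression on subfield records
#'
#' Ordinary least squares of the binding ratio on the two channel
#' abundances after z-scoring all variables, reported in the fixed
#' predictor order (NFT/CB first, TA/TF second): standardized beta and p
#' per predictor plus the model R².
#'
#' @param nftcb,tatf per-subfield abundances of the two channels.
#' @param ratio matched binding ratios (outcome).
#' @return object of class `regression_result`: `coefficients` (data.frame
#'   with `predictor`, `beta`, `p`), `r_squared`, `n`.
#' @export
celltype_regression <- function(nftcb, tatf, ratio) {
  ok <- stats::complete.cases(nftcb, tatf, ratio)
  x1 <- nftcb[ok]; x2 <- tatf[ok]; y <- ratio[ok]
  n <- length(y)
  if (n < 4L) stop("need n > predictors + 1", call. = FALSE)
  if (abs(stats::cor(x1, x2)) >= 1 - 1e-12)
    stop("collinear predictors (|r| = 1)", call. = FALSE)
  z <- function(v) (v - mean(v)) / stats::sd(v)
  fit <- stats::lm(z(y) ~ z(x1) + z(x2))
  sm <- summary(fit)
  structure(list(
    coefficients = data.frame(
      predictor = c("NFT/CB", "TA/TF"),
      beta = unname(stats::coef(fit)[2:3]),
      se = unname(sm$coefficients[2:3, 2L]),
      p = unname(sm$coefficients[2:3, 4L]),
      stringsAsFactors = FALSE),
    r_squared = sm$r.squared, n = n), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> n = %d, R² = %.3f\n", x$n, x$r_squared))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Within-subject correlations as a function of overall tau abundance
#'
#' For each subject, correlates a channel's subfield abundances with the
#' matched binding ratios (requires >= 3 subfields; subjects with undefined
#' correlations — e.g. zero tau in all subfields — are flagged and excluded
#' from the relation fit). Across subjects, the within-subject r is then
#' related to the subject's mean abundance (linear fit), and a
#' sensitivity-threshold summary reports the smallest mean abundance above
#' which every subject's within-subject r exceeds `r_cut`. The default
#' reporting threshold of 0.2 area-% marks the abundance above which
#' dense-tau subfield correlations become reliably strong.
#'
#' @param subject subject identifier per record.
#' @param abundance per-subfield channel area-%.
#' @param ratio matched binding ratios.
#' @param r_cut within-subject correlation cut for the sensitivity summary.
#' @param abundance_threshold reporting threshold on the mean abundance
#'   (area-%, default 0.2).
#' @return list with `per_subject` (data.frame: `subject`, `n_subfields`,
#'   `mean_abundance`, `r`, `included`, `above_threshold`), `relation` (a
#'   `correlation_result` of r vs mean abundance across subjects),
#'   `sensitivity_threshold` (smallest mean abundance above which all
#'   within-subject r > `r_cut`; `NA` when never achieved), and the
#'   parameters used.
#' @export
per_subject_correlation_vs_abundance <- function(subject, abundance, ratio,
                                                 r_cut = 0.5,
                                                 abundance_threshold = 0.2) {
  df <- data.frame(subject = subject, abundance = abundance, ratio = ratio)
  per <- do.call(rbind, lapply(split(df, df$subject), function(d) {
    r <- if (nrow(d) >= 3L && stats::sd(d$abundance) > 0 &&
             stats::sd(d$ratio) > 0)
      stats::cor(d$abundance, d$ratio) else NA_real_
    data.frame(subject = d$subject[1L], n_subfields = nrow(d),
               mean_abundance = mean(d$abundance), r = r,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  per$included <- !is.na(per$r)
  per$above_threshold <- per$mean_abundance > abundance_threshold
  inc <- per[per$included, , drop = FALSE]
  relation <- if (nrow(inc) >= 3L && stats::sd(inc$mean_abundance) > 0 &&
                  stats::sd(inc$r) > 0) {
    ct <- stats::cor.test(inc$mean_abundance, inc$r)
    new_correlation_result(unname(ct$estimate), nrow(inc), ct$p.value)
  } else new_correlation_result(NA_real_, nrow(inc), NA_real_,
                                note = "too few subjects for relation fit")
  ord <- inc[order(inc$mean_abundance), , drop = FALSE]
  sens <- NA_real_
  if (nrow(ord)) {
    ok_from <- rev(cumprod(rev(ord$r > r_cut))) == 1
    if (any(ok_from)) sens <- ord$mean_abundance[which(ok_from)[1L]]
  }
  list(per_subject = per, relation = relation,
       sensitivity_threshold = sens,
       r_cut = r_cut, abundance_threshold = abundance_threshold)
}

#' Lesion intensity vs occupancy as binding predictors
#'
#' Side-by-side Pearson correlations of the AT8 signal intensity and the
#' AT8 occupancy (area-%) against the autoradiography binding ratio over
#' the subfields of one subject (basal-ganglia style analysis, works from
#' n = 3 subfields up).
#'
#' @param intensity per-subfield AT8 mean intensity.
#' @param area_pct per-subfield AT8 area-%.
#' @param ratio matched binding ratios.
#' @return list with `intensity` and `occupancy`, each a
#'   `correlation_result`.
#' @export
intensity_vs_occupancy <- function(intensity, area_pct, ratio) {
  one <- function(x, label) {
    ok <- stats::complete.cases(x, ratio)
    if (sum(ok) < 3L) stop("need >= 3 subfields", call. = FALSE)
    if (stats::sd(x[ok]) == 0 || stats::sd(ratio[ok]) == 0)
      return(new_correlation_result(NA_real_, sum(ok), NA_real_,
                                    note = paste0(label, ": zero variance")))
    ct <- stats::cor.test(x[ok], ratio[ok])
    new_correlation_result(unname(ct$estimate), sum(ok), ct$p.value)
  }
  list(intensity = one(intensity, "intensity"),
       occupancy = one(area_pct, "occupancy"))
}
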