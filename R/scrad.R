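#' @title Single-cell radiotracing arithmetic
#' @description Decay correction, per-cell tracer uptake, %ID*BW
#'   normalization, signal-to-background QC, pellet purity, and the
#'   cell-count extrapolation linking cellular radioactivity to the PET
#'   signal increment over the wild-type background.
#' @name scrad
NULL

#' Decay-correct an activity to injection time
#'
#' `bq * 2^(dt / half_life)` — the measured pellet activity scaled back to
#' the time of tracer injection (F-18 half-life 109.77 min by default; the
#' sorting procedure runs 6-7 h, so corrections of ~10x are routine).
#'
#' @param bq measured activity in Bq (vectorized).
#' @param dt_min minutes elapsed from injection to measurement (>= 0).
#' @param half_life isotope half-life in minutes (> 0).
#' @return activity at injection time, Bq.
#' @export
decay_correct <- function(bq, dt_min, half_life = F18_HALF_LIFE_MIN) {
  if (any(dt_min < 0)) stop("elapsed time must be >= 0", call. = FALSE)
  if (half_life <= 0) stop("half-life must be > 0", call. = FALSE)
  bq * 2^(dt_min / half_life)
}

#' Radioactivity per cell
#'
#' Decay-corrected pellet activity divided by the flow-cytometry cell count.
#'
#' @param measured_bq pellet activity at measurement time (Bq).
#' @param cell_count cells in the pellet (> 0).
#' @param offset_min minutes from injection to measurement.
#' @param half_life isotope half-life (minutes).
#' @return Bq per cell at injection time (vectorized).
#' @export
per_cell_uptake <- function(measured_bq, cell_count, offset_min = 0,
                            half_life = F18_HALF_LIFE_MIN) {
  if (any(cell_count <= 0)) stop("cell count must be > 0", call. = FALSE)
  decay_correct(measured_bq, offset_min, half_life) / cell_count
}

#' Normalize per-cell uptake to injected dose and body weight
#'
#' `%ID*BW = (Bq_per_cell / injected_dose_Bq) * 100 * body_weight_g`. The
#' dose is accepted in MBq at the interface and converted internally; the
#' formula is the conventional reading of the %ID*BW label.
#'
#' @param bq_per_cell Bq per cell.
#' @param injected_dose_mbq injected dose in MBq (> 0).
#' @param body_weight_g body weight in grams (> 0).
#' @return %ID*BW per cell (vectorized).
#' @export
normalize_pidbw <- function(bq_per_cell, injected_dose_mbq, body_weight_g) {
  if (any(injected_dose_mbq <= 0)) stop("dose must be > 0", call. = FALSE)
  if (any(body_weight_g <= 0)) stop("body weight must be > 0", call. = FALSE)
  (bq_per_cell / (injected_dose_mbq * 1e6)) * 100 * body_weight_g
}

#' Signal-to-background quality control
#'
#' A pellet measurement is valid only when its radioactivity is at least
#' twice the background measurement.
#'
#' @param pellet_bq pellet activity (Bq).
#' @param background_bq background activity (Bq, > 0).
#' @param min_ratio acceptance threshold (default 2).
#' @return data.frame with `ratio`, `pass`, and `reason` (`NA` when
#'   passing).
#' @export
qc_signal_to_background <- function(pellet_bq, background_bq, min_ratio = 2) {
  if (any(background_bq <= 0)) stop("background must be > 0", call. = FALSE)
  ratio <- pellet_bq / background_bq
  pass <- ratio >= min_ratio
  data.frame(ratio = ratio, pass = pass,
             reason = ifelse(pass, NA_character_,
                             sprintf("signal/background %.3f < %.1f",
                                     ratio, min_ratio)),
             stringsAsFactors = FALSE)
}

#' Cell-pellet purity
#'
#' Neuron mode: the CD11b-/ACSA-2-negative fraction,
#' `(total - cd11b_pos - acsa2_pos) / total`. Astrocyte mode: the ACSA-2
#' positive fraction, `acsa2_pos / total`. The conventional acceptance
#' threshold (purity > 0.85) is attached as an attribute.
#'
#' @param total total cells in the pellet.
#' @param cd11b_pos CD11b-positive (microglial) cells.
#' @param acsa2_pos ACSA-2-positive (astrocytic) cells.
#' @param mode `"neuron"` or `"astrocyte"`.
#' @param acceptance acceptance threshold attached to the result.
#' @return purity fraction in `[0, 1]` with attribute `acceptance`.
#' @export
pellet_purity <- function(total, cd11b_pos = 0, acsa2_pos = 0,
                          mode = c("neuron", "astrocyte"), acceptance = 0.85) {
  mode <- match.arg(mode)
  if (any(cd11b_pos + acsa2_pos > total))
    stop("marker-positive counts exceed total cells", call. = FALSE)
  p <- if (mode == "neuron") (total - cd11b_pos - acsa2_pos) / total
       else acsa2_pos / total
  structure(p, acceptance = acceptance)
}

#' Brain cell census
#'
#' Published whole-brain cell numbers used as the cell-type abundance
#' surrogate in the extrapolation: 71 million neurons, 21 million
#' astrocytes.
#'
#' @param neurons,astrocytes positive cell counts.
#' @export
brain_cell_census <- function(neurons = 71e6, astrocytes = 21e6) {
  if (neurons <= 0 || astrocytes <= 0)
    stop("census counts must be positive", call. = FALSE)
  list(neurons = neurons, astrocytes = astrocytes)
}

#' Extrapolate cellular uptake to the brain-level PET increment
#'
#' Multiplies each mouse's per-cell tracer uptake by the brain cell census
#' and compares the predicted brain radioactivity with the mouse's PET
#' signal increment over the wild-type mean:
#' `predicted_i = N_neuron * u_neuron_i + N_astro * u_astro_i`. Cohort sums
#' are reported (the summed comparison minimizes per-animal census and
#' methodology variance), together with a paired t-test between predicted
#' and PET increments across mice.
#'
#' @param uptake data.frame with columns `mouse`, `bq_per_neuron`,
#'   `bq_per_astrocyte` (Bq per cell, decay-corrected).
#' @param pet_increments named numeric vector (names = mouse IDs) or
#'   data.frame with `mouse` and `pet_increment_bq`: per-mouse PET
#'   radioactivity increment over the WT mean, Bq.
#' @param census a [brain_cell_census()].
#' @return object of class `extrapolation_result`: `per_mouse` (data.frame
#'   with predicted, increment and residual), `sum_predicted_bq`,
#'   `sum_pet_bq`, `paired_t`, `p_value`, `n`.
#' @export
extrapolate_brain_signal <- function(uptake, pet_increments,
                                     census = brain_cell_census()) {
  if (is.data.frame(pet_increments)) {
    pet <- stats::setNames(pet_increments$pet_increment_bq,
                           pet_increments$mouse)
  } else pet <- pet_increments
  if (!setequal(uptake$mouse, names(pet)))
    stop("mouse sets of uptake table and PET increments differ", call. = FALSE)
  if (nrow(uptake) < 2L)
    stop("need >= 2 mice with complete data", call. = FALSE)
  pet <- pet[uptake$mouse]
  predicted <- census$neurons * uptake$bq_per_neuron +
    census$astrocytes * uptake$bq_per_astrocyte
  diffs <- predicted - pet
  n <- length(diffs)
  if (stats::sd(diffs) < 1e-12 * max(abs(predicted), 1)) {
    tstat <- 0; pval <- 1
  } else {
    tt <- stats::t.test(predicted, pet, paired = TRUE)
    tstat <- unname(tt$statistic); pval <- tt$p.value
  }
  structure(list(
    per_mouse = data.frame(mouse = uptake$mouse,
                           predicted_bq = predicted,
                           pet_increment_bq = unname(pet),
                           residual_bq = diffs,
                           stringsAsFactors = FALSE),
    sum_predicted_bq = sum(predicted),
    sum_pet_bq = sum(pet),
    paired_t = tstat, p_value = pval, n = n),
    class = "extrapolation_result")
}

#' @export
print.extrapolation_result <- function(x, ...) {
  cat(sprintf(
    "<extrapolation_result> n = %d mice\n  sum predicted %.0f Bq vs sum PET increment %.0f Bq\n  paired t = %.3f, p = %.3g\n",
    x$n, x$sum_predicted_bq, x$sum_pet_bq, x$paired_t, x$p_value))
  invisible(x)
}

#' Run the full scRadiotracing pipeline on a pellet table
#'
#' Applies signal-to-background QC, computes decay-corrected per-cell
#' uptake and %ID*BW per pellet, aggregates per mouse, and (for transgenic
#' mice with PET increments available) runs the brain-signal extrapolation.
#'
#' @param pellets data.frame as produced by [gen_scrad_cohort()] (one row
#'   per pellet; see its documentation for column names).
#' @param pet_increments per-mouse PET increments (Bq) for the mice to
#'   extrapolate; `NULL` skips the extrapolation.
#' @param census a [brain_cell_census()].
#' @param min_ratio QC threshold passed to [qc_signal_to_background()].
#' @return list with `pellets` (augmented with `bq_per_cell`, `pidbw`,
#'   `qc_pass`, `purity`), `excluded` (failing pellets with reasons),
#'   `per_mouse` (wide per-mouse uptake table), and `extrapolation` when
#'   increments were given.
#' @export
scrad_pipeline <- function(pellets, pet_increments = NULL,
                           census = brain_cell_census(), min_ratio = 2) {
  qc <- qc_signal_to_background(pellets$measured_bq, pellets$background_bq,
                                min_ratio)
  pellets$qc_pass <- qc$pass
  pellets$qc_reason <- qc$reason
  pellets$bq_per_cell <- per_cell_uptake(pellets$measured_bq,
                                         pellets$cell_count,
                                         pellets$offset_min)
  pellets$pidbw <- normalize_pidbw(pellets$bq_per_cell,
                                   pellets$injected_dose_mbq,
                                   pellets$body_weight_g)
  pellets$purity <- ifelse(
    pellets$cell_type == "neuron",
    pellet_purity(pellets$total_cells, pellets$cd11b_pos, pellets$acsa2_pos,
                  "neuron"),
    pellet_purity(pellets$total_cells, acsa2_pos = pellets$acsa2_pos,
                  mode = "astrocyte"))
  kept <- pellets[pellets$qc_pass, , drop = FALSE]
  wide <- merge(
    stats::setNames(kept[kept$cell_type == "neuron",
                         c("mouse", "genotype", "bq_per_cell")],
                    c("mouse", "genotype", "bq_per_neuron")),
    stats::setNames(kept[kept$cell_type == "astrocyte",
                         c("mouse", "bq_per_cell")],
                    c("mouse", "bq_per_astrocyte")),
    by = "mouse")
  out <- list(pellets = pellets,
              excluded = pellets[!pellets$qc_pass, , drop = FALSE],
              per_mouse = wide)
  if (!is.null(pet_increments)) {
    if (is.data.frame(pet_increments))
      pet_increments <- stats::setNames(pet_increments$pet_increment_bq,
                                        pet_increments$mouse)
    mice <- intersect(wide$mouse, names(pet_increments))
    dropped <- setdiff(names(pet_increments), mice)
    if (length(dropped))
      message("extrapolation skips mice without complete cell data: ",
              paste(dropped, collapse = ", "))
    sub <- wide[wide$mouse %in% mice, , drop = FALSE]
    out$extrapolation <- extrapolate_brain_signal(sub, pet_increments[mice],
                                                  census)
  }
  out
}
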