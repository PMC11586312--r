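# Shared fixtures and independent oracles (kept deliberately naive: the
# oracles must not share code paths with the implementation).

# queue-based flood fill: independent connected-component counter/labeller
flood_fill_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8L)
    rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else rbind(c(-1,0), c(1,0), c(0,-1), c(0,1))
  current <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      i <- (v - 1L) %% nr + 1L; j <- (v - 1L) %/% nr + 1L
      for (t in seq_len(nrow(nb))) {
        ii <- i + nb[t, 1L]; jj <- j + nb[t, 2L]
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- current
          queue <- c(queue, (jj - 1L) * nr + ii)
        }
      }
    }
  }
  lab
}

# literal 4-direction Crofton perimeter by looping over scan lines
crofton_by_hand <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask)
  count_dir <- function(di, dj) {
    n <- 0L
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1L && ii <= nrow(m) && jj >= 1L && jj <= ncol(m) &&
          m[i, j] != m[ii, jj]) n <- n + 1L
    }
    n
  }
  (pi / 8) * (count_dir(0L, 1L) + count_dir(1L, 0L) +
              (count_dir(1L, 1L) + count_dir(1L, -1L)) / sqrt(2))
}

# binary disk raster, radius r px, centered
disk_mask <- function(n, r) {
  c0 <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(i, j) (i - c0)^2 + (j - c0)^2 <= r^2)
}

# closed-form one-tissue response to a mono-exponential input A*exp(-mu t)
analytic_1tcm_monoexp <- function(t, K1, k2, A, mu) {
  K1 * A * (exp(-mu * t) - exp(-k2 * t)) / (k2 - mu)
}

# match segmented objects back to planted ground truth by pixel overlap
match_truth_classes <- function(section, objects) {
  lab <- matrix(0L, nrow(section$image$pixels), ncol(section$image$pixels))
  for (k in seq_along(section$truth$pixels)) lab[section$truth$pixels[[k]]] <- k
  vapply(objects, function(o) {
    ks <- lab[o$pixels]; ks <- ks[ks > 0L]
    if (!length(ks)) return(NA_character_)
    as.character(section$truth$objects$class[
      as.integer(names(which.max(table(ks))))])
  }, character(1L))
}

# a classified generator scene: section + segmented objects + ground-truth
# channels + rules calibrated on a held-out exemplar section
make_classified_scene <- function(seed, n_test = c(NFT = 50, CB = 50, TA = 80, TF = 20),
                                  n_exemplars = 20L, expansion = 0.25) {
  sec <- gen_ihc_section(dims = c(768, 768), n_objects = n_test, seed = seed)
  objs <- segment_objects(sec$image, intensity_threshold = 0.2)
  gt <- match_truth_classes(sec, objs)
  ex <- gen_ihc_section(dims = c(768, 768),
                        n_objects = stats::setNames(rep(n_exemplars, 4),
                                                    c("NFT", "CB", "TA", "TF")),
                        seed = seed + 1000L)
  exo <- segment_objects(ex$image, intensity_threshold = 0.2)
  exc <- match_truth_classes(ex, exo)
  for (i in seq_along(exo)) exo[[i]]$class <- exc[i]
  rules <- calibrate_rules(exo[!is.na(exc)], expansion = expansion)
  list(section = sec, objects = classify_objects(objs, rules),
       truth_channel = ifelse(gt %in% c("NFT", "CB"), "NFT/CB", "TA/TF"),
       rules = rules)
}

# joined subfield/binding-ratio table from one synthetic subject section
make_subject_subfields <- function(seed, dims = c(256, 256), n_rois = 8L,
                                   coupling = c("NFT/CB" = 40, "TA/TF" = 8),
                                   noise_sd = 2,
                                   n_objects = c(NFT = 12, CB = 8, TA = 14, TF = 6)) {
  sec <- gen_ihc_section(dims = dims, n_objects = n_objects, seed = seed)
  arg <- gen_autorad_section(sec$truth, coupling = coupling,
                             noise_sd = noise_sd, seed = seed + 1L)
  nx <- dims[2L]; ny <- dims[1L]
  cols <- 4L; rows_n <- ceiling(n_rois / cols)
  w <- nx / cols; h <- (ny - 16) / rows_n
  ref <- roi_rect(2, ny - 12, nx - 2, ny - 2, id = "ref", label = "reference")
  out <- lapply(seq_len(n_rois), function(i) {
    cx <- (i - 1L) %% cols; cy <- (i - 1L) %/% cols
    r <- roi_rect(cx * w + 1, cy * h + 1, (cx + 1) * w - 1, (cy + 1) * h - 1,
                  id = sprintf("s%d_sf%d", seed, i), label = "cortical")
    rec <- quantify_subfield(
      sec$image,
      c(sec$truth$channel_masks, list(total = sec$truth$positive_mask)), r)
    br <- binding_ratio(arg, r, ref)
    cbind(rec, ratio = br$ratio, subject = paste0("s", seed))
  })
  do.call(rbind, out)
}
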