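#' Synthetic rib-cage phantom specification
#'
#' The phantom is a schematic thorax: each rib is a curved tube on an
#' ellipsoidal surface, parameterized by arc length from the spine, and
#' rasterized into a numbered label map (left ribs 1-12, right ribs
#' 13-24). Fracture centers are planted on rib centerlines with CWIS
#' labels sampled from configurable class frequencies; the location
#' label follows the arc-length convention (first third from the spine
#' posterior, middle third lateral, last third anterior) and a fracture
#' center is always placed inside the corresponding third. Ribs
#' carrying a displaced fracture can be split into two fragments that
#' share a label, emulating severely displaced fractures. Default class
#' frequencies mirror a blunt-trauma case mix in which simple and
#' undisplaced fractures dominate and complex fractures are rare.
#'
#' @param shape grid dimensions (default 128^3).
#' @param spacing voxel size in mm (default 2 mm isotropic).
#' @param n_rib_pairs 12 (default) or 11 — cages with 11 pairs occur.
#' @param rib_radius_mm tube radius of a rib (default 4 mm).
#' @param n_fractures fractures to plant (default 8).
#' @param type_freq,displacement_freq,location_freq named frequency
#'   vectors over each category's vocabulary (must sum to 1).
#' @param split_displaced carve a fragment gap into ribs with a
#'   displaced fracture (default `TRUE`)?
#' @param seed RNG seed making the phantom fully reproducible.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128, 128), spacing = c(2, 2, 2),
                         n_rib_pairs = 12, rib_radius_mm = 4,
                         n_fractures = 8,
                         type_freq = c(simple = 0.70, wedge = 0.20,
                                       complex = 0.10),
                         displacement_freq = c(undisplaced = 0.55,
                                               offset = 0.30,
                                               displaced = 0.15),
                         location_freq = c(anterior = 0.30, lateral = 0.35,
                                           posterior = 0.35),
                         split_displaced = TRUE, seed = 1L) {
  stopifnot(n_rib_pairs %in% c(11L, 12L), rib_radius_mm > 0,
            n_fractures >= 0, length(shape) == 3L, all(shape >= 32),
            length(spacing) == 3L, all(spacing > 0))
  freqs <- list(type = type_freq, displacement = displacement_freq,
                location = location_freq)
  for (cat in cwis_categories) {
    f <- freqs[[cat]]
    stopifnot(setequal(names(f), cwis_vocab[[cat]]),
              abs(sum(f) - 1) < 1e-8, all(f >= 0))
  }
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_rib_pairs = as.integer(n_rib_pairs),
                 rib_radius_mm = rib_radius_mm,
                 n_fractures = as.integer(n_fractures),
                 type_freq = type_freq,
                 displacement_freq = displacement_freq,
                 location_freq = location_freq,
                 split_displaced = split_displaced, seed = seed),
            class = "phantom_spec")
}

# Centerline of one rib: matrix of continuous voxel coordinates plus the
# cumulative arc-length fraction t (0 at the spine / posterior end).
rib_centerline <- function(spec, pair, side, n_samples = 280L) {
  ext <- spec$shape * spec$spacing
  ctr <- ext / 2
  scale_r <- 0.80 + 0.20 * sin(pi * pair / 13)
  a <- 0.38 * ext[1] * scale_r
  b <- 0.30 * ext[2] * scale_r
  z0 <- (0.12 + 0.70 * (pair - 1) / 11) * ext[3]
  phi <- seq(0.18, 2.85, length.out = n_samples)
  sgn <- if (side == "left") -1 else 1
  x <- ctr[1] + sgn * a * sin(phi)
  y <- ctr[2] + b * cos(phi)   # +y posterior (spine), -y anterior
  p <- cbind(x, y, rep(z0, n_samples))
  seg <- sqrt(rowSums(diff(p)^2))
  arc <- c(0, cumsum(seg))
  t <- arc / arc[length(arc)]
  p[, 3] <- z0 + 4 * t  # mild caudal droop toward the sternum
  list(mm = p, vox = sweep(p, 2, spec$spacing, "/"), t = t,
       arc = arc, length_mm = arc[length(arc)])
}

# Sphere stamp: voxel offsets within radius_mm under anisotropic spacing.
sphere_offsets <- function(radius_mm, spacing) {
  r <- ceiling(radius_mm / spacing)
  offs <- as.matrix(expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2],
                                dz = -r[3]:r[3]))
  offs[rowSums(sweep(offs, 2, spacing, "*")^2) <= radius_mm^2, ,
       drop = FALSE]
}

#' Generate a numbered rib-cage phantom with planted fractures
#'
#' See [phantom_spec()] for the geometry and labeling conventions.
#' Fracture reference points are encoded the way reference standards
#' are: a center voxel (guaranteed to carry the rib's label) with a
#' 10 mm sphere radius and a complete CWIS triple plus rib number.
#' Fracture centers are rejected-resampled so that no two reference
#' spheres overlap; an error is raised when the requested number cannot
#' be placed.
#'
#' @param spec a [phantom_spec()].
#' @param scan_id scan identifier written into the reference table.
#' @return list with `ribs` (a [rib_labelmap()]), `refs` (reference
#'   fracture table: `scan_id`, `cx, cy, cz`, `radius_mm`, CWIS labels,
#'   `rib_label`, `rib_number`, `side`, `arc_t`) and `centerlines`.
#' @export
generate_phantom <- function(spec, scan_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    pairs <- seq_len(spec$n_rib_pairs)
    lines <- list()
    for (side in c("left", "right")) for (r in pairs) {
      lab <- if (side == "left") r else r + 12L
      lines[[as.character(lab)]] <- c(rib_centerline(spec, r, side),
                                      list(label = lab))
    }

    # ---- plant fractures on centerlines, spheres pairwise disjoint ----
    refs <- NULL
    radius_mm <- 10
    if (spec$n_fractures > 0) {
      placed_mm <- matrix(numeric(0), ncol = 3)
      rows <- list()
      attempts <- 0L; max_attempts <- 400L * spec$n_fractures
      while (length(rows) < spec$n_fractures) {
        attempts <- attempts + 1L
        if (attempts > max_attempts)
          stop("generate_phantom: could not place ", spec$n_fractures,
               " non-overlapping reference spheres; reduce n_fractures",
               call. = FALSE)
        loc <- sample(names(spec$location_freq), 1,
                      prob = spec$location_freq)
        t_rng <- switch(loc, posterior = c(0.04, 1 / 3),
                        lateral = c(1 / 3, 2 / 3),
                        anterior = c(2 / 3, 0.96))
        ln <- lines[[sample(length(lines), 1)]]
        tt <- stats::runif(1, t_rng[1], t_rng[2])
        i <- which.min(abs(ln$t - tt))
        # separation is enforced on the voxel-rounded centers the
        # reference table stores, so the encoded spheres are disjoint
        vox_c <- round(ln$vox[i, ])
        p_mm <- vox_c * spec$spacing
        if (nrow(placed_mm) &&
            min(sqrt(rowSums(sweep(placed_mm, 2, p_mm)^2))) < 2 * radius_mm)
          next
        placed_mm <- rbind(placed_mm, p_mm)
        rows[[length(rows) + 1L]] <- data.frame(
          scan_id = scan_id,
          cx = vox_c[1], cy = vox_c[2],
          cz = vox_c[3], radius_mm = radius_mm,
          type = sample(names(spec$type_freq), 1, prob = spec$type_freq),
          displacement = sample(names(spec$displacement_freq), 1,
                                prob = spec$displacement_freq),
          location = loc, rib_label = ln$label,
          rib_number = rib_label_to_number(ln$label),
          side = rib_label_to_side(ln$label),
          arc_t = ln$t[i], stringsAsFactors = FALSE)
      }
      refs <- do.call(rbind, rows)
    }
    if (is.null(refs))
      refs <- data.frame(scan_id = character(0), cx = numeric(0),
                         cy = numeric(0), cz = numeric(0),
                         radius_mm = numeric(0), type = character(0),
                         displacement = character(0),
                         location = character(0), rib_label = integer(0),
                         rib_number = integer(0), side = character(0),
                         arc_t = numeric(0), stringsAsFactors = FALSE)

    # ---- fragment gaps for displaced fractures (one split per rib) ----
    gaps <- list()
    if (spec$split_displaced && nrow(refs)) {
      gap_w <- 2 * spec$rib_radius_mm + 4   # wide enough not to re-bridge
      for (i in which(refs$displacement == "displaced")) {
        lab <- as.character(refs$rib_label[i])
        if (!is.null(gaps[[lab]])) next
        ln <- lines[[lab]]
        arc_c <- refs$arc_t[i] * ln$length_mm
        start <- arc_c + radius_mm + 4  # keep the center voxel labeled
        if (start + gap_w > 0.98 * ln$length_mm) next
        gaps[[lab]] <- c(start, start + gap_w)
      }
    }

    # ---- rasterize tubes ----
    grid <- array(0L, dim = spec$shape)
    offs <- sphere_offsets(spec$rib_radius_mm, spec$spacing)
    for (ln in lines) {
      keep <- rep(TRUE, nrow(ln$vox))
      g <- gaps[[as.character(ln$label)]]
      if (!is.null(g)) keep <- ln$arc < g[1] | ln$arc > g[2]
      pts <- round(ln$vox[keep, , drop = FALSE])
      idx <- pts[rep(seq_len(nrow(pts)), each = nrow(offs)), , drop = FALSE] +
             offs[rep(seq_len(nrow(offs)), times = nrow(pts)), , drop = FALSE]
      ok <- idx[, 1] >= 0 & idx[, 1] < spec$shape[1] &
            idx[, 2] >= 0 & idx[, 2] < spec$shape[2] &
            idx[, 3] >= 0 & idx[, 3] < spec$shape[3]
      idx <- idx[ok, , drop = FALSE]
      lin <- unique((idx[, 1] + 1) + idx[, 2] * spec$shape[1] +
                    idx[, 3] * spec$shape[1] * spec$shape[2])
      grid[lin] <- ln$label
    }
    # fracture centers must keep their rib's label even where tubes of
    # neighbouring ribs were stamped later
    if (nrow(refs)) {
      lin <- (refs$cx + 1) + refs$cy * spec$shape[1] +
             refs$cz * spec$shape[1] * spec$shape[2]
      grid[lin] <- refs$rib_label
    }
    list(ribs = rib_labelmap(grid, spec$spacing), refs = refs,
         centerlines = lines, spec = spec)
  })
}

#' Simulated detector profile
#'
#' Describes the error model of one category-specific fracture
#' detector: the probability that a true fracture is emitted as a box
#' (sensitivity), the Poisson rate of false-positive boxes per scan,
#' Gaussian jitter of emitted box centers, the physical box size range,
#' an optional label confusion matrix (rows = true label, columns =
#' emitted label; identity by default) and Beta score distributions for
#' true- and false-positive boxes (true detections score high, false
#' positives low).
#'
#' @param sensitivity detection probability per reference fracture.
#' @param fp_per_scan mean false positives per scan (Poisson).
#' @param jitter_sd_mm SD of the center jitter, mm per axis.
#' @param box_size_mm physical box edge range, mm (uniform per axis);
#'   the default spans roughly the diameter of the 10 mm reference
#'   sphere, so boxes emitted for distinct (non-overlapping) reference
#'   fractures stay disjoint.
#' @param label_confusion square matrix over a category's vocabulary
#'   (rows sum to 1) or `NULL` for identity.
#' @param tp_score_beta,fp_score_beta `c(shape1, shape2)` of the Beta
#'   score distributions.
#' @param off_rib_fraction fraction of false positives placed uniformly
#'   in the volume instead of on a rib.
#' @return a list of class `detector_profile`.
#' @export
detector_profile <- function(sensitivity = 0.8, fp_per_scan = 1.11,
                             jitter_sd_mm = 2, box_size_mm = c(10, 18),
                             label_confusion = NULL,
                             tp_score_beta = c(8, 2),
                             fp_score_beta = c(2, 5),
                             off_rib_fraction = 0) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, fp_per_scan >= 0,
            jitter_sd_mm >= 0, length(box_size_mm) == 2L,
            box_size_mm[1] > 0, box_size_mm[2] >= box_size_mm[1],
            off_rib_fraction >= 0, off_rib_fraction <= 1)
  if (!is.null(label_confusion))
    stopifnot(is.matrix(label_confusion),
              nrow(label_confusion) == ncol(label_confusion),
              all(abs(rowSums(label_confusion) - 1) < 1e-8))
  structure(list(sensitivity = sensitivity, fp_per_scan = fp_per_scan,
                 jitter_sd_mm = jitter_sd_mm, box_size_mm = box_size_mm,
                 label_confusion = label_confusion,
                 tp_score_beta = tp_score_beta,
                 fp_score_beta = fp_score_beta,
                 off_rib_fraction = off_rib_fraction),
            class = "detector_profile")
}

#' Simulate one detector's scored boxes for a phantom scan
#'
#' Emits, per reference fracture, a jittered box with the profile's
#' sensitivity, labeled by drawing from the confusion row of the true
#' label; adds Poisson-many false-positive boxes at random on-rib (or,
#' with `off_rib_fraction`, anywhere-in-volume) locations with labels
#' drawn uniformly from the category vocabulary. Deterministic given
#' `seed`.
#'
#' @param refs reference fracture table (from [generate_phantom()]).
#' @param profile a [detector_profile()].
#' @param category which CWIS category this detector labels.
#' @param ribs the phantom's [rib_labelmap()] (grid shape, spacing and
#'   false-positive placement).
#' @param model_id source-model tag (default `"<category>_model"`).
#' @param seed RNG seed; `NULL` uses the ambient RNG stream.
#' @return scored-box data frame: `scan_id`, `model_id`, `category`,
#'   `label`, `score`, `x0..z1`, plus `ref_idx` (index of the emitting
#'   reference, `NA` for false positives).
#' @export
simulate_detector_outputs <- function(refs, profile, category, ribs,
                                      model_id = paste0(category, "_model"),
                                      seed = NULL) {
  category <- match.arg(category, cwis_categories)
  stopifnot(inherits(profile, "detector_profile"),
            inherits(ribs, "rib_labelmap"))
  vocab <- cwis_vocab[[category]]
  shape <- ribs$shape; spacing <- ribs$spacing
  scan <- if (nrow(refs)) refs$scan_id[1] else "phantom"
  with_seed(seed, {
    rows <- list()
    make_box <- function(center_vox) {
      size_vox <- stats::runif(3, profile$box_size_mm[1],
                               profile$box_size_mm[2]) / spacing
      lo <- round(center_vox - size_vox / 2)
      hi <- lo + pmax(1, round(size_vox))
      lo <- pmax(lo, 0); hi <- pmin(hi, shape)
      lo <- pmin(lo, hi - 1)
      c(lo, hi)
    }
    if (nrow(refs)) for (i in seq_len(nrow(refs))) {
      if (stats::runif(1) > profile$sensitivity) next
      ctr <- c(refs$cx[i], refs$cy[i], refs$cz[i]) +
             stats::rnorm(3, 0, profile$jitter_sd_mm) / spacing
      b <- make_box(ctr)
      true_lab <- refs[[category]][i]
      lab <- if (is.null(profile$label_confusion)) true_lab else
        sample(colnames(profile$label_confusion), 1,
               prob = profile$label_confusion[true_lab, ])
      rows[[length(rows) + 1L]] <- data.frame(
        scan_id = scan, model_id = model_id, category = category,
        label = lab,
        score = stats::rbeta(1, profile$tp_score_beta[1],
                             profile$tp_score_beta[2]),
        x0 = b[1], y0 = b[2], z0 = b[3], x1 = b[4], y1 = b[5], z1 = b[6],
        ref_idx = i, stringsAsFactors = FALSE)
    }
    n_fp <- stats::rpois(1, profile$fp_per_scan)
    if (n_fp > 0) {
      rib_lin <- which(ribs$grid > 0L)
      for (k in seq_len(n_fp)) {
        if (length(rib_lin) &&
            stats::runif(1) >= profile$off_rib_fraction) {
          ctr <- arrayInd(sample(rib_lin, 1), shape) - 1L
        } else {
          ctr <- floor(stats::runif(3) * shape)
        }
        b <- make_box(as.numeric(ctr))
        rows[[length(rows) + 1L]] <- data.frame(
          scan_id = scan, model_id = model_id, category = category,
          label = sample(vocab, 1),
          score = stats::rbeta(1, profile$fp_score_beta[1],
                               profile$fp_score_beta[2]),
          x0 = b[1], y0 = b[2], z0 = b[3], x1 = b[4], y1 = b[5], z1 = b[6],
          ref_idx = NA_integer_, stringsAsFactors = FALSE)
      }
    }
    if (!length(rows))
      return(data.frame(scan_id = character(0), model_id = character(0),
                        category = character(0), label = character(0),
                        score = numeric(0), x0 = integer(0), y0 = integer(0),
                        z0 = integer(0), x1 = integer(0), y1 = integer(0),
                        z1 = integer(0), ref_idx = integer(0),
                        stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
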