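#' Numbered rib label map
#'
#' An integer 3D volume in which voxel value 0 is background and values
#' 1..24 number the ribs: 1-12 are left ribs 1-12 (cranial to caudal),
#' 13-24 the right ribs 1-12. A cage may legitimately hold only 11 rib
#' pairs. Spacing is the physical voxel size in mm per axis.
#'
#' @param grid 3D integer array.
#' @param spacing numeric length-3 voxel size in mm, all positive.
#' @return an object of class `rib_labelmap` with fields `grid`,
#'   `spacing` and `shape`.
#' @export
rib_labelmap <- function(grid, spacing) {
  stopifnot(is.array(grid), length(dim(grid)) == 3L,
            is.numeric(spacing), length(spacing) == 3L, all(spacing > 0))
  vals <- unique(as.integer(grid))
  unknown <- setdiff(vals, 0:24)
  if (length(unknown))
    warning("rib_labelmap: labels outside 0..24 present: ",
            paste(sort(unknown), collapse = ", "), call. = FALSE)
  structure(list(grid = grid, spacing = as.numeric(spacing),
                 shape = dim(grid)),
            class = "rib_labelmap")
}

#' @export
print.rib_labelmap <- function(x, ...) {
  labs <- setdiff(sort(unique(as.integer(x$grid))), 0L)
  cat("Rib label map:", paste(x$shape, collapse = " x "),
      "voxels @", paste(x$spacing, collapse = " x "), "mm\n")
  cat("  rib labels present:", if (length(labs)) paste(labs, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

# label (1..24) -> rib number 1..12 and side
rib_label_to_number <- function(label) ((label - 1L) %% 12L) + 1L
rib_label_to_side <- function(label) ifelse(label <= 12L, "left", "right")

#' Rasterize detection boxes into a binary label map
#'
#' A voxel is foreground (1) iff it lies inside at least one detection
#' box. Boxes extending past the grid are clipped with a warning; boxes
#' entirely outside the grid are ignored with a warning.
#'
#' @param dets data frame of detections with corner columns `x0..z1`
#'   (0-based, half-open).
#' @param shape integer length-3 grid dimensions.
#' @return 3D integer array of 0/1 with dimensions `shape`.
#' @export
boxes_to_labelmap <- function(dets, shape) {
  stopifnot(length(shape) == 3L, all(shape >= 1))
  vol <- array(0L, dim = shape)
  if (is.null(dets) || nrow(dets) == 0L) return(vol)
  validate_boxes(dets, "boxes_to_labelmap")
  clipped <- FALSE; dropped <- 0L
  for (i in seq_len(nrow(dets))) {
    lo <- pmax(c(dets$x0[i], dets$y0[i], dets$z0[i]), 0L)
    hi <- pmin(c(dets$x1[i], dets$y1[i], dets$z1[i]), shape)
    if (any(hi <= lo)) { dropped <- dropped + 1L; next }
    if (any(lo != c(dets$x0[i], dets$y0[i], dets$z0[i])) ||
        any(hi != c(dets$x1[i], dets$y1[i], dets$z1[i]))) clipped <- TRUE
    vol[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3]] <- 1L
  }
  if (dropped) warning(dropped, " box(es) entirely outside the grid ignored",
                       call. = FALSE)
  if (clipped) warning("box(es) extending past the grid were clipped",
                       call. = FALSE)
  vol
}

#' Assign rib numbers to fused detections
#'
#' Each detection box is intersected with the numbered rib segmentation;
#' voxel overlap is counted per rib label inside the box and the rib
#' with the largest overlap is assigned. Detections whose boxes do not
#' touch any rib voxel are discarded. Ties are resolved
#' deterministically: lower rib number first, left before right.
#'
#' @param dets data frame of fused detections (corner columns `x0..z1`).
#' @param ribs a [rib_labelmap()] on the same grid as the detections.
#' @return data frame, one row per detection, with `rib_label` (1-24 or
#'   `NA`), `rib_number` (1-12 or `NA`), `side`, `overlap_voxels` (count
#'   for the assigned rib), `total_overlap` and `discarded`; the per-rib
#'   overlap counts are kept in the list column `overlap_table`.
#' @export
assign_rib_numbers <- function(dets, ribs) {
  stopifnot(inherits(ribs, "rib_labelmap"))
  n <- if (is.null(dets)) 0L else nrow(dets)
  out <- data.frame(rib_label = rep(NA_integer_, n),
                    rib_number = rep(NA_integer_, n),
                    side = rep(NA_character_, n),
                    overlap_voxels = rep(0L, n),
                    total_overlap = rep(0L, n),
                    discarded = rep(TRUE, n),
                    stringsAsFactors = FALSE)
  out$overlap_table <- vector("list", n)
  if (n == 0L) return(out)
  validate_boxes(dets, "assign_rib_numbers")
  shape <- ribs$shape
  for (i in seq_len(n)) {
    lo <- pmax(c(dets$x0[i], dets$y0[i], dets$z0[i]), 0L)
    hi <- pmin(c(dets$x1[i], dets$y1[i], dets$z1[i]), shape)
    if (any(hi <= lo)) next
    sub <- ribs$grid[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3]]
    counts <- tabulate(sub[sub > 0L], nbins = 24L)
    total <- sum(counts)
    out$total_overlap[i] <- total
    out$overlap_table[[i]] <- stats::setNames(counts[counts > 0L],
                                              which(counts > 0L))
    if (total == 0L) next
    best <- which(counts == max(counts))
    # tie-break: lower rib number, then left before right
    key <- rib_label_to_number(best) * 2L + (best > 12L)
    lab <- best[which.min(key)]
    out$rib_label[i] <- lab
    out$rib_number[i] <- rib_label_to_number(lab)
    out$side[i] <- rib_label_to_side(lab)
    out$overlap_voxels[i] <- counts[lab]
    out$discarded[i] <- FALSE
  }
  out
}

#' Attach rib assignments to a fused detection table
#'
#' Convenience merge of [assign_rib_numbers()] output onto the fused
#' detections; discarded detections (no rib overlap) are dropped, as
#' boxes that do not overlap the rib segmentation are not reported.
#'
#' @param dets fused detection data frame.
#' @param ribs a [rib_labelmap()].
#' @param drop_discarded drop detections without rib overlap (default
#'   `TRUE`)?
#' @return `dets` with columns `rib_label`, `rib_number`, `side` added.
#' @export
attach_rib_numbers <- function(dets, ribs, drop_discarded = TRUE) {
  asg <- assign_rib_numbers(dets, ribs)
  dets$rib_label <- asg$rib_label
  dets$rib_number <- asg$rib_number
  dets$side <- asg$side
  if (drop_discarded) dets <- dets[!asg$discarded, , drop = FALSE]
  rownames(dets) <- NULL
  dets
}

#' Structural validation of a numbered rib label map
#'
#' Automates the visual quality criteria used for rib-numbering
#' segmentations: per label, is a single rib represented (one connected
#' component), and do fragments of a severely displaced rib still share
#' one label (components counted per label)? The report lists per label
#' the voxel count and number of 26-connected components, and raises
#' flags for gaps in the 1-12 sequence per side, labels fragmenting into
#' more than two components, and a "short cage" (exactly 11 pairs,
#' which is anatomically legitimate and therefore a flag, not a
#' failure).
#'
#' @param ribs a [rib_labelmap()].
#' @return object of class `ribmap_validation`: data frame `labels`
#'   (label, side, rib_number, present, n_voxels, n_components) plus
#'   character vector `flags`.
#' @export
validate_rib_labelmap <- function(ribs) {
  stopifnot(inherits(ribs, "rib_labelmap"))
  lab <- data.frame(label = 1:24,
                    side = rib_label_to_side(1:24),
                    rib_number = rib_label_to_number(1:24),
                    present = FALSE, n_voxels = 0L, n_components = 0L)
  g <- as.integer(ribs$grid)
  counts <- tabulate(g[g > 0L], nbins = 24L)
  lab$n_voxels <- counts
  lab$present <- counts > 0L
  for (l in which(lab$present)) {
    idx <- which(as.integer(ribs$grid) == l)
    lab$n_components[l] <- count_components_3d(ribs$shape, idx)
  }
  flags <- character(0)
  for (s in c("left", "right")) {
    pres <- lab$rib_number[lab$present & lab$side == s]
    if (length(pres)) {
      gaps <- setdiff(seq_len(max(pres)), pres)
      if (length(gaps))
        flags <- c(flags, sprintf("gap in %s rib sequence: missing rib %s",
                                  s, paste(gaps, collapse = ", ")))
    } else flags <- c(flags, sprintf("no %s ribs present", s))
  }
  eleven <- vapply(c("left", "right"), function(s) {
    pres <- lab$rib_number[lab$present & lab$side == s]
    setequal(pres, 1:11)
  }, logical(1))
  if (all(eleven))
    flags <- c(flags, "short cage: only 11 rib pairs present")
  frag <- lab$label[lab$n_components > 2L]
  if (length(frag))
    flags <- c(flags, sprintf("label(s) with >2 fragments: %s",
                              paste(frag, collapse = ", ")))
  missing <- lab$label[!lab$present]
  if (length(missing) && !all(eleven))
    flags <- c(flags, sprintf("expected label(s) empty: %s",
                              paste(missing, collapse = ", ")))
  structure(list(labels = lab, flags = flags), class = "ribmap_validation")
}

#' @export
print.ribmap_validation <- function(x, ...) {
  cat("Rib label map validation\n")
  cat(sprintf("  labels present: %d of 24\n", sum(x$labels$present)))
  multi <- x$labels[x$labels$n_components > 1L, , drop = FALSE]
  if (nrow(multi))
    cat("  fragmented labels:",
        paste(sprintf("%d (%d parts)", multi$label, multi$n_components),
              collapse = ", "), "\n")
  if (length(x$flags)) {
    cat("  flags:\n")
    for (f in x$flags) cat("   -", f, "\n")
  } else cat("  no flags\n")
  invisible(x)
}

# Number of 26-connected components among the voxels at linear indices
# `idx` of a grid with dimensions `shape`. Frontier BFS on coordinates.
count_components_3d <- function(shape, idx) {
  if (!length(idx)) return(0L)
  inset <- array(FALSE, dim = shape)
  inset[idx] <- TRUE
  visited <- array(FALSE, dim = shape)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  ncomp <- 0L
  remaining <- idx
  while (length(remaining)) {
    seed <- remaining[1L]
    ncomp <- ncomp + 1L
    visited[seed] <- TRUE
    frontier <- matrix(arrayInd(seed, shape), ncol = 3)
    while (nrow(frontier)) {
      cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offs)), ,
                       drop = FALSE] +
              offs[rep(seq_len(nrow(offs)), times = nrow(frontier)), ,
                   drop = FALSE]
      ok <- cand[, 1] >= 1 & cand[, 1] <= shape[1] &
            cand[, 2] >= 1 & cand[, 2] <= shape[2] &
            cand[, 3] >= 1 & cand[, 3] <= shape[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- unique(cand[, 1] + (cand[, 2] - 1) * shape[1] +
                    (cand[, 3] - 1) * shape[1] * shape[2])
      lin <- lin[inset[lin] & !visited[lin]]
      visited[lin] <- TRUE
      frontier <- arrayInd(lin, shape)
    }
    remaining <- remaining[!visited[remaining]]
  }
  ncomp
}
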