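#' Axis-aligned 3D boxes
#'
#' Boxes live on the voxel grid of a single scan and are encoded by six
#' integer columns `x0, y0, z0, x1, y1, z1`: the minimum corner
#' (0-based, inclusive) and the maximum corner (exclusive), so a box
#' covers voxels `x0 <= x < x1` etc. and its volume in voxels is the
#' product of the extents. All geometry below operates on this half-open
#' convention.
#'
#' @param x0,y0,z0 minimum corner (0-based voxel indices, inclusive).
#' @param x1,y1,z1 maximum corner (exclusive).
#' @return a one-row data frame with the six corner columns.
#' @examples
#' b <- box3d(0, 0, 0, 10, 10, 10)
#' box_volume(b)  # 1000 voxels
#' @export
box3d <- function(x0, y0, z0, x1, y1, z1) {
  b <- data.frame(x0 = x0, y0 = y0, z0 = z0, x1 = x1, y1 = y1, z1 = z1)
  validate_boxes(b)
  b
}

box_cols <- c("x0", "y0", "z0", "x1", "y1", "z1")
min_cols <- c("x0", "y0", "z0")
max_cols <- c("x1", "y1", "z1")

as_box_df <- function(b) {
  if (is.numeric(b) && length(b) == 6L) {
    b <- as.data.frame(as.list(stats::setNames(b, box_cols)))
  }
  if (!is.data.frame(b) || !all(box_cols %in% names(b)))
    stop("boxes must be a data frame with columns ",
         paste(box_cols, collapse = ", "), call. = FALSE)
  b
}

#' Validate box geometry
#'
#' Checks that every box has its minimum corner strictly below its
#' maximum corner on all three axes (positive volume); degenerate boxes
#' are rejected.
#'
#' @param boxes data frame with the six corner columns.
#' @param context prefix for error messages.
#' @return the input, invisibly.
#' @export
validate_boxes <- function(boxes, context = "box") {
  boxes <- as_box_df(boxes)
  lo <- as.matrix(boxes[min_cols])
  hi <- as.matrix(boxes[max_cols])
  if (any(!is.finite(lo)) || any(!is.finite(hi)))
    stop(context, ": non-finite box corners", call. = FALSE)
  bad <- which(rowSums(hi > lo) < 3L)
  if (length(bad))
    stop(sprintf("%s: degenerate box(es) with min_corner >= max_corner at row(s) %s",
                 context, paste(bad, collapse = ", ")), call. = FALSE)
  invisible(boxes)
}

#' @rdname box3d
#' @param boxes data frame of boxes.
#' @export
box_volume <- function(boxes) {
  boxes <- as_box_df(boxes)
  (boxes$x1 - boxes$x0) * (boxes$y1 - boxes$y0) * (boxes$z1 - boxes$z0)
}

#' Intersection-over-union of two boxes
#'
#' IoU of the voxel sets covered by two half-open boxes: shared volume
#' divided by the volume of the union. Symmetric, bounded in \[0, 1\],
#' and 0 for disjoint boxes. This is the criterion used for within-model
#' de-duplication, where two detections count as overlapping when their
#' IoU exceeds 50%.
#'
#' @param a,b single boxes (one-row data frames or length-6 numeric
#'   vectors `c(x0, y0, z0, x1, y1, z1)`).
#' @return IoU fraction in \[0, 1\].
#' @examples
#' box_iou(box3d(0, 0, 0, 10, 10, 10), box3d(5, 5, 5, 15, 15, 15))  # 1/15
#' @export
box_iou <- function(a, b) {
  a <- validate_boxes(as_box_df(a)); b <- validate_boxes(as_box_df(b))
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  inter <- prod(pmax(0, pmin(unlist(a[max_cols]), unlist(b[max_cols])) -
                        pmax(unlist(a[min_cols]), unlist(b[min_cols]))))
  inter / (box_volume(a) + box_volume(b) - inter)
}

# Pairwise intersection volumes, n x n.
intersection_matrix <- function(boxes) {
  boxes <- as_box_df(boxes)
  n <- nrow(boxes)
  out <- matrix(0, n, n)
  if (n == 0L) return(out)
  for (ax in 1:3) {
    lo <- boxes[[min_cols[ax]]]; hi <- boxes[[max_cols[ax]]]
    ov <- pmax(0, outer(hi, hi, pmin) - outer(lo, lo, pmax))
    out <- if (ax == 1) ov else out * ov
  }
  out
}

# Pairwise IoU, n x n (diagonal = 1).
iou_matrix <- function(boxes) {
  boxes <- as_box_df(boxes)
  inter <- intersection_matrix(boxes)
  v <- box_volume(boxes)
  un <- outer(v, v, `+`) - inter
  ifelse(un > 0, inter / un, 0)
}

# Smallest axis-aligned box containing all input boxes.
box_union_hull <- function(boxes) {
  boxes <- as_box_df(boxes)
  data.frame(x0 = min(boxes$x0), y0 = min(boxes$y0), z0 = min(boxes$z0),
             x1 = max(boxes$x1), y1 = max(boxes$y1), z1 = max(boxes$z1))
}
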