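#' Read and write detection tables
#'
#' The tabular dialect is tab-separated text with a header row, one
#' record per line. Detection tables carry `scan_id`, `model_id`,
#' `category`, `label`, `score` and the box corner columns
#' `x0 y0 z0 x1 y1 z1` (0-based, half-open). On reading, records are
#' validated — category and label vocabulary (labels are matched
#' case-insensitively and normalized to lower case), score within
#' \[0, 1\], corners integral with minimum strictly below maximum — and
#' every error message names the offending file line.
#'
#' @param path file path.
#' @param dets detection data frame.
#' @return `read_detections()` returns the validated data frame.
#' @export
read_detections <- function(path) {
  d <- read_tsv_checked(path, c("scan_id", "model_id", "category", "label",
                                "score", box_cols))
  d$category <- tolower(trimws(d$category))
  bad <- which(!d$category %in% cwis_categories)
  if (length(bad)) stop_at(path, bad, "unknown category ",
                           sQuote(d$category[bad[1]]))
  for (cat in cwis_categories) {
    rows <- which(d$category == cat)
    if (length(rows))
      d$label[rows] <- normalize_label(d$label[rows], cat,
                                       context = file_ctx(path, rows))
  }
  check_scores(d, path)
  check_corners(d, path)
  d
}

#' @rdname read_detections
#' @export
write_detections <- function(dets, path) {
  write_tsv(dets[c("scan_id", "model_id", "category", "label", "score",
                   box_cols)], path)
}

#' Read and write reference fracture tables
#'
#' References carry `scan_id`, the center voxel coordinates
#' `cx cy cz`, `radius_mm`, the complete CWIS triple (`"unknown"` is
#' not allowed in a reference) and optionally `rib_label` (1-24).
#' The same dialect stores observer annotation tables for agreement
#' analyses (where `radius_mm` and `rib_label` may be absent).
#'
#' @param path file path.
#' @param refs reference data frame.
#' @param require_radius is `radius_mm` mandatory (default `TRUE`;
#'   observer tables may omit it)?
#' @return `read_references()` returns the validated data frame.
#' @export
read_references <- function(path, require_radius = TRUE) {
  need <- c("scan_id", "cx", "cy", "cz", "type", "displacement", "location")
  if (require_radius) need <- append(need, "radius_mm", after = 4)
  d <- read_tsv_checked(path, need)
  for (cat in cwis_categories)
    d[[cat]] <- normalize_label(d[[cat]], cat,
                                context = file_ctx(path, seq_len(nrow(d))))
  if (!is.null(d$radius_mm)) {
    bad <- which(!is.finite(d$radius_mm) | d$radius_mm <= 0)
    if (length(bad)) stop_at(path, bad, "radius_mm must be positive")
  }
  if (!is.null(d$rib_label)) {
    bad <- which(!is.na(d$rib_label) & !(d$rib_label %in% 1:24))
    if (length(bad)) stop_at(path, bad, "rib_label must be in 1..24")
  }
  d
}

#' @rdname read_references
#' @export
write_references <- function(refs, path) {
  keep <- intersect(c("scan_id", "cx", "cy", "cz", "radius_mm",
                      "type", "displacement", "location", "rib_label",
                      "rib_number", "side"), names(refs))
  write_tsv(refs[keep], path)
}

#' Read and write fused detection tables
#'
#' Fused detections carry the union box, the CWIS triple (each
#' component possibly `"unknown"`), the aggregate score, the
#' contributing model ids and per-category source scores; after rib
#' assignment the `rib_label`/`rib_number`/`side` columns are present
#' as well.
#'
#' @param path file path.
#' @param fused fused detection data frame.
#' @return `read_fused()` returns the validated data frame.
#' @export
read_fused <- function(path) {
  d <- read_tsv_checked(path, c("scan_id", box_cols, "type", "displacement",
                                "location", "score", "contributors"))
  for (cat in cwis_categories)
    d[[cat]] <- normalize_label(d[[cat]], cat, allow_unknown = TRUE,
                                context = file_ctx(path, seq_len(nrow(d))))
  check_scores(d, path)
  check_corners(d, path)
  d
}

#' @rdname read_fused
#' @export
write_fused <- function(fused, path) {
  keep <- intersect(c("scan_id", box_cols, "type", "displacement",
                      "location", "score", "n_contributors", "contributors",
                      "score_type", "score_displacement", "score_location",
                      "rib_label", "rib_number", "side"), names(fused))
  write_tsv(fused[keep], path)
}

#' Read and write numbered rib label maps (NIfTI)
#'
#' Volumes are stored as NIfTI with the voxel spacing in the header
#' pixdim. Reading rejects non-integer-valued volumes and volumes
#' without positive spacing, and warns when labels outside 0..24 are
#' present (naming them).
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param ribs a [rib_labelmap()].
#' @return `read_labelmap()` returns a [rib_labelmap()].
#' @export
read_labelmap <- function(path) {
  img <- RNifti::readNifti(path)
  grid <- array(as.numeric(img), dim = dim(img))
  if (length(dim(grid)) != 3L)
    stop("read_labelmap: expected a 3D volume, got ",
         length(dim(grid)), "D", call. = FALSE)
  if (max(abs(grid - round(grid))) > 1e-6)
    stop("read_labelmap: volume is not integer-valued (label maps must ",
         "hold integer rib labels)", call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  if (length(spacing) != 3L || any(!is.finite(spacing)) ||
      any(spacing <= 0))
    stop("read_labelmap: missing or non-positive voxel spacing in header",
         call. = FALSE)
  storage.mode(grid) <- "integer"
  rib_labelmap(grid, spacing)
}

#' @rdname read_labelmap
#' @export
write_labelmap <- function(ribs, path) {
  stopifnot(inherits(ribs, "rib_labelmap"))
  img <- RNifti::asNifti(ribs$grid, internal = FALSE)
  RNifti::pixdim(img) <- ribs$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' A serializable bundle of everything a pipeline run needs: input
#' paths, fusion parameters, matching parameters (spacing, operating
#' threshold or target sensitivity), seeds and the output directory.
#' Round-trips losslessly through YAML.
#'
#' @param paths named list of input paths.
#' @param fusion a [fusion_config()].
#' @param spacing voxel spacing in mm.
#' @param threshold detection-score threshold (or `NULL`).
#' @param target_sensitivity target used to derive the threshold from a
#'   training set (or `NULL`).
#' @param seed master RNG seed.
#' @param out_dir output directory.
#' @return a list of class `run_config`.
#' @export
run_config <- function(paths = list(), fusion = fusion_config(),
                       spacing = c(1, 1, 1), threshold = NULL,
                       target_sensitivity = NULL, seed = 1L,
                       out_dir = ".") {
  structure(list(paths = paths, fusion = unclass(fusion),
                 spacing = as.numeric(spacing), threshold = threshold,
                 target_sensitivity = target_sensitivity,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- run_config()
  for (f in names(x)) cfg[[f]] <- x[[f]]
  cfg$spacing <- as.numeric(cfg$spacing)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# ---- internal helpers -------------------------------------------------

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop(path, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  d
}

# data row i sits on file line i + 1 (header is line 1)
file_ctx <- function(path, rows) {
  sprintf("%s line %s", path, paste(rows[1] + 1L, collapse = ","))
}

stop_at <- function(path, rows, ...) {
  stop(sprintf("%s line %d: ", path, rows[1] + 1L), ..., call. = FALSE)
}

check_scores <- function(d, path) {
  bad <- which(!is.finite(d$score) | d$score < 0 | d$score > 1)
  if (length(bad)) stop_at(path, bad, "score ", d$score[bad[1]],
                           " outside [0, 1]")
  invisible(d)
}

check_corners <- function(d, path) {
  m <- as.matrix(d[box_cols])
  bad <- which(rowSums(!is.finite(m) | m != round(m)) > 0)
  if (length(bad)) stop_at(path, bad, "box corners must be integers")
  bad <- which(d$x1 <= d$x0 | d$y1 <= d$y0 | d$z1 <= d$z0)
  if (length(bad)) stop_at(path, bad,
                           "malformed box (min corner >= max corner)")
  invisible(d)
}
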