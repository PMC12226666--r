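#' Fusion configuration
#'
#' Parameters governing within-model de-duplication and cross-model
#' ensemble fusion.
#'
#' @param dedup_iou_threshold IoU above which two same-model boxes count
#'   as duplicates (default 0.5, i.e. suppression when IoU exceeds 50%).
#' @param cross_model_overlap_rule how two boxes from *different* models
#'   are deemed overlapping during fusion: `"positive-intersection"`
#'   (any shared voxel, the default) or `"iou-threshold"`.
#' @param cross_model_iou_threshold IoU threshold used when
#'   `cross_model_overlap_rule = "iou-threshold"`; defaults to
#'   `dedup_iou_threshold`.
#' @param score_aggregation how the fused probability is aggregated from
#'   the contributing representatives: `"mean"` (default) or `"max"`.
#' @return a list of class `fusion_config`.
#' @export
fusion_config <- function(dedup_iou_threshold = 0.5,
                          cross_model_overlap_rule = c("positive-intersection",
                                                       "iou-threshold"),
                          cross_model_iou_threshold = dedup_iou_threshold,
                          score_aggregation = c("mean", "max")) {
  stopifnot(is.numeric(dedup_iou_threshold), length(dedup_iou_threshold) == 1L,
            dedup_iou_threshold > 0, dedup_iou_threshold < 1)
  structure(list(
    dedup_iou_threshold = dedup_iou_threshold,
    cross_model_overlap_rule = match.arg(cross_model_overlap_rule),
    cross_model_iou_threshold = cross_model_iou_threshold,
    score_aggregation = match.arg(score_aggregation)
  ), class = "fusion_config")
}

# Deterministic greedy order: score descending, ties broken by
# lexicographic minimum corner (then maximum corner).
greedy_order <- function(dets) {
  order(-dets$score, dets$x0, dets$y0, dets$z0, dets$x1, dets$y1, dets$z1)
}

#' Within-model non-maximum suppression
#'
#' Filters one detector's output so that no two retained boxes overlap
#' by more than the IoU threshold, keeping the boxes with the highest
#' probability scores: boxes are visited in descending score order and a
#' box is accepted iff its IoU with every already-accepted box does not
#' exceed the threshold. Score ties are broken by lexicographic minimum
#' corner so the result is deterministic.
#'
#' @param dets data frame of scored boxes from a *single* model: columns
#'   `x0..z1`, `score`, `model_id`, `category`, `label`.
#' @param cfg a [fusion_config()].
#' @return the surviving rows, sorted by descending score.
#' @export
nms_filter <- function(dets, cfg = fusion_config()) {
  stopifnot(is.data.frame(dets))
  if (nrow(dets) == 0L) return(dets)
  if ("model_id" %in% names(dets) && length(unique(dets$model_id)) > 1L)
    stop("nms_filter expects detections from a single model; got model_ids: ",
         paste(unique(dets$model_id), collapse = ", "), call. = FALSE)
  validate_boxes(dets, "nms_filter")
  ord <- greedy_order(dets)
  iou <- iou_matrix(dets)
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) || all(iou[i, keep] <= cfg$dedup_iou_threshold))
      keep <- c(keep, i)
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fuse per-category detector outputs into CWIS-labeled detections
#'
#' Ensemble fusion of the three category-specific detectors (fracture
#' type, displacement, location). Each input list must already be
#' de-duplicated within its model (see [nms_filter()]). An overlap graph
#' is built over all boxes, with an edge between boxes of *different*
#' models that overlap under the configured rule; its connected
#' components are candidate fractures. Components supported by fewer
#' than two models are discarded (a fracture must be seen by at least
#' two detectors). For each surviving component the highest-scoring box
#' per model is taken as that model's representative; the fused box is
#' the smallest axis-aligned box containing all representatives (their
#' union hull), the CWIS triple is read off the representatives'
#' category labels, and a category whose model is absent from the
#' component gets the label `"unknown"`. The fused score aggregates the
#' representatives' scores (mean by default).
#'
#' @param type_dets,disp_dets,loc_dets data frames of scored boxes (may
#'   be `NULL` or empty) with columns `x0..z1`, `score`, `label`,
#'   `category`, `model_id`, optionally `scan_id`.
#' @param cfg a [fusion_config()].
#' @return data frame of fused detections: corner columns, `type`,
#'   `displacement`, `location` (each possibly `"unknown"`), `score`,
#'   `n_contributors`, `contributors` (semicolon-joined model ids) and
#'   per-category source scores `score_type`, `score_displacement`,
#'   `score_location` (`NA` where the category is unknown).
#' @export
fuse_models <- function(type_dets = NULL, disp_dets = NULL, loc_dets = NULL,
                        cfg = fusion_config()) {
  parts <- list(type_dets, disp_dets, loc_dets)
  parts <- Filter(function(d) !is.null(d) && nrow(d) > 0L, parts)
  empty <- fused_empty()
  if (!length(parts)) return(empty)
  all <- do.call(rbind, lapply(parts, function(d) {
    d <- d[, intersect(c("scan_id", "model_id", "category", "label", "score",
                         box_cols), names(d)), drop = FALSE]
    if (is.null(d$scan_id)) d$scan_id <- NA_character_
    d
  }))
  validate_boxes(all, "fuse_models")
  stopifnot(all(all$category %in% cwis_categories))
  n <- nrow(all)

  # overlap graph over boxes of different models
  adj <- switch(cfg$cross_model_overlap_rule,
    "positive-intersection" = intersection_matrix(all) > 0,
    "iou-threshold" = iou_matrix(all) > cfg$cross_model_iou_threshold)
  same_model <- outer(all$model_id, all$model_id, `==`)
  adj <- adj & !same_model

  comp <- connected_components(adj)
  out <- lapply(split(seq_len(n), comp), function(idx) {
    members <- all[idx, , drop = FALSE]
    models <- unique(members$model_id)
    if (length(models) < 2L) return(NULL)
    # per model present, keep its highest-score box (deterministic ties)
    rep_rows <- do.call(rbind, lapply(split(members, members$model_id),
                                      function(m) m[greedy_order(m)[1L], ]))
    hull <- box_union_hull(rep_rows)
    lab <- stats::setNames(rep("unknown", 3L), cwis_categories)
    src <- stats::setNames(rep(NA_real_, 3L), cwis_categories)
    for (cat in cwis_categories) {
      cand <- rep_rows[rep_rows$category == cat, , drop = FALSE]
      if (nrow(cand)) {
        best <- cand[greedy_order(cand)[1L], ]
        lab[cat] <- best$label
        src[cat] <- best$score
      }
    }
    score <- switch(cfg$score_aggregation,
                    mean = mean(rep_rows$score), max = max(rep_rows$score))
    data.frame(scan_id = members$scan_id[1L], hull,
               type = lab[["type"]], displacement = lab[["displacement"]],
               location = lab[["location"]], score = score,
               n_contributors = length(models),
               contributors = paste(sort(models), collapse = ";"),
               score_type = src[["type"]],
               score_displacement = src[["displacement"]],
               score_location = src[["location"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out <- out[order(-out$score, out$x0, out$y0, out$z0), , drop = FALSE]
  rownames(out) <- NULL
  out
}

fused_empty <- function() {
  data.frame(scan_id = character(0), x0 = integer(0), y0 = integer(0),
             z0 = integer(0), x1 = integer(0), y1 = integer(0),
             z1 = integer(0), type = character(0), displacement = character(0),
             location = character(0), score = numeric(0),
             n_contributors = integer(0), contributors = character(0),
             score_type = numeric(0), score_displacement = numeric(0),
             score_location = numeric(0), stringsAsFactors = FALSE)
}

# Connected components of an undirected adjacency matrix via union-find.
connected_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (adj[i, j]) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <- ri }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
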