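#' Match detections against sphere-encoded reference fractures
#'
#' Reference fractures are encoded as spheres of physical radius
#' `radius_mm` (10 mm by default) centered on the fracture. A detection
#' may match a reference iff its box intersects the reference sphere,
#' tested via the closest point of the (continuous) box to the center
#' under anisotropic voxel spacing. Matching is one-to-one: detections
#' are assigned in descending score order, each preferring the closest
#' candidate reference, and an augmenting-path pass guarantees the
#' matching has maximum cardinality (a lower-scored detection never
#' loses its only reference to a higher-scored one that has an
#' alternative). Unmatched detections are false positives — in
#' particular a second detection of an already-matched reference counts
#' as a false positive, the behaviour seen when a displaced fracture is
#' reported as two fractures — and unmatched references are false
#' negatives.
#'
#' @param dets data frame of detections for one scan: corner columns
#'   `x0..z1` and `score` (other columns such as the CWIS labels and
#'   `rib_label` are carried along for downstream metrics).
#' @param refs data frame of reference fractures for the same scan:
#'   `cx, cy, cz` (voxel coordinates), `radius_mm`, CWIS label columns,
#'   optionally `rib_label`.
#' @param spacing numeric length-3 voxel size in mm.
#' @return object of class `match_result`: `scan_id`, `tp` (data frame
#'   of matched det/ref index pairs with center distance in mm), `fp`
#'   (detection indices), `fn` (reference indices), and the input `dets`
#'   and `refs` tables.
#' @export
match_detections <- function(dets, refs, spacing) {
  stopifnot(is.numeric(spacing), length(spacing) == 3L, all(spacing > 0))
  dets <- dets %||% fused_empty()
  nd <- nrow(dets); nr <- nrow(refs)
  scan_ids <- unique(stats::na.omit(c(
    if (nd) as.character(dets$scan_id) else character(0),
    if (nr) as.character(refs$scan_id) else character(0))))
  if (length(scan_ids) > 1L)
    stop("match_detections expects one scan; got scan_ids: ",
         paste(scan_ids, collapse = ", "), call. = FALSE)
  if (nd) validate_boxes(dets, "match_detections")
  radius <- if (nr && !is.null(refs$radius_mm)) refs$radius_mm else
    rep(10, nr)
  stopifnot(all(radius > 0))

  # candidate pairs: box-sphere intersection in physical mm
  cand <- NULL
  if (nd && nr) {
    lo <- as.matrix(dets[min_cols]); hi <- as.matrix(dets[max_cols])
    ctr <- as.matrix(refs[c("cx", "cy", "cz")])
    pairs <- expand.grid(det = seq_len(nd), ref = seq_len(nr))
    d2 <- numeric(nrow(pairs))
    for (ax in 1:3) {
      cl <- pmin(pmax(ctr[pairs$ref, ax], lo[pairs$det, ax]),
                 hi[pairs$det, ax])
      d2 <- d2 + ((cl - ctr[pairs$ref, ax]) * spacing[ax])^2
    }
    pairs$dist <- sqrt(d2)
    cand <- pairs[pairs$dist <= radius[pairs$ref], , drop = FALSE]
  }

  tp <- data.frame(det = integer(0), ref = integer(0), dist = numeric(0))
  if (!is.null(cand) && nrow(cand)) {
    score <- if (!is.null(dets$score)) dets$score else rep(0, nd)
    dist <- matrix(Inf, nd, nr)
    dist[cbind(cand$det, cand$ref)] <- cand$dist
    ref_of <- bipartite_match(dist, order(-score, seq_len(nd)))
    hit <- which(!is.na(ref_of))
    tp <- data.frame(det = hit, ref = ref_of[hit],
                     dist = dist[cbind(hit, ref_of[hit])])
    tp <- tp[order(-score[tp$det], tp$dist), , drop = FALSE]
  }
  fp <- setdiff(seq_len(nd), tp$det)
  fn <- setdiff(seq_len(nr), tp$ref)
  stopifnot(nrow(tp) + length(fn) == nr, nrow(tp) + length(fp) == nd,
            !anyDuplicated(tp$det), !anyDuplicated(tp$ref))
  rownames(tp) <- NULL
  structure(list(scan_id = if (length(scan_ids)) scan_ids else NA_character_,
                 tp = tp, fp = fp, fn = fn, dets = dets, refs = refs),
            class = "match_result")
}

# Maximum-cardinality one-to-one matching (Kuhn's augmenting paths).
# `dist` is a dets x refs matrix with Inf marking infeasible pairs;
# detections are processed in `det_order` and each prefers its closest
# feasible reference, so among maximum matchings the greedy
# score-then-distance assignment is realized wherever possible.
bipartite_match <- function(dist, det_order) {
  nd <- nrow(dist); nr <- ncol(dist)
  ref_of <- rep(NA_integer_, nd)
  det_of <- rep(NA_integer_, nr)
  augment_rec <- function(i, visited) {
    for (j in order(dist[i, ])) {
      if (!is.finite(dist[i, j]) || visited[j]) next
      visited[j] <- TRUE
      holder <- det_of[j]
      if (is.na(holder)) {
        ref_of[i] <<- j; det_of[j] <<- i
        return(list(ok = TRUE, visited = visited))
      }
      res <- augment_rec(holder, visited)
      visited <- res$visited
      if (res$ok) {
        ref_of[i] <<- j; det_of[j] <<- i
        return(list(ok = TRUE, visited = visited))
      }
    }
    list(ok = FALSE, visited = visited)
  }
  for (i in det_order) augment_rec(i, rep(FALSE, nr))
  ref_of
}

as_match_list <- function(matches) {
  if (inherits(matches, "match_result")) list(matches) else {
    stopifnot(all(vapply(matches, inherits, logical(1), "match_result")))
    matches
  }
}

#' Pooled detection metrics
#'
#' Pools true/false positive and false negative counts over scans and
#' reports detection sensitivity TP/(TP+FN), precision TP/(TP+FP), their
#' harmonic mean F1, and the mean number of false positives per scan
#' (FPPS = total FP / number of scans). A macro average (per-scan mean
#' of sensitivity/precision) is available as an option. Rounding is a
#' presentation concern only: percentages print with 0 decimals and
#' FPPS with 2, but stored values are exact.
#'
#' @param matches a [match_detections()] result or list of them (one per
#'   scan).
#' @param average `"pooled"` (default) or `"macro"`.
#' @return object of class `detection_metrics` with fields
#'   `sensitivity`, `precision`, `f1`, `fpps`, `tp`, `fp`, `fn`,
#'   `n_scans`.
#' @export
detection_metrics <- function(matches, average = c("pooled", "macro")) {
  average <- match.arg(average)
  ml <- as_match_list(matches)
  stopifnot(length(ml) >= 1L)
  tp <- sum(vapply(ml, function(m) nrow(m$tp), integer(1)))
  fp <- sum(vapply(ml, function(m) length(m$fp), integer(1)))
  fn <- sum(vapply(ml, function(m) length(m$fn), integer(1)))
  n_scans <- length(ml)
  if (average == "pooled") {
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  } else {
    per <- vapply(ml, function(m) {
      t <- nrow(m$tp)
      c(s = if (t + length(m$fn) > 0) t / (t + length(m$fn)) else NA_real_,
        p = if (t + length(m$fp) > 0) t / (t + length(m$fp)) else NA_real_)
    }, numeric(2))
    sens <- mean(per["s", ], na.rm = TRUE)
    prec <- mean(per["p", ], na.rm = TRUE)
  }
  f1 <- if (!is.na(sens) && !is.na(prec) && sens + prec > 0)
    2 * sens * prec / (sens + prec) else NA_real_
  structure(list(sensitivity = sens, precision = prec, f1 = f1,
                 fpps = fp / n_scans, tp = tp, fp = fp, fn = fn,
                 n_scans = n_scans, average = average),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "undefined" else
    sprintf("%.0f%%", 100 * v)
  cat(sprintf("Detection metrics (%s, %d scan%s):\n", x$average, x$n_scans,
              if (x$n_scans == 1) "" else "s"))
  cat(sprintf("  sensitivity %s  precision %s  F1 %s  FPPS %.2f\n",
              pct(x$sensitivity), pct(x$precision), pct(x$f1), x$fpps))
  cat(sprintf("  TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Per-class detection sensitivity and precision
#'
#' For each CWIS category value v: sensitivity is the fraction of
#' reference fractures labeled v that were detected (matched), and
#' precision the fraction of detections predicted v that are true
#' positives. Also reports the composition of the missed fractures (the
#' share of false negatives per value). Classes absent from both
#' references and predictions yield `NA` entries.
#'
#' @param matches a [match_detections()] result or list of them. The
#'   stored `dets`/`refs` tables must carry the CWIS label columns.
#' @return data frame with `category`, `label`, `n_refs`, `tp_refs`,
#'   `sensitivity`, `n_pred`, `tp_pred`, `precision`, `fn`,
#'   `missed_share`.
#' @export
per_class_metrics <- function(matches) {
  ml <- as_match_list(matches)
  rows <- list()
  total_fn <- sum(vapply(ml, function(m) length(m$fn), integer(1)))
  for (cat in cwis_categories) {
    for (v in cwis_vocab[[cat]]) {
      n_refs <- tp_refs <- n_pred <- tp_pred <- fn_v <- 0L
      for (m in ml) {
        rl <- m$refs[[cat]]
        if (!is.null(rl)) {
          n_refs <- n_refs + sum(rl == v)
          tp_refs <- tp_refs + sum(rl[m$tp$ref] == v)
          fn_v <- fn_v + sum(rl[m$fn] == v)
        }
        dl <- m$dets[[cat]]
        if (!is.null(dl)) {
          n_pred <- n_pred + sum(dl == v)
          tp_pred <- tp_pred + sum(dl[m$tp$det] == v)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat, label = v, n_refs = n_refs, tp_refs = tp_refs,
        sensitivity = if (n_refs > 0) tp_refs / n_refs else NA_real_,
        n_pred = n_pred, tp_pred = tp_pred,
        precision = if (n_pred > 0) tp_pred / n_pred else NA_real_,
        fn = fn_v,
        missed_share = if (total_fn > 0) fn_v / total_fn else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Classification confusion matrices over true positives
#'
#' For each CWIS category, counts reference label (rows) against
#' predicted label (columns, including `"unknown"`) over the true
#' positive pairs only — a missed fracture cannot be classified, so
#' false negatives do not enter, and false positives have no reference
#' label.
#'
#' @param matches a [match_detections()] result or list of them.
#' @return named list of 3 x 4 integer matrices, one per category.
#' @export
confusion_matrices <- function(matches) {
  ml <- as_match_list(matches)
  out <- list()
  for (cat in cwis_categories) {
    ref_levels <- cwis_vocab[[cat]]
    pred_levels <- c(ref_levels, "unknown")
    m0 <- matrix(0L, length(ref_levels), length(pred_levels),
                 dimnames = list(reference = ref_levels,
                                 predicted = pred_levels))
    for (m in ml) {
      if (!nrow(m$tp)) next
      rl <- m$refs[[cat]][m$tp$ref]
      dl <- m$dets[[cat]][m$tp$det]
      if (is.null(rl) || is.null(dl)) next
      tab <- table(factor(rl, ref_levels), factor(dl, pred_levels))
      m0 <- m0 + unclass(tab)
    }
    out[[cat]] <- m0
  }
  out
}

#' Rib-number assignment accuracy
#'
#' Share of true-positive detections whose assigned rib equals the
#' reference fracture's rib. The denominator is the matched detections
#' that carry a rib assignment (detections discarded for lacking rib
#' overlap are excluded) and whose reference has a rib number.
#'
#' @param matches a [match_detections()] result or list of them; the
#'   `dets` and `refs` tables must carry a `rib_label` column (1-24).
#' @return list of class `rib_accuracy`: `accuracy` (fraction, `NA` if
#'   no eligible pairs), `n_correct`, `n_total`.
#' @export
rib_number_accuracy <- function(matches) {
  ml <- as_match_list(matches)
  n_correct <- n_total <- 0L
  for (m in ml) {
    if (!nrow(m$tp)) next
    dl <- m$dets$rib_label[m$tp$det]
    rl <- m$refs$rib_label[m$tp$ref]
    ok <- !is.na(dl) & !is.na(rl)
    n_total <- n_total + sum(ok)
    n_correct <- n_correct + sum(dl[ok] == rl[ok])
  }
  structure(list(accuracy = if (n_total > 0) n_correct / n_total else
                   NA_real_,
                 n_correct = n_correct, n_total = n_total),
            class = "rib_accuracy")
}

#' @export
print.rib_accuracy <- function(x, ...) {
  if (is.na(x$accuracy)) cat("Rib number accuracy: undefined (no eligible",
                             "true positives)\n")
  else cat(sprintf("Rib number accuracy: %.0f%% (%d/%d)\n",
                   100 * x$accuracy, x$n_correct, x$n_total))
  invisible(x)
}

#' Choose the detection-score operating point for a target sensitivity
#'
#' Sweeps all candidate score thresholds (the observed detection
#' scores) and returns the largest threshold t such that keeping
#' detections with score >= t and matching them to the references
#' yields pooled sensitivity at or above the target — the rule used to
#' set the deployment threshold from a training set (e.g. 82% training
#' sensitivity). If even the lowest threshold cannot attain the target,
#' the minimum score minus a small epsilon is returned with a warning.
#'
#' @param dets detections over a scan set (data frame with `scan_id`,
#'   corner columns and `score`).
#' @param refs references over the same scan set (with `scan_id`).
#' @param spacing voxel spacing in mm.
#' @param target_sensitivity fraction in (0, 1].
#' @return the chosen threshold (numeric scalar).
#' @export
choose_operating_point <- function(dets, refs, spacing,
                                   target_sensitivity) {
  stopifnot(target_sensitivity > 0, target_sensitivity <= 1)
  if (is.null(dets) || nrow(dets) == 0L)
    stop("choose_operating_point: empty detection set", call. = FALSE)
  sens_at <- function(t) {
    kept <- dets[dets$score >= t, , drop = FALSE]
    ml <- match_by_scan(kept, refs, spacing)
    detection_metrics(ml)$sensitivity
  }
  cand <- sort(unique(dets$score), decreasing = TRUE)
  for (t in cand) {
    s <- sens_at(t)
    if (!is.na(s) && s >= target_sensitivity) return(t)
  }
  warning(sprintf(
    "target sensitivity %.2f unattainable at any threshold; returning below the minimum score",
    target_sensitivity), call. = FALSE)
  min(dets$score) - 1e-6
}

#' Match detections and references scan by scan
#'
#' Splits multi-scan detection and reference tables on `scan_id` and
#' runs [match_detections()] per scan (scans present in either table
#' are included).
#'
#' @inheritParams choose_operating_point
#' @return list of `match_result`, one per scan.
#' @export
match_by_scan <- function(dets, refs, spacing) {
  scans <- sort(unique(c(as.character(refs$scan_id),
                         if (!is.null(dets) && nrow(dets))
                           as.character(dets$scan_id) else character(0))))
  lapply(scans, function(s) {
    match_detections(dets[!is.null(dets$scan_id) & dets$scan_id == s, ,
                          drop = FALSE],
                     refs[refs$scan_id == s, , drop = FALSE], spacing)
  })
}

#' Detection metrics stratified by scan group
#'
#' Computes [detection_metrics()] separately within groups of scans,
#' e.g. thin versus thick slice spacing. Every scan must be assigned to
#' exactly one group; groups without scans are absent from the result.
#'
#' @param matches list of `match_result` (one per scan).
#' @param scan_groups named character vector mapping `scan_id` to group.
#' @return named list of `detection_metrics`, one per group present.
#' @export
stratified_metrics <- function(matches, scan_groups) {
  ml <- as_match_list(matches)
  ids <- vapply(ml, function(m) as.character(m$scan_id), character(1))
  unknown <- setdiff(ids, names(scan_groups))
  if (length(unknown))
    stop("stratified_metrics: scan(s) missing from grouping: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  groups <- scan_groups[ids]
  out <- lapply(split(ml, groups), detection_metrics)
  out[lengths(out) > 0]
}
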