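# Independent oracles and fixture builders. Everything here is written
# against the definitions, not against the package internals: IoU by
# voxel enumeration, suppression by a literal re-reading of the greedy
# rule, matching by exhaustive search, agreement by the textbook
# formulas.

# -- voxel-enumeration IoU (boxes with coordinates < 64) ----------------
voxel_codes <- function(b) {
  g <- expand.grid(x = b$x0:(b$x1 - 1L), y = b$y0:(b$y1 - 1L),
                   z = b$z0:(b$z1 - 1L))
  g$x + 64L * g$y + 4096L * g$z
}

oracle_iou <- function(a, b) {
  va <- voxel_codes(a); vb <- voxel_codes(b)
  length(intersect(va, vb)) / length(union(va, vb))
}

# -- independent greedy suppression ------------------------------------
oracle_nms <- function(dets, thr) {
  ord <- order(-dets$score, dets$x0, dets$y0, dets$z0,
               dets$x1, dets$y1, dets$z1)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (k in kept)
      if (oracle_iou(dets[i, ], dets[k, ]) > thr) { ok <- FALSE; break }
    if (ok) kept <- c(kept, i)
  }
  dets[kept, , drop = FALSE]
}

random_boxes <- function(n, max_corner = 14L, max_ext = 6L,
                         round_scores = FALSE) {
  lo <- matrix(sample(0:max_corner, 3L * n, replace = TRUE), ncol = 3)
  ext <- matrix(sample(1:max_ext, 3L * n, replace = TRUE), ncol = 3)
  d <- data.frame(x0 = lo[, 1], y0 = lo[, 2], z0 = lo[, 3],
                  x1 = lo[, 1] + ext[, 1], y1 = lo[, 2] + ext[, 2],
                  z1 = lo[, 3] + ext[, 3],
                  score = stats::runif(n), model_id = "m1",
                  category = "type", label = "simple",
                  stringsAsFactors = FALSE)
  if (round_scores) d$score <- round(d$score, 1)  # exercises tie-breaks
  d
}

# -- exhaustive maximum one-to-one matching ----------------------------
oracle_max_matching <- function(feas) {
  nd <- nrow(feas); nr <- ncol(feas)
  if (nd == 0L || nr == 0L) return(0L)
  rec <- function(i, used) {
    if (i > nd) return(0L)
    best <- rec(i + 1L, used)
    for (j in seq_len(nr)) if (feas[i, j] && !used[j])
      best <- max(best, 1L + rec(i + 1L, replace(used, j, TRUE)))
    best
  }
  rec(1L, rep(FALSE, nr))
}

# independent box-sphere feasibility (closest point, physical mm)
oracle_feasible <- function(det, ref, spacing, radius) {
  ctr <- c(ref$cx, ref$cy, ref$cz)
  cl <- pmin(pmax(ctr, c(det$x0, det$y0, det$z0)),
             c(det$x1, det$y1, det$z1))
  sqrt(sum(((cl - ctr) * spacing)^2)) <= radius
}

# -- textbook Krippendorff alpha (nominal, any number of raters) -------
oracle_alpha <- function(values) {
  values <- as.matrix(values)
  units <- lapply(seq_len(nrow(values)), function(u)
    as.character(stats::na.omit(values[u, ])))
  units <- Filter(function(r) length(r) >= 2L, units)
  pool <- unlist(units)
  n <- sum(vapply(units, length, integer(1)))
  # observed disagreement: average pairwise mismatch within units,
  # weighted 1/(m_u - 1)
  do <- 0
  for (r in units) {
    m <- length(r)
    for (a in seq_len(m)) for (b in seq_len(m)) if (a != b)
      do <- do + (r[a] != r[b]) / (m - 1)
  }
  do <- do / n
  tab <- table(pool)
  de <- (sum(tab %o% tab) - sum(tab^2)) / (n * (n - 1))
  if (de == 0) return(1)
  1 - do / de
}

# -- structural match-set builder (for metric arithmetic) ---------------
make_match <- function(tp, fp, fn, scan_id = "s1") {
  structure(list(
    scan_id = scan_id,
    tp = data.frame(det = seq_len(tp), ref = seq_len(tp),
                    dist = rep(0, tp)),
    fp = if (fp) tp + seq_len(fp) else integer(0),
    fn = if (fn) tp + seq_len(fn) else integer(0),
    dets = data.frame(score = rep(1, tp + fp)),
    refs = data.frame(idx = seq_len(tp + fn))), class = "match_result")
}

# -- geometric scan fixture: well-separated references + detections -----
make_scan <- function(n_refs, spacing = c(1, 1, 1), gap = 30,
                      scan_id = "s1") {
  k <- ceiling(n_refs^(1 / 3))
  g <- expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k))[
    seq_len(n_refs), ]
  data.frame(scan_id = scan_id, cx = g$x * gap, cy = g$y * gap,
             cz = g$z * gap, radius_mm = 10,
             type = "simple", displacement = "undisplaced",
             location = "lateral", rib_label = ((seq_len(n_refs) - 1L) %%
                                                24L) + 1L,
             stringsAsFactors = FALSE)
}

# detection box of half-size `h` voxels centered on a reference
det_on_ref <- function(ref, score, h = 5L, label = list()) {
  d <- data.frame(scan_id = ref$scan_id,
                  x0 = ref$cx - h, y0 = ref$cy - h, z0 = ref$cz - h,
                  x1 = ref$cx + h, y1 = ref$cy + h, z1 = ref$cz + h,
                  score = score, type = "simple",
                  displacement = "undisplaced", location = "lateral",
                  rib_label = ref$rib_label, stringsAsFactors = FALSE)
  for (nm in names(label)) d[[nm]] <- label[[nm]]
  d
}

box_cols <- function() c("x0", "y0", "z0", "x1", "y1", "z1")

# cubic scored box [lo, hi)^3
det_box <- function(lo, hi, score, model = "m1", cat = "type",
                    label = "simple") {
  data.frame(x0 = lo, y0 = lo, z0 = lo, x1 = hi, y1 = hi, z1 = hi,
             score = score, model_id = model, category = cat,
             label = label, stringsAsFactors = FALSE)
}
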