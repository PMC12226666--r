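sp1 <- c(1, 1, 1)

test_that("matching pairs detections with reference spheres one-to-one", {
  refs <- make_scan(1)
  m <- match_detections(det_on_ref(refs[1, ], 0.9), refs, sp1)
  expect_equal(nrow(m$tp), 1L)
  expect_length(m$fp, 0)
  expect_length(m$fn, 0)
  # a second detection of the same reference is a false positive
  two <- rbind(det_on_ref(refs[1, ], 0.9), det_on_ref(refs[1, ], 0.8))
  m2 <- match_detections(two, refs, sp1)
  expect_equal(nrow(m2$tp), 1L)
  expect_equal(m2$tp$det, 1L)  # the higher score holds the match
  expect_equal(m2$fp, 2L)
  # far-away detection is FP, lone reference FN
  far <- det_on_ref(refs[1, ], 0.5)
  far[box_cols()] <- far[box_cols()] + 500
  m3 <- match_detections(far, refs, sp1)
  expect_equal(nrow(m3$tp), 0L)
  expect_equal(m3$fp, 1L)
  expect_equal(m3$fn, 1L)
  # mixed scans rejected
  refs2 <- refs; refs2$scan_id <- "other"
  expect_error(match_detections(det_on_ref(refs[1, ], 0.9), refs2, sp1),
               "one scan")
})

test_that("match counts are conserved and matching attains the maximum", {
  set.seed(17)
  for (trial in 1:300) {
    nr <- sample(1:5, 1); nd <- sample(0:6, 1)
    refs <- make_scan(nr, gap = sample(c(12, 18, 30), 1))
    dets <- NULL
    if (nd > 0) {
      dets <- do.call(rbind, lapply(seq_len(nd), function(i) {
        r <- refs[sample(nr, 1), ]
        d <- det_on_ref(r, runif(1), h = sample(4:9, 1))
        d[box_cols()] <- d[box_cols()] + round(rnorm(1, 0, 6))
        d
      }))
    }
    m <- match_detections(dets, refs, sp1)
    expect_equal(nrow(m$tp) + length(m$fn), nr)
    expect_equal(nrow(m$tp) + length(m$fp), nd)
    feas <- matrix(FALSE, max(nd, 0), nr)
    if (nd > 0) for (i in 1:nd) for (j in 1:nr)
      feas[i, j] <- oracle_feasible(dets[i, ], refs[j, ], sp1,
                                    refs$radius_mm[j])
    expect_equal(nrow(m$tp), oracle_max_matching(feas))
  }
})

test_that("pooled metrics reproduce the worked arithmetic", {
  # 80 TP, 20 FN, 12 FP: sensitivity 80%, precision 87%, F1 83%
  dm <- detection_metrics(make_match(80, 12, 20))
  expect_equal(round(100 * dm$sensitivity), 80)
  expect_equal(round(100 * dm$precision), 87)
  expect_equal(round(100 * dm$f1), 83)
  # 27 false positives spread over 28 scans: FPPS 0.96
  ml <- c(lapply(1:27, function(i) make_match(1, 1, 0, paste0("s", i))),
          list(make_match(1, 0, 0, "s28")))
  expect_equal(round(detection_metrics(ml)$fpps, 2), 0.96)
  # perfect detection
  dm3 <- detection_metrics(make_match(10, 0, 0))
  expect_equal(dm3$sensitivity, 1)
  expect_equal(dm3$precision, 1)
  expect_equal(dm3$f1, 1)
  expect_equal(dm3$fpps, 0)
  # no references: sensitivity undefined
  dm4 <- detection_metrics(make_match(0, 3, 0))
  expect_true(is.na(dm4$sensitivity))
})

test_that("per-class sensitivity and precision count correctly", {
  refs <- make_scan(6)
  refs$type <- c(rep("simple", 4), rep("wedge", 2))
  # find 3 of 4 simple and 1 of 2 wedge
  dets <- do.call(rbind, lapply(c(1, 2, 3, 5), function(i)
    det_on_ref(refs[i, ], 0.9, label = list(type = refs$type[i]))))
  m <- match_detections(dets, refs, sp1)
  pc <- per_class_metrics(m)
  expect_equal(pc$sensitivity[pc$label == "simple"], 0.75)
  expect_equal(pc$sensitivity[pc$label == "wedge"], 0.5)
  # complex absent everywhere: entry reported absent (NA)
  expect_true(is.na(pc$sensitivity[pc$label == "complex"]))
  expect_true(is.na(pc$precision[pc$label == "complex"]))
  # all found, single class
  m2 <- match_detections(do.call(rbind, lapply(1:6, function(i)
    det_on_ref(refs[i, ], 0.9, label = list(type = refs$type[i])))),
    refs, sp1)
  pc2 <- per_class_metrics(m2)
  expect_equal(pc2$sensitivity[pc2$label == "simple"], 1)
  expect_equal(pc2$precision[pc2$label == "simple"], 1)
  # missed-fracture composition sums to 1 over each category
  fn_share <- sum(pc$missed_share[pc$category == "type"], na.rm = TRUE)
  expect_equal(fn_share, 1)
})

test_that("confusion matrices count reference vs predicted labels", {
  refs <- make_scan(4)
  refs$type <- c("simple", "wedge", "complex", "simple")
  dets <- do.call(rbind, lapply(1:4, function(i)
    det_on_ref(refs[i, ], 0.9, label = list(type = refs$type[i]))))
  cm <- confusion_matrices(match_detections(dets, refs, sp1))
  expect_equal(sum(diag(cm$type[, 1:3])), 4)
  expect_equal(sum(cm$type), 4)
  # row sums equal per-class TP counts
  expect_equal(unname(rowSums(cm$type)), c(2, 1, 1))
  # an unknown prediction lands in the unknown column
  dets$location <- "unknown"
  cm2 <- confusion_matrices(match_detections(dets, refs, sp1))
  expect_equal(sum(cm2$location[, "unknown"]), 4)
  # permutation invariance
  perm <- c(3, 1, 4, 2)
  cm3 <- confusion_matrices(match_detections(dets[perm, ], refs, sp1))
  expect_equal(cm3, cm2)
})

test_that("rib-number accuracy is computed over assigned true positives", {
  refs <- make_scan(50)
  dets <- do.call(rbind, lapply(1:50, function(i)
    det_on_ref(refs[i, ], 0.9)))
  dets$rib_label[1:3] <- dets$rib_label[1:3] %% 24L + 1L  # 3 wrong
  acc <- rib_number_accuracy(match_detections(dets, refs, sp1))
  expect_equal(round(100 * acc$accuracy), 94)
  expect_equal(acc$n_total, 50L)
  # discarded detections (no rib assignment) leave the denominator
  dets$rib_label[4:8] <- NA
  acc2 <- rib_number_accuracy(match_detections(dets, refs, sp1))
  expect_equal(acc2$n_total, 45L)
  # all correct
  dets2 <- do.call(rbind, lapply(1:50, function(i)
    det_on_ref(refs[i, ], 0.9)))
  expect_equal(rib_number_accuracy(
    match_detections(dets2, refs, sp1))$accuracy, 1)
  # no true positives: undefined
  expect_true(is.na(rib_number_accuracy(
    match_detections(NULL, refs, sp1))$accuracy))
})

test_that("the operating point is the largest threshold meeting the target", {
  refs <- make_scan(5)
  dets <- do.call(rbind, lapply(1:5, function(i)
    det_on_ref(refs[i, ], c(0.9, 0.8, 0.7, 0.6, 0.5)[i])))
  # target 0.8: keeping the top 4 scores suffices
  expect_equal(choose_operating_point(dets, refs, sp1, 0.8), 0.6)
  # target 1.0 attainable: threshold is the minimum TP score
  expect_equal(choose_operating_point(dets, refs, sp1, 1.0), 0.5)
  # one reference never detected: unattainable, warns
  refs6 <- make_scan(6)  # first 5 coincide with refs, 6th is uncovered
  expect_warning(t <- choose_operating_point(dets, refs6, sp1, 1.0),
                 "unattainable")
  expect_lt(t, 0.5)
  expect_error(choose_operating_point(dets[0, ], refs, sp1, 0.8), "empty")
})

test_that("raising the threshold never increases TP or FP", {
  set.seed(29)
  refs <- make_scan(8)
  dets <- do.call(rbind, lapply(1:12, function(i)
    det_on_ref(refs[sample(8, 1), ], runif(1))))
  prev_tp <- Inf; prev_fp <- Inf
  for (t in sort(unique(dets$score))) {
    m <- match_detections(dets[dets$score >= t, ], refs, sp1)
    expect_lte(nrow(m$tp), prev_tp)
    expect_lte(length(m$fp), prev_fp)
    prev_tp <- nrow(m$tp); prev_fp <- length(m$fp)
  }
})

test_that("stratified metrics split scans into groups", {
  m1 <- make_match(8, 2, 2, "a1")   # group thin
  m2 <- make_match(6, 1, 4, "a2")   # group thin
  m3 <- make_match(5, 5, 0, "b1")   # group thick
  groups <- c(a1 = "thin", a2 = "thin", b1 = "thick")
  sm <- stratified_metrics(list(m1, m2, m3), groups)
  expect_equal(sort(names(sm)), c("thick", "thin"))
  expect_equal(sm$thin$sensitivity, 14 / 20)
  expect_equal(sm$thin$precision, 14 / 17)
  expect_equal(sm$thick$fpps, 5)
  # single group equals pooled metrics
  sm1 <- stratified_metrics(list(m1, m2), c(a1 = "g", a2 = "g"))
  expect_equal(sm1$g, detection_metrics(list(m1, m2)))
  expect_error(stratified_metrics(list(m1), c(zz = "g")), "missing")
})
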