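sp1 <- c(1, 1, 1)

# scatter n well-separated annotation points (>= 2 * radius apart)
obs_points <- function(n, gap = 30) {
  k <- ceiling(n^(1 / 3))
  g <- expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k))[
    seq_len(n), ]
  data.frame(scan_id = "s1", cx = g$x * gap, cy = g$y * gap, cz = g$z * gap,
             type = sample(cwis_vocab$type, n, replace = TRUE),
             displacement = sample(cwis_vocab$displacement, n,
                                   replace = TRUE),
             location = sample(cwis_vocab$location, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

test_that("observer matching recovers mutual and solo annotations", {
  set.seed(41)
  ann <- obs_points(20)
  om <- match_observers(ann, ann, sp1)
  expect_equal(unname(om$counts), c(20L, 0L, 0L, 20L))
  # annotations more than the sphere-diameter apart never match
  far <- ann[1, ]; far$cx <- far$cx + 25  # 25 mm > 20 mm
  om2 <- match_observers(ann[1, ], far, sp1)
  expect_equal(unname(om2$counts["both"]), 0L)
  # a 15 mm offset still intersects two 10 mm spheres
  near <- ann[1, ]; near$cx <- near$cx + 15
  expect_equal(unname(match_observers(ann[1, ], near,
                                      sp1)$counts[["both"]]), 1L)
})

test_that("the observer-study overlap structure is reproduced", {
  # 519 fractures: 467 mutual, 16 observer-1 only, 36 observer-2 only
  set.seed(43)
  pts <- obs_points(519)
  mutual <- pts[1:467, ]
  mutual2 <- mutual
  mutual2$cx <- mutual2$cx + sample(-4:4, 467, replace = TRUE)
  ann1 <- rbind(mutual, pts[468:483, ])       # 467 + 16
  ann2 <- rbind(mutual2, pts[484:519, ])      # 467 + 36
  om <- match_observers(ann1, ann2, sp1)
  expect_equal(unname(om$counts[["both"]]), 467L)
  expect_equal(unname(om$counts[["only_obs1"]]), 16L)
  expect_equal(unname(om$counts[["only_obs2"]]), 36L)
  expect_equal(unname(om$counts[["union"]]), 519L)
  expect_equal(nrow(om$pairs), 519L)
  expect_equal(sum(stats::complete.cases(
    om$pairs[c("type_obs1", "type_obs2")])), 467L)
})

test_that("kappa matches the hand formula and an independent package", {
  # perfect agreement
  expect_equal(cohen_kappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  # the worked 2x2 table [[20, 5], [10, 15]]: p_o = 0.7, p_e = 0.5
  x <- rep(c("a", "a", "b", "b"), c(20, 5, 10, 15))
  y <- rep(c("a", "b", "a", "b"), c(20, 5, 10, 15))
  expect_equal(cohen_kappa(x, y), 0.4)
  # observed equal to chance expectation: kappa 0
  x0 <- rep(c("a", "b"), each = 50)
  y0 <- rep(c("a", "b", "a", "b"), each = 25)
  expect_equal(cohen_kappa(x0, y0), 0)
  # both raters constant with the same value: degenerate, perfect
  expect_equal(cohen_kappa(rep("a", 5), rep("a", 5)), 1)
  # cross-check against caret's unweighted kappa on random data
  set.seed(47)
  for (i in 1:5) {
    a <- sample(letters[1:3], 200, replace = TRUE)
    b <- ifelse(runif(200) < 0.7, a, sample(letters[1:3], 200,
                                            replace = TRUE))
    lv <- letters[1:3]
    ref <- caret::confusionMatrix(factor(b, lv), factor(a, lv))
    expect_equal(cohen_kappa(a, b),
                 unname(ref$overall["Kappa"]), tolerance = 1e-10)
  }
})

test_that("alpha matches a brute-force coincidence oracle", {
  # identical complete labelings
  v <- cbind(c("a", "b", "c", "a"), c("a", "b", "c", "a"))
  expect_equal(krippendorff_alpha(v), 1)
  # tiny set with one missing rating
  v2 <- cbind(c("a", "a", "b", "b"), c("a", NA, "b", "a"))
  expect_equal(krippendorff_alpha(v2), oracle_alpha(v2))
  # systematic disagreement on binary data goes negative
  v3 <- cbind(rep(c("a", "b"), 10), rep(c("b", "a"), 10))
  expect_lt(krippendorff_alpha(v3), 0)
  expect_equal(krippendorff_alpha(v3), oracle_alpha(v3))
  # random incomplete data, several shapes
  set.seed(53)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    m <- matrix(sample(c("a", "b", "c", NA), 2 * n, replace = TRUE,
                       prob = c(0.3, 0.3, 0.2, 0.2)), ncol = 2)
    if (sum(rowSums(!is.na(m)) >= 2) < 2) next
    expect_equal(krippendorff_alpha(m), oracle_alpha(m))
  }
  # nothing pairable
  expect_warning(a <- krippendorff_alpha(cbind(c("a", "b"), c(NA, NA))),
                 "pairable")
  expect_true(is.na(a))
})

test_that("alpha and kappa converge on complete two-rater data", {
  set.seed(59)
  truth <- sample(cwis_vocab$type, 1000, replace = TRUE,
                  prob = c(0.7, 0.2, 0.1))
  flip <- function(v) ifelse(runif(1000) < 0.85, v,
                             sample(cwis_vocab$type, 1000, replace = TRUE))
  r1 <- flip(truth); r2 <- flip(truth)
  k <- cohen_kappa(r1, r2)
  a <- krippendorff_alpha(cbind(r1, r2))
  expect_lt(abs(a - k), 0.01)
})

test_that("bootstrap intervals are seeded, stable and centered", {
  df <- data.frame(a = rep(c("x", "x", "y", "y"), c(30, 8, 10, 32)),
                   b = rep(c("x", "y", "x", "y"), c(30, 8, 10, 32)),
                   stringsAsFactors = FALSE)
  stat <- function(d) cohen_kappa(d$a, d$b)
  ci1 <- bootstrap_ci(stat, df, n_boot = 500, seed = 7)
  ci2 <- bootstrap_ci(stat, df, n_boot = 500, seed = 7)
  expect_identical(ci1, ci2)
  est <- stat(df)
  expect_lte(ci1[["low"]], est)
  expect_gte(ci1[["high"]], est)
  # zero-variance data collapse to the point estimate
  same <- data.frame(a = rep(c("x", "y"), 10), b = rep(c("x", "y"), 10))
  ci0 <- bootstrap_ci(function(d) cohen_kappa(d$a, d$b), same,
                      n_boot = 200, seed = 1)
  expect_equal(unname(ci0), c(1, 1))
  # doubling the resample count moves the bounds by < 0.02
  ci4 <- bootstrap_ci(stat, df, n_boot = 1000, seed = 7)
  expect_lt(max(abs(ci4 - ci1)), 0.02)
})

test_that("agreement bands follow the documented scale", {
  expect_equal(interpret_agreement(0.74), "Substantial")
  expect_equal(interpret_agreement(0.82), "Strong")
  expect_equal(interpret_agreement(1.0), "Almost perfect")
  expect_equal(interpret_agreement(0.5), "Moderate")
  expect_equal(interpret_agreement(-0.2), "Poor")
  expect_equal(interpret_agreement(0.85, scale = "landis-koch"),
               "Almost perfect")
})

test_that("disagreements are counted per task and per fracture", {
  p <- data.frame(type_obs1 = "simple", type_obs2 = "simple",
                  displacement_obs1 = "offset", displacement_obs2 = "offset",
                  location_obs1 = "lateral", location_obs2 = "lateral",
                  stringsAsFactors = FALSE)
  expect_equal(disagreement_counts(p)$total_tasks, 0L)
  # one record differing in all three categories: 3 tasks, 1 fracture
  q <- p
  q$type_obs2 <- "wedge"; q$displacement_obs2 <- "displaced"
  q$location_obs2 <- "anterior"
  dc <- disagreement_counts(q)
  expect_equal(dc$total_tasks, 3L)
  expect_equal(dc$n_fractures, 1L)
  # constructed set with 40 / 52 / 70 category disagreements
  n <- 200
  mk <- function(n_dis, a, b) c(rep(b, n_dis), rep(a, n - n_dis))
  big <- data.frame(
    type_obs1 = rep("simple", n), type_obs2 = mk(40, "simple", "wedge"),
    displacement_obs1 = rep("offset", n),
    displacement_obs2 = mk(52, "offset", "displaced"),
    location_obs1 = rep("lateral", n),
    location_obs2 = mk(70, "lateral", "anterior"),
    stringsAsFactors = FALSE)
  dc2 <- disagreement_counts(big)
  expect_equal(unname(dc2$per_category), c(40L, 52L, 70L))
  expect_equal(dc2$total_tasks, 162L)
  # overlap structure: disagreements stacked on the first rows, so the
  # distinct-fracture count is the largest per-category count
  expect_equal(dc2$n_fractures, 70L)
})

test_that("the agreement report carries estimates, CIs and bands", {
  set.seed(61)
  ann <- obs_points(60)
  ann2 <- ann
  for (cat in cwis_categories) {
    flip <- runif(60) < 0.1
    ann2[[cat]][flip] <- sample(cwis_vocab[[cat]], sum(flip),
                                replace = TRUE)
  }
  om <- match_observers(ann, ann2, sp1)
  tab <- agreement_table(om$pairs, n_boot = 200, seed = 3)
  expect_equal(tab$category, cwis_categories)
  expect_true(all(tab$kappa_low <= tab$kappa))
  expect_true(all(tab$kappa_high >= tab$kappa))
  expect_true(all(tab$interpretation %in%
                  c("Poor", "Slight", "Fair", "Moderate", "Substantial",
                    "Strong", "Almost perfect")))
})
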