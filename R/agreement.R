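#' Spatially match two observers' fracture annotations
#'
#' Each observer marks fracture centers; a fracture annotation is
#' encoded as a sphere of `radius_mm` around the center, so two
#' observers annotated the same fracture iff their spheres intersect,
#' i.e. the centers lie within the sum of the radii (20 mm at the
#' default 10 mm radius). Matching is one-to-one and greedy by
#' ascending center distance, per scan — the same matching semantics
#' used for detection evaluation. The result reports how many fractures
#' were seen by both observers and by each alone, plus the paired
#' labels of mutual fractures (solo fractures keep the other observer's
#' labels as missing, for statistics that tolerate missing data).
#'
#' @param ann1,ann2 annotation tables (one per observer): `scan_id`,
#'   `cx, cy, cz` voxel coordinates and the CWIS label columns `type`,
#'   `displacement`, `location`.
#' @param spacing numeric length-3 voxel size in mm.
#' @param radius_mm annotation sphere radius (default 10).
#' @return object of class `observer_match`: `counts` (named vector
#'   `both`, `only_obs1`, `only_obs2`, `union`) and `pairs`, a data
#'   frame with one row per distinct fracture and columns
#'   `<category>_obs1` / `<category>_obs2` (NA where an observer missed
#'   the fracture).
#' @export
match_observers <- function(ann1, ann2, spacing, radius_mm = 10) {
  stopifnot(is.numeric(spacing), length(spacing) == 3L, all(spacing > 0),
            radius_mm > 0)
  scans <- sort(unique(c(as.character(ann1$scan_id),
                         as.character(ann2$scan_id))))
  if (!length(scans)) scans <- NA_character_
  pairs <- list(); n_both <- n1 <- n2 <- 0L
  for (s in scans) {
    a1 <- ann1[is.na(s) | ann1$scan_id == s, , drop = FALSE]
    a2 <- ann2[is.na(s) | ann2$scan_id == s, , drop = FALSE]
    m1 <- as.matrix(a1[c("cx", "cy", "cz")])
    m2 <- as.matrix(a2[c("cx", "cy", "cz")])
    used1 <- logical(nrow(a1)); used2 <- logical(nrow(a2))
    if (nrow(a1) && nrow(a2)) {
      g <- expand.grid(i = seq_len(nrow(a1)), j = seq_len(nrow(a2)))
      d2 <- numeric(nrow(g))
      for (ax in 1:3)
        d2 <- d2 + ((m1[g$i, ax] - m2[g$j, ax]) * spacing[ax])^2
      dist <- matrix(Inf, nrow(a1), nrow(a2))
      feas <- sqrt(d2) <= 2 * radius_mm
      dist[cbind(g$i[feas], g$j[feas])] <- sqrt(d2)[feas]
      # closest-first preference, maximum cardinality (shared matcher)
      ord <- order(apply(dist, 1, min))
      m2_of <- bipartite_match(dist, ord)
      for (i in which(!is.na(m2_of))) {
        used1[i] <- TRUE; used2[m2_of[i]] <- TRUE
        pairs[[length(pairs) + 1L]] <- pair_row(s, a1[i, ], a2[m2_of[i], ])
      }
    }
    for (i in which(!used1))
      pairs[[length(pairs) + 1L]] <- pair_row(s, a1[i, ], NULL)
    for (j in which(!used2))
      pairs[[length(pairs) + 1L]] <- pair_row(s, NULL, a2[j, ])
    n_both <- n_both + sum(used1)
    n1 <- n1 + sum(!used1); n2 <- n2 + sum(!used2)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else NULL
  structure(list(
    counts = c(both = n_both, only_obs1 = n1, only_obs2 = n2,
               union = n_both + n1 + n2),
    pairs = pairs), class = "observer_match")
}

pair_row <- function(scan, a1, a2) {
  row <- data.frame(scan_id = if (is.null(scan)) NA_character_ else scan,
                    stringsAsFactors = FALSE)
  for (cat in cwis_categories) {
    row[[paste0(cat, "_obs1")]] <-
      if (is.null(a1)) NA_character_ else as.character(a1[[cat]])
    row[[paste0(cat, "_obs2")]] <-
      if (is.null(a2)) NA_character_ else as.character(a2[[cat]])
  }
  row
}

#' @export
print.observer_match <- function(x, ...) {
  cat(sprintf(paste0("Observer matching: %d fractures in total, %d seen by",
                     " both,\n  %d by observer 1 only, %d by observer 2",
                     " only\n"),
              x$counts[["union"]], x$counts[["both"]],
              x$counts[["only_obs1"]], x$counts[["only_obs2"]]))
  invisible(x)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), with the
#' expected agreement p_e from the product of the raters' marginal
#' label frequencies. Records with a missing label on either side are
#' excluded. If both raters are constant with the same value (p_e = 1
#' with perfect observed agreement) the degenerate case is reported as
#' perfect agreement (kappa = 1).
#'
#' @param x,y label vectors from rater 1 and 2 (same length).
#' @return kappa in \[-1, 1\].
#' @examples
#' cohen_kappa(rep(c("a", "b"), c(25, 25)),
#'             rep(c("a", "b", "a", "b"), c(20, 5, 10, 15)))  # 0.4
#' @export
cohen_kappa <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- as.character(x[ok]); y <- as.character(y[ok])
  n <- length(x)
  if (n < 2L) stop("cohen_kappa needs at least 2 complete records",
                   call. = FALSE)
  levels <- sort(unique(c(x, y)))
  tab <- table(factor(x, levels), factor(y, levels)) / n
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (1 - pe < .Machine$double.eps^0.5) {
    if (po >= 1 - .Machine$double.eps^0.5) return(1)
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Krippendorff's alpha (nominal) for possibly incomplete ratings
#'
#' alpha = 1 - D_o / D_e over the coincidence matrix of values within
#' units: each unit with m >= 2 ratings contributes each ordered pair
#' of its ratings with weight 1/(m - 1). For the nominal metric the
#' observed disagreement D_o is the off-diagonal coincidence mass and
#' the expected disagreement D_e derives from the value marginals, so
#' alpha = 1 - (n - 1) * sum_off(o_ck) / sum_off(n_c * n_k). Units with
#' fewer than two ratings contribute nothing; missing ratings are
#' handled natively, which is why this statistic complements kappa when
#' one observer missed a fracture.
#'
#' @param values matrix (units x raters) of labels, `NA` for missing.
#' @return alpha (<= 1; negative for systematic disagreement), or `NA`
#'   with a warning when no unit has two pairable ratings.
#' @export
krippendorff_alpha <- function(values) {
  values <- as.matrix(values)
  m_u <- rowSums(!is.na(values))
  use <- m_u >= 2L
  if (!any(use)) {
    warning("krippendorff_alpha: no pairable values", call. = FALSE)
    return(NA_real_)
  }
  vals <- sort(unique(stats::na.omit(as.character(values[use, ]))))
  k <- length(vals)
  o <- matrix(0, k, k, dimnames = list(vals, vals))
  for (u in which(use)) {
    r <- as.character(stats::na.omit(values[u, ]))
    m <- length(r)
    for (a in seq_len(m)) for (b in seq_len(m)) if (a != b)
      o[r[a], r[b]] <- o[r[a], r[b]] + 1 / (m - 1)
  }
  nc <- rowSums(o)
  n <- sum(nc)
  off <- !diag(k)
  de <- sum(outer(nc, nc)[off])
  if (de <= 0) return(1)  # a single value throughout: no possible disagreement
  1 - (n - 1) * sum(o[off]) / de
}

#' Percentile bootstrap confidence interval for an agreement statistic
#'
#' Resamples units (fractures) with replacement `n_boot` times and
#' returns the percentile interval of the statistic. Resamples on which
#' the statistic is undefined are redrawn, up to a cap. Deterministic
#' given the seed.
#'
#' @param stat_fn function taking the resampled `data` rows and
#'   returning a scalar (may be `NA` for degenerate resamples).
#' @param data data frame or matrix; rows are the resampling units.
#' @param n_boot number of bootstrap resamples (>= 100; default 1000).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return named numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(stat_fn, data, n_boot = 1000, seed = 1L,
                         conf = 0.95) {
  stopifnot(n_boot >= 100)
  n <- nrow(data)
  with_seed(seed, {
    stats_out <- numeric(n_boot)
    attempts <- 0L; cap <- 10L * n_boot
    i <- 1L
    while (i <= n_boot && attempts < cap) {
      attempts <- attempts + 1L
      idx <- sample.int(n, n, replace = TRUE)
      v <- suppressWarnings(tryCatch(stat_fn(data[idx, , drop = FALSE]),
                                     error = function(e) NA_real_))
      if (!is.na(v)) { stats_out[i] <- v; i <- i + 1L }
    }
    if (i <= n_boot) {
      warning("bootstrap_ci: redraw cap reached; interval from ",
              i - 1L, " resamples", call. = FALSE)
      stats_out <- stats_out[seq_len(i - 1L)]
    }
    a <- (1 - conf) / 2
    q <- stats::quantile(stats_out, c(a, 1 - a), names = FALSE)
    c(low = q[1], high = q[2])
  })
}

#' Qualitative interpretation of an agreement estimate
#'
#' Maps a kappa/alpha estimate to a verbal band. The default
#' `"observer-study"` scale uses: <= 0 Poor, (0, 0.20] Slight,
#' (0.20, 0.40] Fair, (0.40, 0.60] Moderate, (0.60, 0.80] Substantial,
#' (0.80, 0.90] Strong, (0.90, 1] Almost perfect. The classic
#' Landis-Koch scale is available as an alternative.
#'
#' @param estimate numeric in \[-1, 1\].
#' @param scale `"observer-study"` (default) or `"landis-koch"`.
#' @return character band(s), same length as `estimate`.
#' @examples
#' interpret_agreement(c(0.74, 0.82))  # "Substantial", "Strong"
#' @export
interpret_agreement <- function(estimate,
                                scale = c("observer-study", "landis-koch")) {
  scale <- match.arg(scale)
  stopifnot(all(estimate >= -1 & estimate <= 1))
  bands <- switch(scale,
    "observer-study" = list(breaks = c(-1, 0, 0.2, 0.4, 0.6, 0.8, 0.9, 1),
      labels = c("Poor", "Slight", "Fair", "Moderate", "Substantial",
                 "Strong", "Almost perfect")),
    "landis-koch" = list(breaks = c(-1, 0, 0.2, 0.4, 0.6, 0.8, 1),
      labels = c("Poor", "Slight", "Fair", "Moderate", "Substantial",
                 "Almost perfect")))
  as.character(cut(estimate, breaks = bands$breaks, labels = bands$labels,
                   include.lowest = TRUE, right = TRUE))
}

#' Decompose interobserver disagreement
#'
#' Over fractures labeled by both observers, counts the disagreements
#' per CWIS category (each a "classification task"), the total number
#' of disagreeing tasks, and the number of distinct fractures showing
#' at least one disagreement.
#'
#' @param pairs paired annotation table from [match_observers()].
#' @return list with `per_category` (named counts), `total_tasks`,
#'   `n_fractures` and `n_complete` (fractures with complete pairs).
#' @export
disagreement_counts <- function(pairs) {
  per <- stats::setNames(integer(length(cwis_categories)), cwis_categories)
  any_dis <- rep(FALSE, nrow(pairs))
  complete <- rep(TRUE, nrow(pairs))
  for (cat in cwis_categories) {
    a <- pairs[[paste0(cat, "_obs1")]]
    b <- pairs[[paste0(cat, "_obs2")]]
    ok <- !is.na(a) & !is.na(b)
    complete <- complete & ok
    dis <- ok & a != b
    per[cat] <- sum(dis)
    any_dis <- any_dis | dis
  }
  list(per_category = per, total_tasks = sum(per),
       n_fractures = sum(any_dis), n_complete = sum(complete))
}

#' Interobserver agreement report
#'
#' Computes, per CWIS category, Cohen's kappa (on fractures seen by
#' both observers), Krippendorff's alpha (all fractures; missing labels
#' handled natively), percentile-bootstrap 95% confidence intervals,
#' and the qualitative interpretation band of the kappa estimate.
#'
#' @param pairs paired annotation table from [match_observers()].
#' @param n_boot bootstrap resamples per interval (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param scale interpretation scale, see [interpret_agreement()].
#' @return data frame with one row per category: `kappa`, `kappa_low`,
#'   `kappa_high`, `alpha`, `alpha_low`, `alpha_high`,
#'   `interpretation`, `n_complete`, `n_units`.
#' @export
agreement_table <- function(pairs, n_boot = 1000, seed = 1L,
                            scale = "observer-study") {
  rows <- lapply(seq_along(cwis_categories), function(ci) {
    cat <- cwis_categories[ci]
    a <- pairs[[paste0(cat, "_obs1")]]
    b <- pairs[[paste0(cat, "_obs2")]]
    df <- data.frame(a = a, b = b, stringsAsFactors = FALSE)
    kap <- cohen_kappa(df$a, df$b)
    alp <- krippendorff_alpha(as.matrix(df))
    kci <- bootstrap_ci(function(d) cohen_kappa(d$a, d$b), df,
                        n_boot = n_boot, seed = seed + ci)
    aci <- bootstrap_ci(function(d) krippendorff_alpha(as.matrix(d)), df,
                        n_boot = n_boot, seed = seed + 100L + ci)
    data.frame(category = cat, kappa = kap, kappa_low = kci[["low"]],
               kappa_high = kci[["high"]], alpha = alp,
               alpha_low = aci[["low"]], alpha_high = aci[["high"]],
               interpretation = interpret_agreement(kap, scale),
               n_complete = sum(!is.na(a) & !is.na(b)), n_units = nrow(df),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
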