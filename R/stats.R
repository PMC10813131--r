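#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with mid-ranks for ties. `exact` mode enumerates
#' all C(n+m, n) arrangements of the observed (mid-)ranks — for tie-free data
#' this reduces to the exact Wilcoxon distribution, which is used directly;
#' with ties the enumeration is explicit and limited to n + m <= 20.
#' `normal_approx` (the default for the 15-vs-15 edgewise contrasts, where
#' exact enumeration per edge is needlessly slow) uses the tie-corrected
#' normal approximation with continuity correction, matching
#' [stats::wilcox.test()].
#'
#' @param x,y Non-empty numeric samples.
#' @param mode `"normal_approx"` or `"exact"`.
#' @return List with `statistic` (rank sum of `x`), `u` (Mann-Whitney U),
#'   `p.value` (two-sided), `n`, `mode`, `direction`
#'   (sign of `median(x) - median(y)`).
#' @examples
#' ranksum_test(c(1, 2, 3), c(4, 5, 6), mode = "exact")$p.value  # 0.1
#' @export
ranksum_test <- function(x, y, mode = c("normal_approx", "exact")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop_invalid("samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop_invalid("samples contain NA")
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  U <- W - n * (n + 1) / 2
  if (mode == "exact") {
    if (!any(duplicated(c(x, y)))) {
      u <- min(U, n * m - U)
      p <- if (abs(U - n * m / 2) < 1e-12) 1 else min(1, 2 * pwilcox(u, n, m))
    } else {
      if (N > 20)
        stop_invalid(
          "exact mode with tied data is limited to n + m <= 20 (got %d); use normal_approx",
          N)
      idx <- utils::combn(N, n)
      Ws <- colSums(matrix(r[idx], nrow = n))
      mu <- n * (N + 1) / 2
      p <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
    }
  } else {
    tab <- table(r)
    sig2 <- (n * m / 12) * ((N + 1) - sum(tab^3 - tab) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- U - n * m / 2
      z <- (z - sign(z) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * min(pnorm(z), 1 - pnorm(z)))
    }
  }
  list(statistic = W, u = U, p.value = p, n = c(n = n, m = m), mode = mode,
       direction = sign(median(x) - median(y)))
}

# Row-wise tie-corrected continuity-corrected normal-approximation rank-sum
# over many simultaneous tests (rows). Equals ranksum_test(mode =
# "normal_approx") row by row; used by the edgewise/nodewise contrasts.
ranksum_rows <- function(X, Y) {
  n <- ncol(X); m <- ncol(Y); N <- n + m
  A <- cbind(X, Y)
  r <- t(apply(A, 1, rank))
  W <- rowSums(r[, seq_len(n), drop = FALSE])
  U <- W - n * (n + 1) / 2
  tiesum <- apply(r, 1, function(v) { tb <- table(v); sum(tb^3 - tb) })
  sig2 <- (n * m / 12) * ((N + 1) - tiesum / (N * (N - 1)))
  z0 <- U - n * m / 2
  z <- (z0 - sign(z0) * 0.5) / sqrt(sig2)
  p <- ifelse(sig2 <= 0, 1, pmin(1, 2 * pmin(pnorm(z), 1 - pnorm(z))))
  dir <- sign(apply(X, 1, median) - apply(Y, 1, median))
  mean_rank_diff <- rowMeans(r[, seq_len(n), drop = FALSE]) -
    rowMeans(r[, n + seq_len(m), drop = FALSE])
  dir[dir == 0] <- sign(mean_rank_diff)[dir == 0]
  list(W = W, p = p, direction = dir)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up adjustment: sorted ascending, `q_(i) = min_{j >= i} m p_(j) / j`
#' clipped to 1; hypotheses with `q <= alpha` are rejected.
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @param alpha FDR threshold (default 0.05).
#' @return List with `qvals` and logical `reject`.
#' @export
fdr_bh <- function(pvals, alpha = 0.05) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop_invalid("p-values must be in [0, 1]")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop_invalid("alpha must be in (0, 1]")
  q <- p.adjust(pvals, method = "BH")
  list(qvals = q, reject = q <= alpha)
}

#' Group contrast container
#'
#' Result of an edgewise or nodewise two-group comparison: rank-sum
#' statistics, p-values, BH-FDR q-values and a signed significance coding
#' (+1 = first group significantly greater, -1 = second group significantly
#' greater, 0 = not significant at FDR `alpha`). For edgewise contrasts all
#' fields are symmetric matrices with zero diagonal.
#'
#' @name group_contrast
NULL

new_group_contrast <- function(type, statistic, p, q, sign, channels, band,
                               stage, alpha, mode, n_tests) {
  structure(list(type = type, statistic = statistic, p = p, q = q,
                 sign = sign, channels = channels, band = band, stage = stage,
                 alpha = alpha, mode = mode, n_tests = n_tests),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  bn <- if (is.list(x$band)) x$band$name else as.character(x$band)
  s <- if (is.matrix(x$sign)) x$sign[upper.tri(x$sign)] else x$sign
  cat(sprintf(
    "<group_contrast> %s %s @ %s: %d tests, FDR %g; %d sig (+): DE>HC, %d sig (-): HC>DE\n",
    x$type, bn, x$stage, x$n_tests, x$alpha, sum(s > 0), sum(s < 0)))
  invisible(x)
}

check_matching_matrices <- function(mats, what) {
  ref <- mats[[1]]
  for (M in mats) {
    if (!inherits(M, "plv_matrix")) stop_invalid("%s must be plv_matrix objects", what)
    if (!identical(M$channels, ref$channels))
      stop_invalid("%s have mismatched channel orders", what)
    bn <- function(b) if (is.list(b)) b$name else as.character(b)
    if (bn(M$band) != bn(ref$band) || !identical(M$stage, ref$stage))
      stop_invalid("%s mix bands/stages (%s@%s vs %s@%s)", what,
                   bn(M$band), M$stage, bn(ref$band), ref$stage)
  }
  invisible(ref)
}

#' Edgewise PLV group contrast
#'
#' One rank-sum test per unordered off-diagonal channel pair (1891 tests for
#' 62 channels: the upper triangle only, since the matrix is symmetric and
#' the diagonal trivial), BH-FDR across those tests within the band/stage,
#' and a signed significance matrix coded by the direction of the group
#' median difference (+1 where the first group's PLV is significantly
#' larger).
#'
#' @param de,hc Lists of [plv_matrix()] (>= 2 each) with identical band,
#'   stage and channel order. Conventionally `de` is the DE group, so +1
#'   means DE > HC.
#' @param alpha FDR threshold.
#' @param mode Test mode, see [ranksum_test()].
#' @return A [group_contrast] of type `"edgewise"`.
#' @export
edgewise_contrast <- function(de, hc, alpha = 0.05,
                              mode = c("normal_approx", "exact")) {
  mode <- match.arg(mode)
  if (length(de) < 2L || length(hc) < 2L)
    stop_invalid("need at least 2 subjects per group")
  ref <- check_matching_matrices(c(de, hc), "connectivity matrices")
  C <- length(ref$channels)
  ut <- which(upper.tri(ref$values))
  X <- vapply(de, function(M) M$values[ut], numeric(length(ut)))
  Y <- vapply(hc, function(M) M$values[ut], numeric(length(ut)))
  res <- contrast_rows(X, Y, mode)
  fdr <- fdr_bh(res$p, alpha)
  sgn <- ifelse(fdr$reject, res$direction, 0)
  shape <- function(v) {
    M <- matrix(0, C, C, dimnames = list(ref$channels, ref$channels))
    M[ut] <- v
    M + t(M)
  }
  new_group_contrast("edgewise", shape(res$W), shape(res$p), shape(fdr$qvals),
                     shape(sgn), ref$channels, ref$band, ref$stage, alpha,
                     mode, length(ut))
}

contrast_rows <- function(X, Y, mode) {
  if (mode == "normal_approx") return(ranksum_rows(X, Y))
  k <- nrow(X)
  W <- p <- dir <- numeric(k)
  for (i in seq_len(k)) {
    t <- ranksum_test(X[i, ], Y[i, ], mode = "exact")
    W[i] <- t$statistic; p[i] <- t$p.value; dir[i] <- t$direction
  }
  dir[dir == 0] <- 1
  list(W = W, p = p, direction = dir)
}

#' Nodewise clustering-coefficient group contrast
#'
#' As [edgewise_contrast()], but over the per-node clustering coefficients:
#' one rank-sum test per channel, BH-FDR across the channels of one
#' band/stage.
#'
#' @param de_metrics,hc_metrics Lists of [compute_metrics()] results (their
#'   `$cc` is used) or numeric subject x node matrices.
#' @param alpha FDR threshold.
#' @param mode Test mode.
#' @return A [group_contrast] of type `"nodewise"` whose fields are named
#'   per-node vectors.
#' @export
nodewise_cc_contrast <- function(de_metrics, hc_metrics, alpha = 0.05,
                                 mode = c("normal_approx", "exact")) {
  mode <- match.arg(mode)
  get_cc <- function(g) {
    if (is.matrix(g)) return(t(g))
    cc <- vapply(g, function(x) {
      if (!inherits(x, "graph_metrics")) stop_invalid("expected graph_metrics")
      x$cc
    }, numeric(length(g[[1]]$cc)))
    cc
  }
  X <- get_cc(de_metrics); Y <- get_cc(hc_metrics)
  if (ncol(X) < 2L || ncol(Y) < 2L)
    stop_invalid("need at least 2 subjects per group")
  if (nrow(X) != nrow(Y)) stop_invalid("groups have different node counts")
  channels <- rownames(X)
  if (is.null(channels)) channels <- paste0("n", seq_len(nrow(X)))
  band <- stage <- NA
  if (!is.matrix(de_metrics)) {
    band <- de_metrics[[1]]$band; stage <- de_metrics[[1]]$stage
  }
  res <- contrast_rows(X, Y, mode)
  fdr <- fdr_bh(res$p, alpha)
  sgn <- ifelse(fdr$reject, res$direction, 0)
  nm <- function(v) { names(v) <- channels; v }
  new_group_contrast("nodewise", nm(res$W), nm(res$p), nm(fdr$qvals),
                     nm(sgn), channels, band, stage, alpha, mode, nrow(X))
}

#' Spearman correlation of regional clustering with CES-D
#'
#' Spearman rank correlation (mid-ranks for ties) between each region's
#' average clustering coefficient and the CES-D scores, pooled over all
#' subjects of both groups.
#'
#' @param region_cc Numeric subjects x regions matrix (e.g. rows of
#'   [region_average()] results).
#' @param cesd CES-D scores aligned with the rows.
#' @return Data frame with columns `region, rho, p_value`.
#' @export
spearman_region_cesd <- function(region_cc, cesd) {
  region_cc <- as.matrix(region_cc)
  if (nrow(region_cc) != length(cesd))
    stop_invalid("cesd length (%d) does not match subject rows (%d)",
                 length(cesd), nrow(region_cc))
  if (nrow(region_cc) < 3L) stop_invalid("need at least 3 subjects")
  regions <- colnames(region_cc)
  if (is.null(regions)) regions <- paste0("R", seq_len(ncol(region_cc)))
  out <- lapply(seq_len(ncol(region_cc)), function(j) {
    x <- region_cc[, j]
    if (sd(x) == 0 || sd(cesd) == 0)
      return(data.frame(region = regions[j], rho = NA_real_,
                        p_value = NA_real_))
    ct <- suppressWarnings(cor.test(x, cesd, method = "spearman",
                                    exact = FALSE))
    data.frame(region = regions[j], rho = unname(ct$estimate),
               p_value = ct$p.value)
  })
  do.call(rbind, out)
}

#' Stage durations from a trial event log
#'
#' Each docking trial must log five events in order: trial start, first
#' whole-arm movement, first joint fine-adjustment, second whole-arm
#' movement, docking complete. Stage durations are the consecutive
#' differences (O, LM, FO, D); the subject's stage times are the means
#' across that subject's trials.
#'
#' @param events Data frame with columns `trial, event, time_s` (and
#'   optionally `subject_id`) for one subject.
#' @return A [behavior_record()].
#' @export
stage_durations <- function(events) {
  events <- as.data.frame(events)
  need <- c("trial", "event", "time_s")
  if (!all(need %in% names(events)))
    stop_invalid("event log needs columns trial, event, time_s")
  expected <- c("start", "move_arm", "fine_adjust", "move_arm_again", "dock")
  subject_id <- if ("subject_id" %in% names(events))
    as.character(events$subject_id[1]) else NA_character_
  per_trial <- lapply(split(events, events$trial), function(tr) {
    id <- tr$trial[1]
    if (nrow(tr) != 5L || !identical(as.character(tr$event), expected))
      stop_invalid("malformed event log in trial %s: expected events %s",
                   id, paste(expected, collapse = ", "))
    if (any(diff(tr$time_s) <= 0))
      stop_invalid("malformed event log in trial %s: non-increasing timestamps",
                   id)
    d <- diff(tr$time_s)
    names(d) <- c("O", "LM", "FO", "D")
    d
  })
  times <- rowMeans(do.call(cbind, per_trial))
  behavior_record(subject_id, times)
}

#' Behavioral group contrast
#'
#' Rank-sum tests of the four stage times and the total time between groups.
#' No multiplicity correction is applied across the five tests (matching the
#' per-stage reporting convention); this is flagged in the result's
#' `multiplicity` attribute.
#'
#' @param de,hc Lists of [behavior_record()] (>= 2 each).
#' @param alpha Significance threshold.
#' @param mode Test mode, see [ranksum_test()].
#' @return Data frame with 5 rows (`O, LM, FO, D, total`) and columns
#'   `measure, statistic, p_value, median_de, median_hc, significant`.
#' @export
behavior_contrast <- function(de, hc, alpha = 0.05,
                              mode = c("exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(de) < 2L || length(hc) < 2L)
    stop_invalid("need at least 2 subjects per group")
  pull <- function(recs, what) vapply(recs, function(r)
    if (what == "total") r$total else r$times[[what]], 0)
  measures <- c("O", "LM", "FO", "D", "total")
  out <- lapply(measures, function(ms) {
    x <- pull(de, ms); y <- pull(hc, ms)
    t <- ranksum_test(x, y, mode = mode)
    data.frame(measure = ms, statistic = t$statistic, p_value = t$p.value,
               median_de = median(x), median_hc = median(y),
               significant = t$p.value < alpha)
  })
  out <- do.call(rbind, out)
  attr(out, "multiplicity") <- "uncorrected (5 tests)"
  out
}
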