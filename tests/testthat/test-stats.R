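test_that("exact rank-sum p-values match hand enumeration", {
  t <- ranksum_test(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(t$p.value, 0.1)          # 2/20 arrangements as extreme
  expect_equal(t$statistic, 6)

  # identical samples, shuffled: symmetric null
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(ranksum_test(x, sample(x), mode = "exact")$p.value, 1,
               tolerance = 0.21)        # within enumeration granularity

  # swapping groups preserves p, reverses direction
  set.seed(2)
  a <- rnorm(5); b <- rnorm(6) + 1
  t1 <- ranksum_test(a, b, mode = "exact")
  t2 <- ranksum_test(b, a, mode = "exact")
  expect_equal(t1$p.value, t2$p.value)
  expect_equal(t1$direction, -t2$direction)

  expect_error(ranksum_test(numeric(0), 1:3), "non-empty")
})

test_that("exact mode equals full enumeration for all n + m <= 10", {
  set.seed(14)
  for (n in 2:5) for (m in 2:(10 - n)) {
    # tie-free
    x <- rnorm(n); y <- rnorm(m)
    expect_equal(ranksum_test(x, y, mode = "exact")$p.value,
                 ranksum_enum_oracle(x, y), tolerance = 1e-12)
    # with ties
    xt <- sample(1:3, n, replace = TRUE); yt <- sample(1:3, m, replace = TRUE)
    expect_equal(ranksum_test(xt, yt, mode = "exact")$p.value,
                 ranksum_enum_oracle(xt, yt), tolerance = 1e-12)
  }
})

test_that("normal approximation matches wilcox.test with and without ties", {
  set.seed(15)
  for (rep in 1:20) {
    x <- sample(seq(0, 5, by = 0.5), 8, replace = TRUE)
    y <- sample(seq(0, 5, by = 0.5), 11, replace = TRUE) + 0.25 * rep
    got <- ranksum_test(x, y, mode = "normal_approx")
    want <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                correct = TRUE))
    expect_equal(got$p.value, want$p.value, tolerance = 1e-12)
    expect_equal(unname(got$u), unname(want$statistic))
  }
})

test_that("vectorized rank-sum rows equal the scalar test", {
  set.seed(16)
  X <- matrix(rnorm(50 * 6), 50)
  Y <- matrix(rnorm(50 * 8, 0.5), 50)
  X[1:10, ] <- round(X[1:10, ])  # force ties in some rows
  Y[1:10, ] <- round(Y[1:10, ])
  rr <- plvnet:::ranksum_rows(X, Y)
  for (i in c(1:10, 30, 50)) {
    t <- ranksum_test(X[i, ], Y[i, ], mode = "normal_approx")
    expect_equal(rr$W[i], t$statistic)
    expect_equal(rr$p[i], t$p.value, tolerance = 1e-12)
  }
})

test_that("BH FDR matches the literal step-up oracle", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04))$reject, rep(TRUE, 4))
  expect_equal(fdr_bh(c(0.04, 0.5, 0.6, 0.9))$reject, rep(FALSE, 4))
  z <- fdr_bh(c(0, 0, 0))
  expect_equal(z$qvals, rep(0, 3))
  expect_true(all(z$reject))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(17)
  worst <- 0
  for (rep in 1:1000) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- fdr_bh(p)$qvals
    worst <- max(worst, max(abs(q - bh_oracle(p))))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in sorted order
  }
  expect_lt(worst, 1e-12)
})

test_that("edgewise contrast finds planted differences and nothing in nulls", {
  make_mats <- function(n, shift_pairs = NULL, delta = 0, seed = 1) {
    set.seed(seed)
    lapply(seq_len(n), function(i) {
      C <- 8
      M <- matrix(0.4, C, C) + matrix(runif(C * C, 0, 0.08), C)
      M <- (M + t(M)) / 2
      if (!is.null(shift_pairs))
        for (k in seq_len(nrow(shift_pairs))) {
          a <- shift_pairs[k, 1]; b <- shift_pairs[k, 2]
          M[a, b] <- M[b, a] <- M[a, b] + delta
        }
      diag(M) <- 1
      plv_matrix(pmin(M, 1), paste0("ch", 1:C), "alpha", "RS", paste0("s", i))
    })
  }
  # identical groups: nothing significant
  same <- make_mats(6, seed = 3)
  ec0 <- edgewise_contrast(same, same)
  expect_equal(sum(ec0$sign != 0), 0)

  # planted DE > HC on 5 designated edges
  pairs <- cbind(c(1, 2, 3, 4, 5), c(6, 7, 8, 7, 8))
  de <- make_mats(15, pairs, 0.4, seed = 4)
  hc <- make_mats(15, seed = 5)
  ec <- edgewise_contrast(de, hc)
  hits <- sum(ec$sign[pairs] == 1)
  expect_gte(hits, 4)
  # false positives controlled: off-target significant edges are few
  expect_lte(sum(ec$sign[upper.tri(ec$sign)] != 0), nrow(pairs) + 3)
  # symmetry with zero diagonal
  expect_equal(ec$sign, t(ec$sign))
  expect_equal(unname(diag(ec$sign)), rep(0, 8))
  expect_equal(ec$n_tests, choose(8, 2))

  expect_error(edgewise_contrast(de[1], hc[1]), "2 subjects")
})

test_that("nodewise CC contrast flags inflated nodes with the right sign", {
  set.seed(21)
  C <- 20
  de <- t(replicate(12, runif(C, 0.3, 0.5) + c(rep(0.3, 4), rep(0, C - 4))))
  hc <- t(replicate(12, runif(C, 0.3, 0.5)))
  colnames(de) <- colnames(hc) <- paste0("ch", seq_len(C))
  nc <- nodewise_cc_contrast(de, hc)
  expect_true(all(nc$sign[1:4] == 1))
  expect_lte(sum(nc$sign != 0), C)
  nc0 <- nodewise_cc_contrast(hc, hc)
  expect_equal(sum(nc0$sign != 0), 0)
})

test_that("Spearman correlations equal Pearson on ranks", {
  cesd <- c(5, 12, 18, 22, 25, 30, 8, 15)
  inc <- matrix(cesd * 0.01 + 0.2, ncol = 1)
  expect_equal(spearman_region_cesd(inc, cesd)$rho, 1)
  expect_equal(spearman_region_cesd(-inc, cesd)$rho, -1)

  set.seed(22)
  x <- matrix(sample(1:5, 30, replace = TRUE) + runif(30, 0, 0.01 * 0), 30 / 3, 3)
  cs <- sample(10:30, 10)
  got <- spearman_region_cesd(x, cs)
  for (j in 1:3)
    expect_equal(got$rho[j], cor(rank(x[, j]), rank(cs)), tolerance = 1e-12)
  expect_error(spearman_region_cesd(x, cs[-1]), "does not match")
  expect_error(spearman_region_cesd(x[1:2, ], cs[1:2]), "3 subjects")
})

test_that("stage durations come from ordered event quintuples", {
  ev <- data.frame(trial = 1, event = c("start", "move_arm", "fine_adjust",
                                        "move_arm_again", "dock"),
                   time_s = c(0, 10, 30, 50, 75))
  r <- stage_durations(ev)
  expect_equal(unname(r$times), c(10, 20, 20, 25))
  expect_equal(r$total, 75)

  # worked example with the group-mean times
  ev2 <- ev; ev2$time_s <- c(0, 10.91, 31.43, 50.74, 74.96)
  expect_equal(unname(stage_durations(ev2)$times),
               c(10.91, 20.52, 19.31, 24.22))

  bad <- ev; bad$time_s <- c(0, 10, 5, 50, 75)
  expect_error(stage_durations(bad), "trial 1")
  expect_error(stage_durations(ev[-2, ]), "trial 1")

  # multiple trials average
  ev3 <- rbind(ev, transform(ev, trial = 2, time_s = time_s * 2))
  expect_equal(unname(stage_durations(ev3)$times), c(15, 30, 30, 37.5))
})

test_that("behavior contrast reports five uncorrected tests", {
  zero_sd <- default_behavior_params()
  mk <- function(group, n, params = default_behavior_params())
    lapply(seq_len(n), function(i)
      simulate_behavior(subject_spec(paste0(group, i), group,
                                     if (group == "DE") 25 else 10, 8,
                                     3000 + i), params))
  de <- mk("DE", 10); hc <- mk("HC", 10)
  out <- behavior_contrast(de, hc)
  expect_equal(nrow(out), 5)
  expect_equal(out$measure, c("O", "LM", "FO", "D", "total"))
  expect_match(attr(out, "multiplicity"), "uncorrected")

  same <- behavior_contrast(hc, hc)
  expect_true(all(same$p_value == 1))
})
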