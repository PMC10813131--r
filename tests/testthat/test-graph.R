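test_that("hand-checked small graphs give the known metric values", {
  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  m <- compute_metrics(K3)
  expect_equal(unname(m$cc), rep(1, 3))
  expect_equal(m$cpl, 1)
  expect_equal(m$ge, 1)
  expect_equal(unname(m$nd), rep(2, 3))

  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  p <- compute_metrics(path)
  expect_equal(p$cpl, 4 / 3)
  expect_equal(p$ge, 5 / 6)

  # uniform complete weighted graph: normalization makes CC = 1
  uw <- matrix(0.37, 4, 4); diag(uw) <- 0
  expect_equal(unname(compute_metrics(uw)$cc), rep(1, 4))

  expect_error(compute_metrics(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
  expect_error(compute_metrics(matrix(2, 2, 2)), "\\[0, 1\\]")
})

test_that("weighted metrics match the brute-force oracle on random graphs", {
  set.seed(101)
  worst <- 0
  for (rep in 1:100) {
    n <- 8
    W <- matrix(0, n, n)
    ut <- upper.tri(W)
    vals <- runif(sum(ut))
    vals[runif(sum(ut)) < 0.3] <- 0  # sparsify; some graphs disconnect
    W[ut] <- vals
    W <- W + t(W)
    got <- compute_metrics(W)
    want <- bf_graph_metrics(W)
    worst <- max(worst,
                 max(abs(unname(got$cc) - want$cc)),
                 max(abs(unname(got$le) - want$le)),
                 max(abs(unname(got$nd) - want$nd)),
                 abs(got$cpl - want$cpl), abs(got$ge - want$ge))
  }
  expect_lt(worst, 1e-9)
})

test_that("binary threshold mode keeps the requested density and matches the oracle", {
  set.seed(5)
  n <- 10
  W <- matrix(runif(n * n), n); W <- (W + t(W)) / 2; diag(W) <- 0
  W <- W / max(W)
  m <- compute_metrics(W, "proportional_threshold", density = 0.3)
  kept <- sum(m$nd) / 2
  expect_equal(kept, round(0.3 * choose(n, 2)))
  # binarized oracle on the same surviving edge set
  thr_vals <- sort(W[upper.tri(W)], decreasing = TRUE)
  B <- (W >= thr_vals[kept]) * 1; diag(B) <- 0
  want <- bf_graph_metrics(B)
  expect_equal(unname(m$cc), want$cc, tolerance = 1e-9)
  expect_equal(m$cpl, want$cpl, tolerance = 1e-9)
  expect_equal(m$ge, want$ge, tolerance = 1e-9)
})

test_that("strengthening a connected graph shortens paths and raises efficiency", {
  set.seed(7)
  for (rep in 1:20) {
    n <- 8
    W <- matrix(runif(n * n, 0.1, 0.9), n); W <- (W + t(W)) / 2; diag(W) <- 0
    W[1, 2] <- W[2, 1] <- 1  # pin the max weight so normalization is stable
    m0 <- compute_metrics(W)
    W2 <- W
    ij <- sample(setdiff(seq_len(n), c(1, 2)), 2)
    W2[ij[1], ij[2]] <- W2[ij[2], ij[1]] <- 0.95  # raise a non-maximal weight
    m1 <- compute_metrics(W2)
    expect_lte(m1$cpl, m0$cpl + 1e-12)
    expect_gte(m1$ge, m0$ge - 1e-12)
  }
})

test_that("metrics are equivariant under node relabeling", {
  set.seed(9)
  n <- 7
  W <- matrix(runif(n * n), n); W <- (W + t(W)) / 2; diag(W) <- 0
  perm <- sample(n)
  m <- compute_metrics(W)
  mp <- compute_metrics(W[perm, perm])
  expect_equal(unname(mp$cc), unname(m$cc)[perm], tolerance = 1e-12)
  expect_equal(unname(mp$le), unname(m$le)[perm], tolerance = 1e-12)
  expect_equal(unname(mp$nd), unname(m$nd)[perm], tolerance = 1e-12)
  expect_equal(mp$cpl, m$cpl, tolerance = 1e-12)
  expect_equal(mp$ge, m$ge, tolerance = 1e-12)
})

test_that("disconnected graphs are flagged and CPL uses finite pairs", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 1
  m <- compute_metrics(W)
  expect_false(m$connected)
  expect_equal(m$cpl, 1)           # only the two within-component pairs
  expect_equal(m$ge, 2 / 6)        # disconnected pairs contribute 0
})

test_that("region averaging follows the atlas exactly", {
  atlas <- default_atlas()
  mont <- default_montage()
  const <- rep(0.5, nrow(mont)); names(const) <- mont$name
  expect_equal(unname(region_average(const, atlas)), rep(0.5, 10))

  lf <- atlas$channel[atlas$region == "LF"]
  ind <- as.numeric(mont$name %in% lf); names(ind) <- mont$name
  ra <- region_average(ind, atlas)
  expect_equal(unname(ra["LF"]), 1)
  expect_equal(unname(ra[names(ra) != "LF"]), rep(0, 9))

  set.seed(3)
  x <- runif(nrow(mont)); names(x) <- mont$name
  ra2 <- region_average(x, atlas)
  for (r in c("RF", "LP", "RO"))
    expect_equal(unname(ra2[r]),
                 mean(x[atlas$channel[atlas$region == r]]))

  expect_error(region_average(x[names(x) != "F3"], atlas),
               "missing from metric")
})

test_that("the packaged atlas partitions the lateral channels correctly", {
  atlas <- default_atlas()
  mont <- default_montage()
  expect_equal(nrow(atlas), 54)
  expect_false(any(duplicated(atlas$channel)))
  expect_true(all(atlas$channel %in% mont$name))
  # midline excluded
  expect_false(any(grepl("Z$", atlas$channel)))
  # odd suffix = left regions, even = right
  suff <- as.integer(sub("^[A-Z]+", "", atlas$channel))
  expect_true(all((suff %% 2 == 1) == startsWith(atlas$region, "L")))
})
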