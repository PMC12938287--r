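test_that("turning angles follow the signed counter-clockwise convention", {
  tr <- function(rows, cols) {
    tibble::tibble(t = seq_along(rows) - 1L, slot_id = 1L,
                   kind = "macrophage", segment = 1L,
                   row = rows, col = cols)
  }
  # straight line -> 0; reversal -> pi; left turn -> pi/2 (col = x, row = y)
  expect_equal(turning_angles(tr(c(0, 0, 0), c(0, 1, 2)))$angle, 0)
  expect_equal(turning_angles(tr(c(0, 0, 0), c(0, 1, 0)))$angle, pi)
  expect_equal(turning_angles(tr(c(0, 0, 1), c(0, 1, 1)))$angle, pi / 2)
  # clockwise turn lands in the upper half of [0, 2pi)
  expect_equal(turning_angles(tr(c(0, 0, -1), c(0, 1, 1)))$angle, 3 * pi / 2)
  # fewer than 3 positions: no angles
  expect_equal(nrow(turning_angles(tr(c(0, 0), c(0, 1)))), 0L)
})

test_that("zero-displacement steps are skipped and segments never bridged", {
  tr <- tibble::tibble(
    t = 0:5, slot_id = 1L, kind = "fibroblast",
    segment = c(1L, 1L, 1L, 1L, 2L, 2L),
    row = c(0, 0, 0, 0, 5, 5),
    col = c(0, 1, 1, 2, 5, 6))
  out <- turning_angles(tr)
  # t=2 has zero displacement, killing the angles at t=2 and t=3; the
  # segment boundary prevents any angle for segment 2 (only 2 points)
  expect_equal(nrow(out), 0L)

  tr2 <- tibble::tibble(
    t = 0:6, slot_id = 2L, kind = "macrophage", segment = 1L,
    row = c(0, 0, 0, 0, 0, 0, 0),
    col = c(0, 1, 2, 2, 3, 4, 5))
  out2 <- turning_angles(tr2)
  expect_equal(out2$t, c(2L, 5L, 6L))   # angles need two nonzero steps
  expect_equal(out2$angle, c(0, 0, 0))
})

test_that("discretisation uses 20 equal bins of width pi/10 by default", {
  width <- 2 * pi / 20
  expect_equal(width, pi / 10)
  expect_equal(width, 0.314159, tolerance = 1e-5)
  expect_equal(bin_angles(0), 0L)
  expect_equal(bin_angles(width - 1e-12), 0L)
  expect_equal(bin_angles(width), 1L)
  expect_equal(bin_angles(2 * pi - 1e-9), 19L)
  expect_equal(bin_angles(2 * pi), 19L)   # boundary clamps into last bin
  expect_equal(bin_angles(pi, bins = 4L), 2L)
  # bin index recovers the angle to within half a bin width
  set.seed(1)
  th <- stats::runif(200, 0, 2 * pi)
  sym <- bin_angles(th)
  expect_true(all(abs((sym + 0.5) * width - th) <= width / 2 + 1e-12))
})

test_that("configuration entropy spans 0 (clustered) to log2 B (uniform)", {
  mk <- function(rows, cols) {
    tibble::tibble(t = 0L, slot_id = seq_along(rows), kind = "macrophage",
                   segment = 1L, row = rows, col = cols)
  }
  # all cells in one 10x10 block
  e <- configuration_entropy(mk(c(1, 2, 3, 4), c(1, 2, 3, 4)), 20, 20)
  expect_equal(e$entropy, 0)
  # spread evenly over the four blocks of a 20x20 grid
  e <- configuration_entropy(mk(c(1, 1, 11, 11), c(1, 11, 1, 11)), 20, 20)
  expect_equal(e$entropy, 2)
  # 3 cells in one block, 1 in another
  e <- configuration_entropy(mk(c(1, 2, 3, 11), c(1, 1, 1, 1)), 20, 20)
  expect_equal(e$entropy, -(0.75 * log2(0.75) + 0.25 * log2(0.25)),
               tolerance = 1e-12)
})

test_that("z-score standardises with the population sigma", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)
  z <- zscore(stats::rnorm(50, 10, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_equal(zscore(z), z, tolerance = 1e-12)   # idempotent
  expect_error(zscore(c(5, 5, 5)), "degenerate")
})

test_that("plug-in MI matches closed forms and the brute-force oracle", {
  # I(X;X) = H(X): uniform over 4 symbols
  x <- rep(0:3, 250)
  expect_equal(mutual_information(x, x), 2, tolerance = 1e-12)
  # perfectly dependent 2x2 table with counts (5,0),(0,5) -> 1 bit
  expect_equal(mutual_information(rep(0:1, each = 5), rep(0:1, each = 5)), 1)
  # independence: near zero for long series
  set.seed(2)
  a <- sample(0:3, 10000, TRUE); b <- sample(0:3, 10000, TRUE)
  expect_lt(mutual_information(a, b), 0.01)
  expect_error(mutual_information(1:3, 1:4), "equal length")
  # fuzzed agreement with the explicit-summation oracle
  for (i in 1:20) {
    x <- sample(0:2, 60, TRUE); y <- sample(0:3, 60, TRUE)
    expect_equal(mutual_information(x, y), oracle_mi(x, y), tolerance = 1e-12)
  }
})

test_that("plug-in CMI matches degenerate cases and the brute-force oracle", {
  set.seed(3)
  x <- sample(0:2, 500, TRUE); y <- sample(0:2, 500, TRUE)
  z_const <- rep(1L, 500)
  expect_equal(conditional_mutual_information(x, y, z_const),
               mutual_information(x, y), tolerance = 1e-12)
  # conditioning on x itself leaves no residual information
  expect_equal(conditional_mutual_information(x, y, x), 0, tolerance = 1e-12)
  # random triples agree with the triple-loop oracle
  for (i in 1:12) {
    x <- sample(0:2, 80, TRUE); y <- sample(0:2, 80, TRUE)
    z <- sample(0:2, 80, TRUE)
    expect_equal(conditional_mutual_information(x, y, z),
                 oracle_cmi(x, y, z), tolerance = 1e-12)
  }
})

test_that("transfer entropy equals the lagged CMI and its oracle", {
  set.seed(4)
  src <- sample(0:4, 300, TRUE); tgt <- sample(0:4, 300, TRUE)
  n <- length(tgt)
  expect_equal(transfer_entropy(src, tgt),
               conditional_mutual_information(tgt[-1], src[-n], tgt[-n]),
               tolerance = 1e-12)
  for (i in 1:10) {
    s <- sample(0:3, 120, TRUE); tg <- sample(0:3, 120, TRUE)
    expect_equal(transfer_entropy(s, tg), oracle_te(s, tg), tolerance = 1e-12)
  }
  # missing-value flag below the sample threshold
  expect_true(is.na(transfer_entropy(0:30, 0:30, min_samples = 50)))
  expect_error(transfer_entropy(1:10, 1:11), "equal length")
})

test_that("information measures are non-negative on fuzzed inputs", {
  set.seed(5)
  for (i in 1:40) {
    n <- sample(30:150, 1)
    k <- sample(2:5, 1)
    x <- sample(seq_len(k) - 1L, n, TRUE)
    y <- sample(seq_len(k) - 1L, n, TRUE)
    z <- sample(seq_len(k) - 1L, n, TRUE)
    expect_gte(mutual_information(x, y), -1e-12)
    expect_gte(conditional_mutual_information(x, y, z), -1e-12)
    te <- transfer_entropy(x, y, min_samples = 10)
    expect_gte(te, -1e-12)
  }
})

test_that("a deterministic one-step copy attains the source entropy", {
  set.seed(6)
  src <- sample(0:19, 100000, TRUE)
  tgt <- c(0L, src[-length(src)])   # target copies the source's last symbol
  te <- transfer_entropy(src, tgt)
  expect_equal(te, log2(20), tolerance = 0.05)
  # and an iid target carries no transfer
  expect_lt(transfer_entropy(sample(0:19, 10000, TRUE),
                             sample(0:19, 10000, TRUE)), 0.6)
})

test_that("pairwise TE assembles the slot-pair matrix with missing flags", {
  sim <- simulate_inflammation(tiny_params(stimulus = 0, n_iterations = 80L,
                                           seed = 21))
  te <- pairwise_te(sim$tracks, min_samples = 30L)
  expect_equal(nrow(te), 400L)
  expect_equal(sort(unique(te$m_slot)), 1:20)
  expect_equal(sort(unique(te$f_slot)), 1:20)
  expect_true(all(te$te[!is.na(te$te)] >= -1e-12))
  m <- te_matrix(te)
  expect_equal(dim(m), c(20L, 20L))
  expect_equal(m["M3", "F7"], te$te[te$m_slot == 3 & te$f_slot == 7])

  # pairs below the triple threshold are flagged missing, not numeric
  strict <- pairwise_te(sim$tracks, min_samples = 10000L)
  expect_true(all(is.na(strict$te)))
  expect_equal(strict$n_triples, te$n_triples)
})

test_that("pooling replicate tracks accumulates triples per slot pair", {
  p <- tiny_params(stimulus = 0, n_iterations = 60L)
  sims <- run_replicates(p, 3, base_seed = 31)
  tracks <- lapply(sims, function(s) s$tracks)
  singles <- lapply(tracks, pairwise_te, min_samples = 10L)
  pooled <- pairwise_te(tracks, min_samples = 10L)
  n_single <- Reduce(`+`, lapply(singles, function(x) x$n_triples))
  expect_equal(pooled$n_triples, n_single)
  # pooled estimate differs from the mean of per-replicate estimates
  # (it is one histogram, not an average) but stays non-negative
  expect_true(all(pooled$te[!is.na(pooled$te)] >= -1e-12))
})
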