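# ---- SPA --------------------------------------------------------------------

test_that("orthogonal columns chain in order of decreasing norm", {
  # mutually orthogonal columns with norms 3 > 2 > 1 (after centering)
  Q <- qr.Q(qr(matrix(rnorm(18), 6, 3)))
  Qc <- scale(Q, center = TRUE, scale = FALSE)
  Qc <- qr.Q(qr(Qc))                       # re-orthogonalize centered basis
  X <- Qc %*% diag(c(3, 1, 2))
  X <- sweep(X, 2, colMeans(X))            # already centered
  chains <- spa_chains(X, spa_config(n_min = 1, n_max = 3))
  expect_equal(unname(chains[1, ]), c(1L, 3L, 2L))  # start at norm 3: 3,2,1
  expect_equal(unname(chains[2, ]), c(2L, 1L, 3L))  # projections unchanged
})

test_that("an exactly duplicated channel is appended last", {
  set.seed(4)
  X <- matrix(rnorm(8 * 4), 8, 4)
  X <- cbind(X, X[, 2])                    # duplicate of channel 2
  chains <- spa_chains(X, spa_config(n_max = 5))
  expect_equal(chains[2, 5], 5L)           # twin has zero projection norm
  expect_equal(chains[5, 5], 2L)
  # chains never repeat a channel
  for (k in 1:5) expect_equal(anyDuplicated(chains[k, ]), 0L)
})

test_that("chains equal the Gram-Schmidt brute-force oracle for every start", {
  for (seed in c(3, 14)) {
    set.seed(seed)
    X <- matrix(rnorm(10 * 6), 10, 6)
    chains <- spa_chains(X, spa_config(n_max = 6))
    for (k in 1:6)
      expect_equal(unname(chains[k, ]), naive_spa_chain(X, k, 6))
  }
})

test_that("phase 2 recovers an exact two-channel relationship", {
  set.seed(6)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- 2 * X[, 3] - X[, 6] + 0.4
  cal <- 1:20; val <- 21:30
  cfg <- spa_config(n_min = 1, n_max = 8, max_factors = 8)
  chains <- spa_chains(X[cal, ], cfg)
  ev <- spa_evaluate(chains, X[cal, ], y[cal], X[val, ], y[val], cfg)
  expect_lt(ev$rmsev, 1e-6)
  expect_true(all(c(3, 6) %in% ev$subset))
  # returned minimum is the minimum of the returned table
  expect_equal(ev$rmsev, min(ev$table, na.rm = TRUE))
})

test_that("single-channel evaluation equals the univariate argmin oracle", {
  set.seed(8)
  X <- matrix(rnorm(24 * 6), 24, 6)
  y <- X[, 4] + rnorm(24, 0, 0.3)
  cal <- 1:16; val <- 17:24
  cfg <- spa_config(n_min = 1, n_max = 1, max_factors = 1)
  chains <- matrix(1:6, 6, 1)
  ev <- spa_evaluate(chains, X[cal, ], y[cal], X[val, ], y[val], cfg)
  # exhaustive univariate regressions
  rmsevs <- vapply(1:6, function(j) {
    fit <- lm(y[cal] ~ X[cal, j])
    pred <- cbind(1, X[val, j]) %*% coef(fit)
    sqrt(mean((pred - y[val])^2))
  }, numeric(1))
  expect_equal(ev$subset, which.min(rmsevs))
  expect_equal(ev$rmsev, min(rmsevs), tolerance = 1e-10)
})

test_that("phase 3 drops an appended pure-noise channel", {
  set.seed(12)
  n <- 40
  xA <- rnorm(n); xB <- rnorm(n)          # B is pure noise
  y <- 1.5 * xA + rnorm(n, 0, 0.01)
  X <- cbind(xA, xB)
  cal <- 1:28; val <- 29:40
  el <- spa_eliminate(c(1L, 2L), X[cal, ], y[cal], X[val, ], y[val],
                      spa_config(max_factors = 2))
  expect_equal(el$selected, 1L)
  # single-channel subsets pass through unchanged
  expect_equal(spa_eliminate(2L, X[cal, ], y[cal], X[val, ], y[val],
                             spa_config())$selected, 2L)
})

test_that("the F-criterion behaves correctly in the alpha limits", {
  set.seed(13)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- X[, 1] - X[, 2] + rnorm(30, 0, 0.2)
  cal <- 1:20; val <- 21:30
  subset <- 1:5
  tight <- spa_eliminate(subset, X[cal, ], y[cal], X[val, ], y[val],
                         spa_config(alpha = 0.999))
  loose <- spa_eliminate(subset, X[cal, ], y[cal], X[val, ], y[val],
                         spa_config(alpha = 1e-9))
  # alpha -> 1: only the argmin prefix survives
  expect_equal(length(tight$selected), which.min(tight$trajectory))
  # alpha -> 0: every prefix passes, so the shortest wins
  expect_equal(length(loose$selected), 1L)
})

test_that("spa_select reports a self-consistent selection object", {
  d <- make_fixture("tiny-10x8")
  split <- spxy_split(d$spectra, d$reference, c(3, 1))
  y <- d$reference$scc
  # channel 1 of the tiny fixture is flat; its chain is skipped with a warning
  expect_warning(
  sel <- spa_select(d$spectra$reflectance[split$calibration_idx, ],
                    y[split$calibration_idx],
                    d$spectra$reflectance[split$validation_idx, ],
                    y[split$validation_idx],
                    spa_config(n_min = 1, n_max = 4, max_factors = 3),
                    wavelengths = d$spectra$wavelengths),
  "zero variance")
  expect_s3_class(sel, "wavelength_selection")
  expect_true(all(sel$selected %in% 1:8))
  expect_equal(anyDuplicated(sel$selected), 0L)
  expect_equal(sel$wavelengths, d$spectra$wavelengths[sel$selected])
})

# ---- MCUVE ------------------------------------------------------------------

test_that("stability is seeded-deterministic and handles dead channels", {
  set.seed(20)
  X <- matrix(rnorm(30 * 6), 30, 6)
  X[, 4] <- 0                              # identically zero channel
  y <- X[, 1] + rnorm(30, 0, 0.1)
  cfg <- mcuve_config(n_runs = 50, max_factors = 3, seed = 5L)
  expect_warning(C1 <- mcuve_stability(X, y, cfg), "degenerate")
  expect_warning(C2 <- mcuve_stability(X, y, cfg), "degenerate")
  expect_identical(C1, C2)
  expect_equal(unname(C1[4]), 0)
})

test_that("stability ranking separates informative from noise channels", {
  set.seed(30)
  n <- 60
  y <- rnorm(n)
  X <- cbind(vapply(1:5, function(k) 0.8 * y + rnorm(n, 0, 0.2), numeric(n)),
             matrix(rnorm(n * 15), n, 15))
  C <- mcuve_stability(X, y, mcuve_config(n_runs = 100, max_factors = 5,
                                          seed = 3L))
  expect_gt(min(abs(C[1:5])), max(abs(C[6:20])))
})

test_that("|C| ranking is invariant to positive rescaling of the spectra", {
  set.seed(31)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- X[, 2] - 0.5 * X[, 7] + rnorm(40, 0, 0.1)
  cfg <- mcuve_config(n_runs = 60, max_factors = 4, seed = 9L)
  C1 <- mcuve_stability(X, y, cfg)
  C2 <- mcuve_stability(X * 7.3, y, cfg)
  expect_equal(order(-abs(C1)), order(-abs(C2)))
})

test_that("forward selection minimizes the RMSEV trajectory", {
  set.seed(33)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- 1.2 * X[, 2] - 0.8 * X[, 5]         # exact in channels 2 and 5
  cal <- 1:30; val <- 31:40
  cfg <- mcuve_config(n_runs = 80, max_factors = 4, seed = 21L)
  C <- mcuve_stability(X[cal, ], y[cal], cfg)
  sel <- mcuve_select(C, X[cal, ], y[cal], X[val, ], y[val], cfg)
  expect_setequal(sel$selected, c(2L, 5L))
  expect_lt(sel$rmsev, 1e-6)
  # j* is the argmin of the reported trajectory
  expect_equal(length(sel$selected), which.min(sel$trajectory$rmsev))
  expect_true(all(sel$trajectory$rmsev >= 0))

  # K = 1: the single channel is selected
  s1 <- mcuve_select(2, X[cal, 2, drop = FALSE], y[cal],
                     X[val, 2, drop = FALSE], y[val],
                     mcuve_config(n_runs = 10, max_factors = 1))
  expect_equal(s1$selected, 1L)
})
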