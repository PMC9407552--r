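test_that("SNV standardizes every spectrum to mean 0 and unit sample SD", {
  s <- spectra_set(c(1, 2, 3) * 100, rbind(c(1, 2, 3)), "a")
  expect_equal(unname(snv(s)$reflectance), rbind(c(-1, 0, 1)))

  # idempotent on already-normalized rows
  expect_equal(snv(snv(s))$reflectance, snv(s)$reflectance)

  set.seed(1)
  r <- rand_spectra(20, 50, 1)
  z <- snv(r)$reflectance
  expect_lt(max(abs(rowMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-10)

  bad <- spectra_set(c(500, 600), rbind(c(1, 2), c(3, 3)), c("ok", "flat"))
  expect_error(snv(bad), "flat")
})

test_that("MSC inverts affine gain/offset corruption against the reference", {
  ref <- sin(seq(0, 3, length.out = 40)) + 2
  x <- rbind(0.5 + 2 * ref, ref, 3 * ref - 1)
  s <- spectra_set(seq(500, by = 5, length.out = 40), x, c("a", "b", "c"))
  out <- msc(s, reference = ref)$reflectance
  for (i in 1:3) expect_equal(unname(out[i, ]), ref, tolerance = 1e-10)

  # per-row (a, b) match independent lm fits when using the mean reference
  set.seed(2)
  r <- rand_spectra(6, 30, 2)
  mref <- colMeans(r$reflectance)
  corrected <- msc(r)$reflectance
  for (i in 1:6) {
    fit <- lm(r$reflectance[i, ] ~ mref)
    a <- coef(fit)[1]; b <- coef(fit)[2]
    expect_equal(unname(corrected[i, ]),
                 unname((r$reflectance[i, ] - a) / b), tolerance = 1e-10)
  }
})

test_that("Savitzky-Golay reproduces polynomials and averages windows", {
  wl <- seq(500, by = 2, length.out = 41)
  z <- seq(-1, 1, length.out = 41)
  for (frame in c(3, 5, 7, 9)) {
    for (ord in 1:min(7, frame - 1)) {
      poly_row <- 2 + z - 0.5 * z^ord
      s <- spectra_set(wl, rbind(poly_row), "p")
      expect_equal(unname(savgol(s, frame, ord)$reflectance[1, ]), poly_row,
                   tolerance = 1e-8)
    }
  }

  # (3,1) is the 3-point moving average in the interior
  s3 <- spectra_set(c(500, 510, 520), rbind(c(0, 3, 0)), "a")
  expect_equal(unname(savgol(s3, 3, 1)$reflectance[1, 2]), 1)

  # constant row maps to itself
  sc <- spectra_set(wl, matrix(2.5, 1, 41), "c")
  expect_equal(unname(savgol(sc, 7, 5)$reflectance[1, ]), rep(2.5, 41))

  expect_error(savgol(sc, 4, 1), "odd")
  expect_error(savgol(sc, 7, 7), "< frame")
})

test_that("Savitzky-Golay matches the local least-squares oracle everywhere", {
  set.seed(9)
  x <- cumsum(rnorm(30))
  s <- spectra_set(seq(500, by = 2, length.out = 30), rbind(x), "a")
  for (cfg in list(c(7, 5), c(5, 2), c(9, 3))) {
    got <- savgol(s, cfg[1], cfg[2])$reflectance[1, ]
    expect_equal(unname(got), naive_savgol_row(x, cfg[1], cfg[2]),
                 tolerance = 1e-8)
  }
})

test_that("interior coefficients agree with signal::sgolayfilt", {
  skip_if_not_installed("signal")
  set.seed(10)
  x <- rnorm(50)
  s <- spectra_set(seq(500, by = 2, length.out = 50), rbind(x), "a")
  got <- savgol(s, 7, 5)$reflectance[1, ]
  refsig <- signal::sgolayfilt(x, p = 5, n = 7)
  expect_equal(got[4:47], refsig[4:47], tolerance = 1e-8)
})

test_that("pipelines compose in order and preserve shape and ids", {
  d <- make_fixture("tiny-10x8")
  s <- d$spectra
  expect_identical(apply_preprocess(preprocess_spec("none"), s)$reflectance,
                   s$reflectance)
  combo <- apply_preprocess(preprocess_spec(c("savgol:7:5", "snv")), s)
  expect_equal(combo$reflectance, snv(savgol(s, 7, 5))$reflectance)
  expect_identical(combo$sample_ids, s$sample_ids)
  expect_identical(dim(combo), dim(s))
  expect_error(preprocess_spec("savgol:4:2"), "odd")
  expect_error(preprocess_spec("wiggle"), "unknown")
})

test_that("MSC and SNV both recover shape from pure gain corruption", {
  cfg <- synthetic_config(n_samples = 8, replicates_per_sample = 1,
                          grid = c(500, 1000, 5), scatter_sd = 0.15,
                          drift_sd = 0, noise_sd = 0, seed = 31L)
  d <- simulate_pear_spectra(cfg)
  for (f in list(msc, snv)) {
    z <- f(d$spectra)$reflectance
    # after correction, every row is an affine function of the base shape
    for (i in 1:8) {
      res <- resid(lm(z[i, ] ~ d$truth$base[i, ]))
      expect_lt(max(abs(res)), 1e-8)
    }
  }
})

test_that("preprocessing comparison ranks candidates and breaks ties", {
  cfg <- synthetic_config(n_samples = 30, replicates_per_sample = 1,
                          grid = c(500, 1000, 10), scatter_sd = 0.1,
                          drift_sd = 0, noise_sd = 0.002, seed = 17L)
  d <- simulate_pear_spectra(cfg)
  split <- spxy_split(d$spectra, d$reference, c(3, 1))

  one <- compare_preprocessing(d$spectra, d$reference, split,
                               list(preprocess_spec("snv")), max_factors = 5)
  expect_equal(one$chosen, 1L)

  same <- compare_preprocessing(d$spectra, d$reference, split,
                                list(preprocess_spec("msc"),
                                     preprocess_spec("msc")), max_factors = 5)
  expect_equal(same$chosen, 1L)  # deterministic tie-break: first listed

  cmp <- compare_preprocessing(d$spectra, d$reference, split,
                               list(preprocess_spec("none"),
                                    preprocess_spec("snv"),
                                    preprocess_spec("msc")), max_factors = 5)
  expect_true(all(abs(cmp$table$r_cal) <= 1) && all(cmp$table$rmse_val >= 0))
  # scatter-corrupted data: a scatter correction must outrank raw spectra
  expect_gt(max(cmp$table$r_val[2:3]), cmp$table$r_val[1])
  expect_true(cmp$chosen %in% 2:3)
})

test_that("the S-G grid search scores the admissible grid", {
  cfg <- synthetic_config(n_samples = 24, replicates_per_sample = 1,
                          grid = c(500, 1000, 10), noise_sd = 0.01, seed = 19L)
  d <- simulate_pear_spectra(cfg)
  split <- spxy_split(d$spectra, d$reference, c(3, 1))
  bs <- best_savgol(d$spectra, d$reference, split, max_factors = 5)
  expect_equal(nrow(bs$table), 2 + 4 + 6 + 7)  # odd frames 3,5,7,9
  expect_true(bs$best["frame"] %in% c(3, 5, 7, 9))
  expect_true(bs$best["order"] < bs$best["frame"])
  expect_equal(max(bs$table$r_val),
               bs$table$r_val[bs$table$frame == bs$best["frame"] &
                              bs$table$order == bs$best["order"]])
})
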