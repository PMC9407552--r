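test_that("spectra CSV round-trips bit-identically and validates input", {
  s <- spectra_set(c(500.5, 600, 700.25, 800, 900),
                   matrix(c(runif(15)), 3, 5), c("P001", "P002", "P003"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s, path)
  s2 <- read_spectra(path)
  expect_identical(s2$wavelengths, s$wavelengths)
  expect_identical(unname(s2$reflectance), unname(s$reflectance))
  expect_identical(s2$sample_ids, s$sample_ids)

  # second round trip is byte-stable
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s2, path2)
  expect_identical(readLines(path), readLines(path2))

  # duplicate id named in the error
  writeLines(c("id,500,600", "P001,1,2", "P001,3,4"), path)
  expect_error(read_spectra(path), "P001")
  # ragged row named by position
  writeLines(c("id,500,600", "P001,1,2", "P002,3"), path)
  expect_error(read_spectra(path), "row 3")
  # non-numeric cell
  writeLines(c("id,500,600", "P001,1,x"), path)
  expect_error(read_spectra(path), "non-numeric")
})

test_that("a study-sized synthetic table survives the file interface", {
  d <- make_fixture("paper-like-120")
  s <- average_replicates(d$spectra, d$group_map)
  expect_equal(dim(s), c(120, 1045))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s, path)
  s2 <- read_spectra(path)
  expect_equal(length(s2$sample_ids), 120)
  expect_equal(length(s2$wavelengths), 1045)
  expect_identical(unname(s2$reflectance), unname(s$reflectance))

  rp <- withr::local_tempfile(fileext = ".csv")
  write_reference(d$reference, rp)
  r2 <- read_reference(rp)
  expect_identical(r2$scc, d$reference$scc)
})

test_that("wavelength trimming keeps the closed effective window", {
  wl <- seq(468, 1155, by = 0.5)
  s <- spectra_set(wl, matrix(1, 2, length(wl)), c("a", "b"))
  t1 <- trim_wavelengths(s, 498, 1020)
  expect_true(all(t1$wavelengths >= 498 & t1$wavelengths <= 1020))
  expect_true(498 %in% t1$wavelengths && 1020 %in% t1$wavelengths)

  # identity and idempotence
  expect_identical(trim_wavelengths(s, min(wl), max(wl))$wavelengths, wl)
  expect_identical(trim_wavelengths(t1, 498, 1020)$reflectance,
                   t1$reflectance)

  # channel count equals direct enumeration on a uniform grid
  wl2 <- seq(498, 1020, by = 0.5)
  s2 <- spectra_set(wl2, matrix(0.5, 1, length(wl2)), "a")
  tr <- trim_wavelengths(s2, 600, 700)
  count <- 0
  for (w in wl2) if (w >= 600 && w <= 700) count <- count + 1
  expect_equal(length(tr$wavelengths), count)

  expect_error(trim_wavelengths(s, 2000, 3000), "no channel")
  expect_error(trim_wavelengths(s, 700, 600), "must be <")
})

test_that("replicate averaging is the channel-wise arithmetic mean", {
  wl <- c(500, 600)
  s <- spectra_set(wl, rbind(c(1, 1), c(3, 3), c(5, 7)),
                   c("A_r1", "A_r2", "B_r1"))
  gm <- c(A_r1 = "A", A_r2 = "A", B_r1 = "B")
  av <- average_replicates(s, gm)
  expect_equal(unname(av$reflectance), rbind(c(2, 2), c(5, 7)))
  expect_identical(av$sample_ids, c("A", "B"))

  # identical replicates reproduce the row; singletons are the identity
  s3 <- spectra_set(wl, rbind(c(2, 4), c(2, 4), c(2, 4)),
                    c("A_r1", "A_r2", "A_r3"))
  expect_equal(unname(average_replicates(s3, c(A_r1 = "A", A_r2 = "A",
                                               A_r3 = "A"))$reflectance),
               rbind(c(2, 4)))

  # random 9-row set in 3 groups against a per-group loop
  set.seed(42)
  m <- matrix(runif(9 * 4), 9, 4)
  ids <- sprintf("g%d_r%d", rep(1:3, each = 3), rep(1:3, 3))
  s9 <- spectra_set(seq(500, 650, by = 50), m, ids)
  gm9 <- setNames(sprintf("g%d", rep(1:3, each = 3)), ids)
  av9 <- average_replicates(s9, gm9)
  for (g in 1:3) {
    manual <- colSums(m[(3 * g - 2):(3 * g), ]) / 3
    expect_equal(unname(av9$reflectance[g, ]), manual)
  }

  expect_error(average_replicates(s, c(A_r1 = "A", A_r2 = "A", B_r1 = "B",
                                       ghost = "C")), "zero member")
})

test_that("gravimetric SCC formula and its invariances", {
  expect_equal(compute_scc(scc_measurement(1.0, 1.0, 50)), 0)
  expect_equal(compute_scc(scc_measurement(1.5, 1.0, 100)), 0.5)
  expect_error(scc_measurement(0.9, 1.0, 100), "negative stone mass")

  set.seed(7)
  for (i in 1:50) {
    mf <- runif(1, 0.5, 2); mt <- mf + runif(1, 0, 1); mp <- runif(1, 50, 200)
    expect_equal(compute_scc(scc_measurement(mt, mf, mp)),
                 (mt - mf) / mp * 100, tolerance = 1e-12)
    # homogeneity under mass rescaling
    c0 <- runif(1, 0.1, 10)
    expect_equal(compute_scc(scc_measurement(mt * c0, mf * c0, mp * c0)),
                 compute_scc(scc_measurement(mt, mf, mp)), tolerance = 1e-12)
  }
})

test_that("reference statistics use the sample SD convention", {
  st <- summarize_reference(c(0.4, 0.5, 0.6))
  expect_equal(st$mean, 0.5)
  expect_equal(st$min, 0.4)
  expect_equal(st$max, 0.6)
  expect_equal(st$sd, 0.1)

  expect_warning(s1 <- summarize_reference(0.5), "single value")
  expect_equal(s1$sd, 0)

  set.seed(3)
  x <- runif(90, 0.2, 0.7)
  st90 <- summarize_reference(reference_set(sprintf("s%d", 1:90), x))
  expect_equal(st90$mean, sum(x) / 90)
  expect_equal(st90$sd, sqrt(sum((x - mean(x))^2) / 89))
  expect_error(summarize_reference(numeric(0)), "empty")
})

test_that("two-group ANOVA matches the F distribution and t-test identity", {
  expect_equal(anova_two_groups(c(1, 1, 1), c(1, 1, 1)), list(F = 0, p = 1))

  set.seed(11)
  a <- rnorm(12); b <- rnorm(9, 0.5)
  res <- anova_two_groups(a, b)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)

  # p equals the F CDF tail computed directly
  a2 <- rnorm(90, 0.486, 0.1); b2 <- rnorm(30, 0.481, 0.083)
  r2 <- anova_two_groups(a2, b2)
  expect_equal(r2$p, 1 - pf(r2$F, 1, 118), tolerance = 1e-8)
  expect_true(r2$p >= 0 && r2$p <= 1)

  # label swap invariance
  r3 <- anova_two_groups(b2, a2)
  expect_equal(r3$F, r2$F, tolerance = 1e-12)

  expect_error(anova_two_groups(1, c(1, 2)), "at least 2")
})
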