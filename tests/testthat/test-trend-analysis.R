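test_that("sample_ages respects ranges and collapses zero-width intervals", {
  rec <- data.frame(species = c("a", "b", "c"),
                    older_mya = c(60, 45, 20), younger_mya = c(48, 34, 20))
  set.seed(42)
  ages <- replicate(200, sample_ages(rec))
  expect_true(all(ages[1, ] >= 48 & ages[1, ] <= 60))
  expect_true(all(ages[2, ] >= 34 & ages[2, ] <= 45))
  expect_true(all(ages[3, ] == 20))   # zero-width range is deterministic
  expect_error(sample_ages(data.frame(older_mya = 10, younger_mya = 20)),
               "inverted")
  expect_error(sample_ages(data.frame(older_mya = NA, younger_mya = 1)),
               "finite")
})

test_that("pearson_r_p agrees with cor.test on exchangeable data", {
  set.seed(7)
  x <- rnorm(12); y <- 0.4 * x + rnorm(12)
  got <- pearson_r_p(x, y)
  ref <- cor.test(x, y, method = "pearson")
  expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  # perfectly collinear data: |r| = 1, p = 0
  expect_equal(pearson_r_p(1:5, 2 * (1:5) + 3), list(r = 1, p = 0))
  expect_equal(pearson_r_p(1:5, -(1:5)), list(r = -1, p = 0))
  expect_error(pearson_r_p(1:2, 1:2), ">= 3")
  expect_error(pearson_r_p(rep(1, 5), 1:5), "zero variance")
})

test_that("repeated_correlation is reproducible and leaves the global RNG alone", {
  rec <- data.frame(older_mya = c(60, 45, 34, 22, 15),
                    younger_mya = c(48, 34, 22, 13, 2.6))
  vals <- c(1, 2, 3, 4, 5)
  set.seed(99)
  before <- .Random.seed
  t1 <- repeated_correlation(vals, rec, n_reps = 50, seed = 11)
  expect_identical(.Random.seed, before)   # global stream untouched
  t2 <- repeated_correlation(vals, rec, n_reps = 50, seed = 11)
  expect_identical(t1$coefficients, t2$coefficients)
  expect_identical(t1$p_values, t2$p_values)
  t3 <- repeated_correlation(vals, rec, n_reps = 50, seed = 12)
  expect_false(identical(t1$coefficients, t3$coefficients))
  expect_error(repeated_correlation(vals[1:3], rec, 10), "per species")
})

test_that("zero-width ranges collapse the resampled correlation to a constant", {
  rec <- data.frame(older_mya = c(50, 30, 10), younger_mya = c(50, 30, 10))
  vals <- c(1, 3, 2)
  tr <- repeated_correlation(vals, rec, n_reps = 25, seed = 3)
  ref <- pearson_r_p(vals, c(50, 30, 10))
  expect_equal(tr$coefficients, rep(ref$r, 25), tolerance = 1e-12)
  expect_equal(tr$p_values, rep(ref$p, 25), tolerance = 1e-12)
  ds <- density_summary(tr)
  expect_equal(unname(ds$quantiles["coefficient", ]), rep(ref$r, 5),
               tolerance = 1e-12)
  expect_null(ds$density$coefficient)   # degenerate sample has no density
})

test_that("fully overlapping identical ranges give a null trend (mean r near 0)", {
  # every species shares the same interval, so resampled ages are exchangeable
  # and E[r] = 0 by symmetry; check the Monte Carlo mean within 3 standard errors
  rec <- data.frame(older_mya = rep(40, 6), younger_mya = rep(20, 6))
  vals <- c(2.2, 5.1, 3.3, 7.4, 1.8, 4.4)
  tr <- repeated_correlation(vals, rec, n_reps = 4000, seed = 8)
  se <- sd(tr$coefficients) / sqrt(tr$n_reps)
  expect_lt(abs(mean(tr$coefficients)), 3 * se)
})

test_that("a monotone stress sequence over disjoint ranges gives single-signed r", {
  # stress strictly increasing towards the present across non-overlapping
  # ranges must always correlate negatively with age, whatever the resample
  rec <- data.frame(older_mya = c(60, 45, 34, 22, 15),
                    younger_mya = c(48, 34, 22, 13, 2.6))
  vals <- c(1, 2, 3, 4, 5)   # youngest species most stressed
  tr <- repeated_correlation(vals, rec, n_reps = 500, seed = 5)
  expect_true(all(tr$coefficients < 0))
  expect_true(all(tr$p_values >= 0 & tr$p_values <= 1))
  q <- density_summary(tr)$quantiles
  expect_lt(q["coefficient", "97.5%"], 0)
})

test_that("trend results export replicates CSV plus JSON metadata", {
  rec <- data.frame(species = c("a", "b", "c"),
                    older_mya = c(30, 20, 10), younger_mya = c(25, 15, 5))
  tr <- repeated_correlation(c(1, 5, 3), rec, n_reps = 20, seed = 2)
  pref <- file.path(withr::local_tempdir(), "trend")
  write_trend_result(tr, pref)
  tab <- read.csv(paste0(pref, "_replicates.csv"))
  expect_equal(nrow(tab), 20L)
  expect_equal(tab$r, tr$coefficients, tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(pref, "_meta.json"), simplifyVector = TRUE)
  expect_equal(meta$seed, 2L)
  expect_equal(meta$n_reps, 20L)
  expect_equal(meta$records$species, c("a", "b", "c"))
})
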