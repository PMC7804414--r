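# The 6 x 4 ratings table used below is the classic interrater demonstration
# set; expected ICC values were frozen from an independent implementation
# (brute-force ANOVA mean squares, cross-checked against pingouin).
sf_table <- matrix(c(9, 2, 5, 8,
                     6, 1, 3, 2,
                     8, 4, 6, 8,
                     7, 1, 2, 6,
                     10, 5, 6, 9,
                     6, 2, 4, 7), nrow = 6, byrow = TRUE)

# Independent mean-square oracle computed directly from the sums of squares.
ref_two_way_ms <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  gm <- mean(tab)
  ssr <- k * sum((rowMeans(tab) - gm)^2)
  ssc <- n * sum((colMeans(tab) - gm)^2)
  sst <- sum((tab - gm)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

test_that("ICC(2,1) matches the brute-force mean-square computation", {
  ms <- ref_two_way_ms(sf_table)
  n <- nrow(sf_table); k <- ncol(sf_table)
  want <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
  got <- icc(sf_table)
  expect_equal(got$icc, want, tolerance = 1e-10)
  expect_equal(got$msr, ms$msr, tolerance = 1e-10)
  expect_equal(got$msc, ms$msc, tolerance = 1e-10)
  expect_equal(got$mse, ms$mse, tolerance = 1e-10)
  ## frozen independent values (pingouin ICC(A,1) on the same table)
  expect_equal(got$icc, 0.289763779528, tolerance = 1e-9)
  expect_equal(round(got$lower, 2), 0.02)
  expect_equal(round(got$upper, 2), 0.76)
  ## the other variants agree with their frozen counterparts
  expect_equal(icc(sf_table, "ICC1")$icc, 0.165741768405, tolerance = 1e-9)
  expect_equal(icc(sf_table, "ICC3")$icc, 0.714840714841, tolerance = 1e-9)
})

test_that("ICC edge cases and invariances hold", {
  ## identical columns with non-constant rows: perfect agreement
  tab <- cbind(1:6, 1:6, 1:6)
  expect_equal(icc(tab)$icc, 1)
  ## independently shuffled noise: near-zero ICC at n = 200
  withr::with_seed(14, {
    tab0 <- cbind(rnorm(200), rnorm(200), rnorm(200))
    expect_lt(abs(icc(tab0)$icc), 0.1)
  })
  ## invariant under adding a constant and under positive rescaling
  base <- icc(sf_table)$icc
  expect_equal(icc(sf_table + 100)$icc, base, tolerance = 1e-12)
  expect_equal(icc(sf_table * 3.7)$icc, base, tolerance = 1e-12)
  ## degenerate input is rejected
  expect_error(icc(matrix(5, 4, 3)), "undefined|variance")
  expect_error(icc(sf_table[1, , drop = FALSE]), "at least 2")
  expect_error(icc(cbind(c(1, 2, NA), 1:3)), "missing")
})

test_that("Bland-Altman bias and limits follow their closed forms", {
  a <- c(10, 12, 15, 20, 30)
  ba0 <- bland_altman(a, a)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  ## proportional offset: constant percent difference, zero spread
  b <- a
  a2 <- 1.02 * b
  bap <- bland_altman(a2, b, percent = TRUE)
  expect_equal(bap$bias, 100 * 0.02 / 1.01, tolerance = 1e-12)
  expect_equal(bap$loa_low, bap$loa_high)
  ## antisymmetry under argument swap
  withr::with_seed(3, {
    x <- runif(20, 50, 150)
    y <- x + rnorm(20, 2, 5)
    f <- bland_altman(x, y, percent = TRUE)
    g <- bland_altman(y, x, percent = TRUE)
    expect_equal(f$bias, -g$bias, tolerance = 1e-12)
    expect_equal(f$loa_low, -g$loa_high, tolerance = 1e-12)
    expect_equal(f$loa_high, -g$loa_low, tolerance = 1e-12)
    expect_true(f$loa_low <= f$bias && f$bias <= f$loa_high)
  })
  ## a zero pairwise mean makes percent differences undefined
  expect_error(bland_altman(c(1, -1), c(2, 1), percent = TRUE), "zero")
})

test_that("OLS matches the normal-equation solve", {
  x <- 1:10
  expect_equal(linregress(x, x)$slope, 1, tolerance = 1e-12)
  expect_equal(linregress(x, x)$intercept, 0, tolerance = 1e-12)
  expect_equal(linregress(x, x)$r_squared, 1, tolerance = 1e-12)
  ex <- linregress(x, 2 * x + 3)
  expect_equal(ex$slope, 2, tolerance = 1e-12)
  expect_equal(ex$intercept, 3, tolerance = 1e-12)
  withr::with_seed(6, {
    xr <- rnorm(10)
    yr <- 1.5 * xr + rnorm(10, 0, 0.3)
    fit <- linregress(xr, yr)
    X <- cbind(1, xr)
    beta <- solve(t(X) %*% X, t(X) %*% yr)
    expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
    expect_equal(fit$slope, beta[2], tolerance = 1e-10)
    expect_equal(fit$r_squared, cor(xr, yr)^2, tolerance = 1e-12)
  })
  expect_error(linregress(rep(1, 5), 1:5), "variance")
  expect_error(linregress(1:2, 1:2), "at least 3")
})

test_that("the Jaccard index matches its analytic cases", {
  a <- matrix(0L, 10, 10); a[2:4, 2:4] <- 1L
  expect_equal(jaccard(a, a), 1)
  b <- matrix(0L, 10, 10); b[7:9, 7:9] <- 1L
  expect_equal(jaccard(a, b), 0)
  ## two unit squares overlapping half their area: 0.5 / 1.5 = 1/3
  s1 <- matrix(0L, 10, 20); s1[1:10, 1:10] <- 1L
  s2 <- matrix(0L, 10, 20); s2[1:10, 6:15] <- 1L
  expect_equal(jaccard(s1, s2), 1 / 3)
  ## symmetry, range, and the empty-mask flag
  expect_equal(jaccard(s1, s2), jaccard(s2, s1))
  withr::with_seed(4, {
    for (i in 1:10) {
      r1 <- matrix(rbinom(100, 1, 0.3), 10, 10)
      r2 <- matrix(rbinom(100, 1, 0.3), 10, 10)
      j <- jaccard(r1, r2)
      expect_gte(j, 0)
      expect_lte(j, 1)
      if (!identical(r1, r2)) expect_lt(j, 1)
    }
  })
  e <- matrix(0L, 5, 5)
  expect_warning(res <- jaccard(e, e), "empty")
  expect_true(is.na(res))
})

test_that("long-format ratings CSVs round-trip to the matrix layout", {
  d <- withr::local_tempdir()
  long <- data.frame(subject = rep(1:6, 4), rater = rep(letters[1:4], each = 6),
                     value = as.vector(sf_table))
  p <- file.path(d, "ratings.csv")
  write.csv(long, p, row.names = FALSE)
  tab <- read_ratings(p)
  expect_equal(unname(tab), unname(sf_table))
  expect_equal(icc(tab)$icc, icc(sf_table)$icc, tolerance = 1e-12)
  ## incomplete tables are rejected
  write.csv(long[-1, ], p, row.names = FALSE)
  expect_error(read_ratings(p), "incomplete")
})

test_that("agreement_summary bundles the three statistics", {
  withr::with_seed(9, {
    manual <- runif(30, 100, 400)
    auto <- manual * 1.02 + rnorm(30, 0, 6)
    s <- agreement_summary(manual, auto)
    expect_s3_class(s$icc, "icc_result")
    expect_s3_class(s$bland_altman, "bland_altman")
    expect_s3_class(s$regression, "linregress_result")
    expect_gt(s$icc$icc, 0.9)
    expect_gt(s$regression$r_squared, 0.9)
  })
})
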