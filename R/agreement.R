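## Agreement statistics for validating automated counts against manual ones:
## intraclass correlation (two-way random effects, absolute agreement,
## single rater), Bland-Altman bias with 95% limits of agreement, ordinary
## least-squares regression, and the Jaccard index for mask overlap.

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC computed from
#' the two-way ANOVA mean squares, with the 95% confidence interval from the
#' standard F-based formula (McGraw & Wong). Other common variants are
#' available: `"ICC1"` (one-way random) and `"ICC3"` (two-way mixed,
#' consistency).
#'
#' @param table numeric matrix: rows = subjects (>= 2), columns = raters
#'   (>= 2), no missing cells.
#' @param type `"ICC2"` (default), `"ICC1"` or `"ICC3"`.
#' @param conf_level confidence level (default 0.95).
#' @return an object of class `icc_result`: `icc`, `lower`, `upper`, `type`,
#'   the ANOVA mean squares (`msr`, `msc`, `mse`), and dimensions.
#' @export
icc <- function(table, type = c("ICC2", "ICC1", "ICC3"), conf_level = 0.95) {
  type <- match.arg(type)
  table <- as.matrix(table)
  if (any(!is.finite(table))) stop("ratings table contains missing cells")
  n <- nrow(table); k <- ncol(table)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")

  ## two-way ANOVA mean squares via stats::aov on the long layout
  long <- data.frame(value = as.vector(table),
                     subject = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(aov(value ~ subject + rater, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  ## one-way residual (subjects only), for ICC1
  msw <- (msc * (k - 1) + mse * (k - 1) * (n - 1)) / (n * (k - 1))

  if (var(rowMeans(table)) <= .Machine$double.eps * max(1, mean(table))^2)
    stop("zero between-subject variance: ICC undefined")
  alpha <- 1 - conf_level
  est <- switch(type,
    ICC1 = (msr - msw) / (msr + (k - 1) * msw),
    ICC2 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    ICC3 = (msr - mse) / (msr + (k - 1) * mse)
  )
  ci <- switch(type,
    ICC1 = {
      fl <- (msr / msw) / qf(1 - alpha / 2, n - 1, n * (k - 1))
      fu <- (msr / msw) * qf(1 - alpha / 2, n * (k - 1), n - 1)
      c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    },
    ICC2 = {
      fj <- msc / mse
      vn <- (k - 1) * (n - 1) *
        (k * est * fj + n * (1 + (k - 1) * est) - k * est)^2
      vd <- (n - 1) * k^2 * est^2 * fj^2 +
        (n * (1 + (k - 1) * est) - k * est)^2
      v <- vn / vd
      f3u <- qf(1 - alpha / 2, n - 1, v)
      f3l <- qf(1 - alpha / 2, v, n - 1)
      lower <- n * (msr - f3u * mse) /
        (f3u * (k * msc + (k * n - k - n) * mse) + n * msr)
      upper <- n * (f3l * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f3l * msr)
      c(lower, upper)
    },
    ICC3 = {
      f <- msr / mse
      fl <- f / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      fu <- f * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    }
  )
  structure(list(icc = est, lower = ci[1], upper = ci[2], type = type,
                 conf_level = conf_level, msr = msr, msc = msc, mse = mse,
                 n_subjects = n, n_raters = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("%s = %.3f, %g%% CI [%.3f, %.3f] (%d subjects x %d raters)\n",
              x$type, x$icc, 100 * x$conf_level, x$lower, x$upper,
              x$n_subjects, x$n_raters))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences `a - b` (optionally as percent of the pairwise mean), mean
#' bias, and 95% limits of agreement `bias +/- 1.96 * sd`.
#'
#' @param a,b paired measurement series of equal length >= 2.
#' @param percent express differences as `100 * (a - b) / mean(a, b)`
#'   (pairwise mean denominator)?
#' @param loa_multiplier multiplier of the SD for the limits (1.96 = 95%).
#' @return an object of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `differences`, `means`, `percent`.
#' @export
bland_altman <- function(a, b, percent = FALSE, loa_multiplier = 1.96) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  m <- (a + b) / 2
  d <- a - b
  if (percent) {
    if (any(m == 0)) stop("pairwise mean of zero: percent differences undefined")
    d <- 100 * d / m
  }
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, loa_low = bias - loa_multiplier * s,
                 loa_high = bias + loa_multiplier * s, differences = d,
                 means = m, percent = percent),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  u <- if (x$percent) "%" else ""
  cat(sprintf("Bland-Altman: bias %+.2f%s, 95%% LoA [%+.2f, %+.2f]%s (n = %d)\n",
              x$bias, u, x$loa_low, x$loa_high, u, length(x$differences)))
  invisible(x)
}

#' Plot a Bland-Altman analysis
#'
#' @param x a `bland_altman`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  ylab <- if (x$percent) "difference (%)" else "difference"
  graphics::plot(x$means, x$differences, xlab = "pairwise mean", ylab = ylab,
                 pch = 16, ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
}

#' Ordinary least-squares regression
#'
#' Simple OLS of `y` on `x`; the coefficient of determination is the squared
#' Pearson correlation.
#'
#' @param x,y numeric vectors of equal length >= 3 with `var(x) > 0`.
#' @return an object of class `linregress_result`: `slope`, `intercept`,
#'   `r_squared`, and the underlying [stats::lm] `fit`.
#' @export
linregress <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points")
  if (var(x) == 0) stop("zero variance in x")
  fit <- lm(y ~ x)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = cor(x, y)^2, fit = fit),
            class = "linregress_result")
}

#' @export
print.linregress_result <- function(x, ...) {
  cat(sprintf("OLS: slope %.3f, intercept %.3f, R^2 %.3f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Jaccard index (intersection over union) of two binary masks
#'
#' `|A & B| / |A | B|`; 1 means identical masks, 0 disjoint ones.
#'
#' @param a,b binary matrices of identical shape; at least one foreground
#'   pixel in the union.
#' @return scalar in \[0, 1\]; `NA` with a warning when both masks are empty.
#' @export
jaccard <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- a > 0
  b <- b > 0
  uni <- sum(a | b)
  if (uni == 0) {
    warning("both masks empty: Jaccard index undefined")
    return(NA_real_)
  }
  sum(a & b) / uni
}

#' Read a long-format ratings CSV into a subjects x raters matrix
#'
#' @param path CSV with columns `subject`, `rater`, `value` (one measurement
#'   per row; every subject must be rated by every rater exactly once).
#' @return numeric matrix, rows = subjects, columns = raters.
#' @export
read_ratings <- function(path) {
  d <- read.csv(path)
  need <- c("subject", "rater", "value")
  if (!all(need %in% names(d)))
    stop("ratings CSV needs columns subject, rater, value")
  tab <- tapply(d$value, list(d$subject, d$rater), function(x) {
    if (length(x) != 1) stop("duplicate subject/rater cell")
    x
  })
  if (any(is.na(tab))) stop("incomplete ratings table")
  m <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m
}

#' Agreement summary between two count series
#'
#' Bundles the validation statistics used to compare automated and manual
#' counts: ICC of the two series as raters, percent Bland-Altman bias with
#' limits of agreement, and the OLS fit of `b` on `a`.
#'
#' @param a reference series (e.g. mean manual counts).
#' @param b comparison series (e.g. automated counts).
#' @return list with `icc`, `bland_altman`, `regression`.
#' @export
agreement_summary <- function(a, b) {
  list(icc = icc(cbind(a, b)),
       bland_altman = bland_altman(b, a, percent = TRUE),
       regression = linregress(a, b))
}
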