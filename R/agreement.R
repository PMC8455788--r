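# Reader-agreement statistics for paired biomarker series (TCV, cystic
# index, cyst count): Bland-Altman on percent differences and ordinary
# least-squares regression.

#' Bland-Altman bias and precision of percent differences
#'
#' Per pair, `d_i = 100 * (a_i - b_i) / ((a_i + b_i) / 2)` — the percent
#' difference relative to the pair mean, the symmetric convention under
#' which swapping the series only flips the sign of the bias. Bias is the
#' mean of `d`; precision is the sample (n-1) standard deviation of `d`.
#'
#' @param a,b positive measurement series of equal length (>= 2).
#' @return list with `bias` and `precision`, both in percent.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("series must have equal length", call. = FALSE)
  if (length(a) < 2) stop("at least two pairs are required", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b <= 0)) {
    stop("all values must be positive and finite", call. = FALSE)
  }
  d <- 100 * (a - b) / ((a + b) / 2)
  list(bias = mean(d), precision = sd(d))
}

#' Ordinary least-squares agreement
#'
#' Regresses `y` on `x`; the coefficient of determination equals the squared
#' Pearson correlation, so it is symmetric in `x` and `y` and blind to the
#' sign of the association.
#'
#' @param x,y numeric series of equal length (>= 2); `x` must not be
#'   constant.
#' @return list with `r2`, `slope`, `intercept`.
#' @export
linreg_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length", call. = FALSE)
  if (length(x) < 2) stop("at least two pairs are required", call. = FALSE)
  if (sd(x) == 0) stop("`x` must not be constant", call. = FALSE)
  fit <- lm(y ~ x)
  r2 <- if (sd(y) == 0) 1 else cor(x, y)^2
  list(r2 = r2,
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]))
}

#' Combined agreement report between two measurement series
#'
#' @param a,b positive measurement series (e.g. per-exam TCVs from two
#'   readers).
#' @return an `agreement_report`: Bland-Altman `bias` and `precision` (%),
#'   plus `r2`, `slope`, `intercept` of `b` regressed on `a`.
#' @export
agreement_report <- function(a, b) {
  ba <- bland_altman(a, b)
  lr <- linreg_r2(a, b)
  structure(c(ba, lr), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("bias %.1f%% +/- %.1f%% | R^2 = %.2f (slope %.3f, intercept %.3f)\n",
              x$bias, x$precision, x$r2, x$slope, x$intercept))
  invisible(x)
}

#' Bundled reader-study measurements
#'
#' Per-exam total cyst volumes (mL) and cyst counts for five exams measured
#' by two trained readers and an automated model; used in the package's
#' worked agreement examples.
#'
#' @return data frame with columns `case`, `tcv_reader1`, `tcv_reader2`,
#'   `tcv_model`, `count_reader1`, `count_reader2`, `count_model`.
#' @export
reader_study <- function() {
  read.csv(system.file("extdata", "reader_study.csv", package = "edgecore"),
           stringsAsFactors = FALSE)
}
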