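#' Theil-Sen robust line fit
#'
#' The slope is the median of all pairwise slopes
#' `(y_j - y_i) / (x_j - x_i)` over index pairs `i < j` with `x_i != x_j`;
#' the intercept is the median of `y_i - slope * x_i` over all points. Even
#' cardinalities take the mean of the two central order statistics (the usual
#' sample median). The estimator tolerates a sizeable fraction of gross
#' outliers (breakdown point about 29%), which is why it is preferred over
#' least squares when a subgroup of points does not follow the trend.
#'
#' @param x,y numeric vectors of equal length, at least 2 points and at least
#'   2 distinct `x` values.
#' @return an object of class `theil_sen` with components `coefficients`
#'   (named `(Intercept)`, `x`), `fitted.values`, `residuals`, `x`, `y`, `n`.
#' @examples
#' fit <- theil_sen(c(0, 1, 2), c(0, 1, 10))
#' coef(fit)  # slope 5, intercept 0
#' @export
theil_sen <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 2L) stop("theil_sen needs at least 2 points")
  dx <- outer(x, x, "-")
  lower <- lower.tri(dx) & dx != 0
  if (!any(lower)) stop("degenerate input: all x values identical")
  dy <- outer(y, y, "-")
  slope <- median(dy[lower] / dx[lower])
  intercept <- median(y - slope * x)
  fit <- intercept + slope * x
  structure(list(coefficients = c("(Intercept)" = intercept, x = slope),
                 fitted.values = fit, residuals = y - fit,
                 x = x, y = y, n = n, call = match.call()),
            class = "theil_sen")
}

#' @export
print.theil_sen <- function(x, digits = 4, ...) {
  cat("Theil-Sen regression (median of pairwise slopes)\n")
  cat(sprintf("  n = %d points\n", x$n))
  cat(sprintf("  intercept = %s\n  slope     = %s\n",
              format(x$coefficients[[1L]], digits = digits),
              format(x$coefficients[[2L]], digits = digits)))
  invisible(x)
}

#' Predict from a Theil-Sen fit
#'
#' @param object a `theil_sen` object.
#' @param newdata numeric vector of x values; defaults to the fitted points.
#' @param ... unused.
#' @return predicted y values.
#' @export
#' @method predict theil_sen
predict.theil_sen <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  object$coefficients[[1L]] + object$coefficients[[2L]] * as.numeric(newdata)
}

#' @export
#' @method residuals theil_sen
residuals.theil_sen <- function(object, ...) object$residuals
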