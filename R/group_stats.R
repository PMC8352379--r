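#' Two-tailed Student t-test (pooled variance)
#'
#' Classical equal-variance two-sample Student t-test, the test conventionally
#' used to compare nanorod-injected and saline-control groups on maximum
#' temperature and thermal time constant. A Welch (unequal-variance) variant
#' is available behind a flag. Degenerate inputs are resolved explicitly:
#' zero pooled variance with equal means gives `t = 0, p = 1`; zero pooled
#' variance with unequal means leaves the statistic undefined and errors.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param alpha significance level (default 0.05).
#' @param welch use the Welch test instead of the pooled-variance test.
#' @return An object of class `t_test_result` with fields `t_stat`, `df`,
#'   `p_value`, `significant`, `alpha`, `mean_a`, `mean_b`.
#' @examples
#' students_t_test(c(66, 68, 68, 70), c(51, 52, 52, 53))
#' @export
students_t_test <- function(group_a, group_b, alpha = 0.05, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values")
  pooled_var <- (sum((group_a - mean(group_a))^2) +
                 sum((group_b - mean(group_b))^2)) /
                (length(group_a) + length(group_b) - 2)
  if (!welch && pooled_var == 0) {
    if (mean(group_a) == mean(group_b)) {
      res <- list(t_stat = 0, df = length(group_a) + length(group_b) - 2,
                  p_value = 1)
    } else {
      stop("zero pooled variance with unequal means: t statistic undefined")
    }
  } else {
    ht <- stats::t.test(group_a, group_b, var.equal = !welch,
                        alternative = "two.sided")
    res <- list(t_stat = unname(ht$statistic), df = unname(ht$parameter),
                p_value = ht$p.value)
  }
  structure(
    list(t_stat = res$t_stat, df = res$df, p_value = res$p_value,
         significant = res$p_value < alpha, alpha = alpha,
         mean_a = mean(group_a), mean_b = mean(group_b)),
    class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("<t_test_result> t = %.4g, df = %.4g, p = %.4g (%ssignificant at alpha = %g)\n",
              x$t_stat, x$df, x$p_value, if (x$significant) "" else "not ",
              x$alpha))
  invisible(x)
}

#' Ellipsoid tumor volume from caliper measurements
#'
#' `V = L * W^2 / 2`, the standard caliper formula for subcutaneous tumor
#' volume, with `L` the longest dimension (mm) and `W` measured
#' perpendicular to it.
#'
#' @param length_l tumor length, mm (longest dimension).
#' @param width_w tumor width, mm; must not exceed `length_l`.
#' @return Volume in cubic millimeters.
#' @examples
#' tumor_volume(5, 4)  # 40
#' @export
tumor_volume <- function(length_l, width_w) {
  if (any(width_w <= 0)) stop("width must be positive")
  if (any(width_w > length_l))
    stop("width exceeds length; L is the longest dimension - swap the arguments")
  length_l * width_w^2 / 2
}
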