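#' Aperture area as an ellipse
#'
#' Approximates the shell aperture as an ellipse with aperture height and
#' width as the (full) axes: `area = pi * h * w / 4`, in mm^2.
#'
#' @param aperture_height,aperture_width positive lengths in mm (vectorized).
#' @return Area(s) in mm^2.
#' @export
aperture_area <- function(aperture_height, aperture_width) {
  if (any(aperture_height <= 0 | aperture_width <= 0, na.rm = TRUE))
    stop("aperture axes must be positive")
  pi * aperture_height * aperture_width / 4
}

#' Aperture area relative to shell height
#'
#' Dimensionless normalization of the elliptical aperture area by the
#' squared shell height (area over a length is not scale-free; dividing by
#' height^2 makes the ratio invariant under uniform growth). The raw
#' `area / height` variant is available via `squared = FALSE`; within a
#' fixed shell height the two rank specimens identically.
#'
#' @param record data frame or list with `aperture_height`,
#'   `aperture_width`, `shell_height` (mm); rows with missing values yield
#'   `NA` for downstream exclusion.
#' @param squared divide by `shell_height^2` (default) rather than
#'   `shell_height`.
#' @return Dimensionless ratio(s) (mm when `squared = FALSE`).
#' @export
relative_aperture <- function(record, squared = TRUE) {
  h <- record$shell_height
  if (any(h <= 0, na.rm = TRUE)) stop("shell height must be positive")
  area <- aperture_area(record$aperture_height, record$aperture_width)
  area / if (squared) h^2 else h
}

new_test_result <- function(statistic, value, df, p_value, n, ...) {
  structure(c(list(statistic = statistic, value = unname(value),
                   df = unname(df), p_value = unname(p_value), n = n),
              list(...)),
            class = "morpho_test")
}

#' @export
print.morpho_test <- function(x, ...) {
  df_txt <- if (length(x$df) == 0 || all(is.na(x$df))) ""
            else sprintf(", df = %s", paste(signif(x$df, 6), collapse = ", "))
  cat(sprintf("<morpho_test> %s = %.4f%s, p = %.4g (n = %s)\n",
              x$statistic, x$value, df_txt, x$p_value,
              paste(x$n, collapse = "+")))
  invisible(x)
}

#' Rank correlation (Spearman or Kendall)
#'
#' Tie-corrected rank correlation with a large-sample p-value. For Kendall's
#' tau the normal-approximation z statistic is reported (the convention used
#' when screening collinear environmental variables).
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @param method `"spearman"` or `"kendall"`.
#' @return A `morpho_test` with `value` (rs or tau), `z` (Kendall), `p_value`.
#' @export
rank_correlation <- function(x, y, method = c("spearman", "kendall")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("rank correlation needs n >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant vector")
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  if (method == "kendall") {
    z <- unname(ct$statistic)
    new_test_result("tau", ct$estimate, NA_real_, ct$p.value, n, z = z)
  } else {
    new_test_result("rs", ct$estimate, NA_real_, ct$p.value, n)
  }
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' @param values numeric response.
#' @param groups group labels (>= 2 groups, each with n >= 2).
#' @return A `morpho_test` with the Welch F, fractional df (numerator,
#'   denominator) and p-value.
#' @export
welch_anova <- function(values, groups) {
  g <- droplevels(as.factor(groups))
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stop("Welch ANOVA needs >= 2 groups with n >= 2 each")
  ow <- oneway.test(values ~ g, var.equal = FALSE)
  new_test_result("Welch-F", ow$statistic, unname(ow$parameter),
                  ow$p.value, as.vector(table(g)))
}

#' Mann-Whitney U test
#'
#' Reports U in the smaller-of-the-two convention (`min(U1, U2)`) together
#' with the tie-corrected normal approximation z (continuity-corrected) and
#' the two-sided p-value.
#'
#' @param a,b numeric samples.
#' @return A `morpho_test` with `value` (U), `z`, `p_value`.
#' @export
mann_whitney <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1L || n2 < 1L) stop("empty group")
  r <- rank(c(a, b))
  R1 <- sum(r[seq_len(n1)])
  U1 <- n1 * n2 + n1 * (n1 + 1) / 2 - R1
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  n <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  mu <- n1 * n2 / 2
  z <- if (sigma2 <= 0) 0 else (U - mu + 0.5) / sqrt(sigma2)
  # z is measured from the smaller U, hence always <= 0 up to the correction
  p <- if (sigma2 <= 0) 1 else min(1, 2 * pnorm(-abs((U - mu + 0.5) / sqrt(sigma2))))
  new_test_result("U", U, NA_real_, p, c(n1, n2), z = z, U1 = U1, U2 = U2)
}

#' Two-sample or paired t test
#'
#' Thin wrapper around [stats::t.test()] returning the package's common test
#' container (Welch df for the unpaired case).
#'
#' @param a,b numeric samples (equal length if `paired`).
#' @param paired paired test (default `FALSE`).
#' @return A `morpho_test` with `value` (t), `df`, `p_value`, `estimate`,
#'   `conf_int`.
#' @export
t_test <- function(a, b, paired = FALSE) {
  if (!length(a) || !length(b)) stop("empty group")
  tt <- t.test(a, b, paired = paired)
  new_test_result("t", tt$statistic, unname(tt$parameter), tt$p.value,
                  if (paired) length(a) else c(length(a), length(b)),
                  estimate = unname(tt$estimate)[1L],
                  conf_int = unname(tt$conf.int))
}

#' Determinate-growth check
#'
#' Compares shell heights of the same individuals at two time points
#' (default: paired t test on the height change, matching specimens by id).
#' Determinate growth predicts no change once the apertural lip is complete.
#'
#' @param heights_t0,heights_t1 named numeric vectors (names = specimen ids)
#'   or plain vectors of equal length in matching order.
#' @param paired paired test (default `TRUE`).
#' @return A `morpho_test`; `estimate` is the mean height change (t1 - t0)
#'   with its confidence interval in `conf_int`.
#' @export
growth_check <- function(heights_t0, heights_t1, paired = TRUE) {
  if (!is.null(names(heights_t0)) && !is.null(names(heights_t1))) {
    common <- intersect(names(heights_t0), names(heights_t1))
    if (length(common) != length(heights_t0) ||
        length(common) != length(heights_t1))
      stop("pairing error: specimen ids do not match between time points")
    heights_t1 <- heights_t1[names(heights_t0)]
  } else if (paired && length(heights_t0) != length(heights_t1)) {
    stop("pairing error: unequal lengths without specimen ids")
  }
  if (paired && sd(heights_t1 - heights_t0) == 0) {
    # degenerate but well-defined: uniform (possibly zero) change
    delta <- mean(heights_t1 - heights_t0)
    return(new_test_result("t", if (delta == 0) 0 else sign(delta) * Inf,
                           length(heights_t0) - 1L,
                           if (delta == 0) 1 else 0, length(heights_t0),
                           estimate = delta, conf_int = c(delta, delta)))
  }
  out <- t_test(heights_t1, heights_t0, paired = paired)
  out$statistic <- "t"
  out
}

#' Greedy collinearity screen on Kendall's tau
#'
#' Flags every pair of numeric columns with `|tau| >= threshold` and drops
#' one member per flagged pair: the configured victim when a `drop_list` is
#' supplied (e.g. salinity in favour of conductivity, longitude in favour of
#' latitude), otherwise the later column in table order.
#'
#' @param variables data frame of numeric columns (n >= 2 columns).
#' @param threshold_tau absolute tau at or above which a pair is flagged
#'   (in (0, 1]; default 0.38, the weakest pair dropped in this workflow).
#' @param drop_list optional named character vector `c(victim = keeper, ...)`
#'   honoured verbatim for flagged pairs.
#' @return List with `retained` (column names), `dropped` (data frame:
#'   `dropped`, `kept`, `tau`).
#' @export
screen_collinear <- function(variables, threshold_tau = 0.38,
                             drop_list = NULL) {
  if (threshold_tau <= 0 || threshold_tau > 1)
    stop("threshold_tau must be in (0, 1]")
  vars <- as.data.frame(variables)
  num <- vapply(vars, is.numeric, logical(1))
  vars <- vars[num]
  if (ncol(vars) < 2L) stop("need at least 2 numeric columns")
  nm <- names(vars)
  retained <- nm
  dropped <- data.frame(dropped = character(), kept = character(),
                        tau = numeric())
  for (i in seq_along(nm)[-length(nm)]) for (j in seq((i + 1L), length(nm))) {
    a <- nm[i]; b <- nm[j]
    if (!(a %in% retained) || !(b %in% retained)) next
    tau <- suppressWarnings(cor(vars[[a]], vars[[b]], method = "kendall",
                                use = "pairwise.complete.obs"))
    if (is.na(tau) || abs(tau) < threshold_tau) next
    victim <- b
    if (!is.null(drop_list)) {
      if (a %in% names(drop_list) && drop_list[[a]] == b) victim <- a
      else if (b %in% names(drop_list) && drop_list[[b]] == a) victim <- b
    }
    keeper <- setdiff(c(a, b), victim)
    retained <- setdiff(retained, victim)
    dropped <- rbind(dropped,
                     data.frame(dropped = victim, kept = keeper, tau = tau))
  }
  list(retained = retained, dropped = dropped)
}
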