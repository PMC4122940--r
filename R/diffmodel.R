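# Interaction model linking within-cell-type paralog methylation
# divergence to a site's methylation level and its change on
# differentiation, plus equal-count binned summaries.

#' Fit the paralog-divergence interaction model
#'
#' Ordinary least squares of the paralog methylation difference `y` on the
#' site's methylation level in the base cell type (`x1`), the signed
#' change in methylation following differentiation (`x2`), and their
#' interaction:
#' \deqn{Y_i = \beta_0 + \beta_1 X_{i1} + \beta_2 X_{i2} + \beta_3 X_{i1} X_{i2} + \epsilon_i.}
#'
#' @param data Data frame with numeric columns `x1`, `x2`, `y`; incomplete
#'   rows are dropped.
#' @param min_n Minimum number of complete rows (default 10, exclusive).
#' @return List with `coefficients` (beta0..beta3), `std_errors`,
#'   `p_values`, `r_squared`, `n` and the underlying `fit`.
#' @export
fit_interaction_model <- function(data, min_n = 10) {
  stopifnot(all(c("x1", "x2", "y") %in% names(data)))
  data <- data[complete.cases(data[, c("x1", "x2", "y")]), , drop = FALSE]
  if (nrow(data) <= min_n) stop("need more than ", min_n, " complete rows")
  for (col in c("x1", "x2")) {
    if (sd(data[[col]]) == 0) {
      stop("explanatory variable '", col, "' is constant; model is rank deficient")
    }
  }
  fit <- lm(y ~ x1 * x2, data = data)
  sm <- summary(fit)
  cf <- sm$coefficients
  nm <- c("beta0", "beta1", "beta2", "beta3")
  list(
    coefficients = setNames(cf[, 1], nm),
    std_errors = setNames(cf[, 2], nm),
    p_values = setNames(cf[, 4], nm),
    r_squared = sm$r.squared,
    n = nrow(data),
    fit = fit
  )
}

# equal-count bin assignment: rank-then-split with stable ordering
equal_count_bins <- function(x, k) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * k / length(x)))
}

#' Binned summary of paralog divergence
#'
#' Groups sites by base-cell-type methylation level and by methylation
#' change on differentiation, using equal-count bins per axis (cutoffs
#' chosen so each category holds approximately the same number of sites;
#' ties broken by stable ordering), and reports the mean paralog
#' divergence per cell.
#'
#' @param data Data frame with `x1`, `x2`, `y`.
#' @param n_level_bins Number of bins on the methylation-level axis.
#' @param n_change_bins Number of bins on the methylation-change axis.
#' @return Data frame with `level_bin`, `change_bin`, `n`, `mean_y` (NA
#'   for empty cells); bin edge ranges are attached as attributes
#'   `level_edges` and `change_edges`.
#' @export
binned_divergence_summary <- function(data, n_level_bins = 5, n_change_bins = 4) {
  n <- nrow(data)
  if (n < n_level_bins || n < n_change_bins) {
    stop("fewer rows than requested bins")
  }
  lb <- equal_count_bins(data$x1, n_level_bins)
  cb <- equal_count_bins(data$x2, n_change_bins)
  grid <- expand.grid(level_bin = seq_len(n_level_bins),
                      change_bin = seq_len(n_change_bins))
  grid$n <- 0L
  grid$mean_y <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sel <- lb == grid$level_bin[i] & cb == grid$change_bin[i]
    grid$n[i] <- sum(sel)
    if (any(sel)) grid$mean_y[i] <- mean(data$y[sel])
  }
  attr(grid, "level_edges") <- tapply(data$x1, lb, range)
  attr(grid, "change_edges") <- tapply(data$x2, cb, range)
  grid
}
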