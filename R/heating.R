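# Newtonian heating of model eggs on nest materials. Lab protocol: inner egg
# temperature logged every 15 s for 60 min under an IR lamp; the shifted
# series y = T - T_f follows y = a * exp(b * t) with a = T_i - T_f (< 0 for
# heating), b = -1/Tc. Tc is the characteristic heating time: the time at
# which 63.2% (1 - 1/e) of the total temperature change is complete.

#' Construct a heating time-temperature series
#'
#' @param t seconds from start, strictly increasing.
#' @param T_c temperature in degrees Celsius.
#' @param material material label, e.g. "white pebbles".
#' @param replicate replicate identifier.
#' @return an object of class `heating_series` (data frame with columns
#'   `t`, `T` plus attributes).
#' @export
heating_series <- function(t, T_c, material = NA_character_, replicate = NA) {
  stopifnot(length(t) == length(T_c), all(is.finite(t)), all(is.finite(T_c)))
  if (is.unsorted(t, strictly = TRUE)) stop("t must be strictly increasing")
  structure(data.frame(t = t, T = T_c),
            material = material, replicate = replicate,
            class = c("heating_series", "data.frame"))
}

#' Fit the Newtonian heating model to a series
#'
#' Sets `T_f` to the temperature reached at the end of the run (mean of the
#' last `tail_k` records, so a single noisy sample does not anchor the whole
#' fit), shifts the series to `y = T - T_f`, and fits `y = a * exp(b * t)`
#' by nonlinear least squares (Levenberg-Marquardt). Start values are
#' deterministic: `a0 = T[1] - T_f`; `b0` from a log-linear regression of
#' `log|y|` on `t` over the first half of the series. Returns the
#' characteristic heating time `Tc = -1/b` and the coefficient of
#' determination of the fit on the shifted data.
#'
#' @param series a `heating_series` (or data frame with `t`, `T`), at least
#'   10 samples spanning more than 0.5 degrees C.
#' @param tail_k records averaged for `T_f`, default 5; `tail_k = 1` uses
#'   the bare final record.
#' @return an object of class `heating_fit`: list with `T_i`, `T_f`, `a`,
#'   `b`, `Tc`, `r2`, `n`.
#' @export
fit_heating <- function(series, tail_k = 5) {
  t <- series$t; temp <- series$T
  if (length(t) < 10) stop("need at least 10 samples to fit")
  if (diff(range(temp)) <= 0.5) stop("temperature range too small to fit")
  T_f <- summarize_final_temperature(series, k = min(tail_k, length(temp)))
  y <- temp - T_f
  a0 <- y[1]
  first <- seq_len(max(3L, floor(length(t) / 2)))
  ok <- first[abs(y[first]) > 1e-12]
  if (length(ok) < 2) stop("degenerate series: shifted values vanish early")
  b0 <- unname(coef(stats::lm(log(abs(y[ok])) ~ t[ok]))[2])
  if (!is.finite(b0) || b0 >= 0) b0 <- -1 / max(t[length(t)] / 5, 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(b * t), start = list(a = a0, b = b0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("heating fit did not converge: ",
                             conditionMessage(e)))
  cf <- coef(fit)
  if (cf[["b"]] >= 0)
    stop("not a heating curve: fitted rate b = ", signif(cf[["b"]], 3), " >= 0")
  res <- y - fitted(fit)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  structure(list(T_i = temp[1], T_f = T_f, a = cf[["a"]], b = cf[["b"]],
                 Tc = -1 / cf[["b"]], r2 = r2, n = length(t),
                 material = attr(series, "material"),
                 replicate = attr(series, "replicate")),
            class = "heating_fit")
}

#' Characteristic-time fraction
#'
#' The fraction of the total temperature change completed at `t = Tc` under
#' the exponential model: `100 * (1 - exp(-1))`.
#'
#' @param rounded round to one decimal (default), giving the conventional
#'   63.2.
#' @return percentage.
#' @export
characteristic_fraction <- function(rounded = TRUE) {
  f <- 100 * (1 - exp(-1))
  if (rounded) round(f, 1) else f
}

#' Final temperature of a field series
#'
#' Mean of the last `k` temperature records — the field-protocol summary used
#' when heating curves cannot be fitted (e.g. convection-dominated twigs).
#'
#' @param series a `heating_series` or data frame with `T`.
#' @param k number of trailing records to average, default 5.
#' @return mean temperature, degrees C.
#' @export
summarize_final_temperature <- function(series, k = 5) {
  if (k <= 0) stop("k must be positive")
  temp <- series$T
  if (k > length(temp)) stop("k exceeds series length")
  mean(temp[seq(length(temp) - k + 1, length(temp))])
}

#' Crop a field series to the protocol window
#'
#' @param series a `heating_series`.
#' @param t_max maximum retained time, s (field protocol: 1111 s).
#' @return cropped `heating_series`.
#' @export
crop_series <- function(series, t_max = 1111) {
  keep <- series$t <= t_max
  heating_series(series$t[keep], series$T[keep],
                 material = attr(series, "material"),
                 replicate = attr(series, "replicate"))
}

#' Spearman correlation between material reflectance and temperature
#'
#' Rank correlation (exact p-value for small n, average ranks on ties)
#' between total reflectance and the final temperature reached in the field.
#'
#' @param summaries data frame with columns `reflectance` and `T_final`
#'   (one row per material).
#' @return list with `rs` (Spearman rho), `p` (two-sided), `n`.
#' @export
reflectance_temperature_correlation <- function(summaries) {
  stopifnot(all(c("reflectance", "T_final") %in% names(summaries)))
  n <- nrow(summaries)
  if (n < 4) stop("need at least 4 materials")
  ct <- suppressWarnings(
    stats::cor.test(summaries$reflectance, summaries$T_final,
                    method = "spearman", exact = n <= 8))
  list(rs = unname(ct$estimate), p = ct$p.value, n = n)
}
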