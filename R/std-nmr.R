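#' Fit an STD NMR build-up curve to the mono-exponential model
#'
#' Saturation transfer build-up is modelled as
#' `y = a * (1 - exp(-b * t))` with plateau `a > 0` and rate `b > 0`
#' (1/s); the binding-epitope quantity is the initial slope `a * b`,
#' the STD growth rate at zero saturation time. Unweighted least squares
#' with multi-start initialisation (`a0 = max(y)`, `b0` from the first two
#' points, plus fallback starts) via Levenberg-Marquardt.
#'
#' @param times Saturation times in s, strictly increasing, length >= 3.
#' @param intensities STD intensities (fraction or %) at `times`.
#' @param proton_id Label carried through to the epitope map.
#' @return Object of class `std_fit`: list with `proton_id`, `a`, `b`,
#'   `initial_slope` (= `a*b`), `fitted`, `residuals`, `converged`, and
#'   standard errors `se_a`, `se_b` when estimable.
#' @examples
#' t <- c(0.5, 1, 2, 3, 4, 5)
#' f <- fit_buildup(t, 2 * (1 - exp(-0.5 * t)))
#' f$initial_slope  # 1.0
#' @export
fit_buildup <- function(times, intensities, proton_id = "H") {
  stopifnot(length(times) == length(intensities), length(times) >= 3,
            all(diff(times) > 0), all(times > 0), all(is.finite(intensities)))
  y <- as.numeric(intensities)
  x <- as.numeric(times)
  if (all(y == 0)) stop("degenerate curve: all intensities zero")

  a0 <- max(y)
  b0 <- if (a0 > 0 && y[1] > 0 && y[1] < a0)
    max(-log(1 - y[1] / a0) / x[1], 1e-3) else 0.5
  starts <- list(c(a = a0, b = b0), c(a = a0, b = 0.1),
                 c(a = a0, b = 1), c(a = 2 * a0, b = 0.25))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * (1 - exp(-b * x)),
                        start = as.list(s),
                        lower = c(a = 1e-12, b = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop(sprintf("build-up fit failed to converge for proton '%s'", proton_id))
  cf <- coef(best$fit)
  se <- tryCatch(sqrt(diag(vcov(best$fit))), error = function(e) c(NA, NA))
  flagged <- cf[["a"]] <= 1e-10 || cf[["b"]] <= 1e-10
  structure(list(
    proton_id = proton_id,
    a = cf[["a"]], b = cf[["b"]],
    initial_slope = if (flagged) NA_real_ else cf[["a"]] * cf[["b"]],
    fitted = fitted(best$fit), residuals = residuals(best$fit),
    converged = TRUE, flagged_nonpositive = flagged,
    se_a = se[1], se_b = se[2],
    times = x, intensities = y
  ), class = "std_fit")
}

#' @export
print.std_fit <- function(x, ...) {
  cat(sprintf("std_fit %s: a = %.4g, b = %.4g /s, initial slope a*b = %.4g\n",
              x$proton_id, x$a, x$b, x$initial_slope))
  invisible(x)
}

# Fig.-5-style bin edges on the normalised percentage scale
.epitope_bin <- function(pct) {
  if (pct > 100) "over100"
  else if (pct > 50) "red"
  else if (pct >= 25) "yellow"
  else "blue"
}

#' Binding-epitope map from fitted build-up curves
#'
#' Normalises every proton's initial slope to the reference proton (H7 of
#' the sialic acid ring by convention), which is assigned exactly 100%.
#' Bins follow the standard display convention: blue 0-24%, yellow 25-50%,
#' red 51-100%, `over100` above 100%.
#'
#' @param fits List of `std_fit` objects (see [fit_buildup]), or a
#'   data.frame with columns `proton`, `time_s`, `std_pct` which is fitted
#'   per proton first.
#' @param reference Reference proton id (default `"H7"`).
#' @param ligand_id Ligand label.
#' @return Object of class `epitope_map`: data.frame with `proton`,
#'   `a`, `b`, `initial_slope`, `normalized_pct`, `bin`.
#' @export
epitope_map <- function(fits, reference = "H7", ligand_id = "ligand") {
  if (is.data.frame(fits)) {
    stopifnot(all(c("proton", "time_s", "std_pct") %in% names(fits)))
    fits <- lapply(split(fits, fits$proton), function(d)
      fit_buildup(d$time_s, d$std_pct, proton_id = d$proton[1]))
  }
  ids <- vapply(fits, `[[`, "", "proton_id")
  names(fits) <- ids
  if (!reference %in% ids)
    stop(sprintf("reference proton unavailable: '%s' not fitted", reference))
  ref_slope <- fits[[reference]]$initial_slope
  if (!is.finite(ref_slope) || ref_slope <= 0)
    stop("reference proton unavailable: fit did not yield a positive slope")
  rows <- lapply(fits, function(f) {
    slope <- f$initial_slope
    pct <- if (f$proton_id == reference) 100 else 100 * slope / ref_slope
    data.frame(proton = f$proton_id, a = f$a, b = f$b,
               initial_slope = slope, normalized_pct = pct,
               bin = if (is.finite(pct)) .epitope_bin(pct) else NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ligand_id") <- ligand_id
  attr(out, "reference") <- reference
  class(out) <- c("epitope_map", "data.frame")
  out
}
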