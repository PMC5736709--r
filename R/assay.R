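#' Rank-normalise a glycan microarray table
#'
#' Per glycan: mean and sample SD over replicate RFUs, then
#' `rank_pct = 100 * mean / max(mean)` so the strongest binder is exactly
#' 100 and all ranks are scale-invariant.
#'
#' @param table Data.frame with columns `glycan_id` and `rfu` (long form,
#'   one row per replicate), or a named list of replicate vectors.
#' @return Data.frame with `glycan_id`, `n`, `mean_rfu`, `sd_rfu`,
#'   `rank_pct`, sorted by decreasing rank.
#' @examples
#' rank_glycan_array(data.frame(glycan_id = rep(c("g1", "g2"), each = 2),
#'                              rfu = c(500, 500, 250, 250)))
#' @export
rank_glycan_array <- function(table) {
  if (is.list(table) && !is.data.frame(table)) {
    table <- data.frame(
      glycan_id = rep(names(table), lengths(table)),
      rfu = unlist(table, use.names = FALSE))
  }
  stopifnot(all(c("glycan_id", "rfu") %in% names(table)), nrow(table) >= 1)
  sp <- split(table$rfu, table$glycan_id)
  out <- data.frame(
    glycan_id = names(sp),
    n = lengths(sp),
    mean_rfu = vapply(sp, mean, numeric(1)),
    sd_rfu = vapply(sp, function(x) if (length(x) > 1) sd(x) else 0,
                    numeric(1)))
  mx <- max(out$mean_rfu)
  if (mx <= 0) stop("no signal: all glycan means are zero or negative")
  out$rank_pct <- 100 * out$mean_rfu / mx
  out <- out[order(-out$rank_pct, out$glycan_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Area-weighted sialylation fraction from an assigned-peak table
#'
#' Sum of areas of assigned sialylated mass peaks divided by the sum of
#' areas of all assigned O-glycan peaks.
#'
#' @param peaks Data.frame with columns `area` (>= 0), `sialylated`
#'   (logical) and optionally `assigned` (logical, default all TRUE).
#' @return List with `fraction` in `[0, 1]` and `percent`.
#' @export
sialylation_fraction <- function(peaks) {
  stopifnot(all(c("area", "sialylated") %in% names(peaks)))
  if (is.null(peaks$assigned)) peaks$assigned <- TRUE
  stopifnot(all(peaks$area >= 0))
  p <- peaks[peaks$assigned, , drop = FALSE]
  tot <- sum(p$area)
  if (tot <= 0) stop("zero assigned peak area")
  f <- sum(p$area[p$sialylated]) / tot
  list(fraction = f, percent = 100 * f)
}

#' Normalise ELISA readings to a reference well
#'
#' Blank-subtracted readings scaled so that the reference (LS174T MUC2 in
#' the mucin-binding assay) is exactly 100%:
#' `(reading - blank) / (reference - blank) * 100`.
#'
#' @param readings Named numeric vector of A450 readings.
#' @param blank Blank (no-protein) reading subtracted from every well.
#' @param reference_id Name of the reference well.
#' @return Named numeric vector of normalised percentages.
#' @export
normalize_elisa <- function(readings, blank, reference_id) {
  stopifnot(!is.null(names(readings)), reference_id %in% names(readings))
  ref <- readings[[reference_id]]
  if (ref <= blank) stop("invalid reference: reading not above blank")
  (readings - blank) / (ref - blank) * 100
}

#' Squared Pearson correlation between two assay variables
#'
#' @param x,y Numeric vectors of equal length >= 3; `x` must not be
#'   constant.
#' @return r^2 in `[0, 1]`.
#' @export
linear_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (var(x) == 0) stop("constant x: correlation undefined")
  cor(x, y)^2
}

#' Quantify an analyte against an internal standard
#'
#' `analyte = standard_conc * (analyte_peak / standard_peak) /
#' response_factor`; with a response factor of 1 (default) equal peaks give
#' the standard's concentration.
#'
#' @param analyte_peak,standard_peak Peak areas (or heights), same units.
#' @param standard_conc Concentration of the internal standard.
#' @param response_factor Relative detector response (default 1).
#' @return Analyte concentration in the standard's units.
#' @export
internal_standard_quant <- function(analyte_peak, standard_peak,
                                    standard_conc, response_factor = 1) {
  if (standard_peak <= 0) stop("zero standard peak")
  standard_conc * (analyte_peak / standard_peak) / response_factor
}
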