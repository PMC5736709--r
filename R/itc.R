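#' Construct an ITC titration object
#'
#' Holds the injection schedule and measured heats for a single isothermal
#' titration, with the cell/syringe concentrations needed by the
#' single-site model. Units follow instrument convention: cell volume in
#' ul, cell (macromolecule) concentration in uM, syringe (ligand)
#' concentration in mM, injection volumes in ul, heats in uJ.
#'
#' @param volumes_ul Injection volumes (ul).
#' @param heats_uJ Measured injection heats (uJ).
#' @param cell_conc_uM Cell protein concentration M0 (uM).
#' @param syringe_conc_mM Syringe ligand concentration X0 (mM).
#' @param cell_volume_ul Calorimeter cell volume V0 (ul), default 200.
#' @param control_heats_uJ Optional buffer-control heats, subtracted before
#'   fitting.
#' @param temperature_K Temperature (K), default 298.15.
#' @return Object of class `itc_titration`.
#' @export
itc_titration <- function(volumes_ul, heats_uJ, cell_conc_uM,
                          syringe_conc_mM, cell_volume_ul = 200,
                          control_heats_uJ = NULL, temperature_K = 298.15) {
  stopifnot(length(volumes_ul) == length(heats_uJ), all(volumes_ul > 0),
            cell_conc_uM > 0, syringe_conc_mM > 0, cell_volume_ul > 0)
  if (!is.null(control_heats_uJ))
    stopifnot(length(control_heats_uJ) == length(heats_uJ))
  structure(list(volumes_ul = as.numeric(volumes_ul),
                 heats_uJ = as.numeric(heats_uJ),
                 control_heats_uJ = control_heats_uJ,
                 cell_conc_uM = cell_conc_uM,
                 syringe_conc_mM = syringe_conc_mM,
                 cell_volume_ul = cell_volume_ul,
                 temperature_K = temperature_K),
            class = "itc_titration")
}

#' @export
print.itc_titration <- function(x, ...) {
  cat(sprintf(
    "itc_titration: %d injections, cell %.3g uM / syringe %.3g mM, V0 %.3g ul\n",
    length(x$volumes_ul), x$cell_conc_uM, x$syringe_conc_mM,
    x$cell_volume_ul))
  invisible(x)
}

#' Per-injection model heats for a single-site binding isotherm
#'
#' Implements the standard overfill-cell displacement convention: after a
#' cumulative injected volume `dV`, total cell concentrations are
#' `Mt = M0 (1 - dV/2V0)/(1 + dV/2V0)` and `Xt = X0 (dV/V0)/(1 + dV/2V0)`.
#' The bound-ligand concentration follows from the single-site quadratic
#' (closed form); the cell heat content is `Q = V0 * dH * [bound]`, and the
#' i-th injection heat is `Q_i - Q_{i-1} + (v_i/V0)(Q_i + Q_{i-1})/2`
#' (heat carried by the displaced volume) plus `baseline_uJ`.
#'
#' @param kd_mM Dissociation constant (mM), > 0.
#' @param dH_kJmol Binding enthalpy (kJ/mol).
#' @param titration An [itc_titration] (heats are ignored here) or a vector
#'   of injection volumes in ul combined with the `cell_*`/`syringe_*`
#'   arguments.
#' @param n_sites Stoichiometry N (default 1).
#' @param baseline_uJ Constant per-injection offset (uJ), default 0.
#' @param cell_conc_uM,syringe_conc_mM,cell_volume_ul Used when `titration`
#'   is a plain volume vector.
#' @return Numeric vector of per-injection heats (uJ).
#' @export
itc_forward <- function(kd_mM, dH_kJmol, titration, n_sites = 1,
                        baseline_uJ = 0, cell_conc_uM = NULL,
                        syringe_conc_mM = NULL, cell_volume_ul = 200) {
  if (inherits(titration, "itc_titration")) {
    v <- titration$volumes_ul
    M0 <- titration$cell_conc_uM * 1e-6
    X0 <- titration$syringe_conc_mM * 1e-3
    V0 <- titration$cell_volume_ul * 1e-6       # litres
  } else {
    v <- as.numeric(titration)
    stopifnot(!is.null(cell_conc_uM), !is.null(syringe_conc_mM))
    M0 <- cell_conc_uM * 1e-6
    X0 <- syringe_conc_mM * 1e-3
    V0 <- cell_volume_ul * 1e-6
  }
  stopifnot(kd_mM > 0, all(v > 0), M0 > 0, X0 > 0)
  Kd <- kd_mM * 1e-3
  dH <- dH_kJmol * 1e3                          # J/mol
  vL <- v * 1e-6
  dV <- cumsum(vL)
  f <- dV / (2 * V0)
  Mt <- M0 * (1 - f) / (1 + f)
  Xt <- X0 * (dV / V0) / (1 + f)
  if (any(Mt < 0) || any(Xt < 0)) stop("nonphysical concentrations")
  NM <- n_sites * Mt
  s <- NM + Xt + Kd
  bound <- (s - sqrt(s^2 - 4 * NM * Xt)) / 2    # [bound ligand], M
  Q <- V0 * dH * bound                          # J
  Qprev <- c(0, Q[-length(Q)])
  q <- Q - Qprev + (vL / V0) * (Q + Qprev) / 2
  q * 1e6 + baseline_uJ
}

#' Fit a single-site binding isotherm to an ITC titration
#'
#' Nonlinear least squares over `(log Kd, dH, baseline)` with the
#' stoichiometry fixed at `n_sites` (default 1.0, the crystallographic
#' stoichiometry); set `fix_n = FALSE` to also free N. Buffer-control heats
#' are subtracted first when present. Fitting is done in log-Kd space for
#' conditioning; Kd is reported in mM. The Wiseman `c = M0 * N / Kd` is
#' computed and fits with `c < 0.01` are flagged
#' `"unreliable (low c-value)"`: such titrations constrain only the
#' Kd/dH ratio weakly and the Kd is an estimate.
#'
#' @param titration An [itc_titration].
#' @param n_sites Fixed stoichiometry (default 1.0).
#' @param fix_n Keep N fixed (default TRUE).
#' @param fit_baseline Fit the constant per-injection offset (default TRUE).
#' @param drop_first Discard the first injection before fitting
#'   (default FALSE).
#' @return Object of class `binding_fit` with `kd_mM`, `dH_kJmol`,
#'   `n_sites`, `baseline_uJ`, standard errors, `c_value`, `flags`,
#'   `dG_kJmol`, `minus_TdS_kJmol`, `fitted_uJ`, `residuals_uJ`.
#' @export
fit_isotherm <- function(titration, n_sites = 1, fix_n = TRUE,
                         fit_baseline = TRUE, drop_first = FALSE) {
  stopifnot(inherits(titration, "itc_titration"))
  q <- titration$heats_uJ
  if (!is.null(titration$control_heats_uJ))
    q <- q - titration$control_heats_uJ
  v <- titration$volumes_ul
  keep <- if (drop_first) -1L else seq_along(q)
  qk <- q[keep]
  if (length(qk) < 8L) stop("need at least 8 informative injections")
  if (all(abs(qk) < 1e-9)) {
    warning("no signal after control subtraction; Kd unidentifiable")
    return(structure(list(kd_mM = NA_real_, dH_kJmol = 0,
                          n_sites = n_sites, baseline_uJ = 0,
                          se_kd_mM = NA_real_, se_dH_kJmol = NA_real_,
                          c_value = NA_real_,
                          flags = "unidentifiable (zero signal)",
                          dG_kJmol = NA_real_, minus_TdS_kJmol = NA_real_,
                          fitted_uJ = rep(0, length(q)),
                          residuals_uJ = q,
                          temperature_K = titration$temperature_K),
                     class = "binding_fit"))
  }

  M0 <- titration$cell_conc_uM * 1e-6
  X0 <- titration$syringe_conc_mM * 1e-3
  V0 <- titration$cell_volume_ul * 1e-6
  # dH start: assume the first retained injection binds completely
  dh0 <- (qk[1] * 1e-6) / (X0 * v[keep][1] * 1e-6) / 1e3   # kJ/mol
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -10

  resid_fn <- function(par) {
    kd <- exp(par[["lkd"]])
    n <- if (fix_n) n_sites else exp(par[["ln"]])
    base <- if (fit_baseline) par[["base"]] else 0
    model <- itc_forward(kd, par[["dh"]], v, n_sites = n,
                         baseline_uJ = base,
                         cell_conc_uM = titration$cell_conc_uM,
                         syringe_conc_mM = titration$syringe_conc_mM,
                         cell_volume_ul = titration$cell_volume_ul)
    model[keep] - qk
  }
  starts <- lapply(c(0.05, 0.5, 5, 50), function(kd0) {
    p <- c(lkd = log(kd0), dh = dh0)
    if (fit_baseline) p <- c(p, base = 0)
    if (!fix_n) p <- c(p, ln = log(n_sites))
    p
  })
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(minpack.lm::nls.lm(
      par = p0, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("isotherm fit failed from all starts")
  fit <- best$fit
  par <- fit$par
  kd_mM <- exp(par[["lkd"]])
  dH <- par[["dh"]]
  n_fit <- if (fix_n) n_sites else exp(par[["ln"]])
  base <- if (fit_baseline) par[["base"]] else 0

  # standard errors from the Jacobian (delta method for Kd)
  se <- rep(NA_real_, length(par))
  cv <- tryCatch({
    dof <- max(length(qk) - length(par), 1L)
    s2 <- best$rss / dof
    J <- fit$hessian                 # J'J from nls.lm
    sqrt(diag(solve(J)) * s2)
  }, error = function(e) rep(NA_real_, length(par)))
  names(cv) <- names(par)
  se_kd <- unname(cv["lkd"]) * kd_mM       # d(Kd)/d(logKd) = Kd
  se_dh <- unname(cv["dh"])

  c_value <- (M0 * n_fit) / (kd_mM * 1e-3)
  flags <- character(0)
  if (is.finite(c_value) && c_value < 0.01)
    flags <- c(flags, "unreliable (low c-value)")

  model_q <- itc_forward(kd_mM, dH, v, n_sites = n_fit, baseline_uJ = base,
                         cell_conc_uM = titration$cell_conc_uM,
                         syringe_conc_mM = titration$syringe_conc_mM,
                         cell_volume_ul = titration$cell_volume_ul)
  th <- thermo_summary(kd_mM, dH, titration$temperature_K)
  structure(list(kd_mM = kd_mM, dH_kJmol = dH, n_sites = n_fit,
                 baseline_uJ = base, se_kd_mM = se_kd, se_dH_kJmol = se_dh,
                 c_value = c_value, flags = flags,
                 dG_kJmol = th[["dG_kJmol"]],
                 minus_TdS_kJmol = th[["minus_TdS_kJmol"]],
                 fitted_uJ = model_q, residuals_uJ = q - model_q,
                 temperature_K = titration$temperature_K),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("binding_fit: Kd = %.4g mM (c = %.3g), dH = %.4g kJ/mol\n",
              x$kd_mM, x$c_value, x$dH_kJmol))
  cat(sprintf("  dG = %.4g kJ/mol, -TdS = %.4g kJ/mol at %.2f K\n",
              x$dG_kJmol, x$minus_TdS_kJmol, x$temperature_K))
  if (length(x$flags) > 0L) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Binding thermodynamics from Kd and dH
#'
#' `dG = R T ln(Kd in molar)` and `-TdS = dG - dH`; the identity
#' `dG = dH + (-TdS)` holds exactly as stored. An interaction with dH more
#' negative than dG is enthalpy-driven with unfavourable entropy
#' (`-TdS > 0`).
#'
#' @param kd_mM Dissociation constant (mM).
#' @param dH_kJmol Binding enthalpy (kJ/mol).
#' @param temperature_K Temperature (K), default 298.15.
#' @return Named vector with `dG_kJmol`, `dH_kJmol`, `minus_TdS_kJmol`.
#' @export
thermo_summary <- function(kd_mM, dH_kJmol, temperature_K = 298.15) {
  stopifnot(kd_mM > 0)
  R <- 8.31446261815324e-3                    # kJ/mol/K
  dG <- R * temperature_K * log(kd_mM * 1e-3)
  c(dG_kJmol = dG, dH_kJmol = dH_kJmol, minus_TdS_kJmol = dG - dH_kJmol)
}

#' Read an ITC titration from CSV
#'
#' Expects columns `injection`, `volume_ul`, `heat_uJ` and optionally
#' `control_heat_uJ`.
#'
#' @param path CSV file.
#' @param ... Passed to [itc_titration] (concentrations etc.).
#' @export
read_itc_csv <- function(path, ...) {
  d <- utils::read.csv(path)
  stopifnot(all(c("volume_ul", "heat_uJ") %in% names(d)))
  itc_titration(d$volume_ul, d$heat_uJ,
                control_heats_uJ = d$control_heat_uJ, ...)
}
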