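# One-binding-site analysis of isothermal titration calorimetry data:
# dilution correction, normalization per mole of injectant, the Wiseman
# total-heat isotherm, nonlinear least-squares fitting, and KD fold
# changes.
#
# Units are centralized here: cell/syringe concentrations in mol/L,
# volumes in litres, raw heats in microcalories, enthalpies in kcal/mol.

UCAL_PER_KCAL <- 1e9  # 1 kcal = 1e9 microcal

#' Construct an ITC titration series
#'
#' @param injectionVolumes Injection volumes in litres.
#' @param rawHeats Measured heats per injection, microcalories.
#' @param cellConc Protein concentration in the cell, mol/L.
#' @param syringeConc Ligand concentration in the syringe, mol/L.
#' @param cellVolume Active cell volume in litres (default 1.4 mL, the
#'   usual cell of the calorimeter class used for these titrations;
#'   override to match the instrument).
#' @param dilutionHeats Ligand-into-buffer dilution heats in
#'   microcalories: one value per injection, a single mean value, or
#'   omitted (no correction available).
#' @return A [TitrationSeries].
#' @export
titrationSeries <- function(injectionVolumes, rawHeats, cellConc,
                            syringeConc, cellVolume = 1.4e-3,
                            dilutionHeats = numeric()) {
  new("TitrationSeries", cellVolume = cellVolume, cellConc = cellConc,
      syringeConc = syringeConc,
      injectionVolumes = as.numeric(injectionVolumes),
      rawHeats = as.numeric(rawHeats),
      dilutionHeats = as.numeric(dilutionHeats))
}

#' Dilution-correct and normalize titration heats
#'
#' Subtracts the ligand-dilution heats from the raw injection heats and
#' normalizes by the moles of ligand injected, giving kcal per mole of
#' injectant.  The first injection (the conventional small pre-
#' injection) is retained in the output but flagged for exclusion from
#' fitting.
#'
#' @param series A [TitrationSeries].
#' @return A data.frame with columns `injection`, `molar_ratio`
#'   (total ligand over total protein in the cell), `ndh` (normalized
#'   heat, kcal/mol of injectant) and `use` (logical; `FALSE` for the
#'   first injection).  Attribute `"uncorrected"` is `TRUE` when no
#'   dilution heats were available.
#' @export
correctAndNormalize <- function(series) {
  stopifnot(is(series, "TitrationSeries"))
  v <- series@injectionVolumes
  n <- length(v)
  dil <- series@dilutionHeats
  uncorrected <- FALSE
  if (length(dil) == 0L) {
    warning("no dilution heats supplied; proceeding without correction")
    dil <- numeric(n)
    uncorrected <- TRUE
  } else if (length(dil) == 1L) {
    dil <- rep(dil, n)
  }
  molesInj <- series@syringeConc * v
  ndh <- (series@rawHeats - dil) / (molesInj * UCAL_PER_KCAL)
  conc <- displaced_concentrations(series)
  out <- data.frame(injection = seq_len(n),
                    molar_ratio = conc$Xt / conc$Mt, ndh = ndh,
                    use = seq_len(n) > 1L)
  attr(out, "uncorrected") <- uncorrected
  out
}

# Displaced-cell concentrations after each injection (perfusion model):
# cumulative injected volume dV displaces cell content.
displaced_concentrations <- function(series) {
  dV <- cumsum(series@injectionVolumes)
  V0 <- series@cellVolume
  list(Mt = series@cellConc * (1 - dV / (2 * V0)) / (1 + dV / (2 * V0)),
       Xt = series@syringeConc * (dV / V0) / (1 + dV / (2 * V0)),
       dV = dV)
}

# Wiseman one-site isotherm: per-injection heats in kcal per mole of
# injectant, for stoichiometry n, association constant Ka (1/M) and
# enthalpy dH (kcal/mol).
one_site_ndh <- function(series, n, Ka, dH) {
  cc <- displaced_concentrations(series)
  V0 <- series@cellVolume
  r <- cc$Xt / (n * cc$Mt)
  s <- 1 / (n * Ka * cc$Mt)
  b <- 1 + r + s
  Q <- (n * cc$Mt * dH * V0 / 2) * (b - sqrt(pmax(b^2 - 4 * r, 0)))
  Qprev <- c(0, head(Q, -1L))
  v <- series@injectionVolumes
  dQ <- Q - Qprev + (v / V0) * (Q + Qprev) / 2
  dQ / (series@syringeConc * v)   # kcal / mol injectant
}

#' Fit the one-binding-site model to a titration
#'
#' Least-squares fit of the single-site total-heat (Wiseman) isotherm to
#' the dilution-corrected, concentration-normalized heats, with the
#' first injection excluded.  Three deterministic starts (a c-heuristic,
#' an n = 1 start, and a weak-binding start) guard against local minima;
#' the best sum of squares wins.  Standard errors are asymptotic
#' (Jacobian-based).
#'
#' @param series A [TitrationSeries] with at least 5 usable injections.
#' @param init Optional named list with starting values `n`, `kd`
#'   (mol/L) and `dh` (kcal/mol), replacing the heuristic first start.
#' @param flatTol Peak-to-peak range of normalized heats (kcal/mol)
#'   below which the series is declared "no binding detectable"
#'   (default 0.1).
#' @return A [OneSiteFit].
#' @export
fitOneSite <- function(series, init = NULL, flatTol = 0.1) {
  norm <- suppressWarnings(correctAndNormalize(series))
  use <- which(norm$use)
  if (length(use) < 5L) stop("need at least 5 usable injections")
  y <- norm$ndh[use]
  empty <- new("OneSiteFit", kd = NA_real_, kdSE = NA_real_,
               dh = NA_real_, dhSE = NA_real_, n = NA_real_,
               nSE = NA_real_, residualNorm = NA_real_, converged = FALSE,
               status = "no-binding", normalizedHeats = norm$ndh,
               fitted = numeric(), usedInjections = as.integer(use))
  if (diff(range(y)) < flatTol) return(empty)

  model <- function(p) {
    m <- one_site_ndh(series, exp(p[1L]), exp(p[2L]), p[3L])[use]
    m[!is.finite(m)] <- 0
    m
  }
  resid_fun <- function(p) y - model(p)

  dh0 <- y[which.max(abs(y))]
  M0 <- series@cellConc
  # c-heuristic: molar ratio at half-amplitude approximates n; assume
  # moderate sigmoidicity (c ~ 10) for the Ka start
  half <- which(abs(y) <= abs(dh0) / 2)
  n0 <- if (length(half)) max(norm$molar_ratio[use][half[1L]], 0.2) else 1
  starts <- list(
    c(log(n0), log(10 / M0), dh0),
    c(log(1), log(100 / M0), dh0),
    c(log(1), log(1 / M0), dh0 * 2))
  if (!is.null(init))
    starts[[1L]] <- c(log(init$n), log(1 / init$kd), init$dh)

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) { empty@status <- "not-converged"; return(empty) }

  p <- best$par
  nhat <- exp(p[1L]); Ka <- exp(p[2L]); dh <- p[3L]
  dof <- max(length(y) - 3L, 1L)
  sigma2 <- best$deviance / dof
  se <- rep(NA_real_, 3L)
  vc <- tryCatch(sigma2 * solve(best$hessian), error = function(e) NULL)
  if (!is.null(vc)) se <- sqrt(pmax(diag(vc), 0))
  kdhat <- 1 / Ka
  converged <- best$info %in% 1:4 && is.finite(kdhat) && nhat > 0
  new("OneSiteFit",
      kd = kdhat, kdSE = se[2L] * kdhat,     # delta method on log Ka
      dh = dh, dhSE = se[3L],
      n = nhat, nSE = se[1L] * nhat,
      residualNorm = sqrt(best$deviance / length(y)),
      converged = converged,
      status = if (converged) "ok" else "not-converged",
      normalizedHeats = norm$ndh, fitted = model(p),
      usedInjections = as.integer(use))
}

#' KD fold change relative to a reference
#'
#' @param kdMutant,kdReference Dissociation constants (same units,
#'   both positive).
#' @return A [FoldChange]; `rounded` uses round-half-away-from-zero.
#' @examples
#' foldReduction(151e-6, 2.6e-6)  # rounded 58
#' @export
foldReduction <- function(kdMutant, kdReference) {
  if (kdMutant <= 0 || kdReference <= 0)
    stop("dissociation constants must be positive")
  ratio <- kdMutant / kdReference
  new("FoldChange", ratio = ratio,
      rounded = as.integer(sign(ratio) * floor(abs(ratio) + 0.5)))
}
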