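#' ITC injection schedule
#'
#' Describes a titration: a perfusion cell of volume `cell_volume_ul`
#' containing the macromolecule at `cell_conc`, titrated by syringe
#' injections of the ligand at `syringe_conc`.
#'
#' @param cell_conc macromolecule concentration in the cell (molar).
#' @param syringe_conc titrant concentration in the syringe (molar).
#' @param injection_volumes_ul vector of injection volumes (microliter).
#' @param cell_volume_ul active cell volume (microliter).
#' @param temperature_c temperature (Celsius).
#' @return Object of class `itc_schedule`.
#' @export
itc_schedule <- function(cell_conc, syringe_conc,
                         injection_volumes_ul = rep(1, 60),
                         cell_volume_ul = 340, temperature_c = 27) {
  stopifnot(cell_conc > 0, syringe_conc > 0, cell_volume_ul > 0,
            all(injection_volumes_ul > 0))
  structure(list(cell_conc = cell_conc, syringe_conc = syringe_conc,
                 injection_volumes_ul = injection_volumes_ul,
                 cell_volume_ul = cell_volume_ul,
                 temperature_c = temperature_c),
            class = "itc_schedule")
}

#' @export
print.itc_schedule <- function(x, ...) {
  cat(sprintf(
    "ITC schedule: %.0f ul cell at %.3g uM, %d injections (%.3g ul total) of %.3g uM titrant, %.1f C\n",
    x$cell_volume_ul, x$cell_conc * 1e6, length(x$injection_volumes_ul),
    sum(x$injection_volumes_ul), x$syringe_conc * 1e6, x$temperature_c))
  invisible(x)
}

# Total cell concentrations after each injection for a perfusion
# (constant-volume overfill) cell: injected volume displaces an equal
# volume of the pre-injection mixture, giving the standard instrument-style
# dilution factors in the cumulative injected volume v:
#   Mt = M0 (1 - v/2V0) / (1 + v/2V0),  Xt = X0 (v/V0) / (1 + v/2V0)
itc_concentrations <- function(schedule) {
  V0 <- schedule$cell_volume_ul
  v <- cumsum(schedule$injection_volumes_ul)
  f <- 1 + v / (2 * V0)
  list(Mt = schedule$cell_conc * (1 - v / (2 * V0)) / f,
       Xt = schedule$syringe_conc * (v / V0) / f)
}

# Bound-ligand concentration for one set of n identical independent sites:
# positive root of the single-site quadratic in the fraction of occupied
# sites Theta.
itc_theta <- function(Mt, Xt, n, KD) {
  r <- Xt / (n * Mt)
  k <- KD / (n * Mt)
  b <- 1 + r + k
  (b - sqrt(b^2 - 4 * r)) / 2
}

#' Simulate a one-set-of-sites ITC isotherm
#'
#' Cumulative heat after injection k is
#' \eqn{Q_k = n \Theta_k M_{t,k} \Delta H V_0}, with the bound fraction
#' \eqn{\Theta_k} solved from the single-site quadratic at the total
#' concentrations after the k-th injection. The per-injection heat includes
#' the displacement correction for the expelled volume
#' (\eqn{\Delta Q_k = Q_k - Q_{k-1} + (dV_k/V_0)(Q_k + Q_{k-1})/2}).
#' Optional Gaussian noise and a constant dilution-heat offset can be added
#' for robustness tests.
#'
#' @param schedule an [itc_schedule()].
#' @param n binding sites per cell macromolecule.
#' @param KD dissociation constant (molar).
#' @param dH binding enthalpy (J/mol of ligand bound; any sign).
#' @param noise_sd Gaussian noise SD on each injection heat (J).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @param dilution_offset constant heat added to every injection (J).
#' @return Object of class `itc_data`: the schedule plus a data.frame
#'   `injections` with `injection_index`, `injection_volume_ul`, `heat_J`,
#'   `molar_ratio` (Xt / Mt after the injection).
#' @export
simulate_itc <- function(schedule, n, KD, dH, noise_sd = 0, seed = 1L,
                         dilution_offset = 0) {
  stopifnot(inherits(schedule, "itc_schedule"), n > 0, KD > 0,
            noise_sd >= 0)
  V0_l <- schedule$cell_volume_ul * 1e-6
  cc <- itc_concentrations(schedule)
  theta <- itc_theta(cc$Mt, cc$Xt, n, KD)
  Q <- n * theta * cc$Mt * dH * V0_l
  Qprev <- c(0, Q[-length(Q)])
  dv <- schedule$injection_volumes_ul / schedule$cell_volume_ul
  heats <- Q - Qprev + dv * (Q + Qprev) / 2
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    heats <- heats + stats::rnorm(length(heats), 0, noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  }
  heats <- heats + dilution_offset
  itc_data(schedule, heats)
}

#' Construct ITC data from per-injection heats
#'
#' @param schedule an [itc_schedule()].
#' @param heats_J per-injection heats (J), one per injection.
#' @return Object of class `itc_data`.
#' @export
itc_data <- function(schedule, heats_J) {
  stopifnot(inherits(schedule, "itc_schedule"),
            length(heats_J) == length(schedule$injection_volumes_ul))
  cc <- itc_concentrations(schedule)
  structure(list(schedule = schedule,
                 injections = data.frame(
                   injection_index = seq_along(heats_J),
                   injection_volume_ul = schedule$injection_volumes_ul,
                   heat_J = heats_J,
                   molar_ratio = cc$Xt / cc$Mt)),
            class = "itc_data")
}

#' @export
print.itc_data <- function(x, ...) {
  print(x$schedule)
  h <- x$injections$heat_J
  cat(sprintf("  heats: first %.3g uJ, last %.3g uJ, total %.3g uJ\n",
              h[1] * 1e6, h[length(h)] * 1e6, sum(h) * 1e6))
  invisible(x)
}

#' Write / read ITC data as csv
#'
#' @param x an [itc_data()].
#' @param path output file.
#' @return `path` invisibly (`write`), an [itc_data()] (`read`).
#' @export
write_itc_data <- function(x, path) {
  stopifnot(inherits(x, "itc_data"))
  con <- file(path, "w")
  on.exit(close(con))
  s <- x$schedule
  writeLines(sprintf("# cell_volume_ul=%g cell_conc_M=%g syringe_conc_M=%g temperature_C=%g",
                     s$cell_volume_ul, s$cell_conc, s$syringe_conc,
                     s$temperature_c), con)
  utils::write.csv(x$injections[, c("injection_index",
                                    "injection_volume_ul", "heat_J")],
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_itc_data
#' @param schedule optional [itc_schedule()]; if omitted it is rebuilt from
#'   the header comment written by `write_itc_data`.
#' @export
read_itc_data <- function(path, schedule = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (is.null(schedule)) {
    hd <- grep("^#", lines, value = TRUE)[1]
    if (is.na(hd)) stop("no schedule header in ", path)
    toks <- strsplit(sub("^#\\s*", "", hd), "\\s+")[[1]]
    kv <- strsplit(toks, "=", fixed = TRUE)
    vals <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]),
                                   numeric(1)),
                            vapply(kv, `[`, "", 1))
    get1 <- function(k) unname(vals[[k]])
    df <- utils::read.csv(text = lines[!grepl("^#", lines)])
    schedule <- itc_schedule(cell_conc = get1("cell_conc_M"),
                             syringe_conc = get1("syringe_conc_M"),
                             injection_volumes_ul = df$injection_volume_ul,
                             cell_volume_ul = get1("cell_volume_ul"),
                             temperature_c = get1("temperature_C"))
  } else {
    df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  }
  itc_data(schedule, df$heat_J)
}

#' Fit the one-set-of-sites model to an ITC isotherm
#'
#' Nonlinear least squares (Levenberg-Marquardt, log-KD parametrisation)
#' for the stoichiometry `n`, dissociation constant `KD` and enthalpy `dH`
#' of the model in [simulate_itc()]. Initial values: `dH` from the
#' first-injection heat per mole injected, `n` from the molar ratio at
#' half-total heat, `KD = cell_conc / 100`.
#'
#' When the Wiseman parameter c = n * cell_conc / KD is very large the
#' isotherm is a near-step and carries little information about `KD`; the
#' fit then still converges on noiseless data but `KD` is flagged
#' low-precision (`c > 1000`).
#'
#' @param data an [itc_data()].
#' @param start optional named list overriding the initial values
#'   (`n`, `KD`, `dH`).
#' @return Object of class `itc_fit`: `n`, `KD` (molar), `dH` (J/mol),
#'   `se` (named vector from the fit covariance), `c_value`,
#'   `kd_low_precision`, `fitted`, `residuals`, `data`.
#' @export
fit_itc <- function(data, start = NULL) {
  stopifnot(inherits(data, "itc_data"))
  h <- data$injections$heat_J
  sched <- data$schedule
  if (length(h) < 6) stop("need >= 6 injections")
  tot <- sum(h)
  if (tot == 0 || max(abs(h)) == 0)
    stop("all-zero isotherm: parameters unidentifiable")
  # saturation check: an isotherm that never rolls off has no equivalence
  # point inside the data and neither n nor KD is identifiable
  tail_frac <- mean(abs(h[(length(h) - 2):length(h)])) / max(abs(h))
  if (tail_frac > 0.8)
    stop("isotherm without curvature: KD unidentifiable ",
         "(final heats are ", round(100 * tail_frac), "% of the maximum; ",
         "titration does not reach saturation)")

  V0_l <- sched$cell_volume_ul * 1e-6
  mol_inj1 <- sched$syringe_conc * sched$injection_volumes_ul[1] * 1e-6
  dH0 <- h[1] / mol_inj1
  ratio <- data$injections$molar_ratio
  cumQ <- cumsum(h)
  i_half <- which(abs(cumQ) >= abs(tot) / 2)[1]
  n0 <- max(ratio[i_half], 0.1)
  KD0 <- sched$cell_conc / 100
  if (!is.null(start)) {
    if (!is.null(start$n)) n0 <- start$n
    if (!is.null(start$KD)) KD0 <- start$KD
    if (!is.null(start$dH)) dH0 <- start$dH
  }

  model_heats <- function(n, KD, dH) {
    cc <- itc_concentrations(sched)
    theta <- itc_theta(cc$Mt, cc$Xt, n, KD)
    Q <- n * theta * cc$Mt * dH * V0_l
    Qprev <- c(0, Q[-length(Q)])
    dv <- sched$injection_volumes_ul / sched$cell_volume_ul
    Q - Qprev + dv * (Q + Qprev) / 2
  }
  df <- data.frame(h = h)
  fit <- minpack.lm::nlsLM(
    h ~ model_heats(n, exp(lkd), dH), data = df,
    start = list(n = n0, lkd = log(KD0), dH = dH0),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  cf <- stats::coef(fit)
  n_hat <- unname(cf["n"]); KD_hat <- exp(unname(cf["lkd"]))
  dH_hat <- unname(cf["dH"])
  se <- tryCatch({
    s <- summary(fit)$coefficients[, "Std. Error"]
    c(n = unname(s["n"]), KD = KD_hat * unname(s["lkd"]),
      dH = unname(s["dH"]))
  }, error = function(e) c(n = NA_real_, KD = NA_real_, dH = NA_real_))
  c_value <- n_hat * sched$cell_conc / KD_hat
  structure(list(n = n_hat, KD = KD_hat, dH = dH_hat, se = se,
                 c_value = c_value, kd_low_precision = c_value > 1000,
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit), data = data,
                 convergence = fit$convInfo),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("One-set-of-sites ITC fit\n")
  cat(sprintf("  n  = %.4g sites per macromolecule (se %.2g)\n",
              x$n, x$se["n"]))
  cat(sprintf("  KD = %.4g nM (se %.2g nM)%s\n", x$KD * 1e9,
              x$se["KD"] * 1e9,
              if (isTRUE(x$kd_low_precision))
                sprintf("  [low precision: c = n*Mt/KD = %.0f > 1000]",
                        x$c_value) else ""))
  cat(sprintf("  dH = %.4g kJ/mol (se %.2g)\n", x$dH / 1e3,
              x$se["dH"] / 1e3))
  invisible(x)
}

#' @export
coef.itc_fit <- function(object, ...)
  c(n = object$n, KD = object$KD, dH = object$dH)

#' @export
summary.itc_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  rms residual: %.3g uJ over %d injections\n",
              sqrt(mean(object$residuals^2)) * 1e6,
              length(object$residuals)))
  invisible(object)
}
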