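#' Combined chemical shift perturbation, two nuclei (1H, 15N)
#'
#' Weighted root-mean-square of the amide proton and nitrogen chemical
#' shift changes,
#' \deqn{CCSP = \sqrt{(\Delta\delta_H^2 + (\alpha_N \Delta\delta_N)^2)/2}.}
#' The nitrogen scaling factor compensates for the larger ppm range of the
#' 15N shift; the default 0.16 is the conventional amide weighting. Signs of
#' the shift differences are irrelevant (squares), so differences are taken
#' bound minus free and not absolute-valued.
#'
#' @param dH 1H shift change (ppm).
#' @param dN 15N shift change (ppm).
#' @param alphaN nitrogen scaling factor.
#' @return CCSP in ppm (vectorized).
#' @export
ccsp_2d <- function(dH, dN, alphaN = 0.16) {
  stopifnot(is.finite(alphaN))
  sqrt((dH^2 + (alphaN * dN)^2) / 2)
}

#' Combined chemical shift perturbation, three nuclei (1H, 15N, 13C')
#'
#' Extension of [ccsp_2d()] to HNCO-type spectra with a carbonyl dimension:
#' \deqn{CCSP = \sqrt{(\Delta\delta_H^2 + (\alpha_N \Delta\delta_N)^2 +
#' (\alpha_C \Delta\delta_C)^2)/3}.}
#'
#' @param dH,dN,dC shift changes in ppm.
#' @param alphaN,alphaC nitrogen and carbonyl scaling factors.
#' @return CCSP in ppm (vectorized).
#' @export
ccsp_3d <- function(dH, dN, dC, alphaN = 0.16, alphaC = 0.045) {
  sqrt((dH^2 + (alphaN * dN)^2 + (alphaC * dC)^2) / 3)
}

#' Per-residue CCSP between two peak tables
#'
#' Shift differences are computed bound minus free, matched by
#' chain/residue; the 3d formula is used when both tables carry carbonyl
#' shifts for a residue, the 2d formula otherwise (mode `"auto"`).
#'
#' @param free,bound [peak_table()] objects.
#' @param mode `"auto"`, `"2d"` or `"3d"`.
#' @param alphaN,alphaC scaling factors, see [ccsp_2d()]/[ccsp_3d()].
#' @return data.frame with columns `chain`, `resnum`, `resname`, `dH`,
#'   `dN`, `dC`, `ccsp`.
#' @export
compute_ccsp <- function(free, bound, mode = c("auto", "2d", "3d"),
                         alphaN = 0.16, alphaC = 0.045) {
  mode <- match.arg(mode)
  stopifnot(inherits(free, "peak_table"), inherits(bound, "peak_table"))
  common <- intersect(peak_key(free), peak_key(bound))
  if (length(common) == 0) stop("no residues common to both tables")
  mf <- match(common, peak_key(free))
  mb <- match(common, peak_key(bound))
  dH <- bound$shift_H[mb] - free$shift_H[mf]
  dN <- bound$shift_N[mb] - free$shift_N[mf]
  dC <- bound$shift_C[mb] - free$shift_C[mf]
  use3 <- switch(mode,
                 auto = !is.na(dC),
                 "2d" = rep(FALSE, length(dC)),
                 "3d" = rep(TRUE, length(dC)))
  if (mode == "3d" && any(is.na(dC)))
    stop("mode '3d' requires carbonyl shifts for every matched residue")
  ccsp <- ifelse(use3, ccsp_3d(dH, dN, dC, alphaN, alphaC),
                 ccsp_2d(dH, dN, alphaN))
  data.frame(chain = free$chain[mf], resnum = free$resnum[mf],
             resname = free$resname[mf], dH = dH, dN = dN, dC = dC,
             ccsp = ccsp, stringsAsFactors = FALSE)
}

#' Two-state fast-exchange binding curve for titration CCSP
#'
#' Under fast exchange the observed CCSP is the population-weighted average
#' of the free and bound shifts, which for a single binding equilibrium
#' gives the quadratic solution
#' \deqn{y = \frac{a}{2p}\left[c + p + K_D -
#'   \sqrt{(c + p + K_D)^2 - 4 c p}\right]}
#' where `p` is the total concentration of the observed (labeled) protein,
#' `c` the total concentration of the titrated (unlabeled) ligand and `a`
#' the CCSP of the completely bound labeled protein.
#'
#' @param c ligand total concentration (molar; vectorized).
#' @param p labeled protein total concentration (molar).
#' @param KD dissociation constant (molar).
#' @param a saturation CCSP (ppm).
#' @return CCSP in ppm; monotone non-decreasing in `c`, bounded by `a`.
#' @export
binding_curve <- function(c, p, KD, a) {
  stopifnot(p > 0, KD > 0, all(c >= 0))
  s <- c + p + KD
  (a / (2 * p)) * (s - sqrt(s^2 - 4 * c * p))
}

#' Extrapolate an observed CCSP to full saturation
#'
#' Inverse of [binding_curve()]: from an observed CCSP `y` at known
#' concentrations and dissociation constant, recover the CCSP `a` that would
#' be observed with the labeled protein completely bound. Used to compare
#' binding interfaces measured at partial saturation with reference
#' complexes measured fully bound.
#'
#' @param y observed CCSP (ppm; vectorized).
#' @param c ligand total concentration (molar), must be > 0.
#' @param p labeled protein total concentration (molar).
#' @param KD dissociation constant (molar).
#' @return saturation CCSP `a` in ppm.
#' @export
saturation_ccsp <- function(y, c, p, KD) {
  stopifnot(p > 0, KD > 0)
  if (any(c <= 0)) stop("c must be > 0: zero ligand carries no binding information")
  s <- c + p + KD
  bracket <- s - sqrt(s^2 - 4 * c * p)
  2 * p * y / bracket
}

#' Construct a CCSP titration series
#'
#' @param p total concentration of the observed labeled protein (molar).
#' @param conc ligand total concentrations (molar), strictly increasing,
#'   all >= 0.
#' @param ccsp matrix of CCSP values (ppm), residues in rows (rownames =
#'   residue numbers or `chain:resnum` keys), titration points in columns.
#' @return Object of class `titration_series`.
#' @export
titration_series <- function(p, conc, ccsp) {
  stopifnot(p > 0, all(conc >= 0), !is.unsorted(conc, strictly = TRUE))
  ccsp <- as.matrix(ccsp)
  if (ncol(ccsp) != length(conc))
    stop("ccsp needs one column per titration point")
  if (is.null(rownames(ccsp)))
    stop("ccsp needs residue rownames")
  structure(list(p = p, conc = conc, ccsp = ccsp),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat("CCSP titration series: p =", format(x$p * 1e6), "uM,",
      length(x$conc), "points, ", nrow(x$ccsp), "residues\n")
  cat("  c (uM):", paste(format(x$conc * 1e6), collapse = ", "), "\n")
  invisible(x)
}

# Residual sum of squares with per-residue saturation amplitudes profiled
# out: for fixed KD the model is linear in each a_r, so
# a_r = sum(y f)/sum(f^2) (clamped at 0), f = binding_curve(c, p, KD, 1).
.kd_profile <- function(logKD, p, conc, Y) {
  f <- binding_curve(conc, p, exp(logKD), 1)
  ss <- sum(f^2)
  a <- pmax(as.vector(Y %*% f) / ss, 0)
  r <- Y - outer(a, f)
  list(sse = sum(r^2), a = a)
}

#' Fit a shared dissociation constant to a CCSP titration
#'
#' Least-squares fit of [binding_curve()] jointly over the selected
#' residues: one shared `KD`, one saturation amplitude `a` per residue.
#' Because the model is linear in the amplitudes for fixed `KD`, they are
#' profiled out and `KD` is optimised in one dimension (log scale, grid
#' bracket + Brent refinement), which is exact for this model and fast
#' enough for the nonparametric bootstrap used for the uncertainties.
#'
#' @param series a [titration_series()].
#' @param residues residue keys (matching `rownames(series$ccsp)`) to fit
#'   jointly; default all.
#' @param n_boot bootstrap resamples (over residue x point cells) for the
#'   uncertainties; 0 disables.
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level of the percentile interval.
#' @return Object of class `kd_fit` with elements `KD` (molar), `a` (named
#'   ppm vector), `KD_se`, `KD_ci`, `a_se`, `sse`, `fitted`, `residuals`,
#'   `boot` (bootstrap KD draws).
#' @export
fit_kd_titration <- function(series, residues = rownames(series$ccsp),
                             n_boot = 1000, seed = 1L, conf = 0.95) {
  stopifnot(inherits(series, "titration_series"))
  residues <- as.character(residues)
  missing <- setdiff(residues, rownames(series$ccsp))
  if (length(missing))
    stop("residue(s) not in series: ", paste(missing, collapse = ", "))
  keep <- series$conc > 0
  conc <- series$conc[keep]
  if (length(conc) < 2)
    stop("need at least 2 non-zero concentration points")
  Y <- series$ccsp[residues, keep, drop = FALSE]
  if (any(is.na(Y)))
    stop("selected residues must have CCSP at every titration point")
  if (all(Y == 0)) stop("all CCSP values are zero: KD unidentifiable")
  p <- series$p

  solve_kd <- function(Y) {
    # bracket on a log grid spanning far below/above the sampled range
    lo <- log(min(conc) * 1e-4)
    hi <- log(max(conc) * 1e4)
    grid <- seq(lo, hi, length.out = 60)
    sse <- vapply(grid, function(l) .kd_profile(l, p, conc, Y)$sse,
                  numeric(1))
    i <- which.min(sse)
    a <- grid[max(i - 1, 1)]
    b <- grid[min(i + 1, length(grid))]
    opt <- stats::optimize(function(l) .kd_profile(l, p, conc, Y)$sse,
                           c(a, b), tol = 1e-12)
    opt$minimum
  }

  logKD <- solve_kd(Y)
  prof <- .kd_profile(logKD, p, conc, Y)
  KD <- exp(logKD)
  a <- stats::setNames(prof$a, residues)
  f <- binding_curve(conc, p, KD, 1)
  fitted <- outer(prof$a, f)
  dimnames(fitted) <- dimnames(Y)

  boot_kd <- NULL
  KD_se <- KD_ci <- a_se <- NULL
  if (n_boot > 0) {
    cells <- expand.grid(r = seq_along(residues), j = seq_along(conc))
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    boot <- matrix(NA_real_, n_boot, 1 + length(residues))
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample(nrow(cells), nrow(cells), replace = TRUE)
        # a resample confined to one concentration cannot identify KD
        if (length(unique(cells$j[idx])) >= 2) break
      }
      W <- matrix(0, nrow(Y), ncol(Y))
      Yb <- matrix(0, nrow(Y), ncol(Y))
      for (k in idx) {
        r <- cells$r[k]; j <- cells$j[k]
        W[r, j] <- W[r, j] + 1
        Yb[r, j] <- Y[r, j]
      }
      # weighted profiled fit on the resampled cells
      sse_w <- function(l) {
        fb <- binding_curve(conc, p, exp(l), 1)
        ab <- numeric(nrow(Y))
        for (r in seq_len(nrow(Y))) {
          ss <- sum(W[r, ] * fb^2)
          ab[r] <- if (ss > 0) max(sum(W[r, ] * Y[r, ] * fb) / ss, 0) else 0
        }
        sum(W * (Y - outer(ab, fb))^2)
      }
      lo <- log(min(conc) * 1e-4); hi <- log(max(conc) * 1e4)
      grid <- seq(lo, hi, length.out = 40)
      s <- vapply(grid, sse_w, numeric(1))
      i <- which.min(s)
      opt <- stats::optimize(sse_w, c(grid[max(i - 1, 1)],
                                      grid[min(i + 1, length(grid))]),
                             tol = 1e-9)
      lb <- opt$minimum
      fb <- binding_curve(conc, p, exp(lb), 1)
      ab <- vapply(seq_len(nrow(Y)), function(r) {
        ss <- sum(W[r, ] * fb^2)
        if (ss > 0) max(sum(W[r, ] * Y[r, ] * fb) / ss, 0) else NA_real_
      }, numeric(1))
      boot[b, ] <- c(exp(lb), ab)
    }
    boot_kd <- boot[, 1]
    KD_se <- stats::sd(boot_kd)
    alpha <- (1 - conf) / 2
    KD_ci <- stats::quantile(boot_kd, c(alpha, 1 - alpha), names = FALSE)
    a_se <- apply(boot[, -1, drop = FALSE], 2, stats::sd, na.rm = TRUE)
    names(a_se) <- residues
  }

  structure(list(KD = KD, a = a, KD_se = KD_se, KD_ci = KD_ci, a_se = a_se,
                 conf = conf, p = p, conc = conc, residues = residues,
                 sse = prof$sse, fitted = fitted, residuals = Y - fitted,
                 boot = boot_kd, n_boot = n_boot),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat("Two-state titration fit (shared KD, per-residue amplitude)\n")
  cat(sprintf("  KD = %.4g uM", x$KD * 1e6))
  if (!is.null(x$KD_se))
    cat(sprintf(" +- %.2g (bootstrap %d%% CI %.4g-%.4g)", x$KD_se * 1e6,
                round(x$conf * 100), x$KD_ci[1] * 1e6, x$KD_ci[2] * 1e6))
  cat("\n  residues:", paste(x$residues, collapse = ", "), "\n")
  cat("  a (ppm):", paste(sprintf("%s=%.4g", names(x$a), x$a),
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.kd_fit <- function(object, ...) c(KD = object$KD, object$a)

#' @export
predict.kd_fit <- function(object, c = object$conc, residue = NULL, ...) {
  a <- if (is.null(residue)) object$a else object$a[as.character(residue)]
  out <- outer(a, binding_curve(c, object$p, object$KD, 1))
  colnames(out) <- format(c)
  out
}

#' @export
summary.kd_fit <- function(object, ...) {
  cat(sprintf(
    "KD = %.6g M on %d residues x %d points, SSE = %.3g\n",
    object$KD, length(object$residues), length(object$conc), object$sse))
  invisible(object)
}

#' Degree of modification from peak volumes
#'
#' Fraction of a protein carrying a modification (e.g. phosphorylation),
#' estimated from the volumes of resolved peak pairs of modified and
#' unmodified forms.
#'
#' @param volume_modified,volume_unmodified peak volumes (>= 0, not both 0;
#'   vectorized).
#' @return fraction in \[0, 1\].
#' @export
phospho_degree <- function(volume_modified, volume_unmodified) {
  stopifnot(all(volume_modified >= 0), all(volume_unmodified >= 0))
  tot <- volume_modified + volume_unmodified
  if (any(tot == 0)) stop("both volumes zero")
  volume_modified / tot
}

#' Fast-exchange trajectory linearity diagnostic
#'
#' In two-state fast exchange a titrated peak moves along a straight line in
#' the (1H, scaled 15N) plane. For each residue observed at >= 3 titration
#' points this reports the fraction of positional variance on the first
#' principal axis of its trajectory (1 = perfectly linear). Advisory only.
#'
#' @param tables list of [peak_table()] objects in titration order.
#' @param alphaN nitrogen scaling used for the 2D shift plane.
#' @return data.frame with columns `chain`, `resnum`, `r2`, `n_points`.
#' @export
csp_trajectory_linearity <- function(tables, alphaN = 0.16) {
  stopifnot(length(tables) >= 3)
  keys <- Reduce(intersect, lapply(tables, peak_key))
  rows <- lapply(keys, function(k) {
    pts <- t(vapply(tables, function(tb) {
      i <- match(k, peak_key(tb))
      c(tb$shift_H[i], alphaN * tb$shift_N[i])
    }, numeric(2)))
    pts <- pts[stats::complete.cases(pts), , drop = FALSE]
    if (nrow(pts) < 3) return(NULL)
    cm <- sweep(pts, 2, colMeans(pts))
    ev <- svd(cm)$d^2
    r2 <- if (sum(ev) == 0) 1 else ev[1] / sum(ev)
    i1 <- match(k, peak_key(tables[[1]]))
    data.frame(chain = tables[[1]]$chain[i1],
               resnum = tables[[1]]$resnum[i1], r2 = r2,
               n_points = nrow(pts), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
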