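#' Extract 1H-15N RDCs from IPAP peak positions
#'
#' In an IPAP experiment the in-phase (IP) and anti-phase (AP) components of
#' the amide 15N doublet are separated into subspectra; the splitting is J
#' in an isotropic sample and J + D in a weakly aligning medium, so the
#' residual dipolar coupling is
#' \deqn{^1D_{NH} = (\delta_{IP,or} - \delta_{AP,or}) -
#'   (\delta_{IP,iso} - \delta_{AP,iso})}
#' with the 15N shift differences converted from ppm to Hz using the
#' spectrometer's 15N Larmor frequency. Residues missing from any of the
#' four tables are excluded and reported in the `excluded` attribute.
#'
#' IPAP component ordering varies between processing conventions;
#' `flip_sign = TRUE` negates all couplings.
#'
#' @param ip_oriented,ap_oriented,ip_isotropic,ap_isotropic [peak_table()]
#'   objects carrying 15N shifts (`shift_N`, ppm).
#' @param freq_n15_mhz 15N Larmor frequency in MHz (e.g. 96.3 on a 950 MHz
#'   instrument); 1 ppm of 15N corresponds to this many Hz.
#' @param medium label of the alignment medium.
#' @param flip_sign negate all couplings.
#' @return Object of class `rdc_set`: a data.frame with columns `chain`,
#'   `resnum`, `resname`, `D` (Hz), attribute `medium` and attribute
#'   `excluded` (residue keys dropped).
#' @export
rdc_from_ipap <- function(ip_oriented, ap_oriented, ip_isotropic,
                          ap_isotropic, freq_n15_mhz, medium = "",
                          flip_sign = FALSE) {
  tabs <- list(ip_oriented, ap_oriented, ip_isotropic, ap_isotropic)
  for (tb in tabs) stopifnot(inherits(tb, "peak_table"))
  stopifnot(freq_n15_mhz > 0)
  keys <- lapply(tabs, peak_key)
  common <- Reduce(intersect, keys)
  excluded <- setdiff(Reduce(union, keys), common)
  # residues lacking a nitrogen shift in any subspectrum are excluded too
  shifts <- vapply(seq_along(tabs), function(i)
    tabs[[i]]$shift_N[match(common, keys[[i]])], numeric(length(common)))
  shifts <- matrix(shifts, nrow = length(common))
  ok <- stats::complete.cases(shifts)
  excluded <- c(excluded, common[!ok])
  common <- common[ok]
  if (length(common) == 0) stop("zero residues usable in all four tables")
  shifts <- shifts[ok, , drop = FALSE]
  D_ppm <- (shifts[, 1] - shifts[, 2]) - (shifts[, 3] - shifts[, 4])
  D <- D_ppm * freq_n15_mhz
  if (flip_sign) D <- -D
  i <- match(common, keys[[1]])
  rdc_set(data.frame(chain = ip_oriented$chain[i],
                     resnum = ip_oriented$resnum[i],
                     resname = ip_oriented$resname[i],
                     D = D, stringsAsFactors = FALSE),
          medium = medium, excluded = excluded)
}

#' Construct an RDC set
#'
#' @param data data.frame with columns `resnum` and `D` (Hz); optional
#'   `chain`, `resname`.
#' @param medium alignment-medium label.
#' @param excluded residue keys dropped during extraction.
#' @return Object of class `rdc_set`.
#' @export
rdc_set <- function(data, medium = "", excluded = character()) {
  stopifnot(is.data.frame(data), all(c("resnum", "D") %in% names(data)))
  if (!"chain" %in% names(data)) data$chain <- "."
  if (!"resname" %in% names(data)) data$resname <- NA_character_
  stopifnot(all(is.finite(data$D)))
  key <- paste(data$chain, data$resnum)
  if (anyDuplicated(key)) stop("duplicate residue in RDC set")
  data <- data[order(data$chain, data$resnum),
               c("chain", "resnum", "resname", "D")]
  rownames(data) <- NULL
  structure(data, medium = medium, excluded = excluded,
            class = c("rdc_set", "data.frame"))
}

#' Amide N-H bond unit vectors of a model
#'
#' @param model one model data.frame from a [structure_ensemble()].
#' @param residues optional residue keys `chain:resnum` to restrict to.
#' @return named list: `vectors` is a matrix (rows = residue keys
#'   `chain:resnum`, columns x/y/z) of unit N->H vectors, `missing` the
#'   residue keys lacking an amide N or H (H or HN atom name).
#' @export
nh_vectors <- function(model, residues = NULL) {
  stopifnot(is.data.frame(model))
  key <- paste(model$chain, model$resnum, sep = ":")
  if (is.null(residues)) residues <- unique(key)
  vecs <- matrix(NA_real_, length(residues), 3,
                 dimnames = list(residues, c("x", "y", "z")))
  for (i in seq_along(residues)) {
    sel <- key == residues[i]
    n <- which(sel & model$atom == "N")
    h <- which(sel & model$atom %in% c("H", "HN"))
    if (length(n) == 1 && length(h) >= 1) {
      v <- c(model$x[h[1]] - model$x[n], model$y[h[1]] - model$y[n],
             model$z[h[1]] - model$z[n])
      nv <- sqrt(sum(v^2))
      if (nv > 0) vecs[i, ] <- v / nv
    }
  }
  ok <- stats::complete.cases(vecs)
  list(vectors = vecs[ok, , drop = FALSE], missing = residues[!ok])
}

# design matrix of the linear Saupe problem: D = v' A v with A symmetric
# traceless; unknowns (Axx, Ayy, Axy, Axz, Ayz), Azz = -Axx - Ayy
saupe_design <- function(V) {
  cbind(V[, 1]^2 - V[, 3]^2,
        V[, 2]^2 - V[, 3]^2,
        2 * V[, 1] * V[, 2],
        2 * V[, 1] * V[, 3],
        2 * V[, 2] * V[, 3])
}

saupe_from_params <- function(s) {
  matrix(c(s[1], s[3], s[4],
           s[3], s[2], s[5],
           s[4], s[5], -s[1] - s[2]), 3, 3)
}

#' Fit a molecular alignment tensor to RDCs
#'
#' Linear least squares (singular-value solution) for the five independent
#' elements of the symmetric traceless Saupe order matrix, expressed
#' directly in Hz so that D = v' S v for a unit bond vector v. The
#' eigen-decomposition gives the principal axes, the axial magnitude
#' Da = Szz/2 and the rhombicity R = (2/3)(Sxx - Syy)/Szz, with eigenvalues
#' ordered |Szz| >= |Syy| >= |Sxx| (so 0 <= R <= 2/3).
#'
#' @param rdcs an [rdc_set()] (or data.frame with `chain`, `resnum`, `D`).
#' @param vectors matrix of unit bond vectors with residue-key rownames
#'   (`chain:resnum`), as from [nh_vectors()].
#' @param min_residues minimum residues required (5 parameters).
#' @param max_condition design condition number above which the vector set
#'   is considered degenerate (collinear).
#' @return Object of class `alignment_tensor`: `saupe` (3x3, Hz), `Da`
#'   (Hz), `R`, `axes` (columns = principal x/y/z), `eigenvalues`,
#'   `condition`, `n` and `residues` used.
#' @export
fit_alignment_tensor <- function(rdcs, vectors, min_residues = 5,
                                 max_condition = 1e8) {
  if (is.list(vectors) && !is.null(vectors$vectors))
    vectors <- vectors$vectors
  key <- paste(rdcs$chain, rdcs$resnum, sep = ":")
  common <- intersect(key, rownames(vectors))
  if (length(common) < min_residues)
    stop("insufficient data: ", length(common), " residues with both RDC ",
         "and bond vector (need >= ", min_residues, ")")
  D <- rdcs$D[match(common, key)]
  V <- vectors[common, , drop = FALSE]
  A <- saupe_design(V)
  sv <- svd(A)
  if (sv$d[5] <= 0 || sv$d[1] / sv$d[5] > max_condition)
    stop("rank-deficient design: bond vectors are (nearly) collinear")
  s <- sv$v %*% (crossprod(sv$u, D) / sv$d)
  S <- saupe_from_params(as.vector(s))
  alignment_tensor(S, condition = sv$d[1] / sv$d[5], n = length(common),
                   residues = common)
}

#' Construct an alignment tensor from a Saupe matrix
#'
#' @param saupe symmetric traceless 3x3 matrix in Hz.
#' @param condition,n,residues optional fit metadata.
#' @return Object of class `alignment_tensor`.
#' @export
alignment_tensor <- function(saupe, condition = NA_real_, n = NA_integer_,
                             residues = NULL) {
  saupe <- (saupe + t(saupe)) / 2
  if (abs(sum(diag(saupe))) > 1e-6 * max(abs(saupe), 1e-12))
    stop("Saupe matrix must be traceless")
  e <- eigen(saupe, symmetric = TRUE)
  ord <- order(abs(e$values))          # |Sxx| <= |Syy| <= |Szz|
  Sxx <- e$values[ord[1]]; Syy <- e$values[ord[2]]; Szz <- e$values[ord[3]]
  axes <- e$vectors[, ord, drop = FALSE]
  colnames(axes) <- c("x", "y", "z")
  # right-handed frame
  if (det(axes) < 0) axes[, 1] <- -axes[, 1]
  Da <- Szz / 2
  R <- if (Szz == 0) 0 else (2 / 3) * (Sxx - Syy) / Szz
  structure(list(saupe = saupe, Da = Da, R = R,
                 eigenvalues = c(Sxx = Sxx, Syy = Syy, Szz = Szz),
                 axes = axes, condition = condition, n = n,
                 residues = residues),
            class = "alignment_tensor")
}

#' Build a Saupe matrix from axial magnitude, rhombicity and axes
#'
#' Convenience constructor for simulations: eigenvalues Szz = 2 Da,
#' Sxx/Syy = -Da +- (3/4) R Szz / ... such that R = (2/3)(Sxx - Syy)/Szz.
#'
#' @param Da axial magnitude (Hz).
#' @param R rhombicity in \[0, 2/3\].
#' @param axes 3x3 rotation matrix whose columns are the principal x/y/z
#'   axes (default identity).
#' @return An [alignment_tensor()].
#' @export
tensor_from_da_r <- function(Da, R = 0, axes = diag(3)) {
  stopifnot(R >= 0, R <= 2 / 3)
  Szz <- 2 * Da
  Sxx <- -Da + 0.75 * R * Szz
  Syy <- -Da - 0.75 * R * Szz
  S <- axes %*% diag(c(Sxx, Syy, Szz)) %*% t(axes)
  alignment_tensor(S)
}

#' @export
print.alignment_tensor <- function(x, ...) {
  cat("Alignment tensor (Saupe matrix in Hz)\n")
  cat(sprintf("  Da = %.4g Hz, R = %.4g", x$Da, x$R))
  if (is.finite(x$condition))
    cat(sprintf("  (fit: n = %d, condition = %.3g)", x$n, x$condition))
  cat("\n  eigenvalues:",
      paste(sprintf("%s=%.4g", names(x$eigenvalues), x$eigenvalues),
            collapse = ", "), "\n")
  invisible(x)
}

#' Back-calculate RDCs from a tensor and bond vectors
#'
#' Computed as the Saupe contraction D = v' S v, which is algebraically
#' identical to the polar form
#' \deqn{D = D_a [(3\cos^2\theta - 1) + (3/2) R \sin^2\theta \cos 2\phi]}
#' with (theta, phi) the bond-vector angles in the tensor principal frame.
#'
#' @param tensor an [alignment_tensor()].
#' @param vectors unit-vector matrix with residue-key rownames (or a
#'   [nh_vectors()] result).
#' @return An [rdc_set()] with back-calculated couplings.
#' @export
back_calc_rdc <- function(tensor, vectors) {
  stopifnot(inherits(tensor, "alignment_tensor"))
  if (is.list(vectors) && !is.null(vectors$vectors))
    vectors <- vectors$vectors
  D <- rowSums((vectors %*% tensor$saupe) * vectors)
  keys <- rownames(vectors)
  parts <- strsplit(keys, ":", fixed = TRUE)
  rdc_set(data.frame(chain = vapply(parts, `[`, "", 1),
                     resnum = as.integer(vapply(parts, `[`, "", 2)),
                     D = as.numeric(D), stringsAsFactors = FALSE),
          medium = "back-calculated")
}

#' Q-factor of observed vs back-calculated RDCs
#'
#' Cornilescu-style quality factor: rms(Dobs - Dcalc) / rms(Dobs).
#'
#' @param observed,calculated numeric vectors of couplings (Hz), matched.
#' @return dimensionless Q.
#' @export
rdc_q_factor <- function(observed, calculated) {
  stopifnot(length(observed) == length(calculated), length(observed) > 0)
  sqrt(mean((observed - calculated)^2)) / sqrt(mean(observed^2))
}

#' Compare measured RDCs with a structure ensemble
#'
#' For each model of the ensemble, fits an alignment tensor to the observed
#' couplings against that model's amide bond vectors and back-calculates;
#' reports the per-model Q-factor (denominator: rms of observed couplings)
#' and rmsd, plus the per-residue mean and SD of the back-calculated
#' couplings over models.
#'
#' @param rdcs an [rdc_set()].
#' @param ensemble a [structure_ensemble()].
#' @return Object of class `rdc_comparison`: `per_model` (data.frame with
#'   `model`, `Q`, `rmsd`, `Da`, `R`, `condition`), `per_residue`
#'   (data.frame with `chain`, `resnum`, `D_obs`, `D_calc_mean`,
#'   `D_calc_sd`), `calc` (matrix models x residues).
#' @export
compare_ensemble <- function(rdcs, ensemble) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  key <- paste(rdcs$chain, rdcs$resnum, sep = ":")
  n_mod <- length(ensemble$models)
  calc <- NULL
  per_model <- vector("list", n_mod)
  for (m in seq_len(n_mod)) {
    nh <- nh_vectors(ensemble$models[[m]], residues = key)
    fit <- fit_alignment_tensor(rdcs, nh$vectors)
    bc <- back_calc_rdc(fit, nh$vectors)
    bck <- paste(bc$chain, bc$resnum, sep = ":")
    if (is.null(calc))
      calc <- matrix(NA_real_, n_mod, length(key),
                     dimnames = list(NULL, key))
    calc[m, bck] <- bc$D
    used <- key %in% bck
    q <- rdc_q_factor(rdcs$D[used], calc[m, key[used]])
    per_model[[m]] <- data.frame(
      model = m, Q = q,
      rmsd = sqrt(mean((rdcs$D[used] - calc[m, key[used]])^2)),
      Da = fit$Da, R = fit$R, condition = fit$condition)
  }
  per_residue <- data.frame(
    chain = rdcs$chain, resnum = rdcs$resnum, D_obs = rdcs$D,
    D_calc_mean = colMeans(calc[, key, drop = FALSE]),
    D_calc_sd = apply(calc[, key, drop = FALSE], 2, stats::sd),
    stringsAsFactors = FALSE)
  rownames(per_residue) <- NULL
  structure(list(per_model = do.call(rbind, per_model),
                 per_residue = per_residue, calc = calc,
                 q_denominator = "rms of observed RDCs"),
            class = "rdc_comparison")
}

#' @export
print.rdc_comparison <- function(x, ...) {
  cat("RDC ensemble comparison over", nrow(x$per_model), "models\n")
  cat(sprintf("  Q: mean %.3g (range %.3g-%.3g); denominator: %s\n",
              mean(x$per_model$Q), min(x$per_model$Q), max(x$per_model$Q),
              x$q_denominator))
  invisible(x)
}

#' Write an RDC set as tsv
#' @param x an [rdc_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rdc_set <- function(x, path) {
  df <- as.data.frame(x)
  names(df)[names(df) == "D"] <- "D_Hz"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read an RDC set from tsv
#' @param path tsv with columns `resnum`, `D_Hz` (optional `chain`,
#'   `resname`).
#' @param medium alignment-medium label.
#' @return An [rdc_set()].
#' @export
read_rdc_set <- function(path, medium = "") {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  names(df)[names(df) == "D_Hz"] <- "D"
  rdc_set(df, medium = medium)
}
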