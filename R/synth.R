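#' Build an ideal alpha-helix
#'
#' Calpha trace of a canonical alpha-helix: rise 1.5 A per residue, 100
#' degrees twist per residue, Calpha radius 2.3 A (consecutive Calpha
#' separation ~3.8 A). The helix axis is +z through the origin, with the
#' residue index increasing along +z, before the optional rigid transform
#' is applied. With `backbone = TRUE` amide N and H atoms are added on
#' inner cylinders so amide bond vectors are defined (approximate ideal
#' geometry; NH roughly parallel to the axis, as in a real helix).
#'
#' @param n_res number of residues (>= 4).
#' @param rise rise per residue (Angstrom).
#' @param twist twist per residue (degrees).
#' @param radius Calpha helix radius (Angstrom).
#' @param rotation 3x3 rotation applied to the canonical coordinates.
#' @param translation length-3 offset applied after rotation.
#' @param chain chain id.
#' @param first_resnum numbering of the first residue.
#' @param backbone also generate amide N and H atoms.
#' @return A [structure_ensemble()] with one model.
#' @export
make_ideal_helix <- function(n_res, rise = 1.5, twist = 100, radius = 2.3,
                             rotation = diag(3), translation = c(0, 0, 0),
                             chain = "A", first_resnum = 1L,
                             backbone = FALSE) {
  if (n_res < 4) stop("helix needs n_res >= 4")
  i <- seq_len(n_res) - 1
  ang <- i * twist * pi / 180
  z0 <- (i - (n_res - 1) / 2) * rise
  place <- function(r, dphi, dz, atom) {
    xyz <- cbind(r * cos(ang + dphi), r * sin(ang + dphi), z0 + dz)
    xyz <- xyz %*% t(rotation)
    xyz <- sweep(xyz, 2, translation, "+")
    data.frame(chain = chain, resnum = first_resnum + i, resname = "ALA",
               atom = atom, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  }
  model <- place(radius, 0, 0, "CA")
  if (backbone) {
    # amide N slightly inside the Calpha cylinder, one third of a turn
    # back; H displaced mostly along -z (antiparallel to the axis), the
    # canonical orientation of helical amides
    nN <- place(1.56, -28 * pi / 180, -0.9, "N")
    nH <- place(1.49, -30 * pi / 180, -1.85, "H")
    model <- rbind(model, nN, nH)
    model <- model[order(model$resnum, match(model$atom, c("N", "H", "CA"))), ]
  }
  structure_ensemble(list(model), label = "ideal helix")
}

rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * ca + sa * K + (1 - ca) * tcrossprod(u)
}

#' Build a two-helix toy complex at a requested oriented angle
#'
#' Helix A runs along +z centred at the origin; helix B is centred at
#' `separation` along +x and its axis is helix A's axis rotated by `angle`
#' about +x. Because +x is exactly the midpoint-connection vector used by
#' [oriented_interhelix_angle()], the construction realises the requested
#' signed angle under the package's sign convention.
#'
#' @param angle requested oriented angle in degrees, |angle| <= 180.
#' @param separation inter-axis distance (Angstrom), > 0.
#' @param lengths residue counts of the two helices.
#' @return A [structure_ensemble()] with one model holding chains A and B.
#' @export
make_two_helix_complex <- function(angle, separation = 10,
                                   lengths = c(20, 20)) {
  if (abs(angle) > 180) stop("|angle| must be <= 180")
  if (separation <= 0) stop("degenerate separation 0")
  ha <- make_ideal_helix(lengths[1], chain = "A")
  R <- rotation_about(c(1, 0, 0), angle)
  hb <- make_ideal_helix(lengths[2], chain = "B", rotation = R,
                         translation = c(separation, 0, 0))
  structure_ensemble(list(rbind(ha$models[[1]], hb$models[[1]])),
                     label = sprintf("two-helix complex (%+.0f deg)", angle))
}

#' Synthetic free/bound peak-table pair with a broadened region
#'
#' Free-state peak heights are 1.0; bound-state heights are multiplied by
#' `depth` inside the binding region and 1 outside, then by multiplicative
#' log-normal noise (exact at `noise_sd = 0`).
#'
#' @param n_res number of residues (1..n_res).
#' @param region length-2 residue-number range of the broadened region.
#' @param depth bound/free height ratio inside the region, in \[0, 1\].
#' @param noise_sd SD of the multiplicative noise on the log scale.
#' @param seed RNG seed.
#' @return list with elements `free` and `bound` ([peak_table()]s).
#' @export
synth_broadening <- function(n_res, region, depth, noise_sd = 0,
                             seed = 1L) {
  stopifnot(length(region) == 2, region[1] >= 1, region[2] <= n_res,
            region[1] <= region[2])
  if (depth < 0 || depth > 1) stop("depth must be in [0, 1]")
  res <- seq_len(n_res)
  base <- data.frame(resnum = res, resname = "ALA", shift_H = 8.2,
                     shift_N = 118, height = 1.0)
  ratio <- ifelse(res >= region[1] & res <= region[2], depth, 1)
  bound <- base
  bound$height <- ratio
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    base$height <- base$height * exp(stats::rnorm(n_res, 0, noise_sd))
    bound$height <- bound$height * exp(stats::rnorm(n_res, 0, noise_sd))
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  }
  list(free = peak_table(base, "synthetic free"),
       bound = peak_table(bound, "synthetic bound"))
}

#' Synthetic CCSP titration series
#'
#' CCSP values from [binding_curve()] at the given concentrations, one
#' saturation amplitude per residue, plus additive Gaussian noise (exact at
#' `noise_sd = 0`).
#'
#' @param p labeled-protein concentration (molar).
#' @param concentrations ligand concentrations (molar, strictly
#'   increasing).
#' @param a named vector of per-residue saturation amplitudes (ppm); names
#'   are residue keys.
#' @param KD dissociation constant (molar).
#' @param noise_sd additive noise SD (ppm).
#' @param seed RNG seed.
#' @return A [titration_series()].
#' @export
synth_titration <- function(p, concentrations, a, KD, noise_sd = 0,
                            seed = 1L) {
  stopifnot(!is.null(names(a)), all(nzchar(names(a))))
  f <- binding_curve(concentrations, p, KD, 1)
  Y <- outer(unname(a), f)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    Y <- Y + matrix(stats::rnorm(length(Y), 0, noise_sd), nrow(Y))
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  }
  rownames(Y) <- names(a)
  titration_series(p, concentrations, Y)
}

#' Random unit bond vectors
#'
#' Uniformly distributed directions, keyed as residues `.:(1..n)`, for
#' exercising alignment-tensor fits on well-conditioned designs.
#'
#' @param n number of vectors.
#' @param seed RNG seed.
#' @param chain chain label used in the residue keys.
#' @return unit-vector matrix with residue-key rownames.
#' @export
random_unit_vectors <- function(n, seed = 1L, chain = ".") {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  V <- matrix(stats::rnorm(3 * n), n, 3)
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  V <- V / sqrt(rowSums(V^2))
  rownames(V) <- paste(chain, seq_len(n), sep = ":")
  colnames(V) <- c("x", "y", "z")
  V
}

#' Synthetic RDC set from a tensor
#'
#' Back-calculates couplings for the given bond vectors (or for the amide
#' vectors of a structure's first model) and adds Gaussian noise (exact at
#' `noise_sd = 0`).
#'
#' @param tensor an [alignment_tensor()].
#' @param vectors unit-vector matrix with residue-key rownames; overrides
#'   `structure`.
#' @param structure a [structure_ensemble()] whose first model supplies
#'   amide vectors.
#' @param noise_sd additive noise SD (Hz).
#' @param seed RNG seed.
#' @return An [rdc_set()].
#' @export
synth_rdc <- function(tensor, vectors = NULL, structure = NULL,
                      noise_sd = 0, seed = 1L) {
  if (is.null(vectors)) {
    if (is.null(structure)) stop("supply vectors or a structure")
    vectors <- nh_vectors(structure$models[[1]])$vectors
    if (nrow(vectors) == 0) stop("no amide vectors computable")
  }
  out <- back_calc_rdc(tensor, vectors)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    out$D <- out$D + stats::rnorm(nrow(out), 0, noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  }
  attr(out, "medium") <- "synthetic"
  out
}
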