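#' Fit a helix axis to a residue range
#'
#' The helix centerline is traced by weighted 4-residue Calpha centroids
#' \eqn{P_i = (w_1 C\alpha_i + w_2 C\alpha_{i+1} + w_2 C\alpha_{i+2} +
#' w_1 C\alpha_{i+3})}, with the inner/outer weight ratio
#' \eqn{w_2/w_1 = -\cos(3t/2)/\cos(t/2)} chosen so the window exactly
#' cancels the fundamental helical frequency of an ideal alpha-helix
#' (twist t = 100 degrees per residue); a plain 4-residue average leaves a
#' small residual spiral that biases the axis of short helices. The axis is
#' the principal direction of the centerline points, oriented from the
#' first to the last point (N to C).
#'
#' @param model one model data.frame from a [structure_ensemble()].
#' @param chain chain identifier.
#' @param first,last residue-number range (>= 4 consecutive Calpha).
#' @return Object of class `helix_segment`: `chain`, `first`, `last`,
#'   `point` (centroid of the centerline), `direction` (unit vector),
#'   `fit_rms` (rms distance of centerline points from the axis, Angstrom).
#' @export
fit_helix_axis <- function(model, chain, first, last) {
  stopifnot(is.data.frame(model))
  sel <- model$chain == chain & model$atom == "CA" &
    model$resnum >= first & model$resnum <= last
  ca <- model[sel, , drop = FALSE]
  ca <- ca[order(ca$resnum), , drop = FALSE]
  need <- seq(first, last)
  if (!all(need %in% ca$resnum))
    stop("chain ", chain, " range ", first, "-", last,
         ": missing Calpha for residue(s) ",
         paste(setdiff(need, ca$resnum), collapse = ", "))
  if (length(need) < 4) stop("helix range must span >= 4 residues")
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  n <- nrow(xyz)
  idx <- seq_len(n - 3)
  t_rad <- 100 * pi / 180
  w_in <- -cos(1.5 * t_rad) / cos(0.5 * t_rad)
  w <- c(1, w_in, w_in, 1) / (2 + 2 * w_in)
  P <- w[1] * xyz[idx, , drop = FALSE] + w[2] * xyz[idx + 1, , drop = FALSE] +
    w[3] * xyz[idx + 2, , drop = FALSE] + w[4] * xyz[idx + 3, , drop = FALSE]
  ctr <- colMeans(P)
  if (nrow(P) == 1) {
    # exactly 4 residues: one centroid; fall back to the Calpha principal
    # direction (still well-defined for one turn)
    Pc <- sweep(xyz, 2, colMeans(xyz))
    u <- svd(Pc)$v[, 1]
    span <- xyz[n, ] - xyz[1, ]
  } else {
    Pc <- sweep(P, 2, ctr)
    u <- svd(Pc)$v[, 1]
    span <- P[nrow(P), ] - P[1, ]
  }
  if (sum(u * span) < 0) u <- -u
  d <- Pc - tcrossprod(Pc %*% u, u)
  fit_rms <- sqrt(mean(rowSums(d^2)))
  structure(list(chain = chain, first = first, last = last, point = ctr,
                 direction = as.numeric(u / sqrt(sum(u^2))),
                 fit_rms = fit_rms),
            class = "helix_segment")
}

#' @export
print.helix_segment <- function(x, ...) {
  cat(sprintf(
    "Helix axis %s:%d-%d  direction (%.3f, %.3f, %.3f)  fit rms %.2f A\n",
    x$chain, x$first, x$last, x$direction[1], x$direction[2],
    x$direction[3], x$fit_rms))
  invisible(x)
}

#' Oriented (signed) inter-helix angle
#'
#' The unsigned angle is `acos(ua . ub)` between the two axis directions
#' (each oriented N to C). The sign is that of `(ua x ub) . w`, where `w`
#' is the unit vector from the midpoint of helix `a` to the midpoint of
#' helix `b`; this convention distinguishes the two rotational senses of
#' helix `b` about the connection axis and is recorded in the result.
#' Values are degrees in (-180, 180]; antiparallel axes give +180.
#'
#' @param a,b [fit_helix_axis()] results.
#' @return list with `angle` (signed degrees), `unsigned` (degrees) and
#'   `convention`.
#' @export
oriented_interhelix_angle <- function(a, b) {
  stopifnot(inherits(a, "helix_segment"), inherits(b, "helix_segment"))
  ua <- a$direction; ub <- b$direction
  w <- b$point - a$point
  nw <- sqrt(sum(w^2))
  if (nw < 1e-9) stop("coincident helix midpoints: sign undefined")
  w <- w / nw
  unsigned <- acos(max(-1, min(1, sum(ua * ub)))) * 180 / pi
  cr <- c(ua[2] * ub[3] - ua[3] * ub[2],
          ua[3] * ub[1] - ua[1] * ub[3],
          ua[1] * ub[2] - ua[2] * ub[1])
  s <- sign(sum(cr * w))
  angle <- if (s < 0 && unsigned < 180) -unsigned else unsigned
  list(angle = angle, unsigned = unsigned,
       convention = "sign of (axis_a x axis_b) . (midpoint_b - midpoint_a); axes oriented N->C")
}

#' Identify the more ordered protomer of a docked dimer
#'
#' In docking complexes of a symmetric dimer with an asymmetric ligand, the
#' two protomers can differ in how tightly a probe residue (e.g. an
#' N-terminal isoleucine) packs against the docked peptide. This counts the
#' sub-cutoff heavy-atom pairs between the probe residue of each dimer
#' chain and the peptide chain, summed over all models, and returns the
#' chain with more contacts.
#'
#' @param ensemble a [structure_ensemble()].
#' @param dimer_chains character vector of the two protomer chain ids.
#' @param peptide_chain chain id of the docked peptide.
#' @param probe_resnum residue number of the probe residue (present in both
#'   protomers).
#' @param cutoff heavy-atom distance cutoff in Angstrom.
#' @return list with `chain` (the more ordered protomer) and `counts`
#'   (named pair counts per protomer).
#' @export
identify_ordered_protomer <- function(ensemble, dimer_chains, peptide_chain,
                                      probe_resnum, cutoff = 5) {
  stopifnot(inherits(ensemble, "structure_ensemble"),
            length(dimer_chains) == 2)
  counts <- stats::setNames(c(0L, 0L), dimer_chains)
  for (model in ensemble$models) {
    hv <- !grepl("^H|^[0-9]H", model$atom)
    pep <- as.matrix(model[hv & model$chain == peptide_chain,
                           c("x", "y", "z")])
    if (nrow(pep) == 0) stop("unknown or empty peptide chain ", peptide_chain)
    for (ch in dimer_chains) {
      probe <- as.matrix(model[hv & model$chain == ch &
                                 model$resnum == probe_resnum,
                               c("x", "y", "z")])
      if (nrow(probe) == 0)
        stop("probe residue ", probe_resnum, " missing in chain ", ch)
      d2 <- outer(rowSums(probe^2), rowSums(pep^2), "+") -
        2 * tcrossprod(probe, pep)
      counts[ch] <- counts[ch] + sum(d2 < cutoff^2)
    }
  }
  if (counts[1] == counts[2])
    stop("ambiguous: equal contact counts (", counts[1], ") for chains ",
         paste(dimer_chains, collapse = " and "))
  list(chain = names(counts)[which.max(counts)], counts = counts)
}

# Optimal rotation (no reflection) superposing moving onto fixed, both
# already centered: classic Kabsch via SVD.
kabsch_rotation <- function(fixed, moving) {
  H <- crossprod(moving, fixed)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$u, sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

rmsd_pair <- function(A, B) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  R <- kabsch_rotation(A, B)
  sqrt(mean(rowSums((B %*% R - A)^2)))
}

#' Select atoms of a model
#'
#' Selection spec for RMSD and related operations: a list (or list of
#' lists) with elements `chain`, `first`, `last` and optional `atoms`
#' (default backbone N, CA, C).
#'
#' @param model one model data.frame.
#' @param selection selection spec, or a predicate `function(model)`
#'   returning a logical vector.
#' @return logical vector over the atoms of `model`.
#' @export
select_atoms <- function(model, selection) {
  if (is.function(selection)) return(selection(model))
  if (!is.null(selection$chain)) selection <- list(selection)
  keep <- rep(FALSE, nrow(model))
  for (s in selection) {
    atoms <- if (is.null(s$atoms)) c("N", "CA", "C") else s$atoms
    keep <- keep | (model$chain == s$chain & model$resnum >= s$first &
                      model$resnum <= s$last & model$atom %in% atoms)
  }
  keep
}

#' Mean pairwise RMSD of an ensemble
#'
#' Every pair of models is optimally superposed (rotation + translation, no
#' reflection; Kabsch) on the selected atoms; the reported statistic is the
#' mean over pairs. The RMSD of each model to the (iteratively superposed)
#' mean coordinates is also computed for reference.
#'
#' @param ensemble a [structure_ensemble()] with >= 2 models.
#' @param selection see [select_atoms()]; default all atoms.
#' @return list with `mean_pairwise` (Angstrom), `pairwise` (matrix),
#'   `to_mean` (vector), `n_atoms`.
#' @export
ensemble_rmsd <- function(ensemble, selection = NULL) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  n <- length(ensemble$models)
  if (n < 2) stop("ensemble RMSD needs >= 2 models")
  coords <- lapply(ensemble$models, function(m) {
    keep <- if (is.null(selection)) rep(TRUE, nrow(m)) else
      select_atoms(m, selection)
    mm <- m[keep, , drop = FALSE]
    mm <- mm[order(mm$chain, mm$resnum, mm$atom), , drop = FALSE]
    rownames(mm) <- NULL
    mm
  })
  ref_key <- with(coords[[1]], paste(chain, resnum, atom))
  if (length(ref_key) == 0) stop("empty selection")
  for (i in seq_len(n)) {
    ki <- with(coords[[i]], paste(chain, resnum, atom))
    if (!identical(ki, ref_key))
      stop("selection is not common to all models")
  }
  X <- lapply(coords, function(m) as.matrix(m[, c("x", "y", "z")]))
  pw <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    pw[i, j] <- pw[j, i] <- rmsd_pair(X[[i]], X[[j]])
  }
  # RMSD to the mean: superpose everything on model 1, average, re-measure
  Xc <- lapply(X, function(A) sweep(A, 2, colMeans(A)))
  aligned <- lapply(Xc, function(B) B %*% kabsch_rotation(Xc[[1]], B))
  M <- Reduce(`+`, aligned) / n
  to_mean <- vapply(aligned, function(A) sqrt(mean(rowSums((A - M)^2))),
                    numeric(1))
  list(mean_pairwise = mean(pw[upper.tri(pw)]), pairwise = pw,
       to_mean = to_mean, n_atoms = length(ref_key))
}

#' Intermolecular residue contacts across an ensemble
#'
#' A residue pair (one residue from each chain) is in contact in a model if
#' any heavy-atom pair is closer than `cutoff`. Occupancy is the fraction
#' of models in contact; pairs present in every model are classed
#' `all_models`, the rest `some_models`.
#'
#' @param ensemble a [structure_ensemble()].
#' @param chain_a,chain_b the two chain ids.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 5, a
#'   common NOE-consistent contact definition).
#' @return data.frame with columns `resnum_a`, `resname_a`, `resnum_b`,
#'   `resname_b`, `min_dist` (minimum over models, Angstrom), `occupancy`,
#'   `class`.
#' @export
detect_contacts <- function(ensemble, chain_a, chain_b, cutoff = 5) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  n_mod <- length(ensemble$models)
  acc <- new.env(parent = emptyenv())
  for (model in ensemble$models) {
    hv <- !grepl("^H|^[0-9]H", model$atom)
    ma <- model[hv & model$chain == chain_a, , drop = FALSE]
    mb <- model[hv & model$chain == chain_b, , drop = FALSE]
    if (nrow(ma) == 0) stop("unknown or empty chain ", chain_a)
    if (nrow(mb) == 0) stop("unknown or empty chain ", chain_b)
    A <- as.matrix(ma[, c("x", "y", "z")])
    B <- as.matrix(mb[, c("x", "y", "z")])
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    d2[d2 < 0] <- 0
    # minimum heavy-atom distance per residue pair
    fa <- paste(ma$resnum, ma$resname)
    fb <- paste(mb$resnum, mb$resname)
    mind <- sqrt(tapply_min2(d2, fa, fb))
    hit <- which(mind < cutoff, arr.ind = TRUE)
    for (k in seq_len(nrow(hit))) {
      key <- paste(rownames(mind)[hit[k, 1]], colnames(mind)[hit[k, 2]],
                   sep = "|")
      prev <- acc[[key]]
      if (is.null(prev)) prev <- c(0, Inf)
      acc[[key]] <- c(prev[1] + 1, min(prev[2], mind[hit[k, 1], hit[k, 2]]))
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0)
    return(data.frame(resnum_a = integer(), resname_a = character(),
                      resnum_b = integer(), resname_b = character(),
                      min_dist = numeric(), occupancy = numeric(),
                      class = character(), stringsAsFactors = FALSE))
  rows <- lapply(keys, function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    pa <- strsplit(parts[1], " ")[[1]]
    pb <- strsplit(parts[2], " ")[[1]]
    v <- acc[[k]]
    occ <- as.numeric(v[1]) / n_mod
    data.frame(resnum_a = as.integer(pa[1]), resname_a = pa[2],
               resnum_b = as.integer(pb[1]), resname_b = pb[2],
               min_dist = as.numeric(v[2]), occupancy = occ,
               class = if (occ == 1) "all_models" else "some_models",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$resnum_a, out$resnum_b), , drop = FALSE]
}

# min of a matrix grouped by row and column factors
tapply_min2 <- function(d2, fa, fb) {
  ra <- factor(fa, levels = unique(fa))
  rb <- factor(fb, levels = unique(fb))
  out <- matrix(Inf, nlevels(ra), nlevels(rb),
                dimnames = list(levels(ra), levels(rb)))
  ia <- as.integer(ra); ib <- as.integer(rb)
  for (i in seq_along(ia)) {
    agg <- tapply(d2[i, ], ib, min)
    cols <- as.integer(names(agg))
    out[ia[i], cols] <- pmin(out[ia[i], cols], agg)
  }
  out
}

#' Classify distance restraints by sequence separation
#'
#' Same-chain restraints are binned by residue separation |i-j|:
#' intraresidue (0), sequential (1), medium-range (1 < |i-j| < 5) and
#' long-range (|i-j| >= 5). Restraints between different chains are
#' intermolecular, sub-counted per chain pair. A per-residue-pair count
#' matrix (data.frame) is also returned.
#'
#' @param restraints a [read_cyana_restraints()] result.
#' @param chain_map optional [chain_map()] used to resolve unassigned
#'   chains; every restrained residue must resolve to a chain.
#' @return Object of class `restraint_counts`: `intraresidue`,
#'   `sequential`, `medium_range`, `long_range`, `intermolecular`, `total`,
#'   `intermolecular_by_pair` (named vector), `pair_counts` (data.frame
#'   `chain_a`, `resnum_a`, `chain_b`, `resnum_b`, `n`).
#' @export
classify_restraints <- function(restraints, chain_map = NULL) {
  df <- as.data.frame(restraints)
  if (!is.null(chain_map)) {
    df$chain_a <- ifelse(is.na(df$chain_a),
                         resolve_chain(df$resnum_a, chain_map), df$chain_a)
    df$chain_b <- ifelse(is.na(df$chain_b),
                         resolve_chain(df$resnum_b, chain_map), df$chain_b)
  }
  if (nrow(df) > 0 && (any(is.na(df$chain_a)) || any(is.na(df$chain_b))))
    stop("unresolved chain for restrained residue(s); supply a chain_map")
  same <- df$chain_a == df$chain_b
  sep <- abs(df$resnum_a - df$resnum_b)
  counts <- list(
    intraresidue = sum(same & sep == 0),
    sequential = sum(same & sep == 1),
    medium_range = sum(same & sep > 1 & sep < 5),
    long_range = sum(same & sep >= 5),
    intermolecular = sum(!same),
    total = nrow(df))
  by_pair <- integer(0)
  if (any(!same)) {
    pr <- apply(cbind(df$chain_a[!same], df$chain_b[!same]), 1,
                function(x) paste(sort(x), collapse = "-"))
    by_pair <- c(table(pr))
  }
  pair_counts <- if (nrow(df) == 0) {
    data.frame(chain_a = character(), resnum_a = integer(),
               chain_b = character(), resnum_b = integer(), n = integer(),
               stringsAsFactors = FALSE)
  } else {
    swap <- paste(df$chain_a, sprintf("%06d", df$resnum_a)) >
      paste(df$chain_b, sprintf("%06d", df$resnum_b))
    ca <- ifelse(swap, df$chain_b, df$chain_a)
    ra <- ifelse(swap, df$resnum_b, df$resnum_a)
    cb <- ifelse(swap, df$chain_a, df$chain_b)
    rb <- ifelse(swap, df$resnum_a, df$resnum_b)
    tb <- table(paste(ca, ra, cb, rb))
    parts <- strsplit(names(tb), " ")
    data.frame(chain_a = vapply(parts, `[`, "", 1),
               resnum_a = as.integer(vapply(parts, `[`, "", 2)),
               chain_b = vapply(parts, `[`, "", 3),
               resnum_b = as.integer(vapply(parts, `[`, "", 4)),
               n = as.integer(tb), stringsAsFactors = FALSE)
  }
  structure(c(counts, list(intermolecular_by_pair = by_pair,
                           pair_counts = pair_counts)),
            class = "restraint_counts")
}

#' @export
print.restraint_counts <- function(x, ...) {
  cat("Distance-restraint classification (", x$total, " restraints)\n",
      sep = "")
  cat(sprintf("  intraresidue (|i-j| = 0):      %d\n", x$intraresidue))
  cat(sprintf("  sequential (|i-j| = 1):        %d\n", x$sequential))
  cat(sprintf("  medium-range (1 < |i-j| < 5):  %d\n", x$medium_range))
  cat(sprintf("  long-range (|i-j| >= 5):       %d\n", x$long_range))
  cat(sprintf("  intermolecular:                %d\n", x$intermolecular))
  if (length(x$intermolecular_by_pair))
    cat("    by chain pair:",
        paste(sprintf("%s=%d", names(x$intermolecular_by_pair),
                      x$intermolecular_by_pair), collapse = ", "), "\n")
  invisible(x)
}
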