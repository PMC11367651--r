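test_that("helix axes are recovered within 0.5 degrees and transform equivariantly", {
  h <- make_ideal_helix(20)
  ax <- fit_helix_axis(h$models[[1]], "A", 1, 20)
  expect_lt(acos(min(1, sum(ax$direction * c(0, 0, 1)))) * 180 / pi, 0.5)

  # equivariance under a rigid rotation
  M <- random_rotation(13)
  h2 <- make_ideal_helix(20, rotation = M, translation = c(4, -2, 9))
  ax2 <- fit_helix_axis(h2$models[[1]], "A", 1, 20)
  expect_lt(acos(min(1, sum(ax2$direction * (M %*% c(0, 0, 1))))) *
              180 / pi, 0.5)

  expect_error(fit_helix_axis(h$models[[1]], "A", 1, 3), ">= 4")
  expect_error(fit_helix_axis(h$models[[1]], "Q", 1, 10), "missing Calpha")

  # property sweep over lengths 8-30
  for (n in c(8, 12, 17, 23, 30)) {
    hn <- make_ideal_helix(n, rotation = random_rotation(n))
    axn <- fit_helix_axis(hn$models[[1]], "A", 1, n)
    hn0 <- make_ideal_helix(n)
    ax0 <- fit_helix_axis(hn0$models[[1]], "A", 1, n)
    expect_lt(acos(min(1, sum(ax0$direction * c(0, 0, 1)))) * 180 / pi, 0.5)
    expect_equal(sqrt(sum(axn$direction^2)), 1, tolerance = 1e-9)
  }
})

test_that("ideal helices have canonical Calpha geometry", {
  h <- make_ideal_helix(10)
  xyz <- as.matrix(h$models[[1]][, c("x", "y", "z")])
  d <- sqrt(rowSums(diff(xyz)^2))
  expect_true(all(abs(d - 3.8) < 0.1))
  M <- random_rotation(2)
  hr <- make_ideal_helix(10, rotation = M)
  expect_equal(as.matrix(hr$models[[1]][, c("x", "y", "z")]),
               xyz %*% t(M), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(make_ideal_helix(3), "n_res")
})

test_that("oriented inter-helix angles realise the sign convention", {
  # parallel and antiparallel limits
  par <- make_two_helix_complex(0)
  m <- par$models[[1]]
  a <- fit_helix_axis(m, "A", 1, 20); b <- fit_helix_axis(m, "B", 1, 20)
  expect_lt(abs(oriented_interhelix_angle(a, b)$angle), 1)

  anti <- make_two_helix_complex(180)$models[[1]]
  a <- fit_helix_axis(anti, "A", 1, 20); b <- fit_helix_axis(anti, "B", 1, 20)
  expect_equal(abs(oriented_interhelix_angle(a, b)$angle), 180,
               tolerance = 1)

  for (ang in c(140, -50, 75, -120)) {
    m <- make_two_helix_complex(ang)$models[[1]]
    a <- fit_helix_axis(m, "A", 1, 20)
    b <- fit_helix_axis(m, "B", 1, 20)
    expect_equal(oriented_interhelix_angle(a, b)$angle, ang, tolerance = 2)
  }

  # swapping the helices reverses both the cross product and the
  # connection vector, so the signed angle is invariant to argument order
  m <- make_two_helix_complex(140)$models[[1]]
  a <- fit_helix_axis(m, "A", 1, 20); b <- fit_helix_axis(m, "B", 1, 20)
  expect_equal(oriented_interhelix_angle(b, a)$angle,
               oriented_interhelix_angle(a, b)$angle, tolerance = 1e-9)
  # unsigned angle is invariant under a common rigid transform
  M <- random_rotation(31)
  mr <- m
  mr[, c("x", "y", "z")] <- as.matrix(m[, c("x", "y", "z")]) %*% t(M)
  ar <- fit_helix_axis(mr, "A", 1, 20); br <- fit_helix_axis(mr, "B", 1, 20)
  expect_equal(oriented_interhelix_angle(ar, br)$unsigned,
               oriented_interhelix_angle(a, b)$unsigned, tolerance = 1e-6)
})

test_that("ensemble RMSD matches hand superposition and is rigid-transform invariant", {
  m1 <- toy_model("A", 1:2, "CA", x = c(0, 2), y = c(0, 0), z = c(0, 0))
  m2 <- toy_model("A", 1:2, "CA", x = c(0, 4), y = c(0, 0), z = c(0, 0))
  r <- ensemble_rmsd(structure_ensemble(list(m1, m2)),
                     selection = function(m) rep(TRUE, nrow(m)))
  expect_equal(r$mean_pairwise, 1.0, tolerance = 1e-9)

  # rigid-transformed copies of one model superpose to zero
  h <- make_ideal_helix(15)$models[[1]]
  M <- random_rotation(5)
  h2 <- h
  h2[, c("x", "y", "z")] <-
    as.matrix(h[, c("x", "y", "z")]) %*% t(M) + rep(c(3, -7, 1), each = 15)
  ens <- structure_ensemble(list(h, h2))
  expect_lt(ensemble_rmsd(ens)$mean_pairwise, 1e-6)

  # applying a rigid transform to one model of a noisy ensemble changes nothing
  set.seed(17)
  hn <- h
  hn[, c("x", "y", "z")] <- hn[, c("x", "y", "z")] + rnorm(45, 0, 0.5)
  base <- ensemble_rmsd(structure_ensemble(list(h, hn)))$mean_pairwise
  hnr <- hn
  hnr[, c("x", "y", "z")] <- as.matrix(hn[, c("x", "y", "z")]) %*%
    t(random_rotation(6)) + rep(c(-2, 5, 8), each = 15)
  moved <- ensemble_rmsd(structure_ensemble(list(h, hnr)))$mean_pairwise
  expect_equal(moved, base, tolerance = 1e-6)

  expect_error(ensemble_rmsd(structure_ensemble(list(h))), ">= 2")
  expect_error(ensemble_rmsd(structure_ensemble(list(h, hn)),
                             selection = list(chain = "Z", first = 1,
                                              last = 5)), "empty selection")
})

test_that("in-package Kabsch RMSD agrees with bio3d superposition", {
  set.seed(23)
  A <- matrix(rnorm(30), 10, 3)
  B <- A %*% t(random_rotation(3)) + matrix(rnorm(30, 0, 0.4), 10, 3)
  ours <- nmrbind:::rmsd_pair(A, B)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(A)), mobile = as.vector(t(B))))
  ref <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - A)^2)))
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("contacts are classified by cutoff and occupancy, invariant to model order", {
  mk <- function(dx) rbind(
    toy_model("A", 1, "CB", 0, 0, 0),
    toy_model("A", 1, "HB", 0.5, 0, 0),   # hydrogens ignored
    toy_model("B", 9, "CG", dx, 0, 0))
  near <- mk(4.9); far <- mk(5.1)
  ct <- detect_contacts(structure_ensemble(list(near)), "A", "B", 5.0)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$min_dist, 4.9, tolerance = 1e-9)
  expect_equal(ct$class, "all_models")
  expect_equal(nrow(detect_contacts(structure_ensemble(list(far)),
                                    "A", "B", 5.0)), 0)

  # 7 of 20 models in contact -> occupancy 0.35, some_models
  models <- c(replicate(7, near, simplify = FALSE),
              replicate(13, far, simplify = FALSE))
  ct20 <- detect_contacts(structure_ensemble(models), "A", "B", 5.0)
  expect_equal(ct20$occupancy, 0.35)
  expect_equal(ct20$class, "some_models")
  set.seed(4)
  ct20b <- detect_contacts(structure_ensemble(sample(models)), "A", "B", 5.0)
  expect_equal(ct20b$occupancy, ct20$occupancy)
  expect_error(detect_contacts(structure_ensemble(models), "A", "Z", 5),
               "chain Z")
})

test_that("the more ordered protomer is the one contacting the peptide", {
  probe_b <- lapply(seq(0, 9), function(i)
    toy_model("B", 3, "CD1", 1 + 0.1 * i, 0, 0))
  model <- rbind(
    toy_model("A", 3, "CD1", 50, 50, 50),
    do.call(rbind, probe_b),
    toy_model("C", 103, "CA", 2, 0, 0))
  r <- identify_ordered_protomer(structure_ensemble(list(model)),
                                 c("A", "B"), "C", 3)
  expect_equal(r$chain, "B")
  expect_equal(unname(r$counts), c(0, 10))

  sym <- rbind(toy_model("A", 3, "CD1", 2, 0, 0),
               toy_model("B", 3, "CD1", 2, 0, 0),
               toy_model("C", 103, "CA", 0, 0, 0))
  expect_error(identify_ordered_protomer(structure_ensemble(list(sym)),
                                         c("A", "B"), "C", 3), "ambiguous")
})

test_that("restraints are classified by the Table-1 sequence-separation bounds", {
  mk <- function(i, j, ci = NA, cj = NA) data.frame(
    resnum_a = i, resname_a = "ALA", atom_a = "HN",
    resnum_b = j, resname_b = "ALA", atom_b = "HN",
    upper = 5, chain_a = ci, chain_b = cj, stringsAsFactors = FALSE)
  cm <- chain_map(A = c(1, 100), B = c(101, 200))
  # separations 0, 1, 3, 4, 5 -> intra, sequential, medium, medium, long
  df <- rbind(mk(10, 10), mk(10, 11), mk(10, 13), mk(10, 14), mk(10, 15))
  rl <- structure(df, class = c("restraint_list", "data.frame"))
  cc <- classify_restraints(rl, cm)
  expect_equal(cc$intraresidue, 1)
  expect_equal(cc$sequential, 1)
  expect_equal(cc$medium_range, 2)
  expect_equal(cc$long_range, 1)
  expect_equal(cc$intermolecular, 0)

  # five categories plus one cross-chain restraint
  df2 <- rbind(mk(10, 10), mk(10, 11), mk(10, 12), mk(10, 15), mk(20, 120))
  rl2 <- structure(df2, class = c("restraint_list", "data.frame"))
  c2 <- classify_restraints(rl2, cm)
  expect_equal(c(c2$intraresidue, c2$sequential, c2$medium_range,
                 c2$long_range, c2$intermolecular), c(1, 1, 1, 1, 1))
  expect_equal(unname(c2$intermolecular_by_pair["A-B"]), 1L)
  expect_equal(sum(c2$pair_counts$n), c2$total)

  empty <- structure(mk(1, 2)[0, ], class = c("restraint_list", "data.frame"))
  c0 <- classify_restraints(empty, cm)
  expect_equal(c0$total, 0)
  expect_equal(c0$intermolecular, 0)

  # conservation: random lists always sum to total
  set.seed(12)
  for (k in 1:10) {
    n <- sample(5:40, 1)
    df_r <- do.call(rbind, lapply(seq_len(n), function(q)
      mk(sample(200, 1), sample(200, 1))))
    df_r <- df_r[df_r$resnum_a != df_r$resnum_b | TRUE, ]
    rl_r <- structure(df_r, class = c("restraint_list", "data.frame"))
    cr <- classify_restraints(rl_r, cm)
    expect_equal(cr$intraresidue + cr$sequential + cr$medium_range +
                   cr$long_range + cr$intermolecular, cr$total)
  }
})
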