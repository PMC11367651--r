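test_that("IPAP differences give couplings in Hz with exclusions reported", {
  freq <- 96.3
  mk <- function(shift_N) toy_peaks(1:3, shift_N = shift_N)
  # oriented splitting 98 Hz, isotropic 93 Hz -> D = 5 Hz
  ip_or <- mk(118 + 98 / freq / 2); ap_or <- mk(118 - 98 / freq / 2)
  ip_iso <- mk(118 + 93 / freq / 2); ap_iso <- mk(118 - 93 / freq / 2)
  rdc <- rdc_from_ipap(ip_or, ap_or, ip_iso, ap_iso, freq)
  expect_equal(rdc$D, rep(5, 3), tolerance = 1e-9)

  # oriented = isotropic -> zero coupling
  z <- rdc_from_ipap(ip_iso, ap_iso, ip_iso, ap_iso, freq)
  expect_equal(z$D, rep(0, 3))

  # a residue absent from one subspectrum is excluded and reported
  ap_iso2 <- toy_peaks(1:2, shift_N = 118 - 93 / freq / 2)
  r2 <- rdc_from_ipap(ip_or, ap_or, ip_iso, ap_iso2, freq)
  expect_equal(nrow(r2), 2)
  expect_true(".:3" %in% sub(" ", ":", attr(r2, "excluded")) ||
                any(grepl("3", attr(r2, "excluded"))))
  expect_error(rdc_from_ipap(mk(118), mk(118), mk(118),
                             toy_peaks(7:9, shift_N = 118), freq),
               "zero residues")
  # sign flip convention
  rf <- rdc_from_ipap(ip_or, ap_or, ip_iso, ap_iso, freq, flip_sign = TRUE)
  expect_equal(rf$D, -rdc$D)
})

test_that("amide vectors are unit length and missing atoms are reported", {
  m <- rbind(toy_model("A", 1, "N", 0, 0, 0),
             toy_model("A", 1, "H", 0, 0, 1.02),
             toy_model("A", 2, "N", 5, 5, 5))
  nv <- nh_vectors(m)
  expect_equal(unname(nv$vectors["A:1", ]), c(0, 0, 1))
  expect_equal(nv$missing, "A:2")

  hel <- make_ideal_helix(15, backbone = TRUE)
  vv <- nh_vectors(hel$models[[1]])$vectors
  expect_equal(unname(sqrt(rowSums(vv^2))), rep(1, nrow(vv)),
               tolerance = 1e-9)
})

test_that("tensor fit recovers a known Saupe matrix exactly from noiseless data", {
  V <- random_unit_vectors(50, seed = 7)
  truth <- tensor_from_da_r(Da = 10, R = 0.3,
                            axes = random_rotation(3))
  obs <- synth_rdc(truth, vectors = V)
  fit <- fit_alignment_tensor(obs, V)
  expect_equal(fit$saupe, truth$saupe, tolerance = 1e-9)
  expect_equal(fit$Da, 10, tolerance = 1e-9)
  expect_equal(fit$R, 0.3, tolerance = 1e-9)

  # all-zero data -> zero tensor
  zero <- rdc_set(data.frame(chain = ".", resnum = 1:50, D = 0))
  zfit <- fit_alignment_tensor(zero, V)
  expect_equal(max(abs(zfit$saupe)), 0, tolerance = 1e-12)

  expect_error(fit_alignment_tensor(obs[1:4, ], V), "insufficient")
  # collinear vectors are rank-deficient
  Vc <- matrix(rep(c(0, 0, 1), each = 10), 10, 3)
  Vc <- Vc + 0   # exactly collinear
  rownames(Vc) <- paste(".", 1:10, sep = ":")
  expect_error(fit_alignment_tensor(rdc_set(data.frame(
    chain = ".", resnum = 1:10, D = 1)), Vc), "collinear")
})

test_that("back-calculation obeys the closed-form polar expression", {
  t_ax <- tensor_from_da_r(Da = 8, R = 0)
  vz <- matrix(c(0, 0, 1), 1, dimnames = list(".:1", NULL))
  expect_equal(back_calc_rdc(t_ax, vz)$D, 2 * 8)
  # magic angle zero
  th <- 54.7356103 * pi / 180
  vm <- matrix(c(sin(th), 0, cos(th)), 1, dimnames = list(".:1", NULL))
  expect_lt(abs(back_calc_rdc(t_ax, vm)$D), 1e-6 * 8)

  # Saupe contraction agrees with the (Da, R, theta, phi) formula
  set.seed(11)
  for (i in 1:20) {
    Da <- runif(1, -15, 15)
    R <- runif(1, 0, 2 / 3)
    tn <- tensor_from_da_r(Da, R)
    v <- random_unit_vectors(1, seed = i)
    theta <- acos(v[3]); phi <- atan2(v[2], v[1])
    closed <- Da * ((3 * cos(theta)^2 - 1) +
                      1.5 * R * sin(theta)^2 * cos(2 * phi))
    expect_equal(back_calc_rdc(tn, v)$D, closed, tolerance = 1e-9)
  }
})

test_that("fitted tensors transform equivariantly under rotation of the vectors", {
  V <- random_unit_vectors(40, seed = 21)
  truth <- tensor_from_da_r(Da = 6, R = 0.25, axes = random_rotation(4))
  obs <- synth_rdc(truth, vectors = V, noise_sd = 0.5, seed = 2)
  fit0 <- fit_alignment_tensor(obs, V)
  M <- random_rotation(8)
  VR <- V %*% t(M)
  rownames(VR) <- rownames(V)
  fitR <- fit_alignment_tensor(obs, VR)
  expect_equal(fitR$saupe, M %*% fit0$saupe %*% t(M), tolerance = 1e-9)
  expect_equal(fitR$Da, fit0$Da, tolerance = 1e-9)
  expect_equal(fitR$R, fit0$R, tolerance = 1e-9)
})

test_that("Q-factors and ensemble comparison behave as defined", {
  expect_equal(rdc_q_factor(c(5, -5), c(4, -4)), 0.2)
  # invariance to residue reordering
  set.seed(3)
  o <- rnorm(20); c_ <- rnorm(20)
  perm <- sample(20)
  expect_equal(rdc_q_factor(o, c_), rdc_q_factor(o[perm], c_[perm]))

  # self-consistent synthetic ensemble: identical models -> SD 0, Q 0
  hel <- make_ideal_helix(12, backbone = TRUE)
  m <- hel$models[[1]]
  # jitter the H positions so amide vectors are not collinear
  set.seed(9)
  hsel <- m$atom == "H"
  m[hsel, c("x", "y", "z")] <- m[hsel, c("x", "y", "z")] + rnorm(sum(hsel))
  ens <- structure_ensemble(list(m, m, m))
  V <- nh_vectors(m)$vectors
  obs <- synth_rdc(tensor_from_da_r(9, 0.2), vectors = V)
  cmp <- compare_ensemble(obs, ens)
  expect_equal(nrow(cmp$per_model), 3)
  expect_equal(cmp$per_model$Q, rep(0, 3), tolerance = 1e-9)
  expect_equal(cmp$per_residue$D_calc_sd, rep(0, nrow(cmp$per_residue)),
               tolerance = 1e-9)
  expect_equal(cmp$per_residue$D_calc_mean, cmp$per_residue$D_obs,
               tolerance = 1e-9)
})

test_that("RDC sets round-trip through tsv", {
  V <- random_unit_vectors(10, seed = 5)
  obs <- synth_rdc(tensor_from_da_r(5, 0.1), vectors = V, noise_sd = 1,
                   seed = 3)
  tf <- tempfile(fileext = ".tsv")
  write_rdc_set(obs, tf)
  back <- read_rdc_set(tf)
  expect_equal(back$D, obs$D, tolerance = 1e-9)
  expect_equal(back$resnum, obs$resnum)
})
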