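dip <- function(center, direction, mu = 1) {
  transition_dipole(center, direction, mu)
}

test_that("orientation factor reproduces the analytic cases", {
  # parallel, both perpendicular to the separation vector
  expect_equal(orientation_kappa(dip(c(0, 0, 0), c(0, 0, 1)),
                                 dip(c(10, 0, 0), c(0, 0, 1))), 1)
  # collinear head-to-tail along the separation vector
  expect_equal(orientation_kappa(dip(c(0, 0, 0), c(1, 0, 0)),
                                 dip(c(10, 0, 0), c(1, 0, 0))), -2)
  # mutually perpendicular, one along the separation vector
  expect_equal(orientation_kappa(dip(c(0, 0, 0), c(1, 0, 0)),
                                 dip(c(10, 0, 0), c(0, 1, 0))), 0)
  expect_error(orientation_kappa(dip(c(0, 0, 0), c(1, 0, 0)),
                                 dip(c(0, 0, 0), c(0, 1, 0))), "coincide")
})

test_that("kappa stays within [-2, 2] over random orientations", {
  for (seed in 1:200) {
    set.seed(seed)
    k <- orientation_kappa(dip(stats::rnorm(3), stats::rnorm(3)),
                           dip(stats::rnorm(3) + 5, stats::rnorm(3)))
    expect_gte(k, -2); expect_lte(k, 2)
  }
})

test_that("point-dipole energy matches the unit-conversion oracle", {
  d1 <- dip(c(0, 0, 0), c(0, 0, 1))
  d2 <- dip(c(10, 0, 0), c(0, 0, 1))
  res <- point_dipole_coupling(d1, d2)
  # oracle: e^2/(4 pi eps0) = 14.3996 eV*A; 1 D = 0.20819 e*A; 1 eV = 8065.54 cm-1
  expect_equal(res$energy_cm, coupling_const_oracle() / 1000,
               tolerance = 1e-4)
  expect_equal(res$kappa, 1)
  expect_equal(res$distance_R, 10)
  # kappa = 0 gives exactly zero
  expect_equal(point_dipole_coupling(
    dip(c(0, 0, 0), c(1, 0, 0)), dip(c(10, 0, 0), c(0, 1, 0)))$energy_cm, 0)
})

test_that("point-dipole coupling obeys the inverse-cube law and linearity", {
  at_R <- function(R, mu1 = 2, mu2 = 3) {
    point_dipole_coupling(dip(c(0, 0, 0), c(0, 0, 1), mu1),
                          dip(c(R, 0, 0), c(0, 0, 1), mu2))$energy_cm
  }
  expect_equal(at_R(20) * 8, at_R(10))
  # fitted log-log slope over R in {10, 20, 40}
  R <- c(10, 20, 40)
  E <- abs(vapply(R, at_R, numeric(1)))
  slope <- unname(coef(stats::lm(log(E) ~ log(R)))[2])
  expect_equal(slope, -3, tolerance = 1e-6)
  # linearity in mu1 * mu2
  expect_equal(at_R(10, 4, 6), 4 * at_R(10, 2, 3))
  # sign equals sign of kappa * f
  expect_lt(point_dipole_coupling(dip(c(0, 0, 0), c(1, 0, 0)),
                                  dip(c(10, 0, 0), c(1, 0, 0)))$energy_cm, 0)
  expect_gt(point_dipole_coupling(dip(c(0, 0, 0), c(1, 0, 0)),
                                  dip(c(10, 0, 0), c(1, 0, 0)),
                                  screening_f = -1)$energy_cm, 0)
})

test_that("extended dipole converges to the point dipole as l/R -> 0", {
  d1 <- dip(c(0, 0, 0), c(0, 0, 1), 4)
  d2 <- dip(c(20, 0, 0), c(0, 1, 1), 4)
  pt <- point_dipole_coupling(d1, d2)$energy_cm
  ext <- extended_dipole_coupling(d1, d2, extended_dipole_params(0.01))
  expect_equal(ext$energy_cm, pt, tolerance = 1e-4)
  # monotone convergence of the relative deviation
  ls <- c(4, 2, 1, 0.5, 0.25)
  dev <- vapply(ls, function(l) {
    abs(extended_dipole_coupling(d1, d2,
                                 extended_dipole_params(l))$energy_cm - pt)
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
})

test_that("extended dipole attenuates at short range", {
  # two parallel 8.7 A extended dipoles side by side at R = 9 A
  d1 <- dip(c(0, 0, 0), c(0, 0, 1), 4)
  d2 <- dip(c(9, 0, 0), c(0, 0, 1), 4)
  pt <- point_dipole_coupling(d1, d2)$energy_cm
  ext <- extended_dipole_coupling(d1, d2, extended_dipole_params(8.7))
  expect_lt(abs(ext$energy_cm), abs(pt))
  expect_error(extended_dipole_coupling(d1, dip(c(0, 0, 8.7), c(0, 0, 1), 4),
                                        extended_dipole_params(8.7)),
               "coincident charge sites")
})

test_that("both methods are pair-swap symmetric and rigid-motion invariant", {
  for (seed in 1:5) {
    set.seed(seed)
    d1 <- dip(stats::rnorm(3), stats::rnorm(3), 3.4)
    d2 <- dip(stats::rnorm(3) + 12, stats::rnorm(3), 4.0)
    for (fun in list(
      function(a, b) point_dipole_coupling(a, b)$energy_cm,
      function(a, b) extended_dipole_coupling(a, b)$energy_cm)) {
      expect_equal(fun(d1, d2), fun(d2, d1), tolerance = 1e-12)
      R <- random_rotation(seed + 50)
      t_ <- stats::rnorm(3, sd = 30)
      move <- function(d) transition_dipole(R %*% d$center + t_,
                                            R %*% d$direction,
                                            d$magnitude_debye)
      expect_equal(fun(move(d1), move(d2)), fun(d1, d2), tolerance = 1e-9)
    }
  }
})

test_that("coupling series follow per-frame geometry", {
  cx <- tiny_complex()
  static <- make_trajectory(cx$model, n_frames = 4, seed = 5)$trajectory
  cs <- coupling_series(static, c("A/611", "A/612"), cx$registry)
  expect_equal(nrow(cs), 4L)
  expect_equal(length(unique(cs$energy_cm)), 1L)
  ref <- crystal_coupling(cx$model, c("A/611", "A/612"), cx$registry)
  expect_equal(cs$energy_cm[1], ref$energy_cm)

  # prescribed rotation sweeping kappa: a chl at the origin along z,
  # second chl on x rotating from parallel (kappa 1) to along-r-perp (kappa 0)
  base <- make_complex(pigments = list(
    make_chlorin(c(0, 0, 0), rotation_matrix(c(0, 1, 0), -90), "chl_a",
                 chain = "P", resid = 1),
    make_chlorin(c(12, 0, 0), rotation_matrix(c(0, 1, 0), -90), "chl_a",
                 chain = "P", resid = 2)))
  angles <- seq(0, 90, length.out = 7)
  sched <- schedule_rotation(
    atom_selection(chain = "P", resid_ranges = list(c(2L, 2L))),
    angles_deg = angles, axis = c(1, 0, 0))
  tr <- make_trajectory(base$model, n_frames = 7, schedules = list(sched),
                        seed = 1)$trajectory
  cs <- coupling_series(tr, c("P/1", "P/2"), base$registry)
  # closed form: dipole 1 along z, dipole 2 rotated about x -> kappa = cos(theta)
  expect_vec_equal(cs$kappa, cos(angles * pi / 180), tol = 1e-9)
  expect_lt(abs(cs$energy_cm[7]), 1e-9)
  expect_equal(cs$energy_cm[1],
               point_dipole_coupling(dip(c(0, 0, 0), c(0, 0, 1), 4),
                                     dip(c(12, 0, 0), c(0, 0, 1), 4))$energy_cm,
               tolerance = 1e-9)
})

test_that("missing pigment atoms abort the series with the frame index", {
  cx <- tiny_complex()
  broken <- cx$model
  broken$atoms <- broken$atoms[!(broken$atoms$resid == 612 &
                                   broken$atoms$name == "MG"), ]
  tr <- make_trajectory(broken, n_frames = 2, seed = 3)$trajectory
  expect_error(coupling_series(tr, c("A/611", "A/612"), cx$registry),
               "frame 1")
})

test_that("extended-dipole series through the trajectory API matches direct calls", {
  cx <- tiny_complex()
  tr <- make_trajectory(cx$model, n_frames = 2, seed = 9)$trajectory
  cs <- coupling_series(tr, c("A/611", "A/612"), cx$registry,
                        method = "extended_dipole")
  ref <- crystal_coupling(cx$model, c("A/611", "A/612"), cx$registry,
                          method = "extended_dipole")
  expect_equal(cs$energy_cm[1], ref$energy_cm)
  expect_true(all(is.na(cs$kappa)))
})
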