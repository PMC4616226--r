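test_that("tilt angle reproduces the analytic cases and folds to [0, 90]", {
  z <- protein_axis_vector(c(0, 0, 1))
  expect_equal(tilt_angle(transition_dipole(c(0, 0, 0), c(0, 0, 1), 1), z), 0)
  expect_equal(tilt_angle(transition_dipole(c(0, 0, 0), c(1, 0, 0), 1), z), 90)
  expect_equal(tilt_angle(transition_dipole(c(0, 0, 0), c(1, 0, 1), 1), z),
               45, tolerance = 1e-9)
  # dipole sign is unphysical
  d <- transition_dipole(c(0, 0, 0), c(0.3, -0.2, 0.9), 1)
  dm <- transition_dipole(c(0, 0, 0), -c(0.3, -0.2, 0.9), 1)
  expect_equal(tilt_angle(d, z), tilt_angle(dm, z))
  # invariant under common rotation of dipole and axis
  for (seed in 1:5) {
    R <- random_rotation(seed)
    d2 <- transition_dipole(c(0, 0, 0), R %*% d$direction, 1)
    z2 <- protein_axis_vector(R %*% z$direction)
    expect_equal(tilt_angle(d2, z2), tilt_angle(d, z), tolerance = 1e-9)
  }
})

test_that("protein axis recovers the long axis of a helix bundle", {
  prot <- make_helix_bundle(n_helices = 3, res_per_helix = 30)
  m <- structure_model(transform(prot, serial = seq_len(nrow(prot))))
  ax <- protein_axis(m)
  expect_lt(tilt_angle(transition_dipole(c(0, 0, 0), ax$direction, 1),
                       protein_axis_vector(c(0, 0, 1))), 1)
  # equivariance: rotating the bundle rotates the axis
  R <- rotation_matrix(c(1, 0, 0), 30)
  m2 <- set_coords(m, t(R %*% t(coords(m))))
  ax2 <- protein_axis(m2)
  expect_lt(tilt_angle(transition_dipole(c(0, 0, 0), ax2$direction, 1),
                       protein_axis_vector(R %*% c(0, 0, 1))), 1)
  expect_error(protein_axis(m, atom_selection(resid_ranges = list(c(14, 14)))),
               "at least 3")
  expect_equal(protein_axis(m, mode = "lab_z_after_alignment")$direction,
               c(0, 0, 1))
})

test_that("protein axis sign follows the orientation reference", {
  prot <- make_helix_bundle(n_helices = 3, res_per_helix = 30)
  m <- structure_model(transform(prot, serial = seq_len(nrow(prot))))
  up <- protein_axis(m, orient_point = c(0, 0, 100))
  down <- protein_axis(m, orient_point = c(0, 0, -100))
  expect_vec_equal(up$direction, -down$direction)
})

test_that("static trajectories give zero B-factor and zero RMSD", {
  cx <- tiny_complex()
  tr <- make_trajectory(cx$model, n_frames = 3, seed = 2)$trajectory
  b <- per_atom_bfactor(tr)
  expect_lt(max(b$bfactor), 1e-12)
  dom <- domain_definition("N-terminus", list(c(14L, 33L)), chain = "A")
  r <- domain_rmsd_series(tr, cx$model, dom, atom_names = "CA")
  expect_lt(max(r$rmsd_A), 1e-6)
  expect_error(per_atom_bfactor(trajectory(cx$model, tr$frames[1])),
               "at least 2")
})

test_that("B-factor recovers 8 pi^2 sigma^2 under isotropic jitter", {
  set.seed(31)
  n <- 200
  ref <- matrix(stats::rnorm(3 * n, sd = 8), ncol = 3)
  atoms <- data.frame(record = "ATOM", serial = seq_len(n), name = "CA",
                      altloc = "", resname = "ALA", chain = "A",
                      resid = seq_len(n), inscode = "",
                      x = ref[, 1], y = ref[, 2], z = ref[, 3],
                      occupancy = 1, bfactor = 0, element = "C")
  m <- structure_model(atoms)
  sigma <- 0.5
  tr <- make_trajectory(m, n_frames = 2000, noise_sigma = sigma,
                        seed = 77)$trajectory
  b <- per_atom_bfactor(tr)
  expect_equal(mean(b$bfactor), 8 * pi^2 * sigma^2, tolerance = 0.05)

  # a global rigid rotation on top of the jitter must not change B
  sched <- schedule_rotation(seq_len(n),
                             angles_deg = seq(0, 120, length.out = 300),
                             axis = c(0, 0, 1), pivot = c(0, 0, 0))
  tr2 <- make_trajectory(m, n_frames = 300, noise_sigma = sigma,
                         seed = 78, schedules = list(sched))$trajectory
  tr3 <- make_trajectory(m, n_frames = 300, noise_sigma = sigma,
                         seed = 78)$trajectory
  b2 <- per_atom_bfactor(tr2)
  b3 <- per_atom_bfactor(tr3)
  expect_equal(mean(b2$bfactor), mean(b3$bfactor), tolerance = 0.05)
})

test_that("domain RMSD reports rigid displacement of the domain exactly", {
  cx <- tiny_complex()
  dom <- domain_definition("N-terminus", list(c(14L, 33L)), chain = "A")
  dom_idx <- resolve_selection(cx$model,
                               atom_selection(chain = "A",
                                              resid_ranges = list(c(14L, 33L)),
                                              name = "CA"))
  fit_sel <- atom_selection(chain = "A", resid_ranges = list(c(34L, 73L)),
                            name = "CA")
  off <- matrix(rep(c(2, 0, 0), each = 4), ncol = 3)  # +2 A on x, 4 frames
  sched <- schedule_translation(dom_idx, off)
  tr <- make_trajectory(cx$model, n_frames = 4, schedules = list(sched),
                        seed = 4)$trajectory
  r <- domain_rmsd_series(tr, cx$model, dom, fit_selection = fit_sel,
                          atom_names = "CA")
  expect_vec_equal(r$rmsd_A, rep(2, 4), tol = 1e-6)
})

test_that("domain RMSD under Gaussian noise approaches sqrt(3) sigma", {
  set.seed(55)
  sigma <- 0.4
  cx <- tiny_complex()
  dom <- domain_definition("N-terminus", list(c(14L, 33L)), chain = "A")
  dom_idx <- resolve_selection(cx$model,
                               atom_selection(chain = "A",
                                              resid_ranges = list(c(14L, 33L)),
                                              name = "CA"))
  fit_sel <- atom_selection(chain = "A", resid_ranges = list(c(34L, 73L)),
                            name = "CA")
  n_fr <- 150
  noise <- lapply(seq_len(n_fr), function(i) {
    xyz <- coords(cx$model)
    xyz[dom_idx, ] <- xyz[dom_idx, ] +
      matrix(stats::rnorm(3 * length(dom_idx), sd = sigma), ncol = 3)
    xyz
  })
  tr <- trajectory(cx$model, noise)
  r <- domain_rmsd_series(tr, cx$model, dom, fit_selection = fit_sel,
                          atom_names = "CA")
  expect_equal(mean(r$rmsd_A), sqrt(3) * sigma, tolerance = 0.1)
})

test_that("centroid distances follow hand geometry", {
  # two single atoms 5 A apart, and a 4-atom square vs its center
  sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
  atoms <- data.frame(record = "HETATM", serial = 1:6,
                      name = c("P1", "P2", paste0("S", 1:4)), altloc = "",
                      resname = c("AAA", "BBB", rep("SQR", 4)), chain = "Z",
                      resid = c(1L, 2L, rep(3L, 4)), inscode = "",
                      x = c(0, 5, sq[, 1] + 10), y = c(0, 0, sq[, 2]),
                      z = c(0, 0, sq[, 3]), occupancy = 1, bfactor = 0,
                      element = c("P", "P", rep("C", 4)))
  m <- structure_model(atoms)
  tr <- trajectory(m, list(coords(m), coords(m)))
  selA <- atom_selection(resname = "AAA")
  selB <- atom_selection(resname = "BBB")
  d <- com_distance_series(tr, selA, selB)
  expect_vec_equal(d$distance_A, c(5, 5))
  expect_vec_equal(com_distance_series(tr, selB, selA)$distance_A,
                   d$distance_A)
  dsq <- com_distance_series(tr, atom_selection(resname = "SQR"), selA)
  expect_vec_equal(dsq$distance_A, c(10, 10))
  expect_error(com_distance_series(tr, atom_selection(resname = "NON"), selA),
               "empty selection")
})

test_that("mass weighting shifts the centroid toward heavy atoms", {
  atoms <- data.frame(record = "HETATM", serial = 1:3,
                      name = c("P", "H1", "X"), altloc = "",
                      resname = c("LIG", "LIG", "REF"), chain = "Z",
                      resid = c(1L, 1L, 2L), inscode = "",
                      x = c(0, 10, 0), y = 0, z = 0,
                      occupancy = 1, bfactor = 0,
                      element = c("P", "H", "C"))
  m <- structure_model(atoms)
  tr <- trajectory(m, list(coords(m)), times = 0)
  lig <- atom_selection(resname = "LIG")
  ref <- atom_selection(resname = "REF")
  geo <- com_distance_series(tr, lig, ref)$distance_A
  mw <- com_distance_series(tr, lig, ref, mass_weighting = TRUE)$distance_A
  expect_equal(geo, 5)
  expect_equal(mw, 10 * 1.008 / (30.974 + 1.008), tolerance = 1e-9)
})

test_that("hydrogen bonds follow the distance-and-angle criterion", {
  mk <- function(acc_x, h_pos) {
    atoms <- data.frame(record = "ATOM", serial = 1:3,
                        name = c("OD", "HD", "OA"), altloc = "",
                        resname = "RES", chain = "A",
                        resid = c(1L, 1L, 2L), inscode = "",
                        x = c(0, h_pos[1], acc_x), y = c(0, h_pos[2], 0),
                        z = c(0, h_pos[3], 0), occupancy = 1, bfactor = 0,
                        element = c("O", "H", "O"))
    structure_model(atoms)
  }
  spec <- hbond_spec("A/1/OD", "A/2/OA", hydrogen = "A/1/HD")
  # 2.9 A, H on the donor-acceptor line at 10 degrees -> present
  hx <- c(cos(10 * pi / 180), sin(10 * pi / 180), 0)
  m_in <- mk(2.9, hx)
  tr_in <- trajectory(m_in, list(coords(m_in)), times = 0)
  expect_equal(hbond_occupancy(tr_in, spec)$occupancy, 1)
  # 4.0 A -> absent regardless of angle
  m_far <- mk(4.0, hx)
  tr_far <- trajectory(m_far, list(coords(m_far)), times = 0)
  expect_equal(hbond_occupancy(tr_far, spec)$occupancy, 0)
  # wide angle (50 degrees) -> absent even at 2.9 A
  hw <- c(cos(50 * pi / 180), sin(50 * pi / 180), 0)
  m_wide <- mk(2.9, hw)
  tr_wide <- trajectory(m_wide, list(coords(m_wide)), times = 0)
  expect_equal(hbond_occupancy(tr_wide, spec)$occupancy, 0)
  # without a hydrogen the criterion is distance-only
  spec_d <- hbond_spec("A/1/OD", "A/2/OA")
  expect_equal(hbond_occupancy(tr_wide, spec_d)$occupancy, 1)
  expect_error(hbond_occupancy(tr_in, hbond_spec("A/1/OD", "A/9/OX")),
               class = "lhc_missing_atom")
})

test_that("a 30 percent toggle schedule yields occupancy 0.300 exactly", {
  atoms <- data.frame(record = "ATOM", serial = 1:2,
                      name = c("OD", "OA"), altloc = "",
                      resname = "RES", chain = "A", resid = c(1L, 2L),
                      inscode = "", x = c(0, 2.9), y = 0, z = 0,
                      occupancy = 1, bfactor = 0, element = "O")
  m <- structure_model(atoms)
  n_fr <- 10
  near <- c(2.9, 0, 0); far <- c(4.0, 0, 0)
  pos <- t(vapply(seq_len(n_fr), function(f) if (f <= 3) near else far,
                  numeric(3)))
  sched <- schedule_positions("A/2/OA", pos)
  tr <- make_trajectory(m, n_frames = n_fr, schedules = list(sched),
                        seed = 8)$trajectory
  res <- hbond_occupancy(tr, hbond_spec("A/1/OD", "A/2/OA"))
  expect_identical(res$occupancy, 0.3)
  expect_identical(res$present, c(rep(TRUE, 3), rep(FALSE, 7)))
  # occupancy is monotone non-decreasing in the distance cutoff
  occs <- vapply(c(2.0, 3.0, 3.5, 4.5), function(dc) {
    hbond_occupancy(tr, hbond_spec("A/1/OD", "A/2/OA", d_cut = dc))$occupancy
  }, numeric(1))
  expect_true(all(diff(occs) >= 0))
})

test_that("a prescribed 60-to-90 degree tilt schedule is recovered frame-exactly", {
  car <- make_polyene(c(0, 0, 0), rotation_matrix(c(0, 1, 0), -90),
                      n_atoms = 22, chain = "A", resid = 623,
                      resname = "NEX")
  cx <- make_complex(pigments = list(car))
  angles <- seq(60, 90, length.out = 16)
  sched <- schedule_rotation(
    atom_selection(resid_ranges = list(c(623L, 623L))),
    angles_deg = angles, axis = c(0, 1, 0), pivot = c(0, 0, 0))
  tr <- make_trajectory(cx$model, n_frames = 16, schedules = list(sched),
                        seed = 12)$trajectory
  axis <- protein_axis_vector(c(0, 0, 1))
  ts <- tilt_angle_series(tr, "A/623", axis = axis, registry = cx$registry)
  expect_vec_equal(ts$angle_deg, angles, tol = 1e-6)
})
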