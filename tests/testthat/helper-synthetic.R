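# Shared fixture builders. Everything is generated in code; no files.

random_rotation <- function(seed) {
  set.seed(seed)
  ax <- stats::rnorm(3)
  rotation_matrix(ax, stats::runif(1, 0, 360))
}

# small rigid complex: helix bundle + two chlorins + one polyene
tiny_complex <- function(neo_tilt = 60) {
  prot <- make_helix_bundle(n_helices = 3, res_per_helix = 20,
                            start_resid = 14, chain = "A")
  p1 <- make_chlorin(c(10, 0, 0), diag(3), "chl_a", chain = "A", resid = 611)
  p2 <- make_chlorin(c(10, 0, 10), rotation_matrix(c(0, 0, 1), 30), "chl_a",
                     chain = "A", resid = 612)
  car <- make_polyene(c(-10, 0, 0),
                      rotation_matrix(c(0, 1, 0), neo_tilt - 90),
                      n_atoms = 22, chain = "A", resid = 623,
                      resname = "NEX")
  make_complex(prot, list(p1, p2, car), source = "tiny synthetic complex")
}

# analytic oracle for the vacuum dipole-dipole constant (unit conversion
# from e^2/(4 pi eps0) = 14.3996 eV*A, 1 D = 0.20819 e*A, 1 eV = 8065.54 cm-1)
coupling_const_oracle <- function() {
  0.20819434^2 * 14.399645 * 8065.544
}

expect_vec_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(as.numeric(a) - as.numeric(b))), tol)
}
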