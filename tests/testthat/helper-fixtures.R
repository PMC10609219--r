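# Shared test helpers: bit-column names, rigid motions, and quick fixture
# shortcuts. Fixtures are always generated in code at test time.

bit_cols <- c("hydrophobic", "aromatic_f2f", "aromatic_e2f",
              "hbond_donor", "hbond_acceptor", "ionic_cation", "ionic_anion")

fixture_frame <- function(spec) {
  read_pdb(make_complex_fixture(spec)$text)
}

frame_bits <- function(spec, ...) {
  fp <- compute_frame_ifp(fixture_frame(spec), "LIG", ...)
  as.matrix(as.data.frame(fp)[, bit_cols])
}

# random proper rotation from a random axis and angle
random_rotation <- function() {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  k <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

apply_rigid <- function(atoms, rot, trans) {
  xyz <- cbind(atoms$x, atoms$y, atoms$z) %*% t(rot)
  atoms$x <- xyz[, 1] + trans[1]
  atoms$y <- xyz[, 2] + trans[2]
  atoms$z <- xyz[, 3] + trans[3]
  atoms
}

# the complex specs used for detector/oracle sweeps: every interaction type
# with geometry at the cutoff +/- 0.1 Angstrom plus clear hits and misses
detector_sweep_specs <- function() {
  c(
    lapply(c(3.0, 4.4, 4.5, 4.6, 6.0), function(d) {
      complex_spec("ALA", "methane", distance = d)
    }),
    lapply(c(3.4, 3.5, 3.6, 2.8), function(d) {
      complex_spec("SER", "acetate", distance = d)
    }),
    list(complex_spec("SER", "acetate", distance = 2.8, hbond_angle = 134),
         complex_spec("SER", "acetate", distance = 2.8, hbond_angle = 136),
         complex_spec("SER", "acetate", distance = 2.8, hbond_angle = 90)),
    lapply(c(2.9, 3.4, 3.6), function(d) {
      complex_spec("GLU", "methanol", distance = d)
    }),
    lapply(c(3.0, 3.9, 4.0, 4.1, 4.5), function(d) {
      complex_spec("LYS", "acetate", distance = d)
    }),
    lapply(c(3.0, 3.9, 4.1), function(d) {
      complex_spec("ASP", "methylammonium", distance = d)
    }),
    lapply(c(3.5, 4.4, 4.6, 8.0), function(d) {
      complex_spec("PHE", "benzene", distance = d, ring_angle = 0)
    }),
    lapply(c(29, 31, 45, 59, 61, 90), function(a) {
      complex_spec("PHE", "benzene", distance = 4.4, ring_angle = a)
    }),
    lapply(c(5.0, 5.4, 5.6), function(d) {
      complex_spec("PHE", "benzene", distance = d, ring_angle = 90)
    }),
    list(complex_spec("HIS", "benzene", distance = 3.5, ring_angle = 0),
         complex_spec("HIS", "caffeate", distance = 4.5,
                      metal = list(element = "ZN", distance = 2.1)))
  )
}
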