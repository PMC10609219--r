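test_that("hydrophobic detector thresholds are inclusive at 4.5 A", {
  expect_true(frame_bits(complex_spec("ALA", "methane",
                                      distance = 4.0))[, "hydrophobic"])
  expect_true(frame_bits(complex_spec("ALA", "methane",
                                      distance = 4.5))[, "hydrophobic"])
  expect_false(frame_bits(complex_spec("ALA", "methane",
                                       distance = 4.6))[, "hydrophobic"])
})

test_that("aromatic windows separate F2F, E2F and the dead zone", {
  b <- frame_bits(complex_spec("PHE", "benzene", distance = 3.5,
                               ring_angle = 0))
  expect_true(b[, "aromatic_f2f"]); expect_false(b[, "aromatic_e2f"])
  b <- frame_bits(complex_spec("PHE", "benzene", distance = 5.0,
                               ring_angle = 90))
  expect_false(b[, "aromatic_f2f"]); expect_true(b[, "aromatic_e2f"])
  b <- frame_bits(complex_spec("PHE", "benzene", distance = 4.0,
                               ring_angle = 45))
  expect_false(any(b[, c("aromatic_f2f", "aromatic_e2f")]))
  b <- frame_bits(complex_spec("PHE", "benzene", distance = 8,
                               ring_angle = 0))
  expect_false(any(b[, c("aromatic_f2f", "aromatic_e2f")]))
})

test_that("F2F and E2F are mutually exclusive over the angle range", {
  for (a in seq(0, 90, by = 10)) {
    b <- frame_bits(complex_spec("PHE", "benzene", distance = 4.4,
                                 ring_angle = a))
    expect_false(b[, "aromatic_f2f"] && b[, "aromatic_e2f"])
  }
})

test_that("H-bond detection needs both distance and angle when H present", {
  b <- frame_bits(complex_spec("SER", "acetate", distance = 2.8,
                               hbond_angle = 170))
  expect_true(b[, "hbond_donor"]); expect_false(b[, "hbond_acceptor"])
  b <- frame_bits(complex_spec("SER", "acetate", distance = 2.8,
                               hbond_angle = 90))
  expect_false(b[, "hbond_donor"])
  b <- frame_bits(complex_spec("SER", "acetate", distance = 3.6))
  expect_false(b[, "hbond_donor"]) # distance gate
})

test_that("hydrogen-free structures fall back to the distance criterion", {
  fx <- make_complex_fixture(complex_spec("SER", "acetate", distance = 2.8,
                                          hbond_angle = 90))
  atoms <- read_pdb(fx$text)
  stripped <- atoms[atoms$element != "H", ]
  b <- compute_frame_ifp(stripped, "LIG")
  expect_true(b$hbond_donor) # angle gate vanished with the hydrogens
})

test_that("ionic detector uses group minimum distance at 4.0 A", {
  expect_true(frame_bits(complex_spec("LYS", "acetate",
                                      distance = 3.0))[, "ionic_cation"])
  expect_true(frame_bits(complex_spec("LYS", "acetate",
                                      distance = 4.0))[, "ionic_cation"])
  expect_false(frame_bits(complex_spec("LYS", "acetate",
                                       distance = 4.5))[, "ionic_cation"])
  # neutral ligand: no ionic bits regardless of geometry
  b <- frame_bits(complex_spec("LYS", "methanol", distance = 3.0))
  expect_false(any(b[, c("ionic_cation", "ionic_anion")]))
})

test_that("metal contacts are reported per ligand atom at 2.8 A", {
  fp <- compute_frame_ifp(fixture_frame(
    complex_spec("HIS", "caffeate", distance = 4.5,
                 metal = list(element = "ZN", distance = 2.1))), "LIG")
  mc <- attr(fp, "metal_contacts")
  expect_equal(mc$ligand_atom, "O1")
  expect_equal(mc$dist, 2.1, tolerance = 1e-3) # PDB fixed-point precision

  fp <- compute_frame_ifp(fixture_frame(
    complex_spec("HIS", "caffeate", distance = 4.5,
                 metal = list(element = "ZN", distance = 3.5))), "LIG")
  expect_equal(nrow(attr(fp, "metal_contacts")), 0)

  fp <- compute_frame_ifp(fixture_frame(
    complex_spec("HIS", "caffeate", distance = 4.5)), "LIG")
  expect_equal(nrow(attr(fp, "metal_contacts")), 0)
})

test_that("salt-bridge fixture sets exactly the cation and donor bits", {
  b <- frame_bits(complex_spec("LYS", "acetate", distance = 3.0))
  expect_true(b[, "ionic_cation"])
  expect_true(b[, "hbond_donor"])
  expect_false(any(b[, setdiff(bit_cols,
                               c("ionic_cation", "hbond_donor"))]))
})

test_that("stacked-rings fixture sets F2F and hydrophobic together", {
  b <- frame_bits(complex_spec("PHE", "benzene", distance = 3.5,
                               ring_angle = 0))
  expect_true(b[, "aromatic_f2f"])
  expect_true(b[, "hydrophobic"])
  expect_false(any(b[, c("hbond_donor", "hbond_acceptor",
                         "ionic_cation", "ionic_anion")]))
})

test_that("a far ligand keeps residues in the map with all-false bits", {
  fx <- make_complex_fixture(complex_spec("LYS", "acetate", distance = 3))
  atoms <- read_pdb(fx$text)
  lig <- atoms$res_name == "LIG"
  atoms$x[lig] <- atoms$x[lig] + 50
  fp <- compute_frame_ifp(atoms, "LIG", site = "10")
  expect_equal(nrow(fp), 1)
  expect_false(any(as.matrix(as.data.frame(fp)[, bit_cols])))
  expect_equal(nrow(attr(fp, "metal_contacts")), 0)
})

test_that("engine bits equal the brute-force oracle on every sweep case", {
  cfg <- ifp_config()
  for (spec in detector_sweep_specs()) {
    frame <- fixture_frame(spec)
    fp <- compute_frame_ifp(frame, "LIG", site = "10", config = cfg)
    engine <- as.matrix(as.data.frame(fp)[, bit_cols])
    oracle <- oracle_frame_bits(frame, "LIG", cfg)
    expect_equal(unname(engine[1, ]), unname(oracle[1, ]),
                 label = paste(spec$residue, spec$motif, spec$distance,
                               spec$ring_angle, spec$hbond_angle))
    mc <- attr(fp, "metal_contacts")
    expect_equal(sort(mc$ligand_atom), oracle_metal_contacts(frame, "LIG",
                                                             cfg))
  }
})

test_that("fingerprints are invariant under rigid motion of the complex", {
  set.seed(7)
  fx <- make_complex_fixture(complex_spec("LYS", "acetate", distance = 3))
  ref <- compute_frame_ifp(read_pdb(fx$text), "LIG")
  refm <- as.matrix(as.data.frame(ref)[, bit_cols])
  for (k in 1:10) {
    moved <- apply_rigid(read_pdb(fx$text), random_rotation(),
                         runif(3, -30, 30))
    got <- as.matrix(as.data.frame(
      compute_frame_ifp(moved, "LIG"))[, bit_cols])
    expect_identical(got, refm)
  }
})

test_that("moving the ligand radially away never turns a bit on", {
  fx <- make_complex_fixture(complex_spec("LYS", "acetate", distance = 3))
  base <- read_pdb(fx$text)
  prev <- rep(TRUE, 7)
  for (shift in c(0, 1, 2, 4, 8, 16, 32)) {
    atoms <- base
    lig <- atoms$res_name == "LIG"
    atoms$x[lig] <- atoms$x[lig] + shift
    bits <- as.matrix(as.data.frame(
      compute_frame_ifp(atoms, "LIG", site = "10"))[, bit_cols])[1, ]
    expect_true(all(!bits | prev)) # once off, never back on
    prev <- bits
  }
})

test_that("series fingerprinting follows the bound schedule exactly", {
  traj <- make_trajectory_fixture(trajectory_spec(
    complex_spec("LYS", "acetate", distance = 3),
    n_frames = 8, bound_schedule = 0:2))
  fps <- direct_ifp_series(read_pdb(traj$text), "LIG")
  df <- as.data.frame(fps)
  any_bit <- rowSums(df[, bit_cols]) > 0
  expect_equal(df$frame[any_bit], 0:2)
  expect_equal(attr(fps, "n_frames"), 8)

  static <- make_trajectory_fixture(trajectory_spec(
    complex_spec("LYS", "acetate", distance = 3),
    n_frames = 10, bound_schedule = 0:9))
  sfps <- as.data.frame(direct_ifp_series(read_pdb(static$text), "LIG"))
  for (f in 1:9) {
    expect_equal(sfps[sfps$frame == f, bit_cols],
                 sfps[sfps$frame == 0, bit_cols],
                 ignore_attr = TRUE)
  }

  expect_error(direct_ifp_series(read_pdb(traj$text)[0, ], "LIG"),
               class = "ifpr_selection_error")
})

test_that("union-auto reports the same residue set in every frame", {
  traj <- make_trajectory_fixture(trajectory_spec(
    complex_spec("LYS", "acetate", distance = 3),
    n_frames = 6, bound_schedule = c(0L, 3L)))
  fps <- as.data.frame(direct_ifp_series(read_pdb(traj$text), "LIG",
                                         site = "union-auto"))
  per_frame <- split(paste(fps$chain, fps$res_seq), fps$frame)
  expect_true(all(vapply(per_frame, identical, logical(1),
                         per_frame[[1]])))
})

test_that("identical inputs give bit-identical series", {
  traj <- make_trajectory_fixture(trajectory_spec(
    complex_spec("SER", "acetate", distance = 2.8),
    n_frames = 5, bound_schedule = c(0L, 2L, 4L)))
  a <- direct_ifp_series(read_pdb(traj$text), "LIG")
  b <- direct_ifp_series(read_pdb(traj$text), "LIG")
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("tanimoto counts set bits with the all-zero convention", {
  expect_equal(tanimoto(c(TRUE, TRUE, FALSE, FALSE),
                        c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(tanimoto(c(TRUE, TRUE, FALSE, FALSE),
                        c(FALSE, FALSE, TRUE, TRUE)), 0.0)
  expect_equal(tanimoto(c(TRUE, TRUE, FALSE, FALSE),
                        c(TRUE, FALSE, TRUE, FALSE)), 1 / 3)
  expect_equal(tanimoto(logical(4), logical(4)), 1.0)
  expect_error(tanimoto(logical(3), logical(4)), "mismatch")

  fp1 <- compute_frame_ifp(fixture_frame(
    complex_spec("LYS", "acetate", distance = 3)), "LIG")
  expect_equal(tanimoto(fp1, fp1), 1.0)
})

test_that("threshold overrides flow through the config object", {
  spec <- complex_spec("ALA", "methane", distance = 4.0)
  tight <- ifp_config(hydrophobic_dist = 0.5)
  expect_false(frame_bits(spec, config = tight)[, "hydrophobic"])
  expect_error(ifp_config(hydrophobic_dist = -1), "positive")
})
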