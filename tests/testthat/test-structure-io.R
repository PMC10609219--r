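test_that("plain ATOM records parse with exact fields and one frame", {
  txt <- paste(
    "ATOM      1  N   LYS A 463      11.104  22.000  -3.250  1.00  0.00           N",
    "ATOM      2  CA  LYS A 463      12.500  22.100  -3.000  1.00  0.00           C",
    sep = "\n"
  )
  atoms <- read_pdb(txt)
  expect_equal(n_frames(atoms), 1)
  expect_equal(nrow(atoms), 2)
  expect_equal(atoms$name, c("N", "CA"))
  expect_equal(atoms$res_seq, c(463L, 463L))
  expect_equal(atoms$chain, c("A", "A"))
  expect_equal(atoms$x, c(11.104, 12.5))
  expect_equal(atoms$y, c(22.0, 22.1))
  expect_equal(atoms$z, c(-3.25, -3.0))
  expect_equal(atoms$element, c("N", "C"))
  expect_false(any(atoms$is_hetero))
})

test_that("MODEL blocks become frames and must agree on atom identity", {
  one <- function(model, x) paste0(
    "MODEL ", model, "\n",
    sprintf("ATOM      1  CA  GLY A   1    %8.3f   0.000   0.000  1.00  0.00           C\n", x),
    sprintf("ATOM      2  O   GLY A   1    %8.3f   1.000   0.000  1.00  0.00           O\n", x),
    "ENDMDL"
  )
  txt <- paste(one(1, 0), one(2, 1), one(3, 2), sep = "\n")
  atoms <- read_pdb(txt)
  expect_equal(n_frames(atoms), 3)
  expect_equal(sort(unique(atoms$frame)), 0:2)
  expect_equal(atoms$x[atoms$frame == 2 & atoms$name == "CA"], 2)

  bad <- paste(one(1, 0), gsub(" O ", " N ", one(2, 1)), sep = "\n")
  expect_error(read_pdb(bad), class = "ifpr_series_error")
})

test_that("unreadable ATOM records raise a parse error naming the line", {
  txt <- paste(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  GLY A   1       bad     wrong   text   1.00  0.00           C",
    sep = "\n"
  )
  expect_error(read_pdb(txt), "line 2", class = "ifpr_parse_error")
  expect_error(read_pdb("HEADER only\nEND"), class = "ifpr_parse_error")
})

test_that("loose whitespace-separated dialect is recovered", {
  txt <- "ATOM 1 CA GLY A 1 1.500 2.500 3.500 1.00 0.00 C"
  atoms <- read_pdb(txt)
  expect_equal(atoms$x, 1.5)
  expect_equal(atoms$res_seq, 1L)
  expect_equal(atoms$chain, "A")
})

test_that("alternate locations beyond A are dropped; insertion codes kept", {
  txt <- paste(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA BGLY A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      3  CA  GLY A   2A      2.000   0.000   0.000  1.00  0.00           C",
    sep = "\n"
  )
  atoms <- read_pdb(txt)
  expect_equal(nrow(atoms), 2)
  expect_equal(atoms$alt_loc, c("A", ""))
  expect_equal(atoms$i_code, c("", "A"))
})

test_that("fixture complexes round-trip through write_pdb/read_pdb", {
  for (spec in list(complex_spec("LYS", "acetate", distance = 3),
                    complex_spec("PHE", "benzene", distance = 3.5),
                    complex_spec("HIS", "caffeate", distance = 4.5,
                                 metal = list(element = "ZN",
                                              distance = 2.1)))) {
    fx <- make_complex_fixture(spec)
    back <- read_pdb(paste(write_pdb(fx$atoms), collapse = "\n"))
    expect_equal(nrow(back), nrow(fx$atoms))
    expect_identical(back$name, fx$atoms$name)
    expect_identical(back$res_name, fx$atoms$res_name)
    expect_identical(back$res_seq, fx$atoms$res_seq)
    expect_lt(max(abs(back$x - fx$atoms$x)), 1e-3)
    expect_lt(max(abs(back$y - fx$atoms$y)), 1e-3)
    expect_lt(max(abs(back$z - fx$atoms$z)), 1e-3)
  }
})

test_that("parsed coordinates agree with an independent PDB reader", {
  fx <- make_complex_fixture(complex_spec("LYS", "acetate", distance = 3))
  tf <- tempfile(fileext = ".pdb")
  writeLines(fx$text, tf)
  ours <- read_pdb(tf)
  ref <- bio3d::read.pdb(tf)
  expect_equal(nrow(ours), nrow(ref$atom))
  expect_equal(ours$x, ref$atom$x, tolerance = 1e-6)
  expect_equal(ours$y, ref$atom$y, tolerance = 1e-6)
  expect_equal(ours$z, ref$atom$z, tolerance = 1e-6)
  expect_equal(ours$name, ref$atom$elety)
  unlink(tf)
})

make_benzene_mol2 <- function(charges = FALSE, bad_bond = FALSE) {
  ang <- (0:5) * pi / 3
  atom_lines <- sprintf("%7d C%d %12.4f %9.4f %9.4f C.ar 1 BNZ%s",
                        1:6, 1:6, 1.39 * cos(ang), 1.39 * sin(ang), 0,
                        if (charges) sprintf(" %8.4f", seq(-0.1, 0.15,
                                                           by = 0.05))
                        else " 0.0000")
  bond_to <- c(2:6, if (bad_bond) 99 else 1)
  paste(c("@<TRIPOS>MOLECULE", "benzene", " 6 6 1", "SMALL",
          if (charges) "USER_CHARGES" else "NO_CHARGES", "",
          "@<TRIPOS>ATOM", atom_lines, "@<TRIPOS>BOND",
          sprintf("%6d %4d %4d ar", 1:6, 1:6, bond_to)),
        collapse = "\n")
}

test_that("MOL2 reading keeps verbatim bonds and SYBYL aromatic types", {
  m <- read_mol2(make_benzene_mol2())
  expect_equal(nrow(m$atoms), 6)
  expect_equal(nrow(m$bonds), 6)
  expect_true(all(m$atoms$aromatic))
  expect_true(all(m$bonds$type == "ar"))
  expect_equal(m$atoms$element, rep("C", 6))

  mc <- read_mol2(make_benzene_mol2(charges = TRUE))
  expect_equal(mc$atoms$charge, seq(-0.1, 0.15, by = 0.05), tolerance = 1e-6)

  expect_error(read_mol2(make_benzene_mol2(bad_bond = TRUE)),
               class = "ifpr_parse_error")
  expect_error(read_mol2("@<TRIPOS>MOLECULE\nno atoms"),
               class = "ifpr_parse_error")
})

test_that("PDBQT records parse through ROOT/BRANCH with AutoDock types", {
  txt <- paste(
    "ROOT",
    "ATOM      1  C1  LIG     1       0.000   0.000   0.000  1.00  0.00     0.050 A ",
    "ATOM      2  C2  LIG     1       1.390   0.000   0.000  1.00  0.00     0.050 A ",
    "ENDROOT",
    "BRANCH   2   3",
    "ATOM      3  O1  LIG     1       2.000   1.000   0.000  1.00  0.00    -0.350 OA",
    "ENDBRANCH   2   3",
    "TORSDOF 1",
    sep = "\n"
  )
  atoms <- read_pdbqt(txt)
  expect_equal(nrow(atoms), 3)
  expect_equal(atoms$element, c("C", "C", "O"))
  expect_equal(atoms$aromatic, c(TRUE, TRUE, FALSE))
  expect_equal(atoms$ad_type, c("A", "A", "OA"))
  expect_equal(atoms$charge, c(0.05, 0.05, -0.35), tolerance = 1e-6)
  expect_error(read_pdbqt(""), class = "ifpr_parse_error")
})

test_that("split_complex separates protein, ligand, metal and drops water", {
  fx <- make_complex_fixture(complex_spec("LYS", "acetate", distance = 3,
                                          metal = list(element = "ZN",
                                                       distance = 2.1)))
  atoms <- read_pdb(fx$text)
  hoh <- atoms[1, ]
  hoh$res_name <- "HOH"; hoh$res_seq <- 99L; hoh$name <- "O"
  hoh$element <- "O"; hoh$is_hetero <- TRUE
  atoms2 <- dplyr::bind_rows(atoms, hoh)
  parts <- split_complex(atoms2, "LIG")
  expect_setequal(unique(parts$protein$res_name), "LYS")
  expect_equal(unique(parts$ligand$res_name), "LIG")
  expect_equal(parts$metals$res_name, "ZN")
  expect_false(any(c(parts$protein$res_name, parts$ligand$res_name,
                     parts$metals$res_name) == "HOH"))

  expect_error(split_complex(atoms, "XYZ"), class = "ifpr_selection_error")

  two <- dplyr::bind_rows(atoms,
                          dplyr::mutate(atoms[atoms$res_name == "LIG", ],
                                        res_seq = 5L))
  expect_error(split_complex(two, "LIG"), "ambiguous",
               class = "ifpr_selection_error")
})
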