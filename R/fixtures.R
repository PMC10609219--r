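# Synthetic-complex generator: minimal PDB complexes with exactly
# controlled interaction geometry, and multi-frame trajectories with a
# scheduled bound/unbound ligand, so every detector, trace and table can be
# validated against a known answer without any external data.
#
# Residue side chains are idealized hard-coded internal coordinates (bond
# lengths within normal covalent ranges); ligand motifs likewise. The
# requested anchor distance / ring angle / H-bond angle is realized
# analytically and re-measured from the emitted coordinates.

fixture_atom <- function(name, element, x, y, z) {
  tibble(name = name, element = element, x = x, y = y, z = z)
}

# Shared backbone (N, CA, C, O); CA at the origin, side chain toward +x.
FIXTURE_BACKBONE <- tibble::tibble(
  name = c("N", "CA", "C", "O"),
  element = c("N", "C", "C", "O"),
  x = c(-0.72, 0.00, -0.76, -0.20),
  y = c(1.26, 0.00, -1.32, -2.44),
  z = c(0, 0, 0, 0)
)

fixture_residues <- function() {
  ring6 <- function(cx, cz) {
    ang <- c(180, 120, 60, 0, 300, 240) * pi / 180
    list(x = cx + 1.39 * cos(ang), z = cz + 1.39 * sin(ang))
  }
  phe_ring <- ring6(3.44, 1.43)
  list(
    GLY = list(atoms = NULL, anchor = "CA", u = c(1, 0, 0)),
    ALA = list(
      atoms = fixture_atom("CB", "C", 1.53, 0, 0),
      anchor = "CB", u = c(1, 0, 0)
    ),
    LYS = list(
      atoms = tibble(
        name = c("CB", "CG", "CD", "CE", "NZ", "HZ2", "HZ3"),
        element = c("C", "C", "C", "C", "N", "H", "H"),
        x = c(1.53, 2.04, 3.57, 4.08, 5.57, 5.23, 5.23),
        y = c(0, 0, 0, 0, 0, 0.95, -0.95),
        z = c(0, 1.44, 1.44, 0, 0, 0, 0)
      ),
      anchor = "NZ", u = c(1, 0, 0),
      pointing_h = list(name = "HZ1", heavy = "NZ", r = 1.01)
    ),
    SER = list(
      atoms = tibble(
        name = c("CB", "OG"),
        element = c("C", "O"),
        x = c(1.53, 2.00), y = c(0, 0), z = c(0, 1.34)
      ),
      anchor = "OG", u = c(0.47, 0, 1.34) / sqrt(0.47^2 + 1.34^2),
      pointing_h = list(name = "HG", heavy = "OG", r = 0.96)
    ),
    GLU = list(
      atoms = tibble(
        name = c("CB", "CG", "CD", "OE1", "OE2"),
        element = c("C", "C", "C", "O", "O"),
        x = c(1.53, 2.04, 3.55, 4.17, 4.17),
        y = c(0, 0, 0, 1.07, -1.07),
        z = c(0, 1.44, 1.44, 1.44, 1.44)
      ),
      anchor = "OE1", u = c(1, 0, 0)
    ),
    ASP = list(
      atoms = tibble(
        name = c("CB", "CG", "OD1", "OD2"),
        element = c("C", "C", "O", "O"),
        x = c(1.53, 2.04, 2.66, 2.66),
        y = c(0, 0, 1.07, -1.07),
        z = c(0, 1.44, 1.44, 1.44)
      ),
      anchor = "OD1", u = c(1, 0, 0)
    ),
    PHE = list(
      atoms = tibble(
        name = c("CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
        element = rep("C", 7),
        x = c(1.53, phe_ring$x),
        y = rep(0, 7),
        z = c(0, phe_ring$z)
      ),
      anchor = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
      u = c(0, 1, 0)
    ),
    HIS = list(
      atoms = tibble(
        name = c("CB", "CG", "ND1", "CE1", "NE2", "CD2", "HE2"),
        element = c("C", "C", "N", "C", "N", "C", "H"),
        x = c(1.53, 2.05, 2.856, 4.159, 4.159, 2.856, 4.976),
        y = rep(0, 7),
        z = c(0, 1.43, 2.539, 2.116, 0.744, 0.321, 0.150)
      ),
      anchor = c("CG", "ND1", "CE1", "NE2", "CD2"),
      u = c(0, 1, 0)
    )
  )
}

fixture_motifs <- function() {
  ang6 <- (0:5) * pi / 3
  list(
    benzene = list(
      atoms = tibble(
        name = paste0("C", 1:6), element = rep("C", 6),
        x = rep(0, 6), y = 1.39 * cos(ang6), z = 1.39 * sin(ang6)
      ),
      anchor = "centroid"
    ),
    acetate = list(
      atoms = tibble(
        name = c("O1", "C2", "O2", "C1"),
        element = c("O", "C", "O", "C"),
        x = c(0, 1.100, 1.218, 2.344),
        y = c(0, 0.600, 1.844, -0.220),
        z = c(0, 0, 0, 0)
      ),
      anchor = "O1"
    ),
    methylammonium = list(
      atoms = tibble(
        name = c("N1", "C1", "HN2", "HN3"),
        element = c("N", "C", "H", "H"),
        x = c(0, 1.04, 0.106, 0.106),
        y = c(0, 1.07, -0.573, -0.573),
        z = c(0, 0, 0.824, -0.824)
      ),
      anchor = "N1",
      pointing_h = list(name = "HN1", heavy = "N1", r = 1.01)
    ),
    methanol = list(
      atoms = tibble(
        name = c("O1", "C1"), element = c("O", "C"),
        x = c(0, 1.43), y = c(0, 0), z = c(0, 0)
      ),
      anchor = "O1",
      pointing_h = list(name = "HO1", heavy = "O1", r = 0.96)
    ),
    methane = list(
      atoms = tibble(
        name = c("C1", "H1", "H2", "H3", "H4"),
        element = c("C", "H", "H", "H", "H"),
        x = c(0, 0.629, 0.629, -0.629, -0.629),
        y = c(0, 0.629, -0.629, 0.629, -0.629),
        z = c(0, 0.629, -0.629, -0.629, 0.629)
      ),
      anchor = "C1"
    ),
    caffeate = list(
      atoms = tibble(
        name = c("O1", "O2", "C9", "C8", "C7", "C1", "C2", "C3", "C4",
                 "C5", "C6", "O3", "HO3", "O4", "HO4"),
        element = c("O", "O", "C", "C", "C", "C", "C", "C", "C", "C", "C",
                    "O", "H", "O", "H"),
        x = c(0, 1.083, 1.083, 2.356, 3.516, 4.986, 5.681, 7.071, 7.766,
              7.071, 5.681, 7.751, 8.231, 9.126, 10.086),
        y = c(0, -1.875, -0.625, 0.110, -0.560, -0.560, -1.764, -1.764,
              -0.560, 0.644, 0.644, -2.942, -3.773, -0.560, -0.560),
        z = rep(0, 15)
      ),
      anchor = "O1"
    )
  )
}

#' Specification of a synthetic protein-ligand complex
#'
#' @param residue Residue kind: one of
#'   `"GLY"`, `"ALA"`, `"LYS"`, `"SER"`, `"GLU"`, `"ASP"`, `"PHE"`, `"HIS"`.
#' @param motif Ligand motif: `"benzene"`, `"acetate"`, `"methylammonium"`,
#'   `"methanol"`, `"methane"`, `"caffeate"`.
#' @param distance Anchor-to-anchor distance in Angstrom (atom-to-atom, or
#'   centroid-to-centroid for ring pairs). Must exceed 0.4.
#' @param ring_angle Interplanar angle in degrees for aromatic pairs
#'   (0 = parallel stacking, 90 = T-shaped).
#' @param hbond_angle Realized D-H...A angle in degrees for the pointing
#'   hydrogen of the donor side (default 180: hydrogen on the donor-acceptor
#'   line).
#' @param metal Optional `list(element =, distance =)` placing a monoatomic
#'   ion near the ligand anchor (e.g. `list(element = "ZN", distance = 2.1)`).
#' @return A validated list of class `complex_spec`.
#' @export
complex_spec <- function(residue, motif, distance = 3.5, ring_angle = 0,
                         hbond_angle = 180, metal = NULL) {
  residue <- toupper(residue)
  if (!residue %in% names(fixture_residues())) {
    abort(sprintf("unknown fixture residue kind '%s'", residue),
          class = "ifpr_error")
  }
  if (!motif %in% names(fixture_motifs())) {
    abort(sprintf("unknown ligand motif '%s'", motif), class = "ifpr_error")
  }
  if (distance <= 0.4) {
    abort("fixture distance must exceed 0.4 Angstrom", class = "ifpr_error")
  }
  if (ring_angle < 0 || ring_angle > 180 ||
      hbond_angle < 0 || hbond_angle > 180) {
    abort("fixture angles must lie in [0, 180] degrees",
          class = "ifpr_error")
  }
  structure(list(residue = residue, motif = motif, distance = distance,
                 ring_angle = ring_angle, hbond_angle = hbond_angle,
                 metal = metal),
            class = "complex_spec")
}

rotation_to <- function(u) {
  u <- u / sqrt(sum(u^2))
  v0 <- if (abs(u[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
  v <- v0 - sum(v0 * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  cbind(u, v, w)
}

rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3)
}

anchor_point <- function(atoms, anchor) {
  if (identical(anchor, "centroid")) {
    colMeans(coords_mat(atoms))
  } else if (length(anchor) > 1) {
    colMeans(coords_mat(atoms[atoms$name %in% anchor, ]))
  } else {
    as.numeric(atoms[atoms$name == anchor, c("x", "y", "z")])
  }
}

# place H at distance r from donor D so that the D-H...A angle equals theta
aim_hydrogen <- function(d_pos, a_pos, r, theta) {
  u <- (a_pos - d_pos)
  u <- u / sqrt(sum(u^2))
  if (theta >= 180 - 1e-9) return(d_pos + r * u)
  p0 <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  p <- p0 - sum(p0 * u) * u
  p <- p / sqrt(sum(p^2))
  h_at <- function(psi) d_pos + r * (cos(psi) * u + sin(psi) * p)
  f <- function(psi) angle_deg(h_at(psi), d_pos, a_pos) - theta
  psi <- uniroot(f, c(1e-9, pi - 1e-9), tol = 1e-12)$root
  h_at(psi)
}

finish_atoms <- function(df, res_name, chain, res_seq, hetero) {
  tibble(
    frame = 0L, serial = 0L, name = df$name, alt_loc = "",
    res_name = res_name, chain = chain, res_seq = as.integer(res_seq),
    i_code = "", x = df$x, y = df$y, z = df$z, occupancy = 1,
    element = df$element, is_hetero = hetero, charge = NA_real_
  )
}

#' Build a synthetic protein-ligand complex as PDB text
#'
#' Emits one idealized residue (with backbone), one ligand motif placed so
#' that the requested interaction distance and angles hold analytically, and
#' optionally a metal ion near the ligand anchor. The realized geometry is
#' re-measured from the emitted coordinates and echoed in the `measured`
#' sidecar table.
#'
#' @param spec A [complex_spec()].
#' @return List of class `ifp_fixture`: `text` (PDB text), `atoms` (atom
#'   tibble), `measured` (tibble `quantity`, `value`).
#' @examples
#' fx <- make_complex_fixture(complex_spec("PHE", "benzene",
#'                                         distance = 3.5, ring_angle = 0))
#' fx$measured
#' @export
make_complex_fixture <- function(spec) {
  stopifnot(inherits(spec, "complex_spec"))
  rdef <- fixture_residues()[[spec$residue]]
  mdef <- fixture_motifs()[[spec$motif]]
  res_atoms <- bind_rows(FIXTURE_BACKBONE, rdef$atoms)
  res_anchor <- anchor_point(res_atoms, rdef$anchor)
  u <- rdef$u

  lig_local <- mdef$atoms
  lxyz <- coords_mat(lig_local)
  if (identical(mdef$anchor, "centroid") && spec$ring_angle != 0) {
    lxyz <- lxyz %*% t(rot_y(spec$ring_angle))
  }
  lig_anchor_global <- res_anchor + spec$distance * u
  r3 <- rotation_to(u)
  gxyz <- sweep(lxyz %*% t(r3), 2, lig_anchor_global, "+")
  lig_atoms <- lig_local
  lig_atoms$x <- gxyz[, 1]; lig_atoms$y <- gxyz[, 2]; lig_atoms$z <- gxyz[, 3]

  # pointing hydrogens: protein donor aimed at the ligand anchor, ligand
  # donor aimed at the residue anchor, realizing the requested D-H...A angle
  if (!is.null(rdef$pointing_h)) {
    d_pos <- anchor_point(res_atoms, rdef$pointing_h$heavy)
    h <- aim_hydrogen(d_pos, lig_anchor_global, rdef$pointing_h$r,
                      spec$hbond_angle)
    res_atoms <- bind_rows(res_atoms,
                           fixture_atom(rdef$pointing_h$name, "H",
                                        h[1], h[2], h[3]))
  }
  if (!is.null(mdef$pointing_h)) {
    d_pos <- anchor_point(lig_atoms, mdef$pointing_h$heavy)
    h <- aim_hydrogen(d_pos, res_anchor, mdef$pointing_h$r,
                      spec$hbond_angle)
    lig_atoms <- bind_rows(lig_atoms,
                           fixture_atom(mdef$pointing_h$name, "H",
                                        h[1], h[2], h[3]))
  }

  atoms <- bind_rows(
    finish_atoms(res_atoms, spec$residue, "A", 10, FALSE),
    finish_atoms(lig_atoms, "LIG", "", 1, TRUE)
  )
  if (!is.null(spec$metal)) {
    # approach along the bond from the anchor's heavy neighbour, pointing
    # outward, so the ion does not collide with the rest of the ligand
    apos <- anchor_point(lig_atoms, mdef$anchor)
    heavy <- lig_atoms[lig_atoms$element != "H" &
                         lig_atoms$name != mdef$anchor[1], ]
    if (identical(mdef$anchor, "centroid") || nrow(heavy) == 0) {
      v <- as.numeric(r3 %*% c(0, -1, 0))
    } else {
      dn <- sqrt((heavy$x - apos[1])^2 + (heavy$y - apos[2])^2 +
                   (heavy$z - apos[3])^2)
      nb <- which.min(dn)
      v <- apos - c(heavy$x[nb], heavy$y[nb], heavy$z[nb])
      v <- v / sqrt(sum(v^2))
    }
    mpos <- apos + spec$metal$distance * as.numeric(v)
    msym <- normalize_element(spec$metal$element)
    matoms <- fixture_atom(toupper(msym), msym, mpos[1], mpos[2], mpos[3])
    atoms <- bind_rows(atoms, finish_atoms(matoms, toupper(msym), "", 2,
                                           TRUE))
  }
  atoms$serial <- seq_len(nrow(atoms))

  measured <- fixture_measurements(atoms, spec, rdef, mdef)
  text <- paste(write_pdb(atoms), collapse = "\n")
  structure(list(text = text, atoms = atoms, measured = measured),
            class = "ifp_fixture")
}

fixture_measurements <- function(atoms, spec, rdef, mdef) {
  res <- atoms[!atoms$is_hetero, ]
  lig <- atoms[atoms$res_name == "LIG", ]
  res_anchor <- anchor_point(res, rdef$anchor)
  lig_anchor <- anchor_point(lig, mdef$anchor)
  rows <- tibble(quantity = "anchor_distance",
                 value = sqrt(sum((res_anchor - lig_anchor)^2)))
  if (length(rdef$anchor) > 1 && identical(mdef$anchor, "centroid")) {
    g <- ring_geometry(coords_mat(res[res$name %in% rdef$anchor, ]),
                       coords_mat(lig[lig$element == "C", ]))
    rows <- bind_rows(rows, tibble(quantity = "ring_angle", value = g$theta))
  }
  ph <- rdef$pointing_h %||% mdef$pointing_h
  if (!is.null(ph)) {
    side <- if (!is.null(rdef$pointing_h)) res else lig
    other_anchor <- if (!is.null(rdef$pointing_h)) lig_anchor else res_anchor
    hpos <- anchor_point(side, ph$name)
    dpos <- anchor_point(side, ph$heavy)
    rows <- bind_rows(rows, tibble(
      quantity = "hbond_angle",
      value = angle_deg(hpos, dpos, other_anchor)
    ))
  }
  if (!is.null(spec$metal)) {
    met <- atoms[atoms$res_seq == 2 & atoms$is_hetero &
                   atoms$res_name != "LIG", ]
    rows <- bind_rows(rows, tibble(
      quantity = "metal_distance",
      value = sqrt(sum((anchor_point(met, met$name[1]) - lig_anchor)^2))
    ))
  }
  rows
}

#' @export
print.ifp_fixture <- function(x, ...) {
  nf <- length(unique(x$atoms$frame))
  cat(sprintf("<ifp_fixture> %d atoms, %d frame%s\n",
              nrow(x$atoms[x$atoms$frame == x$atoms$frame[1], ]), nf,
              if (nf > 1) "s" else ""))
  print(x$measured)
  invisible(x)
}

#' Specification of a synthetic snapshot trajectory
#'
#' @param base A [complex_spec()] describing the bound geometry.
#' @param n_frames Number of snapshots.
#' @param bound_schedule 0-based frame indices in which the ligand is bound
#'   (others have the ligand displaced far from the site). May be empty.
#' @param unbound_displacement Displacement in Angstrom applied along +x for
#'   unbound frames (default 50, far beyond every cutoff).
#' @param jitter_sd Gaussian positional noise (Angstrom) applied to ligand
#'   atoms; 0 gives a fully deterministic trajectory.
#' @param seed RNG seed used when `jitter_sd > 0`.
#' @return List of class `trajectory_spec`.
#' @export
trajectory_spec <- function(base, n_frames, bound_schedule = integer(),
                            unbound_displacement = 50, jitter_sd = 0,
                            seed = 1L) {
  stopifnot(inherits(base, "complex_spec"))
  bound_schedule <- as.integer(bound_schedule)
  if (length(bound_schedule) > 0 &&
      (min(bound_schedule) < 0 || max(bound_schedule) >= n_frames)) {
    abort("bound_schedule indices must lie in [0, n_frames)",
          class = "ifpr_error")
  }
  structure(list(base = base, n_frames = as.integer(n_frames),
                 bound_schedule = bound_schedule,
                 unbound_displacement = unbound_displacement,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "trajectory_spec")
}

#' Build a synthetic multi-MODEL trajectory as PDB text
#'
#' Frames listed in the bound schedule carry the bound geometry of the base
#' complex; all other frames translate the ligand by the unbound
#' displacement along +x, far outside every interaction cutoff. Optional
#' Gaussian jitter (ligand atoms only, so the schedule stays an exact
#' oracle) is deterministic for a fixed seed.
#'
#' @param tspec A [trajectory_spec()].
#' @return `ifp_fixture` list: `text` (multi-MODEL PDB), `atoms`
#'   (multi-frame tibble), `measured` (bound-geometry sidecar).
#' @export
make_trajectory_fixture <- function(tspec) {
  stopifnot(inherits(tspec, "trajectory_spec"))
  base <- make_complex_fixture(tspec$base)
  lig_mask <- base$atoms$res_name == "LIG"
  if (tspec$jitter_sd > 0) set.seed(tspec$seed)
  frames <- lapply(seq_len(tspec$n_frames) - 1L, function(f) {
    a <- base$atoms
    a$frame <- f
    if (!f %in% tspec$bound_schedule) {
      a$x[lig_mask] <- a$x[lig_mask] + tspec$unbound_displacement
    }
    if (tspec$jitter_sd > 0) {
      nl <- sum(lig_mask)
      a$x[lig_mask] <- a$x[lig_mask] + rnorm(nl, 0, tspec$jitter_sd)
      a$y[lig_mask] <- a$y[lig_mask] + rnorm(nl, 0, tspec$jitter_sd)
      a$z[lig_mask] <- a$z[lig_mask] + rnorm(nl, 0, tspec$jitter_sd)
    }
    a
  })
  atoms <- bind_rows(frames)
  attr(atoms, "n_frames") <- tspec$n_frames
  text <- paste(write_pdb(atoms), collapse = "\n")
  structure(list(text = text, atoms = atoms, measured = base$measured),
            class = "ifp_fixture")
}

#' Write a named set of example fixtures to a directory
#'
#' Generates one representative complex per interaction type plus a
#' scheduled trajectory, as plain PDB files -- the `fixtures` CLI
#' subcommand.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed for the jittered trajectory.
#' @return Invisibly, the paths written.
#' @export
write_fixture_set <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sets <- list(
    salt_bridge = complex_spec("LYS", "acetate", distance = 3.0),
    stacking_f2f = complex_spec("PHE", "benzene", distance = 3.5,
                                ring_angle = 0),
    stacking_e2f = complex_spec("PHE", "benzene", distance = 5.0,
                                ring_angle = 90),
    hbond_donor = complex_spec("SER", "acetate", distance = 2.8),
    hbond_acceptor = complex_spec("GLU", "methanol", distance = 2.9),
    ionic_anion = complex_spec("ASP", "methylammonium", distance = 3.0),
    hydrophobic = complex_spec("ALA", "methane", distance = 4.0),
    zinc_contact = complex_spec("HIS", "caffeate", distance = 4.5,
                                metal = list(element = "ZN",
                                             distance = 2.1))
  )
  paths <- character()
  for (nm in names(sets)) {
    p <- file.path(dir, paste0(nm, ".pdb"))
    writeLines(make_complex_fixture(sets[[nm]])$text, p)
    paths <- c(paths, p)
  }
  traj <- make_trajectory_fixture(trajectory_spec(
    sets$salt_bridge, n_frames = 8, bound_schedule = 0:2,
    jitter_sd = 0, seed = seed
  ))
  p <- file.path(dir, "trajectory.pdb")
  writeLines(traj$text, p)
  invisible(c(paths, p))
}
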