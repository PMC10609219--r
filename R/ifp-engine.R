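# The direct-IFP core: seven geometric interaction detectors evaluated for
# every (binding-site residue, ligand) pair in every frame, emitting
# per-frame bit vectors, plus ligand-metal contact detection.

# Fixed bit order of the per-residue fingerprint.
BIT_NAMES <- c(
  "hydrophobic", "aromatic_f2f", "aromatic_e2f",
  "hbond_donor", "hbond_acceptor", "ionic_cation", "ionic_anion"
)

# Hotspot-table labels, protein perspective (e.g. "H-bond (Donor)" means the
# protein residue donates the hydrogen).
TYPE_LABELS <- c(
  hydrophobic = "Hydrophobic",
  aromatic_f2f = "Aromatic (Face to face)",
  aromatic_e2f = "Aromatic (Edge to face)",
  hbond_donor = "H-bond (Donor)",
  hbond_acceptor = "H-bond (Acceptor)",
  ionic_cation = "Ionic (Cation)",
  ionic_anion = "Ionic (Anion)"
)

#' Geometric thresholds and switches for fingerprint detection
#'
#' Defaults follow the classical seven-type structural-IFP convention; every
#' value is overridable. Ties at exactly a cutoff are inclusive.
#'
#' @param hydrophobic_dist Max apolar-apolar distance (Angstrom).
#' @param hbond_dist Max donor-acceptor heavy-atom distance.
#' @param hbond_angle Min D-H...A angle in degrees (applied only when the
#'   donor carries explicit hydrogens; hydrogen-free structures fall back to
#'   the distance criterion alone).
#' @param ionic_dist Max minimum heavy-atom distance between a cation group
#'   and an anion group.
#' @param f2f_dist,f2f_angle Face-to-face stacking: max ring-centroid
#'   distance and max interplanar angle (degrees).
#' @param e2f_dist,e2f_angle Edge-to-face stacking: max centroid distance
#'   and min interplanar angle.
#' @param metal_dist Max metal to ligand N/O/S distance.
#' @param site_cutoff Ligand-proximity cutoff (Angstrom) for automatic
#'   binding-site residue selection.
#' @param his_charged Treat histidines as protonated cations?
#' @param planarity_tol Aromatic ring planarity tolerance (Angstrom).
#' @return A list of class `ifp_config`.
#' @export
ifp_config <- function(hydrophobic_dist = 4.5,
                       hbond_dist = 3.5, hbond_angle = 135,
                       ionic_dist = 4.0,
                       f2f_dist = 4.5, f2f_angle = 30,
                       e2f_dist = 5.5, e2f_angle = 60,
                       metal_dist = 2.8,
                       site_cutoff = 6.0,
                       his_charged = FALSE,
                       planarity_tol = 0.10) {
  cfg <- list(
    hydrophobic_dist = hydrophobic_dist, hbond_dist = hbond_dist,
    hbond_angle = hbond_angle, ionic_dist = ionic_dist,
    f2f_dist = f2f_dist, f2f_angle = f2f_angle,
    e2f_dist = e2f_dist, e2f_angle = e2f_angle,
    metal_dist = metal_dist, site_cutoff = site_cutoff,
    his_charged = isTRUE(his_charged), planarity_tol = planarity_tol
  )
  num <- cfg[setdiff(names(cfg), "his_charged")]
  if (any(!vapply(num, is.numeric, logical(1))) ||
      any(unlist(num) <= 0)) {
    abort("all ifp_config thresholds must be positive numbers",
          class = "ifpr_error")
  }
  structure(cfg, class = "ifp_config")
}

min_pair_dist <- function(xyz_a, xyz_b) {
  if (nrow(xyz_a) == 0 || nrow(xyz_b) == 0) return(Inf)
  d2 <- outer(rowSums(xyz_a^2), rowSums(xyz_b^2), "+") -
    2 * (xyz_a %*% t(xyz_b))
  sqrt(max(0, min(d2)))
}

roles_xyz <- function(roles, idx) {
  coords_mat(roles$atoms[idx, , drop = FALSE])
}

#' Hydrophobic contact detector
#'
#' TRUE iff some apolar protein atom and some apolar ligand atom lie within
#' the hydrophobic distance cutoff (default 4.5 Angstrom).
#'
#' @param res_roles,lig_roles `ifp_roles` for the residue and the ligand.
#' @param config An [ifp_config()].
#' @return Logical scalar.
#' @export
detect_hydrophobic <- function(res_roles, lig_roles, config = ifp_config()) {
  min_pair_dist(roles_xyz(res_roles, res_roles$apolar),
                roles_xyz(lig_roles, lig_roles$apolar)) <=
    config$hydrophobic_dist
}

ring_geometry <- function(xyz_a, xyz_b) {
  pa <- fit_plane(xyz_a)
  pb <- fit_plane(xyz_b)
  d <- sqrt(sum((pa$centroid - pb$centroid)^2))
  cosang <- abs(sum(pa$normal * pb$normal))
  theta <- acos(pmin(1, cosang)) * 180 / pi
  list(d = d, theta = theta)
}

#' Aromatic stacking detector
#'
#' For each (protein ring, ligand ring) pair let `d` be the centroid
#' distance and `theta` the acute angle between the least-squares ring
#' planes. Face-to-face requires `d <= 4.5` and `theta <= 30` degrees;
#' edge-to-face requires `d <= 5.5` and `theta >= 60`. Intermediate angles
#' set neither bit, so the two geometries are mutually exclusive for a
#' single ring pair.
#'
#' @inheritParams detect_hydrophobic
#' @return Named logical vector `c(f2f = , e2f = )`.
#' @export
detect_aromatic <- function(res_roles, lig_roles, config = ifp_config()) {
  f2f <- FALSE; e2f <- FALSE
  for (ra in res_roles$rings) {
    for (rb in lig_roles$rings) {
      g <- ring_geometry(roles_xyz(res_roles, ra), roles_xyz(lig_roles, rb))
      if (g$d <= config$f2f_dist && g$theta <= config$f2f_angle) f2f <- TRUE
      if (g$d <= config$e2f_dist && g$theta >= config$e2f_angle) e2f <- TRUE
    }
  }
  c(f2f = f2f, e2f = e2f)
}

angle_deg <- function(at, a, b) {
  # angle at vertex `at` between points a and b
  v1 <- a - at; v2 <- b - at
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

hbond_hit <- function(donor_roles, acceptor_roles, config) {
  acc <- acceptor_roles$acceptors
  if (length(acc) == 0 || length(donor_roles$donors) == 0) return(FALSE)
  axyz <- roles_xyz(acceptor_roles, acc)
  dxyz_all <- coords_mat(donor_roles$atoms)
  for (don in donor_roles$donors) {
    dpos <- dxyz_all[don$heavy, ]
    dd <- sqrt(rowSums(sweep(axyz, 2, dpos)^2))
    for (k in which(dd <= config$hbond_dist)) {
      if (length(don$hydrogens) == 0) return(TRUE)
      ang <- vapply(don$hydrogens, function(h) {
        angle_deg(dxyz_all[h, ], dpos, axyz[k, ])
      }, numeric(1))
      if (max(ang) >= config$hbond_angle) return(TRUE)
    }
  }
  FALSE
}

#' Hydrogen-bond detector
#'
#' A donor heavy atom D and acceptor A on the opposite molecule form a bond
#' iff `dist(D, A) <= 3.5` Angstrom and, when D carries at least one
#' explicit hydrogen, the best D-H...A angle is >= 135 degrees. Without
#' hydrogens (common in MD snapshot exports) the distance criterion alone
#' decides.
#'
#' @inheritParams detect_hydrophobic
#' @return Named logical vector `c(protein_donor = , protein_acceptor = )`.
#' @export
detect_hbond <- function(res_roles, lig_roles, config = ifp_config()) {
  c(protein_donor = hbond_hit(res_roles, lig_roles, config),
    protein_acceptor = hbond_hit(lig_roles, res_roles, config))
}

ionic_hit <- function(cation_roles, cations, anion_roles, anions, config) {
  for (cg in cations) {
    for (ag in anions) {
      if (min_pair_dist(roles_xyz(cation_roles, cg),
                        roles_xyz(anion_roles, ag)) <= config$ionic_dist) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Ionic (salt-bridge) detector
#'
#' A protein cation group and ligand anion group interact iff their minimum
#' heavy-atom group-to-group distance is <= 4.0 Angstrom (and symmetrically
#' for protein anion / ligand cation).
#'
#' @inheritParams detect_hydrophobic
#' @return Named logical vector `c(protein_cation = , protein_anion = )`.
#' @export
detect_ionic <- function(res_roles, lig_roles, config = ifp_config()) {
  c(protein_cation = ionic_hit(res_roles, res_roles$cations,
                               lig_roles, lig_roles$anions, config),
    protein_anion = ionic_hit(lig_roles, lig_roles$cations,
                              res_roles, res_roles$anions, config))
}

#' Ligand-metal contact detector
#'
#' Reports ligand N/O/S atoms within the metal cutoff (default 2.8 Angstrom)
#' of a metal ion. Contacts are stored per frame alongside (not inside) the
#' seven-bit residue vectors, mirroring hotspot tables that tabulate
#' residue interactions only.
#'
#' @param metals Atom tibble of metal ions (from [split_complex()]).
#' @param lig_roles Ligand `ifp_roles`.
#' @param config An [ifp_config()].
#' @return Tibble with columns `metal_name`, `metal_serial`, `ligand_atom`,
#'   `ligand_serial`, `dist`.
#' @export
detect_metal_contact <- function(metals, lig_roles, config = ifp_config()) {
  out <- tibble(metal_name = character(), metal_serial = integer(),
                ligand_atom = character(), ligand_serial = integer(),
                dist = numeric())
  polar <- which(lig_roles$atoms$element %in% c("N", "O", "S"))
  if (is.null(metals) || nrow(metals) == 0 || length(polar) == 0) return(out)
  lxyz <- roles_xyz(lig_roles, polar)
  for (m in seq_len(nrow(metals))) {
    mpos <- c(metals$x[m], metals$y[m], metals$z[m])
    d <- sqrt(rowSums(sweep(lxyz, 2, mpos)^2))
    hit <- which(d <= config$metal_dist)
    if (length(hit) > 0) {
      out <- bind_rows(out, tibble(
        metal_name = metals$name[m], metal_serial = metals$serial[m],
        ligand_atom = lig_roles$atoms$name[polar[hit]],
        ligand_serial = lig_roles$atoms$serial[polar[hit]],
        dist = d[hit]
      ))
    }
  }
  out
}

split_residues <- function(protein) {
  if (nrow(protein) == 0) return(list())
  split(protein, residue_key(protein))
}

site_residue_keys <- function(protein, ligand, site, config) {
  if (is.character(site) && length(site) == 1 && site %in%
      c("auto", "union-auto")) {
    heavy_p <- protein[protein$element != "H", ]
    heavy_l <- ligand[ligand$element != "H", ]
    if (nrow(heavy_p) == 0) return(character())
    d2 <- outer(rowSums(coords_mat(heavy_p)^2),
                rowSums(coords_mat(heavy_l)^2), "+") -
      2 * coords_mat(heavy_p) %*% t(coords_mat(heavy_l))
    near <- sqrt(pmax(0, apply(d2, 1, min))) <= config$site_cutoff
    unique(residue_key(heavy_p[near, ]))
  } else {
    # explicit selection: residue sequence numbers, optionally "chain/seq"
    keys <- residue_key(protein)
    seqs <- protein$res_seq
    sel <- as.character(site)
    hit <- rep(FALSE, nrow(protein))
    for (s in sel) {
      if (grepl("/", s, fixed = TRUE)) {
        parts <- strsplit(s, "/", fixed = TRUE)[[1]]
        hit <- hit | (protein$chain == parts[1] &
                        seqs == as.integer(parts[2]))
      } else {
        hit <- hit | seqs == as.integer(s)
      }
    }
    unique(keys[hit])
  }
}

residue_bits <- function(res_roles, lig_roles, config) {
  ar <- detect_aromatic(res_roles, lig_roles, config)
  hb <- detect_hbond(res_roles, lig_roles, config)
  io <- detect_ionic(res_roles, lig_roles, config)
  setNames(c(detect_hydrophobic(res_roles, lig_roles, config),
             ar[["f2f"]], ar[["e2f"]],
             hb[["protein_donor"]], hb[["protein_acceptor"]],
             io[["protein_cation"]], io[["protein_anion"]]),
           BIT_NAMES)
}

#' Compute the interaction fingerprint of one frame
#'
#' Splits the frame into protein/ligand/metals, perceives roles, selects the
#' binding site and runs all detectors for every selected residue. Residues
#' whose bits are all FALSE are still reported, so the residue set (and thus
#' the bitstring layout) is stable.
#'
#' @param frame Single-frame atom tibble.
#' @param ligand Ligand selector (see [split_complex()]).
#' @param site `"auto"` (residues with any heavy atom within
#'   `config$site_cutoff` of any ligand heavy atom) or an explicit vector of
#'   residue numbers / `"chain/number"` strings.
#' @param config An [ifp_config()].
#' @return Tibble with residue identity columns and one logical column per
#'   fingerprint bit (`hydrophobic`, `aromatic_f2f`, `aromatic_e2f`,
#'   `hbond_donor`, `hbond_acceptor`, `ionic_cation`, `ionic_anion`), in
#'   residue-number order. Metal contacts are attached as the
#'   `metal_contacts` attribute.
#' @examples
#' fx <- make_complex_fixture(complex_spec("LYS", "acetate", distance = 3))
#' fp <- compute_frame_ifp(read_pdb(fx$text), "LIG")
#' fp[, c("res_name", "res_seq", "hbond_donor", "ionic_cation")]
#' @export
compute_frame_ifp <- function(frame, ligand, site = "auto",
                              config = ifp_config()) {
  parts <- split_complex(frame, ligand)
  lig_roles <- assign_ligand_roles(parts$ligand)
  keys <- site_residue_keys(parts$protein, parts$ligand, site, config)
  res_list <- split_residues(parts$protein)
  res_list <- res_list[names(res_list) %in% keys]
  rows <- lapply(res_list, function(res) {
    roles <- assign_protein_roles(res, his_charged = config$his_charged)
    if (is.null(roles)) return(NULL)
    bits <- residue_bits(roles, lig_roles, config)
    bind_cols(tibble(chain = roles$id$chain, res_seq = roles$id$res_seq,
                     i_code = roles$id$i_code, res_name = roles$id$res_name),
              as_tibble(as.list(bits)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) == 0) {
    bind_cols(tibble(chain = character(), res_seq = integer(),
                     i_code = character(), res_name = character()),
              as_tibble(setNames(rep(list(logical()), 7), BIT_NAMES)))
  } else {
    arrange(bind_rows(rows), .data$chain, .data$res_seq, .data$i_code)
  }
  attr(out, "metal_contacts") <- detect_metal_contact(parts$metals,
                                                      lig_roles, config)
  attr(out, "frame") <- frame$frame[1]
  out
}

#' Direct interaction fingerprints over a snapshot series
#'
#' Runs [compute_frame_ifp()] on every frame in order. With
#' `site = "union-auto"` (the default) the binding site is the union of the
#' per-frame automatic selections, so every frame reports the same residue
#' set and per-frame bitstrings align.
#'
#' @param series Multi-frame atom tibble from [read_pdb()].
#' @param ligand Ligand selector.
#' @param site `"union-auto"`, `"auto"` (per-frame selection), or an
#'   explicit residue list.
#' @param config An [ifp_config()].
#' @return A tibble of class `ifp_series`: one row per (frame, residue) with
#'   the seven bit columns. Attributes: `n_frames`, `metal_contacts` (tibble
#'   with a `frame` column), `config`.
#' @export
direct_ifp_series <- function(series, ligand, site = "union-auto",
                              config = ifp_config()) {
  frames <- sort(unique(series$frame))
  if (length(frames) == 0) {
    abort_selection("empty snapshot series: no frames to fingerprint")
  }
  if (identical(site, "union-auto")) {
    keys <- character()
    for (f in frames) {
      parts <- split_complex(get_frame(series, f), ligand)
      keys <- union(keys,
                    site_residue_keys(parts$protein, parts$ligand, "auto",
                                      config))
    }
    # convert keys (chain/seq/icode/name) back to explicit chain/seq selectors
    site <- vapply(strsplit(keys, "/", fixed = TRUE), function(p) {
      paste(p[1], p[2], sep = "/")
    }, character(1))
    if (length(site) == 0) site <- character()
  }
  fps <- lapply(frames, function(f) {
    fp <- compute_frame_ifp(get_frame(series, f), ligand, site, config)
    mc <- attr(fp, "metal_contacts")
    if (nrow(mc) > 0) mc$frame <- f
    list(fp = mutate(fp, frame = f, .before = 1), mc = mc)
  })
  out <- bind_rows(lapply(fps, `[[`, "fp"))
  mcs <- bind_rows(lapply(fps, `[[`, "mc"))
  structure(out,
            class = c("ifp_series", class(tibble())),
            n_frames = length(frames),
            metal_contacts = mcs,
            config = config)
}

fingerprint_matrix <- function(fp) {
  as.matrix(as_tibble(fp)[, BIT_NAMES])
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|` over concatenated bitstrings, defined as 1.0 when
#' both fingerprints are all-zero. Inputs must have equal length and, for
#' fingerprint tables, identical residue ordering.
#'
#' @param fp_a,fp_b Logical vectors, or fingerprint tibbles from
#'   [compute_frame_ifp()] (bits are flattened in residue order).
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  flatten <- function(fp) {
    if (is.data.frame(fp)) as.vector(t(fingerprint_matrix(fp)))
    else as.logical(fp)
  }
  if (is.data.frame(fp_a) && is.data.frame(fp_b)) {
    ka <- residue_key(fp_a); kb <- residue_key(fp_b)
    if (!identical(ka, kb)) {
      abort("fingerprints cover different residue sets or orders",
            class = "ifpr_error")
    }
  }
  a <- flatten(fp_a); b <- flatten(fp_b)
  if (length(a) != length(b)) {
    abort("fingerprint length mismatch", class = "ifpr_error")
  }
  both <- sum(a & b)
  either <- sum(a | b)
  if (either == 0) return(1.0)
  both / either
}

#' Render a fingerprint series as per-frame bitstrings
#'
#' One line per frame: the frame index followed by a 7-character 0/1 block
#' per residue (bit order `r paste(BIT_NAMES, collapse = ", ")`), preceded by
#' a header naming the residues.
#'
#' @param series An `ifp_series`.
#' @return Character vector of text lines.
#' @export
ifp_bitstrings <- function(series) {
  df <- as_tibble(series)
  frames <- sort(unique(df$frame))
  f0 <- df[df$frame == frames[1], ]
  labels <- residue_label(f0$res_name, f0$res_seq, f0$i_code)
  lines <- c(paste("# residues:", paste(labels, collapse = " ")))
  for (f in frames) {
    d <- df[df$frame == f, ]
    blocks <- apply(fingerprint_matrix(d), 1, function(r) {
      paste(as.integer(r), collapse = "")
    })
    lines <- c(lines, paste(f, paste(blocks, collapse = " ")))
  }
  lines
}

bitstrings_table <- function(series) {
  df <- as_tibble(series)
  frames <- sort(unique(df$frame))
  f0 <- df[df$frame == frames[1], ]
  labels <- residue_label(f0$res_name, f0$res_seq, f0$i_code)
  rows <- lapply(frames, function(f) {
    d <- df[df$frame == f, ]
    blocks <- apply(fingerprint_matrix(d), 1, function(r) {
      paste(as.integer(r), collapse = "")
    })
    as_tibble(c(list(frame_index = f), setNames(as.list(blocks), labels)))
  })
  bind_rows(rows)
}
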