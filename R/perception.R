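# Interaction-role perception. Protein residues are template-driven (atom
# names against a shipped role table); ligands are inference-driven (bonds,
# rings, and functional-group ionization rules at pH 7.4).

BOND_SLACK <- 0.45 # Angstrom added to the covalent-radius sum
BOND_MIN <- 0.4

the <- new.env(parent = emptyenv())

#' Residue role template table
#'
#' The template shipped at `inst/extdata/residue_roles.tsv` maps atom names
#' of the 20 standard amino acids to interaction roles (apolar, donor,
#' acceptor, cation/anion group membership, aromatic-ring membership).
#' An alternative file in the same format may be supplied via
#' `options(ifpr.residue_templates = "path")` to cover nonstandard residues.
#'
#' @return Tibble with columns `res_name`, `atom_name`, `roles`.
#' @export
residue_templates <- function() {
  path <- getOption("ifpr.residue_templates",
                    system.file("extdata", "residue_roles.tsv",
                                package = "ifpr"))
  key <- paste0("tmpl:", path)
  if (is.null(the[[key]])) {
    raw <- readLines(path, warn = FALSE)
    raw <- raw[!startsWith(raw, "#")]
    d <- utils::read.delim(text = paste(raw, collapse = "\n"),
                           stringsAsFactors = FALSE)
    the[[key]] <- as_tibble(d)
  }
  the[[key]]
}

coords_mat <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

#' Infer covalent bonds from interatomic distances
#'
#' Atoms i and j are bonded iff
#' `dist(i, j) <= r_cov(i) + r_cov(j) + 0.45` Angstrom and `dist > 0.4`,
#' with covalent radii from a built-in table. Needed for ligands given as
#' PDB, which carries no bond block.
#'
#' @param atoms Atom tibble (heavy atoms and hydrogens).
#' @return Tibble with columns `i`, `j` (row indices into `atoms`, i < j)
#'   and `dist`.
#' @export
infer_bonds <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2) return(tibble(i = integer(), j = integer(), dist = numeric()))
  xyz <- coords_mat(atoms)
  dm <- as.matrix(stats::dist(xyz))
  r <- covalent_radius(atoms$element)
  thr <- outer(r, r, "+") + BOND_SLACK
  hit <- dm <= thr & dm > BOND_MIN
  hit[lower.tri(hit, diag = TRUE)] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  tibble(i = idx[, 1], j = idx[, 2], dist = dm[idx])
}

adjacency <- function(n, bonds) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# Shortest cycle through each bond (BFS with the bond removed); unique
# cycles of size 5 or 6 are candidate rings.
find_small_rings <- function(n, bonds, max_size = 6) {
  adj <- adjacency(n, bonds)
  rings <- list()
  seen <- character()
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$i[k]; b <- bonds$j[k]
    # BFS from a to b avoiding the direct edge
    prev <- rep(NA_integer_, n)
    depth <- rep(NA_integer_, n)
    depth[a] <- 0L
    queue <- a
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (depth[v] >= max_size - 1) next
      for (w in adj[[v]]) {
        if ((v == a && w == b)) next
        if (is.na(depth[w])) {
          depth[w] <- depth[v] + 1L
          prev[w] <- v
          if (w == b) {
            queue <- integer()
            break
          }
          queue <- c(queue, w)
        }
      }
    }
    if (!is.na(depth[b])) {
      path <- b
      while (path[1] != a) path <- c(prev[path[1]], path)
      ring <- sort(path)
      key <- paste(ring, collapse = "-")
      if (!key %in% seen && length(ring) >= 3 && length(ring) <= max_size) {
        seen <- c(seen, key)
        rings[[length(rings) + 1]] <- ring
      }
    }
  }
  rings
}

# Least-squares plane through points; returns unit normal and max deviation.
fit_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  m <- sweep(xyz, 2, ctr)
  sv <- svd(m)
  if (sv$d[2] < 1e-6) {
    abort_geometry("degenerate (collinear) ring coordinates: plane undefined")
  }
  normal <- sv$v[, 3]
  list(centroid = ctr, normal = normal / sqrt(sum(normal^2)),
       max_dev = max(abs(m %*% sv$v[, 3])))
}

#' Perceive aromatic rings in a ligand
#'
#' Smallest rings are found by cycle detection over the bond graph. A ring is
#' aromatic iff all members are C/N/O/S heavy atoms, the ring has 5 or 6
#' members, it is planar (no member further than 0.10 Angstrom from the
#' least-squares ring plane), and every ring carbon has at most 3 heavy-atom
#' neighbours. When SYBYL aromatic types are available (MOL2 input) they
#' override the geometric test.
#'
#' @param atoms Atom tibble.
#' @param bonds Bond tibble from [infer_bonds()] or a MOL2 BOND block; when
#'   `NULL`, bonds are inferred.
#' @param aromatic_flags Optional logical vector (per atom): SYBYL `.ar`
#'   typing; rings whose members are all flagged are accepted directly.
#' @param planarity_tol Max out-of-plane deviation in Angstrom (default 0.10).
#' @return List of integer vectors (row indices of ring member atoms).
#' @export
perceive_rings <- function(atoms, bonds = NULL, aromatic_flags = NULL,
                           planarity_tol = 0.10) {
  if (is.null(bonds)) bonds <- infer_bonds(atoms)
  heavy <- atoms$element != "H"
  hb <- bonds[heavy[bonds$i] & heavy[bonds$j], ]
  rings <- find_small_rings(nrow(atoms), hb, max_size = 6)
  rings <- Filter(function(r) length(r) %in% c(5, 6), rings)
  heavy_deg <- tabulate(c(hb$i, hb$j), nbins = nrow(atoms))
  keep <- vapply(rings, function(r) {
    el <- atoms$element[r]
    if (!all(el %in% c("C", "N", "O", "S"))) return(FALSE)
    if (!is.null(aromatic_flags) && all(aromatic_flags[r])) return(TRUE)
    carbons <- r[el == "C"]
    if (any(heavy_deg[carbons] > 3)) return(FALSE)
    pl <- fit_plane(coords_mat(atoms[r, ]))
    pl$max_dev <= planarity_tol
  }, logical(1))
  rings[keep]
}

empty_roles <- function(atoms, id = NULL) {
  structure(list(
    id = id, atoms = atoms, apolar = integer(), rings = list(),
    donors = list(), acceptors = integer(),
    cations = list(), anions = list()
  ), class = "ifp_roles")
}

#' @export
print.ifp_roles <- function(x, ...) {
  cat("<ifp_roles>",
      if (!is.null(x$id)) paste0(" ", x$id$res_name, x$id$res_seq), "\n",
      sep = "")
  cat(sprintf(
    "  %d atoms | apolar %d | rings %d | donors %d | acceptors %d | cations %d | anions %d\n",
    nrow(x$atoms), length(x$apolar), length(x$rings), length(x$donors),
    length(x$acceptors), length(x$cations), length(x$anions)
  ))
  invisible(x)
}

attach_hydrogens <- function(atoms, heavy_idx) {
  # hydrogens bonded to each donor heavy atom, by distance within the group
  h_idx <- which(atoms$element == "H")
  if (length(h_idx) == 0) {
    return(lapply(heavy_idx, function(i) integer()))
  }
  xyz <- coords_mat(atoms)
  lapply(heavy_idx, function(i) {
    d <- sqrt(colSums((t(xyz[h_idx, , drop = FALSE]) - xyz[i, ])^2))
    thr <- covalent_radius(atoms$element[i]) + 0.31 + BOND_SLACK
    h_idx[d <= thr & d > BOND_MIN]
  })
}

#' Assign interaction roles to one protein residue
#'
#' Template-driven: atom names are matched against [residue_templates()].
#' Backbone N is a donor and backbone O an acceptor for every residue.
#' Apolar atoms, cation groups (LYS NZ; ARG guanidinium), anion groups
#' (ASP/GLU carboxylates), aromatic rings (PHE/TYR/HIS; two for TRP) and
#' side-chain donors/acceptors follow the template. A residue carrying OXT
#' contributes a terminal carboxylate anion group. Histidine is neutral by
#' default (NE2 donor, ND1 acceptor); `his_charged = TRUE` makes it a cation
#' with both ring nitrogens protonated.
#'
#' @param residue Atom tibble for a single residue (hydrogens optional).
#' @param his_charged Treat histidine as protonated (cationic)?
#' @return An `ifp_roles` object, or `NULL` (with a warning) for residues
#'   not covered by the template.
#' @export
assign_protein_roles <- function(residue, his_charged = FALSE) {
  rn <- toupper(residue$res_name[1])
  tmpl <- residue_templates()
  covered <- union(STANDARD_AA, setdiff(unique(tmpl$res_name), "ALL"))
  if (!rn %in% covered) {
    warn(sprintf("residue %s%s not in role template: skipped",
                 rn, residue$res_seq[1]))
    return(NULL)
  }
  rows <- tmpl[tmpl$res_name %in% c(rn, "ALL"), ]
  id <- list(chain = residue$chain[1], res_seq = residue$res_seq[1],
             i_code = residue$i_code[1], res_name = rn)
  rs <- empty_roles(residue, id)
  role_of <- setNames(rows$roles, rows$atom_name)
  idx_of <- function(an) match(an, residue$name)
  donors_heavy <- integer()
  ring_groups <- list()
  cation_groups <- list()
  anion_groups <- list()
  for (an in names(role_of)) {
    i <- idx_of(an)
    if (is.na(i)) next
    roles <- strsplit(role_of[[an]], ",")[[1]]
    for (r in roles) {
      if (r == "apolar") rs$apolar <- c(rs$apolar, i)
      else if (r == "donor") donors_heavy <- c(donors_heavy, i)
      else if (r == "acceptor") rs$acceptors <- c(rs$acceptors, i)
      else if (startsWith(r, "ring")) ring_groups[[r]] <- c(ring_groups[[r]], i)
      else if (startsWith(r, "cation")) cation_groups[[r]] <- c(cation_groups[[r]], i)
      else if (startsWith(r, "anion")) anion_groups[[r]] <- c(anion_groups[[r]], i)
    }
  }
  if (rn == "HIS" && his_charged) {
    nd1 <- idx_of("ND1"); ne2 <- idx_of("NE2")
    grp <- c(nd1, ne2)
    grp <- grp[!is.na(grp)]
    if (length(grp) > 0) cation_groups[["cationH"]] <- grp
    if (!is.na(nd1)) donors_heavy <- c(donors_heavy, nd1)
    rs$acceptors <- setdiff(rs$acceptors, grp)
  }
  # terminal carboxylate when OXT present
  if ("OXT" %in% residue$name && "O" %in% residue$name) {
    anion_groups[["anionT"]] <- c(idx_of("O"), idx_of("OXT"))
  }
  rs$rings <- Filter(function(r) length(r) >= 5, unname(ring_groups))
  rs$cations <- unname(cation_groups)
  rs$anions <- unname(anion_groups)
  donors_heavy <- unique(donors_heavy)
  hs <- attach_hydrogens(residue, donors_heavy)
  rs$donors <- Map(function(i, h) list(heavy = i, hydrogens = h),
                   donors_heavy, hs)
  rs
}

#' Assign interaction roles to a ligand
#'
#' Inference-driven, with rule-based ionization at physiological pH (7.4):
#' a carboxylic acid (carbon bonded to two oxygens, at least one terminal)
#' is deprotonated into an anion group over both oxygens; an aliphatic amine
#' nitrogen (sp3, no adjacent carbonyl, not aromatic) is protonated into a
#' cation; phenol/alcohol oxygens are donor + acceptor; carbonyl, carboxylate
#' and ether oxygens are acceptors; any N-H is a donor and bare imine or
#' aromatic nitrogens are acceptors; apolar atoms are carbons/sulfurs with no
#' bonded N/O; aromatic rings come from [perceive_rings()].
#'
#' @param atoms Ligand atom tibble (PDB-derived), or an `ifp_mol2` object
#'   from [read_mol2()] (its explicit bonds and SYBYL aromatic types are
#'   used directly).
#' @param bonds Optional bond tibble (columns `i`, `j`); inferred when
#'   missing.
#' @param pH Assay pH; the shipped rules encode the 7.4 behaviour (acids
#'   deprotonated below, amines protonated above their typical pKa).
#' @return An `ifp_roles` object.
#' @export
assign_ligand_roles <- function(atoms, bonds = NULL, pH = 7.4) {
  aromatic_flags <- NULL
  if (inherits(atoms, "ifp_mol2")) {
    m <- atoms
    atoms <- tibble(
      frame = 0L, serial = m$atoms$serial, name = m$atoms$name,
      alt_loc = "", res_name = m$atoms$res_name, chain = "",
      res_seq = m$atoms$res_seq, i_code = "",
      x = m$atoms$x, y = m$atoms$y, z = m$atoms$z, occupancy = 1,
      element = m$atoms$element, is_hetero = TRUE, charge = m$atoms$charge
    )
    if (nrow(m$bonds) > 0) {
      pos <- match(seq_along(m$atoms$serial), order(m$atoms$serial))
      map <- setNames(seq_len(nrow(atoms)), m$atoms$serial)
      bonds <- tibble(i = unname(map[as.character(m$bonds$origin)]),
                      j = unname(map[as.character(m$bonds$target)]))
      xyz <- coords_mat(atoms)
      bonds$dist <- sqrt(rowSums((xyz[bonds$i, , drop = FALSE] -
                                    xyz[bonds$j, , drop = FALSE])^2))
    }
    aromatic_flags <- m$atoms$aromatic
  }
  if (is.null(bonds)) bonds <- infer_bonds(atoms)
  if ("aromatic" %in% names(atoms) && is.null(aromatic_flags)) {
    aromatic_flags <- atoms$aromatic
  }
  n <- nrow(atoms)
  el <- atoms$element
  adj <- adjacency(n, bonds)
  heavy_nb <- lapply(adj, function(v) v[el[v] != "H"])
  h_nb <- lapply(adj, function(v) v[el[v] == "H"])
  heavy_deg <- lengths(heavy_nb)
  id <- list(chain = atoms$chain[1], res_seq = atoms$res_seq[1],
             i_code = atoms$i_code[1] %||% "",
             res_name = atoms$res_name[1])
  rs <- empty_roles(atoms, id)
  rs$rings <- perceive_rings(atoms, bonds, aromatic_flags = aromatic_flags)
  ring_members <- unlist(rs$rings)
  xyz <- coords_mat(atoms)
  bond_len <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  is_carbonyl_c <- vapply(seq_len(n), function(i) {
    el[i] == "C" && any(vapply(heavy_nb[[i]], function(j) {
      el[j] == "O" && bond_len(i, j) <= 1.32
    }, logical(1)))
  }, logical(1))

  handled_o <- integer()
  # carboxylic acids / carboxylates -> anion group over both oxygens
  for (i in which(el == "C")) {
    os <- heavy_nb[[i]][el[heavy_nb[[i]]] == "O"]
    if (length(os) == 2 && any(heavy_deg[os] == 1)) {
      rs$anions[[length(rs$anions) + 1]] <- os
      rs$acceptors <- c(rs$acceptors, os)
      handled_o <- c(handled_o, os)
    }
  }
  donors_heavy <- integer()
  for (i in which(el == "O")) {
    if (i %in% handled_o) next
    nb <- heavy_nb[[i]]
    if (heavy_deg[i] == 1 && el[nb] == "C" && is_carbonyl_c[nb] &&
        bond_len(i, nb) <= 1.32) {
      rs$acceptors <- c(rs$acceptors, i) # carbonyl oxygen
    } else if (heavy_deg[i] == 1 && el[nb] == "C") {
      # alcohol / phenol oxygen: donor + acceptor (with or without explicit H)
      donors_heavy <- c(donors_heavy, i)
      rs$acceptors <- c(rs$acceptors, i)
    } else if (heavy_deg[i] == 2) {
      rs$acceptors <- c(rs$acceptors, i) # ether/ester oxygen
    }
  }
  for (i in which(el == "N")) {
    aromatic_n <- i %in% ring_members
    nb <- heavy_nb[[i]]
    aliphatic_amine <- !aromatic_n && length(nb) > 0 &&
      all(el[nb] == "C") && !any(is_carbonyl_c[nb]) && heavy_deg[i] <= 3
    if (aliphatic_amine && pH < 10) {
      rs$cations[[length(rs$cations) + 1]] <- i
    }
    if (length(h_nb[[i]]) > 0 || aliphatic_amine) {
      donors_heavy <- c(donors_heavy, i)
    } else if (heavy_deg[i] <= 2) {
      rs$acceptors <- c(rs$acceptors, i) # imine / aromatic nitrogen
    }
  }
  rs$apolar <- which(el %in% c("C", "S") & vapply(seq_len(n), function(i) {
    !any(el[heavy_nb[[i]]] %in% c("N", "O"))
  }, logical(1)))
  donors_heavy <- unique(donors_heavy)
  rs$donors <- Map(function(i, h) list(heavy = i, hydrogens = h),
                   donors_heavy, h_nb[donors_heavy])
  rs$acceptors <- unique(rs$acceptors)
  rs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
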