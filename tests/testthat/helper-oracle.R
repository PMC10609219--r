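# Independent brute-force evaluator for the seven detectors. Roles are
# shared with the package (the role model is not under test here), but all
# geometry is recomputed with plain loops, and ring normals use an
# edge-cross-product construction rather than the engine's SVD plane fit.

oracle_dist <- function(p, q) sqrt(sum((p - q)^2))

oracle_xyz <- function(roles, idx) {
  a <- roles$atoms[idx, , drop = FALSE]
  cbind(a$x, a$y, a$z)
}

oracle_min_dist <- function(xa, xb) {
  best <- Inf
  for (i in seq_len(nrow(xa))) {
    for (j in seq_len(nrow(xb))) {
      best <- min(best, oracle_dist(xa[i, ], xb[j, ]))
    }
  }
  best
}

# ring normal from sign-aligned cross products over all vertex triples;
# independent of both vertex ordering and the engine's SVD plane fit
oracle_ring_normal <- function(xyz) {
  m <- nrow(xyz)
  n <- c(0, 0, 0)
  ref <- NULL
  for (i in 2:(m - 1)) {
    for (j in (i + 1):m) {
      a <- xyz[i, ] - xyz[1, ]
      b <- xyz[j, ] - xyz[1, ]
      cr <- c(a[2] * b[3] - a[3] * b[2],
              a[3] * b[1] - a[1] * b[3],
              a[1] * b[2] - a[2] * b[1])
      len <- sqrt(sum(cr^2))
      if (len < 1e-8) next
      cr <- cr / len
      if (is.null(ref)) ref <- cr
      if (sum(cr * ref) < 0) cr <- -cr
      n <- n + cr
    }
  }
  n / sqrt(sum(n^2))
}

oracle_angle_at <- function(at, p, q) {
  v1 <- p - at
  v2 <- q - at
  acos(min(1, max(-1, sum(v1 * v2) /
                    sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
}

oracle_residue_bits <- function(res_roles, lig_roles, cfg = ifp_config()) {
  hydro <- FALSE
  xa <- oracle_xyz(res_roles, res_roles$apolar)
  xb <- oracle_xyz(lig_roles, lig_roles$apolar)
  if (nrow(xa) > 0 && nrow(xb) > 0) {
    hydro <- oracle_min_dist(xa, xb) <= cfg$hydrophobic_dist
  }

  f2f <- FALSE; e2f <- FALSE
  for (ra in res_roles$rings) {
    for (rb in lig_roles$rings) {
      pa <- oracle_xyz(res_roles, ra)
      pb <- oracle_xyz(lig_roles, rb)
      d <- oracle_dist(colMeans(pa), colMeans(pb))
      cosang <- abs(sum(oracle_ring_normal(pa) * oracle_ring_normal(pb)))
      th <- acos(min(1, cosang)) * 180 / pi
      if (d <= cfg$f2f_dist && th <= cfg$f2f_angle) f2f <- TRUE
      if (d <= cfg$e2f_dist && th >= cfg$e2f_angle) e2f <- TRUE
    }
  }

  hb_pair <- function(don_roles, acc_roles) {
    don_xyz <- cbind(don_roles$atoms$x, don_roles$atoms$y, don_roles$atoms$z)
    for (don in don_roles$donors) {
      for (ai in acc_roles$acceptors) {
        apos <- oracle_xyz(acc_roles, ai)[1, ]
        dpos <- don_xyz[don$heavy, ]
        if (oracle_dist(dpos, apos) > cfg$hbond_dist) next
        if (length(don$hydrogens) == 0) return(TRUE)
        for (h in don$hydrogens) {
          if (oracle_angle_at(don_xyz[h, ], dpos, apos) >= cfg$hbond_angle) {
            return(TRUE)
          }
        }
      }
    }
    FALSE
  }

  ionic_pair <- function(cat_roles, cats, an_roles, ans) {
    for (cg in cats) {
      for (ag in ans) {
        if (oracle_min_dist(oracle_xyz(cat_roles, cg),
                            oracle_xyz(an_roles, ag)) <= cfg$ionic_dist) {
          return(TRUE)
        }
      }
    }
    FALSE
  }

  c(hydrophobic = hydro, aromatic_f2f = f2f, aromatic_e2f = e2f,
    hbond_donor = hb_pair(res_roles, lig_roles),
    hbond_acceptor = hb_pair(lig_roles, res_roles),
    ionic_cation = ionic_pair(res_roles, res_roles$cations,
                              lig_roles, lig_roles$anions),
    ionic_anion = ionic_pair(lig_roles, lig_roles$cations,
                             res_roles, res_roles$anions))
}

# whole-frame oracle: same splitting/roles, independent geometry
oracle_frame_bits <- function(frame, ligand = "LIG", cfg = ifp_config()) {
  parts <- split_complex(frame, ligand)
  lig_roles <- assign_ligand_roles(parts$ligand)
  res_groups <- split(parts$protein,
                      paste(parts$protein$chain, parts$protein$res_seq))
  out <- lapply(res_groups, function(res) {
    roles <- assign_protein_roles(res, his_charged = cfg$his_charged)
    if (is.null(roles)) return(NULL)
    oracle_residue_bits(roles, lig_roles, cfg)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

oracle_metal_contacts <- function(frame, ligand = "LIG",
                                  cfg = ifp_config()) {
  parts <- split_complex(frame, ligand)
  lig <- parts$ligand
  hits <- character()
  for (m in seq_len(nrow(parts$metals))) {
    for (i in seq_len(nrow(lig))) {
      if (!lig$element[i] %in% c("N", "O", "S")) next
      d <- oracle_dist(c(parts$metals$x[m], parts$metals$y[m],
                         parts$metals$z[m]),
                       c(lig$x[i], lig$y[i], lig$z[i]))
      if (d <= cfg$metal_dist) hits <- c(hits, lig$name[i])
    }
  }
  sort(hits)
}

# numeric minimization oracle for the optimal-superposition RMSD:
# axis-angle rotation + translation, multiple restarts
oracle_min_rmsd <- function(mobile, reference, n_starts = 8) {
  obj <- function(par) {
    th <- sqrt(sum(par[1:3]^2))
    k <- if (th < 1e-12) diag(3) else {
      ax <- par[1:3] / th
      km <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0),
                   3, 3)
      diag(3) + sin(th) * km + (1 - cos(th)) * (km %*% km)
    }
    moved <- sweep(mobile %*% t(k), 2, par[4:6], "+")
    sqrt(mean(rowSums((moved - reference)^2)))
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    p0 <- c(rnorm(3, 0, if (s == 1) 1e-3 else 1.5),
            colMeans(reference) - colMeans(mobile))
    fit <- optim(p0, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}
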