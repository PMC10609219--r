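# Structure file reading/writing: PDB (single and multi-MODEL snapshot
# series), Tripos MOL2 (via bio3d), PDBQT. Atoms are represented as a tidy
# tibble, one row per atom per frame.

ATOM_COLS <- c(
  "frame", "serial", "name", "alt_loc", "res_name", "chain", "res_seq",
  "i_code", "x", "y", "z", "occupancy", "element", "is_hetero", "charge"
)

source_lines <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (length(source) == 1) {
    strsplit(source, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(source)
  }
}

# Whitespace-split fallback for loose MD-exported PDB dialects where the
# fixed columns are broken (e.g. serial overflow shifting fields).
parse_atom_line_loose <- function(line) {
  tok <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(tok) < 8) return(NULL)
  num <- function(i) suppressWarnings(as.numeric(tok[i]))
  has_chain <- is.na(num(5)) && nchar(tok[5]) == 1
  i <- if (has_chain) 6L else 5L
  res_seq <- suppressWarnings(as.integer(gsub("[A-Za-z]$", "", tok[i])))
  i_code <- ifelse(grepl("[A-Za-z]$", tok[i]), substr(tok[i], nchar(tok[i]),
                                                      nchar(tok[i])), "")
  xyz <- c(num(i + 1), num(i + 2), num(i + 3))
  if (any(is.na(xyz)) || is.na(res_seq)) return(NULL)
  occ <- num(i + 4)
  last <- tok[length(tok)]
  element <- if (grepl("^[A-Za-z]{1,2}$", last) && length(tok) > i + 4) {
    last
  } else {
    ""
  }
  list(
    serial = suppressWarnings(as.integer(tok[2])), name = tok[3],
    alt_loc = "", res_name = tok[4],
    chain = if (has_chain) tok[5] else "", res_seq = res_seq,
    i_code = i_code, x = xyz[1], y = xyz[2], z = xyz[3],
    occupancy = if (is.na(occ)) 1 else occ, element = element
  )
}

#' Read a PDB file or text into a snapshot series
#'
#' Parses `ATOM`/`HETATM` records with fixed-column rules, falling back to
#' whitespace splitting on malformed lines (MD exporters produce loose PDB).
#' Each `MODEL` block becomes one frame; a file without `MODEL` records
#' yields exactly one frame (index 0). Insertion codes are preserved as part
#' of residue identity, and alternate locations other than blank or `'A'`
#' are dropped so a single conformer remains.
#'
#' @param source Path to a PDB file, or PDB text (single string or character
#'   vector of lines).
#' @return A tibble with one row per atom per frame and columns
#'   `frame` (0-based), `serial`, `name`, `alt_loc`, `res_name`, `chain`,
#'   `res_seq`, `i_code`, `x`, `y`, `z` (Angstrom), `occupancy`, `element`,
#'   `is_hetero`, `charge`. The attribute `n_frames` holds the frame count.
#'   Multi-frame input is validated so every frame carries the identical
#'   atom sequence; inconsistency is an error.
#' @examples
#' pdb <- make_complex_fixture(complex_spec("LYS", "acetate", distance = 3))
#' atoms <- read_pdb(pdb$text)
#' dplyr::count(atoms, res_name)
#' @export
read_pdb <- function(source) {
  lines <- source_lines(source)
  is_model <- startsWith(lines, "MODEL")
  is_atom <- grepl("^ATOM\\s|^HETATM", lines)
  if (!any(is_atom)) abort_parse("no ATOM/HETATM records found in PDB input")
  block <- cumsum(is_model)
  idx <- which(is_atom)
  al <- lines[idx]
  fr <- block[idx]
  if (any(is_model)) {
    keep <- fr >= 1
    idx <- idx[keep]; al <- al[keep]; fr <- fr[keep] - 1L
  }
  df <- tibble(
    frame = as.integer(fr),
    serial = suppressWarnings(as.integer(substr(al, 7, 11))),
    name = trimws(substr(al, 13, 16)),
    alt_loc = trimws(substr(al, 17, 17)),
    res_name = trimws(substr(al, 18, 20)),
    chain = trimws(substr(al, 22, 22)),
    res_seq = suppressWarnings(as.integer(substr(al, 23, 26))),
    i_code = trimws(substr(al, 27, 27)),
    x = suppressWarnings(as.numeric(substr(al, 31, 38))),
    y = suppressWarnings(as.numeric(substr(al, 39, 46))),
    z = suppressWarnings(as.numeric(substr(al, 47, 54))),
    occupancy = suppressWarnings(as.numeric(substr(al, 55, 60))),
    element = trimws(substr(al, 77, 78)),
    is_hetero = startsWith(al, "HETATM"),
    charge = NA_real_
  )
  bad <- which(is.na(df$x) | is.na(df$y) | is.na(df$z) | is.na(df$res_seq))
  for (b in bad) {
    loose <- parse_atom_line_loose(al[b])
    if (is.null(loose)) {
      abort_parse(sprintf("unreadable ATOM/HETATM record at line %d: '%s'",
                          idx[b], al[b]))
    }
    for (f in names(loose)) df[[f]][b] <- loose[[f]]
  }
  df$occupancy[is.na(df$occupancy)] <- 1
  df <- filter(df, .data$alt_loc %in% c("", "A"))
  no_el <- df$element == "" | is.na(df$element)
  df$element[no_el] <- guess_element(df$name[no_el], df$res_name[no_el],
                                     df$is_hetero[no_el])
  df$element <- normalize_element(df$element)
  validate_series(df)
}

validate_series <- function(atoms) {
  frames <- sort(unique(atoms$frame))
  sig <- function(f) {
    d <- atoms[atoms$frame == f, ]
    paste(d$name, d$res_name, d$res_seq, d$chain, d$i_code, collapse = "|")
  }
  if (length(frames) > 1) {
    ref <- sig(frames[1])
    for (f in frames[-1]) {
      if (!identical(sig(f), ref)) {
        ifp_abort(
          sprintf("inconsistent atom list across MODELs: frame %d differs from frame %d",
                  f, frames[1]),
          "ifpr_series_error"
        )
      }
    }
  }
  attr(atoms, "n_frames") <- length(frames)
  atoms
}

#' Number of frames in an atom table
#' @param atoms An atom tibble from [read_pdb()] or the fixture generators.
#' @return Integer frame count.
#' @export
n_frames <- function(atoms) {
  nf <- attr(atoms, "n_frames")
  if (is.null(nf)) nf <- length(unique(atoms$frame))
  nf
}

#' Extract one frame from a snapshot series
#' @param atoms Atom tibble.
#' @param frame 0-based frame index.
#' @return Atom tibble restricted to that frame.
#' @export
get_frame <- function(atoms, frame) {
  out <- atoms[atoms$frame == frame, ]
  if (nrow(out) == 0) {
    abort_selection(sprintf("frame %s not present in series", frame))
  }
  attr(out, "n_frames") <- 1L
  out
}

format_pdb_lines <- function(d) {
  rec <- ifelse(d$is_hetero, "HETATM", "ATOM  ")
  nm <- ifelse(nchar(d$name) < 4, paste0(" ", d$name), d$name)
  sprintf(
    "%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, d$serial, nm, d$alt_loc, d$res_name,
    ifelse(d$chain == "", " ", d$chain), d$res_seq,
    ifelse(d$i_code == "", " ", d$i_code),
    d$x, d$y, d$z, d$occupancy, 0, toupper(d$element)
  )
}

#' Write an atom table as PDB text
#'
#' Multi-frame tables are written as `MODEL`/`ENDMDL` blocks (1-based model
#' numbers); single frames as a flat record list. Coordinates are fixed-point
#' with three decimals, so a round-trip through [read_pdb()] agrees to
#' 1e-3 Angstrom.
#'
#' @param atoms Atom tibble.
#' @param path Optional output file; when `NULL` the text is returned.
#' @return Invisibly (or visibly when `path` is `NULL`) the PDB text lines.
#' @export
write_pdb <- function(atoms, path = NULL) {
  frames <- sort(unique(atoms$frame))
  if (length(frames) == 1) {
    out <- c(format_pdb_lines(atoms), "END")
  } else {
    out <- unlist(lapply(seq_along(frames), function(i) {
      c(sprintf("MODEL %8d", i),
        format_pdb_lines(atoms[atoms$frame == frames[i], ]),
        "ENDMDL")
    }))
    out <- c(out, "END")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Read a Tripos MOL2 file
#'
#' Backed by [bio3d::read.mol2()]. Bonds are taken verbatim from the BOND
#' block (no inference) and SYBYL atom types are retained so aromatic typing
#' (e.g. `C.ar`) can drive role assignment directly.
#'
#' @param source Path to a MOL2 file, or MOL2 text.
#' @return A list of class `ifp_mol2` with elements `atoms` (tibble:
#'   `serial`, `name`, `x`, `y`, `z`, `sybyl_type`, `element`, `aromatic`,
#'   `res_name`, `res_seq`, `charge`) and `bonds` (tibble: `origin`,
#'   `target`, `type`).
#' @export
read_mol2 <- function(source) {
  lines <- source_lines(source)
  if (!any(grepl("@<TRIPOS>ATOM", lines, fixed = TRUE))) {
    abort_parse("MOL2 input has no @<TRIPOS>ATOM block")
  }
  tf <- tempfile(fileext = ".mol2")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  m <- tryCatch(bio3d::read.mol2(tf),
                error = function(e) abort_parse(paste("MOL2 parse failed:",
                                                      conditionMessage(e))))
  a <- m$atom
  atoms <- tibble(
    serial = as.integer(a$eleno), name = a$elena,
    x = a$x, y = a$y, z = a$z,
    sybyl_type = a$elety,
    element = normalize_element(sub("\\..*$", "", a$elety)),
    aromatic = grepl("\\.ar$", a$elety),
    res_name = if (!is.null(a$resid)) a$resid else "LIG",
    res_seq = if (!is.null(a$resno)) as.integer(a$resno) else 1L,
    charge = if (!is.null(a$charge)) as.numeric(a$charge) else NA_real_
  )
  bonds <- if (!is.null(m$bond) && nrow(m$bond) > 0) {
    tibble(origin = as.integer(m$bond$origin),
           target = as.integer(m$bond$target),
           type = as.character(m$bond$type))
  } else {
    tibble(origin = integer(), target = integer(), type = character())
  }
  if (nrow(bonds) > 0 &&
      !all(c(bonds$origin, bonds$target) %in% atoms$serial)) {
    abort_parse("MOL2 BOND block references a nonexistent atom id")
  }
  structure(list(atoms = atoms, bonds = bonds), class = "ifp_mol2")
}

#' Read a PDBQT file
#'
#' Coordinates are parsed as for PDB; `ROOT`/`BRANCH`/`TORSDOF` records are
#' ignored. The AutoDock atom type column is kept (`ad_type`) and used as the
#' element hint: type `"A"` resolves to carbon with an aromatic flag.
#'
#' @param source Path or PDBQT text.
#' @return Atom tibble as for [read_pdb()], with extra columns `ad_type` and
#'   `aromatic`.
#' @export
read_pdbqt <- function(source) {
  lines <- source_lines(source)
  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | rec == "HETATM"
  if (!any(keep)) abort_parse("no ATOM/HETATM records found in PDBQT input")
  atoms <- read_pdb(paste(lines[keep | startsWith(lines, "MODEL") |
                                  startsWith(lines, "ENDMDL")],
                          collapse = "\n"))
  al <- lines[keep]
  tail_tok <- lapply(strsplit(trimws(substr(al, 67, 200)), "\\s+"),
                     function(t) t[t != ""])
  ad_type <- vapply(tail_tok, function(t) {
    if (length(t) == 0) "" else t[length(t)]
  }, character(1))
  charge <- vapply(tail_tok, function(t) {
    if (length(t) >= 2) suppressWarnings(as.numeric(t[length(t) - 1])) else NA_real_
  }, numeric(1))
  atoms$ad_type <- ad_type
  atoms$charge <- charge
  mapped <- AUTODOCK_TYPES[ad_type]
  known <- !is.na(mapped)
  atoms$element[known] <- normalize_element(mapped[known])
  atoms$aromatic <- ad_type == "A"
  atoms
}

residue_key <- function(d) {
  paste(d$chain, d$res_seq, d$i_code, d$res_name, sep = "/")
}

#' Human-readable residue label, e.g. `"Lys463"`
#' @param res_name,res_seq,i_code Residue identity fields.
#' @return Character label in the style of hotspot tables.
#' @export
residue_label <- function(res_name, res_seq, i_code = "") {
  paste0(stringr::str_to_title(tolower(res_name)), res_seq, i_code)
}

#' Split one frame into protein, ligand and metal components
#'
#' Waters are discarded; monoatomic ions on a fixed name list become metals;
#' residues with standard amino-acid names become the protein. The ligand is
#' picked by residue name or by an explicit `(chain, res_seq)` pair.
#'
#' @param frame Single-frame atom tibble.
#' @param ligand Ligand selector: a residue-name string (e.g. `"LIG"`) or a
#'   list/vector with elements `chain` and `res_seq`.
#' @return List with tibbles `protein`, `ligand`, `metals`.
#' @export
split_complex <- function(frame, ligand) {
  if (length(unique(frame$frame)) > 1) {
    abort_selection("split_complex() expects a single frame; use get_frame()")
  }
  frame <- filter(frame, !(toupper(.data$res_name) %in% WATER_RESIDUES))
  if (is.character(ligand) && length(ligand) == 1) {
    lig_mask <- toupper(frame$res_name) == toupper(ligand)
  } else if (!is.null(ligand$chain) || !is.null(ligand$res_seq)) {
    lig_mask <- frame$res_seq == as.integer(ligand$res_seq)
    if (!is.null(ligand$chain) && nzchar(ligand$chain)) {
      lig_mask <- lig_mask & frame$chain == ligand$chain
    }
  } else {
    abort_selection("ligand selector must be a residue name or (chain, res_seq)")
  }
  if (!any(lig_mask)) {
    abort_selection(sprintf("ligand selector matched zero atoms ('%s')",
                            paste(unlist(ligand), collapse = "/")))
  }
  lig <- frame[lig_mask, ]
  if (length(unique(residue_key(lig))) > 1) {
    abort_selection(sprintf(
      "ligand selector is ambiguous: matches %d residues (%s)",
      length(unique(residue_key(lig))),
      paste(unique(residue_key(lig)), collapse = ", ")
    ))
  }
  rest <- frame[!lig_mask, ]
  metal_mask <- toupper(rest$res_name) %in% METAL_RESIDUES &
    !(toupper(rest$res_name) %in% STANDARD_AA)
  protein_mask <- toupper(rest$res_name) %in% STANDARD_AA
  list(
    protein = rest[protein_mask, ],
    ligand = lig,
    metals = rest[metal_mask, ]
  )
}
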