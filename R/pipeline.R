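# End-to-end pipeline: structure series in, bitstrings + hotspot tables +
# RMSD trace out, with a flat key=value config file and deterministic
# outputs.

CONFIG_KEYS <- c(
  "input", "ligand", "site", "out_dir", "dt_ps", "reference_frame",
  names(formals(ifp_config))
)

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Recognised keys:
#' `input`, `ligand`, `site` (`auto`, `union-auto`, or a comma-separated
#' residue list), `out_dir`, `dt_ps`, `reference_frame`, and every
#' [ifp_config()] threshold.
#'
#' @param path Config file path.
#' @return Named list of values (numbers parsed where possible).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) val <- num
    if (identical(val, "true")) val <- TRUE
    if (identical(val, "false")) val <- FALSE
    out[[key]] <- val
  }
  unknown <- setdiff(names(out), CONFIG_KEYS)
  if (length(unknown) > 0) {
    warn(paste("ignoring unknown config keys:",
               paste(unknown, collapse = ", ")))
    out <- out[names(out) %in% CONFIG_KEYS]
  }
  out
}

#' Assemble a pipeline run configuration
#'
#' Precedence: explicit arguments (CLI flags) > config file > defaults.
#'
#' @param input Path to the structure file (PDB, possibly multi-MODEL).
#' @param ligand Ligand selector (residue name or `"chain/res_seq"`).
#' @param site Site selection: `"union-auto"`, `"auto"`, or residue list.
#' @param out_dir Output directory.
#' @param dt_ps Snapshot interval in picoseconds (default 100).
#' @param reference_frame Reference frame for RMSD traces (default 0).
#' @param config_file Optional flat key=value file.
#' @param ... [ifp_config()] threshold overrides.
#' @return List of class `run_config`.
#' @export
run_config <- function(input = NULL, ligand = NULL, site = NULL,
                       out_dir = NULL, dt_ps = NULL, reference_frame = NULL,
                       config_file = NULL, ...) {
  file_cfg <- if (!is.null(config_file)) read_run_config(config_file)
              else list()
  pick <- function(flag, key, default) {
    if (!is.null(flag)) flag
    else if (!is.null(file_cfg[[key]])) file_cfg[[key]]
    else default
  }
  thr <- list(...)
  thr_names <- names(formals(ifp_config))
  for (k in thr_names) {
    if (is.null(thr[[k]]) && !is.null(file_cfg[[k]])) thr[[k]] <- file_cfg[[k]]
  }
  cfg <- do.call(ifp_config, thr[names(thr) %in% thr_names])
  site <- pick(site, "site", "union-auto")
  if (is.character(site) && length(site) == 1 &&
      !site %in% c("auto", "union-auto")) {
    site <- trimws(strsplit(site, ",", fixed = TRUE)[[1]])
  }
  structure(list(
    input = pick(input, "input", NULL),
    ligand = pick(ligand, "ligand", NULL),
    site = site,
    out_dir = pick(out_dir, "out_dir", "."),
    dt_ps = as.numeric(pick(dt_ps, "dt_ps", 100)),
    reference_frame = as.integer(pick(reference_frame, "reference_frame",
                                      0)),
    ifp = cfg
  ), class = "run_config")
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full fingerprint + hotspot + RMSD pipeline
#'
#' Reads the input series, computes the fingerprint of every frame, the
#' hotspot occupancy tables and the RMSD traces, and writes
#' `bitstrings.txt`, `bitstrings.csv`, `hydrophobic_hotspots.csv`,
#' `other_hotspots.csv`, `rmsd.csv` and (when metal contacts exist)
#' `metal_contacts.csv` into the output directory. On error all partial
#' outputs of this run are removed.
#'
#' @param config A [run_config()].
#' @param quiet Suppress log messages?
#' @return Invisibly, a list with the computed `series`, `hotspots`,
#'   `traces` and the vector of `files` written.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$input) || is.null(config$ligand)) {
    abort_selection("run_pipeline needs both an input file and a ligand selector")
  }
  if (!file.exists(config$input)) {
    abort_parse(sprintf("input file not found: %s", config$input))
  }
  log_msg <- function(...) if (!quiet) message("[ifpr] ", sprintf(...))
  written <- character()
  ok <- FALSE
  on.exit(if (!ok && length(written) > 0) unlink(written), add = TRUE)

  series <- read_pdb(config$input)
  log_msg("frames: %d; atoms per frame: %d", n_frames(series),
          nrow(series) / n_frames(series))
  fps <- direct_ifp_series(series, config$ligand, config$site, config$ifp)
  f0 <- as_tibble(fps)[as_tibble(fps)$frame == min(fps$frame), ]
  log_msg("selected residues: %s",
          paste(residue_label(f0$res_name, f0$res_seq, f0$i_code),
                collapse = " "))
  log_msg("thresholds: %s",
          paste(names(config$ifp), unlist(config$ifp), sep = "=",
                collapse = " "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  writeLines(ifp_bitstrings(fps), out("bitstrings.txt"))
  written <- c(written, out("bitstrings.txt"))
  written <- c(written,
               write_csv_plain(bitstrings_table(fps), out("bitstrings.csv")))

  hs <- aggregate_hotspots(fps)
  tables <- split_tables(hs)
  hydro <- mutate(tables$hydrophobic,
                  occupancy = sprintf("%.2f", .data$occupancy))
  other <- mutate(tables$other,
                  occupancy = sprintf("%.2f", .data$occupancy))
  written <- c(written,
               write_csv_plain(hydro, out("hydrophobic_hotspots.csv")),
               write_csv_plain(other, out("other_hotspots.csv")))
  mc <- aggregate_metal_contacts(fps)
  if (nrow(mc) > 0) {
    mc <- mutate(mc, occupancy = sprintf("%.2f", .data$occupancy))
    written <- c(written, write_csv_plain(mc, out("metal_contacts.csv")))
  }

  traces <- rmsd_traces(series, config$ligand,
                        reference = config$reference_frame,
                        dt_ps = config$dt_ps)
  traces_out <- mutate(traces,
                       backbone_rmsd = sprintf("%.3f", .data$backbone_rmsd),
                       ligmove_rmsd = sprintf("%.3f", .data$ligmove_rmsd),
                       stable = tolower(as.character(.data$stable)))
  written <- c(written, write_csv_plain(traces_out, out("rmsd.csv")))

  log_msg("wrote %d files to %s", length(written), config$out_dir)
  ok <- TRUE
  invisible(list(series = series, fingerprints = fps, hotspots = hs,
                 traces = traces, files = written))
}
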