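# Aggregation of a fingerprint series into interaction-hotspot occupancy
# tables: per (residue, interaction type), the percentage of frames in which
# the interaction is present.

# round half-up at `digits` decimals (R's round() is half-to-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Aggregate a fingerprint series into hotspot occupancy rows
#'
#' Occupancy is `100 * frames-with-bit-set / n_frames`, rounded half-up to
#' two decimals. Zero-occupancy rows are omitted (the tables list observed
#' interactions only). Rows are ordered by residue number, then by the fixed
#' bit order.
#'
#' @param series An `ifp_series` from [direct_ifp_series()].
#' @return Tibble: `chain`, `res_seq`, `i_code`, `res_name`, `residue`
#'   (display label), `type` (label such as `"H-bond (Donor)"`),
#'   `occupancy` (percent), `n_set`, `n_frames`.
#' @examples
#' traj <- make_trajectory_fixture(trajectory_spec(
#'   complex_spec("LYS", "acetate", distance = 3),
#'   n_frames = 8, bound_schedule = 0:2))
#' fps <- direct_ifp_series(read_pdb(traj$text), "LIG")
#' aggregate_hotspots(fps)
#' @export
aggregate_hotspots <- function(series) {
  nf <- attr(series, "n_frames") %||% length(unique(series$frame))
  if (is.null(nf) || nf < 1 || nrow(as_tibble(series)) == 0) {
    abort("cannot aggregate an empty fingerprint series",
          class = "ifpr_error")
  }
  df <- as_tibble(series)
  long <- tidyr::pivot_longer(df, cols = dplyr::all_of(BIT_NAMES),
                              names_to = "bit", values_to = "set")
  out <- long %>%
    group_by(.data$chain, .data$res_seq, .data$i_code, .data$res_name,
             .data$bit) %>%
    summarise(n_set = sum(.data$set), .groups = "drop") %>%
    filter(.data$n_set > 0) %>%
    mutate(
      n_frames = nf,
      occupancy = round_half_up(100 * .data$n_set / nf, 2),
      residue = residue_label(.data$res_name, .data$res_seq, .data$i_code),
      type = unname(TYPE_LABELS[.data$bit])
    ) %>%
    arrange(.data$chain, .data$res_seq, .data$i_code,
            match(.data$bit, BIT_NAMES)) %>%
    select("chain", "res_seq", "i_code", "res_name", "residue", "type",
           "occupancy", "n_set", "n_frames")
  out
}

#' Split hotspot rows into hydrophobic and non-hydrophobic tables
#'
#' Mirrors the conventional presentation: one table of hydrophobic contacts
#' (residue, percentage) and one of all other interaction types (residue,
#' type, percentage). A residue engaging in both kinds appears in both.
#'
#' @param rows Output of [aggregate_hotspots()].
#' @return List with tibbles `hydrophobic` (`residue`, `occupancy`) and
#'   `other` (`residue`, `type`, `occupancy`).
#' @export
split_tables <- function(rows) {
  hydro <- rows %>% filter(.data$type == "Hydrophobic") %>%
    select("residue", "occupancy")
  other <- rows %>% filter(.data$type != "Hydrophobic") %>%
    select("residue", "type", "occupancy")
  list(hydrophobic = hydro, other = other)
}

#' Residues interacting above an occupancy threshold
#'
#' Returns residues having any hotspot row above the threshold (default
#' 10 percent of the simulation), sorted by their maximum occupancy,
#' descending -- the "dominant" interaction partners.
#'
#' @param rows Output of [aggregate_hotspots()].
#' @param threshold_pct Occupancy threshold in percent (exclusive).
#' @return Character vector of residue labels.
#' @export
dominant_residues <- function(rows, threshold_pct = 10.0) {
  rows %>%
    group_by(.data$residue) %>%
    summarise(max_occ = max(.data$occupancy), .groups = "drop") %>%
    filter(.data$max_occ > threshold_pct) %>%
    arrange(desc(.data$max_occ)) %>%
    pull("residue")
}

#' Aggregate per-frame metal contacts into an occupancy table
#'
#' Metal-ligand contacts are kept outside the seven-bit residue fingerprint;
#' this companion table reports, per (metal, ligand atom), the percentage of
#' frames with the contact present.
#'
#' @param series An `ifp_series`.
#' @return Tibble: `metal_name`, `ligand_atom`, `occupancy`, `n_set`,
#'   `n_frames`.
#' @export
aggregate_metal_contacts <- function(series) {
  nf <- attr(series, "n_frames") %||% length(unique(series$frame))
  mc <- attr(series, "metal_contacts")
  if (is.null(mc) || nrow(mc) == 0) {
    return(tibble(metal_name = character(), ligand_atom = character(),
                  occupancy = numeric(), n_set = integer(),
                  n_frames = integer()))
  }
  mc %>%
    distinct(.data$frame, .data$metal_name, .data$ligand_atom) %>%
    group_by(.data$metal_name, .data$ligand_atom) %>%
    summarise(n_set = dplyr::n(), .groups = "drop") %>%
    mutate(occupancy = round_half_up(100 * .data$n_set / nf, 2),
           n_frames = nf) %>%
    select("metal_name", "ligand_atom", "occupancy", "n_set", "n_frames")
}
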