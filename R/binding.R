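#' Equilibrium fraction bound from a simple binding isotherm
#'
#' For a ligand in large excess over binding sites (non-depleting regime;
#' micromolar soluble adapter vs picomolar surface-tethered complexes), the
#' equilibrium fraction of sites occupied is `L / (Kd + L)`. With the
#' adapter-SNARE dissociation constant of 1.5 uM, 0.5 uM ligand leaves only
#' 25% of complexes bound while 20 uM binds 93%.
#'
#' @param ligand_conc Free ligand concentration(s), uM.
#' @param kd Dissociation constant, uM.
#' @return Fraction(s) bound in `[0, 1]`.
#' @export
fraction_bound <- function(ligand_conc, kd = 1.5) {
  stopifnot(kd > 0, all(ligand_conc >= 0))
  ligand_conc / (kd + ligand_conc)
}

#' Equilibrium occupancy under single-site competitive binding
#'
#' Fraction of sites occupied by the reporter ligand when a competitor
#' binds the same site mutually exclusively:
#' `(L/Kd_L) / (1 + L/Kd_L + C/Kd_C)`.
#'
#' @param ligand_conc,kd_ligand Reporter ligand concentration and Kd (uM).
#' @param competitor_conc,kd_competitor Competitor concentration and Kd (uM).
#' @return Occupancy fraction(s) in `[0, 1]`.
#' @export
competitive_occupancy <- function(ligand_conc, kd_ligand,
                                  competitor_conc, kd_competitor) {
  stopifnot(kd_ligand > 0, kd_competitor > 0,
            all(ligand_conc >= 0), all(competitor_conc >= 0))
  x <- ligand_conc / kd_ligand
  (x) / (1 + x + competitor_conc / kd_competitor)
}

#' Normalize competition-assay spot counts
#'
#' Normalizes the count of labeled ligand molecules per field of view by
#' the number of surface-tethered complexes in the same field, then
#' summarizes per competitor concentration as mean +- SD over fields.
#'
#' @param observations A tibble with columns `field_id`, `competitor_conc`,
#'   `n_ligand_spots`, `n_tether_spots`.
#' @return A tibble per concentration: `competitor_conc`, `mean`, `sd`,
#'   `n_fields`. Fields with zero tethered complexes are skipped with a
#'   warning.
#' @export
normalize_competition <- function(observations) {
  bad <- observations$n_tether_spots <= 0
  if (any(bad)) {
    warning(sum(bad), " field(s) with zero tethered complexes skipped")
    observations <- observations[!bad, ]
  }
  observations |>
    dplyr::mutate(ratio = .data$n_ligand_spots / .data$n_tether_spots) |>
    dplyr::group_by(.data$competitor_conc) |>
    dplyr::summarise(
      mean = mean(.data$ratio),
      sd = if (dplyr::n() > 1) sd(.data$ratio) else 0,
      n_fields = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$competitor_conc)
}

#' Simulate a single-molecule competition assay
#'
#' Generates per-field spot counts for a competition titration: each
#' surface-tethered complex is occupied by the labeled ligand with the
#' competitive single-site probability of [competitive_occupancy()]
#' (Bernoulli per tether, each tether counted once).
#'
#' @param kd_ligand,kd_competitor Dissociation constants, uM.
#' @param ligand_conc Labeled ligand concentration, uM.
#' @param competitor_concs Vector of competitor concentrations, uM.
#' @param n_tethers Tethered complexes per field.
#' @param n_fields Fields of view per concentration.
#' @param seed Optional integer seed.
#' @return A tibble of observations suitable for [normalize_competition()].
#' @export
simulate_competition <- function(kd_ligand, kd_competitor, ligand_conc,
                                 competitor_concs, n_tethers, n_fields = 3,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(
    competitor_conc = competitor_concs,
    field = seq_len(n_fields)
  )
  p <- competitive_occupancy(ligand_conc, kd_ligand,
                             grid$competitor_conc, kd_competitor)
  tibble::tibble(
    field_id = sprintf("F%02d", grid$field),
    competitor_conc = grid$competitor_conc,
    n_ligand_spots = rbinom(nrow(grid), n_tethers, p),
    n_tether_spots = n_tethers
  )
}
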