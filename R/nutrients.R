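#' Nutrient density table for the six food groups
#'
#' Group-level nutrient densities (mg per kcal for sodium, potassium and the
#' three fatty-acid classes; energy-share fractions for protein and fat),
#' each with a coefficient of variation for bootstrap draws. The shipped
#' default starts from typical food-composition values for the foods in each
#' group and is rescaled by [calibrate_density_table()] so the
#' traditional-parcel arm mean intake reproduces the reported population
#' baselines exactly (sodium 4,288; potassium 3,834; SFA 26,124; MUFA 28,567;
#' PUFA 26,871 mg/person/day): the published baselines, not any particular
#' database release, are the ground truth.
#'
#' @param calibrated If `TRUE` (default) return the calibrated table.
#' @return Tibble with columns `group`, `nutrient`, `density`, `density_sd`.
#' @export
default_density_table <- function(calibrated = TRUE) {
  raw <- tibble(
    group = rep(food_groups(), times = 7),
    nutrient = rep(c("sodium", "potassium", "sfa", "mufa", "pufa",
                     "protein_share", "fat_share"), each = 6),
    density = c(
      1.5, 1.0, 0.5, 3.0, 0.10, 0.10,     # sodium, mg/kcal
      0.5, 2.5, 6.0, 1.5, 0.02, 0.05,     # potassium, mg/kcal
      2.0, 3.0, 1.0, 40.0, 30.0, 5.0,     # saturated fat, mg/kcal
      3.0, 8.0, 1.5, 35.0, 45.0, 4.0,     # monounsaturated fat, mg/kcal
      5.0, 10.0, 2.0, 15.0, 55.0, 2.0,    # polyunsaturated fat, mg/kcal
      0.12, 0.20, 0.08, 0.30, 0.00, 0.00, # protein share of group energy
      0.06, 0.15, 0.05, 0.50, 1.00, 0.00  # fat share of group energy
    )
  )
  raw$density_sd <- 0.15 * raw$density
  if (!calibrated) {
    return(raw)
  }
  calibrate_density_table(raw, arm_mean_intake("parcel"),
                          targets = c(sodium = 4288, potassium = 3834,
                                      sfa = 26124, mufa = 28567, pufa = 26871))
}

#' Rescale nutrient densities so a reference intake hits published baselines
#'
#' Multiplies each mass nutrient's density vector by a single scalar so that
#' the nutrient total implied by `reference_intake` equals its target; energy
#' shares are left untouched.
#'
#' @param table Density table (see [default_density_table()]).
#' @param reference_intake One-row intake tibble.
#' @param targets Named vector of nutrient targets in mg/person/day.
#' @return The rescaled density table.
#' @export
calibrate_density_table <- function(table, reference_intake, targets) {
  ref <- as.numeric(reference_intake[1, food_groups()])
  for (nm in names(targets)) {
    rows <- table$nutrient == nm
    dens <- table$density[rows][match(food_groups(), table$group[rows])]
    implied <- sum(ref * dens)
    if (implied <= 0) abort_config(sprintf("cannot calibrate '%s': zero implied total", nm))
    scale <- targets[[nm]] / implied
    table$density[rows] <- table$density[rows] * scale
    table$density_sd[rows] <- table$density_sd[rows] * scale
  }
  table
}

density_matrix <- function(table, value_col = "density") {
  nutrients <- unique(table$nutrient)
  m <- matrix(0, nrow = length(food_groups()), ncol = length(nutrients),
              dimnames = list(food_groups(), nutrients))
  for (i in seq_len(nrow(table))) {
    m[table$group[i], table$nutrient[i]] <- table[[value_col]][i]
  }
  m
}

mass_nutrients <- c("sodium", "potassium", "sfa", "mufa", "pufa")

profile_from_densities <- function(intake_mat, dens) {
  totals <- intake_mat %*% dens
  energy <- rowSums(intake_mat)
  out <- as_tibble(totals[, mass_nutrients, drop = FALSE])
  out$energy <- energy
  out$protein_pct <- ifelse(energy > 0, 100 * totals[, "protein_share"] / energy, 0)
  out$fat_pct <- ifelse(energy > 0, 100 * totals[, "fat_share"] / energy, 0)
  out
}

#' Nutrient profile of a food-group intake
#'
#' Maps group-level kcal to the model's mediating nutrient quantities:
#' energy, sodium, potassium and the three fatty-acid classes (mg/day),
#' protein and fat energy shares, and the Mediterranean Dietary Score. The
#' point estimate uses the density means and is linear in intake; with
#' `bootstrap_draws > 0`, densities are redrawn (truncated-normal around their
#' means) and percentile 95% intervals are attached as `<quantity>_lo` /
#' `<quantity>_hi` columns.
#'
#' @param intake Intake tibble (profiled rowwise).
#' @param table Density table ([default_density_table()]).
#' @param bootstrap_draws Number of density redraws (0 = point estimate only).
#' @param seed Integer seed for the bootstrap.
#' @param cutpoints MDS cutpoints passed to [mds_score()].
#' @return Tibble with one row per intake row: `energy`, `sodium`,
#'   `potassium`, `sfa`, `mufa`, `pufa`, `mds`, `protein_pct`, `fat_pct`
#'   (plus interval columns when bootstrapping).
#' @examples
#' nutrients_from_intake(arm_mean_intake("parcel"))
#' @export
nutrients_from_intake <- function(intake, table = default_density_table(),
                                  bootstrap_draws = 0, seed = 1L,
                                  cutpoints = default_mds_cutpoints()) {
  validate_intake(intake)
  missing_groups <- setdiff(food_groups(), unique(table$group))
  if (length(missing_groups)) {
    abort_config(paste0("density table is missing groups: ",
                        paste(missing_groups, collapse = ", ")))
  }
  intake_mat <- as.matrix(intake[food_groups()])
  dens <- density_matrix(table)
  out <- profile_from_densities(intake_mat, dens)
  out$mds <- mds_score(intake, cutpoints = cutpoints)
  out <- out[, c("energy", mass_nutrients, "mds", "protein_pct", "fat_pct")]

  if (bootstrap_draws > 0) {
    sd_mat <- density_matrix(table, "density_sd")
    draw_quants <- c(mass_nutrients, "protein_pct", "fat_pct")
    draws <- with_seed(child_seed(seed, "density-bootstrap"), {
      lapply(seq_len(bootstrap_draws), function(d) {
        dd <- pmax(dens + matrix(rnorm(length(dens)), nrow(dens)) * sd_mat, 0)
        profile_from_densities(intake_mat, dd)
      })
    })
    for (q in draw_quants) {
      mat <- vapply(draws, function(d) d[[q]], numeric(nrow(intake)))
      mat <- matrix(mat, nrow = nrow(intake))
      out[[paste0(q, "_lo")]] <- apply(mat, 1, quantile, 0.025, names = FALSE)
      out[[paste0(q, "_hi")]] <- apply(mat, 1, quantile, 0.975, names = FALSE)
    }
    out$energy_lo <- out$energy_hi <- out$energy # densities do not move energy
  }
  out
}
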