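#' Carbohydrate content by difference (Nifext fraction)
#'
#' Total carbohydrates computed as 100 minus the sum of the other proximate
#' constituents (protein, lipid, ash and, on a wet basis, water). On a dry
#' basis the water term is 0 by definition.
#'
#' @param protein_pct,lipid_pct,ash_pct Constituent percentages,
#'   non-negative; vectorized.
#' @param water_pct Water percentage on the same basis as the other
#'   constituents; 0 for dry-basis records.
#' @return Carbohydrate percentage. The inputs plus the result always sum to
#'   exactly 100.
#' @examples
#' carbohydrates_by_difference(14.96, 2.10, 6.76) # 76.18
#' @export
carbohydrates_by_difference <- function(protein_pct, lipid_pct, ash_pct,
                                        water_pct = 0) {
  args <- cbind(protein_pct, lipid_pct, ash_pct, water_pct)
  if (any(!is.finite(args))) stop("constituents must be finite", call. = FALSE)
  if (any(args < 0)) stop("constituents must be non-negative", call. = FALSE)
  total <- protein_pct + lipid_pct + ash_pct + water_pct
  if (any(total > 100.05)) {
    stop("inconsistent composition: constituents sum above 100.05%", call. = FALSE)
  }
  100 - total
}

#' Atwater energy value
#'
#' Caloric value from the Atwater conversion factors: 4 kcal/g for
#' carbohydrates and proteins, 9 kcal/g for lipids.
#'
#' @param carbohydrate_pct,protein_pct,lipid_pct Macronutrient percentages
#'   (g per 100 g), non-negative; vectorized.
#' @return Energy value, kcal per 100 g.
#' @examples
#' atwater_energy(70.71, 15.39, 7.70) # 413.70
#' @export
atwater_energy <- function(carbohydrate_pct, protein_pct, lipid_pct) {
  args <- cbind(carbohydrate_pct, protein_pct, lipid_pct)
  if (any(!is.finite(args))) stop("macronutrients must be finite", call. = FALSE)
  if (any(args < 0)) stop("macronutrients must be non-negative", call. = FALSE)
  4 * (carbohydrate_pct + protein_pct) + 9 * lipid_pct
}

#' Complete a proximate-composition table
#'
#' Adds the derived columns (carbohydrate by difference and Atwater energy)
#' to a table of measured proximate constituents. For dry-basis records the
#' water content does not enter the carbohydrate difference (macronutrients
#' are already expressed per dry matter); for wet-basis records it does.
#'
#' @param df A data frame with columns `label`, `basis` (`"wet"` or
#'   `"dry"`), `water_pct`, `protein_pct`, `lipid_pct`, `ash_pct`.
#' @return The input with columns `carbohydrate_pct` and `energy_kcal_100g`
#'   appended.
#' @export
proximate_table <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("label", "basis", "water_pct", "protein_pct", "lipid_pct", "ash_pct")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("proximate table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(df$basis %in% c("wet", "dry"))) {
    stop("basis must be 'wet' or 'dry'", call. = FALSE)
  }
  water_term <- ifelse(df$basis == "dry", 0, df$water_pct)
  df$carbohydrate_pct <- carbohydrates_by_difference(
    df$protein_pct, df$lipid_pct, df$ash_pct, water_term
  )
  df$energy_kcal_100g <- atwater_energy(df$carbohydrate_pct, df$protein_pct,
                                        df$lipid_pct)
  df
}
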