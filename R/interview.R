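ACZ_LEVELS <- c("east_south_eastern_coastal_plain", "mid_central_table_land",
                "north_central_plateau", "north_eastern_coastal_plain",
                "north_western_plateau", "western_central_table_land")

INTERVIEW_COLUMNS <- c(
  "field_id", "district", "acz", "season", "year", "water_regime",
  "variety_name", "growth_duration_days", "seedling_age_days",
  "transplant_delay_days", "historical_yield_GYR", "variety_yield_ceiling",
  "previous_crop_yield", "residue_retained_fraction", "selected_products",
  "farmer_applies_zinc")

#' Construct a farmer interview record
#'
#' One field's questionnaire answers: the sole input to the
#' recommendation engine.  Historical yield is the grain yield (14%
#' moisture) the farmer reports for previous seasons with the same or a
#' similar variety; the engine sets the target yield from it.
#'
#' @param field_id identifier for the field/trial
#' @param district,acz,year location descriptors; `acz` must be one of
#'   the six agro-climatic zones (see `ricenm:::ACZ_LEVELS`)
#' @param season `"kharif"` (wet) or `"rabi"` (dry)
#' @param water_regime `"irrigated"` or `"rainfed"`
#' @param variety_name rice variety
#' @param growth_duration_days germination-to-maturity duration, days
#' @param seedling_age_days seedling age at transplanting, days
#' @param transplant_delay_days days of transplanting delay beyond the
#'   critical date (0 = on time)
#' @param historical_yield_GYR farmer-reported yield, Mg/ha
#' @param variety_yield_ceiling optional per-variety cap on the target
#'   yield, Mg/ha (`NA` = none)
#' @param previous_crop_yield previous crop's grain yield, Mg/ha (0 if
#'   no previous crop)
#' @param residue_retained_fraction fraction of the previous crop's
#'   above-ground residue retained in the field
#' @param selected_products character vector of fertilizer product
#'   names the farmer can buy
#' @param farmer_applies_zinc does the farmer's own practice include
#'   zinc sulfate? (used only for the FFP treatment)
#' @return object of class `farmer_interview`
#' @export
#' @examples
#' iv <- farmer_interview("F001", historical_yield_GYR = 4.6,
#'                        growth_duration_days = 140,
#'                        seedling_age_days = 25)
#' set_target_yield(iv, engine_config())
farmer_interview <- function(field_id,
                             district = "unknown",
                             acz = ACZ_LEVELS[1],
                             season = c("kharif", "rabi"),
                             year = "2014",
                             water_regime = c("irrigated", "rainfed"),
                             variety_name = "unnamed",
                             growth_duration_days = 135L,
                             seedling_age_days = 25L,
                             transplant_delay_days = 0,
                             historical_yield_GYR,
                             variety_yield_ceiling = NA_real_,
                             previous_crop_yield = 0,
                             residue_retained_fraction = 0.15,
                             selected_products = c("urea", "DAP", "MOP"),
                             farmer_applies_zinc = FALSE) {
  iv <- list(
    field_id = as.character(field_id), district = district,
    acz = match.arg(acz, ACZ_LEVELS), season = match.arg(season),
    year = as.character(year), water_regime = match.arg(water_regime),
    variety_name = variety_name,
    growth_duration_days = as.integer(growth_duration_days),
    seedling_age_days = as.integer(seedling_age_days),
    transplant_delay_days = as.numeric(transplant_delay_days),
    historical_yield_GYR = as.numeric(historical_yield_GYR),
    variety_yield_ceiling = as.numeric(variety_yield_ceiling),
    previous_crop_yield = as.numeric(previous_crop_yield),
    residue_retained_fraction = as.numeric(residue_retained_fraction),
    selected_products = selected_products,
    farmer_applies_zinc = isTRUE(farmer_applies_zinc)
  )
  class(iv) <- "farmer_interview"
  validate_interview(iv)
  iv
}

validate_interview <- function(iv) {
  if (iv$growth_duration_days < 90 || iv$growth_duration_days > 180)
    stop_input("growth_duration_days must be in [90, 180]")
  if (iv$seedling_age_days < 10 || iv$seedling_age_days > 45 ||
      iv$seedling_age_days >= iv$growth_duration_days)
    stop_input("seedling_age_days must be in [10, 45] and less than the ",
               "growth duration")
  if (!is.finite(iv$historical_yield_GYR) || iv$historical_yield_GYR <= 0)
    stop_input("historical_yield_GYR must be positive")
  if (iv$transplant_delay_days < 0)
    stop_input("transplant_delay_days must be non-negative")
  if (iv$residue_retained_fraction < 0 || iv$residue_retained_fraction > 1)
    stop_input("residue_retained_fraction must be in [0, 1]")
  if (iv$previous_crop_yield < 0)
    stop_input("previous_crop_yield must be non-negative")
  invisible(iv)
}

#' @export
print.farmer_interview <- function(x, ...) {
  cat(sprintf("Farmer interview %s (%s, %s %s, %s)\n", x$field_id,
              x$district, x$season, x$year, x$water_regime))
  cat(sprintf("  variety %s, %d d duration, seedlings %d d, delay %.0f d\n",
              x$variety_name, x$growth_duration_days, x$seedling_age_days,
              x$transplant_delay_days))
  cat(sprintf("  historical yield %.1f Mg/ha; previous crop %.1f Mg/ha, %.0f%% residue retained\n",
              x$historical_yield_GYR, x$previous_crop_yield,
              100 * x$residue_retained_fraction))
  invisible(x)
}

#' Convert interviews to/from a flat table
#'
#' One row per field; column names are exactly the interview field
#' names.  The `selected_products` list-column is serialized as a
#' `;`-separated string.
#'
#' @param interviews list of `farmer_interview`
#' @return data.frame with one row per interview
#' @export
interviews_to_table <- function(interviews) {
  rows <- lapply(interviews, function(iv) {
    iv <- unclass(iv)
    iv$selected_products <- paste(iv$selected_products, collapse = ";")
    as.data.frame(iv, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname interviews_to_table
#' @param tab data.frame as produced by [interviews_to_table()]
#' @export
table_to_interviews <- function(tab) {
  mandatory <- setdiff(INTERVIEW_COLUMNS, "variety_yield_ceiling")
  missing <- setdiff(mandatory, names(tab))
  if (length(missing))
    stop_input("missing mandatory column(s): ", paste(missing, collapse = ", "))
  if (!"variety_yield_ceiling" %in% names(tab))
    tab$variety_yield_ceiling <- NA_real_
  numeric_cols <- c("growth_duration_days", "seedling_age_days",
                    "transplant_delay_days", "historical_yield_GYR",
                    "variety_yield_ceiling", "previous_crop_yield",
                    "residue_retained_fraction")
  for (cl in numeric_cols) {
    v <- suppressWarnings(as.numeric(tab[[cl]]))
    bad <- which(is.na(v) & !is.na(tab[[cl]]) & tab[[cl]] != "" &
                   tab[[cl]] != "NA")
    if (length(bad))
      stop_input(sprintf("malformed numeric in column '%s' at row %d", cl,
                         bad[1]))
    tab[[cl]] <- v
  }
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, , drop = FALSE]
    farmer_interview(
      field_id = r$field_id, district = r$district, acz = r$acz,
      season = r$season, year = r$year, water_regime = r$water_regime,
      variety_name = r$variety_name,
      growth_duration_days = r$growth_duration_days,
      seedling_age_days = r$seedling_age_days,
      transplant_delay_days = r$transplant_delay_days,
      historical_yield_GYR = r$historical_yield_GYR,
      variety_yield_ceiling = r$variety_yield_ceiling,
      previous_crop_yield = r$previous_crop_yield,
      residue_retained_fraction = r$residue_retained_fraction,
      selected_products = strsplit(as.character(r$selected_products), ";",
                                   fixed = TRUE)[[1]],
      farmer_applies_zinc = as.logical(r$farmer_applies_zinc)
    )
  })
}
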