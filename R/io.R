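pkg_version <- function() {
  as.character(utils::packageVersion("ricenm"))
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_engine_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

# commented metadata header: tool version, seed, config hash -- no
# timestamps, so repeated runs with the same seed are byte-identical
meta_header <- function(seed = NULL, cfg = NULL) {
  h <- c(sprintf("# ricenm %s", pkg_version()))
  if (!is.null(seed)) h <- c(h, sprintf("# seed: %d", as.integer(seed)))
  if (!is.null(cfg)) h <- c(h, sprintf("# config_hash: %s", config_hash(cfg)))
  h
}

#' Write or read a flat CSV table with a metadata header
#'
#' Tables are plain CSV preceded by `#`-commented header lines carrying
#' the tool version, the RNG seed, and a hash of the engine
#' configuration, so any output can be rerun exactly.
#'
#' @param df data.frame
#' @param path file path
#' @param seed optional integer recorded in the header
#' @param cfg optional [engine_config()] hashed into the header
#' @return `path` (write) or a data.frame (read), invisibly for write
#' @export
write_table <- function(df, path, seed = NULL, cfg = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(meta_header(seed, cfg), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read and write farmer interviews as a flat CSV table
#'
#' One row per field; columns are exactly the interview field names.
#' Reading validates the schema (a missing mandatory column is an error
#' naming the column; a malformed numeric is an error naming the row)
#' and the write-read round trip is lossless.
#'
#' @param path CSV file path
#' @return list of [farmer_interview()]
#' @export
read_interviews <- function(path) {
  first <- readLines(path, n = 50L, warn = FALSE)
  if (!any(nzchar(first) & !startsWith(first, "#"))) {
    warning("empty interview file: ", path, call. = FALSE)
    return(list())
  }
  table_to_interviews(read_table(path))
}

#' @rdname read_interviews
#' @param interviews list of [farmer_interview()]
#' @inheritParams write_table
#' @export
write_interviews <- function(interviews, path, seed = NULL, cfg = NULL) {
  write_table(interviews_to_table(interviews), path, seed = seed, cfg = cfg)
}

#' Flatten prescriptions to a recommendations table
#'
#' One row per field with the target yield, total elemental rates and
#' the stage schedule; rates are rounded to 0.1 kg/ha at this
#' presentation step only (the engine computes continuous values).
#'
#' @param prescriptions list of [build_prescription()] results
#' @return data.frame
#' @export
prescriptions_to_table <- function(prescriptions) {
  do.call(rbind, lapply(prescriptions, function(p) {
    data.frame(field_id = p$field_id,
               target_yield_mg_per_ha = round(p$target_yield, 2),
               fn_kg_per_ha = round(p$fn, 1),
               fp_kg_per_ha = round(p$fp, 1),
               fk_kg_per_ha = round(p$fk, 1),
               basal_dat = unname(p$schedule["basal"]),
               mid_tillering_dat = unname(p$schedule["mid_tillering"]),
               panicle_initiation_dat =
                 unname(p$schedule["panicle_initiation"]),
               stringsAsFactors = FALSE)
  }))
}

#' Flatten treatment plans to long and totals tables
#'
#' `plans_to_applications()` gives one row per
#' field-treatment-application; `plans_to_totals()` one row per
#' field-treatment with delivered elemental totals and TFC.
#'
#' @param trials list of [trial_record()]
#' @return data.frame
#' @export
plans_to_applications <- function(trials) {
  do.call(rbind, lapply(trials, function(tr) {
    do.call(rbind, lapply(tr$plans, function(pl) {
      cbind(field_id = tr$interview$field_id, treatment = pl$label,
            pl$applications, stringsAsFactors = FALSE)
    }))
  }))
}

#' @rdname plans_to_applications
#' @export
plans_to_totals <- function(trials) {
  do.call(rbind, lapply(trials, function(tr) {
    do.call(rbind, lapply(tr$plans, function(pl) {
      data.frame(field_id = tr$interview$field_id,
                 season = tr$interview$season, year = tr$interview$year,
                 acz = tr$interview$acz,
                 water_regime = tr$interview$water_regime,
                 treatment = pl$label,
                 n_rate_kg_per_ha = round(unname(pl$totals["n"]), 2),
                 p_rate_kg_per_ha = round(unname(pl$totals["p"]), 2),
                 k_rate_kg_per_ha = round(unname(pl$totals["k"]), 2),
                 zinc_sulfate_kg_per_ha = pl$zinc_sulfate,
                 tfc_usd_per_ha = round(pl$tfc, 2),
                 grain_yield_mg_per_ha =
                   round(unname(tr$yields[pl$label]), 3),
                 paddy_price_usd_per_kg = tr$prices$paddy_price,
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Read a fertilizer product table
#'
#' @param path CSV with columns `name`, `grade_n`, `grade_p2o5`,
#'   `grade_k2o`, `price_usd_per_kg`; defaults to the packaged table
#' @return validated product data.frame
#' @export
read_products <- function(path = system.file("extdata",
                                             "products_odisha.csv",
                                             package = "ricenm")) {
  validate_products(read_table(path))
}
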