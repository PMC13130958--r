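#' Read sediment cores from a layer-table CSV
#'
#' Expects one row per layer with columns `station_id`, `date` (ISO 8601),
#' `top_cm`, `bottom_cm` and any of `be7_dpm_cm2`, `p_loose_mg_g`,
#' `p_redox_mg_g`, `p_alfe_mg_g`, `p_ca_mg_g`, `p_org_mg_g`, `porosity`,
#' `rho_b_g_cm3`, `water_depth_m`. Empty cells are missing values. Rows are
#' grouped into one core per (station, date); layers within each core must be
#' contiguous from the interface down.
#'
#' @param path CSV file path.
#' @param constants A [be7_constants()] object, used in core validation.
#' @return Named list of [sediment_core()] objects, names `"station|date"`.
#' @export
read_core_csv <- function(path, constants = be7_constants()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "date", "top_cm", "bottom_cm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  keys <- paste(df$station_id, df$date, sep = "|")
  cores <- lapply(split(df, keys), function(grp) {
    wd <- if ("water_depth_m" %in% names(grp)) grp$water_depth_m[1L] else NA_real_
    sediment_core(grp$station_id[1L], grp$date[1L], wd,
                  grp[setdiff(names(grp), c("station_id", "date", "water_depth_m"))],
                  constants = constants)
  })
  cores[order(names(cores))]
}

#' Read water-column samples from CSV
#'
#' Expects columns `station_id`, `date`, `depth_m` and any of `spm_g_m3`,
#' `tp_g_m3`, `srp_g_m3`, `be7_dpm_m3`, `be7_dpm_g`; one row per sample.
#'
#' @param path CSV file path.
#' @return List of [water_sample()] objects, in file order.
#' @export
read_water_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "date", "depth_m")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  opt <- c("spm_g_m3", "tp_g_m3", "srp_g_m3", "be7_dpm_m3", "be7_dpm_g")
  for (col in opt) if (!col %in% names(df)) df[[col]] <- NA_real_
  lapply(seq_len(nrow(df)), function(i)
    water_sample(df$station_id[i], df$date[i], df$depth_m[i],
                 df$spm_g_m3[i], df$tp_g_m3[i], df$srp_g_m3[i],
                 df$be7_dpm_m3[i], df$be7_dpm_g[i]))
}

#' Write sediment cores to the layer-table CSV schema
#'
#' Inverse of [read_core_csv()]: emits one row per layer with the station,
#' date and water depth repeated.
#'
#' @param cores A [sediment_core()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_core_csv <- function(cores, path) {
  if (inherits(cores, "sediment_core")) cores <- list(cores)
  rows <- lapply(cores, function(core) {
    df <- as.data.frame(core)
    cbind(station_id = attr(core, "station_id"),
          date = format(attr(core, "date")),
          df,
          water_depth_m = attr(core, "water_depth"))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
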