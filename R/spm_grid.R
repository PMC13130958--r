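#' Georeferenced SPM grid
#'
#' A lightweight regular raster: a numeric matrix (row 1 = northernmost row)
#' with square cells, a lower-left origin, a no-data marker and an optional
#' CRS label. `NA` in the matrix marks invalid pixels; the `nodata` value is
#' only used on disk.
#'
#' @param values Numeric matrix of pixel values (g m^-3 for SPM grids, m for
#'   bathymetry).
#' @param cellsize Pixel edge length in metres (> 0); pixel area is
#'   `cellsize^2`.
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @param nodata No-data value used when writing to disk (default -9999).
#' @param crs Optional CRS description string (metadata only).
#' @return An object of class `"spm_grid"`.
#' @examples
#' g <- spm_grid(matrix(1:6, 2, 3), cellsize = 300)
#' pixel_area(g)   # 9e4 m2
#' @export
spm_grid <- function(values, cellsize, xll = 0, yll = 0, nodata = -9999,
                     crs = NA_character_) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("cellsize must be a single positive number (metres)", call. = FALSE)
  structure(list(values = values, cellsize = cellsize, xll = xll, yll = yll,
                 nodata = nodata, crs = crs),
            class = "spm_grid")
}

#' @export
print.spm_grid <- function(x, ...) {
  cat(sprintf("spm_grid: %d x %d pixels, %g m cells, origin (%g, %g)%s\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll,
              if (is.na(x$crs)) "" else paste0(", crs ", x$crs)))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  values: min %.4g, mean %.4g, max %.4g (%d NA)\n",
                min(v), mean(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

#' @rdname spm_grid
#' @param grid An `spm_grid`.
#' @return `pixel_area()`: pixel area in m^2.
#' @export
pixel_area <- function(grid) {
  stopifnot(inherits(grid, "spm_grid"))
  grid$cellsize^2
}

.check_same_geometry <- function(a, b, what = "grids") {
  if (!identical(dim(a$values), dim(b$values)))
    stop(sprintf("%s differ in shape (%s vs %s)", what,
                 paste(dim(a$values), collapse = "x"),
                 paste(dim(b$values), collapse = "x")), call. = FALSE)
  if (abs(a$cellsize - b$cellsize) > 1e-9 ||
      abs(a$xll - b$xll) > 1e-6 || abs(a$yll - b$yll) > 1e-6)
    stop(sprintf("%s are not co-registered (cellsize/origin mismatch)", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Read and write grids as ESRI ASCII rasters
#'
#' Plain-text `.asc` interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' pixel values, north row first. No-data values become `NA` on read and are
#' restored bit-exact on write.
#'
#' @param path File path.
#' @param crs Optional CRS label attached on read.
#' @return `read_ascii_grid()` returns an [spm_grid()]; `write_ascii_grid()`
#'   returns `path` invisibly.
#' @export
read_ascii_grid <- function(path, crs = NA_character_) {
  lines <- readLines(path)
  if (length(lines) < 7L) stop(path, ": not an ASCII grid", call. = FALSE)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop(path, ": malformed ASCII grid header", call. = FALSE)
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != hdr$ncols * hdr$nrows)
    stop(path, ": pixel count does not match header", call. = FALSE)
  m <- matrix(body, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  spm_grid(m, cellsize = hdr$cellsize, xll = hdr$xllcorner,
           yll = hdr$yllcorner, nodata = hdr$nodata_value, crs = crs)
}

#' @rdname read_ascii_grid
#' @param grid An [spm_grid()].
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "spm_grid"))
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", grid$xll),
           sprintf("yllcorner %.10g", grid$yll),
           sprintf("cellsize %.10g", grid$cellsize),
           sprintf("NODATA_value %.10g", grid$nodata))
  rows <- apply(m, 1L, function(r) paste(format(r, digits = 15, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Single-band SPM retrieval configuration
#'
#' Coefficients of the semiempirical single-band SPM algorithm
#' \eqn{SPM = A_\rho \rho_w / (1 - \rho_w / C_\rho)} applied to
#' water-leaving reflectance \eqn{\rho_w = \pi R_{rs}}. Defaults are the
#' published red-band (665 nm) calibration; both coefficients are
#' sensor/region-tunable.
#'
#' @param A_rho Scale coefficient (g m^-3, > 0). Default 355.85.
#' @param C_rho Saturation reflectance (dimensionless, in (0, 1)).
#'   Default 0.1728.
#' @param wavelength Band centre in nm (metadata).
#' @return An object of class `"spm_algorithm"`.
#' @export
spm_algorithm <- function(A_rho = 355.85, C_rho = 0.1728, wavelength = 665) {
  if (!is.numeric(A_rho) || A_rho <= 0) stop("A_rho must be > 0", call. = FALSE)
  if (!is.numeric(C_rho) || C_rho <= 0 || C_rho >= 1)
    stop("C_rho must lie in (0, 1)", call. = FALSE)
  structure(list(A_rho = A_rho, C_rho = C_rho, wavelength = wavelength),
            class = "spm_algorithm")
}

#' SPM from water-leaving reflectance
#'
#' Applies the single-band algorithm pixel-wise. Reflectances at or above the
#' saturation value \eqn{C_\rho}, or negative, are invalid and return `NA`
#' (masked), never a number: near \eqn{C_\rho} the retrieval diverges.
#'
#' @param rho_w Water-leaving reflectance (dimensionless), scalar, vector,
#'   matrix or [spm_grid()].
#' @param config An [spm_algorithm()].
#' @return SPM in g m^-3 in the same shape as `rho_w` (an `spm_grid` in, an
#'   `spm_grid` out), with attribute `n_masked` counting invalidated pixels.
#' @examples
#' spm_from_reflectance(0.05)   # ~25.04 g m-3
#' @export
spm_from_reflectance <- function(rho_w, config = spm_algorithm()) {
  stopifnot(inherits(config, "spm_algorithm"))
  if (inherits(rho_w, "spm_grid")) {
    out <- rho_w
    res <- spm_from_reflectance(rho_w$values, config)
    out$values <- res
    attr(out, "n_masked") <- attr(res, "n_masked")
    return(out)
  }
  bad <- !is.na(rho_w) & (rho_w < 0 | rho_w >= config$C_rho)
  rho <- rho_w
  rho[bad] <- NA_real_
  spm <- config$A_rho * rho / (1 - rho / config$C_rho)
  structure(spm, n_masked = sum(bad))
}

#' @rdname spm_from_reflectance
#' @param spm SPM concentration (g m^-3, >= 0).
#' @return `reflectance_from_spm()`: the closed-form inverse
#'   \eqn{\rho_w = SPM / (A_\rho + SPM / C_\rho)}.
#' @export
reflectance_from_spm <- function(spm, config = spm_algorithm()) {
  stopifnot(inherits(config, "spm_algorithm"))
  if (any(spm < 0, na.rm = TRUE)) stop("spm must be >= 0", call. = FALSE)
  spm / (config$A_rho + spm / config$C_rho)
}

#' Pre/post-event SPM scene pair
#'
#' Two co-registered SPM grids bracketing a resuspension event.
#'
#' @param before,after [spm_grid()] objects on the same geometry.
#' @param date_before,date_after Acquisition dates; `after` must be later.
#' @return An object of class `"scene_pair"`.
#' @export
scene_pair <- function(before, after, date_before = NA, date_after = NA) {
  stopifnot(inherits(before, "spm_grid"), inherits(after, "spm_grid"))
  .check_same_geometry(before, after, "scene pair grids")
  if (!is.na(date_before) && !is.na(date_after) &&
      !(as.Date(date_after) > as.Date(date_before)))
    stop("after scene must postdate before scene", call. = FALSE)
  structure(list(before = before, after = after,
                 date_before = if (is.na(date_before)) NA else as.Date(date_before),
                 date_after = if (is.na(date_after)) NA else as.Date(date_after)),
            class = "scene_pair")
}

#' @export
print.scene_pair <- function(x, ...) {
  cat(sprintf("scene_pair: %s -> %s\n", format(x$date_before),
              format(x$date_after)))
  print(x$before); print(x$after)
  invisible(x)
}

#' Per-pixel change in SPM
#'
#' @param pair A [scene_pair()].
#' @return An [spm_grid()] of `after - before` (g m^-3); `NA` wherever either
#'   input pixel is invalid.
#' @export
delta_spm <- function(pair) {
  stopifnot(inherits(pair, "scene_pair"))
  out <- pair$before
  out$values <- pair$after$values - pair$before$values
  out
}

#' Resuspension pixel classification
#'
#' Flags pixels where the relative SPM increase exceeds the retrieval
#' uncertainty threshold: `100 * (after - before) / before > threshold_pct`.
#' Only increases count — deposition (negative change) is never classified as
#' resuspension. Pixels invalid in either scene, or with non-positive
#' baseline SPM, are `FALSE` and counted in the `n_unevaluable` attribute.
#'
#' @param pair A [scene_pair()].
#' @param threshold_pct Percent-change threshold (> 0). The retrieval
#'   uncertainty (NRMSE, in percent) is the natural choice; see [nrmse()].
#' @return Logical matrix mask with attribute `n_unevaluable`.
#' @export
resuspension_mask <- function(pair, threshold_pct = 13.9) {
  stopifnot(inherits(pair, "scene_pair"))
  if (!is.numeric(threshold_pct) || threshold_pct <= 0)
    stop("threshold_pct must be > 0", call. = FALSE)
  b <- pair$before$values; a <- pair$after$values
  unevaluable <- is.na(b) | is.na(a) | b <= 0
  pct <- 100 * (a - b) / b
  mask <- !unevaluable & pct > threshold_pct
  mask[is.na(mask)] <- FALSE
  structure(mask, n_unevaluable = sum(unevaluable))
}

#' Range-normalised root-mean-square error
#'
#' Retrieval validation metric: RMSE of predictions against observations,
#' normalised by the observed range and expressed in percent. Used as the
#' resuspension classification threshold.
#'
#' @param observed,predicted Paired numeric vectors (>= 2 observations
#'   spanning a non-zero range).
#' @return NRMSE in percent.
#' @examples
#' nrmse(c(10, 20, 30), c(12, 18, 33))   # ~11.9
#' @export
nrmse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  keep <- !is.na(observed) & !is.na(predicted)
  observed <- observed[keep]; predicted <- predicted[keep]
  if (length(observed) < 2L)
    stop("nrmse needs at least two paired observations", call. = FALSE)
  rng <- max(observed) - min(observed)
  if (rng <= 0) stop("observed values span a zero range", call. = FALSE)
  100 * sqrt(mean((predicted - observed)^2)) / rng
}
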