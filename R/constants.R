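#' Physical constants for beryllium-7 sediment analyses
#'
#' Bundles the constants shared across the package: the density of mineral
#' sediment particles, the half-life of the cosmogenic tracer and the number
#' of days used to convert daily rates to annual ones.
#'
#' @param particle_density Particle (grain) density \eqn{\rho_d} in g cm^-3.
#'   The default 2.45 g cm^-3 is typical of fine lacustrine mineral sediment.
#' @param half_life Beryllium-7 half-life in days. Default 53.3 d, the
#'   standard physical value.
#' @param days_per_year Days used in yearly/daily rate conversions.
#' @return An object of class `"be7_constants"`: a named list with components
#'   `particle_density`, `half_life`, `days_per_year` and the derived decay
#'   constant `lambda` (day^-1).
#' @examples
#' cst <- be7_constants()
#' cst$lambda                      # ln(2) / 53.3
#' be7_constants(half_life = 53)$lambda
#' @export
be7_constants <- function(particle_density = 2.45, half_life = 53.3,
                          days_per_year = 365) {
  stopifnot(is.numeric(particle_density), length(particle_density) == 1L,
            is.numeric(half_life), length(half_life) == 1L,
            is.numeric(days_per_year), length(days_per_year) == 1L)
  if (particle_density <= 0 || half_life <= 0 || days_per_year <= 0)
    stop("all constants must be strictly positive", call. = FALSE)
  structure(
    list(particle_density = particle_density,
         half_life = half_life,
         days_per_year = days_per_year,
         lambda = decay_constant(half_life)),
    class = "be7_constants"
  )
}

#' Radioactive decay constant from a half-life
#'
#' @param half_life Half-life in days (> 0).
#' @return Decay constant \eqn{\lambda = \ln(2) / T_{1/2}} in day^-1.
#' @examples
#' decay_constant(53.3)   # 0.013005 d^-1
#' @export
decay_constant <- function(half_life) {
  if (!is.numeric(half_life) || any(half_life <= 0))
    stop("half_life must be a positive number of days", call. = FALSE)
  log(2) / half_life
}

#' Mean lifetime of a radionuclide
#'
#' The mean (average) life \eqn{\tau = T_{1/2} / \ln 2 = 1/\lambda}, the decay
#' time scale over which mixed tracer-tagged particles redistribute.
#'
#' @param half_life Half-life in days (> 0).
#' @return Mean lifetime in days.
#' @examples
#' mean_lifetime(53.3)    # ~76.9 d
#' @export
mean_lifetime <- function(half_life) {
  if (!is.numeric(half_life) || any(half_life <= 0))
    stop("half_life must be a positive number of days", call. = FALSE)
  half_life / log(2)
}
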