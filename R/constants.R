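#' Physical constants used throughout the package
#'
#' CODATA 2018 values. The gas constant is exact in the 2019 SI.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{R_gas}{molar gas constant, J mol^-1 K^-1 (8.314462618)}
#'   \item{hbar}{reduced Planck constant, J s}
#'   \item{mu0_over_4pi}{magnetic constant / 4 pi, T m A^-1 (1e-7)}
#'   \item{gamma_H}{1H gyromagnetic ratio, rad s^-1 T^-1}
#'   \item{gamma_C}{13C gyromagnetic ratio, rad s^-1 T^-1}
#' }
#' @export
spindyn_constants <- list(
  R_gas        = 8.314462618,
  hbar         = 1.054571817e-34,
  mu0_over_4pi = 1e-7,
  gamma_H      = 2.6752218744e8,
  gamma_C      = 6.728284e7
)

# Bondi van der Waals radii (Angstrom) for the elements the pipeline meets.
.bondi_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98
)

#' Van der Waals radii sets
#'
#' Returns a named vector of van der Waals radii in Angstrom. Only the
#' `"bondi"` set is bundled; pass a named numeric vector anywhere a
#' `radii_set` argument is accepted to use custom radii.
#'
#' @param name radii set name; currently `"bondi"`.
#' @return named numeric vector, Angstrom.
#' @export
vdw_radii <- function(name = "bondi") {
  if (is.numeric(name) && !is.null(names(name))) return(name)
  name <- match.arg(name, "bondi")
  .bondi_radii
}

# internal: degrees <-> radians
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# internal: run expr with a temporarily seeded RNG, restoring global state.
# One seeded generator per call keeps generator outputs reproducible without
# disturbing the caller's RNG stream. seed = NULL leaves the RNG alone.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
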