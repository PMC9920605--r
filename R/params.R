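# Physical constants (eV - Angstrom - amu unit system)

#' Physical constants used internally
#'
#' The internal unit system is eV for energy, Angstrom for length and amu for
#' mass. The derived time unit is sqrt(amu A^2 / eV) = 10.180507 fs; all
#' user-facing times are quoted in ps or ns and converted at the interface.
#'
#' @format A named list with elements `kB` (Boltzmann constant, eV/K) and
#'   `time_unit_fs` (internal time unit, fs).
#' @export
pbd_constants <- list(
  kB = 8.617333262e-5,
  # sqrt(amu[kg] * (1 A)^2 [m^2] / eV[J]), expressed in fs
  time_unit_fs = sqrt(1.66053906660e-47 / 1.602176634e-19) * 1e15
)

#' Model parameters for a PBD homopolymer
#'
#' Builds the parameter set of the Peyrard-Bishop-Dauxois model for a
#' homopolymer chain: Morse depth `D` (eV) and inverse width `a` (1/A) of the
#' on-site base-pairing potential, stacking constant `K` (eV/A^2),
#' anharmonicity `rho` (dimensionless) and decay `b` (1/A) of the
#' nearest-neighbour stacking, and the base-pair reduced mass (amu).
#'
#' Presets follow the standard melting-curve parameterisation of the model:
#' AT (poly(dA).poly(dT)): D = 0.05 eV, a = 4.2 /A, K = 0.0228 eV/A^2;
#' GC (poly(dG).poly(dC)): D = 0.075 eV, a = 6.9 /A, K = 0.0192 eV/A^2;
#' shared rho = 2, b = 0.35 /A, mass = 300 amu. The preset also carries the
#' microcanonical energy per site that maps to physiological temperature
#' (~310 K): 0.043 eV for AT, 0.045 eV for GC.
#'
#' @param sequence `"AT"` or `"GC"` homopolymer preset.
#' @param D,a,K,rho,b,mass optional overrides of individual constants.
#' @param energy_per_site optional override of the per-site microcanonical
#'   energy (eV) associated with the preset.
#' @return An object of class `pbd_params` (named list).
#' @examples
#' p <- pbd_params("AT")
#' morse_potential(1, p)
#' @export
pbd_params <- function(sequence = c("AT", "GC"), D = NULL, a = NULL, K = NULL,
                       rho = NULL, b = NULL, mass = NULL,
                       energy_per_site = NULL) {
  sequence <- match.arg(sequence)
  preset <- switch(sequence,
    AT = list(D = 0.05, a = 4.2, K = 0.0228, energy_per_site = 0.043),
    GC = list(D = 0.075, a = 6.9, K = 0.0192, energy_per_site = 0.045)
  )
  par <- list(
    sequence = sequence,
    D = D %||% preset$D,
    a = a %||% preset$a,
    K = K %||% preset$K,
    rho = rho %||% 2,
    b = b %||% 0.35,
    mass = mass %||% 300,
    energy_per_site = energy_per_site %||% preset$energy_per_site
  )
  validate_pbd_params(par)
  structure(par, class = "pbd_params")
}

validate_pbd_params <- function(par) {
  with(par, {
    stopifnot(D > 0, a > 0, K > 0, b > 0, rho >= 0, mass > 0,
              energy_per_site >= 0)
  })
  invisible(par)
}

#' Load model parameters from a YAML/JSON config file
#'
#' The file must contain a `sequence` key (`AT` or `GC`) and may override any
#' of `D`, `a`, `K`, `rho`, `b`, `mass`, `energy_per_site`.
#'
#' @param path path to a YAML (or JSON, which YAML subsumes) file.
#' @return A `pbd_params` object.
#' @export
pbd_params_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$sequence)) {
    rlang::abort("config must name a `sequence` (AT or GC)")
  }
  pbd_params(
    sequence = cfg$sequence, D = cfg$D, a = cfg$a, K = cfg$K,
    rho = cfg$rho, b = cfg$b, mass = cfg$mass,
    energy_per_site = cfg$energy_per_site
  )
}

#' @export
print.pbd_params <- function(x, ...) {
  cat(sprintf(
    "<pbd_params> %s homopolymer: D=%g eV, a=%g /A, K=%g eV/A^2, rho=%g, b=%g /A, mass=%g amu, eps=%g eV/site\n",
    x$sequence, x$D, x$a, x$K, x$rho, x$b, x$mass, x$energy_per_site
  ))
  invisible(x)
}
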