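# PBD Hamiltonian surface: chain states, potentials, energies, forces.

#' Chain state of a PBD homopolymer
#'
#' A microstate of the lattice: transverse base-pair displacements `y` (A)
#' and conjugate momenta `p` (amu A per internal time unit), one per base
#' pair. Periodic boundary conditions (site 0 identified with site N) are
#' assumed by all energy and force routines.
#'
#' @param y numeric vector of displacements (A), length N >= 3.
#' @param p numeric vector of momenta, same length as `y`.
#' @return An object of class `chain_state`.
#' @export
chain_state <- function(y, p = rep(0, length(y))) {
  stopifnot(length(y) == length(p), length(y) >= 3,
            all(is.finite(y)), all(is.finite(p)))
  structure(list(y = as.double(y), p = as.double(p),
                 n_sites = length(y)),
            class = "chain_state")
}

#' @export
print.chain_state <- function(x, ...) {
  cat(sprintf("<chain_state> N=%d, max|y|=%.3g A, sum p^2=%.3g\n",
              x$n_sites, max(abs(x$y)), sum(x$p^2)))
  invisible(x)
}

#' Morse on-site potential
#'
#' `V1(y) = D (exp(-a y) - 1)^2`: the hydrogen-bond pairing potential of one
#' base pair, with dissociation plateau `D` as `y -> Inf`.
#'
#' @param y displacement(s) in A (vectorised).
#' @param params a [pbd_params()] object.
#' @return Energy in eV, same length as `y`.
#' @export
morse_potential <- function(y, params) {
  e <- exp(-params$a * y)
  params$D * (e - 1)^2
}

#' Anharmonic stacking potential
#'
#' `V2(yn, ym) = K/2 (1 + rho exp(-b (yn + ym))) (yn - ym)^2`: the
#' nearest-neighbour stacking coupling, whose effective stiffness drops from
#' `K (1 + rho)` for closed neighbours to `K` when both open. Symmetric in
#' its two displacement arguments.
#'
#' @param y_n,y_prev displacements of the two neighbouring base pairs (A),
#'   vectorised.
#' @inheritParams morse_potential
#' @return Energy in eV.
#' @export
stacking_potential <- function(y_n, y_prev, params) {
  d <- y_n - y_prev
  0.5 * params$K * (1 + params$rho * exp(-params$b * (y_n + y_prev))) * d^2
}

#' Total energy of a chain state
#'
#' Kinetic plus Morse plus stacking energy, with periodic closure (the bond
#' between sites N and 1 is included once).
#'
#' @param state a [chain_state()].
#' @inheritParams morse_potential
#' @return Total energy H in eV (scalar).
#' @export
total_energy <- function(state, params) {
  pbd_total_energy_cpp(state$y, state$p, unclass(params))
}

#' Per-site local energies
#'
#' The local energy of site i is its kinetic and Morse energy plus half of
#' each adjacent stacking bond, so that the local energies sum exactly to
#' the total Hamiltonian.
#'
#' @inheritParams total_energy
#' @return Numeric vector of length N (eV).
#' @export
local_energies <- function(state, params) {
  pbd_local_energies_cpp(state$y, state$p, unclass(params))
}

#' Forces on each site
#'
#' Returns `-dH/dy_n` for every site, including both neighbour stacking
#' contributions and the gradient of the `exp(-b (y_n + y_{n-1}))` stacking
#' prefactor, with periodic indexing.
#'
#' @inheritParams total_energy
#' @return Numeric vector of length N (eV/A).
#' @export
pbd_forces <- function(state, params) {
  pbd_forces_cpp(state$y, unclass(params))
}
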