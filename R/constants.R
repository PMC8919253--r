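#' Physical constants used throughout the package
#'
#' Units are fixed package-wide: length in angstrom (A), time in fs, energy in
#' eV, mass in unified atomic mass units (u), charge in elementary charges (e).
#'
#' @format A named list with elements:
#' \describe{
#'   \item{coulomb}{Coulomb constant, 14.3996 eV A / e^2}
#'   \item{kB}{Boltzmann constant, eV / K}
#'   \item{u_ev}{kinetic-energy conversion: 1 u (A/fs)^2 in eV}
#'   \item{electron_mass_u}{electron mass in u}
#' }
#' @export
xp_constants <- list(
  coulomb         = 14.3996,        # eV A / e^2
  kB              = 8.617333262e-5, # eV / K
  u_ev            = 103.6426966,    # 1 u * (A/fs)^2 in eV
  electron_mass_u = 0.000548579909  # CODATA electron mass, u
)

# CODATA/IUPAC atomic masses. Monoisotopic: most abundant isotope mass;
# average: IUPAC 2021 conventional atomic weights.
.element_data <- data.frame(
  element      = c("H", "C", "N", "O", "S"),
  monoisotopic = c(1.00782503207, 12.0, 14.0030740048, 15.9949146196, 31.97207100),
  average      = c(1.008, 12.011, 14.007, 15.999, 32.06),
  stringsAsFactors = FALSE
)

# van der Waals radii (A), used only to size the non-bonded repulsion.
.vdw_radii <- c(H = 1.10, C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Element mass table
#'
#' Monoisotopic masses and average atomic weights for the elements of
#' cystine chemistry (H, C, N, O, S).
#'
#' @return A tibble with columns `element`, `monoisotopic` (u), `average` (u).
#' @export
#' @examples
#' element_masses()
element_masses <- function() {
  tibble::as_tibble(.element_data)
}

#' Export the element mass table as JSON
#'
#' @param path file to write; the table plus the electron mass constant.
#' @return `path`, invisibly.
#' @export
write_element_masses <- function(path) {
  jsonlite::write_json(
    list(elements = .element_data,
         electron_mass_u = xp_constants$electron_mass_u),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

.element_mass <- function(element, scale = c("monoisotopic", "average")) {
  scale <- match.arg(scale)
  idx <- match(element, .element_data$element)
  if (anyNA(idx)) {
    stop("unknown element(s): ", paste(element[is.na(idx)], collapse = ", "))
  }
  .element_data[[scale]][idx]
}
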