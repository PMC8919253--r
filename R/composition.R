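#' Elemental compositions and m/z
#'
#' A `composition` is an element -> count map plus an integer charge (in
#' elementary charges, sign included). It is the unit in which every m/z in
#' the package is computed.
#'
#' @param counts named integer vector of element counts (all >= 1).
#' @param charge integer charge, sign included. 0 means a neutral species.
#' @return An object of class `composition`.
#' @export
#' @examples
#' composition(c(C = 1, O = 2, H = 1), charge = 1)  # COOH+
composition <- function(counts, charge = 0L) {
  if (length(counts) == 0) stop("composition must contain at least one element")
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("counts must be a named vector of element counts")
  }
  if (any(counts != round(counts)) || any(counts < 1)) {
    stop("element counts must be positive integers")
  }
  if (length(charge) != 1 || charge != round(charge)) {
    stop("charge must be a single integer")
  }
  # collapse duplicated symbols, validate against the element table;
  # store in Hill order (C, H, then the rest alphabetically)
  counts <- tapply(as.integer(counts), names(counts), sum)
  hill <- c("C", "H", sort(setdiff(names(counts), c("C", "H"))))
  counts <- counts[order(match(names(counts), hill))]
  .element_mass(names(counts))  # errors on unknown elements
  structure(
    list(counts = counts, charge = as.integer(charge)),
    class = "composition"
  )
}

#' @export
print.composition <- function(x, ...) {
  cat(format_composition(x), "\n")
  invisible(x)
}

#' Render a composition as a formula string
#'
#' @param comp a [composition()].
#' @param charge_sign append a trailing charge token (`+`, `2+`, ...)?
#' @return A single string, e.g. `"C2SNH4+"` printed in table order.
#' @export
format_composition <- function(comp, charge_sign = TRUE) {
  stopifnot(inherits(comp, "composition"))
  body <- paste0(names(comp$counts),
                 ifelse(comp$counts == 1, "", comp$counts),
                 collapse = "")
  if (!charge_sign || comp$charge == 0) return(body)
  mag <- abs(comp$charge)
  paste0(body, if (comp$charge > 0) "+" else "-", if (mag > 1) mag else "")
}

#' Parse a molecular formula
#'
#' The grammar is order-preserving and parenthesis-free: a sequence of
#' element symbols each followed by an optional positive count, with an
#' optional trailing charge token (`+`, `-`, `2+`, `3-`). Examples:
#' `"COOH"`, `"C2SNH4"`, `"C2O2NH4+"`.
#'
#' @param text formula string.
#' @param charge overrides the charge parsed from the trailing token.
#' @return A [composition()].
#' @export
#' @examples
#' parse_formula("COOH")        # C1 O2 H1, neutral
#' parse_formula("C2SNH4+")     # charge +1
parse_formula <- function(text, charge = NULL) {
  if (!is.character(text) || length(text) != 1 || !nzchar(text)) {
    stop("formula must be a non-empty string")
  }
  # trailing charge token: a sign with optional magnitude after it
  # ("+", "-", "+2", "-3"); a bare sign means one elementary charge
  body <- text
  parsed_charge <- 0L
  m <- regmatches(text, regexec("^(.*?)([+-])([0-9]*)$", text))[[1]]
  if (length(m) == 4) {
    body <- m[2]
    mag <- if (nzchar(m[4])) as.integer(m[4]) else 1L
    parsed_charge <- if (m[3] == "+") mag else -mag
  }
  if (!nzchar(body)) stop("formula has no element symbols: ", text)
  tokens <- regmatches(body, gregexpr("[A-Z][a-z]?[0-9]*", body))[[1]]
  if (sum(nchar(tokens)) != nchar(body)) {
    stop("cannot parse formula: ", text)
  }
  syms <- sub("[0-9]*$", "", tokens)
  nums <- sub("^[A-Za-z]+", "", tokens)
  cnts <- ifelse(nzchar(nums), suppressWarnings(as.integer(nums)), 1L)
  if (any(is.na(cnts)) || any(cnts < 1)) stop("element counts must be >= 1: ", text)
  composition(stats::setNames(cnts, syms),
              charge = if (is.null(charge)) parsed_charge else charge)
}

#' Molecular mass of a composition
#'
#' The mass is the sum of atomic masses minus `charge` electron masses when
#' `electron_correction` is on (a cation is lighter than its neutral parent).
#'
#' @param comp a [composition()].
#' @param scale `"monoisotopic"` or `"average"`.
#' @param electron_correction subtract `charge` electron masses (default TRUE).
#' @return Mass in u.
#' @export
molecular_mass <- function(comp, scale = c("monoisotopic", "average"),
                           electron_correction = TRUE) {
  stopifnot(inherits(comp, "composition"))
  scale <- match.arg(scale)
  m <- sum(comp$counts * .element_mass(names(comp$counts), scale))
  if (electron_correction) m <- m - comp$charge * xp_constants$electron_mass_u
  m
}

#' Mass-to-charge ratio of a composition
#'
#' `m/z = |mass / charge|` in u per elementary charge. The nominal scale is
#' the average mass rounded to the nearest integer (this reproduces the
#' integer peak labels used for unit-resolution spectra, e.g. m/z 64 for the
#' disulfide cation whose average mass is 64.12).
#'
#' @inheritParams molecular_mass
#' @param scale `"monoisotopic"`, `"average"` or `"nominal"`.
#' @return m/z in u/e.
#' @export
#' @examples
#' mz(parse_formula("C2SNH4+"))                      # 74.00590
#' mz(parse_formula("C2O2NH4+"))                     # 74.02365
#' mz(parse_formula("C6H13N2O4S2+"), scale = "average")  # 241.3
mz <- function(comp, scale = c("monoisotopic", "average", "nominal"),
               electron_correction = TRUE) {
  stopifnot(inherits(comp, "composition"))
  scale <- match.arg(scale)
  if (comp$charge == 0) stop("m/z is undefined for charge 0 (mass is; use molecular_mass)")
  base <- if (scale == "nominal") "average" else scale
  val <- abs(molecular_mass(comp, base, electron_correction) / comp$charge)
  if (scale == "nominal") round(val) else val
}
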