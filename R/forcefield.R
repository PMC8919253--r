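#' Default bond parameters for the surrogate potential
#'
#' Morse bonds parameterised by a harmonic stiffness `k` (eV/A^2, the
#' curvature at the minimum), equilibrium length `d0` (A) and well depth
#' `depth` (eV); the Morse width is `a = sqrt(k / (2 depth))`. Values are
#' generic covalent-bond magnitudes: the surrogate exists to produce
#' trajectory ensembles with realistic statistical structure (thermal
#' fluctuations, anharmonicity, dissociation), not to reproduce any specific
#' electronic-structure forces.
#'
#' @return A tibble with columns `type` (sorted element pair), `k`, `d0`,
#'   `depth`.
#' @export
bond_type_params <- function() {
  tibble::tribble(
    ~type,  ~k, ~d0, ~depth,
    "C-C", 27, 1.53, 3.6,
    "C-N", 29, 1.47, 3.3,
    "C-O", 40, 1.30, 4.5,
    "C-S", 19, 1.82, 3.0,
    "S-S", 17, 2.05, 2.8,
    "C-H", 32, 1.09, 4.3,
    "H-N", 35, 1.01, 4.0,
    "H-O", 44, 0.96, 4.8
  )
}

.pair_type <- function(e1, e2) {
  purrr::map2_chr(e1, e2, function(x, y) paste(sort(c(x, y)), collapse = "-"))
}

.resolve_scale <- function(scale, labels, what) {
  if (is.null(names(scale))) {
    if (length(scale) != 1) stop(what, " must be a scalar or a named vector")
    return(rep(scale, length(labels)))
  }
  out <- rep(1, length(labels))
  nm <- normalize_bond(names(scale))
  unknown <- setdiff(nm, labels)
  if (length(unknown)) stop(what, " names are not bonds: ", paste(unknown, collapse = ", "))
  out[match(nm, labels)] <- unname(scale)
  out
}

#' Build a surrogate force field for a molecular graph
#'
#' The potential is a sum of Morse bond terms, pairwise Coulomb interactions
#' on fixed partial charges, and a short-range `(sigma/r)^12` repulsion
#' between non-bonded atoms. Directly bonded (1-2) pairs are excluded from
#' the non-bonded terms, the standard molecular-mechanics convention.
#'
#' @param graph a [molecular_graph()].
#' @param charges per-atom partial charges (e); must sum to `total_charge`.
#' @param total_charge declared total charge (e); defaults to `sum(charges)`.
#' @param bond_params bond parameter table as [bond_type_params()]; every
#'   element pair bonded in `graph` must be covered.
#' @param stiffness_scale scalar, or named vector keyed by bond label
#'   (e.g. `c("C1-C2" = 0.5)`), multiplying `k`.
#' @param depth_scale same shape, multiplying the Morse well depth. Values
#'   below 1 weaken bonds; this is the dial used to emulate the
#'   destabilisation of an ionized state and to engineer known break
#'   probabilities in recovery tests.
#' @param rep_eps repulsion energy scale (eV); 0 switches repulsion off.
#' @param rep_scale `sigma` for a pair is `rep_scale * (rvdw_i + rvdw_j)`.
#' @param kc Coulomb constant (eV A / e^2).
#' @return An object of class `force_field`.
#' @export
force_field <- function(graph, charges,
                        total_charge = NULL,
                        bond_params = bond_type_params(),
                        stiffness_scale = 1, depth_scale = 1,
                        rep_eps = 0.02, rep_scale = 0.55,
                        kc = xp_constants$coulomb) {
  stopifnot(inherits(graph, "mol_graph"))
  n <- nrow(graph$atoms)
  if (length(charges) != n) stop("need one partial charge per atom")
  if (is.null(total_charge)) total_charge <- sum(charges)
  if (abs(sum(charges) - total_charge) > 1e-9) {
    stop("partial charges sum to ", sum(charges), ", not the declared total ",
         total_charge)
  }

  b <- graph$bonds
  typ <- .pair_type(graph$atoms$element[b$i], graph$atoms$element[b$j])
  row <- match(typ, bond_params$type)
  if (anyNA(row)) {
    stop("no bond parameters for type(s): ", paste(unique(typ[is.na(row)]), collapse = ", "))
  }
  k     <- bond_params$k[row] * .resolve_scale(stiffness_scale, b$label, "stiffness_scale")
  depth <- bond_params$depth[row] * .resolve_scale(depth_scale, b$label, "depth_scale")
  if (any(k <= 0) || any(depth <= 0)) stop("bond stiffness and depth must stay > 0")
  bonds <- tibble::tibble(i = b$i, j = b$j, label = b$label,
                          k = k, d0 = bond_params$d0[row], depth = depth,
                          a = sqrt(k / (2 * depth)))

  # non-bonded pair list: all pairs minus 1-2 exclusions
  all_pairs <- utils::combn(n, 2)
  excl <- .bond_key_idx(b$i, b$j)
  keep <- !(.bond_key_idx(all_pairs[1, ], all_pairs[2, ]) %in% excl)
  pi_ <- all_pairs[1, keep]; pj <- all_pairs[2, keep]
  sig <- rep_scale * (.vdw_radii[graph$atoms$element[pi_]] +
                      .vdw_radii[graph$atoms$element[pj]])
  pairs <- tibble::tibble(i = pi_, j = pj,
                          qq = charges[pi_] * charges[pj],
                          sigma = unname(sig))

  # incidence matrices used by the vectorized force evaluation
  inc <- function(ii, jj, m) {
    M <- matrix(0, n, m)
    M[cbind(ii, seq_len(m))] <- 1
    M[cbind(jj, seq_len(m))] <- -1
    M
  }
  structure(list(
    n = n,
    elements = graph$atoms$element,
    masses = .element_mass(graph$atoms$element, "average"),
    charges = charges,
    total_charge = total_charge,
    bonds = bonds,
    pairs = pairs,
    rep_eps = rep_eps,
    kc = kc,
    inc_bonds = inc(bonds$i, bonds$j, nrow(bonds)),
    inc_pairs = inc(pairs$i, pairs$j, nrow(pairs))
  ), class = "force_field")
}

#' @export
print.force_field <- function(x, ...) {
  cat("<force_field> ", x$n, " atoms, ", nrow(x$bonds), " Morse bonds, ",
      nrow(x$pairs), " non-bonded pairs, total charge ",
      format(x$total_charge), " e\n", sep = "")
  invisible(x)
}

#' Surrogate force field for protonated cystine
#'
#' Partial charges follow the default model: the total charge is spread
#' uniformly over the heavy atoms plus the extra amine proton (a classical
#' charge distribution for the ionized state is not uniquely defined; this
#' uniform model is the package default and is configurable through
#' [force_field()]).
#'
#' For the ionized (+3) state the Morse well depths are scaled by
#' `depth_scale` (default 0.15 when `total_charge > 1`): a classical
#' ground-state force field cannot lose bonding electrons, so the weakening
#' stands in for the valence holes left by Auger decay and lets the Coulomb
#' repulsion actually sever bonds.
#'
#' @param graph cystine topology (rebuilt if omitted).
#' @param total_charge total charge in e (+1 thermal ground state, +3 after
#'   ionization and Auger decay).
#' @param depth_scale Morse-depth scaling; `NULL` picks 1 for `total_charge
#'   <= 1` and 0.15 otherwise.
#' @param stiffness_scale passed to [force_field()].
#' @param ... further arguments for [force_field()].
#' @return A `force_field`.
#' @export
cystine_force_field <- function(graph = cystine_topology(), total_charge = 1,
                                depth_scale = NULL, stiffness_scale = 1, ...) {
  if (is.null(depth_scale)) depth_scale <- if (total_charge > 1) 0.15 else 1
  heavy <- graph$atoms$element != "H"
  site <- heavy | graph$atoms$label == "H7"
  charges <- rep(0, nrow(graph$atoms))
  charges[site] <- total_charge / sum(site)
  force_field(graph, charges, total_charge = total_charge,
              depth_scale = depth_scale, stiffness_scale = stiffness_scale, ...)
}

# potential energy and forces at configuration `pos` (N x 3).
# Returns list(F = N x 3 matrix in eV/A, potential = eV).
.ff_eval <- function(pos, ff) {
  Fmat <- matrix(0, ff$n, 3)
  pot <- 0
  b <- ff$bonds
  if (nrow(b)) {
    dv <- pos[b$i, , drop = FALSE] - pos[b$j, , drop = FALSE]
    r <- sqrt(rowSums(dv * dv))
    x <- r - b$d0
    em <- exp(-b$a * x)
    pot <- pot + sum(b$depth * (1 - em)^2)
    dUdr <- 2 * b$depth * b$a * em * (1 - em)
    Fmat <- Fmat + ff$inc_bonds %*% (dv * (-dUdr / r))
  }
  p <- ff$pairs
  if (nrow(p)) {
    dv <- pos[p$i, , drop = FALSE] - pos[p$j, , drop = FALSE]
    r <- sqrt(rowSums(dv * dv))
    coul <- ff$kc * p$qq / r
    s12 <- if (ff$rep_eps > 0) ff$rep_eps * (p$sigma / r)^12 else 0
    pot <- pot + sum(coul) + sum(s12)
    dUdr <- -coul / r - 12 * s12 / r
    Fmat <- Fmat + ff$inc_pairs %*% (dv * (-dUdr / r))
  }
  list(F = Fmat, potential = pot)
}
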