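#' Molecular graphs
#'
#' A `mol_graph` is a labeled simple undirected graph: an atom table, a bond
#' table (unordered index pairs) and a total charge. Coordinates (angstrom)
#' are optional and carry the fixture geometry used to seed simulations.
#'
#' @param atoms tibble/data.frame with columns `element` and `label`
#'   (labels unique where given).
#' @param bonds tibble/data.frame with integer columns `i`, `j` (atom indices).
#' @param charge total integer charge.
#' @param coords optional N x 3 numeric matrix of positions (A).
#' @return An object of class `mol_graph`.
#' @export
molecular_graph <- function(atoms, bonds, charge = 0L, coords = NULL) {
  atoms <- tibble::as_tibble(atoms)
  bonds <- tibble::as_tibble(bonds)
  n <- nrow(atoms)
  stopifnot(all(c("element", "label") %in% names(atoms)),
            all(c("i", "j") %in% names(bonds)))
  if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n)) {
    stop("bond endpoints must be valid atom indices")
  }
  if (any(bonds$i == bonds$j)) stop("self-bonds are not allowed")
  lab <- atoms$label[!is.na(atoms$label)]
  if (anyDuplicated(lab)) stop("atom labels must be unique")
  key <- .bond_key_idx(bonds$i, bonds$j)
  if (anyDuplicated(key)) stop("duplicate bonds are not allowed (simple graph)")
  bonds$label <- .bond_label(atoms$label[pmin(bonds$i, bonds$j)],
                             atoms$label[pmax(bonds$i, bonds$j)])
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == n, ncol(coords) == 3)
  }
  structure(list(atoms = atoms, bonds = bonds,
                 charge = as.integer(charge), coords = coords),
            class = "mol_graph")
}

.bond_key_idx <- function(i, j) paste(pmin(i, j), pmax(i, j))

# canonical bond label: the two atom labels sorted, joined by "-"
.bond_label <- function(a, b) {
  purrr::map2_chr(a, b, function(x, y) paste(sort(c(x, y)), collapse = "-"))
}

#' Normalize a user-written bond name to its canonical label
#'
#' `"S1-C3"`, `"C3-S1"` and `"C3–S1"` all map to `"C3-S1"`.
#'
#' @param x character vector of bond names, two atom labels per entry.
#' @return Canonical labels (atom labels sorted, joined with `-`).
#' @export
normalize_bond <- function(x) {
  parts <- strsplit(gsub("–|—|/", "-", x), "-", fixed = TRUE)
  purrr::map_chr(parts, function(p) {
    p <- trimws(p)
    if (length(p) != 2) stop("bond name must contain two atom labels: ", paste(p, collapse = "-"))
    paste(sort(p), collapse = "-")
  })
}

#' @export
print.mol_graph <- function(x, ...) {
  comp <- graph_composition(x)
  cat("<mol_graph> ", format_composition(comp), ": ",
      nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Elemental composition of a molecular graph
#'
#' @param graph a [molecular_graph()].
#' @return A [composition()] carrying the graph's total charge.
#' @export
graph_composition <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  tab <- table(graph$atoms$element)
  composition(stats::setNames(as.integer(tab), names(tab)), charge = graph$charge)
}

.as_igraph <- function(graph, drop_bonds = character()) {
  keep <- !(graph$bonds$label %in% drop_bonds)
  igraph::make_graph(
    edges = as.vector(rbind(graph$bonds$i[keep], graph$bonds$j[keep])),
    n = nrow(graph$atoms), directed = FALSE
  )
}

#' Protonated cystine topology
#'
#' The cystine dimer (two cysteines joined by the S1-S2 disulfide bridge)
#' with one extra proton on an amine nitrogen: composition C6H13N2O4S2,
#' charge +1, 27 atoms, 26 bonds. Atom notation follows the conventional
#' numbering: C1/C4 are the alpha carbons, C2/C5 the carboxyl carbons,
#' C3/C6 the CH2 carbons bonded to S1/S2. The two nitrogen sites are
#' symmetric; the protonation site is configurable.
#'
#' Coordinates are a deliberately rough extended-conformation build; they are
#' relaxed against the force field (see [minimize_geometry()]) before any
#' dynamics.
#'
#' @param protonation_site `"N1"` (default) or `"N2"`.
#' @return A [molecular_graph()] with fixture coordinates.
#' @export
#' @examples
#' g <- cystine_topology()
#' nrow(g$atoms)   # 27
cystine_topology <- function(protonation_site = c("N1", "N2")) {
  protonation_site <- match.arg(protonation_site)

  heavy <- tibble::tribble(
    ~label, ~element, ~x, ~y, ~z,
    "S1", "S",  0.00,  0.00,  0.00,
    "S2", "S",  2.05,  0.00,  0.00,
    "C3", "C", -1.40,  1.15,  0.00,
    "C1", "C", -2.65,  0.28,  0.10,
    "C2", "C", -4.00,  1.05,  0.20,
    "N1", "N", -2.80, -0.65, -1.05,
    "O1", "O", -5.05,  0.40,  0.35,
    "O2", "O", -4.00,  2.35,  0.15,
    "C6", "C",  3.45,  1.15,  0.00,
    "C4", "C",  4.70,  0.28, -0.10,
    "C5", "C",  6.05,  1.05, -0.20,
    "N2", "N",  4.85, -0.65,  1.05,
    "O3", "O",  7.10,  0.40, -0.35,
    "O4", "O",  6.05,  2.35, -0.15
  )
  hydro <- tibble::tribble(
    ~label, ~parent, ~x, ~y, ~z,
    "H1",  "C1", -2.20,  1.03,  0.80,
    "H2",  "C3", -1.80,  1.80,  0.80,
    "H3",  "C3", -1.80,  1.80, -0.80,
    "H4",  "O2", -3.20,  2.90,  0.15,
    "H5",  "N1", -1.95, -1.15, -1.20,
    "H6",  "N1", -3.65, -1.15, -1.20,
    "H7",  "N1", -2.80, -1.60, -0.70,   # the extra proton (moved if site = N2)
    "H8",  "C4",  4.25,  1.03, -0.80,
    "H9",  "C6",  3.85,  1.80, -0.80,
    "H10", "C6",  3.85,  1.80,  0.80,
    "H11", "O4",  5.25,  2.90, -0.15,
    "H12", "N2",  4.00, -1.15,  1.20,
    "H13", "N2",  5.70, -1.15,  1.20
  )
  if (protonation_site == "N2") {
    k <- hydro$label == "H7"
    hydro$parent[k] <- "N2"
    hydro[k, c("x", "y", "z")] <- list(4.85, -1.60, 0.70)
  }

  atoms <- tibble::tibble(
    element = c(heavy$element, rep("H", nrow(hydro))),
    label   = c(heavy$label, hydro$label)
  )
  coords <- rbind(as.matrix(heavy[, c("x", "y", "z")]),
                  as.matrix(hydro[, c("x", "y", "z")]))
  rownames(coords) <- atoms$label

  idx <- function(lbl) match(lbl, atoms$label)
  heavy_bonds <- matrix(c(
    "S1", "S2",  "S1", "C3",  "C3", "C1",  "C1", "C2",  "C1", "N1",
    "C2", "O1",  "C2", "O2",  "S2", "C6",  "C6", "C4",  "C4", "C5",
    "C4", "N2",  "C5", "O3",  "C5", "O4"
  ), ncol = 2, byrow = TRUE)
  bonds <- tibble::tibble(
    i = c(idx(heavy_bonds[, 1]), idx(hydro$parent)),
    j = c(idx(heavy_bonds[, 2]), idx(hydro$label))
  )
  molecular_graph(atoms, bonds, charge = 1L, coords = coords)
}

#' Fragments from a set of broken bonds
#'
#' Removing the broken bonds from the molecular graph and taking connected
#' components yields the fragments. Each fragment carries its elemental
#' composition (neutral: the classical simulation cannot partition charge),
#' monoisotopic/average/nominal masses, and the nominal m/z of the
#' hypothetical +1 cation used to compare with a mass spectrum.
#'
#' @param graph a [molecular_graph()].
#' @param broken character vector of bond names (any order of the two atom
#'   labels); empty means the intact parent.
#' @return A tibble with one row per fragment: `fragment`, `formula`,
#'   `n_atoms`, `atoms` (list of atom indices), `monoisotopic`, `average`,
#'   `nominal` (u, neutral) and `mz_plus1` (nominal m/z of the +1 cation).
#' @export
#' @examples
#' g <- cystine_topology()
#' fragments_from_broken_bonds(g, c("C3-S1", "C6-S2"))  # SS unit + two halves
fragments_from_broken_bonds <- function(graph, broken = character()) {
  stopifnot(inherits(graph, "mol_graph"))
  broken <- if (length(broken)) normalize_bond(broken) else character()
  missing <- setdiff(broken, graph$bonds$label)
  if (length(missing)) {
    stop("not bonds of the graph: ", paste(missing, collapse = ", "))
  }
  comp_membership <- igraph::components(.as_igraph(graph, drop_bonds = broken))$membership
  split_idx <- split(seq_len(nrow(graph$atoms)), comp_membership)

  purrr::map_dfr(seq_along(split_idx), function(k) {
    ids <- split_idx[[k]]
    tab <- table(graph$atoms$element[ids])
    comp <- composition(stats::setNames(as.integer(tab), names(tab)), charge = 0L)
    cat_comp <- composition(comp$counts, charge = 1L)
    tibble::tibble(
      fragment = k,
      formula = format_composition(comp),
      n_atoms = length(ids),
      atoms = list(ids),
      monoisotopic = molecular_mass(comp, "monoisotopic"),
      average = molecular_mass(comp, "average"),
      nominal = round(molecular_mass(comp, "average")),
      mz_plus1 = mz(cat_comp, scale = "nominal")
    )
  })
}
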