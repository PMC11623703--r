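#' Molecule graph data model
#'
#' A molecule with N atoms is a fully connected graph: every atom carries a
#' 3D position, an atom-type class and a formal-charge class, and every
#' unordered atom pair carries a bond-order class (including an explicit
#' "none" class, so the edge representation is total). Categorical values are
#' stored as 1-based indices into the per-modality vocabularies.
#'
#' Pairs are stored in lexicographic order (1,2), (1,3), ..., (1,N), (2,3),
#' ...; see [pair_index()].
#'
#' @param positions N x 3 numeric matrix of coordinates in Angstrom.
#' @param atom_types Integer vector (length N) of atom-type indices.
#' @param charges Integer vector (length N) of charge-class indices.
#' @param bond_orders Integer vector (length N(N-1)/2) of bond-class indices
#'   per unordered pair.
#' @param vocab List of vocabularies (`atom`, `charge`, `bond`) as returned
#'   by [default_vocabs()].
#' @param name Optional molecule name (used as the SDF title line).
#' @return An object of class `dfmol_graph`.
#' @seealso [validate_graph()], [read_sdf()], [write_sdf()]
#' @export
molecule_graph <- function(positions, atom_types, charges, bond_orders,
                           vocab = default_vocabs(), name = "") {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  g <- structure(
    list(n_atoms = nrow(positions),
         positions = positions,
         atom_types = as.integer(atom_types),
         charges = as.integer(charges),
         bond_orders = as.integer(bond_orders),
         vocab = vocab,
         name = name),
    class = "dfmol_graph"
  )
  viol <- validate_graph(g)
  if (length(viol))
    stop("invalid molecule graph: ", paste(vapply(viol, `[[`, "", "message"),
                                           collapse = "; "))
  g
}

#' @export
print.dfmol_graph <- function(x, ...) {
  elems <- x$vocab$atom$names[x$atom_types]
  cat("<molecule_graph> ", if (nzchar(x$name)) paste0(x$name, ", "),
      x$n_atoms, " atoms (", paste0(names(table(elems)),
      as.integer(table(elems)), collapse = " "), "), ",
      sum(x$bond_orders != 1L), " bonds\n", sep = "")
  invisible(x)
}

#' Number of unordered atom pairs for N atoms
#' @param n Number of atoms.
#' @return `n (n - 1) / 2`.
#' @export
n_pairs <- function(n) as.integer(n * (n - 1) / 2)

#' All unordered atom pairs, in storage order
#' @param n Number of atoms.
#' @return `n_pairs(n) x 2` integer matrix with columns `i < j`, rows in
#'   lexicographic order.
#' @export
pairs_matrix <- function(n) {
  if (n < 2) return(matrix(integer(0), ncol = 2,
                           dimnames = list(NULL, c("i", "j"))))
  m <- t(utils::combn(n, 2L))
  dimnames(m) <- list(NULL, c("i", "j"))
  m
}

#' Storage index of the unordered pair {i, j}
#' @param i,j Atom indices (any order, `i != j`).
#' @param n Number of atoms.
#' @return Integer position of the pair in the `bond_orders` vector.
#' @export
pair_index <- function(i, j, n) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (any(lo == hi)) stop("self-pairs have no bond slot")
  as.integer((lo - 1) * n - lo * (lo - 1) / 2 + (hi - lo))
}

#' Validate molecule-graph invariants
#'
#' Checks field shapes, index ranges (MASK indices are only legal when the
#' vocabulary defines a MASK token), and finiteness of coordinates.
#' Violations are returned, not raised.
#'
#' @param g A `dfmol_graph` (or a structurally similar list).
#' @return A list of violation records, each with elements `field` and
#'   `message`; empty if the graph is well formed.
#' @export
validate_graph <- function(g) {
  v <- list()
  bad <- function(field, message)
    v[[length(v) + 1L]] <<- list(field = field, message = message)
  n <- g$n_atoms
  if (!is.matrix(g$positions) || ncol(g$positions) != 3 ||
      nrow(g$positions) != n)
    bad("positions", sprintf("positions must be %d x 3", n))
  else if (!all(is.finite(g$positions)))
    bad("positions", "non-finite coordinates")
  check_idx <- function(x, vocab, field, len) {
    if (length(x) != len) {
      bad(field, sprintf("%s has length %d, expected %d", field,
                         length(x), len))
      return()
    }
    out <- which(is.na(x) | x < 1L | x > vocab$size)
    if (length(out))
      bad(field, sprintf("%s indices out of range at %s", field,
                         paste(utils::head(out, 5), collapse = ",")))
  }
  check_idx(g$atom_types, g$vocab$atom, "atom_types", n)
  check_idx(g$charges, g$vocab$charge, "charges", n)
  check_idx(g$bond_orders, g$vocab$bond, "bond_orders", n_pairs(n))
  v
}

#' Element symbols of a molecule's atoms
#' @param g A `dfmol_graph`.
#' @return Character vector of element symbols (MASK atoms yield `"<MASK>"`).
#' @export
element_symbols <- function(g) g$vocab$atom$names[g$atom_types]

#' Does a molecule contain any MASK state?
#' @param g A `dfmol_graph`.
#' @return Logical.
#' @export
has_mask <- function(g) {
  mi <- function(vocab, x) !is.na(vocab$mask_index) && any(x == vocab$mask_index)
  mi(g$vocab$atom, g$atom_types) || mi(g$vocab$charge, g$charges) ||
    mi(g$vocab$bond, g$bond_orders)
}

#' Bonded-pair table of a molecule
#' @param g A `dfmol_graph`.
#' @return Data frame with columns `i`, `j`, `class` (bond vocabulary index)
#'   and `order` (numeric bond order), one row per pair whose class is not
#'   "none".
#' @export
bond_table <- function(g) {
  pm <- pairs_matrix(g$n_atoms)
  keep <- g$bond_orders != 1L
  cls <- g$bond_orders[keep]
  data.frame(i = pm[keep, 1], j = pm[keep, 2], class = cls,
             order = bond_order_value(cls))
}
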