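#' Categorical vocabulary
#'
#' A vocabulary maps class labels of one categorical modality (atom types,
#' formal charges, bond orders) to integer indices. The optional MASK token,
#' used by the CTMC flow variant as an absorbing-prior state, is always the
#' last index when present.
#'
#' @param names Character vector of unique class labels, ordered.
#' @param mask Logical; append a MASK token as the final class.
#' @return An object of class `dfmol_vocab` with elements `names`, `size`
#'   (number of classes including MASK) and `mask_index` (integer or `NA`).
#' @examples
#' v <- vocabulary(c("H", "C", "N", "O"), mask = TRUE)
#' v$size        # 5
#' v$mask_index  # 5
#' @export
vocabulary <- function(names, mask = FALSE) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("vocabulary labels must be unique")
  if (mask) names <- c(names, "<MASK>")
  structure(
    list(names = names, size = length(names),
         mask_index = if (mask) length(names) else NA_integer_),
    class = "dfmol_vocab"
  )
}

#' @export
print.dfmol_vocab <- function(x, ...) {
  cat("<vocabulary> ", x$size, " classes: ",
      paste(x$names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of real (non-MASK) classes in a vocabulary
#' @param vocab A `dfmol_vocab`.
#' @return Integer count of classes excluding any MASK token.
#' @export
n_real_classes <- function(vocab) {
  if (is.na(vocab$mask_index)) vocab$size else vocab$size - 1L
}

#' One-hot encoding of a categorical index
#'
#' @param index Integer index in `1..D` (1-based, following R convention).
#' @param D Vocabulary size.
#' @return Numeric vector of length `D` with a single 1 at `index`.
#' @examples
#' encode_onehot(3, 4)  # 0 0 1 0
#' @export
encode_onehot <- function(index, D) {
  if (length(index) != 1L || is.na(index) || index < 1L || index > D)
    stop("index out of range [1, ", D, "]: ", index)
  v <- numeric(D)
  v[index] <- 1
  v
}

#' One-hot encode a vector of indices into a matrix
#'
#' @param indices Integer vector, each in `1..D`.
#' @param D Vocabulary size.
#' @return `length(indices) x D` numeric matrix; each row is one-hot.
#' @export
onehot_matrix <- function(indices, D) {
  indices <- as.integer(indices)
  if (length(indices) && (anyNA(indices) || any(indices < 1L | indices > D)))
    stop("indices out of range [1, ", D, "]")
  m <- matrix(0, nrow = length(indices), ncol = D)
  if (length(indices)) m[cbind(seq_along(indices), indices)] <- 1
  m
}

# Default vocabularies ------------------------------------------------------

# Formal charge classes; the set is a modeling decision (the field's common
# small-molecule range), out-of-range charges are clamped on read.
.charge_values <- c(-2L, -1L, 0L, 1L, 2L, 3L)

# Bond-order classes over the fully connected graph; "none" makes the edge
# representation total. Numeric orders are used for valency sums.
.bond_names  <- c("none", "single", "double", "triple", "aromatic")
.bond_orders <- c(none = 0, single = 1, double = 2, triple = 3, aromatic = 1.5)

#' Default vocabularies for the three categorical modalities
#'
#' @param elements Character vector of element symbols for the atom-type
#'   vocabulary (default `c("H","C","N","O")`, the toy-data elements).
#' @param mask Logical; include MASK tokens (required for the CTMC variant).
#' @return Named list with `dfmol_vocab` entries `atom`, `charge`, `bond`.
#' @export
default_vocabs <- function(elements = c("H", "C", "N", "O"), mask = FALSE) {
  list(
    atom   = vocabulary(elements, mask = mask),
    charge = vocabulary(as.character(.charge_values), mask = mask),
    bond   = vocabulary(.bond_names, mask = mask)
  )
}

#' Numeric bond order of each bond class index
#' @param idx Integer vector of bond class indices (1-based, `none` = 1).
#' @return Numeric vector of bond orders (none 0, single 1, double 2,
#'   triple 3, aromatic 1.5).
#' @export
bond_order_value <- function(idx) unname(.bond_orders[idx])

#' Charge value of each charge class index
#' @param idx Integer vector of charge class indices.
#' @return Integer vector of formal charges.
#' @export
charge_value <- function(idx) .charge_values[idx]

#' Index of a formal charge in the default charge vocabulary
#' @param q Integer vector of formal charges; values outside -2..+3 are
#'   clamped with a warning.
#' @return Integer vector of charge class indices.
#' @export
charge_index <- function(q) {
  q <- as.integer(q)
  out_of_range <- q < min(.charge_values) | q > max(.charge_values)
  if (any(out_of_range)) {
    warning("formal charge(s) outside [-2, 3] clamped: ",
            paste(unique(q[out_of_range]), collapse = ", "))
    q <- pmax(min(.charge_values), pmin(max(.charge_values), q))
  }
  match(q, .charge_values)
}
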