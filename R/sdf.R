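# SDF (MDL SD file) input/output.
#
# The reader accepts V2000 and V3000 connection tables; the writer emits
# V2000 (toy molecules are far below the 999-atom V2000 limit). Formal
# charges are carried through `M  CHG` lines, which take precedence over the
# legacy atom-block charge column. Pairs without a bond record map to the
# explicit "none" bond class, so the fully connected representation is total.

# bond vocab index <-> MDL bond type: single/double/triple/aromatic = 1/2/3/4
.mdl_bond_from_class <- function(cls) cls - 1L
.class_from_mdl_bond <- function(bt) {
  cls <- bt + 1L
  cls[bt < 1L | bt > 4L] <- NA_integer_
  cls
}
# legacy atom-block charge codes: 1..7 -> +3 +2 +1 (radical) -1 -2 -3
.legacy_charge <- c(3L, 2L, 1L, 0L, -1L, -2L, -3L)

#' Read molecules from an SDF file
#'
#' Parses V2000 and V3000 records into [molecule_graph()] objects.
#' Unparseable records are skipped with a warning rather than failing the
#' whole file. Atom pairs without a bond record receive the "none" class.
#'
#' @param path Path to an SDF file.
#' @param vocab Vocabularies used to index the parsed fields. Element symbols
#'   not present in the atom vocabulary cause the record to be skipped;
#'   formal charges outside the charge vocabulary are clamped.
#' @return A list of `dfmol_graph` objects (possibly empty).
#' @export
read_sdf <- function(path, vocab = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines)))) return(list())
  # split into records on $$$$
  ends <- grep("^\\$\\$\\$\\$\\s*$", lines)
  if (!length(ends) || ends[length(ends)] < length(lines))
    ends <- c(ends, length(lines) + 1L)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  mols <- list()
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:min(ends[r] - 1L, length(lines))]
    rec <- rec[cumsum(nzchar(trimws(rec))) > 0 | nzchar(trimws(rec))]
    if (!length(rec) || all(!nzchar(trimws(rec)))) next
    g <- tryCatch(.parse_sdf_record(lines[starts[r]:(ends[r] - 1L)], vocab),
                  error = function(e) {
                    warning("skipping SDF record ", r, ": ",
                            conditionMessage(e), call. = FALSE)
                    NULL
                  })
    if (!is.null(g)) mols[[length(mols) + 1L]] <- g
  }
  mols
}

.parse_sdf_record <- function(rec, vocab) {
  if (length(rec) < 4L || all(!nzchar(trimws(rec)))) {
    if (all(!nzchar(trimws(rec)))) return(NULL)
    stop("record too short")
  }
  name <- trimws(rec[1])
  counts <- rec[4]
  if (grepl("V3000", counts)) return(.parse_v3000(rec, name, vocab))
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  if (is.na(n_atoms) || n_atoms < 1L) stop("bad counts line")
  atom_lines <- rec[5:(4 + n_atoms)]
  xyz <- matrix(NA_real_, n_atoms, 3)
  elem <- character(n_atoms)
  legacy_q <- integer(n_atoms)
  for (k in seq_len(n_atoms)) {
    ln <- atom_lines[k]
    xyz[k, ] <- as.numeric(c(substr(ln, 1, 10), substr(ln, 11, 20),
                             substr(ln, 21, 30)))
    elem[k] <- trimws(substr(ln, 32, 34))
    code <- suppressWarnings(as.integer(substr(ln, 37, 39)))
    legacy_q[k] <- if (!is.na(code) && code >= 1L && code <= 7L)
      .legacy_charge[code] else 0L
  }
  if (anyNA(xyz)) stop("bad atom block coordinates")
  bonds <- matrix(integer(0), ncol = 3)
  if (n_bonds > 0) {
    bl <- rec[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    bonds <- matrix(NA_integer_, n_bonds, 3)
    for (k in seq_len(n_bonds)) {
      ln <- bl[k]
      bonds[k, ] <- as.integer(c(substr(ln, 1, 3), substr(ln, 4, 6),
                                 substr(ln, 7, 9)))
    }
    if (anyNA(bonds)) stop("bad bond block")
  }
  charges <- legacy_q
  chg_lines <- grep("^M  CHG", rec, value = TRUE)
  if (length(chg_lines)) {
    charges <- integer(n_atoms)  # M CHG supersedes the legacy column
    for (ln in chg_lines) {
      f <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
      cnt <- f[1]
      for (e in seq_len(cnt)) charges[f[2 * e]] <- f[2 * e + 1]
    }
  }
  .assemble_graph(name, xyz, elem, charges, bonds, vocab)
}

.parse_v3000 <- function(rec, name, vocab) {
  grab <- function(tag) {
    i0 <- grep(paste0("BEGIN ", tag), rec)
    i1 <- grep(paste0("END ", tag), rec)
    if (!length(i0) || !length(i1)) return(character(0))
    rec[(i0[1] + 1L):(i1[1] - 1L)]
  }
  atoms <- grab("ATOM")
  if (!length(atoms)) stop("V3000 record without ATOM block")
  parse_fields <- function(ln) strsplit(trimws(sub("^M  V30 ", "", ln)),
                                        "\\s+")[[1]]
  n <- length(atoms)
  xyz <- matrix(NA_real_, n, 3)
  elem <- character(n)
  charges <- integer(n)
  ids <- integer(n)
  for (k in seq_len(n)) {
    f <- parse_fields(atoms[k])
    ids[k] <- as.integer(f[1])
    elem[k] <- f[2]
    xyz[k, ] <- as.numeric(f[3:5])
    chg <- grep("^CHG=", f, value = TRUE)
    if (length(chg)) charges[k] <- as.integer(sub("CHG=", "", chg[1]))
  }
  bl <- grab("BOND")
  bonds <- matrix(integer(0), ncol = 3)
  if (length(bl)) {
    bonds <- matrix(NA_integer_, length(bl), 3)
    for (k in seq_along(bl)) {
      f <- as.integer(parse_fields(bl[k])[1:4])
      bonds[k, ] <- c(match(f[3], ids), match(f[4], ids), f[2])
    }
  }
  .assemble_graph(name, xyz, elem, charges, bonds, vocab)
}

.assemble_graph <- function(name, xyz, elem, charges, bonds, vocab) {
  if (is.null(vocab))
    vocab <- default_vocabs(elements = unique(c(c("H", "C", "N", "O"), elem)))
  at <- match(elem, vocab$atom$names)
  if (anyNA(at))
    stop("element(s) not in atom vocabulary: ",
         paste(unique(elem[is.na(at)]), collapse = ", "))
  n <- nrow(xyz)
  bo <- rep(1L, n_pairs(n))  # "none"
  if (nrow(bonds)) {
    cls <- .class_from_mdl_bond(bonds[, 3])
    if (anyNA(cls)) stop("unsupported bond type: ",
                         paste(unique(bonds[is.na(cls), 3]), collapse = ", "))
    bo[pair_index(bonds[, 1], bonds[, 2], n)] <- cls
  }
  molecule_graph(xyz, at, charge_index(charges), bo, vocab = vocab,
                 name = name)
}

#' Write molecules to an SDF file (V2000)
#'
#' Coordinates are written at the format's 4-decimal precision; formal
#' charges as `M  CHG` lines. Round-tripping through [read_sdf()] preserves
#' atom count, elements, charges, bond orders and coordinates to 1e-4.
#'
#' @param mols A `dfmol_graph` or list of them. Molecules must be mask-free.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "dfmol_graph")) mols <- list(mols)
  out <- character(0)
  for (g in mols) {
    if (has_mask(g)) stop("cannot write molecule with MASK states to SDF")
    bt <- bond_table(g)
    hdr <- c(if (nzchar(g$name)) g$name else "dfmol", "  dfmol", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     g$n_atoms, nrow(bt)))
    elems <- element_symbols(g)
    atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     g$positions[, 1], g$positions[, 2], g$positions[, 3],
                     elems)
    bonds <- if (nrow(bt))
      sprintf("%3d%3d%3d  0", bt$i, bt$j, .mdl_bond_from_class(bt$class))
    else character(0)
    q <- charge_value(g$charges)
    chg <- character(0)
    nz <- which(q != 0L)
    if (length(nz)) {
      # at most 8 atom/charge pairs per M CHG line
      for (grp in split(nz, ceiling(seq_along(nz) / 8))) {
        chg <- c(chg, paste0(sprintf("M  CHG%3d", length(grp)),
                             paste(sprintf("%4d%4d", grp, q[grp]),
                                   collapse = "")))
      }
    }
    out <- c(out, hdr, atoms, bonds, chg, "M  END", "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}
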