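# Molecule-quality metric suite: valency-based stability (pure R), RDKit
# default-sanitization validity, MMFF energy Jensen-Shannon divergence,
# SMARTS structural-alert rate, and out-of-distribution ring-system rate,
# with batch-level 95% confidence intervals over repeats.

# allowed valencies per (element, formal charge); anything absent is unstable
.allowed_valency <- local({
  tab <- list(
    "H|0" = 1, "B|0" = 3, "B|-1" = 4, "C|0" = 4, "C|-1" = 3, "C|1" = 3,
    "N|0" = 3, "N|1" = 4, "N|-1" = 2, "O|0" = 2, "O|1" = 3, "O|-1" = 1,
    "F|0" = 1, "F|-1" = 0, "Si|0" = 4, "P|0" = c(3, 5), "P|1" = 4,
    "S|0" = c(2, 4, 6), "S|1" = c(3, 5), "S|-1" = 1,
    "Cl|0" = 1, "Cl|-1" = 0, "Br|0" = 1, "Br|-1" = 0,
    "I|0" = 1, "I|-1" = 0)
  tab
})

#' Valency of one atom
#'
#' The sum of numeric bond orders over all partners of atom `i` in the
#' fully connected graph (none 0, single 1, double 2, triple 3,
#' aromatic 1.5).
#'
#' @param g A mask-free `dfmol_graph`.
#' @param i Atom index.
#' @return Nonnegative numeric valency.
#' @examples
#' atom_valency(fixtures()$methane, 1)  # 4
#' @export
atom_valency <- function(g, i) {
  if (i < 1 || i > g$n_atoms) stop("atom index out of range")
  if (!is.na(g$vocab$bond$mask_index) &&
      any(g$bond_orders == g$vocab$bond$mask_index))
    stop("valency undefined while MASK bonds are present")
  if (g$n_atoms < 2) return(0)
  pm <- pairs_matrix(g$n_atoms)
  on_i <- pm[, 1] == i | pm[, 2] == i
  sum(bond_order_value(g$bond_orders[on_i]))
}

.atom_valencies <- function(g) {
  if (g$n_atoms < 2) return(numeric(g$n_atoms))
  pm <- pairs_matrix(g$n_atoms)
  ord <- bond_order_value(g$bond_orders)
  vapply(seq_len(g$n_atoms), function(i)
    sum(ord[pm[, 1] == i | pm[, 2] == i]), 0)
}

#' Valency-based stability of a batch of molecules
#'
#' An atom is stable iff its (element, formal charge, valency) triple is in
#' the packaged allowed-valency table; a molecule is stable iff all its
#' atoms are. Computed entirely in R, independently of any cheminformatics
#' toolkit, so it cross-checks [validity()].
#'
#' @param mols A `dfmol_graph` or list of them (mask-free).
#' @return Named numeric vector `c(atoms_stable_pct, mols_stable_pct)`.
#' @export
stability <- function(mols) {
  if (inherits(mols, "dfmol_graph")) mols <- list(mols)
  if (!length(mols)) stop("empty batch")
  unseen <- character(0)
  atom_ok <- lapply(mols, function(g) {
    val <- .atom_valencies(g)
    el <- element_symbols(g)
    q <- charge_value(g$charges)
    # atoms with aromatic bonds may sit half a bond order above an allowed
    # valency (fused-ring bridgeheads, e.g. naphthalene C at 4.5)
    arom <- logical(g$n_atoms)
    if (g$n_atoms >= 2) {
      pm <- pairs_matrix(g$n_atoms)
      ar_pairs <- pm[g$bond_orders == 5L, , drop = FALSE]
      arom[unique(as.vector(ar_pairs))] <- TRUE
    }
    ok <- logical(g$n_atoms)
    for (i in seq_len(g$n_atoms)) {
      key <- paste0(el[i], "|", q[i])
      allowed <- .allowed_valency[[key]]
      if (is.null(allowed)) {
        if (!(el[i] %in% unseen) && !(el[i] %in% names(.allowed_valency))) {
          unseen <<- c(unseen, el[i])
        }
        ok[i] <- FALSE
      } else ok[i] <- any(abs(val[i] - allowed) < 1e-9) ||
          (arom[i] && any(abs(val[i] - 0.5 - allowed) < 1e-9))
    }
    ok
  })
  known_elems <- unique(sub("\\|.*", "", names(.allowed_valency)))
  really_unseen <- setdiff(unseen, known_elems)
  if (length(really_unseen))
    message("element(s) without valency table entry counted unstable: ",
            paste(really_unseen, collapse = ", "))
  c(atoms_stable_pct = 100 * mean(unlist(atom_ok)),
    mols_stable_pct = 100 * mean(vapply(atom_ok, all, TRUE)))
}

#' Toolkit-sanitization validity of a batch
#'
#' Percentage of molecules accepted by RDKit's default sanitization after
#' reconstruction from the graph (via SDF).
#'
#' @param mols A `dfmol_graph` or list of them (mask-free).
#' @return Percentage in `[0, 100]`.
#' @export
validity <- function(mols) {
  if (inherits(mols, "dfmol_graph")) mols <- list(mols)
  if (!length(mols)) stop("empty batch")
  ok <- unlist(rdkit_batch(mols, "sanitize")$sanitize)
  100 * mean(ok)
}

#' MMFF94 single-point energies of a batch
#'
#' Energies at the given coordinates (no minimization), from RDKit's MMFF
#' implementation. Failures (unsanitizable molecules, missing force-field
#' parameters) are returned as `NA`, not raised.
#'
#' @param mols A `dfmol_graph` or list of them.
#' @return Numeric vector (kcal/mol), `NA` where evaluation failed.
#' @export
mmff_energy <- function(mols) {
  single <- inherits(mols, "dfmol_graph")
  if (single) mols <- list(mols)
  e <- vapply(rdkit_batch(mols, "mmff")$mmff,
              function(x) if (is.null(x)) NA_real_ else as.numeric(x), 0)
  if (single) e[[1]] else e
}

#' Jensen-Shannon divergence between two energy samples
#'
#' Histograms both samples on shared equal-width bins spanning the pooled
#' finite range and returns the Jensen-Shannon divergence in nats
#' (bounded by `log(2)`).
#'
#' @param e_ref,e_gen Numeric vectors; non-finite entries are dropped.
#' @param n_bins Number of shared equal-width bins.
#' @return JS divergence in `[0, log(2)]`.
#' @export
energy_js <- function(e_ref, e_gen, n_bins = 100) {
  e_ref <- e_ref[is.finite(e_ref)]
  e_gen <- e_gen[is.finite(e_gen)]
  if (!length(e_ref) || !length(e_gen))
    stop("no finite energies in one of the samples")
  rng <- range(c(e_ref, e_gen))
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  p <- tabulate(findInterval(e_ref, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), n_bins) / length(e_ref)
  q <- tabulate(findInterval(e_gen, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), n_bins) / length(e_gen)
  js_divergence(p, q)
}

#' Jensen-Shannon divergence between two discrete distributions
#' @param p,q Nonnegative vectors of equal length (normalized internally).
#' @return JS divergence in nats.
#' @export
js_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch")
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

# Alert catalogs and ring references ----------------------------------------

#' Read a structural-alert catalog
#'
#' Plain-text TSV with columns `name`, `smarts`, `source`; lines starting
#' with `#` are comments. The package ships a small bundled catalog of
#' well-known medicinal-chemistry alert patterns
#' (`system.file("extdata", "alerts_mini.tsv", package = "dfmol")`).
#'
#' @param path Path to the TSV file.
#' @return Data frame of class `dfmol_alert_catalog` with attribute `path`.
#' @export
read_alert_catalog <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = c("name", "smarts", "source"),
                          stringsAsFactors = FALSE)
  for (src in unique(df$source))
    if (anyDuplicated(df$name[df$source == src]))
      stop("duplicate alert names within source ", src)
  structure(df, class = c("dfmol_alert_catalog", "data.frame"), path = path)
}

#' Structural-alert rate of a batch
#'
#' For each sanitizable molecule, the number of distinct catalog patterns
#' with at least one substructure match; reported as the batch mean.
#' Unsanitizable molecules are excluded from the mean and counted in the
#' `n_excluded` attribute.
#'
#' @param mols A `dfmol_graph` or list of them.
#' @param catalog A [read_alert_catalog()] result (or a path to one).
#' @return Mean alerts per molecule, with attribute `n_excluded`.
#' @export
alert_rate <- function(mols, catalog) {
  if (inherits(mols, "dfmol_graph")) mols <- list(mols)
  path <- if (is.character(catalog)) catalog else attr(catalog, "path")
  res <- rdkit_batch(mols, "alerts", smarts_path = path)$alerts
  counts <- vapply(res, function(x) if (is.null(x)) NA_real_
                   else length(unlist(x)), 0)
  structure(mean(counts, na.rm = TRUE), n_excluded = sum(is.na(counts)))
}

#' Ring systems of a molecule
#'
#' Rings sharing an atom or a bond are merged into one system (fused and
#' spiro); each system is keyed by the canonical SMILES of its ring atoms
#' and in-ring bonds.
#'
#' @param mol A sanitizable `dfmol_graph`.
#' @return Character vector of canonical ring-system keys (empty for
#'   acyclic molecules).
#' @export
ring_systems <- function(mol) {
  res <- rdkit_batch(list(mol), "rings")$rings[[1]]
  if (is.null(res)) stop("molecule failed sanitization")
  unlist(res) %||% character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a ring-system reference table
#'
#' TSV with columns `ring_key` (canonical ring-system SMILES) and `count`
#' (occurrences in a reference corpus). A synthetic stand-in for a
#' ChEMBL-derived census is bundled as
#' `system.file("extdata", "ring_reference_synthetic.tsv", package="dfmol")`.
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector: key to count.
#' @export
read_ring_reference <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = c("ring_key", "count"),
                          stringsAsFactors = FALSE)
  if (any(df$count < 0)) stop("negative reference counts")
  stats::setNames(df$count, df$ring_key)
}

#' Out-of-distribution ring-system rate of a batch
#'
#' Mean over sanitizable molecules of the number of ring systems whose key
#' is absent from the reference (or present with count 0).
#'
#' @param mols A `dfmol_graph` or list of them.
#' @param ref A [read_ring_reference()] table.
#' @return Mean OOD rings per molecule, with attribute `n_excluded`.
#' @export
ood_ring_rate <- function(mols, ref) {
  if (inherits(mols, "dfmol_graph")) mols <- list(mols)
  if (!length(ref)) stop("empty ring reference")
  res <- rdkit_batch(mols, "rings")$rings
  counts <- vapply(res, function(keys) {
    if (is.null(keys)) return(NA_real_)
    keys <- unlist(keys) %||% character(0)
    sum(!(keys %in% names(ref)) | ref[keys] == 0, na.rm = FALSE)
  }, 0)
  structure(mean(counts, na.rm = TRUE), n_excluded = sum(is.na(counts)))
}

#' Evaluate the full metric suite over repeated batches
#'
#' Computes stability, validity, energy JS divergence (against a reference
#' energy sample), alert rate and OOD ring rate for each repeat and reports
#' mean with a 95% normal-approximation confidence half-width over repeats
#' (half-width 0 when `length(batches) == 1`).
#'
#' @param batches A list of molecule batches (one per repeat), or a single
#'   list of `dfmol_graph` treated as one repeat.
#' @param e_ref Optional numeric reference energies for `js_energy`.
#' @param catalog Optional alert catalog for `alerts_per_mol`.
#' @param ring_ref Optional ring reference for `ood_rings_per_mol`.
#' @param use_rdkit Logical; compute the toolkit-dependent metrics
#'   (validity, energies, alerts, rings). Stability and any metric whose
#'   reference input is missing are reported regardless.
#' @return A data frame of class `dfmol_metrics_report`: one row per
#'   metric with columns `metric`, `mean`, `ci95`, `n_repeats`.
#' @export
evaluate_batch <- function(batches, e_ref = NULL, catalog = NULL,
                           ring_ref = NULL, use_rdkit = TRUE) {
  if (length(batches) && inherits(batches[[1]], "dfmol_graph"))
    batches <- list(batches)
  if (!length(batches)) stop("no batches")
  per <- lapply(batches, function(mols) {
    st <- stability(mols)
    row <- c(mols_stable_pct = unname(st["mols_stable_pct"]),
             atoms_stable_pct = unname(st["atoms_stable_pct"]))
    if (use_rdkit) {
      row <- c(row, mols_valid_pct = validity(mols))
      if (!is.null(e_ref)) {
        e_gen <- mmff_energy(mols)
        row <- c(row, js_energy = if (all(is.na(e_gen))) NA_real_
                 else energy_js(e_ref, e_gen))
      }
      if (!is.null(catalog))
        row <- c(row, alerts_per_mol = as.numeric(alert_rate(mols, catalog)))
      if (!is.null(ring_ref))
        row <- c(row, ood_rings_per_mol =
                   as.numeric(ood_ring_rate(mols, ring_ref)))
    }
    row
  })
  m <- do.call(rbind, per)
  r <- nrow(m)
  ci <- if (r > 1) 1.96 * apply(m, 2, stats::sd) / sqrt(r) else
    rep(0, ncol(m))
  structure(data.frame(metric = colnames(m), mean = colMeans(m),
                       ci95 = ci, n_repeats = r, row.names = NULL),
            class = c("dfmol_metrics_report", "data.frame"))
}
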