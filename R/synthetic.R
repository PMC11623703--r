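# Synthetic molecules: deterministic fixtures used across the test suite and
# a stochastic toy-molecule distribution with enough type/bond/geometry
# coupling that the flow variants can be trained and ranked on a CPU.

.unit <- function(v) v / sqrt(sum(v^2))

# k hydrogen directions around atom at `pos`, pointing away from the mean
# neighbor direction, fanned on a cone.
.h_positions <- function(pos, neighbor_pos, k, bond_len = 1.09) {
  if (k == 0) return(matrix(numeric(0), 0, 3))
  d0 <- -rowMeans(vapply(seq_len(nrow(neighbor_pos)),
                         function(i) .unit(neighbor_pos[i, ] - pos),
                         numeric(3)))
  d0 <- if (sqrt(sum(d0^2)) < 1e-8) c(0, 0, 1) else .unit(d0)
  ref <- if (abs(d0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- .unit(pracma_cross(d0, ref)); v <- pracma_cross(d0, u)
  phi <- if (k == 1) 0 else 55 * pi / 180
  th <- 2 * pi * (seq_len(k) - 1) / k + 0.3
  dirs <- t(vapply(th, function(a)
    cos(phi) * d0 + sin(phi) * (cos(a) * u + sin(a) * v), numeric(3)))
  sweep(bond_len * dirs, 2, pos, `+`)
}

# cross product (kept local; avoids importing a package for one primitive)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# hexagon vertices: center (cx, cy), circumradius r, first vertex at angle a0
.hexagon <- function(cx, cy, r = 1.397, a0 = 0) {
  a <- a0 + seq(0, 5) * pi / 3
  cbind(cx + r * cos(a), cy + r * sin(a), 0)
}

.ring_graph <- function(xyz, elems, bonds, charges = NULL, name = "",
                        vocab = default_vocabs()) {
  n <- nrow(xyz)
  if (is.null(charges)) charges <- rep(0L, n)
  bo <- rep(1L, n_pairs(n))
  bo[pair_index(bonds[, 1], bonds[, 2], n)] <- bonds[, 3]
  molecule_graph(xyz, match(elems, vocab$atom$names), charge_index(charges),
                 bo, vocab = vocab, name = name)
}

# append one hydrogen per listed carbon, radially outward from `center`
.aromatic_h <- function(xyz, elems, bonds, atoms, centers, ch = 1.086) {
  for (k in seq_along(atoms)) {
    a <- atoms[k]
    d <- .unit(xyz[a, 1:2] - centers[[k]])
    xyz <- rbind(xyz, c(xyz[a, 1:2] + ch * d, 0))
    elems <- c(elems, "H")
    bonds <- rbind(bonds, c(a, nrow(xyz), 2L))  # single
  }
  list(xyz = xyz, elems = elems, bonds = bonds)
}

#' Deterministic fixture molecules
#'
#' Small molecules with 3D coordinates used throughout the test suite:
#' methane, benzene, naphthalene, biphenyl, nitrobenzene, and a deliberately
#' corrupted pentavalent-carbon molecule (methane with a fifth hydrogen)
#' that must fail both the stability and sanitization checks.
#'
#' @return Named list of `dfmol_graph` objects.
#' @export
fixtures <- function() {
  vocab <- default_vocabs()
  single <- 2L; double <- 3L; arom <- 5L
  out <- list()

  # methane: tetrahedral C-H 1.09
  d <- 1.09 / sqrt(3)
  xyz <- rbind(c(0, 0, 0), c(d, d, d), c(-d, -d, d), c(d, -d, -d),
               c(-d, d, -d))
  out$methane <- .ring_graph(xyz, c("C", rep("H", 4)),
                             cbind(1L, 2:5, single), name = "methane",
                             vocab = vocab)

  # pentavalent carbon: methane plus a fifth hydrogen
  xyz5 <- rbind(xyz, c(0, 0, 1.09))
  out$pentavalent <- .ring_graph(xyz5, c("C", rep("H", 5)),
                                 cbind(1L, 2:6, single),
                                 name = "pentavalent", vocab = vocab)

  # benzene
  cx <- .hexagon(0, 0)
  ring_bonds <- cbind(1:6, c(2:6, 1), arom)
  b <- .aromatic_h(cx, rep("C", 6), ring_bonds, 1:6,
                   rep(list(c(0, 0)), 6))
  out$benzene <- .ring_graph(b$xyz, b$elems, b$bonds, name = "benzene",
                             vocab = vocab)

  # naphthalene: two fused hexagons sharing the edge (0, +-0.7)
  r <- 1.4; cxr <- r * cos(pi / 6) * 2 / 2 * sqrt(3) / sqrt(3)  # see below
  cdist <- sqrt(r^2 - 0.7^2) + 0  # center x offset so shared edge is x = 0
  a0 <- atan2(0.7, -cdist)
  vA <- .hexagon(cdist, 0, r, a0)
  vB <- vA; vB[, 1] <- -vB[, 1]
  key <- function(m) paste(round(m[, 1], 3), round(m[, 2], 3))
  all_v <- rbind(vA, vB)
  keep <- !duplicated(key(all_v))
  xyz <- all_v[keep, , drop = FALSE]
  idx_of <- function(v) match(key(v), key(xyz))
  bonds <- NULL
  for (ring in list(vA, vB)) {
    id <- idx_of(ring)
    bonds <- rbind(bonds, cbind(id, c(id[-1], id[1]), arom))
  }
  bonds <- bonds[!duplicated(t(apply(bonds[, 1:2], 1, sort))), ]
  bridge <- idx_of(rbind(c(0, 0.7, 0), c(0, -0.7, 0)))
  outer <- setdiff(seq_len(nrow(xyz)), bridge)
  centers <- lapply(outer, function(a)
    if (xyz[a, 1] > 0) c(cdist, 0) else c(-cdist, 0))
  b <- .aromatic_h(xyz, rep("C", nrow(xyz)), bonds, outer, centers)
  out$naphthalene <- .ring_graph(b$xyz, b$elems, b$bonds,
                                 name = "naphthalene", vocab = vocab)

  # biphenyl: two benzene rings joined by a single C-C bond
  c1 <- .hexagon(-2.17, 0); c2 <- .hexagon(2.17, 0, a0 = pi)
  xyz <- rbind(c1, c2)
  bonds <- rbind(cbind(1:6, c(2:6, 1), arom),
                 cbind(7:12, c(8:12, 7), arom),
                 c(1L, 7L, single))  # vertices at (-0.773, 0) and (0.773, 0)
  hcarbons <- c(2:6, 8:12)
  centers <- lapply(hcarbons, function(a)
    if (a <= 6) c(-2.17, 0) else c(2.17, 0))
  b <- .aromatic_h(xyz, rep("C", 12), bonds, hcarbons, centers)
  out$biphenyl <- .ring_graph(b$xyz, b$elems, b$bonds, name = "biphenyl",
                              vocab = vocab)

  # nitrobenzene: benzene with one H replaced by a charged nitro group
  cx <- .hexagon(0, 0)
  bonds <- cbind(1:6, c(2:6, 1), arom)
  b <- .aromatic_h(cx, rep("C", 6), bonds, 2:6, rep(list(c(0, 0)), 5))
  xyz <- b$xyz; elems <- b$elems; bonds <- b$bonds
  nN <- nrow(xyz) + 1L
  xyz <- rbind(xyz, c(1.397 + 1.47, 0, 0))          # N
  xyz <- rbind(xyz, c(2.867 + 0.61, 1.056, 0))      # O (double bond)
  xyz <- rbind(xyz, c(2.867 + 0.61, -1.056, 0))     # O- (single bond)
  elems <- c(elems, "N", "O", "O")
  bonds <- rbind(bonds, c(1L, nN, single), c(nN, nN + 1L, double),
                 c(nN, nN + 2L, single))
  charges <- rep(0L, nrow(xyz)); charges[nN] <- 1L; charges[nN + 2L] <- -1L
  out$nitrobenzene <- .ring_graph(xyz, elems, bonds, charges = charges,
                                  name = "nitrobenzene", vocab = vocab)
  out
}

# Toy distribution ----------------------------------------------------------

# neutral valencies used to saturate heavy atoms with hydrogens
.toy_valency <- c(H = 1, C = 4, N = 3, O = 2)

#' Configuration of the toy molecule distribution
#'
#' The toy distribution emulates the structure of a small-molecule training
#' set at desk scale: a scaffold (chain or ring of heavy atoms, all single
#' bonds), scaffold-conditioned heavy-atom element draws, hydrogen
#' saturation to exact neutral valency, and idealized geometry with Gaussian
#' coordinate noise. Every generated molecule is 100% stable and
#' sanitizable by construction.
#'
#' @param n_heavy_range Integer vector of allowed heavy-atom counts.
#' @param p_ring Probability that the scaffold is a ring (else a chain).
#' @param p_terminal,p_interior,p_ring_atom Named element probabilities for
#'   chain-terminal, chain-interior and ring slots (over C, N, O).
#' @param sigma Coordinate noise standard deviation, Angstrom.
#' @return A list of class `dfmol_toy_config`.
#' @export
toy_config <- function(n_heavy_range = 3:6, p_ring = 0.3,
                       p_terminal = c(C = 0.5, N = 0.2, O = 0.3),
                       p_interior = c(C = 0.6, N = 0.2, O = 0.2),
                       p_ring_atom = c(C = 0.7, N = 0.2, O = 0.1),
                       sigma = 0.05) {
  stopifnot(all(n_heavy_range >= 3), sigma >= 0,
            abs(sum(p_terminal) - 1) < 1e-9, abs(sum(p_interior) - 1) < 1e-9,
            abs(sum(p_ring_atom) - 1) < 1e-9)
  structure(list(n_heavy_range = as.integer(n_heavy_range), p_ring = p_ring,
                 p_terminal = p_terminal, p_interior = p_interior,
                 p_ring_atom = p_ring_atom, sigma = sigma,
                 elements = c("H", "C", "N", "O")),
            class = "dfmol_toy_config")
}

#' Sample molecules from the toy distribution
#'
#' @param cfg A [toy_config()].
#' @param n Number of molecules.
#' @param seed Optional RNG seed for reproducibility.
#' @param vocab Vocabularies for the generated graphs (must contain H,C,N,O).
#' @return List of `dfmol_graph`, each 100% stable and valid by
#'   construction.
#' @export
generate_toy_dataset <- function(cfg, n, seed = NULL,
                                 vocab = default_vocabs()) {
  if (!inherits(cfg, "dfmol_toy_config")) stop("cfg must be a toy_config()")
  if (n < 0) stop("n must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(k) .sample_toy_molecule(cfg, vocab, k))
}

.sample_toy_molecule <- function(cfg, vocab, k) {
  m <- sample(cfg$n_heavy_range, 1)
  is_ring <- stats::runif(1) < cfg$p_ring
  elems <- character(m)
  if (is_ring) {
    elems[] <- sample(names(cfg$p_ring_atom), m, replace = TRUE,
                      prob = cfg$p_ring_atom)
    deg <- rep(2L, m)
    heavy_bonds <- cbind(1:m, c(2:m, 1))
  } else {
    elems[c(1, m)] <- sample(names(cfg$p_terminal), 2, replace = TRUE,
                             prob = cfg$p_terminal)
    if (m > 2) elems[2:(m - 1)] <- sample(names(cfg$p_interior), m - 2,
                                          replace = TRUE,
                                          prob = cfg$p_interior)
    deg <- c(1L, rep(2L, m - 2), 1L)
    heavy_bonds <- cbind(1:(m - 1), 2:m)
  }
  n_h <- .toy_valency[elems] - deg
  # idealized geometry
  if (is_ring) {
    r <- 1.5 / (2 * sin(pi / m))
    a <- 2 * pi * (seq_len(m) - 1) / m
    hxyz <- cbind(r * cos(a), r * sin(a), 0)
  } else {
    hxyz <- cbind(1.25 * (seq_len(m) - 1), 0.77 * (seq_len(m) %% 2), 0)
  }
  xyz <- hxyz; all_elems <- elems
  bonds <- cbind(heavy_bonds, 2L)
  for (a in seq_len(m)) {
    if (n_h[a] == 0) next
    nb <- hxyz[bonds_of(heavy_bonds, a), , drop = FALSE]
    hp <- .h_positions(hxyz[a, ], nb, n_h[a])
    for (hh in seq_len(nrow(hp))) {
      xyz <- rbind(xyz, hp[hh, ]); all_elems <- c(all_elems, "H")
      bonds <- rbind(bonds, c(a, nrow(xyz), 2L))
    }
  }
  xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = cfg$sigma), nrow(xyz))
  .ring_graph(xyz, all_elems, bonds, name = sprintf("toy_%d", k),
              vocab = vocab)
}

bonds_of <- function(heavy_bonds, a) {
  nb <- c(heavy_bonds[heavy_bonds[, 1] == a, 2],
          heavy_bonds[heavy_bonds[, 2] == a, 1])
  unique(nb)
}

# Exact distributions under the toy config -----------------------------------

# distribution of hydrogens contributed by one slot: named prob over h values
.slot_h_dist <- function(p_elem, deg) {
  h <- .toy_valency[names(p_elem)] - deg
  tapply(p_elem, h, sum)
}

.convolve_counts <- function(dists) {
  # dists: list of named prob vectors (names = integer values)
  acc <- c(`0` = 1)
  for (d in dists) {
    vals <- outer(as.integer(names(acc)), as.integer(names(d)), `+`)
    pr <- outer(acc, d)
    acc <- tapply(as.vector(pr), as.vector(vals), sum)
  }
  acc
}

#' Exact size distribution of the toy molecule distribution
#'
#' @param cfg A [toy_config()].
#' @return Named numeric vector: probability of each total atom count N
#'   (heavy atoms plus hydrogens).
#' @export
toy_size_distribution <- function(cfg) {
  acc <- numeric(0)
  add <- function(acc, vals, pr) {
    for (i in seq_along(vals)) {
      key <- as.character(vals[i])
      acc[key] <- (if (key %in% names(acc)) acc[key] else 0) + pr[i]
    }
    acc
  }
  p_m <- 1 / length(cfg$n_heavy_range)
  for (m in cfg$n_heavy_range) {
    for (scaf in c("chain", "ring")) {
      p_s <- if (scaf == "ring") cfg$p_ring else 1 - cfg$p_ring
      dists <- if (scaf == "ring")
        rep(list(.slot_h_dist(cfg$p_ring_atom, 2L)), m)
      else c(rep(list(.slot_h_dist(cfg$p_terminal, 1L)), 2),
             rep(list(.slot_h_dist(cfg$p_interior, 2L)), max(0, m - 2)))
      hd <- .convolve_counts(dists)
      acc <- add(acc, m + as.integer(names(hd)), p_m * p_s * hd)
    }
  }
  acc[order(as.integer(names(acc)))]
}

#' Exact pooled atom-type and bond-order marginals of the toy distribution
#'
#' Marginals are those of the infinite pooled population of atoms
#' (respectively atom pairs): expected class counts divided by the expected
#' number of atoms (pairs) per molecule.
#'
#' @param cfg A [toy_config()].
#' @return List with `atom` (probabilities over H, C, N, O) and `bond`
#'   (probabilities over none/single/double/triple/aromatic) and `size`
#'   (the exact size distribution).
#' @export
toy_marginals <- function(cfg) {
  p_m <- 1 / length(cfg$n_heavy_range)
  e_count <- c(H = 0, C = 0, N = 0, O = 0)
  e_atoms <- 0; e_pairs <- 0; e_single <- 0
  for (m in cfg$n_heavy_range) {
    for (scaf in c("chain", "ring")) {
      p_s <- p_m * (if (scaf == "ring") cfg$p_ring else 1 - cfg$p_ring)
      slots <- if (scaf == "ring")
        rep(list(list(p = cfg$p_ring_atom, deg = 2L)), m)
      else c(rep(list(list(p = cfg$p_terminal, deg = 1L)), 2),
             rep(list(list(p = cfg$p_interior, deg = 2L)), max(0, m - 2)))
      eh <- vapply(slots, function(s)
        sum(s$p * (.toy_valency[names(s$p)] - s$deg)), 0)
      vh <- vapply(slots, function(s) {
        h <- .toy_valency[names(s$p)] - s$deg
        sum(s$p * h^2) - sum(s$p * h)^2
      }, 0)
      for (s in slots)
        for (e in names(s$p)) e_count[e] <- e_count[e] + p_s * s$p[e]
      e_count["H"] <- e_count["H"] + p_s * sum(eh)
      eN <- m + sum(eh); vN <- sum(vh)
      e_atoms <- e_atoms + p_s * eN
      e_pairs <- e_pairs + p_s * ((vN + eN^2) - eN) / 2
      n_heavy_bonds <- if (scaf == "ring") m else m - 1
      e_single <- e_single + p_s * (n_heavy_bonds + sum(eh))
    }
  }
  atom <- e_count / e_atoms
  bond <- c(none = 1 - e_single / e_pairs, single = e_single / e_pairs,
            double = 0, triple = 0, aromatic = 0)
  list(atom = atom, bond = bond, size = toy_size_distribution(cfg))
}

#' Total variation between a batch of molecules and the toy distribution
#'
#' Pools atoms (and atom pairs) over the batch and compares the empirical
#' atom-type and bond-order marginals with the exact marginals of the toy
#' distribution.
#'
#' @param mols List of `dfmol_graph`.
#' @param cfg A [toy_config()].
#' @return List with `atom_tv`, `bond_tv` and `combined` (their mean), each
#'   a total-variation distance in `[0, 1]`.
#' @export
tv_to_toy <- function(mols, cfg) {
  if (!length(mols)) stop("empty batch")
  ref <- toy_marginals(cfg)
  vocab <- mols[[1]]$vocab
  at <- unlist(lapply(mols, function(g) g$atom_types))
  bo <- unlist(lapply(mols, function(g) g$bond_orders))
  emp_atom <- vapply(names(ref$atom), function(e)
    mean(vocab$atom$names[at] == e), 0)
  emp_bond <- vapply(names(ref$bond), function(b)
    mean(vocab$bond$names[bo] == b), 0)
  atom_tv <- sum(abs(emp_atom - ref$atom)) / 2
  bond_tv <- sum(abs(emp_bond - ref$bond)) / 2
  list(atom_tv = atom_tv, bond_tv = bond_tv,
       combined = (atom_tv + bond_tv) / 2)
}
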