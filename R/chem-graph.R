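# Minimal molecular graph built from a V2000 molblock. Heavy atoms only;
# implicit hydrogens recovered from a standard-valence model for the organic
# subset (B, C, N, O, P, S, halogens, common counterions). OpenBabel emits
# Kekule bond orders, so aromatic systems appear as alternating single/double
# bonds; all graph algorithms here work on that representation.

.default_valence <- c(
  B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
  F = 1, Cl = 1, Br = 1, I = 1, Si = 4, Se = 2,
  Na = 0, K = 0, Li = 0, Ca = 0, Mg = 0, "*" = 0
)

.atomic_mass <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
  S = 32.065, F = 18.998, Cl = 35.453, Br = 79.904, I = 126.904,
  Si = 28.086, Se = 78.971, Na = 22.99, K = 39.098, Li = 6.94,
  Ca = 40.078, Mg = 24.305, "*" = 0
)

.atomic_number <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Si = 14,
  P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Se = 34, Br = 35, I = 53,
  Li = 3, "*" = 0
)

#' Parse a V2000 molblock into a molecular graph
#'
#' @param molblock character scalar holding one V2000 molblock.
#' @return a `mol_graph` list: `elem`, `charge`, `bonds` (data.frame
#'   `a1`,`a2`,`order`), `n_atoms`, plus derived fields `degree`, `h_count`,
#'   `ring_atom`, `ring_bond`, `n_rings`.
#' @keywords internal
parse_molblock <- function(molblock) {
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na)) stop("malformed molblock counts line")
  elem <- character(na)
  if (na > 0L) {
    al <- lines[5:(4 + na)]
    elem <- trimws(substr(al, 32, 34))
  }
  bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  if (nb > 0L) {
    bl <- lines[(5 + na):(4 + na + nb)]
    bonds <- data.frame(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  }
  charge <- integer(na)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[[:space:]]+")[[1]])
    cnt <- f[1]
    for (k in seq_len(cnt)) charge[f[2 * k]] <- f[2 * k + 1]
  }
  g <- list(elem = elem, charge = charge, bonds = bonds, n_atoms = na)
  class(g) <- "mol_graph"
  .derive_graph_fields(g)
}

.derive_graph_fields <- function(g) {
  na <- g$n_atoms
  deg <- integer(na)
  bsum <- integer(na)
  if (nrow(g$bonds) > 0L) {
    t1 <- tabulate(g$bonds$a1, na)
    t2 <- tabulate(g$bonds$a2, na)
    deg <- t1 + t2
    for (i in seq_len(nrow(g$bonds))) {
      o <- g$bonds$order[i]
      bsum[g$bonds$a1[i]] <- bsum[g$bonds$a1[i]] + o
      bsum[g$bonds$a2[i]] <- bsum[g$bonds$a2[i]] + o
    }
  }
  dv <- .default_valence[g$elem]
  dv[is.na(dv)] <- 0
  # charge-adjusted valence: cations of N/O/S/P gain a bond, anions lose one;
  # carbanions/carbocations both lose one H in this simplified organic model
  adj <- ifelse(g$charge > 0 & g$elem %in% c("N", "O", "S", "P"),
                g$charge, ifelse(g$charge != 0, -abs(g$charge), 0))
  g$degree <- deg
  g$bond_order_sum <- bsum
  g$h_count <- pmax(0L, as.integer(dv + adj - bsum))
  rb <- .ring_bonds(na, g$bonds)
  g$ring_bond <- rb
  g$ring_atom <- rep(FALSE, na)
  if (any(rb)) {
    g$ring_atom[unique(c(g$bonds$a1[rb], g$bonds$a2[rb]))] <- TRUE
  }
  g$n_rings <- nrow(g$bonds) - na + .n_components(na, g$bonds)
  g
}

.adj_list <- function(n, bonds) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$a1[i]; b <- bonds$a2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

.n_components <- function(n, bonds) {
  if (n == 0L) return(0L)
  comp <- .components(n, bonds)
  max(comp)
}

# connected component id per atom (BFS)
.components <- function(n, bonds) {
  adj <- .adj_list(n, bonds)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  comp
}

# a bond is a ring bond iff it is not a bridge
.ring_bonds <- function(n, bonds) {
  nb <- nrow(bonds)
  if (nb == 0L) return(logical(0))
  out <- logical(nb)
  for (i in seq_len(nb)) {
    # connectivity between endpoints without bond i
    b2 <- bonds[-i, , drop = FALSE]
    comp <- .components(n, b2)
    out[i] <- comp[bonds$a1[i]] == comp[bonds$a2[i]]
  }
  out
}

heavy_atom_count <- function(g) sum(g$elem != "H" & g$elem != "*")

# count of rotatable bonds: acyclic single bonds between two non-terminal
# atoms, excluding bonds adjacent to a triple bond (matches the common
# "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]" definition)
rotatable_bond_count <- function(g) {
  if (nrow(g$bonds) == 0L) return(0L)
  triple_atom <- rep(FALSE, g$n_atoms)
  tr <- g$bonds$order == 3
  if (any(tr)) triple_atom[unique(c(g$bonds$a1[tr], g$bonds$a2[tr]))] <- TRUE
  keep <- g$bonds$order == 1 & !g$ring_bond &
    g$degree[g$bonds$a1] >= 2 & g$degree[g$bonds$a2] >= 2 &
    !triple_atom[g$bonds$a1] & !triple_atom[g$bonds$a2]
  sum(keep)
}

# Write a V2000 molblock for a subset of atoms (1-based indices into g).
# `extra_dummy_bond_to`: optional atom index (in the subset's original ids)
# that receives a bonded dummy atom "*" marking an attachment point.
subgraph_molblock <- function(g, atoms, extra_dummy_bond_to = NULL) {
  atoms <- sort(unique(atoms))
  map <- integer(g$n_atoms)
  map[atoms] <- seq_along(atoms)
  elem <- g$elem[atoms]
  charge <- g$charge[atoms]
  keep <- g$bonds$a1 %in% atoms & g$bonds$a2 %in% atoms
  b <- g$bonds[keep, , drop = FALSE]
  na <- length(atoms)
  nb <- nrow(b)
  dummy <- !is.null(extra_dummy_bond_to)
  if (dummy) {
    na <- na + 1L
    nb <- nb + 1L
  }
  hdr <- c("", " nutrascreen", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  at_lines <- sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                      elem)
  if (dummy) {
    at_lines <- c(at_lines,
      "    0.0000    0.0000    0.0000 *   0  0  0  0  0  0  0  0  0  0  0  0")
  }
  bd_lines <- character(0)
  if (nrow(b) > 0L) {
    bd_lines <- sprintf("%3d%3d%3d  0  0  0  0", map[b$a1], map[b$a2], b$order)
  }
  if (dummy) {
    bd_lines <- c(bd_lines,
                  sprintf("%3d%3d  1  0  0  0  0", map[extra_dummy_bond_to], na))
  }
  chg <- which(charge != 0)
  chg_lines <- if (length(chg) > 0L) {
    vapply(chg, function(i) sprintf("M  CHG  1 %3d %3d", i, charge[i]), character(1))
  } else character(0)
  paste(c(hdr, at_lines, bd_lines, chg_lines, "M  END", ""), collapse = "\n")
}

# indices of atoms in each connected fragment, ordered by decreasing heavy
# atom count (ties broken later by the caller)
fragment_atom_sets <- function(g) {
  comp <- .components(g$n_atoms, g$bonds)
  if (g$n_atoms == 0L) return(list())
  split(seq_len(g$n_atoms), comp)
}
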