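#' Default fingerprint parameters
#'
#' Circular (Morgan-style) fingerprint settings used throughout the pipeline:
#' radius 2, 2048 bits, chirality ignored. Screening-library featurization
#' must reuse the exact training parameters; [fingerprint_matrix()] embeds a
#' parameter hash so the echo can be asserted.
#'
#' @param radius integer neighbourhood radius (default 2).
#' @param n_bits fingerprint length (default 2048).
#' @param use_chirality logical; chirality is not encoded and must be FALSE.
#' @return a list of class `fp_params`.
#' @export
fp_params <- function(radius = 2L, n_bits = 2048L, use_chirality = FALSE) {
  stopifnot(radius >= 0L, n_bits >= 2L, identical(use_chirality, FALSE))
  p <- list(radius = as.integer(radius), n_bits = as.integer(n_bits),
            use_chirality = FALSE)
  p$hash <- digest::digest(p[c("radius", "n_bits", "use_chirality")],
                           algo = "sha256")
  class(p) <- "fp_params"
  p
}

# deterministic integer mixing, exact in double arithmetic (mod 2^31)
.mix <- function(h, xs) {
  for (x in xs) h <- (h * 33 + x) %% 2147483647
  h
}

# Circular fingerprint of one molecular graph. Returns bit indices (0-based)
# and, when info=TRUE, the bit -> (atom, radius) map.
.morgan_graph <- function(g, params, info = FALSE) {
  na <- g$n_atoms
  heavy <- which(g$elem != "H")
  if (length(heavy) == 0L) stop("molecule has no heavy atoms")
  zn <- .atomic_number[g$elem]
  zn[is.na(zn)] <- 0
  inv <- vapply(seq_len(na), function(i) {
    .mix(5381, c(zn[i], g$degree[i], g$h_count[i], g$charge[i] + 10,
                 as.integer(g$ring_atom[i])))
  }, numeric(1))
  nb <- vector("list", na)
  if (nrow(g$bonds) > 0L) {
    for (i in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a1[i]; b <- g$bonds$a2[i]; o <- g$bonds$order[i]
      nb[[a]] <- rbind(nb[[a]], c(b, o))
      nb[[b]] <- rbind(nb[[b]], c(a, o))
    }
  }
  records <- data.frame(atom = heavy, radius = 0L,
                        bit = as.integer(inv[heavy] %% params$n_bits))
  if (params$radius > 0L) {
    for (r in seq_len(params$radius)) {
      new_inv <- inv
      for (i in heavy) {
        pairs <- nb[[i]]
        if (is.null(pairs)) {
          new_inv[i] <- .mix(5381, c(r, inv[i]))
        } else {
          key <- order(pairs[, 2], inv[pairs[, 1]])
          xs <- c(r, inv[i])
          for (k in key) xs <- c(xs, pairs[k, 2], inv[pairs[k, 1]])
          new_inv[i] <- .mix(5381, xs)
        }
      }
      inv <- new_inv
      records <- rbind(records,
                       data.frame(atom = heavy, radius = r,
                                  bit = as.integer(inv[heavy] %% params$n_bits)))
    }
  }
  if (info) records else sort(unique(records$bit))
}

#' Fingerprint a set of molecules
#'
#' Canonicalizes each SMILES, builds its molecular graph and computes a
#' fixed-length binary circular fingerprint. Two SMILES dialects of the same
#' molecule share a canonical form and therefore an identical bit vector.
#'
#' @param smiles character vector of (parseable) SMILES.
#' @param params [fp_params()] settings.
#' @return integer 0/1 matrix, one row per input, `n_bits` columns; attribute
#'   `fp_hash` carries the parameter hash for the training/screening echo
#'   check. Rows of unparsable inputs are an error: pre-filter structures.
#' @export
fingerprint_matrix <- function(smiles, params = fp_params()) {
  stopifnot(inherits(params, "fp_params"))
  can <- canonical_smiles(smiles)
  if (anyNA(can)) stop("unparsable SMILES at rows: ",
                       paste(utils::head(which(is.na(can)), 5), collapse = ", "))
  ucan <- unique(can)
  mbs <- smiles_to_molblock(ucan)
  if (anyNA(mbs)) stop("canonical SMILES failed molblock conversion")
  X <- matrix(0L, length(ucan), params$n_bits)
  for (i in seq_along(ucan)) {
    bits <- .morgan_graph(parse_molblock(mbs[i]), params)
    X[i, bits + 1L] <- 1L
  }
  out <- X[match(can, ucan), , drop = FALSE]
  dimnames(out) <- list(NULL, sprintf("F%d", seq_len(params$n_bits) - 1L))
  attr(out, "fp_hash") <- params$hash
  out
}

#' Fingerprint one molecule with its bit environment map
#'
#' @param smiles a single SMILES string.
#' @param params [fp_params()] settings.
#' @return list with `bits` (0-based, unique, sorted) and `info`, a data.frame
#'   of (atom, radius, bit) rows for every atom-centred environment.
#' @export
fingerprint_one <- function(smiles, params = fp_params()) {
  can <- canonical_smiles(smiles)
  if (is.na(can)) stop("unparsable SMILES: ", smiles)
  mb <- smiles_to_molblock(can)
  g <- parse_molblock(mb)
  rec <- .morgan_graph(g, params, info = TRUE)
  list(bits = sort(unique(rec$bit)), info = rec, graph = g, canonical = can)
}

#' Tanimoto similarity between two fingerprints
#'
#' `|A intersect B| / |A union B|` over bit sets; defined as 0 when both
#' vectors are all-zero.
#'
#' @param fp_a,fp_b 0/1 vectors of identical length.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) stop("fingerprint length mismatch")
  a <- as.logical(fp_a); b <- as.logical(fp_b)
  un <- sum(a | b)
  if (un == 0L) return(0)
  sum(a & b) / un
}

#' All-pairs Tanimoto similarity between two fingerprint sets
#' @param A,B 0/1 matrices with identical column counts.
#' @return `nrow(A)` x `nrow(B)` similarity matrix.
#' @export
tanimoto_matrix <- function(A, B) {
  if (ncol(A) != ncol(B)) stop("fingerprint length mismatch")
  A <- matrix(as.numeric(A), nrow(A)); B <- matrix(as.numeric(B), nrow(B))
  inter <- A %*% t(B)
  un <- outer(rowSums(A), rowSums(B), "+") - inter
  s <- ifelse(un == 0, 0, inter / un)
  s
}

#' Bemis-Murcko scaffold
#'
#' Ring systems plus connecting linkers with side chains removed. Atoms
#' double- or triple-bonded directly to the retained framework (e.g. a linker
#' carbonyl oxygen) are kept. Acyclic molecules yield the empty scaffold `""`.
#'
#' @param smiles character vector of parseable SMILES.
#' @return character vector of canonical scaffold SMILES (`""` when no ring).
#' @export
murcko_scaffold <- function(smiles) {
  can <- canonical_smiles(smiles)
  if (anyNA(can)) stop("unparsable SMILES in murcko_scaffold()")
  ucan <- unique(can)
  mbs <- smiles_to_molblock(ucan)
  res <- vapply(seq_along(ucan), function(i) {
    g <- parse_molblock(mbs[i])
    .murcko_graph(g)
  }, character(1))
  res[match(can, ucan)]
}

.murcko_graph <- function(g) {
  if (!any(g$ring_atom)) return("")
  keep <- rep(TRUE, g$n_atoms)
  keep[g$elem == "H"] <- FALSE
  repeat {
    deg <- integer(g$n_atoms)
    for (i in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a1[i]; b <- g$bonds$a2[i]
      if (keep[a] && keep[b]) { deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L }
    }
    drop <- keep & !g$ring_atom & deg <= 1L
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  # add back atoms multiply bonded to the framework
  for (i in seq_len(nrow(g$bonds))) {
    if (g$bonds$order[i] >= 2L) {
      a <- g$bonds$a1[i]; b <- g$bonds$a2[i]
      if (keep[a] && !keep[b] && g$elem[b] != "H") keep[b] <- TRUE
      if (keep[b] && !keep[a] && g$elem[a] != "H") keep[a] <- TRUE
    }
  }
  mb <- subgraph_molblock(g, which(keep))
  s <- molblock_to_smiles(mb)
  if (is.na(s)) "" else s
}

#' Physicochemical descriptor profile
#'
#' Computes, per compound: molecular weight (Da), Crippen-type logP,
#' hydrogen-bond donors and acceptors, topological polar surface area,
#' rotatable bonds, ring count, and the number of Lipinski rule-of-five
#' violations among MW>500, logP>5, HBD>5, HBA>10. Violations are summary
#' indicators only; no compound is excluded on this basis.
#'
#' @param smiles character vector of parseable SMILES.
#' @return data.frame with columns `mw`, `logp`, `hbd`, `hba`, `tpsa`,
#'   `rotatable_bonds`, `ring_count`, `lipinski_violations`.
#' @export
compute_descriptors <- function(smiles) {
  can <- canonical_smiles(smiles)
  if (anyNA(can)) stop("unparsable SMILES in compute_descriptors()")
  ucan <- unique(can)
  props <- ob_properties(ucan)
  mbs <- smiles_to_molblock(ucan)
  extra <- t(vapply(seq_along(ucan), function(i) {
    g <- parse_molblock(mbs[i])
    c(rot = rotatable_bond_count(g), rings = g$n_rings)
  }, c(rot = 0, rings = 0)))
  d <- data.frame(
    mw = props$MW, logp = props$logP, hbd = as.integer(props$HBD),
    hba = as.integer(props$HBA2), tpsa = props$TPSA,
    rotatable_bonds = as.integer(extra[, "rot"]),
    ring_count = as.integer(extra[, "rings"])
  )
  d$lipinski_violations <- (d$mw > 500) + (d$logp > 5) + (d$hbd > 5) + (d$hba > 10)
  d[match(can, ucan), , drop = FALSE]
}
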