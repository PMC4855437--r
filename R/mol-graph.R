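# Molecular-graph sanitization: kekulization, implicit hydrogens, valence
# checking, aromaticity perception and ring (SSSR) perception.
#
# The valence model is the classic SMILES one: each element has a list of
# allowed total valences (bond-order sum + attached hydrogens), shifted by
# formal charge for the common heteroatom ions.

STANDARD_VALENCES <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = c(1L, 3L, 5L, 7L), Br = c(1L, 3L, 5L, 7L), I = c(1L, 3L, 5L, 7L),
  Si = 4L, Se = c(2L, 4L, 6L), As = c(3L, 5L)
)

ATOMIC_MASSES <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.99, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  K = 39.098, Ca = 40.078, As = 74.922, Se = 78.971, Br = 79.904, I = 126.904,
  Li = 6.94, Zn = 65.38, Fe = 55.845
)

valence_error <- function(msg) {
  structure(class = c("valence_error", "error", "condition"),
            list(message = msg, call = NULL))
}

# Allowed total valences for an element/charge combination; NULL = unchecked.
allowed_valences <- function(element, charge) {
  base <- STANDARD_VALENCES[[element]]
  if (is.null(base)) return(NULL)
  if (charge == 0L) return(base)
  if (element %in% c("N", "O", "P", "S", "Se", "As") && charge > 0L)
    return(base + charge)
  if (charge < 0L) {
    v <- base + charge            # e.g. O- -> 1, N- -> 2, C- -> 3 (via C:4)
    if (element == "C") v <- 4L + charge
    return(v[v >= 0L])
  }
  if (element == "C") return(4L - abs(charge))
  base
}

adjacency_list <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  if (nrow(mol$bonds) > 0) {
    for (b in seq_len(nrow(mol$bonds))) {
      a1 <- mol$bonds$a1[b]; a2 <- mol$bonds$a2[b]
      adj[[a1]] <- c(adj[[a1]], a2)
      adj[[a2]] <- c(adj[[a2]], a1)
    }
  }
  adj
}

# bond index lookup: key "min-max" -> row in bonds
bond_index_map <- function(mol) {
  if (nrow(mol$bonds) == 0) return(list())
  keys <- paste(pmin(mol$bonds$a1, mol$bonds$a2),
                pmax(mol$bonds$a1, mol$bonds$a2), sep = "-")
  stats::setNames(as.list(seq_along(keys)), keys)
}

bond_order_sum <- function(mol) {
  n <- nrow(mol$atoms)
  s <- integer(n)
  if (nrow(mol$bonds) > 0) {
    for (b in seq_len(nrow(mol$bonds))) {
      s[mol$bonds$a1[b]] <- s[mol$bonds$a1[b]] + mol$bonds$order[b]
      s[mol$bonds$a2[b]] <- s[mol$bonds$a2[b]] + mol$bonds$order[b]
    }
  }
  s
}

heavy_degree <- function(mol) {
  n <- nrow(mol$atoms)
  d <- integer(n)
  if (nrow(mol$bonds) > 0) {
    t1 <- tabulate(mol$bonds$a1, n); t2 <- tabulate(mol$bonds$a2, n)
    d <- t1 + t2
  }
  d
}

mol_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds)) mol$bonds[, c("a1", "a2")] else
      data.frame(a1 = integer(), a2 = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol$atoms))))
}

# All-pairs topological (bond count) distance matrix.
topo_distances <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 1) return(matrix(0, 1, 1))
  d <- igraph::distances(mol_igraph(mol))
  dimnames(d) <- NULL
  d
}

mol_components <- function(mol) {
  igraph::components(mol_igraph(mol))$membership
}

# ---------------------------------------------------------------------------
# Kekulization.
#
# An aromatic atom "needs" exactly one double bond in the kekulized form when
# its valence has room for one after counting sigma connections; pyrrole-type
# NH / O / S contribute a lone pair instead. Finding a Kekule structure is a
# perfect-matching problem over the aromatic bonds restricted to needing
# atoms, solved by backtracking (aromatic systems are small).

kekule_needs_double <- function(mol, arom_bond) {
  n <- nrow(mol$atoms)
  needs <- rep(FALSE, n)
  deg <- heavy_degree(mol)
  # pi electrons already committed through non-aromatic multiple bonds
  pi_extra <- integer(n)
  for (b in which(!arom_bond & mol$bonds$order > 1L)) {
    pi_extra[mol$bonds$a1[b]] <- pi_extra[mol$bonds$a1[b]] + mol$bonds$order[b] - 1L
    pi_extra[mol$bonds$a2[b]] <- pi_extra[mol$bonds$a2[b]] + mol$bonds$order[b] - 1L
  }
  for (a in which(mol$atoms$arom)) {
    el <- mol$atoms$element[a]
    hx <- if (!is.null(mol$atoms$nh)) mol$atoms$nh[a] else mol$atoms$hexp[a]
    if (is.na(hx)) {
      # organic-subset aromatic atom: c takes one double bond; n/p only when
      # two-connected (pyridine-type; three-connected n is pyrrole-type);
      # o/s/b never
      needs[a] <- pi_extra[a] == 0L &&
        (el == "C" || (el %in% c("N", "P") && deg[a] == 2L))
    } else {
      occupied <- deg[a] + hx + pi_extra[a]
      av <- allowed_valences(el, mol$atoms$charge[a])
      target <- if (is.null(av)) occupied else
        suppressWarnings(min(av[av >= occupied]))
      needs[a] <- is.finite(target) && (target - occupied) >= 1L
    }
  }
  needs
}

# Backtracking perfect matching of `needs` atoms over candidate bonds.
# cand: two-column matrix of atom pairs (rows are candidate double bonds),
# pre-ordered; returns logical vector over rows, or NULL if no matching.
match_double_bonds <- function(n_atoms, cand, needs) {
  matched <- rep(FALSE, n_atoms)
  chosen <- logical(nrow(cand))
  order_atoms <- which(needs)
  # adjacency from atom to candidate rows
  rows_of <- vector("list", n_atoms)
  for (r in seq_len(nrow(cand))) {
    rows_of[[cand[r, 1]]] <- c(rows_of[[cand[r, 1]]], r)
    rows_of[[cand[r, 2]]] <- c(rows_of[[cand[r, 2]]], r)
  }
  bt <- function(idx) {
    while (idx <= length(order_atoms) && matched[order_atoms[idx]])
      idx <- idx + 1L
    if (idx > length(order_atoms)) return(TRUE)
    a <- order_atoms[idx]
    for (r in rows_of[[a]]) {
      b <- if (cand[r, 1] == a) cand[r, 2] else cand[r, 1]
      if (matched[b] || !needs[b]) next
      matched[a] <<- TRUE; matched[b] <<- TRUE; chosen[r] <<- TRUE
      if (bt(idx + 1L)) return(TRUE)
      matched[a] <<- FALSE; matched[b] <<- FALSE; chosen[r] <<- FALSE
    }
    FALSE
  }
  if (!bt(1L)) return(NULL)
  chosen
}

# Assign integer orders to aromatic bonds. `rank_order` (optional) is a
# per-atom canonical rank used to make the chosen Kekule structure unique.
kekulize <- function(mol, rank_order = NULL) {
  ab <- which(mol$bonds$arom)
  if (length(ab) == 0) return(mol)
  needs <- kekule_needs_double(mol, arom_bond = mol$bonds$arom)
  cand <- as.matrix(mol$bonds[ab, c("a1", "a2"), drop = FALSE])
  keep <- needs[cand[, 1]] & needs[cand[, 2]]
  cand_rows <- ab[keep]
  cand <- cand[keep, , drop = FALSE]
  if (!is.null(rank_order) && nrow(cand) > 1) {
    key1 <- pmin(rank_order[cand[, 1]], rank_order[cand[, 2]])
    key2 <- pmax(rank_order[cand[, 1]], rank_order[cand[, 2]])
    o <- order(key1, key2)
    cand <- cand[o, , drop = FALSE]
    cand_rows <- cand_rows[o]
  }
  chosen <- match_double_bonds(nrow(mol$atoms), cand, needs)
  if (is.null(chosen))
    stop(valence_error("kekulization failed: no valid alternating bond pattern"))
  mol$bonds$order[ab] <- 1L
  mol$bonds$order[cand_rows[chosen]] <- 2L
  mol
}

# ---------------------------------------------------------------------------
# Implicit hydrogens and valence check (requires integer bond orders).

assign_hydrogens <- function(mol) {
  bos <- bond_order_sum(mol)
  nh <- integer(nrow(mol$atoms))
  for (a in seq_len(nrow(mol$atoms))) {
    hx <- mol$atoms$hexp[a]
    if (!is.na(hx)) { nh[a] <- hx; next }
    av <- allowed_valences(mol$atoms$element[a], mol$atoms$charge[a])
    if (is.null(av)) { nh[a] <- 0L; next }
    fit <- av[av >= bos[a]]
    nh[a] <- if (length(fit)) min(fit) - bos[a] else 0L
  }
  mol$atoms$nh <- nh
  mol
}

check_valences <- function(mol) {
  bos <- bond_order_sum(mol)
  for (a in seq_len(nrow(mol$atoms))) {
    av <- allowed_valences(mol$atoms$element[a], mol$atoms$charge[a])
    if (is.null(av)) next
    tot <- bos[a] + mol$atoms$nh[a]
    if (!(tot %in% av))
      stop(valence_error(sprintf(
        "valence %d not allowed for %s (charge %+d) at atom %d",
        tot, mol$atoms$element[a], mol$atoms$charge[a], a)))
  }
  invisible(mol)
}

# ---------------------------------------------------------------------------
# Ring perception: smallest set of smallest rings (SSSR).
#
# Candidate rings are the shortest cycle through every non-bridge edge; a
# greedy GF(2) independence filter over bond incidence vectors retains
# exactly circuit-rank rings, smallest first.

shortest_cycle_through <- function(adj, u, v) {
  # shortest path u..v avoiding the edge (u,v); BFS
  n <- length(adj)
  prev <- rep(NA_integer_, n)
  seen <- rep(FALSE, n)
  seen[u] <- TRUE
  queue <- u
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    for (y in sort(adj[[x]])) {
      if ((x == u && y == v) || (x == v && y == u)) next
      if (!seen[y]) {
        seen[y] <- TRUE; prev[y] <- x
        if (y == v) {
          path <- y
          while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
          return(path)
        }
        queue <- c(queue, y)
      }
    }
  }
  NULL
}

#' @keywords internal
get_sssr <- function(mol) {
  nb <- nrow(mol$bonds)
  n <- nrow(mol$atoms)
  if (nb == 0) return(list())
  g <- mol_igraph(mol)
  comp <- igraph::components(g)$no
  rank_needed <- nb - n + comp
  if (rank_needed <= 0) return(list())
  bridges <- as.integer(igraph::bridges(g))
  cyc_edges <- setdiff(seq_len(nb), bridges)
  adj <- adjacency_list(mol)
  bmap <- bond_index_map(mol)
  ring_bond_rows <- function(path) {
    k <- length(path)
    vapply(seq_len(k), function(i) {
      a <- path[i]; b <- path[if (i == k) 1 else i + 1]
      bmap[[paste(min(a, b), max(a, b), sep = "-")]]
    }, integer(1))
  }
  cands <- list()
  for (e in cyc_edges) {
    u <- mol$bonds$a1[e]; v <- mol$bonds$a2[e]
    p <- shortest_cycle_through(adj, u, v)
    if (!is.null(p)) cands[[length(cands) + 1L]] <- p
  }
  if (!length(cands)) return(list())
  cands <- cands[order(vapply(cands, length, integer(1)))]
  # GF(2) gaussian elimination over bond incidence vectors
  basis <- list()
  rings <- list()
  for (p in cands) {
    vec <- rep(FALSE, nb)
    vec[ring_bond_rows(p)] <- TRUE
    red <- vec
    for (b in basis) {
      pivot <- which(b)[1]
      if (red[pivot]) red <- xor(red, b)
    }
    if (any(red)) {
      basis[[length(basis) + 1L]] <- red
      rings[[length(rings) + 1L]] <- p
      if (length(rings) == rank_needed) break
    }
  }
  rings
}

# atoms/bonds that are members of any ring (via biconnected structure)
ring_membership <- function(mol) {
  nb <- nrow(mol$bonds)
  n <- nrow(mol$atoms)
  bond_in_ring <- rep(FALSE, nb)
  atom_in_ring <- rep(FALSE, n)
  if (nb > 0) {
    g <- mol_igraph(mol)
    bridges <- as.integer(igraph::bridges(g))
    bond_in_ring[setdiff(seq_len(nb), bridges)] <- TRUE
    atom_in_ring[unique(c(mol$bonds$a1[bond_in_ring],
                          mol$bonds$a2[bond_in_ring]))] <- TRUE
  }
  list(atom = atom_in_ring, bond = bond_in_ring)
}

# ---------------------------------------------------------------------------
# Aromaticity perception (simplified Hueckel over SSSR rings).
#
# A ring is aromatic when every member can be planar-conjugated and the pi
# electron count is 4n+2. Contributions: atom with an in-ring double bond 1;
# exocyclic double bond 0; saturated N/O/S (and anionic C/N) lone pair 2;
# carbocation 0. Fused systems aromatic only as a union of aromatic SSSR
# rings (azulene-type perimeter aromaticity is not perceived).

perceive_aromaticity <- function(mol) {
  n <- nrow(mol$atoms)
  mol$atoms$arom <- rep(FALSE, n)
  if (nrow(mol$bonds)) mol$bonds$arom <- rep(FALSE, nrow(mol$bonds))
  rings <- get_sssr(mol)
  if (!length(rings)) return(mol)
  bmap <- bond_index_map(mol)
  adj <- adjacency_list(mol)
  dbl_partner <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (b in which(mol$bonds$order == 2L)) {
      dbl_partner[[mol$bonds$a1[b]]] <- c(dbl_partner[[mol$bonds$a1[b]]], mol$bonds$a2[b])
      dbl_partner[[mol$bonds$a2[b]]] <- c(dbl_partner[[mol$bonds$a2[b]]], mol$bonds$a1[b])
    }
  }
  has_triple <- rep(FALSE, n)
  for (b in which(mol$bonds$order == 3L)) {
    has_triple[mol$bonds$a1[b]] <- TRUE; has_triple[mol$bonds$a2[b]] <- TRUE
  }
  deg <- heavy_degree(mol)

  ring_bonds <- function(p) {
    k <- length(p)
    vapply(seq_len(k), function(i) {
      a <- p[i]; b <- p[if (i == k) 1 else i + 1]
      bmap[[paste(min(a, b), max(a, b), sep = "-")]]
    }, integer(1))
  }

  for (p in rings) {
    if (length(p) < 5 || length(p) > 7) next
    pset <- p
    pi_e <- 0L
    ok <- TRUE
    for (a in pset) {
      el <- mol$atoms$element[a]; ch <- mol$atoms$charge[a]
      dp <- dbl_partner[[a]]
      if (has_triple[a]) { ok <- FALSE; break }
      if (length(dp) >= 2) { ok <- FALSE; break }   # cumulated double bonds
      if (length(dp) == 1) {
        if (dp %in% pset) pi_e <- pi_e + 1L          # in-ring double bond
        else if (mol$atoms$element[dp] == "C" && ch == 0L)
          pi_e <- pi_e + 1L   # fusion-type double bond into a neighboring ring
        # carbonyl-type exocyclic double (C=O etc.) contributes none
        next
      }
      # no double bond: lone-pair donor or vacant orbital
      if (el %in% c("N", "P") && ch <= 0L) pi_e <- pi_e + 2L
      else if (el %in% c("O", "S", "Se") && ch == 0L) pi_e <- pi_e + 2L
      else if (el == "C" && ch == -1L) pi_e <- pi_e + 2L
      else if (el == "C" && ch == 1L) pi_e <- pi_e + 0L
      else if (el == "C" && deg[a] + mol$atoms$nh[a] >= 4L) { ok <- FALSE; break }
      else { ok <- FALSE; break }
    }
    if (ok && pi_e %% 4L == 2L) {
      mol$atoms$arom[pset] <- TRUE
      mol$bonds$arom[ring_bonds(p)] <- TRUE
    }
  }
  mol
}

# ---------------------------------------------------------------------------
# Sanitize: kekulize aromatic input, assign hydrogens, check valences,
# perceive aromaticity from scratch, then re-kekulize deterministically using
# canonical atom ranks so bond-type counts do not depend on the input form.

#' Sanitize a parsed molecular graph
#'
#' Kekulizes aromatic notation, assigns implicit hydrogens, validates atom
#' valences against the standard valence model, perceives aromaticity
#' (simplified Hueckel rule over SSSR rings of size 5-7) and fixes one
#' canonical Kekule structure. Errors of class `valence_error` signal
#' impossible valences or unkekulizable aromatic systems.
#'
#' @param mol a `molgraph` from [parse_smiles()] or [read_sdf()].
#' @return a sanitized `molgraph` with `nh` (attached hydrogens) per atom and
#'   consistent aromatic flags and bond orders.
#' @export
sanitize_mol <- function(mol) {
  if (any(mol$atoms$arom)) {
    # hydrogens on needing atoms are known pre-kekulization for bracket atoms;
    # organic-subset aromatic atoms are resolved by the needs-double rule
    mol <- kekulize(mol)
  }
  mol$atoms$arom <- rep(FALSE, nrow(mol$atoms))
  if (nrow(mol$bonds)) mol$bonds$arom <- rep(FALSE, nrow(mol$bonds))
  mol <- assign_hydrogens(mol)
  check_valences(mol)
  mol <- perceive_aromaticity(mol)
  ranks <- canonical_ranks(mol)
  if (any(mol$bonds$arom)) {
    mol$bonds$order[mol$bonds$arom] <- 1L
    mol <- kekulize(mol, rank_order = ranks)
  }
  mol
}

# Reindex atoms of a molgraph by a permutation (new index i holds old atom
# perm[i]); used by order-invariance property tests.
#' @keywords internal
permute_molgraph <- function(mol, perm) {
  stopifnot(length(perm) == nrow(mol$atoms), !anyDuplicated(perm))
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds
  if (nrow(bonds)) {
    bonds$a1 <- inv[bonds$a1]
    bonds$a2 <- inv[bonds$a2]
  }
  new_molgraph(atoms, bonds)
}
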