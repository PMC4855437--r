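# Canonical atom ranking (iterative neighborhood refinement) and canonical
# SMILES output. Residual rank ties after refinement correspond to graph
# automorphisms in ordinary chemical graphs; the writer additionally resolves
# neighbor-order ties with subtree signatures and takes the lexicographically
# smallest string over all minimal-rank start atoms, so the output does not
# depend on input atom order.

canonical_ranks <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- adjacency_list(mol)
  deg <- heavy_degree(mol)
  inring <- ring_membership(mol)$atom
  nh <- if (!is.null(mol$atoms$nh)) mol$atoms$nh else
    ifelse(is.na(mol$atoms$hexp), 0L, mol$atoms$hexp)
  key <- paste(mol$atoms$element, mol$atoms$charge, nh, deg,
               mol$atoms$arom, inring, mol$atoms$iso, sep = "|")
  rank <- match(key, sort(unique(key)))
  repeat {
    nbr_sig <- vapply(seq_len(n), function(a) {
      paste(sort(rank[adj[[a]]]), collapse = ",")
    }, character(1))
    key2 <- paste(rank, nbr_sig, sep = ";")
    rank2 <- match(key2, sort(unique(key2)))
    if (length(unique(rank2)) == length(unique(rank))) break
    rank <- rank2
  }
  rank
}

# Order-independent signature of the branch entered at `v` coming from `u`:
# breadth-first profile of (distance, rank) multisets in the graph minus u.
branch_signature <- function(adj, rank, v, u) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[u] <- -1L  # blocked
  dist[v] <- 0L
  queue <- v
  out <- character(0)
  lvl <- list()
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    d <- dist[x] + 1L
    for (y in adj[[x]]) {
      if (is.na(dist[y])) {
        dist[y] <- d
        if (d > length(lvl)) lvl[[d]] <- integer(0)
        lvl[[d]] <- c(lvl[[d]], rank[y])
        queue <- c(queue, y)
      }
    }
  }
  sigs <- c(as.character(rank[v]),
            vapply(lvl, function(r) paste(sort(r), collapse = ","), character(1)))
  paste(sigs, collapse = "/")
}

# atom token for SMILES output
atom_token <- function(mol, a) {
  el <- mol$atoms$element[a]
  arom <- mol$atoms$arom[a]
  ch <- mol$atoms$charge[a]
  iso <- mol$atoms$iso[a]
  nh <- mol$atoms$nh[a]
  sym <- if (arom) tolower(el) else el
  organic <- el %in% c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
  if (organic && ch == 0L && iso == 0L) {
    # would a bare atom re-read with the same hydrogen count?
    deg <- length(which(mol$bonds$a1 == a | mol$bonds$a2 == a))
    implied <- if (arom) {
      base <- STANDARD_VALENCES[[el]][1]
      extra <- if (el %in% c("C", "N", "P")) 1L else 0L
      max(0L, base - deg - extra)
    } else {
      bos <- sum(mol$bonds$order[mol$bonds$a1 == a | mol$bonds$a2 == a])
      av <- STANDARD_VALENCES[[el]]
      fit <- av[av >= bos]
      if (length(fit)) min(fit) - bos else 0L
    }
    if (implied == nh) return(sym)
  }
  h <- if (nh == 0L) "" else if (nh == 1L) "H" else paste0("H", nh)
  q <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-" else
    sprintf("%+d", ch)
  is <- if (iso == 0L) "" else as.character(iso)
  paste0("[", is, sym, h, q, "]")
}

bond_token <- function(mol, brow) {
  if (mol$bonds$arom[brow]) return("")
  ord <- mol$bonds$order[brow]
  if (ord == 2L) return("=")
  if (ord == 3L) return("#")
  # explicit single needed between two aromatic atoms (biphenyl-type bond)
  if (mol$atoms$arom[mol$bonds$a1[brow]] && mol$atoms$arom[mol$bonds$a2[brow]])
    return("-")
  ""
}

# Write one connected fragment starting from `start`; deterministic traversal
# by (rank, branch signature).
write_fragment_from <- function(mol, adj, bmap, rank, start) {
  n <- nrow(mol$atoms)
  visited <- rep(FALSE, n)
  parent <- rep(NA_integer_, n)
  children <- vector("list", n)
  ring_bonds <- list()  # list of c(a, b) with a visited before b
  order_visit <- integer(0)

  dfs <- function(a) {
    visited[a] <<- TRUE
    order_visit <<- c(order_visit, a)
    nbrs <- adj[[a]]
    if (!is.na(parent[a])) nbrs <- nbrs[nbrs != parent[a]]
    if (length(nbrs) > 1) {
      sig <- vapply(nbrs, function(v) branch_signature(adj, rank, v, a),
                    character(1))
      nbrs <- nbrs[order(rank[nbrs], sig)]
    }
    for (v in nbrs) {
      if (visited[v]) {
        key <- paste(min(a, v), max(a, v), sep = "-")
        if (!key %in% names(ring_bonds))
          ring_bonds[[key]] <<- c(v, a)
      } else {
        parent[v] <<- a
        children[[a]] <<- c(children[[a]], v)
        dfs(v)
      }
    }
  }
  dfs(start)

  # assign ring-closure digits in emission order of the first endpoint
  rb_open <- vector("list", n)   # atom -> vector of ring bond ids opened here
  rb_close <- vector("list", n)  # atom -> ring bond ids closed here
  if (length(ring_bonds)) {
    pos <- match(seq_len(n), order_visit)
    ids <- seq_along(ring_bonds)
    # deterministic order: by visit position of opening atom, then closing
    opens <- vapply(ring_bonds, `[`, integer(1), 1)
    closes <- vapply(ring_bonds, `[`, integer(1), 2)
    o <- order(pos[opens], pos[closes])
    ring_bonds <- ring_bonds[o]
    for (id in seq_along(ring_bonds)) {
      a <- ring_bonds[[id]][1]; b <- ring_bonds[[id]][2]
      rb_open[[a]] <- c(rb_open[[a]], id)
      rb_close[[b]] <- c(rb_close[[b]], id)
    }
  }
  digit_of <- integer(length(ring_bonds))
  free_digits <- 1:99
  in_use <- logical(99)

  digit_str <- function(d) if (d < 10) as.character(d) else sprintf("%%%02d", d)

  emit <- function(a) {
    out <- atom_token(mol, a)
    for (id in rb_open[[a]]) {
      d <- which(!in_use)[1]
      in_use[d] <<- TRUE
      digit_of[id] <<- d
      b <- ring_bonds[[id]]
      brow <- bmap[[paste(min(b[1], b[2]), max(b[1], b[2]), sep = "-")]]
      out <- paste0(out, bond_token(mol, brow), digit_str(d))
    }
    for (id in rb_close[[a]]) {
      d <- digit_of[id]
      in_use[d] <<- FALSE
      out <- paste0(out, digit_str(d))
    }
    kids <- children[[a]]
    if (length(kids)) {
      for (i in seq_along(kids)) {
        v <- kids[i]
        brow <- bmap[[paste(min(a, v), max(a, v), sep = "-")]]
        btok <- bond_token(mol, brow)
        sub <- emit(v)
        if (i < length(kids)) out <- paste0(out, "(", btok, sub, ")")
        else out <- paste0(out, btok, sub)
      }
    }
    out
  }
  emit(start)
}

#' Canonical SMILES of a sanitized molecular graph
#'
#' Produces a canonical constitution-level SMILES string: independent of the
#' input atom order and of the input Kekule structure for perceived-aromatic
#' systems. Multi-fragment graphs are written as dot-separated fragments in
#' lexicographic order. Stereochemistry is not represented.
#'
#' @param mol sanitized `molgraph` (see [sanitize_mol()]).
#' @return a single SMILES string.
#' @export
mol_to_smiles <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  if (is.null(mol$atoms$nh))
    stop("molecule must be sanitized first (see sanitize_mol)", call. = FALSE)
  rank <- canonical_ranks(mol)
  comp <- mol_components(mol)
  adj <- adjacency_list(mol)
  bmap <- bond_index_map(mol)
  frags <- character(0)
  deg <- heavy_degree(mol)
  for (cc in sort(unique(comp))) {
    members <- which(comp == cc)
    # invariant start set: terminal atoms plus the minimal-rank class; pick
    # the string with fewest branch parentheses, then lexicographically first
    starts <- union(members[deg[members] <= 1L],
                    members[rank[members] == min(rank[members])])
    cand <- vapply(starts, function(s)
      write_fragment_from(mol, adj, bmap, rank, s), character(1))
    npar <- vapply(cand, function(s)
      nchar(gsub("[^(]", "", s)), integer(1))
    cand <- cand[order(npar, cand)]
    frags <- c(frags, cand[1])
  }
  paste(sort(frags), collapse = ".")
}
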