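# The five fingerprints: MQN (42 integer counts), SMIfp (34 character
# counts), APfp (20 HAC-normalized atom-pair counts), Xfp (55 category
# atom-pair components) and Sfp (1024-bit hashed linear-path substructure
# fingerprint), plus the two metrics used on them (city-block distance for
# the scalar kinds, Tanimoto for Sfp).

FP_KINDS <- c("mqn", "smifp", "apfp", "xfp", "sfp")
FP_LENGTHS <- c(mqn = 42L, smifp = 34L, apfp = 20L, xfp = 55L, sfp = 1024L)

MQN_NAMES <- c(
  "c", "f", "cl", "br", "i", "s", "p", "an", "cn", "ao", "co", "hac",
  "asb", "adb", "atb", "csb", "cdb", "ctb", "rbc",
  "hbas", "hba", "hbds", "hbd", "neg", "pos",
  "amv", "adv", "atv", "aqv", "cdv", "ctv", "cqv",
  "r3", "r4", "r5", "r6", "r7", "r8", "r9", "rg10", "afr", "bfr")

# SMIfp alphabet: 14 atom symbols + 11 structural symbols + ring digits 1-9.
# Two-letter symbols consume both characters before single-letter matching;
# ')' and ']' are redundant with their partners and are not counted.
SMIFP_ALPHABET <- c("C", "c", "N", "n", "O", "o", "S", "s", "P", "F",
                    "Cl", "Br", "I", "B",
                    "=", "#", "(", "[", "+", "-", ".", "@", "/", "\\", "%",
                    as.character(1:9))

XFP_BLOCKS <- c("hydrophobic", "hbd", "hba", "sp2", "cross")

new_fp <- function(values, kind, names = NULL) {
  stopifnot(kind %in% FP_KINDS, length(values) == FP_LENGTHS[[kind]])
  if (!is.null(names)) names(values) <- names
  structure(values, kind = kind, class = c("fp_vector", class(values)))
}

#' @export
print.fp_vector <- function(x, ...) {
  cat(sprintf("<%s fingerprint, %d components, %d nonzero>\n",
              attr(x, "kind"), length(x), sum(x != 0)))
  invisible(x)
}

fp_kind <- function(x) attr(x, "kind")

std_graph <- function(mol) {
  if (inherits(mol, "std_mol")) mol$graph
  else if (inherits(mol, "molgraph")) mol
  else stop("expected a std_mol or molgraph", call. = FALSE)
}

# ---------------------------------------------------------------------------
# MQN

count_incident <- function(mol, rows) {
  n <- nrow(mol$atoms)
  cnt <- integer(n)
  for (b in rows) {
    cnt[mol$bonds$a1[b]] <- cnt[mol$bonds$a1[b]] + 1L
    cnt[mol$bonds$a2[b]] <- cnt[mol$bonds$a2[b]] + 1L
  }
  cnt
}

# H-bond donor/acceptor perception shared by MQN and Xfp.
polar_flags <- function(mol) {
  el <- mol$atoms$element
  nh <- mol$atoms$nh
  ch <- mol$atoms$charge
  arom <- mol$atoms$arom
  adj <- adjacency_list(mol)
  ndbl <- count_incident(mol, which(mol$bonds$order == 2L))

  hbd <- (el %in% c("N", "O")) & nh >= 1L
  # amide N: nitrogen single-bonded to a carbonyl carbon
  amide_n <- rep(FALSE, length(el))
  for (a in which(el == "N")) {
    for (nb in adj[[a]]) {
      if (el[nb] == "C" && ndbl[nb] >= 1L) {
        dbl_o <- any(vapply(adj[[nb]], function(x)
          el[x] == "O" && has_order2(mol, nb, x), logical(1)))
        if (dbl_o && !has_order2(mol, a, nb)) amide_n[a] <- TRUE
      }
    }
  }
  pyrrole_n <- el == "N" & arom & ndbl == 0L  # lone pair in the ring
  hba <- (el %in% c("N", "O")) & ch <= 0L & !(amide_n) & !(pyrrole_n) &
    !(el == "N" & ch > 0L)
  list(hbd = hbd, hba = hba)
}

has_order2 <- function(mol, a, b) {
  any((mol$bonds$a1 == a & mol$bonds$a2 == b |
         mol$bonds$a1 == b & mol$bonds$a2 == a) & mol$bonds$order == 2L)
}

# rotatable bond: acyclic single bond between two non-terminal heavy atoms,
# excluding amide C-N
rotatable_bonds <- function(mol) {
  if (!nrow(mol$bonds)) return(logical(0))
  deg <- heavy_degree(mol)
  rm_ <- ring_membership(mol)
  el <- mol$atoms$element
  adj <- adjacency_list(mol)
  out <- logical(nrow(mol$bonds))
  for (b in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$order[b] != 1L || rm_$bond[b]) next
    a1 <- mol$bonds$a1[b]; a2 <- mol$bonds$a2[b]
    if (deg[a1] < 2L || deg[a2] < 2L) next
    # amide C-N
    amide <- FALSE
    for (pr in list(c(a1, a2), c(a2, a1))) {
      cc <- pr[1]; nn <- pr[2]
      if (el[cc] == "C" && el[nn] == "N") {
        if (any(vapply(adj[[cc]], function(x)
          el[x] == "O" && has_order2(mol, cc, x), logical(1)))) amide <- TRUE
      }
    }
    if (!amide) out[b] <- TRUE
  }
  out
}

#' Molecular quantum numbers (MQN) fingerprint
#'
#' 42 integer counts of atom types, bond types (on the canonical Kekule
#' structure), polar groups and topological features (SSSR ring sizes).
#' Component order: C, F, Cl, Br, I, S, P, acyclic/cyclic N, acyclic/cyclic
#' O, heavy atoms; acyclic and cyclic single/double/triple bonds, rotatable
#' bonds; H-bond acceptor sites/atoms, donor sites/atoms, negative/positive
#' charges; acyclic mono-/di-/tri-/tetravalent and cyclic di-/tri-/
#' tetravalent nodes; 3- to 9-membered rings, rings of 10 or more, atoms and
#' bonds shared by two or more SSSR rings.
#'
#' @param mol a `std_mol` (or sanitized `molgraph`).
#' @return an `fp_vector` of kind `"mqn"`.
#' @export
fp_mqn <- function(mol) {
  g <- std_graph(mol)
  el <- g$atoms$element
  rm_ <- ring_membership(g)
  v <- integer(42)
  names(v) <- MQN_NAMES
  v["c"] <- sum(el == "C"); v["f"] <- sum(el == "F")
  v["cl"] <- sum(el == "Cl"); v["br"] <- sum(el == "Br")
  v["i"] <- sum(el == "I"); v["s"] <- sum(el == "S"); v["p"] <- sum(el == "P")
  v["an"] <- sum(el == "N" & !rm_$atom); v["cn"] <- sum(el == "N" & rm_$atom)
  v["ao"] <- sum(el == "O" & !rm_$atom); v["co"] <- sum(el == "O" & rm_$atom)
  v["hac"] <- nrow(g$atoms)

  if (nrow(g$bonds)) {
    ord <- g$bonds$order; cyc <- rm_$bond
    v["asb"] <- sum(ord == 1L & !cyc); v["adb"] <- sum(ord == 2L & !cyc)
    v["atb"] <- sum(ord == 3L & !cyc)
    v["csb"] <- sum(ord == 1L & cyc); v["cdb"] <- sum(ord == 2L & cyc)
    v["ctb"] <- sum(ord == 3L & cyc)
    v["rbc"] <- sum(rotatable_bonds(g))
  }

  pf <- polar_flags(g)
  nh <- g$atoms$nh; ch <- g$atoms$charge
  v["hbd"] <- sum(pf$hbd)
  v["hbds"] <- sum(nh[pf$hbd])
  v["hba"] <- sum(pf$hba)
  # acceptor sites: available lone pairs (O 2, O- 3, N 1, N- 2)
  sites <- ifelse(el == "O", 2L + pmax(0L, -ch), 1L + pmax(0L, -ch))
  v["hbas"] <- sum(sites[pf$hba])
  v["neg"] <- sum(ch < 0L)
  v["pos"] <- sum(ch > 0L)

  deg <- heavy_degree(g)
  v["amv"] <- sum(!rm_$atom & deg == 1L)
  v["adv"] <- sum(!rm_$atom & deg == 2L)
  v["atv"] <- sum(!rm_$atom & deg == 3L)
  v["aqv"] <- sum(!rm_$atom & deg == 4L)
  v["cdv"] <- sum(rm_$atom & deg == 2L)
  v["ctv"] <- sum(rm_$atom & deg == 3L)
  v["cqv"] <- sum(rm_$atom & deg == 4L)

  rings <- get_sssr(g)
  if (length(rings)) {
    sizes <- vapply(rings, length, integer(1))
    for (s in 3:9) v[paste0("r", s)] <- sum(sizes == s)
    v["rg10"] <- sum(sizes >= 10L)
    atom_rc <- integer(nrow(g$atoms))
    bond_rc <- integer(nrow(g$bonds))
    bmap <- bond_index_map(g)
    for (p in rings) {
      atom_rc[p] <- atom_rc[p] + 1L
      k <- length(p)
      for (i in seq_len(k)) {
        a <- p[i]; b <- p[if (i == k) 1 else i + 1]
        r <- bmap[[paste(min(a, b), max(a, b), sep = "-")]]
        bond_rc[r] <- bond_rc[r] + 1L
      }
    }
    v["afr"] <- sum(atom_rc >= 2L)
    v["bfr"] <- sum(bond_rc >= 2L)
  }
  new_fp(as.integer(v), "mqn", MQN_NAMES)
}

# ---------------------------------------------------------------------------
# SMIfp

#' SMILES fingerprint (SMIfp)
#'
#' Counts occurrences of a fixed 34-symbol alphabet in the canonical SMILES
#' of the molecule (always recomputed, never taken from user input).
#' Two-letter element symbols (Cl, Br) are consumed before single-character
#' matching, so chlorine never inflates the carbon count.
#'
#' @param mol a `std_mol`, sanitized `molgraph`, or a SMILES string (a string
#'   is parsed, sanitized and canonicalized first).
#' @return an `fp_vector` of kind `"smifp"`.
#' @export
fp_smifp <- function(mol) {
  smi <- if (is.character(mol)) {
    mol_to_smiles(sanitize_mol(parse_smiles(mol)))
  } else if (inherits(mol, "std_mol")) {
    mol$canonical_smiles
  } else {
    mol_to_smiles(std_graph(mol))
  }
  counts <- stats::setNames(integer(34), SMIFP_ALPHABET)
  i <- 1L; nc <- nchar(smi)
  while (i <= nc) {
    two <- substr(smi, i, i + 1L)
    if (two %in% c("Cl", "Br")) {
      counts[two] <- counts[two] + 1L
      i <- i + 2L
      next
    }
    ch <- substr(smi, i, i)
    if (ch %in% SMIFP_ALPHABET) counts[ch] <- counts[ch] + 1L
    i <- i + 1L
  }
  new_fp(as.integer(counts), "smifp", SMIFP_ALPHABET)
}

# ---------------------------------------------------------------------------
# APfp

#' Atom-pair shape fingerprint (APfp)
#'
#' Component d (d = 1..20) is the number of unordered heavy-atom pairs at
#' topological (shortest-path) distance exactly d bonds, divided by the heavy
#' atom count. Pairs farther than 20 bonds are dropped.
#'
#' @param mol a `std_mol` or sanitized `molgraph`.
#' @return an `fp_vector` of kind `"apfp"`.
#' @export
fp_apfp <- function(mol) {
  g <- std_graph(mol)
  n <- nrow(g$atoms)
  dm <- topo_distances(g)
  d <- dm[upper.tri(dm)]
  d <- d[is.finite(d) & d >= 1 & d <= 20]
  v <- tabulate(d, nbins = 20) / n
  new_fp(v, "apfp", paste0("d", 1:20))
}

# ---------------------------------------------------------------------------
# Xfp

#' Pharmacophore atom-category flags
#'
#' Per heavy atom: hydrophobic (carbon or halogen with no N/O neighbor),
#' H-bond donor (N/O bearing at least one hydrogen), H-bond acceptor (N/O
#' accepting; excludes pyrrole-type aromatic N, amide N and positively
#' charged atoms) and sp2 (aromatic, or carrying exactly one double bond).
#'
#' @param mol a `std_mol` or sanitized `molgraph`.
#' @return data.frame with logical columns hydrophobic, hbd, hba, sp2.
#' @export
assign_categories <- function(mol) {
  g <- std_graph(mol)
  el <- g$atoms$element
  adj <- adjacency_list(g)
  no_het_nbr <- vapply(seq_along(el), function(a)
    !any(el[adj[[a]]] %in% c("N", "O")), logical(1))
  hydrophobic <- el %in% c("C", "F", "Cl", "Br", "I") & no_het_nbr
  pf <- polar_flags(g)
  ndbl <- count_incident(g, which(g$bonds$order == 2L))
  ntrp <- count_incident(g, which(g$bonds$order == 3L))
  sp2 <- g$atoms$arom | (ndbl == 1L & ntrp == 0L)
  data.frame(hydrophobic = hydrophobic, hbd = pf$hbd, hba = pf$hba, sp2 = sp2)
}

#' Category-extended atom-pair pharmacophore fingerprint (Xfp)
#'
#' Five 11-component blocks (topological distances 0..10): hydrophobic,
#' donor, acceptor and sp2 same-category pair counts plus acceptor/donor
#' cross-pair counts, each normalized to the number of category atoms. At
#' distance 0 each category atom counts once as a self-pair (so a non-empty
#' same-category block always starts at 1); the cross block counts atoms that
#' are both acceptor and donor at d = 0 and is normalized to the size of the
#' acceptor-donor union.
#'
#' @param mol a `std_mol` or sanitized `molgraph`.
#' @return an `fp_vector` of kind `"xfp"`.
#' @export
fp_xfp <- function(mol) {
  g <- std_graph(mol)
  cats <- assign_categories(g)
  dm <- topo_distances(g)
  v <- numeric(55)
  labs <- as.vector(vapply(XFP_BLOCKS, function(b)
    paste0(b, "_d", 0:10), character(11)))
  blk <- 0L
  for (b in c("hydrophobic", "hbd", "hba", "sp2")) {
    atoms <- which(cats[[b]])
    if (length(atoms)) {
      comp <- numeric(11)
      comp[1] <- length(atoms)  # d = 0 self-pairs
      if (length(atoms) >= 2) {
        sub <- dm[atoms, atoms, drop = FALSE]
        dd <- sub[upper.tri(sub)]
        dd <- dd[is.finite(dd) & dd >= 1 & dd <= 10]
        comp[2:11] <- tabulate(dd, nbins = 10)
      }
      v[blk + 1:11] <- comp / length(atoms)
    }
    blk <- blk + 11L
  }
  hba <- which(cats$hba); hbd <- which(cats$hbd)
  uni <- union(hba, hbd)
  if (length(uni)) {
    comp <- numeric(11)
    comp[1] <- length(intersect(hba, hbd))
    if (length(hba) && length(hbd)) {
      pairs <- expand.grid(a = hba, b = hbd)
      pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
      if (nrow(pairs)) {
        key <- paste(pmin(pairs$a, pairs$b), pmax(pairs$a, pairs$b))
        pairs <- pairs[!duplicated(key), , drop = FALSE]
        dd <- dm[cbind(pairs$a, pairs$b)]
        dd <- dd[is.finite(dd) & dd >= 1 & dd <= 10]
        comp[2:11] <- tabulate(dd, nbins = 10)
      }
    }
    v[blk + 1:11] <- comp / length(uni)
  }
  new_fp(v, "xfp", labs)
}

# ---------------------------------------------------------------------------
# Sfp

SFP_BITS <- 1024L
SFP_MAX_PATH <- 7L
SFP_BITS_PER_PATH <- 2L

# deterministic string hash (31-bit polynomial, exact in doubles)
hash_string <- function(s, base) {
  h <- 7
  for (code in utf8ToInt(s)) {
    h <- (h * base + code) %% 2147483647
  }
  h
}

sfp_atom_label <- function(mol, a) {
  paste0(mol$atoms$element[a], if (mol$atoms$arom[a]) "~" else "",
         if (mol$atoms$charge[a] != 0L) sprintf("%+d", mol$atoms$charge[a]) else "")
}

sfp_bond_label <- function(mol, brow) {
  if (mol$bonds$arom[brow]) ":" else c("-", "=", "#")[mol$bonds$order[brow]]
}

#' Hashed substructure fingerprint (Sfp)
#'
#' Enumerates all linear paths of 0 to 7 bonds over element / charge /
#' aromaticity atom labels and bond-order labels, and folds each distinct
#' path into a 1024-bit vector (two bits per path, polynomial string
#' hashing). Deterministic; no bit-compatibility with any external
#' implementation is claimed.
#'
#' @param mol a `std_mol` or sanitized `molgraph`.
#' @return an `fp_vector` of kind `"sfp"` (0/1 integer components).
#' @export
fp_sfp <- function(mol) {
  g <- std_graph(mol)
  n <- nrow(g$atoms)
  adj <- adjacency_list(g)
  bmap <- bond_index_map(g)
  alab <- vapply(seq_len(n), function(a) sfp_atom_label(g, a), character(1))
  paths <- new.env(hash = TRUE, parent = emptyenv())
  walk <- function(a, s, rev_s, used) {
    key <- if (s <= rev_s) s else rev_s
    assign(key, TRUE, envir = paths)
    if (sum(used) > SFP_MAX_PATH) return(invisible())
    for (nb in adj[[a]]) {
      if (used[nb]) next
      brow <- bmap[[paste(min(a, nb), max(a, nb), sep = "-")]]
      bl <- sfp_bond_label(g, brow)
      used[nb] <- TRUE
      walk(nb, paste0(s, bl, alab[nb]), paste0(alab[nb], bl, rev_s), used)
      used[nb] <- FALSE
    }
  }
  for (a in seq_len(n)) {
    used <- rep(FALSE, n)
    used[a] <- TRUE
    walk(a, alab[a], alab[a], used)
  }
  bits <- integer(SFP_BITS)
  for (key in ls(paths)) {
    h1 <- hash_string(key, 131)
    h2 <- hash_string(key, 257)
    bits[(h1 %% SFP_BITS) + 1L] <- 1L
    bits[(h2 %% SFP_BITS) + 1L] <- 1L
  }
  new_fp(bits, "sfp", paste0("bit", seq_len(SFP_BITS)))
}

# ---------------------------------------------------------------------------
# dispatch + metrics

#' Compute a fingerprint of a given kind
#'
#' @param mol a `std_mol` or sanitized `molgraph`.
#' @param kind one of `"mqn"`, `"smifp"`, `"apfp"`, `"xfp"`, `"sfp"`.
#' @return an `fp_vector`.
#' @export
fingerprint <- function(mol, kind = c("mqn", "smifp", "apfp", "xfp", "sfp")) {
  kind <- match.arg(kind)
  switch(kind, mqn = fp_mqn(mol), smifp = fp_smifp(mol), apfp = fp_apfp(mol),
         xfp = fp_xfp(mol), sfp = fp_sfp(mol))
}

#' Fingerprint matrix for a standardized library
#'
#' @param mols list of `std_mol`.
#' @param kind fingerprint kind.
#' @return numeric matrix, one row per molecule, rownames = molecule ids,
#'   with attribute `kind`.
#' @export
fingerprint_matrix <- function(mols, kind = c("mqn", "smifp", "apfp", "xfp",
                                              "sfp")) {
  kind <- match.arg(kind)
  stopifnot(length(mols) >= 1)
  rows <- lapply(mols, fingerprint, kind = kind)
  m <- do.call(rbind, lapply(rows, as.numeric))
  colnames(m) <- names(rows[[1]])
  rownames(m) <- vapply(mols, function(m) m$record$id, character(1))
  attr(m, "kind") <- kind
  m
}

check_same_kind <- function(u, v) {
  ku <- fp_kind(u); kv <- fp_kind(v)
  if (is.null(ku) || is.null(kv) || ku != kv)
    stop("fingerprint kind mismatch", call. = FALSE)
  ku
}

#' City-block distance between two scalar fingerprints
#'
#' @param u,v `fp_vector`s of the same scalar kind (mqn, smifp, apfp, xfp).
#' @return non-negative number, the sum of absolute component differences.
#' @export
cbd <- function(u, v) {
  kind <- check_same_kind(u, v)
  if (kind == "sfp")
    stop("city-block distance is for scalar fingerprints; use tanimoto()",
         call. = FALSE)
  sum(abs(as.numeric(u) - as.numeric(v)))
}

#' Tanimoto coefficient between two binary Sfp fingerprints
#'
#' Defined as 1 when both vectors are all-zero.
#'
#' @param a,b `fp_vector`s of kind `"sfp"`.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  kind <- check_same_kind(a, b)
  if (kind != "sfp")
    stop("tanimoto() is defined for sfp fingerprints; use cbd()",
         call. = FALSE)
  av <- as.numeric(a) > 0; bv <- as.numeric(b) > 0
  uni <- sum(av | bv)
  if (uni == 0) return(1)
  sum(av & bv) / uni
}
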