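# Rule-based ionization at pH 7.4.
#
# Deterministic approximation in place of pKa prediction: deprotonate
# carboxylic, sulfonic/sulfinic acids, one proton per phosphate/phosphonate
# group and tetrazole NH; protonate aliphatic amines (not amides, not
# anilines, not aromatic N), amidines and guanidines at the imine nitrogen.
# Where one proton out of several equivalent sites must be picked, canonical
# atom ranks break the tie so the result is independent of input atom order.

neighbors_of <- function(adj, a) adj[[a]]

bond_between <- function(mol, bmap, a, b) {
  r <- bmap[[paste(min(a, b), max(a, b), sep = "-")]]
  if (is.null(r)) NULL else mol$bonds[r, ]
}

# acidic hydroxyl oxygens attached to `center` (single-bonded O with H)
acidic_hydroxyls <- function(mol, adj, bmap, center) {
  out <- integer(0)
  for (nb in adj[[center]]) {
    if (mol$atoms$element[nb] == "O" && mol$atoms$charge[nb] == 0L &&
        mol$atoms$nh[nb] >= 1L) {
      bo <- bond_between(mol, bmap, center, nb)
      if (!is.null(bo) && bo$order == 1L) out <- c(out, nb)
    }
  }
  out
}

has_double_to <- function(mol, adj, bmap, center, element) {
  for (nb in adj[[center]]) {
    if (mol$atoms$element[nb] == element) {
      bo <- bond_between(mol, bmap, center, nb)
      if (!is.null(bo) && bo$order == 2L) return(TRUE)
    }
  }
  FALSE
}

# Apply the pH 7.4 charging rules in place; returns the modified molgraph.
apply_ph74_rules <- function(mol) {
  adj <- adjacency_list(mol)
  bmap <- bond_index_map(mol)
  ranks <- canonical_ranks(mol)
  el <- mol$atoms$element
  n <- nrow(mol$atoms)

  deprotonate <- function(o) {
    mol$atoms$charge[o] <<- mol$atoms$charge[o] - 1L
    mol$atoms$nh[o] <<- mol$atoms$nh[o] - 1L
  }
  protonate <- function(a) {
    mol$atoms$charge[a] <<- mol$atoms$charge[a] + 1L
    mol$atoms$nh[a] <<- mol$atoms$nh[a] + 1L
  }
  pick_by_rank <- function(cands) cands[which.min(ranks[cands])]

  # --- acids ---------------------------------------------------------------
  for (c_at in which(el == "C" & !mol$atoms$arom)) {
    # carboxylic acid: C(=O)OH -> carboxylate (all OH on a carboxyl carbon)
    if (has_double_to(mol, adj, bmap, c_at, "O")) {
      for (o in acidic_hydroxyls(mol, adj, bmap, c_at)) deprotonate(o)
    }
  }
  for (s_at in which(el == "S")) {
    # sulfonic/sulfinic acid: S(=O)(=O)OH or S(=O)OH
    if (has_double_to(mol, adj, bmap, s_at, "O")) {
      oh <- acidic_hydroxyls(mol, adj, bmap, s_at)
      if (length(oh)) deprotonate(pick_by_rank(oh))
    }
  }
  for (p_at in which(el == "P")) {
    # phosphate/phosphonate: remove one proton per phosphorus group
    if (has_double_to(mol, adj, bmap, p_at, "O")) {
      oh <- acidic_hydroxyls(mol, adj, bmap, p_at)
      if (length(oh)) deprotonate(pick_by_rank(oh))
    }
  }
  # tetrazole NH: aromatic 5-ring of 4 N + 1 C
  rings <- get_sssr(mol)
  for (p in rings) {
    if (length(p) != 5) next
    if (sum(el[p] == "N") == 4L && sum(el[p] == "C") == 1L &&
        all(mol$atoms$arom[p])) {
      nh_n <- p[el[p] == "N" & mol$atoms$nh[p] >= 1L &
                  mol$atoms$charge[p] == 0L]
      if (length(nh_n)) deprotonate(pick_by_rank(nh_n))
    }
  }

  # --- bases ---------------------------------------------------------------
  # amidine/guanidine: C(=N)(N...) -> protonate the imine N
  amidine_n <- integer(0)
  amidine_member <- rep(FALSE, n)  # any N in an amidine/guanidine group
  for (c_at in which(el == "C" & !mol$atoms$arom)) {
    nbrs <- adj[[c_at]]
    nN <- nbrs[el[nbrs] == "N"]
    if (length(nN) < 2) next
    imine <- integer(0); single <- integer(0)
    for (nb in nN) {
      bo <- bond_between(mol, bmap, c_at, nb)
      if (bo$order == 2L && !mol$atoms$arom[nb]) imine <- c(imine, nb)
      else if (bo$order == 1L && !mol$atoms$arom[nb]) single <- c(single, nb)
    }
    if (length(imine) == 1L && length(single) >= 1L) {
      amidine_n <- c(amidine_n, imine)
      amidine_member[c(imine, single)] <- TRUE
    }
  }
  for (a in unique(amidine_n)) {
    if (mol$atoms$charge[a] == 0L) protonate(a)
  }
  # aliphatic amines: sp3 N, <=3 heavy neighbors, no aromatic neighbor,
  # no adjacent carbonyl/thiocarbonyl/imine carbon (amide-like), not itself
  # part of an amidine/guanidine group
  bos <- bond_order_sum(mol)
  deg <- heavy_degree(mol)
  for (a in which(el == "N")) {
    if (mol$atoms$arom[a] || mol$atoms$charge[a] != 0L) next
    if (amidine_member[a]) next
    if (bos[a] != deg[a]) next                 # has multiple bond: not sp3
    if (deg[a] > 3L) next
    nbrs <- adj[[a]]
    if (any(mol$atoms$arom[nbrs])) next        # aniline-type
    amide_like <- FALSE
    for (nb in nbrs) {
      if (el[nb] == "C" &&
          (has_double_to(mol, adj, bmap, nb, "O") ||
           has_double_to(mol, adj, bmap, nb, "S") ||
           has_double_to(mol, adj, bmap, nb, "N"))) amide_like <- TRUE
      if (el[nb] %in% c("S", "P") &&
          has_double_to(mol, adj, bmap, nb, "O")) amide_like <- TRUE
    }
    if (amide_like) next
    if (!all(el[nbrs] %in% "C")) next          # hydrazines/hydroxylamines: skip
    protonate(a)
  }
  mol
}
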