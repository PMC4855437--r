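# SMILES reader producing an unsanitized molecular graph.
#
# Supported: organic subset (B C N O P S F Cl Br I, aromatic b c n o p s),
# bracket atoms with isotope / chirality marks / H count / charge / atom class,
# bonds - = # : / \, branches, ring closures (digits and %nn), dot-separated
# fragments. Tetrahedral and cis/trans stereo descriptors are accepted and
# discarded: the package works at the constitution level.

ORGANIC_ALIPHATIC <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")
ORGANIC_AROMATIC <- c("b", "c", "n", "o", "p", "s")

new_molgraph <- function(atoms, bonds) {
  structure(list(atoms = atoms, bonds = bonds), class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph: %d atoms, %d bonds>\n", nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

empty_atoms <- function() {
  data.frame(element = character(), charge = integer(), arom = logical(),
             hexp = integer(), iso = integer(), stringsAsFactors = FALSE)
}

empty_bonds <- function() {
  data.frame(a1 = integer(), a2 = integer(), order = integer(),
             arom = logical(), stringsAsFactors = FALSE)
}

smiles_error <- function(smi, pos, msg) {
  stop(sprintf("SMILES parse error at position %d in '%s': %s", pos, smi, msg),
       call. = FALSE)
}

# Parse one bracket atom body (between '[' and ']'). Returns a list or NULL.
parse_bracket_body <- function(body) {
  m <- regmatches(body, regexec(
    "^([0-9]*)([A-IK-PR-Zacbnops][a-z]?|\\*)(@{1,2}|@TH[12])?(H[0-9]*)?([+-][0-9]*|\\+{2,}|-{2,})?(:[0-9]+)?$",
    body))[[1]]
  if (length(m) == 0) return(NULL)
  sym <- m[3]
  if (sym == "*") return(NULL)  # wildcard atoms unsupported
  arom <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
  elem <- if (arom) {
    paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  } else sym
  hexp <- 0L
  if (nzchar(m[5])) {
    hexp <- if (m[5] == "H") 1L else as.integer(substring(m[5], 2))
  }
  charge <- 0L
  cs <- m[6]
  if (nzchar(cs)) {
    if (grepl("^\\+{2,}$", cs)) charge <- nchar(cs)
    else if (grepl("^-{2,}$", cs)) charge <- -nchar(cs)
    else if (cs == "+") charge <- 1L
    else if (cs == "-") charge <- -1L
    else charge <- as.integer(cs)  # "+2" / "-2"
  }
  iso <- if (nzchar(m[2])) as.integer(m[2]) else 0L
  list(element = elem, arom = arom, hexp = as.integer(hexp),
       charge = as.integer(charge), iso = iso)
}

#' Parse a SMILES string into a molecular graph
#'
#' Produces a raw (unsanitized) molecular graph: atoms with element, formal
#' charge, aromatic flag, explicit hydrogen count (`NA` when hydrogens are
#' implicit, i.e. the atom was written without brackets) and isotope label;
#' bonds with order 1/2/3 and an aromatic flag. Stereochemistry descriptors
#' are discarded. Use [sanitize_mol()] to kekulize, assign implicit
#' hydrogens, check valences and perceive aromaticity.
#'
#' @param smi a single SMILES string.
#' @return an object of class `molgraph`.
#' @export
parse_smiles <- function(smi) {
  stopifnot(is.character(smi), length(smi) == 1)
  smi <- trimws(smi)
  if (!nzchar(smi)) stop("empty SMILES", call. = FALSE)

  n_guess <- nchar(smi)
  elem <- character(n_guess); charge <- integer(n_guess)
  arom <- logical(n_guess); hexp <- rep(NA_integer_, n_guess)
  iso <- integer(n_guess)
  b_a1 <- integer(0); b_a2 <- integer(0); b_ord <- integer(0); b_arm <- logical(0)

  na <- 0L                     # atoms emitted so far
  prev <- 0L                   # previous atom (0 = none, fresh fragment)
  pend_bond <- ""              # pending explicit bond symbol
  stack <- integer(0)          # branch stack
  ring <- list()               # open ring closures: digit -> c(atom, bondcode)
  i <- 1L
  nc <- nchar(smi)

  add_atom <- function(e, ar, hx, ch, is) {
    na <<- na + 1L
    if (na > length(elem)) {   # growth is rare; SMILES length bounds atom count
      elem <<- c(elem, character(16)); charge <<- c(charge, integer(16))
      arom <<- c(arom, logical(16)); hexp <<- c(hexp, rep(NA_integer_, 16))
      iso <<- c(iso, integer(16))
    }
    elem[na] <<- e; arom[na] <<- ar; hexp[na] <<- hx
    charge[na] <<- ch; iso[na] <<- is
    na
  }

  bond_from_symbol <- function(sym, at1, at2) {
    # returns c(order, aromatic)
    if (sym == "") {
      if (arom[at1] && arom[at2]) return(c(1L, TRUE))
      return(c(1L, FALSE))
    }
    switch(sym,
      "-" = c(1L, FALSE), "/" = c(1L, FALSE), "\\" = c(1L, FALSE),
      "=" = c(2L, FALSE), "#" = c(3L, FALSE), ":" = c(1L, TRUE),
      smiles_error(smi, i, paste0("unsupported bond '", sym, "'")))
  }

  add_bond <- function(at1, at2, sym) {
    ob <- bond_from_symbol(sym, at1, at2)
    b_a1 <<- c(b_a1, at1); b_a2 <<- c(b_a2, at2)
    b_ord <<- c(b_ord, ob[1]); b_arm <<- c(b_arm, as.logical(ob[2]))
  }

  close_or_open_ring <- function(key, atom, sym) {
    if (!is.null(ring[[key]])) {
      op <- ring[[key]]
      sym_open <- op$sym
      use <- if (nzchar(sym)) sym else sym_open
      if (nzchar(sym) && nzchar(sym_open) && sym != sym_open &&
          !(sym %in% c("/", "\\") && sym_open %in% c("/", "\\")))
        smiles_error(smi, i, "conflicting ring-closure bond symbols")
      if (op$atom == atom)
        smiles_error(smi, i, "ring closure to the same atom")
      add_bond(op$atom, atom, use)
      ring[[key]] <<- NULL
    } else {
      ring[[key]] <<- list(atom = atom, sym = sym)
    }
  }

  while (i <= nc) {
    ch <- substr(smi, i, i)
    new_atom <- NULL

    if (ch == "[") {
      j <- regexpr("]", substring(smi, i), fixed = TRUE)
      if (j < 0) smiles_error(smi, i, "unterminated bracket atom")
      body <- substr(smi, i + 1L, i + j - 2L)
      at <- parse_bracket_body(body)
      if (is.null(at)) smiles_error(smi, i, paste0("bad bracket atom [", body, "]"))
      new_atom <- add_atom(at$element, at$arom, at$hexp, at$charge, at$iso)
      i <- i + j
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      if (nzchar(pend_bond)) smiles_error(smi, i, "two consecutive bond symbols")
      pend_bond <- ch
      i <- i + 1L
    } else if (ch == "(") {
      if (prev == 0L) smiles_error(smi, i, "branch with no preceding atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) smiles_error(smi, i, "unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      if (nzchar(pend_bond)) smiles_error(smi, i, "bond before '.'")
      prev <- 0L
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (prev == 0L) smiles_error(smi, i, "ring closure with no preceding atom")
      if (ch == "%") {
        key <- substr(smi, i + 1L, i + 2L)
        if (!grepl("^[0-9]{2}$", key))
          smiles_error(smi, i, "'%' must be followed by two digits")
        i <- i + 3L
      } else {
        key <- ch
        i <- i + 1L
      }
      close_or_open_ring(key, prev, pend_bond)
      pend_bond <- ""
    } else {
      # organic-subset atom (two-letter symbols first)
      two <- substr(smi, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        new_atom <- add_atom(two, FALSE, NA_integer_, 0L, 0L)
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        new_atom <- add_atom(ch, FALSE, NA_integer_, 0L, 0L)
        i <- i + 1L
      } else if (ch %in% ORGANIC_AROMATIC) {
        new_atom <- add_atom(toupper(ch), TRUE, NA_integer_, 0L, 0L)
        i <- i + 1L
      } else {
        smiles_error(smi, i, paste0("unexpected character '", ch, "'"))
      }
    }

    if (!is.null(new_atom)) {
      if (prev != 0L) add_bond(prev, new_atom, pend_bond)
      else if (nzchar(pend_bond)) smiles_error(smi, i, "dangling bond symbol")
      pend_bond <- ""
      prev <- new_atom
    }
  }

  if (length(stack) > 0L) smiles_error(smi, nc, "unmatched '('")
  if (length(ring) > 0L) smiles_error(smi, nc, "unclosed ring bond")
  if (nzchar(pend_bond)) smiles_error(smi, nc, "dangling bond symbol")
  if (na == 0L) smiles_error(smi, 1L, "no atoms")

  atoms <- data.frame(element = elem[seq_len(na)], charge = charge[seq_len(na)],
                      arom = arom[seq_len(na)], hexp = hexp[seq_len(na)],
                      iso = iso[seq_len(na)], stringsAsFactors = FALSE)
  dup <- duplicated(rbind(cbind(b_a1, b_a2), cbind(b_a2, b_a1)))[seq_along(b_a1)]
  if (any(dup)) stop("duplicate bond in SMILES", call. = FALSE)
  bonds <- data.frame(a1 = b_a1, a2 = b_a2, order = b_ord, arom = b_arm,
                      stringsAsFactors = FALSE)
  new_molgraph(atoms, bonds)
}
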