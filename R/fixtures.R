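# Deterministic synthetic molecule libraries: template-enumerated chemistry
# (valid by construction) covering alkanes, rings, and decorated aromatics
# with N/O substituents, with optional planted duplicates, salt forms and
# oversized molecules to exercise the standardization paths.

#' Linear alkane SMILES
#'
#' @param n number of carbons (heavy atoms), `n >= 1`.
#' @return SMILES string `"CC...C"`.
#' @export
make_alkane <- function(n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  paste(rep("C", n), collapse = "")
}

# substituents for aromatic cores (attachment point is the leading atom)
AROMATIC_SUBSTITUENTS <- c("F", "Cl", "Br", "O", "N", "OC", "C", "CC",
                           "C(=O)O", "C#N", "C=C", "OCC", "S", "I",
                           "C(=O)N", "CO", "C(C)C", "[N+](=O)[O-]")

AROMATIC_CORES <- c(
  "c1ccccc1", "c1ccncc1", "c1ccc2ccccc2c1", "c1cc[nH]c1", "c1ccoc1",
  "c1ccsc1", "c1cnccn1", "c1ccc2[nH]ccc2c1")

RING_CORES <- c("C1CC1", "C1CCC1", "C1CCCC1", "C1CCCCC1", "C1CCCCCC1",
                "C1CCC2CCCCC2C1", "C1CCOC1", "C1CCNC1", "C1CCOCC1",
                "C1CCNCC1", "C1CCSC1")

CHAIN_TEMPLATES <- c("NCCO", "OCCO", "NCCN", "CCOC(=O)C", "CC(=O)NC",
                     "CC(N)C(=O)O", "NCCCN", "OCC(O)CO", "CC(O)CN",
                     "CCSCC", "CC(=O)CC", "CCOCC", "NC(=N)N", "CCC#N",
                     "OS(=O)(=O)C", "OP(=O)(O)OC")

# attach substituents to an aromatic core at distinct positions (simple
# string surgery on single-ring cores written as c1ccccc1-likes)
decorate_core <- function(core, subs) {
  out <- core
  for (s in subs) out <- sub("cc", paste0("c(", s, ")c"), out, fixed = TRUE)
  out
}

#' Generate a deterministic synthetic SMILES library
#'
#' A pure function of its arguments: molecules are enumerated from chemical
#' templates (alkanes and branched alkanes, carbo- and heterocycles,
#' decorated aromatic cores, polar chains), mixed by a seeded sampler.
#' Optionally plants exact duplicates, one salt form and oversized molecules
#' so the standardization and deduplication paths have known ground truth.
#'
#' @param n number of library lines to emit.
#' @param seed integer seed; same (n, seed, options) gives an identical
#'   library.
#' @param duplicates how many duplicate lines (re-emissions of earlier
#'   molecules under a new name) to plant.
#' @param salts how many lines to emit as salt forms (`.[Na+]` or `.Cl`
#'   appended; the parent fragment is also in the library, so these become
#'   duplicates after salt stripping).
#' @param oversized how many oversized (51-carbon alkane) lines to plant.
#' @param size_range heavy-atom range targeted for the alkane family.
#' @return character vector of `"SMILES name"` lines, length `n`.
#' @export
make_library <- function(n, seed = 7L, duplicates = 0L, salts = 0L,
                         oversized = 0L, size_range = c(3L, 14L)) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())),
          add = TRUE)
  set.seed(seed)

  n_regular <- n - duplicates - salts - oversized
  if (n_regular < 1)
    stop("n too small for the requested planted lines", call. = FALSE)

  # the regular pool is kept collision-free at the canonical-SMILES level so
  # planted duplicates/salts are the only deduplication events downstream
  smis <- character(0)
  seen <- character(0)
  attempts <- 0L
  while (length(smis) < n_regular) {
    attempts <- attempts + 1L
    if (attempts > 60L * n_regular)
      stop("template space exhausted for requested n", call. = FALSE)
    family <- sample(c("alkane", "ring", "aromatic", "chain"), 1,
                     prob = c(0.2, 0.2, 0.35, 0.25))
    smi <- switch(family,
      alkane = {
        len <- sample(size_range[1]:size_range[2], 1)
        if (runif(1) < 0.3 && len >= 4) {
          # one methyl branch at a random interior position
          pos <- sample(2:(len - 2), 1)
          paste0(paste(rep("C", pos), collapse = ""), "(C)",
                 paste(rep("C", len - pos - 1), collapse = ""))
        } else make_alkane(len)
      },
      ring = {
        core <- sample(RING_CORES, 1)
        if (runif(1) < 0.5) sub("1C", "1(C)C", core, fixed = TRUE) else core
      },
      aromatic = {
        core <- sample(AROMATIC_CORES, 1)
        k <- sample(0:3, 1)
        subs <- if (k > 0) sample(AROMATIC_SUBSTITUENTS, k) else character(0)
        decorate_core(core, subs)
      },
      chain = sample(CHAIN_TEMPLATES, 1))
    can <- tryCatch(mol_to_smiles(sanitize_mol(parse_smiles(smi))),
                    error = function(e) NA_character_)
    if (is.na(can) || can %in% seen) next
    seen <- c(seen, can)
    smis <- c(smis, smi)
  }

  extra <- character(0)
  if (duplicates > 0) {
    src <- sample(seq_along(smis), duplicates, replace = duplicates > length(smis))
    extra <- c(extra, smis[src])
  }
  if (salts > 0) {
    src <- sample(seq_along(smis), salts, replace = salts > length(smis))
    counter <- sample(c(".[Na+]", ".Cl", ".[K+]"), salts, replace = TRUE)
    extra <- c(extra, paste0(smis[src], counter))
  }
  if (oversized > 0) extra <- c(extra, rep(make_alkane(51L), oversized))

  all_smis <- c(smis, extra)
  paste(all_smis, sprintf("fx%04d", seq_along(all_smis)))
}

#' Standardized fixture library in one call
#'
#' Convenience wrapper: [make_library()], [parse_lines()],
#' [standardize_library()].
#'
#' @inheritParams make_library
#' @param ... passed to [make_library()].
#' @return list of `std_mol` with `rejections` attribute.
#' @export
make_std_library <- function(n, seed = 7L, ...) {
  standardize_library(parse_lines(make_library(n, seed = seed, ...)))
}
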