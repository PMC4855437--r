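# Library reading and standardization: parse, valence-check, strip
# counterions, apply pH 7.4 charging rules, enforce the heavy-atom cap and
# deduplicate on canonical SMILES. Every input record ends up either in the
# output or in the rejection log, never both, never neither.

REJECT_REASONS <- c("parse_error", "valence_error", "too_large", "duplicate",
                    "empty_after_saltstrip")

new_mol_record <- function(id, name, smiles_input, graph, source_index) {
  structure(list(id = id, name = name, smiles_input = smiles_input,
                 graph = graph, source_index = as.integer(source_index)),
            class = "mol_record")
}

#' @export
print.mol_record <- function(x, ...) {
  cat(sprintf("<mol_record %s (%s): %d atoms>\n", x$id, x$name,
              nrow(x$graph$atoms)))
  invisible(x)
}

new_std_mol <- function(record, graph, canonical_smiles, hac) {
  structure(list(record = record, graph = graph,
                 canonical_smiles = canonical_smiles, hac = as.integer(hac)),
            class = "std_mol")
}

#' @export
print.std_mol <- function(x, ...) {
  cat(sprintf("<std_mol %s: %s (hac=%d)>\n", x$record$id, x$canonical_smiles,
              x$hac))
  invisible(x)
}

#' Read a SMILES library file
#'
#' Each non-blank, non-comment (`#`-prefixed) line is `SMILES` optionally
#' followed by a space and a name. Unparsable lines are logged as rejections,
#' not fatal.
#'
#' @param path path to the text file.
#' @return list of `mol_record` objects with a `rejections` attribute
#'   (data.frame of id/reason).
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (!length(lines)) stop("empty library: ", path, call. = FALSE)
  parse_lines(lines)
}

#' Parse SMILES lines into molecule records
#'
#' Workhorse behind [read_smiles_file()], usable directly on an in-memory
#' character vector of `"SMILES name"` lines.
#'
#' @param lines character vector, one molecule per element.
#' @return list of `mol_record` with `rejections` attribute.
#' @export
parse_lines <- function(lines) {
  records <- list()
  rej_id <- character(0); rej_reason <- character(0)
  idx <- 0L
  for (k in seq_along(lines)) {
    line <- trimws(lines[k])
    sp <- regexpr("\\s", line)
    smi <- if (sp > 0) substr(line, 1, sp - 1) else line
    name <- if (sp > 0) trimws(substring(line, sp + 1)) else ""
    if (!nzchar(name)) name <- sprintf("mol%d", k)
    g <- tryCatch(parse_smiles(smi), error = function(e) e)
    if (inherits(g, "error")) {
      rej_id <- c(rej_id, name)
      rej_reason <- c(rej_reason, "parse_error")
      next
    }
    records[[length(records) + 1L]] <- new_mol_record(
      id = name, name = name, smiles_input = smi, graph = g,
      source_index = idx)
    idx <- idx + 1L
  }
  ids <- vapply(records, `[[`, character(1), "id")
  dup <- duplicated(ids)
  for (i in which(dup)) records[[i]]$id <- sprintf("%s_%d", records[[i]]$id, i)
  attr(records, "rejections") <- data.frame(
    id = rej_id, reason = rej_reason, stringsAsFactors = FALSE)
  records
}

# keep the fragment with most heavy atoms; ties: higher molecular mass, then
# lexicographically smallest canonical SMILES
strip_salts <- function(mol) {
  comp <- mol_components(mol)
  ncomp <- max(comp)
  if (ncomp == 1) return(mol)
  hacs <- tabulate(comp, ncomp)
  cand <- which(hacs == max(hacs))
  if (length(cand) > 1) {
    mass <- vapply(cand, function(cc) {
      a <- which(comp == cc)
      sum(ATOMIC_MASSES[mol$atoms$element[a]], na.rm = TRUE) +
        sum(mol$atoms$nh[a]) * ATOMIC_MASSES[["H"]]
    }, numeric(1))
    cand <- cand[mass == max(mass)]
  }
  if (length(cand) > 1) {
    smis <- vapply(cand, function(cc) {
      sub <- subgraph_component(mol, which(comp == cc))
      mol_to_smiles(sub)
    }, character(1))
    cand <- cand[order(smis)][1]
  }
  subgraph_component(mol, which(comp == cand[1]))
}

subgraph_component <- function(mol, atoms_keep) {
  map <- integer(nrow(mol$atoms))
  map[atoms_keep] <- seq_along(atoms_keep)
  at <- mol$atoms[atoms_keep, , drop = FALSE]
  rownames(at) <- NULL
  keep_b <- mol$bonds$a1 %in% atoms_keep & mol$bonds$a2 %in% atoms_keep
  bd <- mol$bonds[keep_b, , drop = FALSE]
  if (nrow(bd)) { bd$a1 <- map[bd$a1]; bd$a2 <- map[bd$a2] }
  rownames(bd) <- NULL
  new_molgraph(at, bd)
}

#' Standardize one molecule record
#'
#' Applies, in order: valence check (sanitization), counterion removal
#' (largest fragment by heavy-atom count; ties by molecular mass, then by
#' smallest canonical SMILES), rule-based pH 7.4 ionization, and the
#' heavy-atom-count cap.
#'
#' @param rec a `mol_record`.
#' @param max_hac maximum heavy atom count retained (default 50).
#' @return a `std_mol`, or a rejection (class `mol_rejection`: list with
#'   `id` and `reason`, one of `valence_error`, `too_large`,
#'   `empty_after_saltstrip`).
#' @export
standardize_mol <- function(rec, max_hac = 50L) {
  stopifnot(inherits(rec, "mol_record"))
  reject <- function(reason)
    structure(list(id = rec$id, reason = reason), class = "mol_rejection")
  g <- tryCatch(sanitize_mol(rec$graph), error = function(e) e)
  if (inherits(g, "error")) return(reject("valence_error"))
  if (nrow(g$atoms) == 0) return(reject("empty_after_saltstrip"))
  g <- strip_salts(g)
  if (nrow(g$atoms) == 0) return(reject("empty_after_saltstrip"))
  g <- apply_ph74_rules(g)
  # charging can change hydrogen counts: re-validate
  ok <- tryCatch({ check_valences(g); TRUE }, error = function(e) FALSE)
  if (!ok) return(reject("valence_error"))
  hac <- nrow(g$atoms)
  if (hac > max_hac) return(reject("too_large"))
  new_std_mol(rec, g, mol_to_smiles(g), hac)
}

#' Standardize a library of molecule records
#'
#' Runs [standardize_mol()] over a record list and deduplicates survivors on
#' canonical SMILES (first occurrence wins, input order preserved). The
#' conservation invariant holds: every input record appears exactly once in
#' either the output or the rejection log (parse rejections carried in the
#' input's `rejections` attribute are merged in).
#'
#' @param records list of `mol_record` (from [read_smiles_file()],
#'   [read_sdf()] or [parse_lines()]).
#' @param max_hac heavy-atom cap, default 50.
#' @param deduplicate drop canonical-SMILES duplicates (default TRUE).
#' @return list of `std_mol` with attribute `rejections` (data.frame id,
#'   reason).
#' @export
standardize_library <- function(records, max_hac = 50L, deduplicate = TRUE) {
  rej <- attr(records, "rejections")
  if (is.null(rej))
    rej <- data.frame(id = character(), reason = character(),
                      stringsAsFactors = FALSE)
  out <- list()
  for (rec in records) {
    s <- standardize_mol(rec, max_hac = max_hac)
    if (inherits(s, "mol_rejection")) {
      rej <- rbind(rej, data.frame(id = s$id, reason = s$reason,
                                   stringsAsFactors = FALSE))
    } else {
      out[[length(out) + 1L]] <- s
    }
  }
  if (deduplicate) {
    dd <- deduplicate_mols(out)
    out <- dd$kept
    if (nrow(dd$duplicates)) rej <- rbind(rej, dd$duplicates)
  }
  attr(out, "rejections") <- rej
  out
}

#' Deduplicate standardized molecules on canonical SMILES
#'
#' First occurrence per canonical SMILES is kept; later ones are logged as
#' `duplicate`. Input order is preserved.
#'
#' @param mols list of `std_mol`.
#' @return list with `kept` (list of `std_mol`) and `duplicates` (data.frame
#'   id/reason).
#' @export
deduplicate_mols <- function(mols) {
  smis <- vapply(mols, `[[`, character(1), "canonical_smiles")
  dup <- duplicated(smis)
  dups <- data.frame(
    id = vapply(mols[dup], function(m) m$record$id, character(1)),
    reason = rep("duplicate", sum(dup)), stringsAsFactors = FALSE)
  list(kept = mols[!dup], duplicates = dups)
}

#' Write a standardized library as SMILES text
#'
#' One `"canonical_smiles id"` line per molecule.
#' @param mols list of `std_mol`.
#' @param path output file.
#' @export
write_smiles_file <- function(mols, path) {
  lines <- vapply(mols, function(m)
    paste(m$canonical_smiles, m$record$id), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a rejection log as TSV
#' @param rejections data.frame with columns id, reason.
#' @param path output file.
#' @export
write_rejections_tsv <- function(rejections, path) {
  utils::write.table(rejections, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
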