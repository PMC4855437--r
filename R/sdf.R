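# V2000 SDF reader. One MoleculeRecord per well-formed molecule block;
# malformed blocks are collected, not fatal.

OLD_SDF_CHARGE <- c(`1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
                    `6` = -2L, `7` = -3L)

parse_sdf_block <- function(lines) {
  if (length(lines) < 4) stop("truncated molfile block", call. = FALSE)
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1)
    stop("bad counts line", call. = FALSE)
  if (length(lines) < 4 + natoms + nbonds)
    stop("truncated atom/bond block", call. = FALSE)
  at <- lines[5:(4 + natoms)]
  elem <- trimws(substr(at, 32, 34))
  if (any(!nzchar(elem))) stop("missing element symbol", call. = FALSE)
  oldchg <- suppressWarnings(as.integer(substr(at, 37, 39)))
  oldchg[is.na(oldchg)] <- 0L
  charge <- unname(ifelse(oldchg >= 1 & oldchg <= 7,
                          OLD_SDF_CHARGE[as.character(oldchg)], 0L))
  atoms <- data.frame(element = elem, charge = as.integer(charge),
                      arom = FALSE, hexp = NA_integer_, iso = 0L,
                      stringsAsFactors = FALSE)
  if (nbonds > 0) {
    bl <- lines[(5 + natoms):(4 + natoms + nbonds)]
    a1 <- suppressWarnings(as.integer(substr(bl, 1, 3)))
    a2 <- suppressWarnings(as.integer(substr(bl, 4, 6)))
    bt <- suppressWarnings(as.integer(substr(bl, 7, 9)))
    if (any(is.na(a1) | is.na(a2) | is.na(bt)) ||
        any(a1 < 1 | a1 > natoms | a2 < 1 | a2 > natoms) || any(a1 == a2))
      stop("bad bond block", call. = FALSE)
    if (!all(bt %in% c(1L, 2L, 3L, 4L)))
      stop("unsupported bond type", call. = FALSE)
    arom <- bt == 4L
    ord <- ifelse(arom, 1L, bt)
    atoms$arom[unique(c(a1[arom], a2[arom]))] <- TRUE
    bonds <- data.frame(a1 = a1, a2 = a2, order = as.integer(ord),
                        arom = arom, stringsAsFactors = FALSE)
  } else {
    bonds <- empty_bonds()
  }
  # property lines: M CHG overrides atom-block charges
  rest <- lines[-seq_len(4 + natoms + nbonds)]
  chg_lines <- grep("^M  CHG", rest, value = TRUE)
  if (length(chg_lines)) {
    atoms$charge <- 0L
    for (cl in chg_lines) {
      toks <- scan(text = substring(cl, 7), what = integer(), quiet = TRUE)
      k <- toks[1]
      for (i in seq_len(k)) {
        atoms$charge[toks[2 * i]] <- toks[2 * i + 1]
      }
    }
  }
  new_molgraph(atoms, bonds)
}

#' Read a V2000 SDF file
#'
#' Parses each molecule block into a raw `molgraph` (not yet standardized).
#' Malformed blocks are skipped and reported in the `rejections` attribute
#' rather than aborting the read.
#'
#' @param path path to an SDF file.
#' @return a list of molecule records (class `mol_record`: fields `id`,
#'   `name`, `smiles_input`, `graph`, `source_index`), with attribute
#'   `rejections` (a data.frame of id/reason rows, reason `parse_error`).
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines))))
    stop("empty library: no molecule blocks in ", path, call. = FALSE)
  delim <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, delim + 1L)
  ends <- c(delim - 1L, length(lines))
  records <- list()
  rej_id <- character(0); rej_reason <- character(0)
  idx <- 0L
  for (b in seq_along(starts)) {
    if (starts[b] > ends[b]) next
    block <- lines[starts[b]:ends[b]]
    if (all(!nzchar(trimws(block)))) next
    name <- trimws(block[1])
    id <- if (nzchar(name)) name else sprintf("mol%d", length(records) + 1L)
    g <- tryCatch(parse_sdf_block(block), error = function(e) e)
    if (inherits(g, "error")) {
      rej_id <- c(rej_id, id)
      rej_reason <- c(rej_reason, "parse_error")
      next
    }
    records[[length(records) + 1L]] <- new_mol_record(
      id = id, name = name, smiles_input = NA_character_,
      graph = g, source_index = idx)
    idx <- idx + 1L
  }
  if (!length(records))
    stop("empty library: no parsable molecule blocks in ", path, call. = FALSE)
  ids <- vapply(records, `[[`, character(1), "id")
  dup <- duplicated(ids)
  if (any(dup)) {
    for (i in which(dup))
      records[[i]]$id <- sprintf("%s_%d", records[[i]]$id, i)
  }
  attr(records, "rejections") <- data.frame(
    id = rej_id, reason = rej_reason, stringsAsFactors = FALSE)
  records
}
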