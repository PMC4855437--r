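# Reading, standardization, deduplication and the conservation invariant.

test_that("read_smiles_file parses 'SMILES name' lines and logs bad ones", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "# a comment", "CCN", "not_a_smiles x"), f)
  recs <- read_smiles_file(f)
  expect_length(recs, 2)
  expect_equal(recs[[1]]$name, "ethanol")
  expect_equal(recs[[1]]$smiles_input, "CCO")
  expect_match(recs[[2]]$name, "^mol")     # auto-assigned name
  expect_equal(vapply(recs, `[[`, integer(1), "source_index"), c(0L, 1L))
  rej <- attr(recs, "rejections")
  expect_equal(rej$reason, "parse_error")
})

test_that("read_smiles_file errors on an empty library", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(character(0), f)
  expect_error(read_smiles_file(f), "empty")
})

make_test_sdf <- function(entries) {
  # entries: list of list(name, atoms = data.frame(el,x..), bonds = matrix)
  blocks <- vapply(entries, function(e) {
    na <- nrow(e$atoms); nb <- nrow(e$bonds)
    counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb)
    atoms <- vapply(seq_len(na), function(i) sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, e$atoms$el[i]), character(1))
    bonds <- if (nb) vapply(seq_len(nb), function(i) sprintf(
      "%3d%3d%3d  0  0  0  0", e$bonds[i, 1], e$bonds[i, 2], e$bonds[i, 3]),
      character(1)) else character(0)
    paste(c(e$name, "  test", "", counts, atoms, bonds, "M  END"),
          collapse = "\n")
  }, character(1))
  paste0(paste(blocks, collapse = "\n$$$$\n"), "\n$$$$")
}

test_that("read_sdf reads V2000 blocks in order and skips corrupt ones", {
  ethanol <- list(name = "ethanol",
                  atoms = data.frame(el = c("C", "C", "O")),
                  bonds = rbind(c(1, 2, 1), c(2, 3, 1)))
  benzene <- list(name = "benzene",
                  atoms = data.frame(el = rep("C", 6)),
                  bonds = cbind(1:6, c(2:6, 1), rep(4, 6)))  # aromatic bonds
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(make_test_sdf(list(ethanol, benzene)), f)
  recs <- read_sdf(f)
  expect_length(recs, 2)
  expect_equal(vapply(recs, `[[`, character(1), "id"), c("ethanol", "benzene"))
  expect_equal(vapply(recs, `[[`, integer(1), "source_index"), c(0L, 1L))
  std <- standardize_library(recs)
  expect_equal(vapply(std, `[[`, character(1), "canonical_smiles"),
               c("CCO", "c1ccccc1"))

  # corrupt middle block: skipped and logged, not fatal
  txt <- make_test_sdf(list(ethanol, benzene))
  broken <- sub("  6  6  0", "  9  6  0", txt, fixed = TRUE)
  writeLines(broken, f)
  recs2 <- read_sdf(f)
  expect_length(recs2, 1)
  expect_equal(attr(recs2, "rejections")$reason, "parse_error")

  # empty file is an error
  writeLines("", f)
  expect_error(read_sdf(f), "empty library")
})

test_that("standardize strips salts, charges at pH 7.4 and caps size", {
  m <- std1("CC(=O)O.[Na+]")
  expect_s3_class(m, "std_mol")
  expect_equal(m$hac, 4L)
  # kept fragment is the deprotonated acetate
  expect_identical(m$canonical_smiles, std1("CC(=O)[O-]")$canonical_smiles)

  expect_identical(std1("CCO")$canonical_smiles, "CCO")  # no rule fires

  r <- std1(make_alkane(51))
  expect_s3_class(r, "mol_rejection")
  expect_equal(r$reason, "too_large")
  expect_equal(std1(make_alkane(50))$hac, 50L)

  expect_equal(std1("C(C)(C)(C)(C)C")$reason, "valence_error")
})

test_that("pH 7.4 rules hit the documented groups and nothing else", {
  can <- function(s) std1(s)$canonical_smiles
  expect_identical(can("CCN"), can("CC[NH3+]"))            # amine protonated
  expect_identical(can("Nc1ccccc1"), can("Nc1ccccc1"))     # aniline untouched
  expect_false(grepl("\\+", can("Nc1ccccc1")))
  expect_false(grepl("\\+", can("CC(=O)NC")))              # amide untouched
  expect_match(can("NC(=N)N"), "\\+")                      # guanidinium
  expect_match(can("OS(=O)(=O)C"), "O-", fixed = TRUE)     # sulfonate
  expect_match(can("OP(=O)(O)OC"), "O-", fixed = TRUE)     # phosphate -1
  # exactly one proton comes off the phosphate
  expect_equal(sum(S("OP(=O)(O)OC")$atoms$charge),
               sum(std1("OP(=O)(O)OC")$graph$atoms$charge) + 1L)
  expect_match(can("c1nnn[nH]1"), "n-", fixed = TRUE)      # tetrazolate
  expect_false(grepl("\\+", can("c1ccncc1")))              # pyridine N free
})

test_that("standardization is idempotent on the canonical form", {
  for (smi in c("CCO", "CC(=O)O.[Na+]", "CCN", "NC(=N)N", "c1nnn[nH]1",
                "OS(=O)(=O)c1ccccc1")) {
    first <- std1(smi)
    again <- std1(first$canonical_smiles)
    expect_identical(again$canonical_smiles, first$canonical_smiles,
                     label = smi)
  }
})

test_that("salt stripping keeps the largest fragment with the tie chain", {
  expect_equal(std1("CCN.Cl")$hac, 3L)                  # larger fragment
  # heavy-atom tie broken by molecular mass: CCO (46) vs CCN (45)
  expect_identical(std1("CCO.CCN")$canonical_smiles, "CCO")
  # full tie: lexicographically smallest canonical SMILES survives
  expect_identical(std1("CCC.CCC")$canonical_smiles, "CCC")
})

test_that("deduplicate keeps first occurrences in order", {
  recs <- parse_lines(c("CCO a", "OCC b", "CCN c"))
  lib <- standardize_library(recs)
  expect_length(lib, 2)
  expect_equal(vapply(lib, function(m) m$record$id, character(1)),
               c("a", "c"))
  rej <- attr(lib, "rejections")
  expect_equal(rej$id, "b")
  expect_equal(rej$reason, "duplicate")

  # all distinct: identity
  lib2 <- standardize_library(parse_lines(c("CCO a", "CCN b", "CCC c")))
  expect_length(lib2, 3)

  # counting: 2 kept, 1 duplicate
  dd <- deduplicate_mols(lapply(parse_lines(c("CCO a", "CCO b", "CCN c")),
                                standardize_mol))
  expect_length(dd$kept, 2)
  expect_equal(nrow(dd$duplicates), 1)
})

test_that("conservation: |input| = |output| + |rejections|", {
  lines <- make_library(40, seed = 5, duplicates = 2, salts = 1, oversized = 1)
  lines <- c(lines, "xx#bad bad1")  # one parse error on top
  recs <- parse_lines(lines)
  lib <- standardize_library(recs)
  expect_equal(length(lines), length(lib) + nrow(attr(lib, "rejections")))
  expect_true(all(attr(lib, "rejections")$reason %in%
                    c("parse_error", "valence_error", "too_large",
                      "duplicate", "empty_after_saltstrip")))
  # order stability: surviving ids keep input relative order
  ids <- vapply(lib, function(m) m$record$id, character(1))
  src <- vapply(lib, function(m) m$record$source_index, integer(1))
  expect_false(is.unsorted(src))
})
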