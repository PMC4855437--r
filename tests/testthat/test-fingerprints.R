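# The five fingerprints: dimensionality, hand-enumerated oracles, invariants
# and the two metrics.

test_that("fingerprint dimensionality is 42/34/20/55/1024 by kind", {
  m <- std1("CC(=O)Nc1ccccc1")
  expect_length(fp_mqn(m), 42)
  expect_length(fp_smifp(m), 34)
  expect_length(fp_apfp(m), 20)
  expect_length(fp_xfp(m), 55)
  expect_length(fp_sfp(m), 1024)
})

test_that("MQN matches manual enumeration on methane, benzene, ethanol", {
  v <- fp_mqn(S("C"))
  expect_equal(unname(v[c("c", "hac")]), c(1L, 1L))
  expect_equal(sum(v), 2L)  # every other component zero

  v <- fp_mqn(S("c1ccccc1"))
  expect_equal(unname(v[c("c", "hac", "r6", "csb", "cdb", "rbc", "cdv")]),
               c(6L, 6L, 1L, 3L, 3L, 0L, 6L))
  expect_equal(sum(v), 6L + 6L + 1L + 3L + 3L + 6L)

  v <- fp_mqn(S("CCO"))
  expect_equal(unname(v[c("c", "ao", "hac", "asb", "hbd", "hbds", "hba",
                          "amv", "adv")]),
               c(2L, 1L, 3L, 2L, 1L, 1L, 1L, 2L, 1L))
})

test_that("MQN counts rings, fused atoms/bonds and rotatable bonds", {
  v <- fp_mqn(S("c1ccc2ccccc2c1"))       # naphthalene
  expect_equal(unname(v["r6"]), 2L)
  expect_equal(unname(v["afr"]), 2L)      # two fusion atoms
  expect_equal(unname(v["bfr"]), 1L)      # one shared bond
  expect_equal(unname(fp_mqn(S("CCCC"))["rbc"]), 1L)
  expect_equal(unname(fp_mqn(S("CC(=O)NC"))["rbc"]), 0L)  # amide C-N excluded
  expect_equal(unname(fp_mqn(S("C1CC1C2CC2"))["rbc"]), 1L)
})

test_that("SMIfp counts the pinned 34-symbol alphabet on canonical SMILES", {
  v <- fp_smifp("CCO")
  expect_equal(unname(v["C"]), 2L)
  expect_equal(unname(v["O"]), 1L)
  expect_equal(sum(v), 3L)

  v <- fp_smifp("C1CC1")
  expect_equal(unname(v["C"]), 3L)
  expect_equal(unname(v["1"]), 2L)

  v <- fp_smifp("ClCCl")
  expect_equal(unname(v["Cl"]), 2L)
  expect_equal(unname(v["C"]), 1L)  # no spurious C from Cl

  # recomputed canonical form, not the input string: same counts either way
  expect_equal(as.numeric(fp_smifp("OCC")), as.numeric(fp_smifp("CCO")))
  # aromatic lowercase symbols counted separately
  v <- fp_smifp("c1ccccc1")
  expect_equal(unname(v["c"]), 6L)
  expect_equal(unname(v["C"]), 0L)
})

test_that("APfp matches manual enumeration and drops distances > 20", {
  expect_equal(as.numeric(fp_apfp(S("CC"))), c(0.5, rep(0, 19)))
  expect_equal(as.numeric(fp_apfp(S("CCC"))), c(2 / 3, 1 / 3, rep(0, 18)))
  expect_equal(as.numeric(fp_apfp(S("C"))), rep(0, 20))
  v <- fp_apfp(S(make_alkane(25)))        # longest distance 24: dropped
  expect_equal(unname(v[20]), 5 / 25)
  expect_equal(sum(as.numeric(v) * 25), sum(vapply(1:20, function(d) 25 - d,
                                                   numeric(1))))
})

test_that("atom categories follow the stated rules", {
  cats <- assign_categories(S("CO"))      # methanol
  expect_false(cats$hydrophobic[1])       # C bonded to O
  expect_true(cats$hbd[2] && cats$hba[2])

  cats <- assign_categories(S("c1ccccc1"))
  expect_true(all(cats$hydrophobic) && all(cats$sp2))

  cats <- assign_categories(S("CC(N)=O")) # acetamide
  el <- S("CC(N)=O")$atoms$element
  expect_true(cats$hba[el == "O"])
  expect_true(cats$hbd[el == "N"])
  expect_false(cats$hba[el == "N"])       # amide N not an acceptor

  cats <- assign_categories(S("c1cc[nH]c1"))
  n_at <- S("c1cc[nH]c1")$atoms$element == "N"
  expect_false(cats$hba[n_at])            # pyrrole N not an acceptor
  expect_true(cats$hbd[n_at])
  cats <- assign_categories(S("c1ccncc1"))
  n_at <- S("c1ccncc1")$atoms$element == "N"
  expect_true(cats$hba[n_at])             # pyridine N accepts
})

test_that("Xfp matches manual enumeration on the spec molecules", {
  nm <- function(v) stats::setNames(as.numeric(v), names(v))
  v <- nm(fp_xfp(S("CO")))
  expect_equal(unname(v["hbd_d0"]), 1)
  expect_equal(sum(v[paste0("hbd_d", 1:10)]), 0)

  v <- nm(fp_xfp(S("NCCO")))              # ethanolamine: donors N,O at d3
  expect_equal(unname(v["hbd_d0"]), 1)
  expect_equal(unname(v["hbd_d3"]), 0.5)

  v <- nm(fp_xfp(S(make_alkane(6))))      # alkane: only hydrophobic block
  expect_equal(unname(v["hydrophobic_d0"]), 1)
  expect_equal(sum(v[grep("hbd|hba|cross", names(v))]), 0)
})

test_that("Xfp same-category d0 components are always 0 or 1", {
  lib <- tiny_library()
  for (m in lib[seq_len(min(30, length(lib)))]) {
    v <- fp_xfp(m)
    d0 <- as.numeric(v[paste0(c("hydrophobic", "hbd", "hba", "sp2"), "_d0")])
    expect_true(all(d0 %in% c(0, 1)))
  }
})

test_that("APfp/Xfp equal the independent brute-force oracle (<=10 HAC)", {
  lib <- tiny_library()
  small <- Filter(function(m) m$hac <= 10, lib)
  expect_gte(length(small), 10)
  for (m in small) {
    expect_equal(as.numeric(fp_apfp(m)), oracle_apfp(m$graph),
                 tolerance = 1e-12, label = m$canonical_smiles)
    expect_equal(as.numeric(fp_xfp(m)),
                 oracle_xfp(m$graph, assign_categories(m)),
                 tolerance = 1e-12, label = m$canonical_smiles)
  }
})

test_that("APfp mass balance bounds the pair count", {
  lib <- tiny_library()
  for (m in lib[seq_len(min(40, length(lib)))]) {
    tot <- sum(as.numeric(fp_apfp(m))) * m$hac
    expect_lte(tot, m$hac * (m$hac - 1) / 2 + 1e-9)
  }
})

test_that("Sfp is deterministic, bounded and path-sensitive", {
  expect_identical(as.integer(fp_sfp(S("CC(=O)Nc1ccccc1"))),
                   as.integer(fp_sfp(S("CC(=O)Nc1ccccc1"))))
  v <- fp_sfp(S("C"))
  expect_gte(sum(v), 1)
  expect_true(all(as.integer(v) %in% c(0L, 1L)))
  tb <- tanimoto(fp_sfp(S("c1ccccc1")), fp_sfp(S("Cc1ccccc1")))
  expect_gt(tb, 0)   # shared ring paths
  expect_lt(tb, 1)   # toluene has paths benzene lacks
})

test_that("fingerprints are invariant under input atom order", {
  withr::local_seed(99)
  for (s in c("CC(=O)Nc1ccccc1", "OC(=O)c1ccc(N)cc1", "C1CCC2CCCCC2C1",
              "NCCO")) {
    raw <- parse_smiles(s)
    ref <- lapply(c("mqn", "apfp", "xfp", "sfp"), function(k)
      as.numeric(fingerprint(sanitize_mol(raw), k)))
    for (r in 1:3) {
      g <- sanitize_mol(chemspace3d:::permute_molgraph(raw,
                                                       sample(nrow(raw$atoms))))
      got <- lapply(c("mqn", "apfp", "xfp", "sfp"), function(k)
        as.numeric(fingerprint(g, k)))
      expect_equal(got, ref, label = sprintf("%s / perm %d", s, r))
    }
  }
})

test_that("city-block distance and Tanimoto behave as metrics", {
  u <- chemspace3d:::new_fp(c(1, 2, rep(0, 18)), "apfp")
  v <- chemspace3d:::new_fp(c(3, 0, rep(0, 18)), "apfp")
  expect_equal(cbd(u, v), 4)
  expect_equal(cbd(u, u), 0)
  withr::local_seed(1)
  for (r in 1:5) {
    a <- chemspace3d:::new_fp(rpois(42, 3), "mqn")
    b <- chemspace3d:::new_fp(rpois(42, 3), "mqn")
    expect_equal(cbd(a, b), cbd(b, a))
    expect_gte(cbd(a, b), 0)
  }
  mk <- function(bits) chemspace3d:::new_fp(
    as.integer(seq_len(1024) %in% bits), "sfp")
  expect_equal(tanimoto(mk(1:2), mk(1:2)), 1)
  expect_equal(tanimoto(mk(1:2), mk(3:4)), 0)
  expect_equal(tanimoto(mk(c(1, 2)), mk(c(1, 3))), 1 / 3)
  expect_equal(tanimoto(mk(integer(0)), mk(integer(0))), 1)
  expect_error(cbd(u, mk(1:2)), "mismatch")
  expect_error(tanimoto(u, u), "sfp")
})
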