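# Shared helpers: quick constructors and an independent brute-force oracle
# for topological distances / atom-pair fingerprints (Floyd-Warshall over the
# bond list, written without the package's igraph-based path).

S <- function(smi) sanitize_mol(parse_smiles(smi))

std1 <- function(smi, name = "x", max_hac = 50L) {
  standardize_mol(parse_lines(paste(smi, name))[[1]], max_hac = max_hac)
}

# independent all-pairs shortest path (Floyd-Warshall)
oracle_distances <- function(mol) {
  n <- nrow(mol$atoms)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$a1[b]; j <- mol$bonds$a2[b]
    d[i, j] <- 1; d[j, i] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# brute-force APfp: enumerate every unordered pair, tabulate distances
oracle_apfp <- function(mol) {
  n <- nrow(mol$atoms)
  d <- oracle_distances(mol)
  v <- numeric(20)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dd <- d[i, j]
      if (is.finite(dd) && dd >= 1 && dd <= 20) v[dd] <- v[dd] + 1
    }
  }
  v / n
}

# brute-force Xfp from category flags (same flags, independent pair walk)
oracle_xfp <- function(mol, cats) {
  d <- oracle_distances(mol)
  n <- nrow(mol$atoms)
  v <- numeric(55)
  blk <- 0
  for (b in c("hydrophobic", "hbd", "hba", "sp2")) {
    atoms <- which(cats[[b]])
    m <- length(atoms)
    if (m) {
      comp <- numeric(11)
      comp[1] <- m
      if (m >= 2) {
        for (x in seq_len(m - 1)) for (y in (x + 1):m) {
          dd <- d[atoms[x], atoms[y]]
          if (is.finite(dd) && dd >= 1 && dd <= 10) comp[dd + 1] <- comp[dd + 1] + 1
        }
      }
      v[blk + 1:11] <- comp / m
    }
    blk <- blk + 11
  }
  hba <- which(cats$hba); hbd <- which(cats$hbd)
  uni <- union(hba, hbd)
  if (length(uni)) {
    comp <- numeric(11)
    comp[1] <- length(intersect(hba, hbd))
    if (n >= 2) {
      for (x in seq_len(n - 1)) for (y in (x + 1):n) {
        cross <- (cats$hba[x] && cats$hbd[y]) || (cats$hba[y] && cats$hbd[x])
        if (!cross) next
        dd <- d[x, y]
        if (is.finite(dd) && dd >= 1 && dd <= 10) comp[dd + 1] <- comp[dd + 1] + 1
      }
    }
    v[blk + 1:11] <- comp / length(uni)
  }
  v
}

# small shared standardized library (built once per test run)
tiny_library <- local({
  cache <- NULL
  function(n = 60, seed = 11, ...) {
    if (is.null(cache))
      cache <<- standardize_library(parse_lines(make_library(n, seed = seed, ...)))
    cache
  }
})
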