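# 3D binning of PC coordinates onto a 300^3 grid with a single global bin
# size, occupancy/resolution statistics, and HSL property color coding.
#
# The grid range is global over all axes (pc_min/pc_max taken over the
# pooled PC-1..PC-3 values), with bin size (pc_max - pc_min)/n_bins shared
# by the three axes; values at pc_max map to the top index (closed edge).

cell_key <- function(idx) apply(idx, 1, paste, collapse = ",")

bin_axis <- function(v, pc_min, bin_size, n_bins) {
  if (bin_size == 0) return(rep(0L, length(v)))
  i <- floor((v - pc_min) / bin_size)
  as.integer(pmin(pmax(i, 0), n_bins - 1L))
}

#' Bin 3D PC coordinates onto a cubic grid
#'
#' The global minimum and maximum over all three coordinate columns define
#' the value range; the bin size is that range divided by `n_bins` and is
#' identical on the three axes. A molecule sitting exactly at the maximum is
#' assigned the top index `n_bins - 1` (closed top edge).
#'
#' @param coords n x 3 matrix of PC scores.
#' @param n_bins bins per axis (default 300).
#' @return an object of class `grid3d`: list with `n_bins`, `pc_min`,
#'   `pc_max`, `bin_size`, `cell_index` (n x 3 integer matrix) and `cells`
#'   (named list mapping `"i,j,k"` to member molecule indices).
#' @export
build_grid <- function(coords, n_bins = 300L) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) >= 1)
  if (n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
  pc_min <- min(coords); pc_max <- max(coords)
  bin_size <- (pc_max - pc_min) / n_bins
  idx <- vapply(1:3, function(j)
    bin_axis(coords[, j], pc_min, bin_size, n_bins),
    integer(nrow(coords)))
  if (nrow(coords) == 1) idx <- matrix(idx, nrow = 1)
  keys <- cell_key(idx)
  cells <- split(seq_len(nrow(coords)), keys)
  structure(list(n_bins = as.integer(n_bins), pc_min = pc_min,
                 pc_max = pc_max, bin_size = bin_size,
                 cell_index = idx, cells = cells),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("<grid3d: %d^3 bins, %d occupied cells, %d molecules>\n",
              x$n_bins, length(x$cells), nrow(x$cell_index)))
  invisible(x)
}

#' Fraction of molecules in singly-occupied 3D grid cells
#'
#' @param grid a `grid3d`.
#' @return fraction in `[0, 1]`.
#' @export
occupancy_stats <- function(grid) {
  stopifnot(inherits(grid, "grid3d"))
  n <- nrow(grid$cell_index)
  if (n == 0) stop("empty grid", call. = FALSE)
  singles <- sum(lengths(grid$cells) == 1L)
  singles / n
}

#' Fraction of molecules with a unique fingerprint value combination
#'
#' A "bin" in the original fingerprint space is one exact fingerprint value
#' combination; this returns the fraction of molecules whose combination
#' occurs exactly once in the library.
#'
#' @param fps fingerprint matrix (rows = molecules) or list of `fp_vector`s
#'   of uniform kind.
#' @return fraction in `[0, 1]`.
#' @export
unique_fp_fraction <- function(fps) {
  if (is.list(fps) && !is.matrix(fps)) {
    kinds <- unique(vapply(fps, fp_kind, character(1)))
    if (length(kinds) != 1) stop("mixed fingerprint kinds", call. = FALSE)
    fps <- do.call(rbind, lapply(fps, as.numeric))
  }
  fps <- as.matrix(fps)
  if (nrow(fps) == 0) stop("empty fingerprint list", call. = FALSE)
  keys <- apply(fps, 1, paste, collapse = "|")
  tab <- table(keys)
  sum(tab[keys] == 1) / nrow(fps)
}

#' Fraction of molecules in singly-occupied 2D pixels
#'
#' Same single-occupancy statistic on a 2D map built with the same
#' global-range rule (pooled PC-1/PC-2 range, square pixels).
#'
#' @param coords n x 2 matrix of PC scores.
#' @param n_bins pixels per axis (default 300).
#' @return fraction in `[0, 1]`.
#' @export
pixel_stats_2d <- function(coords, n_bins = 300L) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, nrow(coords) >= 1)
  if (n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
  pc_min <- min(coords); pc_max <- max(coords)
  bin_size <- (pc_max - pc_min) / n_bins
  idx <- vapply(1:2, function(j)
    bin_axis(coords[, j], pc_min, bin_size, n_bins),
    integer(nrow(coords)))
  if (nrow(coords) == 1) idx <- matrix(idx, nrow = 1)
  keys <- apply(idx, 1, paste, collapse = ",")
  tab <- table(keys)
  sum(tab[keys] == 1) / nrow(coords)
}

# ---------------------------------------------------------------------------
# Display properties (PropertyTable)

#' Display descriptors for color coding
#'
#' Per molecule: SSSR ring count, aromatic carbon count, rotatable bond
#' count, fraction of aromatic heavy atoms, H-bond acceptor count, heavy
#' atom count and the number of N-C=C substructure matches (nitrogen single-
#' bonded to a carbon that is double-bonded to another carbon; aromatic
#' bonds match both roles).
#'
#' @param mols list of `std_mol`.
#' @return data.frame with columns `ringcount`, `aromatic_c`, `rotatable`,
#'   `frac_aromatic`, `hba_count`, `hac`, `ncc_count`; one row per molecule,
#'   rownames = molecule ids.
#' @export
compute_properties <- function(mols) {
  one <- function(m) {
    g <- m$graph
    el <- g$atoms$element
    arom <- g$atoms$arom
    rings <- get_sssr(g)
    pf <- polar_flags(g)
    c(ringcount = length(rings),
      aromatic_c = sum(el == "C" & arom),
      rotatable = sum(rotatable_bonds(g)),
      frac_aromatic = sum(arom) / nrow(g$atoms),
      hba_count = sum(pf$hba),
      hac = nrow(g$atoms),
      ncc_count = count_ncc(g))
  }
  tab <- as.data.frame(t(vapply(mols, one, numeric(7))))
  rownames(tab) <- vapply(mols, function(m) m$record$id, character(1))
  tab
}

# N-C=C pattern: N bonded (single or aromatic) to C double- or aromatic-
# bonded to another C; each distinct (N, C, C) atom triple counts once.
count_ncc <- function(g) {
  el <- g$atoms$element
  if (!nrow(g$bonds)) return(0L)
  adj <- adjacency_list(g)
  bmap <- bond_index_map(g)
  bond_row <- function(a, b) g$bonds[bmap[[paste(min(a, b), max(a, b), sep = "-")]], ]
  cnt <- 0L
  for (n_at in which(el == "N")) {
    for (c1 in adj[[n_at]]) {
      if (el[c1] != "C") next
      b1 <- bond_row(n_at, c1)
      if (!(b1$order == 1L || b1$arom)) next
      for (c2 in adj[[c1]]) {
        if (c2 == n_at || el[c2] != "C") next
        b2 <- bond_row(c1, c2)
        if (b2$order == 2L || b2$arom) cnt <- cnt + 1L
      }
    }
  }
  cnt
}

# ---------------------------------------------------------------------------
# HSL color coding

# standard HSL -> RGB (h degrees, s/l in [0,1]); returns integer 0..255
hsl_to_rgb <- function(h, s, l) {
  h <- ((h %% 360) + 360) %% 360
  c_ <- (1 - abs(2 * l - 1)) * s
  x <- c_ * (1 - abs((h / 60) %% 2 - 1))
  m <- l - c_ / 2
  sextant <- floor(h / 60)
  rgb1 <- switch(as.character(sextant),
                 "0" = c(c_, x, 0), "1" = c(x, c_, 0), "2" = c(0, c_, x),
                 "3" = c(0, x, c_), "4" = c(x, 0, c_), "5" = c(c_, 0, x),
                 c(c_, x, 0))
  as.integer(round((rgb1 + m) * 255))
}

#' Color grid cells by a molecular property
#'
#' Hue encodes the cell-mean property along the blue (240 degrees) to
#' magenta (300 degrees, i.e. -60) ramp, linear in the min-max-normalized
#' mean over occupied cells. Saturation encodes the local spread: 1 minus
#' the ratio of the population standard deviation of the property over all
#' molecules within `radius` grid cells in each direction (Chebyshev
#' neighborhood, borders truncated) to the global population standard
#' deviation, floored at 0. Lightness is fixed at 0.5.
#'
#' @param grid a `grid3d`.
#' @param props data.frame from [compute_properties()] (rows follow the
#'   molecule order used to build the grid).
#' @param descriptor column name in `props`.
#' @param radius neighborhood half-width in cells (default 5).
#' @return data.frame with columns i, j, k, n_members, mean_property,
#'   local_std, hue, saturation, lightness, r, g, b.
#' @export
color_cells <- function(grid, props, descriptor, radius = 5L) {
  stopifnot(inherits(grid, "grid3d"))
  if (!descriptor %in% colnames(props))
    stop("unknown descriptor: ", descriptor, call. = FALSE)
  vals <- props[[descriptor]]
  n <- nrow(grid$cell_index)
  stopifnot(length(vals) == n)

  keys <- names(grid$cells)
  idx <- do.call(rbind, lapply(strsplit(keys, ","), as.integer))
  means <- vapply(grid$cells, function(m) mean(vals[m]), numeric(1))

  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  gsd <- pop_sd(vals)
  ci <- grid$cell_index
  local_std <- vapply(seq_along(keys), function(c0) {
    sel <- abs(ci[, 1] - idx[c0, 1]) <= radius &
      abs(ci[, 2] - idx[c0, 2]) <= radius &
      abs(ci[, 3] - idx[c0, 3]) <= radius
    pop_sd(vals[sel])
  }, numeric(1))

  rng <- range(means)
  t_ <- if (diff(rng) == 0) rep(0, length(means)) else
    (means - rng[1]) / diff(rng)
  hue <- 240 - 300 * t_
  sat <- if (gsd == 0) rep(1, length(means)) else
    1 - pmin(1, local_std / gsd)
  rgb <- t(vapply(seq_along(hue), function(i)
    hsl_to_rgb(hue[i], sat[i], 0.5), integer(3)))

  data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
             n_members = unname(lengths(grid$cells)),
             mean_property = unname(means), local_std = unname(local_std),
             hue = unname(hue), saturation = unname(sat), lightness = 0.5,
             r = rgb[, 1], g = rgb[, 2], b = rgb[, 3],
             row.names = NULL)
}
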