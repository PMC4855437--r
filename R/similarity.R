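# Exact nearest-neighbor search in the original high-dimensional fingerprint
# spaces: full scan with city-block distance for the scalar kinds and
# Tanimoto similarity for Sfp, ties broken by library order (stable sort).

#' Nearest neighbors of a query fingerprint
#'
#' Scans the whole library (no approximate index): scalar fingerprints are
#' ranked by ascending city-block distance, Sfp by descending Tanimoto
#' similarity; ties keep library insertion order.
#'
#' @param query an `fp_vector`, or a numeric vector when `library_fps` is a
#'   plain matrix.
#' @param library_fps fingerprint matrix (rows = molecules, attribute `kind`
#'   as produced by [fingerprint_matrix()]) or list of `fp_vector`s.
#' @param k number of neighbors to return; capped at the library size.
#' @return object of class `neighbor_list`: data.frame with columns `rank`,
#'   `id`, `score` plus attributes `metric` and `query_kind`.
#' @export
nearest_neighbors <- function(query, library_fps, k = 10L) {
  if (is.list(library_fps) && !is.matrix(library_fps)) {
    kinds <- unique(vapply(library_fps, fp_kind, character(1)))
    if (length(kinds) != 1) stop("mixed fingerprint kinds", call. = FALSE)
    m <- do.call(rbind, lapply(library_fps, as.numeric))
    attr(m, "kind") <- kinds
    library_fps <- m
  }
  kind <- attr(library_fps, "kind")
  qkind <- fp_kind(query)
  if (!is.null(qkind) && !is.null(kind) && qkind != kind)
    stop("fingerprint kind mismatch: query is ", qkind, ", library is ", kind,
         call. = FALSE)
  if (is.null(kind)) kind <- qkind
  if (is.null(kind)) stop("fingerprint kind unknown", call. = FALSE)
  n <- nrow(library_fps)
  if (n == 0) stop("empty library", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  q <- as.numeric(query)
  if (length(q) != ncol(library_fps))
    stop("query length does not match library fingerprint length",
         call. = FALSE)
  if (kind == "sfp") {
    qb <- q > 0
    lb <- library_fps > 0
    inter <- as.numeric(lb %*% qb)
    uni <- sum(qb) + rowSums(lb) - inter
    score <- ifelse(uni == 0, 1, inter / uni)
    ord <- order(-score, seq_len(n))  # stable: ties by library order
    metric <- "tanimoto"
  } else {
    score <- as.numeric(abs(sweep(library_fps, 2, q)) %*% rep(1, length(q)))
    ord <- order(score, seq_len(n))
    metric <- "cbd"
  }
  k <- min(k, n)
  take <- ord[seq_len(k)]
  ids <- rownames(library_fps)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  out <- data.frame(rank = seq_len(k), id = ids[take],
                    index = take, score = score[take],
                    stringsAsFactors = FALSE)
  structure(out, metric = metric, query_kind = kind,
            class = c("neighbor_list", "data.frame"))
}
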