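#' Detect all alpha-clusters of an index
#'
#' An alpha-cluster is a maximal block `(pS, pE)` of eBWT positions whose
#' associated suffixes pairwise share a prefix of length at least `alpha`
#' (`lcp[i] >= alpha` for `pS < i <= pE`, with `lcp[pS] < alpha` and
#' `lcp[pE+1] < alpha`) and that contains symbols of at least one read and
#' at least one genome. Blocks whose colors fall entirely on one side are
#' discarded. Detection is a single sequential scan of the LCP and document
#' arrays (vectorized as a run-length pass).
#'
#' @param index An `ebwt_index` with `r >= 1` reads and `g >= 1` genomes.
#' @param alpha Positive integer: minimum shared-context length.
#' @return A data.frame with columns `pS`, `pE`, `size`, ordered by
#'   increasing `pS`; zero rows if no cluster exists.
#' @examples
#' ex <- running_example()
#' detect_alpha_clusters(build_ebwt_index(ex$collection), alpha = 2)
#' @export
detect_alpha_clusters <- function(index, alpha) {
  stopifnot(inherits(index, "ebwt_index"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 1 || alpha != floor(alpha)) {
    stop("alpha must be a positive integer")
  }
  alpha <- as.integer(alpha)
  r <- index$meta$r
  if (r < 1L || index$meta$g < 1L) stop("index must contain at least one read and one genome")
  read_len_max <- max(index$meta$lengths[seq_len(r)])
  if (alpha >= read_len_max) {
    warning(sprintf(
      "alpha = %d is not smaller than the maximum read length (%d); clusters cannot cover whole-read contexts",
      alpha, read_len_max))
  }
  N <- index$meta$N
  empty <- structure(data.frame(pS = integer(0), pE = integer(0), size = integer(0)),
                     alpha = alpha)
  if (N < 2L) return(empty)
  # v[t] is TRUE when suffixes t and t+1 share >= alpha symbols; a maximal
  # TRUE-run t1..t2 is the candidate block (pS = t1, pE = t2 + 1)
  v <- index$lcp[2:N] >= alpha
  rl <- rle(v)
  if (!any(rl$values)) return(empty)
  run_end <- cumsum(rl$lengths)
  run_start <- run_end - rl$lengths + 1L
  pS <- run_start[rl$values]
  pE <- run_end[rl$values] + 1L
  # mixed-color condition via cumulative read counts
  is_read <- cumsum(c(0L, as.integer(index$da <= r)))
  nread <- is_read[pE + 1L] - is_read[pS]
  size <- pE - pS + 1L
  keep <- nread > 0L & nread < size
  structure(data.frame(pS = pS[keep], pE = pE[keep], size = size[keep]),
            alpha = alpha)
}

#' Per-sequence, per-symbol counts of one cluster
#'
#' Tallies the eBWT block `pS..pE` by (color, symbol). End-marker symbols
#' are counted under the reserved symbol `"$"`: they participate in the
#' exact symbol-matching phase as one shared symbol, but carry no IUPAC code
#' set, so they never enter the ambiguity-matching phase.
#'
#' @param index An `ebwt_index`.
#' @param pS,pE 1-based inclusive cluster bounds (or a one-row cluster
#'   data.frame as `pS`, in which case `pE` is taken from it).
#' @return An object of class `cluster_profile`: integer matrix with one row
#'   per color present and one column per symbol, plus attributes `pS`,
#'   `pE`, `totals` (named per-color totals).
#' @export
profile_cluster <- function(index, pS, pE = NULL) {
  stopifnot(inherits(index, "ebwt_index"))
  if (is.data.frame(pS)) {
    stopifnot(nrow(pS) == 1L)
    pE <- pS$pE; pS <- pS$pS
  }
  N <- index$meta$N
  if (pS < 1L || pE > N || pS > pE) stop(sprintf("cluster (%d,%d) out of range [1,%d]", pS, pE, N))
  pos <- pS:pE
  cols <- sort(unique(index$da[pos]))
  syms <- c(ALPHABET_SORTED, END_MARKER)
  counts <- table(factor(index$da[pos], levels = cols),
                  factor(index$ebwt[pos], levels = syms))
  mat <- matrix(as.integer(counts), nrow = length(cols), ncol = length(syms),
                dimnames = list(color = as.character(cols), symbol = syms))
  structure(mat, class = c("cluster_profile", "matrix"),
            pS = pS, pE = pE, r = index$meta$r,
            totals = setNames(rowSums(mat), rownames(mat)))
}
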