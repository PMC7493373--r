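#' @importFrom data.table data.table :=
NULL

#' Maximum IUPAC ambiguity matching between residual symbol counts
#'
#' After the exact per-symbol minimum matching of a cluster has been
#' removed, the leftover symbols on the read side and the genome side may
#' still pair up through the degenerate-base codes: symbols `x` and `y` are
#' compatible iff one of them is an ambiguity code and the other is a
#' concrete base in its code set. (A code matches itself only through the
#' exact phase; two different codes are never compatible; end markers carry
#' no code set.) The value returned is the size of a maximum one-to-one
#' pairing between the two residual multisets, computed as an integer
#' max-flow on the small symbol-type bipartite graph, which is
#' order-independent and deterministic.
#'
#' Because edges only ever connect a code with a concrete base, the matching
#' decomposes into two independent transportation problems (read codes vs
#' genome bases, and genome codes vs read bases), each solved exactly.
#'
#' @param read_counts,genome_counts Named non-negative integer vectors of
#'   residual symbol counts (names are symbols).
#' @return Non-negative integer: the maximum number of pairings.
#' @examples
#' delta_iupac(c(R = 1), c(G = 1))          # 1: G is in bases(R)
#' delta_iupac(c(R = 2), c(A = 1, C = 1))   # 1: only A is in bases(R)
#' @export
delta_iupac <- function(read_counts, genome_counts) {
  if (any(read_counts < 0) || any(genome_counts < 0)) stop("negative residual counts")
  read_counts <- read_counts[read_counts > 0]
  genome_counts <- genome_counts[genome_counts > 0]
  if (!length(read_counts) || !length(genome_counts)) return(0L)
  pick <- function(x, set) x[names(x) %in% set]
  concrete <- c("A", "C", "G", "T")
  flow_codes_to_bases(pick(read_counts, AMBIGUITY_CODES), pick(genome_counts, concrete)) +
    flow_codes_to_bases(pick(genome_counts, AMBIGUITY_CODES), pick(read_counts, concrete))
}

# Exact max flow between ambiguity-code counts and concrete-base counts
# (code -> base edge iff the base is in the code's set). BFS augmenting
# paths with bottleneck augmentation on a graph of at most 11 x 4 types.
flow_codes_to_bases <- function(code_counts, base_counts) {
  if (!length(code_counts) || !length(base_counts)) return(0L)
  codes <- names(code_counts); bases <- names(base_counts)
  nl <- length(codes); nr <- length(bases)
  compat <- matrix(FALSE, nl, nr)
  for (i in seq_len(nl)) compat[i, ] <- bases %in% IUPAC_BASES[[codes[i]]]
  supply <- as.integer(code_counts)
  demand <- as.integer(base_counts)
  flow <- matrix(0L, nl, nr)
  total <- 0L
  repeat {
    par_l <- integer(nl)    # 0 unseen, -1 from source, j>0 via back-edge
    par_r <- integer(nr)    # 0 unseen, i>0 via forward edge
    par_l[supply > 0L] <- -1L
    queue <- which(supply > 0L)          # left nodes; right nodes coded nl+j
    found <- 0L
    while (length(queue) && !found) {
      nxt <- integer(0)
      for (node in queue) {
        if (node <= nl) {
          for (j in which(compat[node, ] & par_r == 0L)) {
            par_r[j] <- node
            if (demand[j] > 0L) { found <- j; break }
            nxt <- c(nxt, nl + j)
          }
        } else {
          j <- node - nl
          hit <- which(flow[, j] > 0L & par_l == 0L)
          par_l[hit] <- j
          nxt <- c(nxt, hit)
        }
        if (found) break
      }
      queue <- nxt
    }
    if (!found) break
    # trace the augmenting path back to the source, find the bottleneck
    j <- found; bottleneck <- demand[j]
    fwd <- matrix(0L, 0, 2); bwd <- matrix(0L, 0, 2)
    repeat {
      i <- par_r[j]
      fwd <- rbind(fwd, c(i, j))
      if (par_l[i] == -1L) { bottleneck <- min(bottleneck, supply[i]); src <- i; break }
      j2 <- par_l[i]
      bwd <- rbind(bwd, c(i, j2))
      bottleneck <- min(bottleneck, flow[i, j2])
      j <- j2
    }
    flow[fwd] <- flow[fwd] + bottleneck
    if (nrow(bwd)) flow[bwd] <- flow[bwd] - bottleneck
    supply[src] <- supply[src] - bottleneck
    demand[found] <- demand[found] - bottleneck
    total <- total + bottleneck
  }
  total
}

profile_counts <- function(profile, color) {
  key <- as.character(color)
  if (key %in% rownames(profile)) profile[key, ] else
    setNames(integer(ncol(profile)), colnames(profile))
}

check_pair_colors <- function(profile, read_color, genome_color) {
  r <- attr(profile, "r")
  if (!is.null(r) && !(read_color <= r && genome_color > r)) {
    stop(sprintf("expected read color <= %d < genome color, got (%d, %d)",
                 r, read_color, genome_color))
  }
}

#' Symbol-matching (eBWT) similarity contribution of one cluster
#'
#' For a (read, genome) color pair, sums the exact per-symbol minima
#' `min(occ_a(i,x), occ_a(j,x))` over all symbols (end markers count as the
#' one shared symbol `$`), then adds the maximum IUPAC ambiguity matching
#' [delta_iupac()] on the residual counts.
#'
#' @param profile A `cluster_profile`.
#' @param read_color,genome_color Colors of the read and the genome.
#' @return Non-negative integer contribution.
#' @export
ebwt_cluster_similarity <- function(profile, read_color, genome_color) {
  check_pair_colors(profile, read_color, genome_color)
  ci <- profile_counts(profile, read_color)
  cj <- profile_counts(profile, genome_color)
  exact <- pmin(ci, cj)
  resid_i <- ci - exact
  resid_j <- cj - exact
  sum(exact) + delta_iupac(resid_i, resid_j)
}

#' Color-count (DA) similarity contribution of one cluster
#'
#' Ignores symbol identity entirely: the contribution is the minimum of the
#' read's and the genome's symbol totals in the cluster.
#'
#' @inheritParams ebwt_cluster_similarity
#' @return Non-negative integer contribution.
#' @export
da_cluster_similarity <- function(profile, read_color, genome_color) {
  check_pair_colors(profile, read_color, genome_color)
  min(sum(profile_counts(profile, read_color)),
      sum(profile_counts(profile, genome_color)))
}

#' Build the normalized read-by-genome similarity matrix
#'
#' Accumulates the chosen per-cluster similarity over all alpha-clusters for
#' every (read, genome) pair and normalizes by `min(n_i, n_j) + 1 - alpha`,
#' which bounds both measures, so every score lies in `[0, 1]`. Accumulation
#' is implemented as grouped aggregation over cluster symbol counts;
#' the result does not depend on cluster processing order.
#'
#' @param index An `ebwt_index`.
#' @param clusters Cluster data.frame from [detect_alpha_clusters()] (built
#'   at the same `alpha`).
#' @param measure `"ebwt"` (symbol matching + IUPAC residual matching) or
#'   `"da"` (color counts only).
#' @param alpha The minimum context length the clusters were detected at.
#' @param role Orientation label, e.g. `"F"`, `"RC"`, `"1F"`, `"2RC"`.
#' @return An object of class `similarity_matrix`: list with `values`
#'   (normalized r x g matrix), `raw` (integer accumulators), `denom`,
#'   `alpha`, `measure`, `role`, `read_ids`, `genome_ids`.
#' @export
build_similarity_matrix <- function(index, clusters, measure = c("ebwt", "da"),
                                    alpha, role = "F") {
  stopifnot(inherits(index, "ebwt_index"))
  measure <- match.arg(measure)
  alpha <- as.integer(alpha)
  cl_alpha <- attr(clusters, "alpha")
  if (!is.null(cl_alpha) && cl_alpha != alpha) {
    stop(sprintf("clusters were detected at alpha = %d, not %d", cl_alpha, alpha))
  }
  r <- index$meta$r; g <- index$meta$g
  raw <- matrix(0, r, g)
  if (nrow(clusters) > 0L) {
    pos <- sequence(clusters$size, from = clusters$pS)
    DT <- data.table::data.table(
      cl = rep.int(seq_len(nrow(clusters)), clusters$size),
      color = index$da[pos], sym = index$ebwt[pos])
    counts <- DT[, list(n = .N), by = c("cl", "color", "sym")]
    rc <- counts[counts$color <= r]
    gc_ <- counts[counts$color > r]
    if (measure == "da") {
      rt <- rc[, list(tot = sum(n)), by = c("cl", "color")]
      gt <- gc_[, list(tot = sum(n)), by = c("cl", "color")]
      J <- merge(rt, gt, by = "cl", allow.cartesian = TRUE, suffixes = c(".r", ".g"))
      J[, "v" := pmin(J$tot.r, J$tot.g)]
      agg <- J[, list(v = sum(v)), by = c("color.r", "color.g")]
      raw[cbind(agg$color.r, agg$color.g - r)] <- agg$v
    } else {
      E <- merge(rc, gc_, by = c("cl", "sym"), allow.cartesian = TRUE,
                 suffixes = c(".r", ".g"))
      if (nrow(E)) {
        E[, "v" := pmin(E$n.r, E$n.g)]
        agg <- E[, list(v = sum(v)),
                 by = c("color.r", "color.g")]
        raw[cbind(agg$color.r, agg$color.g - r)] <- agg$v
      }
      # residual IUPAC phase: only clusters containing an ambiguity code can
      # contribute beyond the exact matching
      amb_cl <- unique(counts$cl[counts$sym %in% AMBIGUITY_CODES])
      syms <- c(ALPHABET_SORTED, END_MARKER)
      for (q in amb_cl) {
        sub <- counts[counts$cl == q]
        M <- matrix(0L, length(unique(sub$color)), length(syms),
                    dimnames = list(as.character(sort(unique(sub$color))), syms))
        M[cbind(as.character(sub$color), sub$sym)] <- sub$n
        rcols <- as.integer(rownames(M)); rcols_r <- rcols[rcols <= r]
        rcols_g <- rcols[rcols > r]
        for (i in rcols_r) for (j in rcols_g) {
          ci <- M[as.character(i), ]; cj <- M[as.character(j), ]
          ex <- pmin(ci, cj)
          d <- delta_iupac(ci - ex, cj - ex)
          if (d > 0L) raw[i, j - r] <- raw[i, j - r] + d
        }
      }
    }
  }
  n_reads <- index$meta$lengths[seq_len(r)]
  n_gen <- index$meta$lengths[r + seq_len(g)]
  denom <- outer(n_reads, n_gen, pmin) + 1 - alpha
  values <- ifelse(denom > 0, raw / denom, 0)
  dimnames(values) <- dimnames(raw) <-
    list(index$meta$ids[seq_len(r)], index$meta$ids[r + seq_len(g)])
  structure(list(role = role, measure = measure, alpha = alpha,
                 values = values, raw = raw, denom = denom,
                 read_ids = index$meta$ids[seq_len(r)],
                 genome_ids = index$meta$ids[r + seq_len(g)]),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix [%s, %s, alpha=%d]: %d reads x %d genomes\n",
              x$role, x$measure, x$alpha, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write a similarity matrix as TSV
#'
#' Read ids as rows, genome ids as columns, normalized values at 6 decimal
#' places (or the raw integer accumulators).
#'
#' @param mat A `similarity_matrix`.
#' @param path Output file.
#' @param raw Write the unnormalized accumulators instead.
#' @export
write_similarity_matrix <- function(mat, path, raw = FALSE) {
  stopifnot(inherits(mat, "similarity_matrix"))
  v <- if (raw) mat$raw else round(mat$values, 6)
  df <- data.frame(read_id = mat$read_ids, v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write detected clusters as TSV (diagnostic)
#'
#' Columns: `pS`, `pE`, `size`, `n_read`, `n_genome` (symbol totals on the
#' read and genome side of each cluster).
#'
#' @param index The `ebwt_index` the clusters came from.
#' @param clusters Cluster data.frame.
#' @param path Output file.
#' @export
write_clusters <- function(index, clusters, path) {
  r <- index$meta$r
  cum_read <- cumsum(c(0L, as.integer(index$da <= r)))
  n_read <- cum_read[clusters$pE + 1L] - cum_read[clusters$pS]
  out <- data.frame(pS = clusters$pS, pE = clusters$pE, size = clusters$size,
                    n_read = n_read, n_genome = clusters$size - n_read)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
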