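# Independent brute-force oracles: suffix sorting via column-wise
# lexicographic order() on a padded code matrix, direct LCP comparison,
# loop-based cluster scan, and exhaustive-recursion IUPAC matching. Kept
# deliberately separate from the package's prefix-doubling / aggregation
# implementations.

ORACLE_ALPHA <- sort(c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                       "B", "D", "H", "V", "N"))

ORACLE_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
ORACLE_AMB <- setdiff(names(ORACLE_CODES), c("A", "C", "G", "T"))

# Full index by explicit suffix enumeration. seqs: named character vector.
oracle_index <- function(seqs) {
  m <- length(seqs)
  codes <- lapply(seqs, function(s) {
    match(strsplit(s, "", fixed = TRUE)[[1]], ORACLE_ALPHA) + m
  })
  suf <- list()
  for (j in seq_len(m)) {
    full <- c(codes[[j]], j)                   # sentinel j sorts below letters
    for (k in seq_along(full)) {
      suf[[length(suf) + 1L]] <- list(j = j, k = k, v = full[k:length(full)])
    }
  }
  N <- length(suf)
  maxlen <- max(lengths(lapply(suf, `[[`, "v")))
  pad <- t(vapply(suf, function(s) c(s$v, rep(0L, maxlen - length(s$v))),
                  integer(maxlen)))
  ord <- do.call(order, as.data.frame(pad))
  lcp <- integer(N + 1L)
  for (i in 2:N) {
    a <- suf[[ord[i - 1L]]]$v; b <- suf[[ord[i]]]$v
    l <- 0L
    while (l < length(a) && l < length(b) && a[l + 1L] == b[l + 1L]) l <- l + 1L
    lcp[i] <- l
  }
  ebwt <- character(N); da <- integer(N)
  for (i in seq_len(N)) {
    s <- suf[[ord[i]]]
    full <- c(codes[[s$j]], s$j)
    prev <- if (s$k == 1L) s$j else full[s$k - 1L]
    ebwt[i] <- if (prev <= m) "$" else ORACLE_ALPHA[prev - m]
    da[i] <- s$j
  }
  list(ebwt = ebwt, da = da, lcp = lcp, N = N)
}

# Maximal lcp >= alpha runs with mixed colors, by a plain loop.
oracle_clusters <- function(lcp, da, r, alpha) {
  N <- length(da)
  out <- NULL
  i <- 2L
  while (i <= N) {
    if (lcp[i] >= alpha) {
      start <- i - 1L
      while (i <= N && lcp[i] >= alpha) i <- i + 1L
      end <- i - 1L
      d <- da[start:end]
      if (any(d <= r) && any(d > r)) out <- rbind(out, c(start, end))
    } else i <- i + 1L
  }
  if (is.null(out)) data.frame(pS = integer(0), pE = integer(0))
  else data.frame(pS = out[, 1], pE = out[, 2])
}

# Maximum IUPAC matching on residual symbol unit lists: unit-level Kuhn
# augmenting-path matching (a different algorithm from the package's
# type-graph flow).
oracle_delta <- function(left, right) {
  if (!length(left) || !length(right)) return(0L)
  compat <- outer(left, right, Vectorize(function(a, b) {
    (a %in% ORACLE_AMB && b %in% ORACLE_CODES[[a]]) ||
      (b %in% ORACLE_AMB && a %in% ORACLE_CODES[[b]])
  }))
  nr <- length(right)
  match_of <- integer(nr)                      # right unit -> left unit (0 free)
  total <- 0L
  for (i in seq_along(left)) {
    visited <- logical(nr)
    dfs <- function(u) {
      for (q in which(compat[u, ] & !visited)) {
        visited[q] <<- TRUE
        if (match_of[q] == 0L || dfs(match_of[q])) {
          match_of[q] <<- u
          return(TRUE)
        }
      }
      FALSE
    }
    if (dfs(i)) total <- total + 1L
  }
  total
}

# Per-pair similarity recomputed directly from an oracle index.
oracle_similarity <- function(oidx, clusters, r, read_color, genome_color, measure) {
  total <- 0L
  for (q in seq_len(nrow(clusters))) {
    pos <- clusters$pS[q]:clusters$pE[q]
    e <- oidx$ebwt[pos]; d <- oidx$da[pos]
    ei <- e[d == read_color]; ej <- e[d == genome_color]
    if (measure == "da") { total <- total + min(length(ei), length(ej)); next }
    syms <- c(ORACLE_ALPHA, "$")
    ci <- table(factor(ei, levels = syms)); cj <- table(factor(ej, levels = syms))
    ex <- pmin(ci, cj)
    li <- rep(names(ci), ci - ex); lj <- rep(names(cj), cj - ex)
    total <- total + sum(ex) + oracle_delta(li, lj)
  }
  total
}

# Random collection: r reads + g genomes, short sequences, ~8% ambiguity.
random_collection <- function(max_seqs = 5, max_len = 30) {
  r <- sample(1:2, 1)
  g <- sample(1:min(3, max_seqs - r), 1)
  rand_seq <- function() {
    n <- sample(3:max_len, 1)
    paste(sample(c(rep(c("A", "C", "G", "T"), 6), ORACLE_AMB), n, replace = TRUE),
          collapse = "")
  }
  reads <- setNames(vapply(seq_len(r), function(i) rand_seq(), ""),
                    paste0("r", seq_len(r)))
  genomes <- setNames(vapply(seq_len(g), function(i) rand_seq(), ""),
                      paste0("g", seq_len(g)))
  sequence_collection(reads, genomes)
}

# Small fixed taxonomy used across classification/evaluation tests:
# two phyla; genus 20 holds species 30 (genomes gA, gB) and 31 (gC);
# genus 21 holds species 32 (gD); genus 22 (other phylum) holds species 33 (gE).
toy_taxonomy <- function() {
  nodes <- data.frame(
    taxid = c(1L, 10L, 11L, 20L, 21L, 22L, 30L, 31L, 32L, 33L,
              40L, 41L, 42L, 43L, 44L),
    parent = c(1L, 1L, 1L, 10L, 10L, 11L, 20L, 20L, 21L, 22L,
               30L, 30L, 31L, 32L, 33L),
    rank = c("no_rank", "phylum", "phylum", "genus", "genus", "genus",
             "species", "species", "species", "species",
             "genome", "genome", "genome", "genome", "genome"),
    name = c("root", "phyA", "phyB", "genA", "genB", "genC",
             "spA", "spB", "spC", "spD", "gA", "gB", "gC", "gD", "gE")
  )
  list(tree = taxonomy_tree(nodes),
       map = c(gA = 40L, gB = 41L, gC = 42L, gD = 43L, gE = 44L))
}

# Fabricate a similarity_matrix for classification tests.
toy_matrix <- function(values, role, read_ids = paste0("r", seq_len(nrow(values))),
                       genome_ids = colnames(values)) {
  dimnames(values) <- list(read_ids, genome_ids)
  structure(list(role = role, measure = "ebwt", alpha = 16L,
                 values = values, raw = values, denom = values * 0 + 1,
                 read_ids = read_ids, genome_ids = genome_ids),
            class = "similarity_matrix")
}
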