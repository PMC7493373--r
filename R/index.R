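# Sorted order of the letter alphabet used for suffix comparison. All
# per-sequence end markers sort below every letter, ordered among
# themselves by sequence index.
ALPHABET_SORTED <- sort(names(IUPAC_BASES))

INDEX_FORMAT_VERSION <- 1L

#' Build the eBWT, LCP array and document array of a collection
#'
#' Each sequence `S_j` is terminated by its own end marker `$_j`; end markers
#' sort below every letter and `$_1 < $_2 < ... < $_m`, which makes the
#' suffix order total (ties between otherwise equal suffixes break by
#' sequence index). All suffixes of the terminated sequences are sorted
#' lexicographically; `ebwt[i]` is the symbol circularly preceding the i-th
#' sorted suffix, `da[i]` its sequence color, and `lcp[i]` (for `2 <= i <= N`)
#' the longest-common-prefix length of the suffixes ranked `i` and `i-1`,
#' with distinct end markers treated as unequal symbols and
#' `lcp[1] = lcp[N+1] = 0`.
#'
#' Internally the suffix order is computed by prefix doubling and the LCP
#' array from the retained rank hierarchy; the result is identical to a
#' naive sort of all suffixes (property-tested against one).
#'
#' @param collection A `seq_collection`.
#' @return An object of class `ebwt_index`: list with `ebwt` (character
#'   vector of length N; all end markers appear as `"$"`), `da` (integer
#'   colors 1..m), `lcp` (integer, length N+1) and `meta` (r, g, m, N, ids,
#'   lengths).
#' @examples
#' cl <- sequence_collection(c(r1 = "A"), c(g1 = "AC"))
#' build_ebwt_index(cl)
#' @export
build_ebwt_index <- function(collection) {
  stopifnot(inherits(collection, "seq_collection"))
  m <- collection$m
  lens <- collection$lengths
  # integer text: end marker of sequence j -> code j; letter -> m + rank
  pieces <- vector("list", m)
  for (j in seq_len(m)) {
    ch <- strsplit(collection$seqs[j], "", fixed = TRUE)[[1]]
    pieces[[j]] <- c(match(ch, ALPHABET_SORTED) + m, j)
  }
  text <- unlist(pieces, use.names = FALSE)
  N <- length(text)
  seqid <- rep.int(seq_len(m), lens + 1L)
  seq_start <- cumsum(c(1L, (lens + 1L)[-m]))

  # --- suffix order by prefix doubling; keep every rank level for the LCP
  rk <- as.integer(factor(text))            # ranks on 1-symbol prefixes
  levels <- list(rk)
  lev_len <- 1L
  sa <- order(rk)
  k <- 1L
  while (max(rk) < N) {
    rk2 <- c(rk[(k + 1L):N], rep.int(0L, min(k, N)))
    o <- order(rk, rk2, method = "radix")
    new_group <- c(TRUE, rk[o[-1L]] != rk[o[-N]] | rk2[o[-1L]] != rk2[o[-N]])
    nr <- cumsum(new_group)
    rk <- integer(N); rk[o] <- nr
    sa <- o
    k <- k * 2L
    levels[[length(levels) + 1L]] <- rk
    lev_len <- c(lev_len, k)
  }

  # --- LCP of adjacent sorted suffixes via the rank hierarchy (vectorized)
  lcp <- integer(N + 1L)
  if (N >= 2L) {
    a <- sa[-N]; b <- sa[-1L]
    l <- integer(N - 1L)
    for (t in rev(seq_along(levels))) {
      step <- lev_len[t]
      ra <- a + l; rb <- b + l
      ok <- ra <= N & rb <= N
      eq <- ok
      eq[ok] <- levels[[t]][ra[ok]] == levels[[t]][rb[ok]]
      l[eq] <- l[eq] + step
    }
    lcp[2:N] <- l
  }

  # --- eBWT: symbol circularly preceding each sorted suffix
  first <- sa %in% seq_start
  pred <- integer(N)
  pred[!first] <- text[sa[!first] - 1L]
  pred[first] <- seqid[sa[first]]          # wrap to the sequence's end marker
  sym <- character(N)
  is_sent <- pred <= m
  sym[is_sent] <- END_MARKER
  sym[!is_sent] <- ALPHABET_SORTED[pred[!is_sent] - m]

  structure(list(
    ebwt = sym,
    da = seqid[sa],
    lcp = lcp,
    meta = list(r = collection$r, g = collection$g, m = m, N = N,
                ids = collection$ids, lengths = lens)
  ), class = "ebwt_index")
}

#' @export
print.ebwt_index <- function(x, ...) {
  cat(sprintf("ebwt_index: N=%d over %d reads + %d genomes\n",
              x$meta$N, x$meta$r, x$meta$g))
  invisible(x)
}

#' Count exact occurrences of a pattern in the indexed collection
#'
#' Backward search over the eBWT (FM-index style): the suffix range of the
#' pattern is narrowed one symbol at a time from right to left, and its
#' width is the number of occurrences across all sequences. Matching is by
#' exact symbol: an ambiguity code in the text matches only the identical
#' code in the pattern.
#'
#' @param index An `ebwt_index`.
#' @param pattern Character scalar over the nucleotide alphabet.
#' @return Integer occurrence count.
#' @export
count_pattern <- function(index, pattern) {
  stopifnot(inherits(index, "ebwt_index"), is.character(pattern), nchar(pattern) >= 1L)
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  check_alphabet(chars, "pattern")
  e <- index$ebwt
  N <- index$meta$N
  m <- index$meta$m
  # C[c]: number of text symbols strictly smaller than c (all m end markers
  # are smaller than every letter)
  tab <- table(factor(e, levels = c(END_MARKER, ALPHABET_SORTED)))
  cum <- cumsum(as.integer(tab))
  Cof <- function(ch) cum[match(ch, ALPHABET_SORTED)]  # counts <= previous symbol
  sp <- 1L; ep <- N
  for (ch in rev(chars)) {
    occ <- cumsum(e == ch)
    base <- Cof(ch)
    sp_new <- base + (if (sp > 1L) occ[sp - 1L] else 0L) + 1L
    ep_new <- base + occ[ep]
    if (sp_new > ep_new) return(0L)
    sp <- sp_new; ep <- ep_new
  }
  as.integer(ep - sp + 1L)
}

#' Serialize an index to disk
#'
#' Writes four files sharing a prefix: `<prefix>.ebwt` (raw byte string,
#' end marker serialized as `#`), `<prefix>.da` and `<prefix>.lcp`
#' (little-endian unsigned 32-bit integers; the document array has length N,
#' the LCP array N+1) and `<prefix>.meta.json` (r, g, m, N, per-sequence ids
#' and lengths, format version).
#'
#' @param index An `ebwt_index`.
#' @param prefix Path prefix for the component files.
#' @return Invisibly, the prefix.
#' @export
write_index <- function(index, prefix) {
  stopifnot(inherits(index, "ebwt_index"))
  e <- index$ebwt
  e[e == END_MARKER] <- "#"
  writeBin(charToRaw(paste(e, collapse = "")), paste0(prefix, ".ebwt"))
  writeBin(as.integer(index$da), paste0(prefix, ".da"), size = 4L, endian = "little")
  writeBin(as.integer(index$lcp), paste0(prefix, ".lcp"), size = 4L, endian = "little")
  meta <- index$meta
  meta$format_version <- INDEX_FORMAT_VERSION
  jsonlite::write_json(meta, paste0(prefix, ".meta.json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' Read a serialized index
#'
#' Validates that all component files exist, that lengths agree with the
#' metadata and that the format version matches; see [write_index()] for
#' the file contract. `read_index(write_index(x))` reproduces `x` exactly.
#'
#' @param prefix Path prefix used at write time.
#' @return An `ebwt_index`.
#' @export
read_index <- function(prefix) {
  paths <- paste0(prefix, c(".ebwt", ".da", ".lcp", ".meta.json"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop(sprintf("missing index component(s): %s", paste(missing, collapse = ", ")))
  }
  meta <- jsonlite::read_json(paths[4], simplifyVector = TRUE)
  if (is.null(meta$format_version) || meta$format_version != INDEX_FORMAT_VERSION) {
    stop("index format version mismatch")
  }
  N <- meta$N
  raw_e <- readBin(paths[1], "raw", n = file.size(paths[1]))
  e <- strsplit(rawToChar(raw_e), "", fixed = TRUE)[[1]]
  e[e == "#"] <- END_MARKER
  da <- readBin(paths[2], "integer", n = file.size(paths[2]) / 4L,
                size = 4L, endian = "little")
  lcp <- readBin(paths[3], "integer", n = file.size(paths[3]) / 4L,
                 size = 4L, endian = "little")
  if (length(e) != N || length(da) != N || length(lcp) != N + 1L) {
    stop(sprintf(
      "index component lengths (ebwt=%d, da=%d, lcp=%d) inconsistent with meta N=%d",
      length(e), length(da), length(lcp), N))
  }
  structure(list(
    ebwt = e, da = as.integer(da), lcp = as.integer(lcp),
    meta = list(r = as.integer(meta$r), g = as.integer(meta$g),
                m = as.integer(meta$m), N = as.integer(meta$N),
                ids = meta$ids, lengths = as.integer(meta$lengths))
  ), class = "ebwt_index")
}
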