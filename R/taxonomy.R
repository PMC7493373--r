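# Rank ladder from most to least specific. "no_rank" nodes are transparent:
# they are skipped when walking lineages.
RANK_LADDER <- c("genome", "species", "genus", "family", "order", "class", "phylum")

rank_level <- function(rank) match(rank, RANK_LADDER)

#' Load a taxonomy tree and a genome-to-taxon map
#'
#' The nodes file is a TSV with columns `taxid`, `parent`, `rank`, `name`
#' (NCBI nodes.dmp style, simplified); the map file has columns `genome_id`,
#' `taxid`. The tree must have exactly one root (parent = self), acyclic
#' parent pointers, and every mapped taxid must exist.
#'
#' @param nodes_path Path to the nodes TSV.
#' @param map_path Path to the genome map TSV.
#' @return A list with `tree` (a `taxonomy_tree`) and `map` (named integer
#'   vector: genome id -> taxid).
#' @export
load_taxonomy <- function(nodes_path, map_path) {
  nodes <- utils::read.delim(nodes_path, header = TRUE, stringsAsFactors = FALSE)
  needed <- c("taxid", "parent", "rank")
  if (!all(needed %in% names(nodes))) {
    stop("nodes file must have columns taxid, parent, rank (and optionally name)")
  }
  if (!"name" %in% names(nodes)) nodes$name <- as.character(nodes$taxid)
  tree <- taxonomy_tree(nodes)
  mp <- utils::read.delim(map_path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("genome_id", "taxid") %in% names(mp))) {
    stop("genome map file must have columns genome_id, taxid")
  }
  map <- setNames(as.integer(mp$taxid), mp$genome_id)
  bad <- names(map)[!(map %in% tree$nodes$taxid)]
  if (length(bad)) {
    stop(sprintf("genome(s) mapped to unknown taxid: %s", paste(bad, collapse = ", ")))
  }
  list(tree = tree, map = map)
}

#' Construct and validate a taxonomy tree
#'
#' @param nodes data.frame with columns `taxid`, `parent`, `rank`, and
#'   optionally `name`. Ranks must be one of genome, species, genus, family,
#'   order, class, phylum, or `"no_rank"`.
#' @return A `taxonomy_tree`.
#' @export
taxonomy_tree <- function(nodes) {
  nodes$taxid <- as.integer(nodes$taxid)
  nodes$parent <- as.integer(nodes$parent)
  if (!"name" %in% names(nodes)) nodes$name <- as.character(nodes$taxid)
  if (anyDuplicated(nodes$taxid)) stop("duplicated taxid in nodes")
  bad_rank <- setdiff(unique(nodes$rank), c(RANK_LADDER, "no_rank"))
  if (length(bad_rank)) stop(sprintf("unknown rank(s): %s", paste(bad_rank, collapse = ", ")))
  roots <- nodes$taxid[nodes$taxid == nodes$parent]
  if (length(roots) != 1L) stop(sprintf("expected exactly one root, found %d", length(roots)))
  dangling <- setdiff(nodes$parent, nodes$taxid)
  if (length(dangling)) {
    stop(sprintf("dangling parent taxid(s): %s", paste(dangling, collapse = ", ")))
  }
  parent_of <- setNames(nodes$parent, nodes$taxid)
  # cycle check: every node must reach the root
  for (t in nodes$taxid) {
    seen <- integer(0); cur <- t
    while (cur != roots) {
      if (cur %in% seen) stop(sprintf("cycle in taxonomy involving taxid %d", cur))
      seen <- c(seen, cur)
      cur <- parent_of[[as.character(cur)]]
    }
  }
  structure(list(nodes = nodes, parent = parent_of,
                 rank = setNames(nodes$rank, nodes$taxid),
                 root = roots),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("taxonomy_tree: %d nodes, root taxid %d\n", nrow(x$nodes), x$root))
  invisible(x)
}

# Lineage of a taxid from itself up to the root (inclusive), no_rank nodes
# retained; used internally.
lineage <- function(tree, taxid) {
  key <- as.character(taxid)
  if (!key %in% names(tree$parent)) stop(sprintf("unknown taxid %s", key))
  out <- integer(0); cur <- as.integer(taxid)
  repeat {
    out <- c(out, cur)
    if (cur == tree$root) break
    cur <- tree$parent[[as.character(cur)]]
  }
  out
}

#' Ancestor (or self) of a taxid at a given rank
#'
#' Walks the lineage upward, skipping `no_rank` nodes, and returns the
#' unique node carrying the requested rank, or `NA` if the lineage lacks it.
#'
#' @param tree A `taxonomy_tree`.
#' @param taxid Taxid present in the tree.
#' @param rank One of the rank ladder values.
#' @return Integer taxid or `NA_integer_`.
#' @export
taxon_at_rank <- function(tree, taxid, rank) {
  stopifnot(rank %in% RANK_LADDER)
  lin <- lineage(tree, taxid)
  ranks <- tree$rank[as.character(lin)]
  hit <- which(ranks == rank)
  if (length(hit)) lin[hit[1]] else NA_integer_
}

#' Lowest shared taxon of a set of taxids at or above a minimum rank
#'
#' In `"fixed"` mode, returns the shared taxon at exactly `min_rank` (all
#' lineages must agree there), or `NULL`. In `"lineage"` mode, scans ranks
#' from `min_rank` upward to phylum and returns the first rank at which all
#' lineages agree on a single taxon, or `NULL` if they only agree above
#' phylum.
#'
#' @param tree A `taxonomy_tree`.
#' @param taxids Non-empty vector of taxids.
#' @param min_rank Minimum (most specific) rank considered.
#' @param mode `"fixed"` or `"lineage"`.
#' @return `NULL`, or a list with `taxid` and `rank`.
#' @export
common_taxon <- function(tree, taxids, min_rank = "species",
                         mode = c("fixed", "lineage")) {
  mode <- match.arg(mode)
  stopifnot(length(taxids) >= 1L, min_rank %in% RANK_LADDER)
  taxids <- unique(as.integer(taxids))
  ranks_to_try <- if (mode == "fixed") min_rank else
    RANK_LADDER[seq(rank_level(min_rank), length(RANK_LADDER))]
  for (rk in ranks_to_try) {
    at <- vapply(taxids, function(t) taxon_at_rank(tree, t, rk), integer(1))
    if (!anyNA(at) && length(unique(at)) == 1L) {
      return(list(taxid = at[1], rank = rk))
    }
  }
  NULL
}
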