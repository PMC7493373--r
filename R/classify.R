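#' Classification parameters
#'
#' @param beta Score threshold in `[0, 1)`: a read whose best normalized
#'   similarity does not exceed `beta` is left unclassified. Lower values
#'   classify more reads (higher sensitivity) at the cost of precision.
#' @param tolerance Absolute slack on normalized scores when collecting
#'   candidate genomes "approximately equal" to a maximum.
#' @param min_rank Minimum (most specific) taxonomic rank of assignments.
#' @param mode `"paired"` (four orientation matrices 1F/1RC/2F/2RC) or
#'   `"single"` (two matrices F/RC).
#' @param fallback Classify reads left ambiguous after phase 3 at the lowest
#'   higher rank where the tied genomes share a taxon (lineage fallback).
#' @param strict Use exact maxima instead of the tolerance band when testing
#'   uniqueness in the phase 2/3 re-examinations.
#' @return A `classify_params` list.
#' @export
classify_params <- function(beta = 0.25, tolerance = 0.02, min_rank = "species",
                            mode = c("paired", "single"), fallback = FALSE,
                            strict = FALSE) {
  mode <- match.arg(mode)
  stopifnot(beta >= 0, beta < 1, tolerance >= 0, min_rank %in% RANK_LADDER)
  structure(list(beta = beta, tolerance = tolerance, min_rank = min_rank,
                 mode = mode, fallback = fallback, strict = strict),
            class = "classify_params")
}

ROLES_PAIRED <- c("1F", "1RC", "2F", "2RC")
ROLES_SINGLE <- c("F", "RC")

check_matrices <- function(matrices, params) {
  want <- if (params$mode == "paired") ROLES_PAIRED else ROLES_SINGLE
  if (!all(want %in% names(matrices))) {
    stop(sprintf("%s mode needs matrices named %s", params$mode,
                 paste(want, collapse = ", ")))
  }
  dims <- vapply(matrices[want], function(m) dim(m$values), integer(2))
  if (length(unique(apply(dims, 2, paste, collapse = "x"))) != 1L) {
    stop("similarity matrices differ in shape across roles")
  }
  matrices[want]
}

assignment_row <- function(read_id, status, taxid = NA_integer_,
                           rank = NA_character_, score = NA_real_,
                           phase = NA_character_, tied = "") {
  data.frame(read_id = read_id, status = status, taxid = taxid, rank = rank,
             score = score, phase = phase, tied = tied,
             stringsAsFactors = FALSE)
}

resolve_unit <- function(tree, map, genome_ids, params, score, phase, read_id) {
  taxids <- map[genome_ids]
  ct <- common_taxon(tree, taxids, params$min_rank, mode = "fixed")
  if (!is.null(ct)) {
    return(assignment_row(read_id, "classified", ct$taxid, ct$rank, score, phase))
  }
  NULL
}

#' Phase 1: per-matrix maxima with tolerance
#'
#' Computes the overall maximum `M_i` across all role matrices for one read.
#' If `M_i <= beta` the read is not classified. Otherwise the candidate set
#' `I_i` collects every genome reaching `M_i` within the tolerance in at
#' least one role; if all candidates belong to one taxonomic unit at the
#' minimum rank, the read is classified in phase 1, else the candidate set
#' is handed to the re-examination phases.
#'
#' @param rows Named list (one element per role) of the read's normalized
#'   score vectors over genomes.
#' @param params A `classify_params`.
#' @param tree A `taxonomy_tree`.
#' @param map Named genome id -> taxid vector.
#' @param genome_ids Genome ids in matrix column order.
#' @param read_id Id used in the returned record.
#' @return A one-row assignment data.frame, or a `candidate_set` list
#'   (`I` = candidate genome indices, `M` = the overall maximum).
#' @export
phase1 <- function(rows, params, tree, map, genome_ids, read_id = "read") {
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) stop("score rows differ in length across roles")
  M_i <- max(unlist(rows))
  if (M_i <= params$beta) {
    return(assignment_row(read_id, "not_classified", score = M_i))
  }
  within <- Reduce(`|`, lapply(rows, function(v) v >= M_i - params$tolerance))
  I_i <- which(within)
  res <- resolve_unit(tree, map, genome_ids[I_i], params, M_i, "1", read_id)
  if (!is.null(res)) return(res)
  structure(list(I = I_i, M = M_i), class = "candidate_set")
}

#' Mate-pair score of a read against genomes
#'
#' In paired mode, each strand pairing sums a mate-1 matrix entry with its
#' FR-oriented mate-2 counterpart (1F with 2RC, 1RC with 2F); the returned
#' score is the pairing that gives the maximum, never the sum of all four.
#' In single mode it is the larger of the forward and reverse-complement
#' scores.
#'
#' @param matrices Named list of `similarity_matrix` objects.
#' @param i Read (row) index.
#' @param j Optional genome (column) index; when omitted the whole row
#'   vector over genomes is returned.
#' @return Numeric score or vector of scores.
#' @export
paired_sum <- function(matrices, i, j = NULL) {
  if (all(ROLES_PAIRED %in% names(matrices))) {
    v <- pmax(matrices[["1F"]]$values[i, ] + matrices[["2RC"]]$values[i, ],
              matrices[["1RC"]]$values[i, ] + matrices[["2F"]]$values[i, ])
  } else if (all(ROLES_SINGLE %in% names(matrices))) {
    v <- pmax(matrices[["F"]]$values[i, ], matrices[["RC"]]$values[i, ])
  } else {
    stop("matrices must be named 1F/1RC/2F/2RC (paired) or F/RC (single)")
  }
  if (is.null(j)) v else v[[j]]
}

re_candidates <- function(sums, params) {
  M <- max(sums)
  if (params$strict) which(sums >= M - 1e-12) else which(sums >= M - params$tolerance)
}

#' Phase 2: re-examination of phase-1 candidates by mate-pair sums
#'
#' Restricted to the phase-1 candidate set, computes [paired_sum()] scores,
#' keeps the genomes within tolerance of the new maximum, and classifies if
#' they reduce to one taxonomic unit; otherwise the read passes to phase 3.
#'
#' @param candidates A `candidate_set` from [phase1()].
#' @param matrices Named list of `similarity_matrix` objects.
#' @param i Read index.
#' @inheritParams phase1
#' @return A one-row assignment data.frame or a `candidate_set`.
#' @export
phase2 <- function(candidates, matrices, i, params, tree, map, genome_ids,
                   read_id = "read") {
  if (!length(candidates$I)) stop("empty candidate set")
  sums <- paired_sum(matrices, i)[candidates$I]
  keep <- candidates$I[re_candidates(sums, params)]
  res <- resolve_unit(tree, map, genome_ids[keep], params, max(sums), "2", read_id)
  if (!is.null(res)) return(res)
  structure(list(I = keep, M = max(sums)), class = "candidate_set")
}

#' Phase 3: re-examination over all genomes, with optional lineage fallback
#'
#' Maximizes the mate-pair sum over every genome (not only the candidate
#' set). If the genomes within tolerance of this maximum still span several
#' taxonomic units at the minimum rank, the read is reported ambiguous when
#' fallback is off; with fallback on, the tied set is walked up the lineage
#' and the read is classified at the lowest higher rank where the set
#' shares a taxon (status classified, phase `"fallback"`), or left
#' ambiguous if it only agrees above phylum.
#'
#' @inheritParams phase2
#' @return A one-row assignment data.frame.
#' @export
phase3 <- function(matrices, i, params, tree, map, genome_ids, read_id = "read") {
  sums <- paired_sum(matrices, i)
  keep <- re_candidates(sums, params)
  M <- max(sums)
  res <- resolve_unit(tree, map, genome_ids[keep], params, M, "3", read_id)
  if (!is.null(res)) return(res)
  taxids <- map[genome_ids[keep]]
  if (params$fallback) {
    ct <- common_taxon(tree, taxids, params$min_rank, mode = "lineage")
    if (!is.null(ct)) {
      return(assignment_row(read_id, "classified", ct$taxid, ct$rank, M, "fallback"))
    }
  }
  tied <- vapply(taxids, function(t) {
    v <- taxon_at_rank(tree, t, params$min_rank)
    if (is.na(v)) as.integer(t) else v
  }, integer(1))
  assignment_row(read_id, "ambiguous", score = M,
                 tied = paste(sort(unique(tied)), collapse = ","))
}

#' Assign every read (or read pair) to a taxon
#'
#' Runs the three-phase procedure per read over the role-labeled similarity
#' matrices: per-matrix maxima with tolerance (phase 1), mate-pair
#' re-examination of the candidate set (phase 2), re-examination over all
#' genomes (phase 3), and optional lineage fallback. Deterministic; one
#' record per read pair (paired mode) or per read (single mode), in matrix
#' row order.
#'
#' @param matrices Named list of `similarity_matrix` objects covering the
#'   roles of the chosen mode.
#' @param tree A `taxonomy_tree`.
#' @param map Named genome id -> taxid vector covering every genome column.
#' @param params A `classify_params`.
#' @return A data.frame with columns `read_id`, `status` (`classified` /
#'   `ambiguous` / `not_classified`), `taxid`, `rank`, `score`, `phase`,
#'   `tied` (diagnostic taxid list for ambiguous reads).
#' @export
classify_reads <- function(matrices, tree, map, params = classify_params()) {
  stopifnot(inherits(params, "classify_params"))
  matrices <- check_matrices(matrices, params)
  first <- matrices[[1]]
  genome_ids <- first$genome_ids
  unmapped <- setdiff(genome_ids, names(map))
  if (length(unmapped)) {
    stop(sprintf("genome(s) missing from the taxon map: %s",
                 paste(unmapped, collapse = ", ")))
  }
  read_ids <- first$read_ids
  out <- vector("list", length(read_ids))
  for (i in seq_along(read_ids)) {
    rows <- lapply(matrices, function(m) m$values[i, , drop = TRUE])
    res <- phase1(rows, params, tree, map, genome_ids, read_ids[i])
    if (inherits(res, "candidate_set")) {
      res <- phase2(res, matrices, i, params, tree, map, genome_ids, read_ids[i])
    }
    if (inherits(res, "candidate_set")) {
      res <- phase3(matrices, i, params, tree, map, genome_ids, read_ids[i])
    }
    out[[i]] <- res
  }
  do.call(rbind, out)
}

#' Write assignments as TSV
#'
#' Columns: `read_id`, `status` coded `C`/`A`/`U`, `taxid` (0 when absent),
#' `rank`, `score`, `phase`, `tied`. One header line; rows in input read
#' order.
#'
#' @param assignments Assignment data.frame from [classify_reads()].
#' @param path Output file.
#' @export
write_assignments <- function(assignments, path) {
  df <- assignments
  df$status <- c(classified = "C", ambiguous = "A", not_classified = "U")[df$status]
  df$taxid[is.na(df$taxid)] <- 0L
  df$rank[is.na(df$rank)] <- "-"
  df$phase[is.na(df$phase)] <- "-"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read assignments written by [write_assignments()]
#'
#' @param path TSV path.
#' @return Assignment data.frame in the in-memory convention.
#' @export
read_assignments <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c(read_id = "character", tied = "character"))
  df$status <- c(C = "classified", A = "ambiguous", U = "not_classified")[df$status]
  df$taxid[df$taxid == 0L] <- NA_integer_
  df$rank[df$rank == "-"] <- NA_character_
  df$phase[df$phase == "-"] <- NA_character_
  if (is.null(df$tied)) df$tied <- ""
  df$tied[is.na(df$tied)] <- ""
  df
}
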