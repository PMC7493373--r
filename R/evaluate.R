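# Resolve one assignment row to a taxon at `level`, walking up from the
# assigned taxon; NA when the read is not classified at/below that level.
resolved_at_level <- function(assignments, tree, level) {
  out <- rep(NA_integer_, nrow(assignments))
  cls <- which(assignments$status == "classified")
  for (i in cls) {
    out[i] <- taxon_at_rank(tree, assignments$taxid[i], level)
  }
  setNames(out, assignments$read_id)
}

#' Confusion counts of assignments against a known truth
#'
#' Evaluated at species level. For non-random reads: `TP` are reads
#' assigned to their true species (assignments at genome rank resolve
#' upward); `FP` are reads assigned to a wrong species; `FN` are unassigned
#' non-random reads plus non-random reads assigned only above species.
#' For negative-control (random) reads: `TN` counts those not assigned to
#' any species. Random reads never enter TP/FP/FN and non-random reads
#' never enter TN.
#'
#' @param assignments Assignment data.frame from [classify_reads()].
#' @param truth data.frame with columns `read_id`, `species_taxid`,
#'   `is_random`; must cover every assigned read.
#' @param tree A `taxonomy_tree` used to resolve assignments to species.
#' @return A `confusion_counts` list: `TP`, `FP`, `FN`, `TN`, `t_random`.
#' @export
score_against_truth <- function(assignments, truth, tree) {
  if (nrow(assignments) == 0L) stop("empty assignment list")
  missing <- setdiff(assignments$read_id, truth$read_id)
  if (length(missing)) {
    stop(sprintf("read(s) absent from truth: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  tr <- truth[match(assignments$read_id, truth$read_id), ]
  species <- resolved_at_level(assignments, tree, "species")
  pos <- !as.logical(tr$is_random)
  TP <- sum(pos & !is.na(species) & species == tr$species_taxid, na.rm = TRUE)
  FP <- sum(pos & !is.na(species) & species != tr$species_taxid, na.rm = TRUE)
  FN <- sum(pos & is.na(species))
  TN <- sum(!pos & is.na(species))
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN, t_random = sum(!pos)),
            class = "confusion_counts")
}

#' Accuracy metrics from confusion counts
#'
#' `SEN = TP/(TP+FN)`, `PREC = TP/(TP+FP)`, `F1 = 2TP/(2TP+FP+FN)` (the
#' harmonic mean of sensitivity and precision), `SPEC = TN/t_random`.
#' A metric whose denominator is zero is reported as `NA` (undefined), not 0.
#'
#' @param counts A `confusion_counts`.
#' @return Named list with `SEN`, `PREC`, `F1`, `SPEC`.
#' @export
metrics <- function(counts) {
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  with(counts, list(
    SEN = safe(TP, TP + FN),
    PREC = safe(TP, TP + FP),
    F1 = safe(2 * TP, 2 * TP + FP + FN),
    SPEC = safe(TN, t_random)
  ))
}

#' Concordance between two classifiers' assignments
#'
#' Represents the reads each classifier assigns at `level` as sets `A` and
#' `B`; with `t = |A U B|`, the identifier intersection `I_id = |A n B|`
#' and the same-assignment intersection `I_as` (reads both classify to the
#' same taxon), the Jaccard-style agreement rates are `r_id = I_id / t` and
#' `r_as = I_as / t`.
#'
#' @param a,b Assignment data.frames over the same read universe.
#' @param level Rank of the comparison (default species).
#' @param tree Optional `taxonomy_tree` to resolve assignments (e.g. genome
#'   rank) up to `level`; without it, reads assigned at exactly `level` are
#'   compared by taxid directly.
#' @return A `concordance_result` list: `t`, `I_id`, `I_as`, `r_id`, `r_as`.
#' @export
concordance <- function(a, b, level = "species", tree = NULL) {
  classified_at <- function(df) {
    if (anyDuplicated(df$read_id)) stop("duplicated read ids within one output")
    if (!is.null(tree)) {
      v <- resolved_at_level(df, tree, level)
      v[!is.na(v)]
    } else {
      sel <- df$status == "classified" & !is.na(df$rank) & df$rank == level
      setNames(df$taxid[sel], df$read_id[sel])
    }
  }
  A <- classified_at(a); B <- classified_at(b)
  t_union <- length(union(names(A), names(B)))
  ids <- intersect(names(A), names(B))
  I_id <- length(ids)
  I_as <- sum(A[ids] == B[ids])
  structure(list(t = t_union, I_id = I_id, I_as = I_as,
                 r_id = if (t_union > 0) I_id / t_union else NA_real_,
                 r_as = if (t_union > 0) I_as / t_union else NA_real_),
            class = "concordance_result")
}

#' Three-way concordance region counts
#'
#' Venn-style breakdown of the reads three classifiers assign at a level:
#' for every non-empty subset of \{a, b, c\} the number of reads classified
#' by exactly those classifiers, plus the number classified identically by
#' all three.
#'
#' @param a,b,c Assignment data.frames over the same read universe.
#' @inheritParams concordance
#' @return Named list of the seven region counts (`a`, `b`, `c`, `ab`,
#'   `ac`, `bc`, `abc`) and `abc_same_taxon`.
#' @export
concordance_venn <- function(a, b, c, level = "species", tree = NULL) {
  one <- function(df) {
    if (!is.null(tree)) {
      v <- resolved_at_level(df, tree, level); v[!is.na(v)]
    } else {
      sel <- df$status == "classified" & !is.na(df$rank) & df$rank == level
      setNames(df$taxid[sel], df$read_id[sel])
    }
  }
  A <- one(a); B <- one(b); C <- one(c)
  inA <- names(A); inB <- names(B); inC <- names(C)
  region <- function(yes, no) {
    length(setdiff(Reduce(intersect, yes), Reduce(union, c(no, list(character(0))))))
  }
  all3 <- Reduce(intersect, list(inA, inB, inC))
  list(
    a = region(list(inA), list(inB, inC)),
    b = region(list(inB), list(inA, inC)),
    c = region(list(inC), list(inA, inB)),
    ab = region(list(inA, inB), list(inC)),
    ac = region(list(inA, inC), list(inB)),
    bc = region(list(inB, inC), list(inA)),
    abc = length(all3),
    abc_same_taxon = sum(A[all3] == B[all3] & B[all3] == C[all3])
  )
}
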