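#' Run the full classification pipeline on in-memory sequences
#'
#' For a paired-end collection, four orientation indexes are built (mate 1
#' forward, mate 1 reverse-complemented, mate 2 forward, mate 2
#' reverse-complemented, each together with the genomes), alpha-clusters
#' are detected in each, and four normalized similarity matrices feed the
#' three-phase assignment. For single-end reads only the forward and
#' reverse-complement indexes are built. Re-indexing per orientation keeps
#' the construction simple and exact at this scale.
#'
#' @param reads1 Named character vector of reads (mate 1 in paired mode).
#' @param genomes Named character vector of reference genomes.
#' @param tree A `taxonomy_tree`.
#' @param map Named genome id -> taxid vector.
#' @param reads2 Optional named character vector of mate-2 reads (paired
#'   mode when given).
#' @param alpha Minimum shared-context length (default 16).
#' @param beta Classification score threshold (default 0.25).
#' @param measure `"ebwt"` or `"da"`.
#' @param tolerance,min_rank,fallback,strict Passed to [classify_params()].
#' @return A `classification_run` list: `assignments`, `matrices`,
#'   `params`, `alpha`, `measure`.
#' @examples
#' ref <- simulate_reference_set(sim_params(n_genomes = 2, genome_length = 400,
#'   n_read_pairs = 4, insert_size = 200, substitution_rate = 0, seed = 3))
#' rd <- simulate_paired_reads(ref, sim_params(n_genomes = 2,
#'   genome_length = 400, n_read_pairs = 4, insert_size = 200,
#'   substitution_rate = 0, seed = 3))
#' run <- run_classification(rd$mate1, ref$genomes, ref$tree, ref$map,
#'   reads2 = rd$mate2, alpha = 16, beta = 0.25)
#' table(run$assignments$status)
#' @export
run_classification <- function(reads1, genomes, tree, map, reads2 = NULL,
                               alpha = 16, beta = 0.25, measure = c("ebwt", "da"),
                               tolerance = 0.02, min_rank = "species",
                               fallback = FALSE, strict = FALSE) {
  measure <- match.arg(measure)
  mode <- if (is.null(reads2)) "single" else "paired"
  rc <- function(x) setNames(vapply(x, reverse_complement, ""), names(x))
  role_reads <- if (mode == "paired") {
    list("1F" = reads1, "1RC" = rc(reads1), "2F" = reads2, "2RC" = rc(reads2))
  } else {
    list("F" = reads1, "RC" = rc(reads1))
  }
  matrices <- lapply(names(role_reads), function(role) {
    coll <- sequence_collection(role_reads[[role]], genomes)
    idx <- build_ebwt_index(coll)
    cl <- detect_alpha_clusters(idx, alpha)
    build_similarity_matrix(idx, cl, measure = measure, alpha = alpha, role = role)
  })
  names(matrices) <- names(role_reads)
  params <- classify_params(beta = beta, tolerance = tolerance,
                            min_rank = min_rank, mode = mode,
                            fallback = fallback, strict = strict)
  assignments <- classify_reads(matrices, tree, map, params)
  structure(list(assignments = assignments, matrices = matrices,
                 params = params, alpha = alpha, measure = measure),
            class = "classification_run")
}

#' @export
print.classification_run <- function(x, ...) {
  tab <- table(factor(x$assignments$status,
                      levels = c("classified", "ambiguous", "not_classified")))
  cat(sprintf("classification_run [alpha=%d, beta=%.2f, %s, %s]:\n",
              x$alpha, x$params$beta, x$measure, x$params$mode))
  cat(sprintf("  classified %d, ambiguous %d, not classified %d\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}
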