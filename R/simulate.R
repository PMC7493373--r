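# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' The three-sequence worked example
#'
#' One 9-bp read `S1 = GGCGTACCA` against two genomes `S2 = GGGGCGTAT` and
#' `S3 = ACGARTACGAC` (note the purine ambiguity code `R` at position 5 of
#' `S3`). Returned together with the expected index and similarity
#' artifacts at `alpha = 2`, frozen for test harnesses: the 2-cluster list,
#' the LCP value at sorted position 17, raw and normalized similarities
#' under both measures, and substring occurrence counts.
#'
#' @return A list with `collection` (a `seq_collection`) and `expected`.
#' @export
running_example <- function() {
  collection <- sequence_collection(
    reads = c(S1 = "GGCGTACCA"),
    genomes = c(S2 = "GGGGCGTAT", S3 = "ACGARTACGAC")
  )
  expected <- list(
    N = 32L,
    lcp17 = 4L,
    alpha = 2L,
    clusters = data.frame(pS = c(5L, 14L, 20L, 22L, 26L, 30L),
                          pE = c(8L, 17L, 21L, 25L, 27L, 32L),
                          size = c(4L, 4L, 2L, 4L, 2L, 3L)),
    per_cluster_ebwt = list(S2 = c(0L, 1L, 1L, 1L, 1L, 1L),
                            S3 = c(1L, 0L, 0L, 0L, 0L, 1L)),
    per_cluster_da = list(S2 = c(0L, 1L, 1L, 1L, 1L, 1L),
                          S3 = c(1L, 1L, 0L, 0L, 0L, 1L)),
    raw_ebwt = c(S2 = 5L, S3 = 2L),
    raw_da = c(S2 = 5L, S3 = 3L),
    norm_ebwt = c(S2 = 0.625, S3 = 0.250),
    norm_da = c(S2 = 0.625, S3 = 0.375),
    substring_counts = c(GT = 2L, T = 4L)
  )
  list(collection = collection, expected = expected)
}

#' Simulation parameters
#'
#' Defaults describe the study conditions the package is exercised under:
#' 100-bp paired-end reads from a small set of 10-kb genomes in distinct
#' species, 1% substitution noise, and shuffled negative controls.
#'
#' @param n_genomes Number of reference genomes.
#' @param genome_length Length of each genome (bp).
#' @param n_read_pairs Number of simulated read pairs.
#' @param read_length Read length (bp).
#' @param insert_size Outer fragment length from the start of mate 1 to the
#'   end of mate 2 (bp); mate 2 is the reverse complement of the fragment's
#'   downstream end (FR orientation).
#' @param substitution_rate Per-base probability of a substitution to a
#'   different uniformly chosen base.
#' @param n_negative Number of shuffled negative-control reads.
#' @param n_same_species_pairs Number of genome pairs placed in one species
#'   (0 keeps all genomes in distinct species).
#' @param seed Integer seed; every simulation is deterministic under it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_genomes = 5, genome_length = 10000, n_read_pairs = 500,
                       read_length = 100, insert_size = 300,
                       substitution_rate = 0.01, n_negative = 100,
                       n_same_species_pairs = 0, seed = 1) {
  stopifnot(n_genomes >= 1, genome_length >= 1, n_read_pairs >= 0,
            read_length >= 1, insert_size >= read_length,
            insert_size <= genome_length,
            substitution_rate >= 0, substitution_rate <= 1,
            n_negative >= 0, n_same_species_pairs >= 0,
            2 * n_same_species_pairs <= n_genomes)
  structure(as.list(environment()), class = "sim_params")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Simulate a reference genome set with a toy taxonomy
#'
#' Genomes are i.i.d. uniform A/C/G/T strings. The taxonomy places each
#' genome as a leaf (rank `genome`) under a species; species are grouped
#' two-per-genus under two phyla beneath an unranked root. The first
#' `n_same_species_pairs` genome pairs share a species (for testing
#' agreement at species rank); all other genomes get distinct species.
#' Deterministic under the seed.
#'
#' @param params A `sim_params`.
#' @return A list with `genomes` (named character vector), `nodes`
#'   (taxonomy node data.frame), `tree` (a `taxonomy_tree`) and `map`
#'   (genome id -> taxid).
#' @export
simulate_reference_set <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    ng <- params$n_genomes
    genomes <- setNames(
      vapply(seq_len(ng), function(i) random_dna(params$genome_length), ""),
      paste0("G", seq_len(ng)))

    # species assignment: pairs first, then singletons
    sp_of <- integer(ng)
    sp <- 0L
    for (p in seq_len(params$n_same_species_pairs)) {
      sp <- sp + 1L
      sp_of[c(2L * p - 1L, 2L * p)] <- sp
    }
    for (i in seq_len(ng)) if (sp_of[i] == 0L) { sp <- sp + 1L; sp_of[i] <- sp }
    n_sp <- sp
    genus_of_sp <- ceiling(seq_len(n_sp) / 2)
    n_gen <- max(genus_of_sp)
    phylum_of_gen <- ifelse(seq_len(n_gen) <= ceiling(n_gen / 2), 1L, 2L)
    n_phy <- length(unique(phylum_of_gen))

    root <- 1L
    phy_ids <- root + seq_len(n_phy)
    gen_ids <- max(phy_ids) + seq_len(n_gen)
    sp_ids <- max(gen_ids) + seq_len(n_sp)
    leaf_ids <- max(sp_ids) + seq_len(ng)
    nodes <- rbind(
      data.frame(taxid = root, parent = root, rank = "no_rank", name = "root"),
      data.frame(taxid = phy_ids, parent = root, rank = "phylum",
                 name = paste0("phylum", seq_len(n_phy))),
      data.frame(taxid = gen_ids, parent = phy_ids[phylum_of_gen], rank = "genus",
                 name = paste0("genus", seq_len(n_gen))),
      data.frame(taxid = sp_ids, parent = gen_ids[genus_of_sp], rank = "species",
                 name = paste0("species", seq_len(n_sp))),
      data.frame(taxid = leaf_ids, parent = sp_ids[sp_of], rank = "genome",
                 name = names(genomes))
    )
    tree <- taxonomy_tree(nodes)
    map <- setNames(leaf_ids, names(genomes))
    list(genomes = genomes, nodes = nodes, tree = tree, map = map)
  })
}

substitute_bases <- function(chars, rate) {
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  chars
}

#' Simulate paired-end reads with substitution errors
#'
#' Each pair draws a uniform genome and a uniform locus; mate 1 is the
#' forward fragment prefix, mate 2 the reverse complement of the fragment's
#' last `read_length` bases at `insert_size` (FR orientation). Each base is
#' substituted to a different uniformly chosen base with probability
#' `substitution_rate`. The truth table records the source genome and its
#' species. Deterministic under the seed (offset from the reference seed so
#' genomes and reads draw independent streams).
#'
#' @param ref Output of [simulate_reference_set()].
#' @param params A `sim_params`.
#' @return A list with `mate1`, `mate2` (named character vectors) and
#'   `truth` (data.frame: `read_id`, `genome_id`, `species_taxid`, `pos` =
#'   1-based fragment start in the source genome, `is_random`).
#' @export
simulate_paired_reads <- function(ref, params) {
  stopifnot(inherits(params, "sim_params"))
  np <- params$n_read_pairs
  L <- params$read_length
  ins <- params$insert_size
  with_seed(params$seed + 1L, {
    glens <- nchar(ref$genomes)
    src <- sample(length(ref$genomes), np, replace = TRUE)
    mate1 <- character(np); mate2 <- character(np); locus <- integer(np)
    for (k in seq_len(np)) {
      glen <- glens[src[k]]
      if (ins > glen) stop("insert_size exceeds genome length")
      p <- sample.int(glen - ins + 1L, 1L)
      locus[k] <- p
      gch <- strsplit(substr(ref$genomes[src[k]], p, p + ins - 1L), "", fixed = TRUE)[[1]]
      m1 <- substitute_bases(gch[seq_len(L)], params$substitution_rate)
      m2 <- substitute_bases(gch[(ins - L + 1L):ins], params$substitution_rate)
      mate1[k] <- paste(m1, collapse = "")
      mate2[k] <- reverse_complement(paste(m2, collapse = ""))
    }
    ids <- sprintf("p%04d", seq_len(np))
    names(mate1) <- names(mate2) <- ids
    gid <- names(ref$genomes)[src]
    sp <- vapply(ref$map[gid], function(t) taxon_at_rank(ref$tree, t, "species"),
                 integer(1))
    truth <- data.frame(read_id = ids, genome_id = gid, species_taxid = sp,
                        pos = locus, is_random = FALSE, stringsAsFactors = FALSE)
    list(mate1 = mate1, mate2 = mate2, truth = truth)
  })
}

#' Shuffled negative-control reads
#'
#' Each control read is a uniform random permutation of a source read's
#' symbols: base composition is preserved, order is destroyed — mimicking
#' sequences from organisms absent from the reference set.
#'
#' @param reads Named character vector of source reads.
#' @param n Number of controls (must not exceed the source count unless
#'   `replace = TRUE`).
#' @param seed Integer seed.
#' @param replace Sample source reads with replacement.
#' @return A list with `reads` (named character vector, ids `neg...`) and
#'   `truth` (data.frame with `is_random = TRUE`).
#' @export
simulate_negative_control <- function(reads, n, seed, replace = FALSE) {
  if (!replace && n > length(reads)) {
    stop("n exceeds the number of source reads (use replace = TRUE)")
  }
  with_seed(seed, {
    src <- sample(length(reads), n, replace = replace)
    shuffled <- vapply(reads[src], function(s) {
      paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
    }, "")
    ids <- sprintf("neg%04d", seq_len(n))
    names(shuffled) <- ids
    truth <- data.frame(read_id = ids, genome_id = NA_character_,
                        species_taxid = NA_integer_, pos = NA_integer_,
                        is_random = TRUE, stringsAsFactors = FALSE)
    list(reads = shuffled, truth = truth)
  })
}

#' Write sequences as FASTA or FASTQ
#'
#' FASTQ qualities are written as constant `I` (they are ignored
#' downstream).
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param format `"fasta"` or `"fastq"`.
#' @export
write_sequences <- function(seqs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::BStringSet(seqs)
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  } else {
    quals <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  }
  invisible(path)
}

#' Write a simulated reference set's taxonomy files
#'
#' Emits the nodes TSV (`taxid`, `parent`, `rank`, `name`) and the genome
#' map TSV (`genome_id`, `taxid`) in the formats [load_taxonomy()] reads.
#'
#' @param ref Output of [simulate_reference_set()].
#' @param nodes_path,map_path Output files.
#' @export
write_taxonomy <- function(ref, nodes_path, map_path) {
  utils::write.table(ref$nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(genome_id = names(ref$map), taxid = unname(ref$map)),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nodes_path)
}
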