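test_that("the packaged worked example is constant and carries the R code", {
  ex1 <- running_example()
  ex2 <- running_example()
  expect_identical(ex1, ex2)
  expect_equal(ex1$collection$r, 1L)
  expect_equal(ex1$collection$g, 2L)
  expect_equal(substr(ex1$collection$seqs[3], 5, 5), "R")
})

test_that("reference simulation is deterministic and taxonomy covers all genomes", {
  p <- sim_params(n_genomes = 5, genome_length = 500, n_read_pairs = 10,
                  insert_size = 200, seed = 7)
  ref1 <- simulate_reference_set(p)
  ref2 <- simulate_reference_set(p)
  expect_identical(ref1$genomes, ref2$genomes)
  expect_identical(ref1$nodes, ref2$nodes)
  expect_equal(sum(ref1$nodes$rank == "genome"), 5L)
  expect_equal(length(ref1$map), 5L)
  # distinct species by default
  sp <- vapply(ref1$map, function(t) taxon_at_rank(ref1$tree, t, "species"), 1L)
  expect_equal(length(unique(sp)), 5L)

  # with a same-species pair, the pair shares its species taxon
  p2 <- sim_params(n_genomes = 5, genome_length = 500, n_read_pairs = 10,
                   insert_size = 200, n_same_species_pairs = 1, seed = 7)
  ref3 <- simulate_reference_set(p2)
  ct <- common_taxon(ref3$tree, ref3$map[c("G1", "G2")], "species", "fixed")
  expect_false(is.null(ct))
  expect_equal(ct$rank, "species")
})

test_that("noise-free mates are exact substrings in FR orientation", {
  p <- sim_params(n_genomes = 3, genome_length = 600, n_read_pairs = 30,
                  read_length = 50, insert_size = 200,
                  substitution_rate = 0, seed = 11)
  ref <- simulate_reference_set(p)
  rd <- simulate_paired_reads(ref, p)
  expect_equal(nrow(rd$truth), 30L)
  expect_identical(names(rd$mate1), names(rd$mate2))  # mates pair 1:1 by id
  expect_false(anyDuplicated(rd$truth$read_id) > 0)
  for (k in seq_len(30)) {
    src <- ref$genomes[rd$truth$genome_id[k]]
    expect_true(grepl(rd$mate1[k], src, fixed = TRUE))
    expect_true(grepl(reverse_complement(rd$mate2[k]), src, fixed = TRUE))
  }
})

test_that("full substitution destroys every mate; partial rates match binomial expectation", {
  p1 <- sim_params(n_genomes = 2, genome_length = 400, n_read_pairs = 10,
                   read_length = 40, insert_size = 150,
                   substitution_rate = 1, seed = 13)
  ref <- simulate_reference_set(p1)
  rd <- simulate_paired_reads(ref, p1)
  for (k in seq_len(10)) {
    src <- ref$genomes[rd$truth$genome_id[k]]
    expect_false(grepl(rd$mate1[k], src, fixed = TRUE))
  }

  p2 <- sim_params(n_genomes = 2, genome_length = 5000, n_read_pairs = 1000,
                   read_length = 100, insert_size = 300,
                   substitution_rate = 0.01, seed = 17)
  ref2 <- simulate_reference_set(p2)
  rd2 <- simulate_paired_reads(ref2, p2)
  # the truth table records each fragment's locus: compare every mate to its
  # clean source substring
  mismatches <- 0L
  for (k in seq_len(1000)) {
    src <- ref2$genomes[rd2$truth$genome_id[k]]
    pos <- rd2$truth$pos[k]
    clean1 <- substr(src, pos, pos + 99L)
    clean2 <- reverse_complement(substr(src, pos + 300L - 100L, pos + 300L - 1L))
    mismatches <- mismatches +
      sum(strsplit(rd2$mate1[k], "")[[1]] != strsplit(clean1, "")[[1]]) +
      sum(strsplit(rd2$mate2[k], "")[[1]] != strsplit(clean2, "")[[1]])
  }
  rate_hat <- mismatches / (2 * 1000 * 100)
  # within 3 binomial standard deviations of the nominal 0.01
  se <- sqrt(0.01 * 0.99 / (2 * 1000 * 100))
  expect_lt(abs(rate_hat - 0.01), 3 * se)
})

test_that("negative controls preserve composition, destroy order, and reproduce", {
  reads <- c(a = "AAAA", b = "ACGTACGTACGTACGTACGT", c = "GGGTTTCCCAAA")
  n1 <- simulate_negative_control(reads, 3, seed = 19)
  n2 <- simulate_negative_control(reads, 3, seed = 19)
  expect_identical(n1, n2)
  expect_true(all(n1$truth$is_random))
  for (k in seq_len(3)) {
    src <- reads[[which(vapply(reads, nchar, 1L) == nchar(n1$reads[[k]]))[1]]]
    expect_equal(sort(strsplit(n1$reads[[k]], "")[[1]]),
                 sort(strsplit(src, "")[[1]]))
  }
  # a homopolymer shuffles to itself
  h <- simulate_negative_control(c(x = "AAAA"), 1, seed = 23)
  expect_equal(unname(h$reads[1]), "AAAA")
  expect_error(simulate_negative_control(reads, 10, seed = 1), "replace")
  expect_equal(length(simulate_negative_control(reads, 10, 1, replace = TRUE)$reads), 10L)
})

test_that("FASTA/FASTQ emitters round-trip through the loader", {
  p <- sim_params(n_genomes = 2, genome_length = 300, n_read_pairs = 5,
                  read_length = 40, insert_size = 120, seed = 29)
  ref <- simulate_reference_set(p)
  rd <- simulate_paired_reads(ref, p)
  fa <- tempfile(fileext = ".fasta"); fq <- tempfile(fileext = ".fastq")
  write_sequences(ref$genomes, fa)
  write_sequences(rd$mate1, fq, format = "fastq")
  coll <- load_collection(fq, fa)
  expect_equal(coll$r, 5L)
  expect_equal(coll$g, 2L)
  expect_equal(coll$seqs[seq_len(5)], unname(rd$mate1))
})
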