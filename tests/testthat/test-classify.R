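# Classification tests build small fabricated matrices over the toy
# taxonomy: genomes gA,gB (species 30), gC (31), gD (32), gE (33, other
# phylum).

mk_roles <- function(rows, genome_ids = c("gA", "gB", "gC", "gD", "gE")) {
  lapply(rows, function(v) toy_matrix(matrix(v, nrow = 1), role = "x",
                                      genome_ids = genome_ids))
}

paired_set <- function(v1F, v1RC, v2F, v2RC, genome_ids = c("gA", "gB", "gC", "gD", "gE")) {
  m <- list(toy_matrix(matrix(v1F, nrow = 1), "1F", genome_ids = genome_ids),
            toy_matrix(matrix(v1RC, nrow = 1), "1RC", genome_ids = genome_ids),
            toy_matrix(matrix(v2F, nrow = 1), "2F", genome_ids = genome_ids),
            toy_matrix(matrix(v2RC, nrow = 1), "2RC", genome_ids = genome_ids))
  names(m) <- c("1F", "1RC", "2F", "2RC")
  m
}

test_that("phase 1 classifies dominant and same-species maxima, thresholds the rest", {
  tax <- toy_taxonomy()
  p <- classify_params(beta = 0.25, mode = "paired")
  gids <- c("gA", "gB", "gC", "gD", "gE")

  # unique dominant genome
  rows <- list(`1F` = c(0.9, 0.1, 0.1, 0.1, 0.1), `1RC` = rep(0, 5),
               `2F` = rep(0, 5), `2RC` = rep(0, 5))
  res <- phase1(rows, p, tax$tree, tax$map, gids, "rd")
  expect_equal(res$status, "classified")
  expect_equal(res$taxid, 30L)    # gA's species
  expect_equal(res$phase, "1")

  # everything at or below beta
  rows_low <- lapply(rows, function(v) pmin(v, 0.25))
  res <- phase1(rows_low, p, tax$tree, tax$map, gids, "rd")
  expect_equal(res$status, "not_classified")

  # two genomes of one species within tolerance
  rows2 <- list(`1F` = c(0.80, 0.79, 0.1, 0.1, 0.1), `1RC` = rep(0, 5),
                `2F` = rep(0, 5), `2RC` = rep(0, 5))
  res <- phase1(rows2, p, tax$tree, tax$map, gids, "rd")
  expect_equal(res$status, "classified")
  expect_equal(res$taxid, 30L)
  expect_equal(res$phase, "1")

  # cross-species tie hands back a candidate set
  rows3 <- list(`1F` = c(0.80, 0.1, 0.79, 0.1, 0.1), `1RC` = rep(0, 5),
                `2F` = rep(0, 5), `2RC` = rep(0, 5))
  res <- phase1(rows3, p, tax$tree, tax$map, gids, "rd")
  expect_s3_class(res, "candidate_set")
  expect_equal(res$I, c(1L, 3L))
})

test_that("mate-pair scores take the best strand pairing, never the sum of four", {
  m <- paired_set(v1F = c(0.5, 0, 0, 0, 0), v1RC = c(0.1, 0, 0, 0, 0),
                  v2F = c(0.1, 0, 0, 0, 0), v2RC = c(0.4, 0, 0, 0, 0))
  expect_equal(paired_sum(m, 1, 1), 0.9)   # 1F+2RC dominates, not 1.1
  m2 <- paired_set(rep(0.3, 5), rep(0.3, 5), rep(0.3, 5), rep(0.3, 5))
  expect_equal(paired_sum(m2, 1, 1), 0.6)
  single <- list(F = toy_matrix(matrix(c(0.2, 0, 0, 0, 0), 1), "F",
                                genome_ids = c("gA", "gB", "gC", "gD", "gE")),
                 RC = toy_matrix(matrix(c(0.7, 0, 0, 0, 0), 1), "RC",
                                 genome_ids = c("gA", "gB", "gC", "gD", "gE")))
  expect_equal(paired_sum(single, 1, 1), 0.7)
})

test_that("phase 2 resolves candidate sets by mate evidence; ties fall through", {
  tax <- toy_taxonomy()
  p <- classify_params(beta = 0.25, mode = "paired")
  gids <- c("gA", "gB", "gC", "gD", "gE")
  cand <- structure(list(I = c(1L, 3L), M = 0.8), class = "candidate_set")

  # gA's paired sum 1.2 beats gC's 0.9 -> gA's species, phase 2
  m <- paired_set(v1F = c(0.8, 0, 0.79, 0, 0), v1RC = rep(0, 5),
                  v2F = rep(0, 5), v2RC = c(0.4, 0, 0.11, 0, 0))
  res <- phase2(cand, m, 1, p, tax$tree, tax$map, gids, "rd")
  expect_equal(res$status, "classified")
  expect_equal(res$taxid, 30L)
  expect_equal(res$phase, "2")

  # same-species candidates classify regardless of the sums
  cand_ab <- structure(list(I = c(1L, 2L), M = 0.8), class = "candidate_set")
  m2 <- paired_set(v1F = c(0.8, 0.8, 0, 0, 0), v1RC = rep(0, 5),
                   v2F = rep(0, 5), v2RC = c(0.3, 0.3, 0, 0, 0))
  res <- phase2(cand_ab, m2, 1, p, tax$tree, tax$map, gids, "rd")
  expect_equal(res$status, "classified")
  expect_equal(res$taxid, 30L)

  # equal sums across species -> unresolved candidate set
  m3 <- paired_set(v1F = c(0.8, 0, 0.8, 0, 0), v1RC = rep(0, 5),
                   v2F = rep(0, 5), v2RC = c(0.3, 0, 0.3, 0, 0))
  res <- phase2(cand, m3, 1, p, tax$tree, tax$map, gids, "rd")
  expect_s3_class(res, "candidate_set")
  expect_error(phase2(structure(list(I = integer(0), M = 1),
                                class = "candidate_set"),
                      m3, 1, p, tax$tree, tax$map, gids), "empty candidate")
})

test_that("phase 3 scans all genomes and can overturn the phase-1 ranking", {
  tax <- toy_taxonomy()
  p <- classify_params(beta = 0.25, mode = "paired")
  gids <- c("gA", "gB", "gC", "gD", "gE")
  # phase-1 candidates were {gA, gC} but gD (outside) has the top paired sum
  m <- paired_set(v1F = c(0.80, 0, 0.80, 0.70, 0), v1RC = rep(0, 5),
                  v2F = rep(0, 5), v2RC = c(0.10, 0, 0.10, 0.90, 0))
  res <- phase3(m, 1, p, tax$tree, tax$map, gids, "rd")
  expect_equal(res$status, "classified")
  expect_equal(res$taxid, 32L)   # gD's species
  expect_equal(res$phase, "3")
})

test_that("lineage fallback classifies genus-level ties and reports phylum-level ones", {
  tax <- toy_taxonomy()
  gids <- c("gA", "gB", "gC", "gD", "gE")
  # tie between gA (species 30) and gC (species 31), same genus 20
  m <- paired_set(v1F = c(0.8, 0, 0.8, 0, 0), v1RC = rep(0, 5),
                  v2F = rep(0, 5), v2RC = c(0.3, 0, 0.3, 0, 0))
  p_fb <- classify_params(beta = 0.25, mode = "paired", fallback = TRUE)
  res <- phase3(m, 1, p_fb, tax$tree, tax$map, gids, "rd")
  expect_equal(res$status, "classified")
  expect_equal(res$taxid, 20L)
  expect_equal(res$rank, "genus")
  expect_equal(res$phase, "fallback")

  p_nofb <- classify_params(beta = 0.25, mode = "paired", fallback = FALSE)
  res <- phase3(m, 1, p_nofb, tax$tree, tax$map, gids, "rd")
  expect_equal(res$status, "ambiguous")
  expect_equal(res$tied, "30,31")

  # tie across the two phyla stays ambiguous even with fallback
  m2 <- paired_set(v1F = c(0.8, 0, 0, 0, 0.8), v1RC = rep(0, 5),
                   v2F = rep(0, 5), v2RC = c(0.3, 0, 0, 0, 0.3))
  res <- phase3(m2, 1, p_fb, tax$tree, tax$map, gids, "rd")
  expect_equal(res$status, "ambiguous")
})

test_that("classification is deterministic, phase-ordered, and writes round-trip TSV", {
  tax <- toy_taxonomy()
  gids <- c("gA", "gB", "gC", "gD", "gE")
  vals <- rbind(c(0.9, 0.1, 0.1, 0.1, 0.1),     # phase 1
                c(0.80, 0.1, 0.79, 0.1, 0.1),   # needs re-examination
                c(0.2, 0.2, 0.2, 0.2, 0.2))     # below beta
  m <- list(`1F` = toy_matrix(vals, "1F", genome_ids = gids),
            `1RC` = toy_matrix(vals * 0, "1RC", genome_ids = gids),
            `2F` = toy_matrix(vals * 0, "2F", genome_ids = gids),
            `2RC` = toy_matrix(rbind(c(0, 0, 0, 0, 0),
                                     c(0.4, 0, 0.11, 0, 0),
                                     c(0, 0, 0, 0, 0)), "2RC", genome_ids = gids))
  p <- classify_params(beta = 0.25, mode = "paired")
  a <- classify_reads(m, tax$tree, tax$map, p)
  expect_equal(a$status, c("classified", "classified", "not_classified"))
  expect_equal(a$phase, c("1", "2", NA))
  expect_identical(a, classify_reads(m, tax$tree, tax$map, p))
  # statuses partition the read set
  expect_equal(nrow(a), 3L)

  tsv <- tempfile(fileext = ".tsv")
  write_assignments(a, tsv)
  b <- read_assignments(tsv)
  expect_equal(b$status, a$status)
  expect_equal(b$taxid, a$taxid)
  expect_equal(b$score, a$score)
})

test_that("raising beta never classifies more reads", {
  tax <- toy_taxonomy()
  gids <- c("gA", "gB", "gC", "gD", "gE")
  set.seed(808)
  vals <- matrix(runif(40 * 5, 0, 0.6), 40, 5)
  m <- list(`1F` = toy_matrix(vals, "1F", genome_ids = gids),
            `1RC` = toy_matrix(vals * 0.5, "1RC", genome_ids = gids),
            `2F` = toy_matrix(vals * 0.3, "2F", genome_ids = gids),
            `2RC` = toy_matrix(vals * 0.8, "2RC", genome_ids = gids))
  classified_at <- function(beta) {
    a <- classify_reads(m, tax$tree, tax$map,
                        classify_params(beta = beta, mode = "paired"))
    a$read_id[a$status == "classified"]
  }
  sets <- lapply(c(0.15, 0.25, 0.40), classified_at)
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
  expect_gt(length(sets[[1]]), length(sets[[3]]))
})

test_that("zero tolerance with a strictly unique maximizer classifies at genome rank", {
  tax <- toy_taxonomy()
  gids <- c("gA", "gB", "gC", "gD", "gE")
  rows <- list(`1F` = c(0.81, 0.80, 0.1, 0.1, 0.1), `1RC` = rep(0, 5),
               `2F` = rep(0, 5), `2RC` = rep(0, 5))
  p <- classify_params(beta = 0.25, tolerance = 0, min_rank = "genome",
                       mode = "paired")
  res <- phase1(rows, p, tax$tree, tax$map, gids, "rd")
  expect_equal(res$status, "classified")
  expect_equal(res$taxid, 40L)    # the genome leaf itself
  expect_equal(res$rank, "genome")
  expect_equal(res$phase, "1")
})
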