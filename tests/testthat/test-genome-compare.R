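test_that("quality filter is inclusive at both published boundaries", {
  rec <- tibble::tibble(
    genome_id = c("a", "b", "c", "d"),
    completeness = c(80, 79.9, 95, 95),
    contamination = c(10, 5, 10.1, 0)
  )
  kept <- filter_quality(rec)
  expect_setequal(kept$genome_id, c("a", "d"))
})

test_that("genome score matches its closed form and monotonicity", {
  rec <- tibble::tibble(
    genome_id = c("a", "b"),
    completeness = c(100, 80), contamination = c(0, 10),
    strain_heterogeneity = c(0, 0), contig_N50 = c(1e5, 1e4)
  )
  expect_equal(score_genome(rec)$score, c(102.5, 32.0))
  # increasing contamination strictly decreases the score
  xs <- seq(0, 15, by = 0.5)
  s <- score_genome(tibble::tibble(
    genome_id = as.character(xs), completeness = 90, contamination = xs,
    strain_heterogeneity = 40, contig_N50 = 1e5))$score
  expect_true(all(diff(s) < 0))
  rec$contig_N50[1] <- 0
  expect_error(score_genome(rec), "N50")
})

test_that("sketches are canonical, deterministic and size-bounded", {
  set.seed(21)
  s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
             collapse = "")
  sk <- sketch_genome(s)
  expect_identical(sk$hashes, sketch_genome(s)$hashes)
  expect_identical(sketch_genome(revcomp_chr(s))$hashes, sk$hashes)
  expect_true(all(diff(sk$hashes) > 0))
  expect_equal(length(sketch_genome(s, s = 100)$hashes), 100)
  expect_error(sketch_genome("ACGT", k = 21), "shorter")
  # non-ACGT k-mers are skipped
  skn <- sketch_genome(paste0(substr(s, 1, 100), "N",
                              substr(s, 101, 200)))
  expect_lt(length(skn$hashes), 181)
})

test_that("sketch distances follow the Mash closed form", {
  set.seed(22)
  s <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
             collapse = "")
  sk <- sketch_genome(s)
  d_self <- sketch_distance(sk, sk)
  expect_equal(d_self$jaccard, 1)
  expect_equal(d_self$distance, 0)
  expect_equal(d_self$pid, 100)
  # disjoint genomes cap at distance 1
  s2 <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
              collapse = "")
  d2 <- sketch_distance(sk, sketch_genome(s2))
  expect_equal(d2$distance, 1, tolerance = 1e-12)
  # direct evaluation of -(1/21) ln(2j/(1+j)) at j = 0.5
  expect_equal(round(magcentric:::mash_from_jaccard(0.5, 21), 6),
               0.019308)
  expect_error(sketch_distance(sk, sketch_genome(s, k = 15)),
               "mismatched")
})

test_that("MinHash Jaccard tracks the exact string-set oracle", {
  g <- simulate_genomes(c(2), genome_length = 2000, d_secondary = 0.02,
                        seed = 23)
  a <- g$sequences[[1]]
  b <- g$sequences[[2]]
  exact <- oracle_jaccard(a, b)
  expect_equal(kmer_jaccard(a, b), exact, tolerance = 1e-12)
  # subsampled sketch estimate stays close
  ja <- magcentric:::cpp_jaccard(sketch_genome(a, s = 500)$hashes,
                                 sketch_genome(b, s = 500)$hashes, 500)
  expect_lt(abs(ja - exact), 0.05)
})

test_that("dereplication matches the brute-force threshold oracle", {
  g <- simulate_genomes(rep(c(1, 2, 3), times = c(4, 4, 2)),
                        genome_length = 3000, seed = 24)  # 18 genomes
  dr <- dereplicate(g$quality, g$sequences)
  ids <- dr$genome_id
  n <- length(ids)
  dmat <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      jac <- oracle_jaccard(g$sequences[[ids[i]]], g$sequences[[ids[j]]])
      dmat[i, j] <- dmat[j, i] <-
        magcentric:::mash_from_jaccard(jac, 21)
    }
  }
  expect_true(same_partition(dr$secondary_cluster,
                             oracle_threshold_clusters(dmat, 0.01)))
  expect_true(same_partition(dr$primary_cluster,
                             oracle_threshold_clusters(dmat, 0.10)))
})

test_that("winners are the highest-scoring genome of each cluster", {
  g <- simulate_genomes(c(2), genome_length = 500, d_secondary = 0,
                        seed = 25)
  dr <- dereplicate(g$quality, g$sequences)
  expect_equal(length(unique(dr$secondary_cluster)), 1)
  expect_equal(sum(dr$is_winner), 1)
  expect_equal(dr$genome_id[dr$is_winner],
               dr$genome_id[which.max(dr$score)])
  # deterministic tie-break on equal scores
  q <- g$quality
  q$completeness <- 90
  q$contamination <- 0
  q$strain_heterogeneity <- 0
  q$contig_N50 <- 1000L
  dr2 <- dereplicate(q, g$sequences)
  expect_equal(dr2$genome_id[dr2$is_winner], sort(q$genome_id)[1])
})

test_that("cluster-size summary reproduces the published totals", {
  summ <- cluster_size_summary(mag_cluster_size_distribution())
  totals <- summ[is.na(summ$cluster_size), ]
  expect_equal(totals$n_clusters, 850)
  expect_equal(totals$n_genomes, 1200)
  expect_equal(summ$pct_genomes[summ$cluster_size == 1 &
                                  !is.na(summ$cluster_size)], 51.33)
  expect_equal(summ$n_genomes[summ$cluster_size == 2 &
                                !is.na(summ$cluster_size)], 330)
  all1 <- cluster_size_summary(
    tibble::tibble(cluster_size = 1L, n_clusters = 10L))
  expect_equal(all1$pct_genomes[1], 100)
})

test_that("minimum-distance novelty search excludes self-hits", {
  g <- simulate_genomes(c(1, 1, 1), genome_length = 1500,
                        seed = 26)
  sk <- sketch_genomes(g$sequences)
  hit <- min_distance_to_set(sk[1], c(sk[2:3], sk[1]))
  expect_false(hit$per_query$subject_id == names(sk)[1])
  ident <- min_distance_to_set(sk[1], setNames(sk[1], "copy"))
  expect_equal(ident$per_query$min_distance, 0)
  expect_equal(ident$per_query$max_pid, 100)
  # unrelated random genomes stay below 90 percent identity
  novel <- min_distance_to_set(sk, sk)
  expect_true(all(novel$per_query$max_pid < 90))
  expect_equal(novel$bin_counts$n_queries[
    novel$bin_counts$pid_threshold == 90], 0L)
  expect_error(min_distance_to_set(sk, list()), "empty reference")
})

test_that("sketch distance is a symmetric premetric on genomes", {
  g <- simulate_genomes(c(2, 1), genome_length = 1000,
                        d_secondary = 0.01, seed = 27)
  sk <- sketch_genomes(g$sequences)
  d <- mash_distance_matrix(sk)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})
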