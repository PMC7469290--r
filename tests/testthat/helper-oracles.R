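# Independent pure-R oracles used to check the compiled implementations,
# plus a cached run of the full synthetic pipeline shared across files.

revcomp_chr <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# exact canonical k-mer set by string enumeration
oracle_kmer_set <- function(seq, k = 21) {
  n <- nchar(seq)
  fwd <- substring(seq, seq_len(n - k + 1), k:n)
  rc_full <- revcomp_chr(seq)
  i <- seq_len(n - k + 1)
  rc <- substring(rc_full, n - i - k + 2, n - i + 1)
  unique(pmin(fwd, rc))
}

oracle_jaccard <- function(a, b, k = 21) {
  sa <- oracle_kmer_set(a, k)
  sb <- oracle_kmer_set(b, k)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

# per-position mismatch fraction between equal-length sequences
oracle_mismatch_rate <- function(a, b) {
  mean(strsplit(a, "", fixed = TRUE)[[1]] !=
         strsplit(b, "", fixed = TRUE)[[1]])
}

# brute-force PERMANOVA partitioning (double loops, no shortcuts)
oracle_permanova <- function(d, groups) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  lv <- unique(groups)
  a <- length(lv)
  ss_total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) ss_total <- ss_total + d2[i, j]
  }
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in lv) {
    idx <- which(groups == g)
    s <- 0
    for (i in idx) for (j in idx) if (i < j) s <- s + d2[i, j]
    ss_within <- ss_within + s / length(idx)
  }
  ss_between <- ss_total - ss_within
  list(F = (ss_between / (a - 1)) / (ss_within / (n - a)),
       R2 = ss_between / ss_total)
}

# brute-force threshold clustering: connected components of the graph
# with edges d < h (equals average linkage when clusters are separated)
oracle_threshold_clusters <- function(d, h) {
  n <- nrow(d)
  labels <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (d[i, j] < h && labels[i] != labels[j]) {
          labels[labels == labels[j]] <- labels[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  as.integer(factor(labels, levels = unique(labels)))
}

# two partitions describe the same clustering
same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    all(tapply(a, b, function(x) length(unique(x)) == 1))
}

# NB counts under the crossover design with no diet effect
make_nb_null <- function(nf, md, alpha = 0.1) {
  an <- unique(md$animal_id)
  a <- stats::setNames(rnorm(length(an), 0, 0.3), an)
  pp <- stats::setNames(rnorm(4, 0, 0.15), as.character(1:4))
  dep <- rnorm(nrow(md), 0, 0.3)
  mu0 <- exp(rnorm(nf, log(500), 1))
  m <- sapply(seq_len(nrow(md)), function(j) {
    mu <- mu0 * exp(dep[j] + a[[md$animal_id[j]]] +
                      pp[[as.character(md$period[j])]])
    if (alpha > 0) rnbinom(nf, mu = mu, size = 1 / alpha) else
      rpois(nf, mu)
  })
  rownames(m) <- sprintf("f%04d", seq_len(nf))
  colnames(m) <- md$sample_id
  m
}

# one full synthetic study pushed through the whole pipeline, cached
.pipeline_cache <- new.env(parent = emptyenv())
study_pipeline <- function() {
  if (!is.null(.pipeline_cache$res)) return(.pipeline_cache$res)
  st <- simulate_study(seed = 7)
  md <- filter_samples(st$metadata)
  corrected <- correct_bias(st$counts, st$contigs)
  abundance <- aggregate_to_mag(corrected, st$contigs)[, md$sample_id]
  da <- nb_lrt(abundance, md)
  sig <- da_features(da)
  ko_sample <- ko_per_sample(st$ko_matrix, abundance)
  ko_da <- nb_lrt(ko_sample, md)
  contrib <- taxon_contribution(st$ko_matrix, abundance, st$taxonomy,
                                md, st$pathway_map,
                                da_mags = sig$features$feature_id)
  scen <- classify_scenarios(ko_da, ko_sample, contrib, st$pathway_map,
                             md)
  .pipeline_cache$res <- list(
    study = st, metadata = md, corrected = corrected,
    abundance = abundance, da = da, sig = sig, ko_sample = ko_sample,
    ko_da = ko_da, contrib = contrib, scenarios = scen
  )
  .pipeline_cache$res
}
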