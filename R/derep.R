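#' Filter genomes on completeness and contamination
#'
#' Keeps genomes with completeness at or above `min_completeness` percent
#' and contamination at or below `max_contamination` percent (both
#' boundaries inclusive), the standard high-quality MAG gate.
#'
#' @param records Data frame of genome quality records with columns
#'   `genome_id`, `completeness`, `contamination`.
#' @param min_completeness Minimum completeness percent (default 80).
#' @param max_contamination Maximum contamination percent (default 10).
#' @return The retained records as a tibble (possibly empty).
#' @export
filter_quality <- function(records, min_completeness = 80,
                           max_contamination = 10) {
  records <- as_tibble(records)
  stopifnot(all(c("completeness", "contamination") %in% colnames(records)))
  out <- records[records$completeness >= min_completeness &
                   records$contamination <= max_contamination, ,
                 drop = FALSE]
  if (nrow(out) == 0) message("no genomes pass the quality filter")
  out
}

#' Dereplication quality score
#'
#' Scores each genome as
#' `S = completeness - 5 * contamination +
#'  contamination * (strain_heterogeneity / 100) + 0.5 * log10(N50)`,
#' so contamination is penalised (less so when it is strain
#' heterogeneity, i.e. closely related contamination) and contiguity is
#' mildly rewarded. Within each secondary cluster the highest-scoring
#' genome is retained as the cluster winner.
#'
#' @param records Data frame with columns `completeness`,
#'   `contamination`, `strain_heterogeneity`, `contig_N50`.
#' @return The input tibble with a `score` column appended.
#' @export
score_genome <- function(records) {
  records <- as_tibble(records)
  need <- c("completeness", "contamination", "strain_heterogeneity",
            "contig_N50")
  miss <- setdiff(need, colnames(records))
  if (length(miss) > 0) {
    abort(sprintf("missing quality fields: %s", paste(miss, collapse = ", ")))
  }
  if (any(records$contig_N50 < 1)) abort("contig_N50 must be >= 1")
  records$score <- records$completeness -
    5 * records$contamination +
    records$contamination * (records$strain_heterogeneity / 100) +
    0.5 * log10(records$contig_N50)
  records
}

# average-linkage clustering of a distance matrix cut at height h;
# returns integer labels renumbered in order of first appearance
threshold_clusters <- function(d, h) {
  n <- nrow(d)
  if (n == 1) return(1L)
  cl <- cutree(hclust(as.dist(d), method = "average"), h = h)
  as.integer(factor(cl, levels = unique(cl)))
}

#' Two-stage ANI dereplication of genomes
#'
#' Reproduces the dereplication workflow used for MAG catalogues:
#' genomes are first grouped into primary clusters by average-linkage
#' hierarchical clustering of Mash distances cut at `1 - primary_ani`
#' (default 90% ANI), then each primary cluster is split into secondary
#' clusters with a higher-resolution distance - here the Mash transform
#' of the exact full k-mer Jaccard (no subsampling) - cut at
#' `1 - secondary_ani` (default 99% ANI). One winner per secondary
#' cluster is retained: the genome with the highest quality score (ties
#' broken by lexicographic `genome_id`).
#'
#' @param records Quality records (see [score_genome()]) for the genomes
#'   to dereplicate; `genome_id` must match `names(sequences)`. Records
#'   are assumed to be quality-filtered already (see [filter_quality()]).
#' @param sequences Named character vector of genome sequences.
#' @param primary_ani Primary-cluster ANI threshold (default 0.90).
#' @param secondary_ani Secondary-cluster ANI threshold (default 0.99).
#' @param k K-mer length for sketching (default 21).
#' @param s Sketch size for the primary Mash stage (default 1000,
#'   the dereplication tool's own Mash default; the secondary stage
#'   always uses the exact full k-mer sets).
#' @param seed Hash seed (default 42).
#' @param sketches Optional pre-computed named list of sketches (from
#'   [sketch_genomes()]); computed from `sequences` when `NULL`.
#' @return Tibble with one row per genome: `genome_id`,
#'   `primary_cluster`, `secondary_cluster` (id of the form
#'   `"<primary>_<k>"`), `score`, `is_winner`.
#' @export
dereplicate <- function(records, sequences, primary_ani = 0.90,
                        secondary_ani = 0.99, k = 21, s = 1000, seed = 42,
                        sketches = NULL) {
  records <- score_genome(records)
  ids <- as.character(records$genome_id)
  check_no_duplicates(ids, "genome_id")
  if (!all(ids %in% names(sequences))) {
    abort("every genome_id needs a sequence (missing sketch input)")
  }
  sequences <- sequences[ids]
  if (is.null(sketches)) {
    sketches <- sketch_genomes(sequences, k = k, s = s, seed = seed)
  } else {
    if (!all(ids %in% names(sketches))) abort("missing sketch")
    sketches <- sketches[ids]
  }

  dmat <- mash_distance_matrix(sketches)
  primary <- threshold_clusters(dmat, h = 1 - primary_ani)

  # secondary stage: exact full k-mer sets within each primary cluster
  full <- sketch_genomes(sequences, k = k, s = Inf, seed = seed)
  secondary <- character(length(ids))
  for (p in unique(primary)) {
    idx <- which(primary == p)
    if (length(idx) == 1) {
      secondary[idx] <- sprintf("%d_1", p)
      next
    }
    dd <- cpp_pairwise_mash(lapply(full[idx], `[[`, "hashes"),
                            as.integer(k), Inf)
    sub <- threshold_clusters(dd, h = 1 - secondary_ani)
    secondary[idx] <- sprintf("%d_%d", p, sub)
  }

  out <- tibble(
    genome_id = ids,
    primary_cluster = primary,
    secondary_cluster = secondary,
    score = records$score
  )
  out <- out |>
    dplyr::group_by(.data$secondary_cluster) |>
    dplyr::mutate(is_winner = seq_along(.data$genome_id) ==
                    order(-.data$score, .data$genome_id)[1]) |>
    dplyr::ungroup()
  out
}

#' Cluster-size summary of a dereplication run
#'
#' Summarises how many clusters and genomes fall in each cluster size,
#' with the percentage of all genomes (2 decimal places) and a totals
#' row (`cluster_size = NA`), matching the usual presentation of MAG
#' dereplication results.
#'
#' @param x Either a dereplication result (tibble with a
#'   `secondary_cluster` column) or a size distribution tibble with
#'   columns `cluster_size` and `n_clusters` (e.g.
#'   [mag_cluster_size_distribution()]).
#' @return Tibble with columns `cluster_size`, `n_clusters`, `n_genomes`,
#'   `pct_genomes`, sorted by decreasing size, totals row last.
#' @export
cluster_size_summary <- function(x) {
  x <- as_tibble(x)
  if ("secondary_cluster" %in% colnames(x)) {
    sizes <- table(x$secondary_cluster)
    dist <- as_tibble(table(size = as.integer(sizes)))
    colnames(dist) <- c("cluster_size", "n_clusters")
    dist$cluster_size <- as.integer(dist$cluster_size)
  } else {
    stopifnot(all(c("cluster_size", "n_clusters") %in% colnames(x)))
    dist <- x[, c("cluster_size", "n_clusters")]
  }
  dist <- dist[order(-dist$cluster_size), ]
  dist$n_genomes <- dist$cluster_size * dist$n_clusters
  total_genomes <- sum(dist$n_genomes)
  dist$pct_genomes <- round(100 * dist$n_genomes / total_genomes, 2)
  totals <- tibble(
    cluster_size = NA_integer_,
    n_clusters = sum(dist$n_clusters),
    n_genomes = total_genomes,
    pct_genomes = round(sum(dist$pct_genomes), 2)
  )
  dplyr::bind_rows(dist, totals)
}
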