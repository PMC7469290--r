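#' Expand a cluster-size distribution into per-cluster sizes
#'
#' @param distribution Tibble with columns `cluster_size`, `n_clusters`
#'   (e.g. [mag_cluster_size_distribution()]).
#' @return Integer vector with one entry (its size) per secondary cluster.
#' @export
expand_cluster_sizes <- function(distribution) {
  rep(as.integer(distribution$cluster_size),
      times = as.integer(distribution$n_clusters))
}

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute each position independently with probability p, drawing one
# of the three other bases uniformly (substitution-only mutation model)
mutate_sequence <- function(seq, p) {
  if (p <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(bases)) < p)
  if (length(hit) > 0) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    pick <- sample.int(3L, length(hit), replace = TRUE)
    bases[hit] <- unlist(Map(function(b, i) alt[[b]][i], bases[hit], pick),
                         use.names = FALSE)
  }
  paste(bases, collapse = "")
}

#' Simulate clustered genomes with planted ANI structure
#'
#' Generates genomes organised in a two-level cluster hierarchy that
#' mirrors primary (90% ANI) / secondary (99% ANI) dereplication.
#' Primary-cluster ancestors are mutated copies of a common random root
#' at rate `d_primary` (pairwise divergence about `2 d_primary`, well
#' above the 10% primary cut). Secondary-cluster ancestors within a
#' primary cluster diverge from the primary ancestor at rate
#' `d_between_secondary` (pairwise about 6% by default, between the two
#' cuts). Genomes within a secondary cluster are mutated at
#' `d_secondary / 2` from their ancestor so that pairwise divergence is
#' approximately `d_secondary` (default 0.5%, under the 1% secondary
#' cut). Substitution-only: no indels, so ANI is analytically controlled.
#'
#' Quality metrics are drawn to straddle the 80/10 quality gate:
#' completeness uniform on `[70, 100]`, contamination uniform on
#' `[0, 15]`, strain heterogeneity uniform on `[0, 30]`.
#'
#' @param sizes Integer vector: size of each secondary cluster (see
#'   [expand_cluster_sizes()]).
#' @param primary_of Integer vector mapping each secondary cluster to a
#'   primary cluster; default gives each secondary cluster its own
#'   primary cluster.
#' @param genome_length Genome length in bp.
#' @param d_primary Substitution rate from the root to each primary
#'   ancestor (default 0.12).
#' @param d_secondary Target pairwise divergence within a secondary
#'   cluster (default 0.005).
#' @param d_between_secondary Substitution rate from primary ancestor to
#'   each secondary ancestor (default 0.03).
#' @param seed Optional integer seed (`set.seed`).
#' @return List with `sequences` (named character), `quality` (tibble:
#'   `genome_id`, `completeness`, `contamination`,
#'   `strain_heterogeneity`, `contig_N50`, `genome_size`) and `truth`
#'   (tibble: `genome_id`, `primary_cluster`, `secondary_cluster`).
#' @export
simulate_genomes <- function(sizes, primary_of = seq_along(sizes),
                             genome_length = 20000, d_primary = 0.12,
                             d_secondary = 0.005,
                             d_between_secondary = 0.03, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- as.integer(sizes)
  if (any(sizes < 1)) abort("cluster sizes must be >= 1")
  if (length(primary_of) != length(sizes)) {
    abort("primary_of must have one entry per secondary cluster")
  }
  if (genome_length < 21) abort("genome_length shorter than the k-mer size")
  if (!(d_primary > d_secondary)) abort("need d_primary > d_secondary")

  n_genomes <- sum(sizes)
  root <- random_sequence(genome_length)
  primary_ids <- sort(unique(primary_of))
  prim_anc <- setNames(
    lapply(primary_ids, function(p) mutate_sequence(root, d_primary)),
    as.character(primary_ids)
  )

  sequences <- character(n_genomes)
  truth <- vector("list", length(sizes))
  g <- 0L
  for (ci in seq_along(sizes)) {
    p <- primary_of[[ci]]
    # lone secondary cluster in its primary cluster: ancestor is the
    # primary ancestor itself; otherwise diverge below the primary cut
    anc <- if (sum(primary_of == p) == 1) {
      prim_anc[[as.character(p)]]
    } else {
      mutate_sequence(prim_anc[[as.character(p)]], d_between_secondary)
    }
    for (m in seq_len(sizes[[ci]])) {
      g <- g + 1L
      sequences[g] <- mutate_sequence(anc, d_secondary / 2)
    }
    truth[[ci]] <- tibble(
      genome_id = sprintf("MAG%04d", (g - sizes[[ci]] + 1L):g),
      primary_cluster = p,
      secondary_cluster = ci
    )
  }
  names(sequences) <- sprintf("MAG%04d", seq_len(n_genomes))
  truth <- dplyr::bind_rows(truth)

  quality <- tibble(
    genome_id = names(sequences),
    completeness = runif(n_genomes, 70, 100),
    contamination = runif(n_genomes, 0, 15),
    strain_heterogeneity = runif(n_genomes, 0, 30),
    contig_N50 = pmax(1L, as.integer(round(genome_length *
                                             runif(n_genomes, 0.2, 0.8)))),
    genome_size = as.integer(genome_length)
  )
  list(sequences = sequences, quality = quality, truth = truth)
}

#' Catalogue-shaped genome simulation preset
#'
#' Convenience wrapper generating the full published cluster-size
#' distribution (1200 genomes in 850 secondary clusters, see
#' [mag_cluster_size_distribution()]) at a genome length where the
#' within-cluster ANI is tightly concentrated, so two-stage
#' dereplication recovers the planted clustering exactly.
#'
#' @param seed Optional integer seed.
#' @param genome_length Genome length in bp (default 4000).
#' @return See [simulate_genomes()].
#' @export
simulate_genomes_preset <- function(seed = NULL, genome_length = 4000) {
  simulate_genomes(expand_cluster_sizes(mag_cluster_size_distribution()),
                   genome_length = genome_length, seed = seed)
}
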