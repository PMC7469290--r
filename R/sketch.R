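#' MinHash sketch of a genome
#'
#' Hashes every distinct canonical 21-mer (lexicographic minimum of a
#' k-mer and its reverse complement) with a seeded 64-bit mixing hash and
#' keeps the `s` smallest values. The fraction of shared values between
#' two sketches estimates the Jaccard similarity of the underlying k-mer
#' sets, from which a Mash distance and an average nucleotide identity
#' are derived. k-mers containing non-ACGT symbols are skipped.
#'
#' @param sequence A single nucleotide sequence (character scalar).
#' @param k K-mer length (default 21, maximum 31).
#' @param s Sketch size: number of smallest hash values retained
#'   (default 100000). `Inf` keeps every distinct k-mer hash, giving the
#'   exact Jaccard on comparison.
#' @param seed Integer seed of the hash function (default 42). Sketches
#'   are only comparable for equal `k`, `s` and `seed`.
#' @return An object of class `mag_sketch`: list with elements `k`, `s`,
#'   `seed` and `hashes` (strictly increasing numeric vector).
#' @export
sketch_genome <- function(sequence, k = 21, s = 1e5, seed = 42) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < k) {
    abort(sprintf("sequence length %d is shorter than k = %d",
                  nchar(sequence), k))
  }
  if (k > 31) abort("k must be <= 31")
  hashes <- cpp_sketch(sequence, as.integer(k), as.numeric(s),
                       as.numeric(seed))
  structure(list(k = as.integer(k), s = as.numeric(s),
                 seed = as.numeric(seed), hashes = hashes),
            class = "mag_sketch")
}

#' @export
print.mag_sketch <- function(x, ...) {
  cat(sprintf("<mag_sketch> k=%d s=%s seed=%d hashes=%d\n",
              x$k, format(x$s), x$seed, length(x$hashes)))
  invisible(x)
}

#' Sketch a set of genomes
#'
#' @param sequences Named character vector of sequences.
#' @inheritParams sketch_genome
#' @return Named list of `mag_sketch` objects.
#' @export
sketch_genomes <- function(sequences, k = 21, s = 1e5, seed = 42) {
  stopifnot(!is.null(names(sequences)))
  purrr::map(as.list(sequences), sketch_genome, k = k, s = s, seed = seed)
}

#' Jaccard, Mash distance and percent identity between two sketches
#'
#' The Jaccard similarity j is estimated by the merged bottom-s
#' procedure: among the s smallest distinct hashes of the union of the
#' two sketches, the fraction present in both. The Mash distance is
#' `d = min(1, -(1/k) ln(2j / (1 + j)))` and percent identity is
#' `(1 - d) * 100`; `j = 0` maps to `d = 1`.
#'
#' @param a,b `mag_sketch` objects with identical `k`, `s` and `seed`.
#' @return One-row tibble with columns `jaccard`, `distance`, `pid`.
#' @export
sketch_distance <- function(a, b) {
  stopifnot(inherits(a, "mag_sketch"), inherits(b, "mag_sketch"))
  if (a$k != b$k || !identical(a$s, b$s) || a$seed != b$seed) {
    abort("sketches have mismatched k, s or seed")
  }
  j <- cpp_jaccard(a$hashes, b$hashes, a$s)
  d <- mash_from_jaccard(j, a$k)
  tibble(jaccard = j, distance = d, pid = (1 - d) * 100)
}

mash_from_jaccard <- function(j, k) {
  ifelse(j <= 0, 1, pmin(1, pmax(0, -log(2 * j / (1 + j)) / k)))
}

#' Exact k-mer Jaccard similarity of two sequences
#'
#' Compares the full canonical k-mer sets (no subsampling); used as the
#' high-resolution distance in the secondary dereplication stage and as
#' the oracle against which sketch estimates are tested.
#'
#' @param a,b Nucleotide sequences (character scalars).
#' @inheritParams sketch_genome
#' @return Exact Jaccard similarity in `[0, 1]`.
#' @export
kmer_jaccard <- function(a, b, k = 21, seed = 42) {
  sa <- sketch_genome(a, k = k, s = Inf, seed = seed)
  sb <- sketch_genome(b, k = k, s = Inf, seed = seed)
  cpp_jaccard(sa$hashes, sb$hashes, Inf)
}

#' All-pairs Mash distance matrix over a list of sketches
#'
#' @param sketches Named list of `mag_sketch` objects sharing `k`, `s`
#'   and `seed`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
mash_distance_matrix <- function(sketches) {
  stopifnot(length(sketches) >= 1, !is.null(names(sketches)))
  ks <- unique(vapply(sketches, function(x) x$k, numeric(1)))
  ss <- unique(vapply(sketches, function(x) x$s, numeric(1)))
  if (length(ks) != 1 || length(ss) != 1) {
    abort("all sketches must share k and s")
  }
  d <- cpp_pairwise_mash(lapply(sketches, `[[`, "hashes"),
                         as.integer(ks), as.numeric(ss))
  dimnames(d) <- list(names(sketches), names(sketches))
  d
}

#' Minimum distance of each query genome to a reference set
#'
#' For each query sketch, finds the nearest reference genome by Mash
#' distance and reports the maximum percent identity. When query and
#' reference sets share genome ids, self-comparisons are excluded, so
#' the same set can be compared against itself to measure within-set
#' divergence. Counts of queries reaching each percent-identity
#' threshold summarise how much of the query set is "novel" relative to
#' the references.
#'
#' @param queries,references Named lists of `mag_sketch` objects.
#' @param pid_bins Percent-identity thresholds for the binned counts.
#' @return List with `per_query` (tibble: `query_id`, `subject_id`,
#'   `min_distance`, `max_pid`) and `bin_counts` (tibble: `pid_threshold`,
#'   `n_queries` with `max_pid >=` threshold).
#' @export
min_distance_to_set <- function(queries, references,
                                pid_bins = c(90, 95, 99, 100)) {
  if (length(references) == 0) abort("empty reference set")
  if (length(queries) == 0) abort("empty query set")
  qn <- names(queries)
  rn <- names(references)
  per <- purrr::map_dfr(qn, function(q) {
    refs <- references[setdiff(rn, q)]
    if (length(refs) == 0) abort("no references left after self-exclusion")
    ds <- vapply(refs, function(r) sketch_distance(queries[[q]], r)$distance,
                 numeric(1))
    i <- which.min(ds)
    tibble(query_id = q, subject_id = names(refs)[i],
           min_distance = ds[[i]], max_pid = (1 - ds[[i]]) * 100)
  })
  bins <- tibble(
    pid_threshold = pid_bins,
    n_queries = vapply(pid_bins, function(t) sum(per$max_pid >= t),
                       integer(1))
  )
  list(per_query = per, bin_counts = bins)
}
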