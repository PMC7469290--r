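#' Correct contig counts for GC and length bias
#'
#' Removes the dependence of read counts on contig GC content and
#' length within each sample. Counts are first scaled to a
#' count-per-kilobase rate, contigs are stratified into GC bins of
#' equal frequency (ties broken by contig id for determinism), and the
#' per-bin median rates - anchored at the bin median GC - are
#' interpolated into a smooth per-sample GC-bias curve on the log
#' scale; each rate is divided by the curve at its contig's GC. Rates
#' are rescaled by length and the sample total is restored, so
#' correction never changes library size. Because the curve is built
#' from bin medians, it is insensitive to a minority of genuinely
#' shifted (differentially abundant) contigs, and a sample with no GC
#' trend is returned unchanged; after correction on data with a
#' planted monotone GC bias, the per-sample Spearman correlation
#' between counts and GC is near zero.
#'
#' @param contig_counts Contig-by-sample count matrix (or data frame,
#'   first column contig ids).
#' @param contigs Contig records: tibble with `contig_id`, `mag_id`,
#'   `length` (bp), `gc` (fraction).
#' @param n_bins Number of GC strata (default 10, i.e. deciles).
#' @return Corrected count matrix, same dimensions and totals.
#' @export
correct_bias <- function(contig_counts, contigs, n_bins = 10) {
  m <- as_count_matrix(contig_counts, "contig_counts")
  check_nonnegative(m)
  missing_ids <- setdiff(rownames(m), contigs$contig_id)
  if (length(missing_ids) > 0) {
    abort(sprintf("contigs missing from the contig table: %s",
                  paste(head(missing_ids, 5), collapse = ", ")))
  }
  info <- contigs[match(rownames(m), contigs$contig_id), ]
  n <- nrow(m)
  n_bins <- min(n_bins, n)
  # equal-frequency GC strata, deterministic under ties
  ord <- order(info$gc, info$contig_id)
  bin <- integer(n)
  bin[ord] <- as.integer(ceiling(seq_len(n) / (n / n_bins)))
  bin[bin > n_bins] <- n_bins
  gc_center <- tapply(info$gc, bin, median)

  len_kb <- info$length / 1000
  out <- m
  for (j in seq_len(ncol(m))) {
    rate <- m[, j] / len_kb
    med <- tapply(rate, bin, median)
    eps <- min(rate[rate > 0], 1) / 2
    if (all(med <= 0)) {
      out[, j] <- m[, j]
      next
    }
    log_curve <- log(pmax(med, eps))
    log_curve <- log_curve - mean(log_curve)
    adj <- if (n_bins > 1) {
      exp(stats::approx(gc_center, log_curve, xout = info$gc,
                        rule = 2)$y)
    } else {
      rep(1, n)
    }
    corrected <- rate / adj * len_kb
    tot <- sum(m[, j])
    if (sum(corrected) > 0) corrected <- corrected * tot / sum(corrected)
    out[, j] <- corrected
  }
  out
}

#' Aggregate contig counts to MAG counts
#'
#' Sums the (raw or bias-corrected) counts of each MAG's contigs,
#' preserving per-sample totals.
#'
#' @inheritParams correct_bias
#' @return MAG-by-sample abundance matrix.
#' @export
aggregate_to_mag <- function(contig_counts, contigs) {
  m <- as_count_matrix(contig_counts, "contig_counts")
  unmapped <- setdiff(rownames(m), contigs$contig_id)
  if (length(unmapped) > 0) {
    abort(sprintf("unmapped contigs: %s",
                  paste(head(unmapped, 5), collapse = ", ")))
  }
  mag <- contigs$mag_id[match(rownames(m), contigs$contig_id)]
  out <- rowsum(m, group = mag, reorder = TRUE)
  out[sort(rownames(out)), , drop = FALSE]
}

#' Hellinger transformation
#'
#' Square root of the relative abundance: each cell becomes
#' `sqrt(count / sample total)`, so every sample has unit sum of
#' squares. This accounts for library-size differences and tames the
#' sparse, long-tailed abundance distributions of microbiome data,
#' making Euclidean distances between samples ecologically meaningful.
#'
#' @param matrix Feature-by-sample matrix with positive column sums.
#' @return Transformed matrix.
#' @export
hellinger <- function(matrix) {
  m <- as_count_matrix(matrix, "matrix")
  check_nonnegative(m)
  tot <- colSums(m)
  if (any(tot <= 0)) {
    abort(sprintf("all-zero sample: %s",
                  paste(colnames(m)[tot <= 0], collapse = ", ")))
  }
  sweep(sqrt(m), 2, sqrt(tot), "/")
}

#' Remove animal and period batch effects
#'
#' Fits, per feature, a linear model with the diet effect and the batch
#' variables, and subtracts only the estimated batch components
#' (via [limma::removeBatchEffect()]). Intended for the Hellinger
#' transformed matrix ahead of ordination and PERMANOVA. Errors if a
#' batch variable is completely aliased with a kept variable, since the
#' batch effect would then be unidentifiable.
#'
#' @param matrix Feature-by-sample matrix (samples as columns, in
#'   `metadata` order or named by `sample_id`).
#' @param metadata Sample metadata tibble.
#' @param batch_vars Metadata columns treated as batches
#'   (default `animal_id`, `period`).
#' @param keep_vars Metadata columns whose effects are preserved
#'   (default `diet`).
#' @return Matrix with batch components removed.
#' @export
remove_batch <- function(matrix, metadata,
                         batch_vars = c("animal_id", "period"),
                         keep_vars = "diet") {
  m <- matrix
  if (is.data.frame(m)) m <- as_count_matrix(m, "matrix")
  metadata <- as_sample_metadata(metadata)
  if (!is.null(colnames(m))) {
    if (!all(colnames(m) %in% metadata$sample_id)) {
      abort("matrix columns missing from metadata")
    }
    metadata <- metadata[match(colnames(m), metadata$sample_id), ]
  }
  keep <- lapply(metadata[keep_vars], factor)
  design <- model.matrix(~ ., data = as.data.frame(keep))
  for (bv in batch_vars) {
    b <- factor(metadata[[bv]])
    if (nlevels(b) < 2) next
    Mb <- model.matrix(~b)
    combined <- cbind(design, Mb[, -1, drop = FALSE])
    rk_c <- qr(combined)$rank
    # aliasing in either direction makes batch and kept effects
    # inseparable: batch nested in the kept design, or the kept design
    # carrying no information beyond the batch
    if (rk_c <= qr(design)$rank || rk_c <= qr(Mb)$rank) {
      abort(sprintf("batch variable '%s' is aliased with %s", bv,
                    paste(keep_vars, collapse = "+")))
    }
  }
  batches <- lapply(metadata[batch_vars], factor)
  out <- limma::removeBatchEffect(
    m,
    batch = batches[[1]],
    batch2 = if (length(batches) > 1) batches[[2]] else NULL,
    design = design
  )
  out
}

#' Mean phylum relative abundance per diet
#'
#' Computes per-sample phylum percentages from a (bias-corrected,
#' untransformed) MAG abundance matrix and averages them across the
#' samples of each diet, so each diet column sums to 100.
#'
#' @param matrix MAG-by-sample abundance matrix.
#' @param taxonomy Taxonomy tibble with `genome_id` and `phylum`.
#' @param metadata Sample metadata tibble.
#' @return Tibble with `phylum` and one column per diet level (percent).
#' @export
phylum_relative_abundance <- function(matrix, taxonomy, metadata) {
  m <- as_count_matrix(matrix, "matrix")
  metadata <- as_sample_metadata(metadata)
  miss <- setdiff(rownames(m), taxonomy$genome_id)
  if (length(miss) > 0) {
    abort(sprintf("MAG missing taxonomy: %s",
                  paste(head(miss, 5), collapse = ", ")))
  }
  metadata <- metadata[match(colnames(m), metadata$sample_id), ]
  ph <- taxonomy$phylum[match(rownames(m), taxonomy$genome_id)]
  phym <- rowsum(m, group = ph)
  pct <- sweep(phym, 2, colSums(phym), "/") * 100
  diets <- sort(unique(metadata$diet))
  out <- matrix(
    unlist(lapply(diets, function(d) {
      rowMeans(pct[, metadata$diet == d, drop = FALSE])
    })),
    nrow = nrow(pct)
  )
  colnames(out) <- as.character(diets)
  dplyr::bind_cols(tibble(phylum = rownames(phym)), as_tibble(out))
}
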