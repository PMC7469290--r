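#' Filter KEGG ortholog annotation hits
#'
#' Keeps hits with percent identity at or above `min_identity` and
#' E-value strictly below `max_evalue` (defaults 50% and 1e-5).
#'
#' @param hits Tibble with columns `percent_identity` and `e_value`.
#' @param min_identity Inclusive identity threshold (percent).
#' @param max_evalue Exclusive E-value threshold.
#' @return Filtered tibble.
#' @export
filter_ko_hits <- function(hits, min_identity = 50, max_evalue = 1e-5) {
  hits <- as_tibble(hits)
  hits[hits$percent_identity >= min_identity &
         hits$e_value < max_evalue, , drop = FALSE]
}

#' Filter CAZyme annotation hits
#'
#' Keeps hits with coverage at or above `min_coverage` (fraction) and
#' E-value strictly below `max_evalue` (defaults 0.35 and 1e-18).
#'
#' @param hits Tibble with columns `coverage_fraction` and `e_value`.
#' @param min_coverage Inclusive coverage threshold (fraction).
#' @param max_evalue Exclusive E-value threshold.
#' @return Filtered tibble.
#' @export
filter_cazy_hits <- function(hits, min_coverage = 0.35,
                             max_evalue = 1e-18) {
  hits <- as_tibble(hits)
  hits[hits$coverage_fraction >= min_coverage &
         hits$e_value < max_evalue, , drop = FALSE]
}

#' Build a MAG-by-target annotation count matrix
#'
#' Counts filtered hits per (MAG, target). A protein hitting several
#' distinct targets counts once per target (best hit per
#' (protein, target) by lowest E-value), so multi-domain proteins can
#' contribute more than one site.
#'
#' @param hits Filtered hits with columns `protein_id`, `mag_id`,
#'   `target_id`, `e_value`.
#' @param mags Character vector declaring the matrix rows; hits
#'   referencing MAGs outside it are an error. Defaults to the MAGs
#'   present in `hits`.
#' @return Integer matrix MAG x target.
#' @export
build_annotation_matrix <- function(hits, mags = NULL) {
  hits <- as_tibble(hits)
  if (is.null(mags)) mags <- sort(unique(hits$mag_id))
  unknown <- setdiff(unique(hits$mag_id), mags)
  if (length(unknown) > 0) {
    abort(sprintf("hit references unknown MAG: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  targets <- sort(unique(hits$target_id))
  m <- matrix(0L, nrow = length(mags), ncol = length(targets),
              dimnames = list(mags, targets))
  if (nrow(hits) == 0) return(m)
  best <- hits |>
    dplyr::group_by(.data$protein_id, .data$target_id) |>
    dplyr::slice_min(.data$e_value, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  tab <- table(best$mag_id, best$target_id)
  m[rownames(tab), colnames(tab)] <- m[rownames(tab), colnames(tab)] +
    as.integer(tab)
  m
}

# CAZy module of a family name, e.g. GH13 -> GH
cazy_module_of <- function(families) {
  mod <- stringr::str_match(families, "^(GH|GT|PL|CE|AA|CBM)")[, 2]
  if (anyNA(mod)) {
    abort(sprintf("family without module assignment: %s",
                  paste(head(families[is.na(mod)], 5), collapse = ", ")))
  }
  mod
}

#' Dataset-wide CAZy module counts and percentages
#'
#' Sums family counts over all MAGs, aggregates them into the six CAZy
#' modules (GH, GT, PL, CE, AA, CBM) and reports each module's percent
#' of the total to 2 decimal places.
#'
#' @param x MAG-by-family count matrix, or a named numeric vector of
#'   family (or module) counts.
#' @param module_map Optional named vector family -> module; by default
#'   the module is read off the family-name prefix.
#' @return Tibble with `module`, `count`, `pct`.
#' @export
cazy_module_percentages <- function(x, module_map = NULL) {
  fam <- if (is.matrix(x)) colSums(x) else x
  mods <- if (is.null(module_map)) cazy_module_of(names(fam)) else {
    unmapped <- setdiff(names(fam), names(module_map))
    if (length(unmapped) > 0) {
      abort(sprintf("family without module assignment: %s",
                    paste(head(unmapped, 5), collapse = ", ")))
    }
    unname(module_map[names(fam)])
  }
  cnt <- tapply(as.numeric(fam), mods, sum)
  out <- tibble(module = names(cnt), count = as.numeric(cnt))
  lv <- c("GH", "GT", "PL", "CE", "AA", "CBM")
  out <- out[order(match(out$module, lv)), ]
  out$pct <- round(100 * out$count / sum(out$count), 2)
  out
}

#' Per-phylum CAZy module proportions
#'
#' Within each phylum, the percent of that phylum's CAZyme sites in
#' each module; rows sum to 100.
#'
#' @param matrix MAG-by-family count matrix.
#' @param taxonomy Taxonomy tibble with `genome_id`, `phylum`.
#' @return Tibble: `phylum` plus one percent column per module.
#' @export
phylum_cazy_proportions <- function(matrix, taxonomy) {
  miss <- setdiff(rownames(matrix), taxonomy$genome_id)
  if (length(miss) > 0) {
    abort(sprintf("MAG without phylum: %s",
                  paste(head(miss, 5), collapse = ", ")))
  }
  ph <- taxonomy$phylum[match(rownames(matrix), taxonomy$genome_id)]
  mods <- cazy_module_of(colnames(matrix))
  bym <- t(rowsum(t(rowsum(matrix, ph)), mods))
  pct <- sweep(bym, 1, rowSums(bym), "/") * 100
  lv <- intersect(c("GH", "GT", "PL", "CE", "AA", "CBM"), colnames(pct))
  pct <- pct[, lv, drop = FALSE]
  dplyr::bind_cols(tibble(phylum = rownames(pct)),
                   as_tibble(round(pct, 2)))
}

#' Log-count matrix and clustering order for a CAZy family heatmap
#'
#' Prepares the standard CAZyme-profile heatmap input: cells are
#' `log(count + 1)`; columns (families) are ordered by average-linkage
#' hierarchical clustering on one minus the Spearman correlation of the
#' per-taxon-group mean profiles; rows (MAGs) are arranged
#' taxonomically. Constant columns, whose correlation is undefined, are
#' placed last and flagged.
#'
#' @param matrix MAG-by-family count matrix.
#' @param taxonomy Taxonomy tibble (`genome_id`, `phylum`, optionally
#'   `genus`).
#' @return List with `log_counts` (rows in taxonomy order, columns in
#'   cluster order), `column_order`, `flagged_constant`.
#' @export
cazy_family_heatmap_input <- function(matrix, taxonomy) {
  ph <- taxonomy$phylum[match(rownames(matrix), taxonomy$genome_id)]
  gmeans <- rowsum(matrix, ph) / as.vector(table(ph)[sort(unique(ph))])
  sdv <- apply(gmeans, 2, sd)
  const <- sdv == 0
  keep <- colnames(matrix)[!const]
  if (length(keep) > 2) {
    rho <- suppressWarnings(cor(gmeans[, keep, drop = FALSE],
                                method = "spearman"))
    hc <- hclust(as.dist(1 - rho), method = "average")
    ord <- keep[hc$order]
  } else {
    ord <- keep
  }
  col_order <- c(ord, colnames(matrix)[const])
  tax_key <- taxonomy[match(rownames(matrix), taxonomy$genome_id), ]
  row_order <- rownames(matrix)[order(tax_key$phylum,
                                      tax_key$genus %||% "",
                                      tax_key$genome_id)]
  list(log_counts = log(matrix[row_order, col_order, drop = FALSE] + 1),
       column_order = col_order,
       flagged_constant = colnames(matrix)[const])
}

#' KO-per-sample functional potential matrix
#'
#' Multiplies per-MAG KO copy numbers by per-sample MAG abundance:
#' `entry(k, j) = sum_m count(m, k) * abundance(m, j)`, a matrix
#' product representing the community's functional potential in each
#' sample. Values are rounded to integers for downstream count models.
#'
#' @param ko_matrix MAG-by-KO count matrix.
#' @param abundance MAG-by-sample abundance matrix; MAG sets must
#'   match.
#' @param round_counts Round to nearest integer (default TRUE).
#' @return KO-by-sample matrix.
#' @export
ko_per_sample <- function(ko_matrix, abundance, round_counts = TRUE) {
  if (!setequal(rownames(ko_matrix), rownames(abundance))) {
    abort("MAG sets of ko_matrix and abundance do not match")
  }
  ab <- abundance[rownames(ko_matrix), , drop = FALSE]
  out <- crossprod(ko_matrix, ab)
  if (round_counts) out <- round(out)
  out
}

#' Aggregate a KO-by-sample matrix into pathway modules
#'
#' Pathway counts are sums over member KOs; a KO belonging to several
#' pathways contributes to each. KOs absent from the map fall into an
#' `"unassigned"` bucket (with a message). Pathways present in the map
#' but without counts are retained as zero rows.
#'
#' @param ko_sample KO-by-sample matrix (see [ko_per_sample()]).
#' @param pathway_map Tibble with columns `ko`, `pathway`.
#' @return Pathway-by-sample matrix.
#' @export
aggregate_pathways <- function(ko_sample, pathway_map) {
  pathway_map <- as_tibble(pathway_map)
  unmapped <- setdiff(rownames(ko_sample), pathway_map$ko)
  if (length(unmapped) > 0) {
    message(sprintf("%d KOs not in pathway map -> 'unassigned'",
                    length(unmapped)))
    pathway_map <- dplyr::bind_rows(
      pathway_map, tibble(ko = unmapped, pathway = "unassigned"))
  }
  pws <- sort(unique(pathway_map$pathway))
  out <- matrix(0, nrow = length(pws), ncol = ncol(ko_sample),
                dimnames = list(pws, colnames(ko_sample)))
  pm <- pathway_map[pathway_map$ko %in% rownames(ko_sample), ]
  for (pw in pws) {
    kos <- pm$ko[pm$pathway == pw]
    if (length(kos) > 0) {
      out[pw, ] <- colSums(ko_sample[kos, , drop = FALSE])
    }
  }
  out
}

contrast_diets <- function(contrast) {
  switch(contrast, "40vs80" = c(40L, 80L), "60vs80" = c(60L, 80L),
         abort(sprintf("unknown contrast: %s", contrast)))
}

#' Taxon-group contributions to pathway shifts from DA MAGs
#'
#' Restricts the functional potential to the differentially abundant
#' (DA) MAGs, aggregates KO copy number times abundance into pathway
#' modules per taxonomic group and diet, and reports
#' `lfc = log2((count_low + c) / (count_high + c))` per
#' (group, pathway, contrast) with pseudocount `c`, where the counts
#' are per-diet aggregates. By default the abundance columns are
#' library-size normalised (median-of-ratios over all MAGs) and
#' aggregated as per-sample means, so the fold change is not biased by
#' sequencing depth or by unequal group sizes (4 vs 5 samples in the
#' retained crossover design). Rows with `taxon_group = "total"` carry
#' the total-over-groups fold change per pathway, i.e. the change
#' attributable to the DA MAGs as a whole.
#'
#' @param ko_matrix MAG-by-KO count matrix.
#' @param abundance MAG-by-sample abundance matrix (bias-corrected,
#'   untransformed).
#' @param taxonomy Taxonomy tibble with `genome_id` and a grouping
#'   column.
#' @param metadata Sample metadata.
#' @param pathway_map Tibble `ko`, `pathway`.
#' @param da_mags Character vector of DA MAG ids (nonempty).
#' @param group_col Taxonomy column used for grouping (default
#'   `"genus"`).
#' @param pseudocount Pseudocount `c > 0` (default 1).
#' @param contrasts Contrasts to evaluate (default 40vs80 and 60vs80).
#' @param normalize Normalise abundance columns by median-of-ratios
#'   size factors and aggregate as per-sample means (default TRUE);
#'   `FALSE` uses raw within-diet sums.
#' @return Tibble of class `mag_contribution`: `taxon_group`,
#'   `pathway`, `contrast`, `count_low`, `count_high`, `lfc`.
#' @export
taxon_contribution <- function(ko_matrix, abundance, taxonomy, metadata,
                               pathway_map, da_mags, group_col = "genus",
                               pseudocount = 1,
                               contrasts = c("40vs80", "60vs80"),
                               normalize = TRUE) {
  if (length(da_mags) == 0) abort("DA MAG set is empty")
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  metadata <- as_sample_metadata(metadata)
  metadata <- metadata[metadata$sample_id %in% colnames(abundance) &
                         metadata$diet %in% c(40L, 60L, 80L), ]
  miss <- setdiff(da_mags, taxonomy$genome_id)
  if (length(miss) > 0) {
    abort(sprintf("taxon group missing for: %s",
                  paste(head(miss, 5), collapse = ", ")))
  }
  groups <- taxonomy[[group_col]][match(da_mags, taxonomy$genome_id)]

  ab <- abundance[, metadata$sample_id, drop = FALSE]
  if (normalize) {
    ab <- sweep(ab, 2, size_factors(ab), "/")
  }
  agg <- if (normalize) function(x) rowMeans(x) else function(x) rowSums(x)

  out <- purrr::map_dfr(contrasts, function(ctr) {
    diets <- contrast_diets(ctr)
    per_group <- purrr::map_dfr(unique(groups), function(g) {
      gm <- da_mags[groups == g]
      pw <- aggregate_pathways(
        ko_per_sample(ko_matrix[gm, , drop = FALSE],
                      ab[gm, , drop = FALSE],
                      round_counts = FALSE),
        pathway_map)
      lo_s <- metadata$sample_id[metadata$diet == diets[1]]
      hi_s <- metadata$sample_id[metadata$diet == diets[2]]
      tibble(taxon_group = g, pathway = rownames(pw), contrast = ctr,
             count_low = unname(agg(pw[, lo_s, drop = FALSE])),
             count_high = unname(agg(pw[, hi_s, drop = FALSE])))
    })
    totals <- per_group |>
      dplyr::group_by(.data$pathway, .data$contrast) |>
      dplyr::summarise(count_low = sum(.data$count_low),
                       count_high = sum(.data$count_high),
                       .groups = "drop") |>
      dplyr::mutate(taxon_group = "total")
    dplyr::bind_rows(per_group, totals)
  })
  out$lfc <- log2((out$count_low + pseudocount) /
                    (out$count_high + pseudocount))
  out <- out[, c("taxon_group", "pathway", "contrast", "count_low",
                 "count_high", "lfc")]
  class(out) <- c("mag_contribution", class(out))
  out
}

#' @rdname taxon_contribution
#' @param object A `mag_contribution` table.
#' @param ... Unused.
#' @export
autoplot.mag_contribution <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[df$taxon_group != "total", ]
  ggplot2::ggplot(df, ggplot2::aes(.data$pathway, .data$lfc,
                                   fill = .data$taxon_group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "log2 fold change vs 80% MER", x = NULL) +
    ggplot2::theme_minimal()
}

# shared classification rule; also used on expected quantities by the
# synthetic generator's ground truth
scenario_rule <- function(has_sig, overall, attr, threshold) {
  attr_present <- is.finite(attr) && abs(attr) >= threshold
  if (!has_sig || is.na(overall)) {
    return(if (attr_present) "attribution-only" else "none")
  }
  overall_present <- abs(overall) >= threshold
  if (overall_present && attr_present) {
    return(if (sign(overall) == sign(attr)) "agreement" else "disconnect")
  }
  if (!overall_present && attr_present) {
    # meaningful attributable change without a meaningful overall one:
    # opposite tendency is a disconnect, same tendency effectively
    # attribution-only
    return(if (sign(overall) != 0 && sign(overall) != sign(attr))
      "disconnect" else "attribution-only")
  }
  "none"
}

#' Classify pathway-level interplay scenarios
#'
#' Contrasts, per pathway and diet contrast, the overall shift in
#' functional potential (the log2 fold change of the pooled
#' KO-per-sample counts of the pathway's significantly differentially
#' abundant KOs) with the shift attributable to the DA MAGs (the
#' `"total"` rows of [taxon_contribution()]):
#'
#' * **agreement** - both shifts meet the threshold with the same sign;
#' * **disconnect** - both present but opposed, or a meaningful
#'   attributable shift against an overall change of opposite sign;
#' * **attribution-only** - no significant KO in the pathway (or no
#'   meaningful same-sign overall change) yet a meaningful attributable
#'   shift;
#' * **none** - otherwise.
#'
#' @param ko_da KO-level [nb_lrt()] result.
#' @param ko_sample KO-by-sample matrix used for that test.
#' @param contributions [taxon_contribution()] result.
#' @param pathway_map Tibble `ko`, `pathway`.
#' @param metadata Sample metadata.
#' @param fdr KO significance threshold on `padj` (default 0.05).
#' @param lfc_threshold Scenario threshold on |LFC| (default 0.5).
#' @param pseudocount Pseudocount for pooled-count fold changes.
#' @param normalize Library-size normalise `ko_sample` columns and pool
#'   as per-sample means, matching [taxon_contribution()] (default
#'   TRUE).
#' @return Tibble: `pathway`, `contrast`, `n_sig_kos`, `overall_lfc`,
#'   `attributable_lfc`, `scenario`.
#' @export
classify_scenarios <- function(ko_da, ko_sample, contributions,
                               pathway_map, metadata, fdr = 0.05,
                               lfc_threshold = 0.5, pseudocount = 1,
                               normalize = TRUE) {
  metadata <- as_sample_metadata(metadata)
  metadata <- metadata[metadata$sample_id %in% colnames(ko_sample), ]
  ko_sample <- ko_sample[, metadata$sample_id, drop = FALSE]
  if (normalize) {
    ko_sample <- sweep(ko_sample, 2, size_factors(ko_sample), "/")
  }
  pool <- if (normalize) {
    function(x) sum(x) / ncol(x)
  } else {
    function(x) sum(x)
  }
  sig_kos <- ko_da$feature_id[!is.na(ko_da$padj) & ko_da$padj < fdr]
  totals <- contributions[contributions$taxon_group == "total", ]
  pathways <- unique(pathway_map$pathway)
  purrr::map_dfr(unique(totals$contrast), function(ctr) {
    diets <- contrast_diets(ctr)
    lo_s <- metadata$sample_id[metadata$diet == diets[1]]
    hi_s <- metadata$sample_id[metadata$diet == diets[2]]
    purrr::map_dfr(pathways, function(pw) {
      kos <- intersect(pathway_map$ko[pathway_map$pathway == pw],
                       rownames(ko_sample))
      sk <- intersect(kos, sig_kos)
      overall <- NA_real_
      if (length(sk) > 0) {
        lo <- pool(ko_sample[sk, lo_s, drop = FALSE])
        hi <- pool(ko_sample[sk, hi_s, drop = FALSE])
        overall <- log2((lo + pseudocount) / (hi + pseudocount))
      }
      att <- totals$lfc[totals$pathway == pw & totals$contrast == ctr]
      att <- if (length(att) == 0) NA_real_ else att[[1]]
      tibble(pathway = pw, contrast = ctr, n_sig_kos = length(sk),
             overall_lfc = overall, attributable_lfc = att,
             scenario = scenario_rule(length(sk) > 0, overall, att,
                                      lfc_threshold))
    })
  })
}

#' Correlation of phylum proportions between two genome catalogues
#'
#' Converts per-phylum genome counts to proportions within each
#' catalogue (union of phyla, zero-filled) and reports Pearson's r and
#' Spearman's rho (midranks for ties).
#'
#' @param counts_a,counts_b Named numeric vectors of per-phylum genome
#'   counts.
#' @return Tibble with `pearson_r` and `spearman_rho`.
#' @export
phylum_proportion_correlation <- function(counts_a, counts_b) {
  phyla <- union(names(counts_a), names(counts_b))
  if (length(phyla) < 3) abort("need at least 3 phyla")
  a <- setNames(numeric(length(phyla)), phyla)
  b <- a
  a[names(counts_a)] <- counts_a
  b[names(counts_b)] <- counts_b
  pa <- a / sum(a)
  pb <- b / sum(b)
  tibble(pearson_r = cor(pa, pb, method = "pearson"),
         spearman_rho = cor(pa, pb, method = "spearman"))
}
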