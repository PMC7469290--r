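hits_fixture <- function() {
  tibble::tibble(
    protein_id = c("p1", "p2", "p3", "p4", "p5"),
    mag_id = c("m1", "m1", "m1", "m2", "m2"),
    target_id = c("K1", "K1", "K1", "K2", "K2"),
    percent_identity = c(50, 49.9, 80, 60, 70),
    coverage_fraction = c(0.35, 0.349, 0.9, 0.5, 0.6),
    e_value = c(1e-6, 1e-7, 1e-5, 1e-19, 1e-30)
  )
}

test_that("KO hit filtering applies the published thresholds", {
  h <- filter_ko_hits(hits_fixture())
  # identity >= 50 inclusive, E < 1e-5 strict
  expect_setequal(h$protein_id, c("p1", "p4", "p5"))
  expect_false("p3" %in% h$protein_id)   # e = 1e-5 exactly -> dropped
  expect_false("p2" %in% h$protein_id)   # identity 49.9 -> dropped
})

test_that("CAZy hit filtering applies the published thresholds", {
  h <- filter_cazy_hits(hits_fixture())
  expect_setequal(h$protein_id, c("p4", "p5"))   # coverage + E gates
  expect_false("p2" %in% h$protein_id)           # coverage 0.349
  h2 <- filter_cazy_hits(transform(hits_fixture(), e_value = 1e-18))
  expect_equal(nrow(h2), 0)                      # e = 1e-18 exactly
})

test_that("annotation matrices count best hits per protein and target", {
  hits <- tibble::tibble(
    protein_id = c("p1", "p2", "p3", "p1", "p1"),
    mag_id = c("m1", "m1", "m1", "m1", "m1"),
    target_id = c("K1", "K1", "K1", "K2", "K2"),
    e_value = c(1e-10, 1e-9, 1e-8, 1e-9, 1e-20)
  )
  m <- build_annotation_matrix(hits, mags = c("m1", "m2"))
  expect_equal(m["m1", "K1"], 3L)   # three proteins hit K1
  expect_equal(m["m1", "K2"], 1L)   # duplicate (p1, K2) deduplicated
  expect_equal(sum(m["m2", ]), 0L)
  empty <- build_annotation_matrix(hits[0, ], mags = c("m1", "m2"))
  expect_equal(sum(empty), 0L)
  expect_equal(rownames(empty), c("m1", "m2"))
  expect_error(build_annotation_matrix(hits, mags = "mX"), "unknown MAG")
})

test_that("CAZy module percentages reproduce the published table", {
  counts <- c(GH = 39566, GT = 17473, PL = 1052, CE = 9060, AA = 111,
              CBM = 2366)
  tab <- cazy_module_percentages(counts)
  expect_equal(sum(tab$count), 69628)
  expect_equal(tab$pct[tab$module == "GH"], 56.82)
  expect_equal(tab$pct[tab$module == "GT"], 25.09)
  one <- cazy_module_percentages(c(GH5 = 10, GH13 = 5))
  expect_equal(one$pct, 100)
  expect_error(cazy_module_percentages(c(XYZ9 = 1)), "module")
})

test_that("per-phylum CAZy proportions recover the planted mixtures", {
  st <- study_pipeline()$study
  tab <- phylum_cazy_proportions(st$cazy_matrix, st$taxonomy)
  mods <- setdiff(colnames(tab), "phylum")
  expect_equal(rowSums(as.matrix(tab[, mods])), rep(100, nrow(tab)),
               tolerance = 0.01, ignore_attr = TRUE)
  mix <- st$truth$cazy_mixture
  for (ph in intersect(tab$phylum, rownames(mix))) {
    got <- unlist(tab[tab$phylum == ph, mods])
    expect_equal(unname(got[names(got)]), unname(100 * mix[ph, mods]),
                 tolerance = 2)
  }
  expect_error(phylum_cazy_proportions(st$cazy_matrix,
                                       st$taxonomy[-1, ]), "phylum")
})

test_that("heatmap input clusters columns like a brute-force oracle", {
  st <- study_pipeline()$study
  hm <- cazy_family_heatmap_input(st$cazy_matrix, st$taxonomy)
  expect_equal(min(hm$log_counts), 0)      # log(0 + 1)
  expect_setequal(colnames(hm$log_counts), colnames(st$cazy_matrix))
  # duplicated columns are mutually closest, hence adjacent
  set.seed(71)
  toy6 <- matrix(rpois(60, 10), 10, 6,
                 dimnames = list(sprintf("m%02d", 1:10),
                                 c("GH1", "GH2", "GT1", "CE1", "PL1",
                                   "CBM1")))
  tax6 <- tibble::tibble(genome_id = rownames(toy6),
                         phylum = rep(paste0("P", 1:5), each = 2),
                         genus = "g")
  m2 <- cbind(toy6, GH2b = toy6[, "GH2"])
  hm2 <- cazy_family_heatmap_input(m2, tax6)
  pos <- match(c("GH2", "GH2b"), hm2$column_order)
  expect_equal(abs(diff(pos)), 1)
  # 4-column toy against hand agglomeration: {a,b} pair first, then c, d
  toy <- cbind(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 6),
               c = c(5, 4, 3, 2, 1), d = c(2, 1, 4, 3, 5))
  rownames(toy) <- sprintf("m%d", 1:5)
  tax <- tibble::tibble(genome_id = rownames(toy),
                        phylum = c("P1", "P1", "P2", "P2", "P3"),
                        genus = "g")
  colnames(toy) <- c("GH1", "GH2", "GH3", "GH4")
  ord <- cazy_family_heatmap_input(toy, tax)$column_order
  expect_true(abs(diff(match(c("GH1", "GH2"), ord))) == 1)
})

test_that("constant CAZy columns are placed last and flagged", {
  st <- study_pipeline()$study
  m <- cbind(st$cazy_matrix, GHX = 3L)
  hm <- cazy_family_heatmap_input(m, st$taxonomy)
  expect_equal(utils::tail(hm$column_order, 1), "GHX")
  expect_equal(hm$flagged_constant, "GHX")
})

test_that("KO-per-sample is the matrix product of content and abundance", {
  K <- matrix(c(2, 1, 0, 3), 2, 2,
              dimnames = list(c("m1", "m2"), c("K1", "K2")))
  A <- matrix(c(10, 1), 2, 1, dimnames = list(c("m1", "m2"), "S"))
  ks <- ko_per_sample(K, A)
  expect_equal(ks["K1", "S"], 21)
  expect_equal(ks["K2", "S"], 3)
  # identity abundance copies the KO matrix
  I2 <- diag(2)
  dimnames(I2) <- list(c("m1", "m2"), c("s1", "s2"))
  expect_equal(unname(ko_per_sample(K, I2)), unname(t(K)))
  # zero-abundance MAG contributes nothing; linearity in abundance
  A0 <- A
  A0["m1", ] <- 0
  expect_equal(ko_per_sample(K, A0)["K1", "S"], 1)
  expect_equal(ko_per_sample(K, 2 * A, round_counts = FALSE),
               2 * ko_per_sample(K, A, round_counts = FALSE))
  expect_error(ko_per_sample(K, A[1, , drop = FALSE]), "MAG sets")
})

test_that("pathway aggregation sums members and keeps empty pathways", {
  ks <- matrix(c(3, 4, 5), 3, 1,
               dimnames = list(c("K1", "K2", "K3"), "s1"))
  map <- tibble::tibble(ko = c("K1", "K2", "K2", "K3", "K9"),
                        pathway = c("pw1", "pw1", "pw2", "pw2", "pwE"))
  agg <- aggregate_pathways(ks, map)
  expect_equal(agg["pw1", "s1"], 7)
  expect_equal(agg["pw2", "s1"], 9)    # K2 counted in both pathways
  expect_equal(agg["pwE", "s1"], 0)    # empty pathway retained
  expect_gte(sum(agg[, "s1"]), sum(ks[, "s1"]))
  expect_message(aggregate_pathways(rbind(ks, K8 = 1), map),
                 "unassigned")
})

test_that("contribution fold changes match hand computation", {
  md <- crossover_design()[c(3, 10), ]   # one 40% and one 80% sample
  K <- matrix(4, 1, 1, dimnames = list("m1", "K1"))
  A <- matrix(c(2, 0.5), 1, 2,
              dimnames = list("m1", md$sample_id))
  tax <- tibble::tibble(genome_id = "m1", phylum = "P", genus = "G")
  map <- tibble::tibble(ko = "K1", pathway = "pw")
  ct <- taxon_contribution(K, A, tax, md, map, da_mags = "m1",
                           contrasts = "40vs80", normalize = FALSE)
  # counts 8 (40%) vs 2 (80%), c = 1 -> log2(9/3)
  tot <- ct[ct$taxon_group == "total", ]
  expect_equal(tot$count_low, 8)
  expect_equal(tot$count_high, 2)
  expect_equal(tot$lfc, log2(9 / 3), tolerance = 1e-12)
  expect_equal(round(tot$lfc, 3), 1.585)
  # equal counts give zero fold change
  A2 <- matrix(c(1, 1), 1, 2, dimnames = dimnames(A))
  ct2 <- taxon_contribution(K, A2, tax, md, map, da_mags = "m1",
                            contrasts = "40vs80", normalize = FALSE)
  expect_equal(ct2$lfc[ct2$taxon_group == "total"], 0)
  expect_error(taxon_contribution(K, A, tax, md, map,
                                  da_mags = character()), "empty")
})

test_that("group contributions conserve the DA-restricted totals", {
  pl <- study_pipeline()
  ct <- pl$contrib
  by_pw <- split(ct[ct$taxon_group != "total", ],
                 paste(ct$pathway, ct$contrast)[ct$taxon_group != "total"])
  for (chunk in by_pw) {
    tot <- ct[ct$taxon_group == "total" &
                ct$pathway == chunk$pathway[1] &
                ct$contrast == chunk$contrast[1], ]
    expect_equal(sum(chunk$count_low), tot$count_low,
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(sum(chunk$count_high), tot$count_high,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # contribution signs match the planted expectation
  signs <- pl$study$truth$group_signs
  keyed <- merge(as.data.frame(ct[ct$taxon_group != "total" &
                                    ct$contrast == "40vs80", ]),
                 as.data.frame(signs),
                 by = c("taxon_group", "pathway"))
  strong <- keyed[keyed$expected_sign != 0 &
                    pmax(keyed$count_low, keyed$count_high) > 1, ]
  expect_true(all(sign(strong$lfc) == strong$expected_sign))
  expect_s3_class(autoplot(ct), "ggplot")
})

test_that("scenario classification reproduces the published examples", {
  rule <- magcentric:::scenario_rule
  expect_equal(rule(TRUE, 0.72, 1.67, 0.5), "agreement")
  expect_equal(rule(TRUE, -0.13, 1.34, 0.5), "disconnect")
  expect_equal(rule(FALSE, NA, 1.07, 0.5), "attribution-only")
  expect_equal(rule(FALSE, NA, 0.1, 0.5), "none")
  expect_equal(rule(TRUE, -0.9, -1.2, 0.5), "agreement")
  expect_equal(rule(TRUE, 0.9, -1.2, 0.5), "disconnect")
  expect_equal(rule(TRUE, 0.9, 0.1, 0.5), "none")
})

test_that("the pipeline recovers all planted interplay scenarios", {
  pl <- study_pipeline()
  cmp <- merge(as.data.frame(pl$scenarios),
               as.data.frame(pl$study$truth$scenarios
                             [, c("pathway", "contrast", "scenario")]),
               by = c("pathway", "contrast"),
               suffixes = c("_est", "_true"))
  expect_equal(nrow(cmp), 10)
  expect_equal(cmp$scenario_est, cmp$scenario_true)
  expect_setequal(unique(cmp$scenario_est),
                  c("agreement", "disconnect", "attribution-only",
                    "none"))
})

test_that("phylum-proportion correlations match published and toy values", {
  tab <- rumen_phylum_counts()
  a <- setNames(tab$winning_mags, tab$phylum)
  b <- setNames(tab$scottish_rugs, tab$phylum)
  cc <- phylum_proportion_correlation(a, b)
  expect_equal(round(cc$pearson_r, 2), 0.99)
  expect_equal(round(cc$spearman_rho, 2), 0.79)
  same <- phylum_proportion_correlation(a, a)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$spearman_rho, 1)
  toy <- phylum_proportion_correlation(
    c(p1 = 1, p2 = 2, p3 = 3), c(p1 = 2, p2 = 4, p3 = 5))
  expect_equal(round(toy$pearson_r, 4), 0.982)
  expect_error(phylum_proportion_correlation(c(a = 1, b = 2),
                                             c(a = 1, b = 2)),
               "3 phyla")
})
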