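#' Scenario planting specification for synthetic KO annotations
#'
#' Each row plants one block of KEGG-ortholog (KO) content for one
#' pathway module. Masses are abundance-weighted totals of copy number
#' times expected MAG abundance, split over the planted
#' differentially abundant (DA) up-set, DA down-set and non-DA MAGs;
#' per-MAG copy numbers are derived from them so that the expected
#' KO-per-sample totals hit the planted design regardless of the random
#' per-MAG baselines. The default plants the three interplay scenarios:
#'
#' * `amino_acid_metabolism`, `energy_metabolism`: KO content dominated
#'   by up-shifted DA MAGs - overall functional shift and DA-attributable
#'   shift agree (**agreement**).
#' * `carbohydrate_metabolism`: a small KO block carried by down-shifted
#'   DA MAGs drives a significant negative overall shift, while the bulk
#'   of the pathway's DA-attributable content sits in up-shifted MAGs
#'   diluted by a large non-DA background (**disconnect**).
#' * `nucleotide_metabolism`: DA carriage swamped by non-DA background,
#'   so no KO shifts overall, yet the DA-restricted content shifts
#'   strongly (**attribution-only**).
#' * `housekeeping`: up- and down-DA masses balanced (down = 4 x up
#'   exactly offsets a +/-2 log2 fold change), so neither the overall
#'   nor the attributable potential moves (**none**).
#'
#' @return Tibble with columns `pathway`, `block`, `n_kos`, `up_mass`,
#'   `down_mass`, `non_mass`.
#' @export
default_scenario_spec <- function() {
  tibble(
    pathway = c("amino_acid_metabolism", "energy_metabolism",
                "carbohydrate_metabolism", "carbohydrate_metabolism",
                "nucleotide_metabolism", "housekeeping"),
    block = c("main", "main", "diluted", "down", "main", "main"),
    n_kos = c(8L, 6L, 12L, 3L, 2L, 10L),
    up_mass = c(30, 20, 10, 0, 30, 8),
    down_mass = c(4, 3, 0.5, 40, 8, 32),
    non_mass = c(30, 40, 1600, 10, 5600, 60)
  )
}

#' Simulate a genome taxonomy with DA-linked genera
#'
#' Assigns rumen-typical genus and phylum labels. Planted up- and
#' down-shifted DA MAGs get disjoint genera (up: Bacteroides,
#' Ruminococcus, Clostridium; down: Prevotella, Clostridiales) so that
#' per-group contribution signs are unambiguous; the remaining MAGs
#' rotate through a wider set of rumen taxa. Ranks below genus are never
#' resolved; some genomes are left `"unclassified"` at genus level.
#'
#' @param mags Character vector of MAG ids.
#' @param da_up,da_down Character vectors of planted DA MAG ids.
#' @return Taxonomy tibble with `genome_id`, `domain`, `phylum`,
#'   `genus`.
#' @export
simulate_taxonomy <- function(mags, da_up = character(),
                              da_down = character()) {
  genus_phylum <- c(
    Bacteroides = "Bacteroidetes", Prevotella = "Bacteroidetes",
    Bacteroidales = "Bacteroidetes", Ruminococcus = "Firmicutes",
    Clostridium = "Firmicutes", Clostridiales = "Firmicutes",
    Selenomonas = "Firmicutes", Treponema = "Spirochaetes",
    Victivallis = "Lentisphaerae", Methanobrevibacter = "Euryarchaeota",
    unclassified = "Bacteria"
  )
  up_gen <- c("Bacteroides", "Ruminococcus", "Clostridium")
  down_gen <- c("Prevotella", "Clostridiales")
  other_gen <- setdiff(names(genus_phylum), c(up_gen, down_gen))
  genus <- setNames(rep(other_gen, length.out = length(mags)), mags)
  genus[da_up] <- rep(up_gen, length.out = length(da_up))
  genus[da_down] <- rep(down_gen, length.out = length(da_down))
  tibble(
    genome_id = mags,
    domain = ifelse(genus == "Methanobrevibacter", "Archaea", "Bacteria"),
    phylum = unname(genus_phylum[genus]),
    genus = unname(genus)
  )
}

# integer copy numbers hitting a target abundance-weighted mass:
# per-MAG share of `mass` divided by its weight, rounded
mass_to_copies <- function(mass, weights) {
  if (length(weights) == 0 || mass <= 0) {
    return(setNames(integer(length(weights)), names(weights)))
  }
  per <- mass / length(weights)
  round(per / weights)
}

#' Simulate KO and CAZy annotation matrices with planted scenarios
#'
#' Builds the MAG-by-KO copy-number matrix from a scenario
#' specification (see [default_scenario_spec()]), a KO-to-pathway map,
#' and a MAG-by-CAZy-family matrix with phylum-specific module
#' mixtures. The ground truth records, per (pathway, contrast), the
#' expected overall log2 fold change of the pathway's expected-DA KOs,
#' the expected DA-attributable fold change, and the scenario label
#' derived analytically from the planted masses and realised copy
#' numbers (the same classification rule the pipeline applies, but fed
#' with expected rather than estimated quantities).
#'
#' @param mags Character vector of MAG ids.
#' @param taxonomy Taxonomy tibble (see [simulate_taxonomy()]).
#' @param da_up,da_down Planted DA MAG ids (up/down relative to the 80%
#'   MER reference diet).
#' @param weights Named positive numeric: expected abundance weight per
#'   MAG (e.g. baseline times total contig kb). Copy numbers are scaled
#'   by `1/weight` so planted masses are met.
#' @param lfc Planted log2 fold change magnitude of the DA MAGs
#'   (default 2; down MAGs use `-lfc`).
#' @param scenario_spec Scenario specification tibble.
#' @param lfc_threshold Scenario threshold on log2 fold changes
#'   (default 0.5).
#' @param n_background_carriers Number of non-DA MAGs carrying the
#'   non-DA ("background") KO mass (default 2). Concentrating the
#'   background in a few high-copy carriers mimics pathway specialists
#'   and keeps the planted attribution signal insensitive to which
#'   non-DA MAGs a downstream analysis might misclassify.
#' @param seed Optional integer seed (CAZy noise only; KO copy numbers
#'   are deterministic given `weights`).
#' @return List with `ko_matrix` (MAG x KO), `cazy_matrix` (MAG x
#'   family), `pathway_map`, `cazy_mixture` (phylum x module planted
#'   proportions) and `truth` (list: `ko` tibble, `scenarios` tibble,
#'   `group_signs` tibble).
#' @export
simulate_annotations <- function(mags, taxonomy, da_up, da_down, weights,
                                 lfc = 2,
                                 scenario_spec = default_scenario_spec(),
                                 lfc_threshold = 0.5,
                                 n_background_carriers = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(mags %in% taxonomy$genome_id), all(names(weights) == mags))
  non <- setdiff(mags, c(da_up, da_down))
  carriers <- non[seq_len(min(n_background_carriers, length(non)))]
  w <- weights / mean(weights)

  # KO matrix ---------------------------------------------------------
  spec <- as_tibble(scenario_spec)
  n_ko <- sum(spec$n_kos)
  ko_ids <- sprintf("K%05d", seq_len(n_ko))
  K <- matrix(0L, nrow = length(mags), ncol = n_ko,
              dimnames = list(mags, ko_ids))
  map <- tibble(ko = ko_ids, pathway = rep(spec$pathway, spec$n_kos))
  ko_at <- 0L
  for (r in seq_len(nrow(spec))) {
    cu <- mass_to_copies(spec$up_mass[r], w[da_up])
    cd <- mass_to_copies(spec$down_mass[r], w[da_down])
    cn <- mass_to_copies(spec$non_mass[r], w[carriers])
    for (kk in seq_len(spec$n_kos[r])) {
      ko_at <- ko_at + 1L
      K[da_up, ko_at] <- cu
      K[da_down, ko_at] <- cd
      K[carriers, ko_at] <- cn
    }
  }

  # analytic ground truth from realised copy numbers and weights ------
  mult <- setNames(rep(1, length(mags)), mags)   # 2^lfc per MAG, low diets
  mult[da_up] <- 2^lfc
  mult[da_down] <- 2^(-lfc)
  tot80 <- as.numeric(crossprod(K, w))                  # per-KO, 80% diet
  totlo <- as.numeric(crossprod(K, w * mult))           # per-KO, 40/60%
  explfc <- log2(totlo / tot80)
  ko_truth <- tibble(
    ko = ko_ids, pathway = map$pathway,
    explfc40 = explfc, explfc60 = explfc,
    is_da = abs(explfc) >= lfc_threshold
  )

  da <- c(da_up, da_down)
  scen_truth <- purrr::map_dfr(unique(spec$pathway), function(pw) {
    in_pw <- map$pathway == pw
    sig <- in_pw & ko_truth$is_da
    overall <- if (any(sig)) log2(sum(totlo[sig]) / sum(tot80[sig])) else NA_real_
    attr80 <- sum(crossprod(K[da, in_pw, drop = FALSE], w[da]))
    attrlo <- sum(crossprod(K[da, in_pw, drop = FALSE], (w * mult)[da]))
    attr <- log2((attrlo + 1e-9) / (attr80 + 1e-9))
    purrr::map_dfr(c("40vs80", "60vs80"), function(ctr) {
      tibble(pathway = pw, contrast = ctr, n_sig_kos = sum(sig),
             overall_lfc = overall, attributable_lfc = attr,
             scenario = scenario_rule(sum(sig) > 0, overall, attr,
                                      lfc_threshold))
    })
  })

  # per-(taxon group, pathway) expected contribution signs ------------
  tax <- taxonomy[match(da, taxonomy$genome_id), ]
  group_signs <- purrr::map_dfr(unique(spec$pathway), function(pw) {
    in_pw <- map$pathway == pw
    purrr::map_dfr(unique(tax$genus), function(g) {
      gm <- da[tax$genus == g]
      lo <- sum(crossprod(K[gm, in_pw, drop = FALSE], (w * mult)[gm]))
      hi <- sum(crossprod(K[gm, in_pw, drop = FALSE], w[gm]))
      tibble(taxon_group = g, pathway = pw,
             expected_sign = sign(round(log2((lo + 1e-9) / (hi + 1e-9)), 8)))
    })
  })

  # CAZy matrix: deterministic phylum-specific module mixtures --------
  families <- c(GH2 = "GH", GH3 = "GH", GH5 = "GH", GH13 = "GH",
                GH43 = "GH", GT2 = "GT", GT4 = "GT", PL1 = "PL",
                CE1 = "CE", CE4 = "CE", AA3 = "AA", CBM6 = "CBM",
                CBM50 = "CBM")
  phyla <- unique(taxonomy$phylum)
  modules <- c("GH", "GT", "PL", "CE", "AA", "CBM")
  # module mixture per phylum: GH-heavy for Bacteroidetes/Firmicutes,
  # GT-heavy for archaea, mixed otherwise
  mixture <- t(vapply(phyla, function(ph) {
    m <- switch(ph,
      Bacteroidetes = c(60, 20, 2, 13, 0, 5),
      Firmicutes = c(54, 27, 1, 14, 0, 4),
      Euryarchaeota = c(6, 84, 0, 6, 4, 0),
      Lentisphaerae = c(65, 19, 1, 12, 1, 2),
      c(40, 45, 1, 10, 1, 3))
    m / sum(m)
  }, numeric(6)))
  colnames(mixture) <- modules
  fam_per_mod <- table(factor(unname(families), levels = modules))
  C <- matrix(0L, nrow = length(mags), ncol = length(families),
              dimnames = list(mags, names(families)))
  base_total <- 100
  ph_of <- setNames(taxonomy$phylum, taxonomy$genome_id)
  for (m in mags) {
    mix <- mixture[ph_of[[m]], ]
    C[m, ] <- as.integer(round(base_total * mix[unname(families)] /
                                 as.numeric(fam_per_mod[unname(families)])))
  }

  list(ko_matrix = K, cazy_matrix = C, pathway_map = map,
       cazy_mixture = mixture,
       truth = list(ko = ko_truth, scenarios = scen_truth,
                    group_signs = group_signs))
}
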