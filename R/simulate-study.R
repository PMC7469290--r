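#' Simulate a complete synthetic crossover study
#'
#' Orchestrates the generators into a full input bundle with recorded
#' ground truth: crossover metadata (the bundled 6-animal, 4-period
#' design), a contig-by-sample count matrix with planted DA MAGs,
#' GC/length bias and animal/period batch effects, a taxonomy, KO and
#' CAZy annotation matrices with the planted interplay scenarios, and a
#' KO-to-pathway map. Every downstream stage of the pipeline can be
#' exercised against the returned truth without any external data.
#'
#' @param seed Integer seed; the whole bundle is reproducible from it.
#' @param n_mags Number of MAGs in the community (default 60).
#' @param n_up,n_down Numbers of planted DA MAGs shifted up/down in the
#'   restricted (40%/60% MER) diets relative to 80% (defaults 6 and 3).
#' @param lfc Magnitude of the planted log2 fold change (default 2).
#' @param effects Optional [effect_spec()]; by default one is built with
#'   the planted DA set and default noise/bias settings.
#' @param scenario_spec Scenario planting (see [default_scenario_spec()]).
#' @param metadata Sample metadata (default [crossover_design()]).
#' @return List with `metadata`, `mags`, `taxonomy`, `counts`,
#'   `contigs`, `ko_matrix`, `cazy_matrix`, `pathway_map` and `truth`
#'   (planted DA MAGs, KO truth, scenario truth, group signs, batch and
#'   baseline parameters).
#' @export
simulate_study <- function(seed = NULL, n_mags = 60, n_up = 6, n_down = 3,
                           lfc = 2, effects = NULL,
                           scenario_spec = default_scenario_spec(),
                           metadata = crossover_design()) {
  if (!is.null(seed)) set.seed(seed)
  mags <- sprintf("MAG%04d", seq_len(n_mags))
  da_up <- sort(sample(mags, n_up))
  da_down <- sort(sample(setdiff(mags, da_up), n_down))
  planted <- tibble(
    mag_id = c(da_up, da_down),
    lfc40 = c(rep(lfc, n_up), rep(-lfc, n_down)),
    lfc60 = c(rep(lfc, n_up), rep(-lfc, n_down))
  )
  if (is.null(effects)) effects <- effect_spec(planted_da = planted)

  cs <- simulate_counts(metadata, mags, effects)
  taxonomy <- simulate_taxonomy(mags, da_up, da_down)

  # expected abundance weight per MAG: baseline x biased contig mass
  wtab <- cs$contigs
  wtab$mass <- wtab$length / 1000 * effects$gc_bias(wtab$gc)
  weights <- tapply(wtab$mass, wtab$mag_id, sum)[mags] *
    exp(cs$truth$baseline[mags])

  ann <- simulate_annotations(mags, taxonomy, da_up, da_down,
                              weights = as.numeric(weights) |>
                                setNames(mags),
                              lfc = lfc, scenario_spec = scenario_spec)

  list(
    metadata = metadata, mags = mags, taxonomy = taxonomy,
    counts = cs$counts, contigs = cs$contigs,
    ko_matrix = ann$ko_matrix, cazy_matrix = ann$cazy_matrix,
    pathway_map = ann$pathway_map,
    truth = c(list(da_mags = planted, da_up = da_up, da_down = da_down,
                   cazy_mixture = ann$cazy_mixture),
              ann$truth, cs$truth["animal_effects"],
              cs$truth["period_effects"], cs$truth["baseline"])
  )
}
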