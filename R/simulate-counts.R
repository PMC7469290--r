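#' Effect specification for the synthetic community
#'
#' Collects the tunables of the count and annotation generators: the
#' planted differential-abundance (DA) MAGs with their log2 fold changes
#' relative to the 80% MER reference diet, the additive animal/period
#' batch effects (log scale), the negative-binomial dispersion
#' (`variance = mu + dispersion * mu^2`, matching the downstream model),
#' the monotone GC bias and the contig length range.
#'
#' @param planted_da Tibble with columns `mag_id`, `lfc40`, `lfc60`:
#'   planted log2 fold changes of the 40% and 60% diets versus 80%.
#'   `NULL` plants no differential abundance.
#' @param batch_sd_animal,batch_sd_period SDs of the additive per-animal
#'   and per-period effects on the natural-log scale.
#' @param dispersion NB dispersion alpha (0 gives Poisson counts).
#' @param gc_bias Strictly positive function of GC fraction multiplying
#'   the expected coverage; the default `exp(gc_slope * (gc - 0.5))` is
#'   monotone in GC.
#' @param gc_slope Slope of the default GC bias (0 disables the bias).
#' @param n_contigs_per_mag Contigs simulated per MAG.
#' @param length_range Contig length range in bp.
#' @param gc_range Contig GC-fraction range.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-MAG baseline coverage density (counts per kb per contig).
#' @param depth_sdlog SD of the per-sample log library-depth factor.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(planted_da = NULL, batch_sd_animal = 0.30,
                        batch_sd_period = 0.15, dispersion = 0.10,
                        gc_bias = NULL, gc_slope = 2,
                        n_contigs_per_mag = 5L,
                        length_range = c(2000, 20000),
                        gc_range = c(0.30, 0.70),
                        baseline_meanlog = log(150),
                        baseline_sdlog = 0.8, depth_sdlog = 0.30) {
  if (!is.null(planted_da)) {
    planted_da <- as_tibble(planted_da)
    stopifnot(all(c("mag_id", "lfc40", "lfc60") %in% colnames(planted_da)))
    if (!all(is.finite(planted_da$lfc40)) ||
        !all(is.finite(planted_da$lfc60))) {
      abort("planted fold changes must be finite")
    }
  }
  if (dispersion < 0) abort("dispersion must be >= 0")
  if (is.null(gc_bias)) {
    force(gc_slope)
    gc_bias <- function(gc) exp(gc_slope * (gc - 0.5))
  }
  if (any(gc_bias(seq(0, 1, by = 0.1)) <= 0)) {
    abort("gc_bias must be strictly positive")
  }
  structure(
    list(planted_da = planted_da, batch_sd_animal = batch_sd_animal,
         batch_sd_period = batch_sd_period, dispersion = dispersion,
         gc_bias = gc_bias, n_contigs_per_mag = as.integer(n_contigs_per_mag),
         length_range = length_range, gc_range = gc_range,
         baseline_meanlog = baseline_meanlog,
         baseline_sdlog = baseline_sdlog, depth_sdlog = depth_sdlog),
    class = "effect_spec"
  )
}

#' Simulate a contig-by-sample count matrix with planted structure
#'
#' Draws negative-binomial read counts under the log-linear model
#' `log mu = log depth_j + baseline_m + diet effect + animal effect +
#' period effect + log(length_kb) + log(gc_bias(gc))`, i.e. the
#' structure the bias-correction, batch-removal and differential
#' abundance stages assume. The planted DA MAGs shift by their log2 fold
#' change in the 40%/60% diets relative to 80% (100% MER samples, which
#' are excluded from comparisons anyway, follow the 80% baseline).
#'
#' @param metadata Sample metadata tibble (see [as_sample_metadata()]).
#' @param mags Character vector of MAG ids.
#' @param effects An [effect_spec()].
#' @param seed Optional integer seed.
#' @return List with `counts` (contig x sample integer matrix),
#'   `contigs` (tibble: `contig_id`, `mag_id`, `length`, `gc`) and
#'   `truth` (list: `planted_da`, `animal_effects`, `period_effects`,
#'   `depth`, `baseline`).
#' @export
simulate_counts <- function(metadata, mags, effects = effect_spec(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  metadata <- as_sample_metadata(metadata)
  stopifnot(inherits(effects, "effect_spec"))
  n_mag <- length(mags)
  nc <- effects$n_contigs_per_mag

  contigs <- tibble(
    contig_id = sprintf("%s_c%02d", rep(mags, each = nc),
                        rep(seq_len(nc), times = n_mag)),
    mag_id = rep(mags, each = nc),
    length = round(runif(n_mag * nc, effects$length_range[1],
                         effects$length_range[2])),
    gc = runif(n_mag * nc, effects$gc_range[1], effects$gc_range[2])
  )

  baseline <- setNames(
    rnorm(n_mag, effects$baseline_meanlog, effects$baseline_sdlog), mags)
  if (any(!is.finite(baseline))) abort("non-positive genome abundance baseline")
  animals <- unique(metadata$animal_id)
  periods <- sort(unique(metadata$period))
  a_eff <- setNames(rnorm(length(animals), 0, effects$batch_sd_animal),
                    animals)
  p_eff <- setNames(rnorm(length(periods), 0, effects$batch_sd_period),
                    as.character(periods))
  depth <- setNames(rnorm(nrow(metadata), 0, effects$depth_sdlog),
                    metadata$sample_id)

  # per-MAG diet effect in natural log units, by diet level
  diet_shift <- matrix(0, nrow = n_mag, ncol = 4,
                       dimnames = list(mags, c("40", "60", "80", "100")))
  if (!is.null(effects$planted_da)) {
    pd <- effects$planted_da
    if (!all(pd$mag_id %in% mags)) abort("planted DA MAG not in mags")
    diet_shift[pd$mag_id, "40"] <- pd$lfc40 * log(2)
    diet_shift[pd$mag_id, "60"] <- pd$lfc60 * log(2)
  }

  counts <- matrix(0L, nrow = nrow(contigs), ncol = nrow(metadata),
                   dimnames = list(contigs$contig_id, metadata$sample_id))
  log_len <- log(contigs$length / 1000)
  log_gcb <- log(effects$gc_bias(contigs$gc))
  base_c <- baseline[contigs$mag_id]
  for (j in seq_len(nrow(metadata))) {
    sm <- metadata[j, ]
    lmu <- depth[[sm$sample_id]] + base_c +
      diet_shift[contigs$mag_id, as.character(sm$diet)] +
      a_eff[[sm$animal_id]] + p_eff[[as.character(sm$period)]] +
      log_len + log_gcb
    mu <- exp(lmu)
    counts[, j] <- if (effects$dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / effects$dispersion)
    } else {
      rpois(length(mu), mu)
    }
  }

  list(counts = counts, contigs = contigs,
       truth = list(planted_da = effects$planted_da,
                    animal_effects = a_eff, period_effects = p_eff,
                    depth = depth, baseline = baseline))
}
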