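#' Crossover feeding trial design
#'
#' The experimental design of the African (Boran) cattle feeding trial
#' bundled as the default metadata fixture: six yearling steers fed at
#' 40%, 60%, 80% and 100% of maintenance energy requirement (MER) over
#' four periods in a crossover design, one rumen sample per animal per
#' period (24 samples).
#'
#' @return A sample metadata tibble (`sample_id`, `animal_id`, `period`,
#'   `diet`).
#' @export
crossover_design <- function() {
  diets <- rbind(
    c(80, 60, 40, 100),   # animal 41
    c(60, 40, 100, 80),   # animal 43
    c(100, 80, 60, 40),   # animal 46
    c(40, 100, 80, 60),   # animal 47
    c(40, 100, 80, 60),   # animal 49
    c(100, 80, 60, 40)    # animal 52
  )
  animals <- c("41", "43", "46", "47", "49", "52")
  out <- tibble(
    animal_id = rep(animals, each = 4L),
    period = rep(1:4, times = 6L),
    diet = as.integer(t(diets))
  )
  out$sample_id <- sprintf("A%s_P%d", out$animal_id, out$period)
  as_sample_metadata(out[, c("sample_id", "animal_id", "period", "diet")])
}

#' Secondary-cluster size distribution of the African MAG catalogue
#'
#' Published distribution of 1200 high-quality rumen MAGs over 850
#' secondary (99% ANI) dereplication clusters: cluster sizes 7 down to 1
#' with 3, 3, 7, 12, 44, 165 and 616 clusters respectively.
#'
#' @return Tibble with columns `cluster_size` and `n_clusters`.
#' @export
mag_cluster_size_distribution <- function() {
  tibble(
    cluster_size = c(7L, 6L, 5L, 4L, 3L, 2L, 1L),
    n_clusters = c(3L, 3L, 7L, 12L, 44L, 165L, 616L)
  )
}

#' Phylum-level genome counts for rumen MAG catalogues
#'
#' Published per-phylum genome counts for the African high-quality MAGs
#' (1200), the dereplicated winning set (850), the original Scottish
#' rumen uncultured genomes (RUGs, 850 shown) and the RUG 2.0 set (4941).
#' Used for cross-catalogue phylum-proportion correlations.
#'
#' @return Tibble with columns `phylum`, `hq_mags`, `winning_mags`,
#'   `scottish_rugs`, `rug2`.
#' @export
rumen_phylum_counts <- function() {
  tibble(
    phylum = c("Bacteroidetes", "Firmicutes", "Proteobacteria",
               "Fibrobacteres", "Actinobacteria", "Lentisphaerae",
               "Spirochaetes", "Tenericutes", "Planctomycetes",
               "Fusobacteria", "Verrucomicrobia", "Elusimicrobia",
               "Synergistetes", "Ignavibacteriae", "Euryarchaeota",
               "Bacteria"),
    hq_mags       = c(385L, 514L, 85L, 3L, 3L, 76L, 7L, 22L, 9L, 5L, 1L,
                      16L, 1L, 1L, 7L, 65L),
    winning_mags  = c(253L, 377L, 65L, 2L, 2L, 50L, 6L, 16L, 5L, 4L, 1L,
                      13L, 1L, 1L, 6L, 48L),
    scottish_rugs = c(288L, 391L, 30L, 6L, 30L, 8L, 10L, 4L, 4L, 1L, 0L,
                      8L, 0L, 0L, 29L, 41L),
    rug2          = c(1707L, 2407L, 133L, 42L, 164L, 20L, 59L, 118L, 12L,
                      0L, 47L, 26L, 0L, 0L, 126L, 80L)
  )
}

#' CAZy module counts for rumen MAG catalogues
#'
#' Published counts of carbohydrate-active enzyme sites per CAZy module
#' (GH glycoside hydrolases, GT glycosyl transferases, PL polysaccharide
#' lyases, CE carbohydrate esterases, AA auxiliary activities, CBM
#' carbohydrate binding modules) in the African MAG, Scottish RUG and
#' RUG 2.0 catalogues.
#'
#' @return Tibble with columns `module`, `african_mags`, `scottish_rugs`,
#'   `rug2`.
#' @export
cazy_module_reference_counts <- function() {
  tibble(
    module = c("GH", "GT", "PL", "CE", "AA", "CBM"),
    african_mags  = c(39566L, 17473L, 1052L, 9060L, 111L, 2366L),
    scottish_rugs = c(40140L, 19722L, 1121L, 9119L, 154L, 2545L),
    rug2          = c(235001L, 120494L, 6834L, 55523L, 907L, 23928L)
  )
}
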