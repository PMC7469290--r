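#' Default analysis configuration
#'
#' All tunables of the pipeline in one nested list, with defaults equal
#' to the study's stated settings where they exist: quality thresholds
#' (completeness 80 / contamination 10), sketching (k = 21,
#' s = 100000, hash seed 42), dereplication ANI cuts (0.90 / 0.99),
#' PERMANOVA permutations (9999), power-analysis settings (1000
#' matrices, 10000 permutations, designs 3:3:3 to 5:5:5), DA
#' thresholds (FDR 0.05), annotation-hit filters and scenario
#' threshold.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    samples = list(exclude_periods = 1L, exclude_diets = 100L),
    quality = list(min_completeness = 80, max_contamination = 10),
    sketch = list(k = 21L, s = 1e5, seed = 42L),
    dereplicate = list(primary_ani = 0.90, secondary_ani = 0.99),
    bias = list(n_gc_bins = 10L),
    permanova = list(n_perm = 9999L),
    power = list(n_matrices = 1000L, n_perm = 10000L,
                 designs = list(c(3L, 3L, 3L), c(4L, 4L, 4L),
                                c(4L, 5L, 5L), c(5L, 5L, 5L)),
                 alpha = c(0.05, 0.01, 0.001)),
    da = list(fdr = 0.05, dispersion_floor = 1e-8),
    hits = list(ko_min_identity = 50, ko_max_evalue = 1e-5,
                cazy_min_coverage = 0.35, cazy_max_evalue = 1e-18),
    attribution = list(pseudocount = 1, lfc_threshold = 0.5)
  )
}

#' Read / write a configuration as YAML
#'
#' User-supplied values are merged over [default_config()]; unknown
#' keys are an error so typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return For `read_config`, the merged configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config sections: %s",
                  paste(unknown, collapse = ", ")))
  }
  for (sec in names(user)) {
    bad <- setdiff(names(user[[sec]]), names(base[[sec]]))
    if (length(bad) > 0) {
      abort(sprintf("unknown config keys in '%s': %s", sec,
                    paste(bad, collapse = ", ")))
    }
    base[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  base
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
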