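#' Euclidean distances between samples
#'
#' @param matrix Feature-by-sample matrix (samples as columns).
#' @return Symmetric distance matrix with sample dimnames.
#' @export
euclidean_distances <- function(matrix) {
  m <- matrix
  if (is.data.frame(m)) m <- as_count_matrix(m, "matrix")
  if (ncol(m) < 2) abort("need at least 2 samples")
  as.matrix(dist(t(m), method = "euclidean"))
}

#' Principal coordinate analysis (classical MDS)
#'
#' Double-centres the squared distance matrix and eigendecomposes the
#' resulting Gram matrix; axes are ordered by eigenvalue and the
#' variance fraction of each axis is its eigenvalue over the sum of
#' positive eigenvalues. Substantially negative eigenvalues (beyond
#' `-1e-8 * max`) indicate a non-Euclidean input and trigger a warning;
#' they are clamped out of the variance accounting.
#'
#' @param distances Distance matrix (or `dist`).
#' @return Object of class `mag_pcoa`: list with `points` (samples x
#'   axes), `eig`, `var_explained`.
#' @export
pcoa <- function(distances) {
  d <- as.matrix(distances)
  n <- nrow(d)
  fit <- cmdscale(as.dist(d), k = n - 1, eig = TRUE)
  eig <- fit$eig
  if (any(eig < -1e-8 * max(eig))) {
    warning("negative eigenvalues: distances are not Euclidean; clamping")
  }
  pos <- eig > 1e-12 * max(eig)
  ve <- ifelse(pos, eig / sum(eig[pos]), 0)
  pts <- fit$points
  colnames(pts) <- paste0("Axis.", seq_len(ncol(pts)))
  structure(list(points = pts, eig = eig,
                 var_explained = ve[seq_len(ncol(pts))]),
            class = "mag_pcoa")
}

#' @export
print.mag_pcoa <- function(x, ...) {
  cat(sprintf("<mag_pcoa> %d samples, %d axes; Axis.1 %.1f%%, Axis.2 %.1f%%\n",
              nrow(x$points), ncol(x$points), 100 * x$var_explained[1],
              100 * x$var_explained[2] %||% NA))
  invisible(x)
}

#' @rdname pcoa
#' @param x A `mag_pcoa` object.
#' @param ... Unused.
#' @export
tidy.mag_pcoa <- function(x, ...) {
  dplyr::bind_cols(tibble(sample_id = rownames(x$points)),
                   as_tibble(x$points))
}

#' @rdname pcoa
#' @param object A `mag_pcoa` object.
#' @param groups Optional grouping vector (e.g. diet) for colouring.
#' @export
autoplot.mag_pcoa <- function(object, groups = NULL, ...) {
  df <- tidy.mag_pcoa(object)
  if (!is.null(groups)) df$group <- as.factor(groups)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$Axis.1, .data$Axis.2)) +
    ggplot2::labs(
      x = sprintf("Axis.1 [%.1f%%]", 100 * object$var_explained[1]),
      y = sprintf("Axis.2 [%.1f%%]", 100 * object$var_explained[2])
    ) +
    ggplot2::theme_minimal()
  if (is.null(groups)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2.5)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squared distances into between- and
#' within-group components: `SS_total = sum_{i<j} d_ij^2 / N`,
#' `SS_within = sum_groups sum_{i<j in group} d_ij^2 / n_group`, and
#' `pseudo-F = (SS_between / (a - 1)) / (SS_within / (N - a))`. The
#' p-value comes from free permutation of sample labels with the
#' add-one convention `p = (1 + #[F_perm > F_obs]) / (n_perm + 1)`,
#' counting strict exceedances so that a permutation which merely
#' reproduces the observed partition (and hence its F) does not count
#' against it; fully separated groups therefore attain the minimum
#' 0.0001 at 9999 permutations. `R2 = SS_between / SS_total`.
#'
#' @param distances Distance matrix (or `dist`) of samples.
#' @param groups Group labels, one per sample; at least 2 groups with
#'   at least 2 samples each.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed.
#' @param strata Optional blocking factor: permutations are then
#'   restricted to within-stratum label exchanges.
#' @return Object of class `mag_permanova` with fields `pseudo_F`,
#'   `R2`, `p`, `n_perm`, `df`, `seed`.
#' @export
permanova <- function(distances, groups, n_perm = 9999, seed = NULL,
                      strata = NULL) {
  d <- as.matrix(distances)
  groups <- as.factor(groups)
  if (length(groups) != nrow(d)) abort("one group label per sample required")
  if (nlevels(droplevels(groups)) < 2) abort("need at least 2 groups")
  if (any(table(groups) < 2)) abort("every group needs at least 2 samples")
  if (!is.null(seed)) set.seed(seed)
  d2 <- d^2
  gi <- as.integer(droplevels(groups)) - 1L
  a <- nlevels(droplevels(groups))
  obs <- cpp_permanova_stat(d2, gi, a)
  if (is.null(strata)) {
    perms <- cpp_permanova_perms(d2, gi, a, as.integer(n_perm))
  } else {
    strata <- as.factor(strata)
    perms <- vapply(seq_len(n_perm), function(i) {
      idx <- seq_along(gi)
      for (s in levels(strata)) {
        w <- which(strata == s)
        idx[w] <- w[sample.int(length(w))]
      }
      cpp_permanova_stat(d2, gi[idx], a)[1]
    }, numeric(1))
  }
  p <- (1 + sum(perms > obs[1] + 1e-12)) / (n_perm + 1)
  structure(list(pseudo_F = obs[1], R2 = obs[2], p = p, n_perm = n_perm,
                 df = c(between = a - 1L, within = nrow(d) - a),
                 seed = seed, groups = groups),
            class = "mag_permanova")
}

#' @export
print.mag_permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.3f (df %d, %d), R2 = %.3f, p = %.4g (%d perms)\n",
    x$pseudo_F, x$df[1], x$df[2], x$R2, x$p, x$n_perm))
  invisible(x)
}

#' @rdname permanova
#' @param x,object A `mag_permanova` object.
#' @param ... Unused.
#' @export
tidy.mag_permanova <- function(x, ...) {
  tibble(term = "groups", df = x$df[[1]], statistic = x$pseudo_F,
         R2 = x$R2, p.value = x$p)
}

#' @rdname permanova
#' @export
glance.mag_permanova <- function(x, ...) {
  tibble(pseudo_F = x$pseudo_F, R2 = x$R2, p.value = x$p,
         n_perm = x$n_perm, n_samples = sum(x$df) + 1L)
}

#' Pairwise PERMANOVA with Benjamini-Hochberg correction
#'
#' Runs [permanova()] on every pair of groups and adjusts the p-values
#' across pairs with the BH step-up procedure.
#'
#' @inheritParams permanova
#' @return Tibble with one row per pair: `group1`, `group2`,
#'   `pseudo_F`, `R2`, `p`, `padj`.
#' @export
pairwise_permanova <- function(distances, groups, n_perm = 9999,
                               seed = NULL) {
  d <- as.matrix(distances)
  groups <- as.factor(groups)
  if (!is.null(seed)) set.seed(seed)
  lv <- levels(droplevels(groups))
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    keep <- groups %in% pr
    fit <- permanova(d[keep, keep], droplevels(groups[keep]),
                     n_perm = n_perm)
    tibble(group1 = pr[1], group2 = pr[2], pseudo_F = fit$pseudo_F,
           R2 = fit$R2, p = fit$p)
  })
  out$padj <- bh_adjust(out$p)
  out
}

#' Bootstrap PERMANOVA power analysis over design sizes
#'
#' For each candidate design (group sizes such as 3:3:3 or 4:5:5),
#' repeatedly resamples samples within each group from the supplied
#' (transformed, batch-corrected) abundance matrix, recomputes
#' Euclidean distances, and runs a PERMANOVA per resampled matrix.
#' Power at a significance level is the proportion of resampled
#' matrices reaching `p <= alpha`; its sampling distribution is
#' obtained by bootstrapping the per-matrix indicators, and the median
#' of that distribution is reported as the power estimate.
#'
#' Resampling is a noise-adjusted smoothed bootstrap. A plain
#' within-group bootstrap is anti-conservative three times over:
#' duplicated samples (zero mutual distance, always within a group)
#' inflate the pseudo-F; the empirical group-mean differences of a
#' finite null data set are re-detected as if they were real effects;
#' and chance differences in within-group dispersion persist across
#' resamples. Resampled columns are therefore built as `overall mean +
#' c * group-mean deviation + pooled residual draw + smoothing noise`:
#' residuals (sample minus its group mean) are drawn from the pooled
#' residual set so all groups share one dispersion; the shrinkage
#' factor `c = max(0, 1 - E[noise] / observed between-group sum of
#' squares)` estimates how much of the observed group separation
#' exceeds its sampling noise, so `c` is near 0 for exchangeable data
#' (null power then sits at the significance level) and near 1 for
#' well-separated groups (power preserved); and smoothing noise
#' (`bandwidth` times the pooled residual standard deviation) keeps
#' duplicated draws distinct.
#'
#' @param matrix Feature-by-sample matrix (samples as columns).
#' @param groups Group labels, one per sample.
#' @param designs List of integer vectors of per-group sample sizes,
#'   each as long as the number of groups (group order = sorted
#'   levels).
#' @param alpha Significance levels (default 0.05, 0.01, 0.001).
#' @param n_matrices Resampled matrices per design (default 1000).
#' @param n_perm Permutations per PERMANOVA (default 999).
#' @param n_boot Bootstrap resamples of the indicators for the power
#'   distribution (default 200).
#' @param bandwidth Smoothing bandwidth as a multiple of the
#'   within-group standard deviation (default 1; 0 gives the plain
#'   bootstrap).
#' @param seed Optional integer seed.
#' @return Object of class `mag_power`: tibble with one row per
#'   (design, alpha): `design`, `alpha`, `power`, `median_power`,
#'   `power_distribution` (list column).
#' @export
permanova_power <- function(matrix, groups, designs,
                            alpha = c(0.05, 0.01, 0.001),
                            n_matrices = 1000, n_perm = 999,
                            n_boot = 200, bandwidth = 1, seed = NULL) {
  m <- matrix
  if (is.data.frame(m)) m <- as_count_matrix(m, "matrix")
  groups <- as.factor(groups)
  if (!is.null(seed)) set.seed(seed)
  lv <- levels(droplevels(groups))
  idx_by_group <- lapply(lv, function(g) which(groups == g))
  ng <- lengths(idx_by_group)
  overall <- rowMeans(m)
  gmean <- lapply(idx_by_group, function(idx) {
    rowMeans(m[, idx, drop = FALSE])
  })
  sd_by_group <- lapply(idx_by_group, function(idx) {
    apply(m[, idx, drop = FALSE], 1, sd)
  })
  # shrink observed group-mean deviations by their sampling noise
  delta <- lapply(gmean, function(gm) gm - overall)
  ss_between <- sum(vapply(seq_along(lv), function(g) {
    ng[g] * sum(delta[[g]]^2)
  }, numeric(1)))
  noise <- sum(vapply(seq_along(lv), function(g) {
    sum(sd_by_group[[g]]^2) * (1 - ng[g] / sum(ng))
  }, numeric(1)))
  shrink <- max(0, 1 - noise / max(ss_between, 1e-300))
  resid <- m
  for (g in seq_along(lv)) {
    resid[, idx_by_group[[g]]] <- m[, idx_by_group[[g]], drop = FALSE] -
      gmean[[g]]
  }
  pooled_sd <- apply(resid, 1, sd)
  out <- purrr::map_dfr(designs, function(des) {
    if (length(des) != length(lv)) {
      abort("design length must equal the number of groups")
    }
    if (any(des < 1)) abort("design group size 0")
    pvals <- vapply(seq_len(n_matrices), function(i) {
      sub <- do.call(cbind, lapply(seq_along(lv), function(g) {
        take <- sample(ncol(resid), des[g], replace = TRUE)
        x <- overall + shrink * delta[[g]] +
          resid[, take, drop = FALSE]
        if (bandwidth > 0) {
          x <- x + bandwidth * pooled_sd *
            matrix(rnorm(length(x)), nrow = nrow(x))
        }
        x
      }))
      colnames(sub) <- sprintf("bs%03d", seq_len(ncol(sub)))
      dd <- euclidean_distances(sub)
      glab <- rep(lv, times = des)
      permanova(dd, glab, n_perm = n_perm)$p
    }, numeric(1))
    purrr::map_dfr(alpha, function(al) {
      hit <- as.numeric(pvals <= al)
      boot <- vapply(seq_len(n_boot), function(b) {
        mean(sample(hit, length(hit), replace = TRUE))
      }, numeric(1))
      tibble(design = paste(des, collapse = ":"), alpha = al,
             power = mean(hit), median_power = median(boot),
             power_distribution = list(boot))
    })
  })
  class(out) <- c("mag_power", class(out))
  out
}

#' @rdname permanova_power
#' @param object A `mag_power` result.
#' @param ... Unused.
#' @export
autoplot.mag_power <- function(object, ...) {
  df <- tidyr::unnest(
    dplyr::mutate(as_tibble(object),
                  alpha = factor(.data$alpha)),
    "power_distribution")
  ggplot2::ggplot(df, ggplot2::aes(.data$design, .data$power_distribution,
                                   fill = .data$alpha)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = "design (samples per diet group)",
                  y = "bootstrap power") +
    ggplot2::theme_minimal()
}
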