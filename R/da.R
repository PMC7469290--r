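#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features
#' (restricted to features with nonzero counts in every sample) of the
#' ratio of the feature's count to its across-sample geometric mean;
#' factors are then normalised to geometric mean 1. This is the
#' standard library-size correction for count models, robust to a
#' minority of differentially abundant features.
#'
#' @param counts Feature-by-sample count matrix.
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  m <- as_count_matrix(counts, "counts")
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep)) abort("no feature has nonzero counts in every sample")
  lg <- log(m[keep, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- exp(apply(lg - geo, 2, median))
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Negative-binomial dispersion estimates
#'
#' Per feature, the method-of-moments estimate of the dispersion
#' `alpha` in `variance = mu + alpha * mu^2` is computed from
#' size-factor-normalised counts residualised on the design:
#' `alpha_hat = max(floor, (var - mean) / mean^2)`, with the residual
#' variance from a least-squares fit so condition effects do not
#' inflate it. With the few residual degrees of freedom of a crossover
#' design these per-feature estimates are noisy, which makes a
#' fixed-dispersion likelihood-ratio test anti-conservative; the
#' default therefore moderates them towards a common dispersion
#' calibrated so that the aggregate Pearson statistic of the
#' design-fitted NB models matches its degrees of freedom, weighting
#' feature and common estimates by `df_res` and `prior_df`
#' respectively. Features whose raw estimate lies far above the common
#' value (more than `outlier_mult` times it) are genuinely more
#' dispersed and keep their own estimate, so moderation never makes
#' the test anti-conservative for them. All-zero features get the
#' floor and are flagged (attribute `"flagged"`).
#'
#' @param counts Feature-by-sample count matrix.
#' @param size_factors Per-sample size factors (see [size_factors()]).
#' @param design Design matrix (samples x terms) used to residualise.
#' @param floor Dispersion floor (default 1e-8).
#' @param method `"moderated"` (default), `"feature"` (raw per-feature
#'   moments) or `"common"` (Pearson-calibrated common value for all
#'   features).
#' @param prior_df Weight of the common dispersion in the moderated
#'   estimate (default 50).
#' @param outlier_mult Per-feature estimates above `outlier_mult *
#'   common` are not moderated (default 2).
#' @return Named numeric vector of dispersions with attributes
#'   `"flagged"` (logical) and `"common"` (the common dispersion).
#' @export
estimate_dispersion <- function(counts, size_factors, design,
                                floor = 1e-8,
                                method = c("moderated", "feature",
                                           "common"),
                                prior_df = 50, outlier_mult = 2) {
  method <- match.arg(method)
  m <- as_count_matrix(counts, "counts")
  norm <- sweep(m, 2, size_factors, "/")
  qrX <- qr(design)
  res <- t(qr.resid(qrX, t(norm)))
  dfres <- ncol(m) - qrX$rank
  mu <- rowMeans(norm)
  v <- rowSums(res^2) / max(dfres, 1)
  a <- ifelse(mu > 0, pmax(floor, (v - mu) / mu^2), floor)
  flagged <- mu == 0

  common <- NA_real_
  if (method != "feature") {
    common <- pearson_common_dispersion(m, size_factors, design,
                                        init = max(mean(a, trim = 0.1),
                                                   floor),
                                        floor = floor)
    a <- switch(method,
      common = rep(common, nrow(m)),
      moderated = ifelse(
        a > outlier_mult * common, a,
        (max(dfres, 1) * a + prior_df * common) /
          (max(dfres, 1) + prior_df))
    )
    a <- pmax(a, floor)
  }
  a[flagged] <- floor
  a <- setNames(as.numeric(a), rownames(m))
  attr(a, "flagged") <- setNames(flagged, rownames(m))
  attr(a, "common") <- common
  a
}

# common NB dispersion calibrated on the aggregate Pearson statistic of
# design-fitted GLMs; a deterministic subset of features keeps it cheap
pearson_common_dispersion <- function(m, sf, design, init, floor,
                                      max_features = 200, n_iter = 4) {
  keep <- which(rowSums(m) > 0)
  if (length(keep) == 0) return(floor)
  if (length(keep) > max_features) {
    keep <- keep[unique(as.integer(seq(1, length(keep),
                                       length.out = max_features)))]
  }
  off <- log(sf)
  n <- ncol(m)
  p <- qr(design)$rank
  alpha <- max(init, 1e-4)
  for (it in seq_len(n_iter)) {
    fam <- MASS::negative.binomial(theta = 1 / alpha)
    ps <- 0
    dfs <- 0
    for (i in keep) {
      fit <- tryCatch(
        suppressWarnings(stats::glm.fit(design, m[i, ], family = fam,
                                        offset = off)),
        error = function(e) NULL)
      if (is.null(fit)) next
      muh <- fit$fitted.values
      ps <- ps + sum((m[i, ] - muh)^2 / (muh + alpha * muh^2))
      dfs <- dfs + (n - p)
    }
    if (dfs == 0) break
    fac <- ps / dfs
    alpha <- max(floor, alpha * fac^1.5)
    if (abs(fac - 1) < 0.02) break
  }
  alpha
}

# design matrix from a formula over metadata factors, with aliased
# columns dropped deterministically (first occurrence kept)
build_design <- function(formula, metadata) {
  mf <- as.data.frame(metadata)
  for (v in all.vars(formula)) mf[[v]] <- factor(mf[[v]])
  X <- model.matrix(formula, data = mf)
  q <- qr(X)
  if (q$rank < ncol(X)) X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  X
}

nb_loglik <- function(y, mu, theta) {
  sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
}

#' Negative-binomial likelihood-ratio test for differential abundance
#'
#' Fits, per feature, negative-binomial GLMs (log link, log size
#' factors as offset, dispersion fixed at the supplied or
#' method-of-moments estimate) under a full design including diet and
#' a reduced design without it, and tests `LR = 2 (ll_full - ll_red)`
#' against a chi-squared distribution with df equal to the number of
#' diet parameters (2 for three diets). Log2 fold changes per contrast
#' (40 vs 80, 60 vs 80) come from the full-model diet coefficients
#' with 80% MER as reference level. P-values are BH-adjusted across
#' features; non-converging features are flagged and excluded from the
#' adjustment.
#'
#' @param counts Feature-by-sample matrix of nonnegative counts (MAG
#'   abundances or KO-per-sample values, rounded to integers).
#' @param metadata Sample metadata; only samples present in `counts`
#'   columns are used, and diets are restricted to 40/60/80.
#' @param full,reduced Model formulas (defaults
#'   `~ period + animal_id + diet` vs `~ period + animal_id`).
#' @param dispersions Optional per-feature dispersions; estimated by
#'   [estimate_dispersion()] when `NULL`.
#' @param sf Optional size factors; [size_factors()] when `NULL`.
#' @return Tibble of class `mag_da`: `feature_id`, `base_mean`,
#'   `lfc_40vs80`, `lfc_60vs80`, `lr_stat`, `df`, `p`, `padj`,
#'   `converged`.
#' @export
nb_lrt <- function(counts, metadata,
                   full = ~ period + animal_id + diet,
                   reduced = ~ period + animal_id,
                   dispersions = NULL, sf = NULL) {
  m <- as_count_matrix(counts, "counts")
  metadata <- as_sample_metadata(metadata)
  metadata <- metadata[match(colnames(m), metadata$sample_id), ]
  if (anyNA(metadata$sample_id)) abort("count columns missing from metadata")
  keep <- metadata$diet %in% c(40L, 60L, 80L)
  m <- m[, keep, drop = FALSE]
  metadata <- metadata[keep, , drop = FALSE]
  m <- round(m)
  storage.mode(m) <- "double"

  md <- as.data.frame(metadata)
  md$diet <- stats::relevel(factor(md$diet), ref = "80")
  for (v in unique(c(all.vars(full), all.vars(reduced)))) {
    if (v != "diet") md[[v]] <- factor(md[[v]])
  }
  Xf <- model.matrix(full, data = md)
  qf <- qr(Xf)
  if (qf$rank < ncol(Xf)) Xf <- Xf[, qf$pivot[seq_len(qf$rank)], drop = FALSE]
  Xr <- model.matrix(reduced, data = md)
  qr_ <- qr(Xr)
  if (qr_$rank < ncol(Xr)) Xr <- Xr[, qr_$pivot[seq_len(qr_$rank)], drop = FALSE]
  df_test <- ncol(Xf) - ncol(Xr)
  if (df_test < 1) df_test <- 0L

  if (is.null(sf)) sf <- size_factors(m)
  off <- log(sf)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersion(m, sf, Xf)
  }

  ctrl <- glm.control(epsilon = 1e-8, maxit = 100)
  fit_one <- function(y, alpha) {
    theta <- 1 / max(alpha, 1e-8)
    fam <- MASS::negative.binomial(theta = theta)
    # non-convergence is detected below and flagged per feature
    ff <- tryCatch(
      suppressWarnings(stats::glm.fit(Xf, y, family = fam, offset = off,
                                      control = ctrl)),
      error = function(e) NULL)
    fr <- tryCatch(
      suppressWarnings(stats::glm.fit(Xr, y, family = fam, offset = off,
                                      control = ctrl)),
      error = function(e) NULL)
    if (is.null(ff) || is.null(fr) || !ff$converged || !fr$converged) {
      return(list(lr = NA_real_, lfc40 = NA_real_, lfc60 = NA_real_,
                  conv = FALSE))
    }
    lr <- 2 * (nb_loglik(y, ff$fitted.values, theta) -
                 nb_loglik(y, fr$fitted.values, theta))
    cf <- ff$coefficients
    list(lr = max(lr, 0),
         lfc40 = unname(cf["diet40"]) / log(2),
         lfc60 = unname(cf["diet60"]) / log(2),
         conv = TRUE)
  }

  norm_mean <- rowMeans(sweep(m, 2, sf, "/"))
  fits <- lapply(seq_len(nrow(m)), function(i) fit_one(m[i, ], dispersions[i]))
  out <- tibble(
    feature_id = rownames(m),
    base_mean = norm_mean,
    lfc_40vs80 = vapply(fits, `[[`, numeric(1), "lfc40"),
    lfc_60vs80 = vapply(fits, `[[`, numeric(1), "lfc60"),
    lr_stat = vapply(fits, `[[`, numeric(1), "lr"),
    df = df_test,
    converged = vapply(fits, `[[`, logical(1), "conv")
  )
  out$p <- ifelse(out$converged,
                  pchisq(out$lr_stat, df = df_test, lower.tail = FALSE),
                  NA_real_)
  out$padj <- NA_real_
  ok <- !is.na(out$p)
  out$padj[ok] <- bh_adjust(out$p[ok])
  class(out) <- c("mag_da", class(out))
  out
}

#' @rdname nb_lrt
#' @param x,object A `mag_da` result.
#' @param ... Unused.
#' @export
glance.mag_da <- function(x, ...) {
  tibble(n_features = nrow(x), n_converged = sum(x$converged),
         n_da = sum(x$padj < 0.05, na.rm = TRUE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wraps
#' `p.adjust(method = "BH")`) with input validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Split differentially abundant features by fold-change sign
#'
#' @param results A [nb_lrt()] result.
#' @param fdr FDR threshold on `padj` (default 0.05; kept iff
#'   `padj < fdr`).
#' @return List with `features` (the significant subset of `results`)
#'   and `summary` (tibble: `contrast`, `n_total`, `n_up`, `n_down`,
#'   `n_zero`).
#' @export
da_features <- function(results, fdr = 0.05) {
  sig <- results[!is.na(results$padj) & results$padj < fdr, , drop = FALSE]
  summ <- purrr::map_dfr(
    c(lfc_40vs80 = "40vs80", lfc_60vs80 = "60vs80"), function(ctr) {
      col <- names(which(c(lfc_40vs80 = "40vs80",
                           lfc_60vs80 = "60vs80") == ctr))
      tibble(contrast = ctr, n_total = nrow(sig),
             n_up = sum(sig[[col]] > 0), n_down = sum(sig[[col]] < 0),
             n_zero = sum(sig[[col]] == 0))
    })
  list(features = sig, summary = summ)
}
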