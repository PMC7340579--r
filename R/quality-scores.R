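#' Tie-averaged quality percentile ranks
#'
#' Ranks deposits 1..N from worst to best quality and converts ranks to
#' percentiles on the scale `100 * rank / N`, so the worst deposit scores
#' `100/N` and the best scores 100 (higher is always better). Groups of
#' tied values receive the average rank of the group, hence a shared
#' percentile.
#'
#' @param values Numeric vector, no missing values (impute first).
#' @param better Orientation of the input metric: `"lower"` when smaller
#'   values mean better quality (the case for every validation metric),
#'   `"higher"` when larger values are better (composite Q1 scores).
#' @param convention Percentile convention. `"inclusive"` (default) is
#'   `100 * rank / N`; `"midpoint"` is `100 * (rank - 0.5) / N`, which
#'   centres the scale but never awards exactly 100.
#' @return Numeric vector of percentiles in `(0, 100]` (inclusive
#'   convention). The mean of the returned vector is always
#'   `100 (N + 1) / (2N)` under the inclusive convention.
#' @examples
#' percentile_rank(c(10, 20, 20, 40), better = "lower")  # 100 62.5 62.5 25
#' @export
percentile_rank <- function(values, better = c("lower", "higher"),
                            convention = c("inclusive", "midpoint")) {
  better <- match.arg(better)
  convention <- match.arg(convention)
  if (!length(values)) stop("percentile_rank: empty input")
  if (anyNA(values)) stop("percentile_rank: missing values; impute first")
  ## rank 1 = worst: for "lower is better" the largest value is worst
  oriented <- if (better == "lower") -values else values
  r <- rank(oriented, ties.method = "average")
  n <- length(values)
  if (convention == "inclusive") 100 * r / n else 100 * (r - 0.5) / n
}

#' Fit the geometry PCA aggregate
#'
#' Fits a principal component analysis of the three geometry metrics
#' (Clashscore, Ramachandran outliers, Rotamer outliers) over the protein
#' group (proteins plus protein-nucleic-acid complexes). Structures with
#' extreme geometry (Rotamer outliers > 50\%, Ramachandran outliers >
#' 45\%, or Clashscore > 250) are excluded from the fit -- standardization
#' parameters and loadings alike -- but are still scored like any other
#' deposit by [score_geometry()]. Inputs are standardized to zero mean and
#' unit variance before the decomposition, and PC1 is oriented so that all
#' three loadings are non-negative: larger PC1 means worse geometry.
#'
#' @param records Deposit tibble; only protein-group rows complete in the
#'   three geometry metrics are used.
#' @param outlier_thresholds Named list of exclusion thresholds
#'   (`rota_outliers`, `rama_outliers`, `clashscore`).
#' @return An object of class `geometry_pca`: standardization `means` and
#'   `sds`, the orthonormal 3x3 `loadings` matrix, `explained_variance`
#'   fractions (non-increasing, summing to 1), and `outlier_ids`.
#' @export
fit_geometry_pca <- function(records,
                             outlier_thresholds = list(rota_outliers = 50,
                                                       rama_outliers = 45,
                                                       clashscore = 250)) {
  geom_cols <- c("clashscore", "rama_outliers", "rota_outliers")
  prot <- records[molecule_group(records$molecule_class) == "protein", , drop = FALSE]
  prot <- prot[stats::complete.cases(prot[, geom_cols]), , drop = FALSE]
  if (nrow(prot) < 3) stop("need at least 3 complete protein-group deposits")

  is_outlier <- prot$rota_outliers > outlier_thresholds$rota_outliers |
    prot$rama_outliers > outlier_thresholds$rama_outliers |
    prot$clashscore > outlier_thresholds$clashscore
  fit_set <- prot[!is_outlier, geom_cols, drop = FALSE]
  if (nrow(fit_set) < 3) stop("fewer than 3 deposits left after outlier exclusion")

  means <- vapply(fit_set, mean, numeric(1))
  sds <- vapply(fit_set, sd, numeric(1))
  if (any(sds == 0)) stop("zero variance in a geometry metric")

  z <- scale(as.matrix(fit_set), center = means, scale = sds)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  loadings <- pc$rotation
  ## orient PC1 so that all loadings are non-negative (badness direction)
  if (sum(loadings[, 1]) < 0) loadings[, 1] <- -loadings[, 1]
  ev <- pc$sdev^2 / sum(pc$sdev^2)

  structure(list(means = means, sds = sds, loadings = loadings,
                 explained_variance = ev,
                 outlier_ids = prot$pdb_id[is_outlier],
                 n_fit = nrow(fit_set),
                 thresholds = outlier_thresholds),
            class = "geometry_pca")
}

#' @export
print.geometry_pca <- function(x, ...) {
  cat("Geometry PCA (Clashscore, Ramachandran outliers, Rotamer outliers)\n")
  cat(sprintf("  fitted on %d protein-group deposits (%d outliers excluded)\n",
              x$n_fit, length(x$outlier_ids)))
  cat(sprintf("  explained variance: %s\n",
              paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = " / ")))
  cat(sprintf("  PC1 loadings: %s\n",
              paste(sprintf("%.3f", x$loadings[, 1]), collapse = " / ")))
  invisible(x)
}

#' Score deposits on the geometry PC1 axis
#'
#' Projects deposits onto the first principal component of a fitted
#' [fit_geometry_pca()] model, using the model's standardization
#' parameters. Deposits that were excluded as outliers during fitting are
#' scored like any other; nucleic-acid-only deposits cannot be scored
#' (their Ramachandran/Rotamer metrics are inapplicable) and raise an
#' error.
#'
#' @param model A `geometry_pca` object.
#' @param records Deposit tibble, complete in the three geometry metrics.
#' @return Numeric PC1 score per row; larger means worse geometry.
#' @export
score_geometry <- function(model, records) {
  if (any(records$molecule_class == "nucleic_acid")) {
    stop("geometry PCA is inapplicable to nucleic-acid-only deposits")
  }
  geom_cols <- c("clashscore", "rama_outliers", "rota_outliers")
  m <- as.matrix(records[, geom_cols])
  if (anyNA(m)) stop("geometry metrics incomplete; impute first")
  z <- scale(m, center = model$means[geom_cols], scale = model$sds[geom_cols])
  drop(z %*% model$loadings[geom_cols, 1])
}

#' Composite quality scores Q1 and their percentiles
#'
#' Computes, per deposit, the composite quality score from three component
#' percentiles and the final quality percentile `P_Q1` of that score
#' within the deposit's molecule group. For the protein group (proteins
#' and complexes) the components are the percentiles of R-free, RSRZ
#' outliers, and the geometry PC1 aggregate (the Q1p construction); for
#' nucleic acids the geometry aggregate is replaced by the Clashscore
#' percentile (Q1n). The averaging variant is the mean of the three
#' component percentiles and the minimum variant is their minimum ("a
#' structure is as good as its weakest feature"); both are always
#' returned, and `p_q1` ranks the variant selected by `variant`.
#'
#' Component percentiles are computed within the molecule group over the
#' full (imputed) dataset; protein and nucleic populations never mix.
#'
#' @param records Completed deposit tibble (no missing applicable metrics).
#' @param pca A fitted [fit_geometry_pca()] model (required when any
#'   protein-group rows are present).
#' @param variant Which composite feeds the final percentile:
#'   `"averaging"` (default) or `"minimum"`.
#' @param convention Percentile convention, see [percentile_rank()].
#' @return A tibble: `pdb_id`, `group`, component percentiles (`p_rfree`,
#'   `p_rsrz`, `p_geom`), `q1` (averaging), `q1_min` (minimum), and `p_q1`.
#' @export
compute_q1 <- function(records, pca = NULL,
                       variant = c("averaging", "minimum"),
                       convention = c("inclusive", "midpoint")) {
  variant <- match.arg(variant)
  convention <- match.arg(convention)
  need <- c("r_free", "rsrz_outliers", "clashscore")
  if (anyNA(records[, need])) stop("missing component metrics; impute first")

  group <- molecule_group(records$molecule_class)
  out <- tibble::tibble(pdb_id = records$pdb_id, group = group,
                        p_rfree = NA_real_, p_rsrz = NA_real_, p_geom = NA_real_)

  for (g in unique(group)) {
    idx <- which(group == g)
    sub <- records[idx, , drop = FALSE]
    out$p_rfree[idx] <- percentile_rank(sub$r_free, "lower", convention)
    out$p_rsrz[idx] <- percentile_rank(sub$rsrz_outliers, "lower", convention)
    if (g == "protein") {
      if (is.null(pca)) stop("protein-group rows require a fitted geometry PCA model")
      pc1 <- score_geometry(pca, sub)
      out$p_geom[idx] <- percentile_rank(pc1, "lower", convention)
    } else {
      out$p_geom[idx] <- percentile_rank(sub$clashscore, "lower", convention)
    }
  }

  out$q1 <- (out$p_rfree + out$p_rsrz + out$p_geom) / 3
  out$q1_min <- pmin(out$p_rfree, out$p_rsrz, out$p_geom)
  chosen <- if (variant == "averaging") out$q1 else out$q1_min
  out$p_q1 <- NA_real_
  for (g in unique(group)) {
    idx <- which(group == g)
    out$p_q1[idx] <- percentile_rank(chosen[idx], "higher", convention)
  }
  attr(out, "variant") <- variant
  attr(out, "convention") <- convention
  out
}

#' PCA-free approximation of the protein composite score
#'
#' Approximates the protein composite by replacing the geometry PC1
#' percentile with the plain average of the three geometry-metric
#' percentiles:
#' `(P_Rfree + P_RSRZ + (P_Clash + P_Rama + P_Rota) / 3) / 3`.
#' The approximation rests on the near-equal PC1 loadings of the three
#' geometry metrics; on realistic data it is rank-correlated with the
#' exact score above 0.95.
#'
#' @param p_rfree,p_rsrz,p_clash,p_rama,p_rota Component percentiles in
#'   `(0, 100]`.
#' @return Numeric approximate composite score.
#' @export
q1p_approx <- function(p_rfree, p_rsrz, p_clash, p_rama, p_rota) {
  comps <- list(p_rfree, p_rsrz, p_clash, p_rama, p_rota)
  for (x in comps) {
    if (any(is.na(x)) || any(x < 0 | x > 100)) {
      stop("component percentiles must lie in [0, 100]")
    }
  }
  (p_rfree + p_rsrz + (p_clash + p_rama + p_rota) / 3) / 3
}
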