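#' Extract the complete portion of a deposit table
#'
#' Returns the rows whose applicable imputable cells (the five quality
#' metrics plus R; Ramachandran/Rotamer only where applicable) are all
#' observed. This subset is the ground truth for the masking-based
#' evaluation of imputation methods.
#'
#' @param deposits Deposit tibble.
#' @return The complete-row subset.
#' @export
complete_subset <- function(deposits) {
  ok <- rep(TRUE, nrow(deposits))
  for (m in .imputable_cols) {
    app <- metric_applicable(deposits$molecule_class, m)
    ok <- ok & (!app | !is.na(deposits[[m]]))
  }
  deposits[ok, , drop = FALSE]
}

#' Hide observed cells at archive-like rates
#'
#' Randomly masks cells of a complete deposit table, independently per
#' metric at the given rates, emulating the archive's missing-data
#' pattern so that imputation methods can be scored against the hidden
#' truth. The fraction of deposits left with at least one missing metric
#' is emergent from the per-metric rates (at archive rates it lands near
#' 12.7\%).
#'
#' @details With `target_any_fraction = NULL` (the default) cells are
#' hidden independently per metric, and the fraction of deposits with at
#' least one hidden cell is whatever the product rule implies. In the
#' archive, however, missingness is correlated across metrics (RSRZ and
#' R-free are co-missing in early depositions), so the archive's
#' any-missing share is lower than the independence product. Supplying
#' `target_any_fraction` switches to a common-factor Gaussian-copula
#' masking: each deposit draws a shared latent, each metric's indicator
#' thresholds a mixture of the shared and an idiosyncratic latent, which
#' preserves every per-metric rate exactly in the marginal while the
#' factor loading -- solved by root-finding -- sets the expected
#' any-missing fraction to the target. The target must lie between the
#' comonotone lower bound (max of the rates) and the independence upper
#' bound.
#'
#' @param complete Deposit tibble with no missing applicable cells.
#' @param fractions Named per-metric masking probabilities (defaults:
#'   archive missing-value rates).
#' @param target_any_fraction Optional target for the fraction of
#'   deposits with at least one hidden cell (see Details).
#' @param seed Integer seed; masking is deterministic given it.
#' @return A list of class `masked_dataset`: `masked` (the table with
#'   cells hidden), `mask` (tibble `row`, `metric`), `truth` (hidden
#'   values, aligned with `mask`), `realized_fractions`, and
#'   `any_missing_fraction`.
#' @export
inject_missingness <- function(complete,
                               fractions = synthetic_config()$missing_fractions,
                               target_any_fraction = NULL,
                               seed = 1) {
  for (m in .imputable_cols) {
    app <- metric_applicable(complete$molecule_class, m)
    if (any(is.na(complete[[m]][app]))) stop("input not complete in ", m)
  }
  bad <- names(fractions)[fractions > 0 & !vapply(
    names(fractions),
    function(m) any(metric_applicable(complete$molecule_class, m)), logical(1))]
  if (length(bad)) {
    stop("positive masking fraction on fully inapplicable column(s): ",
         paste(bad, collapse = ", "))
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  n <- nrow(complete)
  rho <- if (is.null(target_any_fraction)) 0 else {
    solve_masking_factor(fractions, target_any_fraction,
                         complete$molecule_class)
  }
  shared <- if (rho > 0) rnorm(n) else numeric(n)

  masked <- complete
  rows <- integer(0); metrics <- character(0); truth <- numeric(0)
  realized <- setNames(numeric(length(fractions)), names(fractions))
  for (m in names(fractions)) {
    app <- which(metric_applicable(complete$molecule_class, m))
    z <- rho * shared[app] + sqrt(1 - rho^2) * rnorm(length(app))
    hide <- app[z < stats::qnorm(fractions[[m]])]
    masked[[m]][hide] <- NA_real_
    rows <- c(rows, hide)
    metrics <- c(metrics, rep(m, length(hide)))
    truth <- c(truth, complete[[m]][hide])
    realized[m] <- length(hide) / length(app)
  }
  any_missing <- length(unique(rows)) / nrow(complete)
  structure(list(masked = masked,
                 mask = tibble::tibble(row = rows, metric = metrics),
                 truth = truth,
                 realized_fractions = realized,
                 any_missing_fraction = any_missing),
            class = "masked_dataset")
}

## Expected any-missing fraction under the common-factor masking model,
## averaged over the applicability classes present in the data.
expected_any_missing <- function(rho, fractions, molecule_class) {
  classes <- table(molecule_class == "nucleic_acid") / length(molecule_class)
  p_any_class <- function(nucleic) {
    mets <- names(fractions)[fractions > 0]
    if (nucleic) mets <- setdiff(mets, c("rama_outliers", "rota_outliers"))
    if (!length(mets)) return(0)
    thr <- stats::qnorm(unlist(fractions[mets]))
    f <- function(u) {
      p_none <- rep(1, length(u))
      for (t in thr) {
        p_none <- p_none * (1 - pnorm((t - rho * u) / sqrt(1 - rho^2)))
      }
      stats::dnorm(u) * (1 - p_none)
    }
    stats::integrate(f, -8, 8, rel.tol = 1e-9)$value
  }
  tot <- 0
  for (nm in names(classes)) {
    tot <- tot + classes[[nm]] * p_any_class(nm == "TRUE")
  }
  tot
}

## Root-find the factor loading that hits the target any-missing fraction.
solve_masking_factor <- function(fractions, target, molecule_class) {
  lo <- expected_any_missing(0.999, fractions, molecule_class)
  hi <- expected_any_missing(0, fractions, molecule_class)
  if (target > hi || target < lo) {
    stop(sprintf(paste0("target any-missing fraction %.4f outside the ",
                        "attainable range [%.4f, %.4f]"), target, lo, hi))
  }
  if (abs(target - hi) < 1e-10) return(0)
  stats::uniroot(function(r) expected_any_missing(r, fractions, molecule_class) - target,
                 c(1e-6, 0.999), tol = 1e-6)$root
}

#' Imputation error statistics
#'
#' Per-metric error measures comparing imputed values against the hidden
#' truth at masked cells: MAD (median absolute error), MAE (mean absolute
#' error), and RMSE (root-mean-square error).
#'
#' @param truth,imputed Numeric vectors of equal length, values at masked
#'   cells.
#' @param metric Character vector assigning each pair to a metric (or
#'   `NULL` to pool everything under `"all"`).
#' @param mad_mode `"median_abs_error"` (default): MAD is the median of
#'   the absolute errors, on the same scale as MAE/RMSE.
#'   `"dispersion"`: the classical median-absolute-deviation of the
#'   errors about their median.
#' @return Tibble with columns `metric`, `mad`, `mae`, `rmse`, `n`.
#'   Metrics with no pairs are reported with `NA` statistics.
#' @export
error_stats <- function(truth, imputed, metric = NULL,
                        mad_mode = c("median_abs_error", "dispersion")) {
  mad_mode <- match.arg(mad_mode)
  if (length(truth) != length(imputed)) stop("truth/imputed length mismatch")
  if (is.null(metric)) metric <- rep("all", length(truth))
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(metric = metric, err = truth - imputed), .data$metric),
    mad = if (mad_mode == "median_abs_error") median(abs(.data$err))
          else median(abs(.data$err - median(.data$err))),
    mae = mean(abs(.data$err)),
    rmse = sqrt(mean(.data$err^2)),
    n = dplyr::n(),
    .groups = "drop")
}

#' Evaluate imputation methods by repeated masking
#'
#' Reproduces the masking protocol for benchmarking imputation methods:
#' in each repetition, cells of the complete table are hidden at the
#' archive's per-metric rates, every method imputes the *same* masked
#' table (a paired design), and the imputations are scored against the
#' hidden truth with MAD/MAE/RMSE per metric. Across repetitions the
#' per-(metric, error-measure) method comparison is tested with a
#' Friedman test (repetitions as blocks) and Nemenyi post hoc pairwise
#' tests.
#'
#' @param complete Deposit tibble with no missing applicable cells.
#' @param methods Character vector among `"mean"`, `"median"`, `"mice"`,
#'   and `"oracle"` (returns the truth; useful as a sanity check).
#' @param n_repetitions Number of masking repetitions (>= 2).
#' @param fractions Per-metric masking rates, see [inject_missingness()].
#' @param target_any_fraction Optional any-missing target passed to
#'   [inject_missingness()].
#' @param seed Integer root seed; repetition `r` uses `seed + r`.
#' @param mice_iterations Cycles for the chained-equations method.
#' @param mad_mode MAD convention, see [error_stats()].
#' @return An object of class `imputation_eval`: `results` (per
#'   repetition x method x metric errors), `summary` (mean and SD per
#'   method x metric x measure), `friedman` (per metric x measure
#'   p-values), `nemenyi` (pairwise p-value matrices), and
#'   `n_repetitions` actually completed.
#' @export
run_evaluation <- function(complete, methods = c("mean", "median", "mice"),
                           n_repetitions = 100,
                           fractions = synthetic_config()$missing_fractions,
                           target_any_fraction = NULL,
                           seed = 1, mice_iterations = 10,
                           mad_mode = c("median_abs_error", "dispersion")) {
  mad_mode <- match.arg(mad_mode)
  if (n_repetitions < 2) stop("need at least 2 repetitions")
  stopifnot(all(methods %in% c("mean", "median", "mice", "oracle")))

  rows <- list()
  done <- 0L
  for (r in seq_len(n_repetitions)) {
    msk <- inject_missingness(complete, fractions,
                              target_any_fraction = target_any_fraction,
                              seed = seed + r)
    rep_ok <- TRUE
    for (meth in methods) {
      imput <- tryCatch({
        if (meth == "oracle") {
          complete
        } else if (meth == "mice") {
          mice_impute(msk$masked, n_iterations = mice_iterations, seed = seed + r)$completed
        } else {
          impute_constant(msk$masked, meth)$completed
        }
      }, error = function(e) {
        warning("repetition ", r, ", method ", meth, " failed: ", conditionMessage(e))
        NULL
      })
      if (is.null(imput)) { rep_ok <- FALSE; break }
      imputed_vals <- vapply(seq_len(nrow(msk$mask)), function(k) {
        imput[[msk$mask$metric[k]]][msk$mask$row[k]]
      }, numeric(1))
      st <- error_stats(msk$truth, imputed_vals, msk$mask$metric, mad_mode)
      st$method <- meth
      st$repetition <- r
      rows[[length(rows) + 1]] <- st
    }
    if (rep_ok) done <- done + 1L
  }
  results <- dplyr::bind_rows(rows)

  long <- tidyr::pivot_longer(results, c("mad", "mae", "rmse"),
                              names_to = "measure", values_to = "error")
  summary <- dplyr::summarise(
    dplyr::group_by(long, .data$method, .data$metric, .data$measure),
    mean_error = mean(.data$error), sd_error = sd(.data$error),
    .groups = "drop")

  friedman <- list(); nemenyi <- list()
  for (met in unique(long$metric)) {
    for (ms in unique(long$measure)) {
      sub <- long[long$metric == met & long$measure == ms, ]
      wide <- tidyr::pivot_wider(sub[, c("repetition", "method", "error")],
                                 names_from = "method", values_from = "error")
      mat <- as.matrix(wide[, methods, drop = FALSE])
      mat <- mat[stats::complete.cases(mat), , drop = FALSE]
      if (nrow(mat) >= 2 && ncol(mat) >= 2) {
        fr <- friedman_nemenyi(mat)
        friedman[[paste(met, ms, sep = ".")]] <- fr$friedman_p
        nemenyi[[paste(met, ms, sep = ".")]] <- fr$nemenyi_p
      }
    }
  }
  structure(list(results = results, summary = summary,
                 friedman = unlist(friedman), nemenyi = nemenyi,
                 n_repetitions = done, methods = methods,
                 mad_mode = mad_mode),
            class = "imputation_eval")
}

#' @export
print.imputation_eval <- function(x, ...) {
  cat(sprintf("Imputation evaluation: %d repetition(s), methods: %s\n",
              x$n_repetitions, paste(x$methods, collapse = ", ")))
  best <- dplyr::slice_min(
    dplyr::group_by(x$summary, .data$metric, .data$measure),
    .data$mean_error, n = 1, with_ties = FALSE)
  cat("Best method per metric x measure:\n")
  print(as.data.frame(best), row.names = FALSE)
  invisible(x)
}

#' Friedman test with Nemenyi post hoc on a block x treatment error matrix
#'
#' Rank-based comparison of methods over paired blocks (here: masking
#' repetitions). The Friedman test asks whether any method differs; the
#' Nemenyi post hoc compares all method pairs through the studentized
#' range distribution of their mean-rank differences.
#'
#' @param mat Numeric matrix, rows = blocks, columns = treatments
#'   (smaller error = better).
#' @return List with `friedman_p` and the symmetric `nemenyi_p` matrix.
#' @export
friedman_nemenyi <- function(mat) {
  k <- ncol(mat); n <- nrow(mat)
  fr <- friedman.test(mat)
  ranks <- t(apply(mat, 1, rank))
  mean_ranks <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (12 * n))
  p <- matrix(NA_real_, k, k, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) {
      q <- abs(mean_ranks[i] - mean_ranks[j]) / se
      p[i, j] <- 1 - ptukey(q, nmeans = k, df = Inf)
    }
  }
  list(friedman_p = fr$p.value, nemenyi_p = p, mean_ranks = mean_ranks)
}
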