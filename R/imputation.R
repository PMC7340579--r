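#' Impute missing quality metrics
#'
#' Fills missing cells of the imputable metric columns (the five quality
#' metrics plus the supporting R factor) by one of three methods:
#' per-column mean, per-column median, or chained-equations regression
#' (`"mice"`, see Details). Observed cells are never altered;
#' structurally inapplicable cells (Ramachandran/Rotamer outliers of
#' nucleic-acid-only deposits) are excluded from fitting and never filled.
#' Imputed values falling outside a metric's legal range are clipped to
#' it.
#'
#' @details The chained-equations method initializes missing cells with
#' column means and then cycles over the incomplete columns in order of
#' decreasing missingness. For each column it fits a Bayesian-ridge linear
#' regression of the observed entries on all other imputable columns plus
#' the always-complete supporting variables (resolution, deposition
#' year), with the regularization and noise precisions estimated by
#' evidence maximization, and replaces the column's missing entries with
#' posterior-mean predictions. Cycles repeat up to `iterations` times,
#' stopping early when the largest absolute change of any imputed cell
#' drops below `tol`. Predictions are posterior means, so the procedure is
#' deterministic given the input (the `seed` is recorded for provenance).
#'
#' @param deposits Deposit tibble.
#' @param method `"mean"`, `"median"`, or `"mice"`.
#' @param iterations Maximum chained-equations cycles (default 10).
#' @param seed Integer, recorded in the result.
#' @param tol Early-stop tolerance on the largest absolute change of an
#'   imputed cell between cycles.
#' @return An object of class `imputation_result`: `completed` (the
#'   deposit tibble with no missing applicable cells), `provenance` (a
#'   tibble flagging each imputable cell `observed`, `imputed`, or
#'   `inapplicable`), `method`, `seed`, and `n_iterations` (cycles
#'   actually run).
#' @export
impute_deposits <- function(deposits, method = c("mean", "median", "mice"),
                            iterations = 10, seed = 1, tol = 1e-4) {
  method <- match.arg(method)
  cols <- .imputable_cols
  applicable <- vapply(cols, function(m) metric_applicable(deposits$molecule_class, m),
                       logical(nrow(deposits)))
  if (nrow(deposits) == 1) applicable <- matrix(applicable, nrow = 1, dimnames = list(NULL, cols))
  observed <- vapply(cols, function(m) !is.na(deposits[[m]]), logical(nrow(deposits)))
  if (nrow(deposits) == 1) observed <- matrix(observed, nrow = 1, dimnames = list(NULL, cols))

  completed <- deposits
  n_iter <- 0L
  if (method %in% c("mean", "median")) {
    statf <- if (method == "mean") mean else median
    for (m in cols) {
      obs <- observed[, m] & applicable[, m]
      fill <- !obs & applicable[, m]
      if (!any(fill)) next
      if (!any(obs)) stop("metric fully missing, cannot impute: ", m)
      completed[[m]][fill] <- clip_to_range(statf(deposits[[m]][obs]), m)
    }
  } else {
    res <- chained_equations(deposits, observed, applicable,
                             iterations = iterations, tol = tol)
    completed <- res$completed
    n_iter <- res$n_iterations
  }

  prov <- matrix("inapplicable", nrow(deposits), length(cols),
                 dimnames = list(NULL, cols))
  prov[applicable & observed] <- "observed"
  prov[applicable & !observed] <- "imputed"
  provenance <- tibble::as_tibble(as.data.frame(prov, stringsAsFactors = FALSE))
  provenance <- tibble::add_column(provenance, pdb_id = deposits$pdb_id, .before = 1)

  structure(list(completed = completed, provenance = provenance,
                 method = method, seed = seed, n_iterations = n_iter),
            class = "imputation_result")
}

#' Constant-value imputation
#'
#' Convenience wrapper around [impute_deposits()] that fills each missing
#' cell with the column statistic computed over observed cells only.
#'
#' @param deposits Deposit tibble.
#' @param statistic `"mean"` or `"median"`.
#' @return An `imputation_result`, see [impute_deposits()].
#' @export
impute_constant <- function(deposits, statistic = c("mean", "median")) {
  impute_deposits(deposits, method = match.arg(statistic))
}

#' Chained-equations imputation
#'
#' Convenience wrapper around [impute_deposits()] for the
#' chained-equations method with a Bayesian-ridge predictor.
#'
#' @param deposits Deposit tibble.
#' @param n_iterations Maximum cycles over the incomplete columns.
#' @param seed Integer, recorded in the result (predictions are posterior
#'   means, hence deterministic).
#' @return An `imputation_result`, see [impute_deposits()].
#' @export
mice_impute <- function(deposits, n_iterations = 10, seed = 1) {
  impute_deposits(deposits, method = "mice", iterations = n_iterations, seed = seed)
}

#' @export
print.imputation_result <- function(x, ...) {
  n_imp <- sum(as.matrix(x$provenance[, .imputable_cols]) == "imputed")
  cat(sprintf("Imputation (%s): %d cells filled across %d deposits",
              x$method, n_imp, nrow(x$completed)))
  if (x$method == "mice") cat(sprintf(", %d cycle(s)", x$n_iterations))
  cat("\n")
  invisible(x)
}

## Chained-equations sweep. Columns are visited in descending missingness
## order; each incomplete column is regressed on every other variable's
## current values with a Bayesian ridge and its missing entries replaced
## by posterior-mean predictions.
chained_equations <- function(deposits, observed, applicable, iterations, tol) {
  cols <- .imputable_cols
  pred_cols <- c(cols, .support_cols)
  X <- as.matrix(deposits[, pred_cols])
  mode(X) <- "double"

  obs_app <- observed & applicable
  miss_app <- !observed & applicable
  n_missing <- colSums(miss_app)
  incomplete <- cols[n_missing > 0]
  if (sum(colSums(obs_app) > 0) < 2) stop("need at least 2 columns with observed data")

  ## init: column means over observed cells; inapplicable cells get the
  ## mean too, purely as predictor placeholders (never reported)
  col_means <- vapply(cols, function(m) {
    if (!any(obs_app[, m])) stop("metric fully missing, cannot impute: ", m)
    mean(X[obs_app[, m], m])
  }, numeric(1))
  for (m in cols) X[!obs_app[, m], m] <- col_means[[m]]

  visit <- incomplete[order(-n_missing[incomplete])]
  n_iter <- 0L
  for (it in seq_len(iterations)) {
    max_change <- 0
    for (m in visit) {
      others <- setdiff(pred_cols, m)
      fit_rows <- obs_app[, m]
      prd_rows <- miss_app[, m]
      new_vals <- tryCatch(
        bayesian_ridge_predict(X[fit_rows, others, drop = FALSE],
                               X[fit_rows, m],
                               X[prd_rows, others, drop = FALSE]),
        error = function(e) {
          warning("ridge fit degenerate for ", m, "; falling back to column mean")
          rep(col_means[[m]], sum(prd_rows))
        })
      new_vals <- clip_to_range(new_vals, m)
      if (length(new_vals)) {
        max_change <- max(max_change, max(abs(new_vals - X[prd_rows, m])))
      }
      X[prd_rows, m] <- new_vals
    }
    n_iter <- it
    if (max_change < tol) break
  }

  completed <- deposits
  for (m in cols) {
    vals <- deposits[[m]]
    vals[miss_app[, m]] <- X[miss_app[, m], m]
    completed[[m]] <- vals
  }
  list(completed = completed, n_iterations = n_iter)
}

## Bayesian ridge regression by evidence maximization (type-II maximum
## likelihood): iterates closed-form updates of the weight precision
## lambda and noise precision alpha, returns posterior-mean predictions.
bayesian_ridge_predict <- function(X, y, Xnew, max_iter = 100, tol = 1e-6) {
  if (!nrow(Xnew)) return(numeric(0))
  ## constant predictors carry no information and break conditioning
  keep <- apply(X, 2, sd) > 0
  if (!any(keep)) stop("no varying predictors")
  X <- X[, keep, drop = FALSE]
  Xnew <- Xnew[, keep, drop = FALSE]
  if (nrow(X) <= ncol(X) + 1) stop("too few observations for ridge fit")
  xm <- colMeans(X)
  xs <- apply(X, 2, sd)
  Xc <- scale(X, center = xm, scale = xs)
  ym <- mean(y)
  yc <- y - ym

  p <- ncol(Xc); n <- nrow(Xc)
  XtX <- crossprod(Xc)
  Xty <- crossprod(Xc, yc)
  ## work in the eigenbasis of X'X: stable under collinear predictors
  ed <- eigen(XtX, symmetric = TRUE)
  d <- pmax(ed$values, 0)
  null_dir <- d < max(d) * 1e-12
  b <- drop(crossprod(ed$vectors, Xty))
  b[null_dir] <- 0   # no data support along null directions

  alpha <- 1 / max(stats::var(yc), 1e-12)
  lambda <- 1
  w <- rep(0, p)
  for (i in seq_len(max_iter)) {
    coef_eig <- alpha * b / (alpha * d + lambda)
    w_new <- drop(ed$vectors %*% coef_eig)
    gamma <- sum(alpha * d / (lambda + alpha * d))
    rss <- sum((yc - drop(Xc %*% w_new))^2)
    lambda <- min(max(gamma / max(sum(w_new^2), 1e-12), 1e-10), 1e10)
    alpha <- min(max(n - gamma, 1e-6) / max(rss, 1e-12), 1e12)
    if (max(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
  }
  Xnc <- scale(Xnew, center = xm, scale = xs)
  drop(Xnc %*% w) + ym
}
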