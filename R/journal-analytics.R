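#' Arithmetic, geometric, and V-mean of resolutions
#'
#' Three summaries of a set of resolutions: the arithmetic mean, the
#' geometric mean (log-average), and the V-mean -- the power mean of
#' exponent -3, `(mean(d^-3))^(-1/3)`, which averages in inverse volume
#' and therefore weights the best (smallest) resolutions most. By the
#' power-mean inequality V-mean <= G-mean <= arithmetic mean.
#'
#' @param resolutions Numeric vector of resolutions in Angstrom, all > 0.
#' @return Named numeric vector `c(mean, g_mean, v_mean)`.
#' @export
resolution_means <- function(resolutions) {
  if (!length(resolutions)) stop("empty resolution vector")
  if (any(is.na(resolutions)) || any(resolutions <= 0)) {
    stop("resolutions must be positive")
  }
  c(mean = mean(resolutions),
    g_mean = exp(mean(log(resolutions))),
    v_mean = mean(resolutions^-3)^(-1 / 3))
}

## join temporal scores to deposits and pick the ranking measure
measure_frame <- function(temporal_scores, records, measure) {
  if (is.null(temporal_scores[[measure]])) {
    stop("temporal scores lack measure column: ", measure)
  }
  i <- match(temporal_scores$pdb_id, records$pdb_id)
  if (anyNA(i)) stop("temporal scores contain pdb_ids absent from records")
  journal <- if ("journal" %in% names(records)) records$journal else
    normalize_journal(records$journal_raw)
  tibble::tibble(pdb_id = temporal_scores$pdb_id,
                 journal = journal[i],
                 issn = records$issn[i],
                 deposition_date = records$deposition_date[i],
                 deposition_year = records$deposition_year[i],
                 resolution = records$resolution[i],
                 score = temporal_scores[[measure]])
}

#' All-time (or date-restricted) journal quality ranking
#'
#' Ranks journals by the mean of a temporal quality percentile over the
#' deposits citing them, keeping only journals with at least `min_count`
#' structures. Each journal's deposits are compared against all other
#' deposits with a two-sided Welch t-test, Bonferroni-corrected over the
#' number of ranked journals at significance level `alpha`. "To be
#' published" is a venue like any other. An optional `date_cutoff`
#' restricts the input to deposits dated strictly before it, which turns
#' the same pipeline into a retrospective ranking.
#'
#' @param temporal_scores Tibble from [temporal_percentile()].
#' @param records Deposit tibble with canonical `journal` names (see
#'   [clean_journal_names()]).
#' @param min_count Minimum number of structures for a journal to be
#'   ranked (default 100).
#' @param measure Score column to average (default `"p_q1_td"`).
#' @param date_cutoff Optional `Date` (or string): keep deposits dated
#'   strictly before it.
#' @param alpha Family-wise significance level before Bonferroni division
#'   (default 0.001).
#' @return A tibble sorted by descending mean score: `rank` (dense),
#'   `journal`, `mean_score`, `mean_resolution`, `g_mean_resolution`,
#'   `v_mean_resolution`, `n_structures`, `p_value` (Welch, uncorrected),
#'   `significant` (after Bonferroni).
#' @export
rank_journals <- function(temporal_scores, records, min_count = 100,
                          measure = "p_q1_td", date_cutoff = NULL,
                          alpha = 0.001) {
  df <- measure_frame(temporal_scores, records, measure)
  if (!is.null(date_cutoff)) {
    df <- df[df$deposition_date < as.Date(date_cutoff), , drop = FALSE]
  }
  counts <- table(df$journal)
  eligible <- names(counts)[counts >= min_count]
  if (!length(eligible)) {
    warning("no journal meets the minimum structure count")
    return(tibble::tibble(rank = integer(), journal = character(),
                          mean_score = numeric(), mean_resolution = numeric(),
                          g_mean_resolution = numeric(), v_mean_resolution = numeric(),
                          n_structures = integer(), p_value = numeric(),
                          significant = logical()))
  }
  rows <- lapply(eligible, function(j) {
    in_j <- df$journal == j
    x <- df$score[in_j]
    y <- df$score[!in_j]   # complement: all deposits not citing j
    p <- if (length(y) >= 2) t.test(x, y)$p.value else NA_real_
    rm <- resolution_means(df$resolution[in_j])
    tibble::tibble(journal = j, mean_score = mean(x),
                   mean_resolution = rm[["mean"]],
                   g_mean_resolution = rm[["g_mean"]],
                   v_mean_resolution = rm[["v_mean"]],
                   n_structures = sum(in_j), p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha / nrow(out)
  out <- out[order(-out$mean_score), , drop = FALSE]
  out <- tibble::add_column(out, rank = dplyr::dense_rank(dplyr::desc(out$mean_score)),
                            .before = 1)
  out
}

#' Journal rankings within consecutive year windows
#'
#' Partitions the time axis into consecutive windows of `window_years`
#' years, anchored so the last window ends at the dataset's final year,
#' and ranks journals within each window by mean score. A journal appears
#' in a window only if it has at least `min_count` structures there.
#'
#' @inheritParams rank_journals
#' @param window_years Window length in years (default 5).
#' @param min_count Minimum in-window structures (default 30).
#' @return Tibble: `window_start`, `window_end`, `journal`, `mean_score`,
#'   `n_structures`, `rank` (dense, per window).
#' @export
windowed_ranking <- function(temporal_scores, records, window_years = 5,
                             min_count = 30, measure = "p_q1_td") {
  df <- measure_frame(temporal_scores, records, measure)
  last <- max(df$deposition_year)
  ## window index counted backwards from the final year
  w <- (last - df$deposition_year) %/% window_years
  df$window_end <- last - w * window_years
  df$window_start <- df$window_end - window_years + 1

  agg <- dplyr::summarise(
    dplyr::group_by(df, .data$window_start, .data$window_end, .data$journal),
    mean_score = mean(.data$score), n_structures = dplyr::n(),
    .groups = "drop")
  agg <- agg[agg$n_structures >= min_count, , drop = FALSE]
  agg <- dplyr::mutate(
    dplyr::group_by(agg, .data$window_start),
    rank = dplyr::dense_rank(dplyr::desc(.data$mean_score)))
  dplyr::arrange(dplyr::ungroup(agg), .data$window_start, .data$rank)
}

#' Correlation between journal quality and journal impact over time
#'
#' For each calendar year, pairs every journal's mean quality score over
#' the deposits it published that year with the journal's impact
#' indicators (IPP and SNIP) for the same year, and reports Spearman rank
#' correlations. Journals contribute a point only when they have at least
#' `min_deposits` deposits in the year; years with fewer than 3 journal
#' points yield `NA` correlations.
#'
#' @inheritParams rank_journals
#' @param bibliometrics Tibble from [read_bibliometrics()].
#' @param min_deposits Minimum deposits per journal-year (default 5).
#' @return Tibble: `year`, `rho_ipp`, `rho_snip`, `n_journals`.
#' @export
correlate_impact <- function(temporal_scores, records, bibliometrics,
                             min_deposits = 5, measure = "p_q1_td") {
  df <- measure_frame(temporal_scores, records, measure)
  df <- df[!is.na(df$issn), , drop = FALSE]
  jy <- dplyr::summarise(
    dplyr::group_by(df, .data$issn, year = .data$deposition_year),
    mean_score = mean(.data$score), n = dplyr::n(), .groups = "drop")
  jy <- jy[jy$n >= min_deposits, , drop = FALSE]
  jy <- dplyr::inner_join(jy, bibliometrics, by = c("issn", "year"))

  out <- lapply(sort(unique(jy$year)), function(yr) {
    sub <- jy[jy$year == yr, , drop = FALSE]
    if (nrow(sub) < 3) {
      return(tibble::tibble(year = yr, rho_ipp = NA_real_, rho_snip = NA_real_,
                            n_journals = nrow(sub)))
    }
    tibble::tibble(year = yr,
                   rho_ipp = cor(sub$mean_score, sub$ipp, method = "spearman"),
                   rho_snip = cor(sub$mean_score, sub$snip, method = "spearman"),
                   n_journals = nrow(sub))
  })
  dplyr::bind_rows(out)
}
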