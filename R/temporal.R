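#' Bin a resolution onto the 0.1 Angstrom grid
#'
#' Rounds resolutions (half-up) to the nearest 0.1 Angstrom and caps the
#' result at 1.0 and 4.0 Angstrom, the grid on which the
#' resolution-conditioned percentile `P_Q1(t,d)` defines its reference
#' populations.
#'
#' @param resolution Numeric vector of resolutions in Angstrom, all > 0.
#' @return Numeric vector of on-grid bin values in `[1.0, 4.0]`.
#' @examples
#' resolution_bin(c(2.04, 0.48, 4.65))  # 2.0 1.0 4.0
#' @export
resolution_bin <- function(resolution) {
  if (any(is.na(resolution)) || any(resolution <= 0)) {
    stop("resolution must be positive")
  }
  ## round half up, not banker's rounding
  binned <- floor(resolution * 10 + 0.5) / 10
  pmin(pmax(binned, 1), 4)
}

#' Quality percentiles at the time of deposition
#'
#' Computes, for every deposit, the percentile of its composite Q1 score
#' within the population of deposits of the same molecule group that were
#' deposited strictly before it (plus the deposit itself) -- `P_Q1(t)` --
#' and optionally further restricted to the same 0.1-Angstrom resolution
#' bin -- `P_Q1(t,d)`. These measures rank every structure against the
#' archive as it stood on its own deposition date, so a model refined to a
#' high standard in its day is not penalized for the later improvement of
#' the field.
#'
#' Deposits sharing a deposition date are excluded from each other's
#' reference populations; the chronologically first deposit of a group is
#' ranked against itself alone and scores 100. The computation is a single
#' chronological sweep (a Fenwick tree over compressed Q1 values) and
#' never inspects deposits dated after the one being scored.
#'
#' @param scores Tibble from [compute_q1()] (columns `pdb_id`, `group`,
#'   and the composite to rank).
#' @param records Deposit tibble aligned with `scores` by `pdb_id`
#'   (supplies `deposition_date` and `resolution`).
#' @param conditioning `"none"` for `P_Q1(t)` only, `"resolution"` to also
#'   compute `P_Q1(t,d)` (default computes both).
#' @param measure Column of `scores` holding the composite to rank
#'   (`"q1"`, the averaging variant, by default; use `"q1_min"` for the
#'   minimum variant).
#' @param convention Percentile convention, see [percentile_rank()].
#' @return A tibble: `pdb_id`, `group`, `deposition_date`,
#'   `resolution_bin`, `p_q1_t`, `n_ref_t`, and (with resolution
#'   conditioning) `p_q1_td`, `n_ref_td`. Reference counts include the
#'   deposit itself.
#' @export
temporal_percentile <- function(scores, records,
                                conditioning = c("both", "none", "resolution"),
                                measure = "q1",
                                convention = c("inclusive", "midpoint")) {
  conditioning <- match.arg(conditioning)
  convention <- match.arg(convention)
  i <- match(scores$pdb_id, records$pdb_id)
  if (anyNA(i)) stop("scores contain pdb_ids absent from records")
  date <- records$deposition_date[i]
  if (anyNA(date)) stop("undated deposit; temporal percentiles need deposition dates")
  if (is.null(scores[[measure]])) stop("unknown measure column: ", measure)

  out <- tibble::tibble(pdb_id = scores$pdb_id, group = scores$group,
                        deposition_date = date,
                        resolution_bin = resolution_bin(records$resolution[i]))
  q1 <- scores[[measure]]

  sweep_by <- function(strata) {
    p <- rep(NA_real_, nrow(out))
    n <- rep(NA_integer_, nrow(out))
    for (s in unique(strata)) {
      idx <- which(strata == s)
      r <- temporal_sweep(q1[idx], as.integer(date[idx]), convention)
      p[idx] <- r$percentile
      n[idx] <- r$n_ref
    }
    list(p = p, n = n)
  }

  if (conditioning %in% c("both", "none")) {
    r <- sweep_by(out$group)
    out$p_q1_t <- r$p
    out$n_ref_t <- r$n
  }
  if (conditioning %in% c("both", "resolution")) {
    r <- sweep_by(paste(out$group, out$resolution_bin))
    out$p_q1_td <- r$p
    out$n_ref_td <- r$n
  }
  out
}

## Single chronological sweep over one stratum. Deposits are processed in
## batches of equal date; each batch is scored against the Fenwick-tree
## state before the batch is inserted, so same-date deposits never see one
## another. For deposit with n_less strictly-worse and n_eq tied prior
## deposits, the tie group (prior ties + self) occupies ranks
## n_less+1 .. n_less+n_eq+1 whose average is n_less + (n_eq + 2)/2, and
## the percentile is 100 * avg_rank / (n_prior + 1).
temporal_sweep <- function(q1, date_key, convention = "inclusive") {
  n <- length(q1)
  lev <- sort(unique(q1))
  val <- match(q1, lev)            # compressed value, 1..m
  m <- length(lev)
  tree <- integer(m)

  bit_add <- function(i) {
    while (i <= m) {
      tree[i] <<- tree[i] + 1L
      i <- i + bitwAnd(i, -i)
    }
  }
  bit_sum <- function(i) {         # count of inserted values <= i
    s <- 0L
    while (i > 0) {
      s <- s + tree[i]
      i <- i - bitwAnd(i, -i)
    }
    s
  }

  ord <- order(date_key)
  percentile <- numeric(n)
  n_ref <- integer(n)
  inserted <- 0L
  b <- 1L
  while (b <= n) {
    e <- b
    while (e < n && date_key[ord[e + 1L]] == date_key[ord[b]]) e <- e + 1L
    batch <- ord[b:e]
    for (j in batch) {
      v <- val[j]
      le <- bit_sum(v)
      n_less <- bit_sum(v - 1L)
      n_eq <- le - n_less
      avg_rank <- n_less + (n_eq + 2) / 2
      N <- inserted + 1L
      percentile[j] <- if (convention == "inclusive") 100 * avg_rank / N
                       else 100 * (avg_rank - 0.5) / N
      n_ref[j] <- N
    }
    for (j in batch) bit_add(val[j])
    inserted <- inserted + length(batch)
    b <- e + 1L
  }
  list(percentile = percentile, n_ref = n_ref)
}
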