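#' Bin an age in years into its decade stratum
#'
#' Decades are left-closed: `[20,30)`, `[30,40)`, ... — a boundary age of
#' exactly 30 belongs to `[30,40)`.
#'
#' @param age numeric vector of ages in years (> 0).
#' @return character vector of decade labels.
#' @export
age_decade <- function(age) {
  if (any(age <= 0)) abort("ages must be positive")
  lo <- 10 * floor(age / 10)
  sprintf("[%d,%d)", lo, lo + 10)
}

#' Request describing a balanced template cohort
#'
#' @param total_n total cohort size.
#' @param status_quotas named integer vector: clinical status -> exact
#'   number of participants to select; must sum to `total_n`.
#' @param balance_factors factors to balance, a subset of `"site"`,
#'   `"sex"`, `"clinical_status"`, `"age_decade"`.
#' @param seed seed for tie-breaking and restarts.
#' @return an object of class `cohort_request`.
#' @export
cohort_request <- function(total_n, status_quotas,
                           balance_factors = c("site", "sex", "age_decade"),
                           seed = 0L) {
  ok <- c("site", "sex", "clinical_status", "age_decade")
  if (!all(balance_factors %in% ok))
    abort("balance_factors must be a subset of: ", paste(ok, collapse = ", "))
  if (is.null(names(status_quotas)) || any(!nzchar(names(status_quotas))))
    abort("status_quotas must be named by clinical status")
  if (sum(status_quotas) != total_n)
    abort("status quotas sum to ", sum(status_quotas),
          ", not total_n = ", total_n)
  structure(list(total_n = as.integer(total_n),
                 status_quotas = vapply(status_quotas, as.integer, integer(1)),
                 balance_factors = balance_factors,
                 seed = as.integer(seed)),
            class = "cohort_request")
}

pool_factor_matrix <- function(pool, factors) {
  cols <- list(site = pool$site, sex = pool$sex,
               clinical_status = pool$clinical_status,
               age_decade = age_decade(pool$age))
  lapply(factors, function(f) factor(cols[[f]]))
}

#' Imbalance score of a selection
#'
#' The objective minimized by [select_balanced_cohort()]: the equal-weight
#' sum, over the balance factors, of the variance of the selected-count per
#' stratum (population variance across the factor's levels present in the
#' pool). Zero if and only if every factor's strata are filled equally.
#'
#' @param selected_idx integer indices into the pool.
#' @param fmat list of per-factor level assignments (from the pool).
#' @return non-negative real.
#' @noRd
imbalance_of <- function(selected_idx, fmat) {
  sum(vapply(fmat, function(fac) {
    counts <- tabulate(as.integer(fac)[selected_idx], nbins = nlevels(fac))
    mean((counts - mean(counts))^2)
  }, numeric(1)))
}

#' Select a balanced template-building cohort
#'
#' Chooses `total_n` participants meeting exact per-clinical-status quotas
#' while balancing the cohort across site, sex and age decade (and any other
#' requested factor). Balance is the equal-weight sum of per-factor
#' stratum-count variances; a seeded greedy-swap optimizer with restarts
#' minimizes it. Quotas are always met exactly; among quota-feasible
#' selections ties are broken by the seed-shuffled candidate order, so the
#' result is deterministic given `(pool, request, seed)`.
#'
#' @param pool data frame with columns `participant_id`, `site`, `sex`,
#'   `clinical_status`, `age`.
#' @param request a [cohort_request()].
#' @param n_restarts optimizer restarts (more restarts, better optima).
#' @param max_passes swap passes per restart.
#' @return an object of class `cohort_selection` with elements `selected`
#'   (participant IDs), `imbalance_score`, and `tallies` (per-factor stratum
#'   counts).
#' @export
select_balanced_cohort <- function(pool, request, n_restarts = 10L,
                                   max_passes = 50L) {
  need <- c("participant_id", "site", "sex", "clinical_status", "age")
  if (!all(need %in% names(pool)))
    abort("pool needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(pool$participant_id))
    abort("duplicate participant_id in pool")
  if (nrow(pool) < request$total_n)
    abort("pool size ", nrow(pool), " is below total_n ", request$total_n)
  for (st in names(request$status_quotas)) {
    avail <- sum(pool$clinical_status == st)
    if (avail < request$status_quotas[[st]])
      abort("infeasible quota for clinical status '", st, "': need ",
            request$status_quotas[[st]], ", only ", avail, " available")
  }
  fmat <- pool_factor_matrix(pool, request$balance_factors)
  status <- as.character(pool$clinical_status)
  by_status <- lapply(names(request$status_quotas),
                      function(st) which(status == st))
  names(by_status) <- names(request$status_quotas)

  best <- NULL
  with_seed(request$seed, {
    for (rs in seq_len(n_restarts)) {
      # quota-feasible start: first `quota` candidates per status, shuffled
      sel <- unlist(lapply(names(by_status), function(st) {
        idx <- by_status[[st]]
        if (length(idx) > 1L) idx <- sample(idx)
        idx[seq_len(request$status_quotas[[st]])]
      }))
      score <- imbalance_of(sel, fmat)
      # first-improvement swap descent within each status stratum
      for (pass in seq_len(max_passes)) {
        improved <- FALSE
        for (st in names(by_status)) {
          repeat {
            in_st <- intersect(sel, by_status[[st]])
            out_st <- setdiff(by_status[[st]], sel)
            found <- FALSE
            for (i in in_st) {
              for (j in out_st) {
                cand <- c(setdiff(sel, i), j)
                s2 <- imbalance_of(cand, fmat)
                if (s2 < score - 1e-12) {
                  sel <- cand; score <- s2
                  found <- TRUE; improved <- TRUE
                  break
                }
              }
              if (found) break
            }
            if (!found) break
          }
        }
        if (!improved) break
      }
      if (is.null(best) || score < best$score - 1e-12) {
        best <- list(sel = sel, score = score)
      }
    }
  })
  sel <- sort(best$sel)
  tallies <- lapply(seq_along(request$balance_factors), function(k) {
    fac <- fmat[[k]]
    counts <- tabulate(as.integer(fac)[sel], nbins = nlevels(fac))
    stats::setNames(counts, levels(fac))
  })
  names(tallies) <- request$balance_factors
  structure(list(selected = pool$participant_id[sel],
                 imbalance_score = best$score,
                 tallies = tallies),
            class = "cohort_selection")
}

#' @export
print.cohort_selection <- function(x, ...) {
  cat("<cohort_selection> n = ", length(x$selected),
      ", imbalance = ", format(x$imbalance_score, digits = 4), "\n", sep = "")
  for (f in names(x$tallies))
    cat("  ", f, ": ", paste(names(x$tallies[[f]]), x$tallies[[f]],
                             sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Exhaustively find the minimum-imbalance selection (oracle, tiny pools)
#'
#' Brute-force enumeration of every quota-feasible subset; intended as an
#' independent check of [select_balanced_cohort()] on pools of at most ~15
#' candidates.
#'
#' @inheritParams select_balanced_cohort
#' @return list with `score` (the optimum) and `selected` (one optimal
#'   selection's participant IDs).
#' @export
exhaustive_cohort_optimum <- function(pool, request) {
  fmat <- pool_factor_matrix(pool, request$balance_factors)
  status <- as.character(pool$clinical_status)
  per_status <- lapply(names(request$status_quotas), function(st) {
    idx <- which(status == st)
    q <- request$status_quotas[[st]]
    if (length(idx) < q) abort("infeasible quota for '", st, "'")
    utils::combn(idx, q, simplify = FALSE)
  })
  best <- NULL
  grids <- expand.grid(lapply(per_status, seq_along))
  for (r in seq_len(nrow(grids))) {
    sel <- unlist(lapply(seq_along(per_status),
                         function(k) per_status[[k]][[grids[r, k]]]))
    s <- imbalance_of(sel, fmat)
    if (is.null(best) || s < best$score - 1e-12)
      best <- list(score = s, selected = pool$participant_id[sort(sel)])
  }
  best
}

#' Demographic summary table of a selected cohort
#'
#' One row per clinical status plus a `Total` row, reporting N, mean and
#' sample (n-1) standard deviation of age, and female/male counts — the
#' layout of a conventional template-cohort overview table. A single-member
#' group gets sd 0 and a degenerate-sample flag.
#'
#' @param selection a `cohort_selection` or a character vector of
#'   participant IDs.
#' @param pool the candidate data frame the selection was drawn from.
#' @return data frame with columns `clinical_status`, `n`, `age_mean`,
#'   `age_sd`, `n_female`, `n_male`, `age_label`, `degenerate`.
#' @export
tabulate_cohort <- function(selection, pool) {
  ids <- if (inherits(selection, "cohort_selection")) selection$selected
         else as.character(selection)
  if (!all(ids %in% pool$participant_id))
    abort("selection contains IDs not in the pool")
  rows <- pool[match(ids, pool$participant_id), ]
  one <- function(label, d) {
    n <- nrow(d)
    mu <- if (n) mean(d$age) else NA_real_
    sdv <- if (n >= 2) stats::sd(d$age) else if (n == 1) 0 else NA_real_
    data.frame(clinical_status = label, n = n,
               age_mean = round(mu, 1), age_sd = round(sdv, 1),
               n_female = sum(d$sex == "F"), n_male = sum(d$sex == "M"),
               age_label = if (n) sprintf("%.0f ± %.1f", mu, sdv) else "",
               degenerate = n < 2,
               stringsAsFactors = FALSE)
  }
  statuses <- unique(as.character(rows$clinical_status))
  out <- do.call(rbind, lapply(statuses, function(st)
    one(st, rows[rows$clinical_status == st, ])))
  rbind(out, one("Total", rows))
}
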