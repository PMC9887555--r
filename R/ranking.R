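#' Rank procedures by urgency
#'
#' Rank 1 is the most urgent procedure (largest DALY/month); ties receive
#' average ranks. For display, tied procedures are ordered by id so output
#' is deterministic.
#'
#' @param results Data.frame with columns `procedure_id` and
#'   `daly_per_month` (finite, one row per procedure).
#' @return The input with a `rank` column, sorted by rank then id.
#' @export
rank_procedures <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("`results` must be a non-empty data.frame", call. = FALSE)
  if (anyDuplicated(results$procedure_id))
    stop("duplicate procedure_id in results", call. = FALSE)
  if (any(!is.finite(results$daly_per_month)))
    stop("non-finite daly_per_month", call. = FALSE)
  results$rank <- rank(-results$daly_per_month, ties.method = "average")
  results[order(results$rank, results$procedure_id), , drop = FALSE]
}

#' Spearman rank correlation of two rankings
#'
#' Pearson correlation of the two rank vectors, which equals Spearman's rho
#' and handles (average-rank) ties correctly.
#'
#' @param ranks_a,ranks_b Numeric rank vectors of equal length (n >= 2),
#'   matched element-wise by procedure.
#' @return rho in \[-1, 1\].
#' @export
spearman_rho <- function(ranks_a, ranks_b) {
  if (length(ranks_a) != length(ranks_b))
    stop("rank vectors differ in length", call. = FALSE)
  if (length(ranks_a) < 2) stop("need n >= 2", call. = FALSE)
  stats::cor(ranks_a, ranks_b, method = "pearson")
}

#' Compare two urgency rankings
#'
#' Joins two DALY/month result sets by procedure, ranks each, and reports
#' per-procedure rank shifts (positive = dropped, i.e. less urgent under B),
#' Spearman's rho, and the procedure whose DALY/month changed most.
#'
#' @param results_a,results_b Data.frames with `procedure_id` and
#'   `daly_per_month` over the same procedure set.
#' @return A list of class `ranking_comparison`: `table` (data.frame
#'   `procedure_id`, `delta_a`, `delta_b`, `rank_a`, `rank_b`, `rank_shift`),
#'   `rho`, `n`, `max_change_procedure`, `max_change` (|delta_a - delta_b|).
#' @export
compare_rankings <- function(results_a, results_b) {
  missing_b <- setdiff(results_a$procedure_id, results_b$procedure_id)
  missing_a <- setdiff(results_b$procedure_id, results_a$procedure_id)
  if (length(missing_a) || length(missing_b))
    stop("procedure sets differ; missing from A: ",
         paste(missing_a, collapse = ", "), "; missing from B: ",
         paste(missing_b, collapse = ", "), call. = FALSE)
  ra <- rank_procedures(results_a)
  rb <- rank_procedures(results_b)
  tab <- merge(
    data.frame(procedure_id = ra$procedure_id, delta_a = ra$daly_per_month,
               rank_a = ra$rank, stringsAsFactors = FALSE),
    data.frame(procedure_id = rb$procedure_id, delta_b = rb$daly_per_month,
               rank_b = rb$rank, stringsAsFactors = FALSE),
    by = "procedure_id")
  tab$rank_shift <- tab$rank_b - tab$rank_a
  tab <- tab[order(tab$rank_a, tab$procedure_id), , drop = FALSE]
  rownames(tab) <- NULL
  imax <- which.max(abs(tab$delta_a - tab$delta_b))
  structure(list(
    table = tab,
    rho = spearman_rho(tab$rank_a, tab$rank_b),
    n = nrow(tab),
    max_change_procedure = tab$procedure_id[imax],
    max_change = abs(tab$delta_a - tab$delta_b)[imax]
  ), class = "ranking_comparison")
}

#' @export
print.ranking_comparison <- function(x, ...) {
  cat(sprintf(
    "Ranking comparison (n = %d): rho = %.4f\n  largest DALY/month change: %s (|delta| = %.4g)\n",
    x$n, x$rho, x$max_change_procedure, x$max_change))
  invisible(x)
}
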