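# Protocol-outcome ranking: the Q-score combines R_free with the MolProbity
# score percentile so that protocols with worse geometry see their R_free
# inflated in proportion to the geometry deficit relative to the best
# protocol. The functional form used here,
#
#     q = r_free + c * (mp_max - mp),   c = (r_max - r_min) / (mp_max - mp_min)
#
# is reconstructed from the verbal definition of the score (the weight c is
# the ratio of the R_free range to the MolProbity-percentile range; the
# protocol with the best geometry suffers no inflation; in the degenerate
# equal-percentile case c = 0). Exact numerical parity with the original
# program's score is not claimed.

#' Compute Q-scores for a set of protocol results
#'
#' @param results Data frame with columns \code{protocol}, \code{r_free}
#'   (percent) and \code{mp_percentile} (percent, no missing values), e.g.
#'   from [read_protocol_results()]. Extra columns are carried through.
#' @return An object of class \code{"q_score_table"}: list with
#'   \code{table} (the input plus a \code{q} column), the weight \code{c} and
#'   the extrema \code{r_min}, \code{r_max}, \code{mp_min}, \code{mp_max}.
#' @examples
#' res <- data.frame(protocol = c("P1", "P2", "P3"),
#'                   r_free = c(25.0, 25.5, 26.0),
#'                   mp_percentile = c(50, 80, 60))
#' compute_q_scores(res)$table$q  # 26.0, 25.5, 26.667
#' @export
compute_q_scores <- function(results) {
  results <- validate_results(results)
  if (anyNA(results$mp_percentile))
    stop_lrr("fallback_required",
             "MolProbity percentile missing for some protocols; ",
             "rank by r_free instead")
  r <- results$r_free
  mp <- results$mp_percentile
  r_min <- min(r); r_max <- max(r)
  mp_min <- min(mp); mp_max <- max(mp)
  cc <- if (mp_max > mp_min) (r_max - r_min) / (mp_max - mp_min) else 0
  results$q <- r + cc * (mp_max - mp)
  structure(list(table = results, c = cc, r_min = r_min, r_max = r_max,
                 mp_min = mp_min, mp_max = mp_max),
            class = "q_score_table")
}

#' Select the best-performing protocol
#'
#' With geometry statistics available, the protocol with the lowest Q-score
#' wins; otherwise the one with the lowest R_free. Ties are broken by lower
#' R_free, then higher MolProbity percentile, then input order. Statistics
#' agreeing within 1e-6 (percent) are treated as tied, so protocols that a
#' backend drives to indistinguishable convergence are separated by the
#' documented tie-break chain rather than by floating-point noise.
#'
#' @param results Data frame as for [compute_q_scores()];
#'   \code{mp_percentile} may be absent or NA when
#'   \code{geometry_available = FALSE}.
#' @param geometry_available Logical; defaults to TRUE when every result has
#'   a MolProbity percentile.
#' @return The \code{protocol} id (character scalar) of the winner.
#' @export
select_best_protocol <- function(results,
                                 geometry_available =
                                   !anyNA(results$mp_percentile %||% NA)) {
  results <- validate_results(results)
  if (nrow(results) == 0)
    stop_lrr("selection_error", "no protocol results to select from")
  mp <- results$mp_percentile %||% rep(NA_real_, nrow(results))
  quant <- function(x) round(x / 1e-6) * 1e-6
  rf <- quant(results$r_free)
  if (geometry_available) {
    q <- quant(compute_q_scores(results)$table$q)
    ord <- order(q, rf, -mp, seq_len(nrow(results)))
  } else {
    mp_key <- ifelse(is.na(mp), -Inf, mp)
    ord <- order(rf, -mp_key, seq_len(nrow(results)))
  }
  results$protocol[ord[1]]
}

validate_results <- function(results) {
  if (!is.data.frame(results))
    stop_lrr("input_error", "protocol results must be a data frame")
  need <- c("protocol", "r_free")
  miss <- setdiff(need, names(results))
  if (length(miss))
    stop_lrr("input_error", "protocol results lack column(s): ",
             paste(miss, collapse = ", "))
  if (nrow(results) && (any(results$r_free < 0 | results$r_free > 100)))
    stop_lrr("input_error", "r_free must lie in [0, 100] percent")
  if (!is.null(results$mp_percentile) && nrow(results)) {
    mp <- results$mp_percentile
    if (any(!is.na(mp) & (mp < 0 | mp > 100)))
      stop_lrr("input_error", "mp_percentile must lie in [0, 100]")
  }
  results
}

#' Read / write protocol result tables
#'
#' Small CSV files with columns \code{protocol}, \code{r_work},
#' \code{r_free} and optionally \code{mp_percentile}.
#'
#' @param path CSV file path.
#' @return \code{read_protocol_results}: a data frame.
#' @export
read_protocol_results <- function(path) {
  if (!file.exists(path)) stop_lrr("io_error", "file not found: ", path)
  validate_results(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_protocol_results
#' @param results Data frame of protocol results.
#' @export
write_protocol_results <- function(results, path) {
  utils::write.csv(validate_results(results), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.q_score_table <- function(x, ...) {
  cat(sprintf("<q_score_table> %d protocols, c = %.4g (R_free range %.2f-%.2f, MP range %.1f-%.1f)\n",
              nrow(x$table), x$c, x$r_min, x$r_max, x$mp_min, x$mp_max))
  tab <- x$table[order(x$table$q), c("protocol", "r_free", "mp_percentile", "q")]
  print(tab, row.names = FALSE)
  invisible(x)
}
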