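#' Confusion counts at a similarity threshold
#'
#' A query is *assigned* when its top-hit similarity is strictly greater
#' than the threshold `t`. Among results that have a hit:
#' TP = correct and assigned, FP = incorrect and assigned,
#' FN = correct and unassigned, TN = incorrect and unassigned
#' (an "incorrect but withheld" assignment counts as a true negative).
#' Results without a hit are excluded.
#'
#' @param results An `identification_results` tibble.
#' @param t Similarity threshold in percent.
#' @param rank `"order"` or `"family"`.
#' @return A tibble `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_at_threshold <- function(results, t, rank = c("order", "family")) {
  rank <- match.arg(rank)
  r <- results[!is.na(results$similarity), ]
  correct <- r[[paste0("correct_", rank)]]
  assigned <- r$similarity > t
  tibble::tibble(
    TP = sum(correct & assigned),
    FP = sum(!correct & assigned),
    TN = sum(!correct & !assigned),
    FN = sum(correct & !assigned)
  )
}

# candidate thresholds: observed similarities (descending) plus a sentinel
# below the minimum so the curve reaches TPR = FPR = 1 under the strict rule
candidate_thresholds <- function(sims) {
  u <- sort(unique(sims), decreasing = TRUE)
  c(u, min(u) - 1)
}

#' ROC curve over observed similarity thresholds
#'
#' Sweeps every observed similarity value (plus a sentinel below the
#' minimum) as a candidate threshold, computing TPR = TP/(TP+FN) and
#' FPR = FP/(FP+TN) under the strict "assigned iff similarity > t" rule, and
#' the trapezoidal AUC. With both classes present this AUC equals the
#' concordance probability with ties counted 1/2. If only one class is
#' present the AUC is undefined (`NA`) and flagged with a reason.
#'
#' @inheritParams confusion_at_threshold
#' @return A `roc_curve` tibble (`threshold`, `TP`, `FP`, `TN`, `FN`, `TPR`,
#'   `FPR`, `precision`, `accuracy`, `assigned_fraction`) with attributes
#'   `auc`, `rank`, `n` and, when degenerate, `auc_reason`.
#' @export
roc_curve <- function(results, rank = c("order", "family")) {
  rank <- match.arg(rank)
  r <- results[!is.na(results$similarity), ]
  if (nrow(r) == 0) stop("no results with a hit", call. = FALSE)
  correct <- r[[paste0("correct_", rank)]]
  sims <- r$similarity
  ts <- candidate_thresholds(sims)
  n_pos <- sum(correct)
  n_neg <- sum(!correct)
  rows <- purrr::map(ts, function(t) {
    cbind(threshold = t, confusion_at_threshold(r, t, rank))
  })
  curve <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      TPR = if (n_pos > 0) .data$TP / n_pos else NA_real_,
      FPR = if (n_neg > 0) .data$FP / n_neg else NA_real_,
      precision = ifelse(.data$TP + .data$FP > 0,
                         .data$TP / (.data$TP + .data$FP), NA_real_),
      accuracy = (.data$TP + .data$TN) / nrow(r),
      assigned_fraction = (.data$TP + .data$FP) / nrow(r)
    )
  degenerate <- n_pos == 0 || n_neg == 0
  auc <- NA_real_
  if (!degenerate) {
    # trapezoid over the (FPR, TPR) staircase; ts descend so FPR ascends
    auc <- sum(diff(curve$FPR) * (utils::head(curve$TPR, -1) + utils::tail(curve$TPR, -1)) / 2)
  }
  structure(curve,
    class = c("roc_curve", class(tibble::tibble())),
    auc = auc, rank = rank, n = nrow(r),
    auc_reason = if (degenerate) {
      paste0("AUC undefined: no ", if (n_pos == 0) "correct" else "incorrect",
             " results at rank ", rank)
    } else NULL
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("# ROC curve (%s rank): %d candidate thresholds, n = %d, AUC = %s\n",
              attr(x, "rank"), nrow(x), attr(x, "n"),
              ifelse(is.na(attr(x, "auc")), "undefined", sprintf("%.4f", attr(x, "auc")))))
  NextMethod()
}

#' @exportS3Method generics::tidy
tidy.roc_curve <- function(x, ...) tibble::as_tibble(x)

#' @exportS3Method generics::glance
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = attr(x, "auc"), rank = attr(x, "rank"), n = attr(x, "n"))
}

#' Youden's J optimal threshold
#'
#' The candidate threshold maximising J = TPR - FPR; ties are resolved
#' towards the largest (most conservative) threshold.
#'
#' @param roc A [roc_curve()].
#' @return A tibble `threshold`, `J`.
#' @export
youden_threshold <- function(roc) {
  j <- roc$TPR - roc$FPR
  best <- which(j == max(j))[1]  # thresholds descend, so [1] is the largest
  tibble::tibble(threshold = roc$threshold[best], J = j[best])
}

#' Precision-guaranteed similarity threshold (P100/P99/P95)
#'
#' Returns the smallest candidate threshold `t` such that precision is at
#' least `1 - allowed_error` at `t` and at every higher candidate threshold
#' (candidates where nothing is assigned are vacuously fine). If the
#' criterion holds at every candidate, the threshold falls back to the
#' minimum observed similarity score. `allowed_error` of 0, 0.01 and 0.05
#' give the P100, P99 and P95 thresholds.
#'
#' @inheritParams confusion_at_threshold
#' @param allowed_error Tolerated error fraction in the accepted
#'   (positive-predicted) class.
#' @return The threshold, a single similarity percent.
#' @export
precision_threshold <- function(results, rank = c("order", "family"), allowed_error = 0) {
  rank <- match.arg(rank)
  stopifnot(allowed_error >= 0, allowed_error < 1)
  r <- results[!is.na(results$similarity), ]
  if (nrow(r) == 0) stop("no results with a hit", call. = FALSE)
  correct <- r[[paste0("correct_", rank)]]
  ts <- sort(unique(r$similarity), decreasing = TRUE)  # observed scores only
  ok <- vapply(ts, function(t) {
    assigned <- r$similarity > t
    if (!any(assigned)) return(TRUE)
    sum(correct & assigned) / sum(assigned) >= 1 - allowed_error
  }, logical(1))
  if (all(ok)) return(min(r$similarity))
  run_end <- which(!ok)[1] - 1L  # last index of the leading all-ok run
  if (run_end == 0L) return(ts[1])
  ts[run_end]
}

#' Calibrate assignment thresholds from identification results
#'
#' Produces the full threshold report: for each rank, the Youden's J
#' threshold and the P100/P99/P95 precision thresholds, each annotated with
#' its confusion counts, accuracy, precision and assigned fraction, plus the
#' ROC AUC. With `scope = "per_order"` every order is calibrated
#' independently on the queries whose *true* order it is; orders whose
#' results contain fewer than two distinct outcomes get `NA` for the
#' AUC-dependent fields (AUC, Youden) while the precision thresholds are
#' still reported.
#'
#' @param results An `identification_results` tibble.
#' @param rank Ranks to calibrate, subset of `c("order", "family")`.
#' @param scope `"all"`, `"per_order"`, or both.
#' @param precision_levels Tolerated error fractions for the precision
#'   thresholds, named by their conventional labels.
#' @return A `threshold_report` tibble: `scope`, `group`, `rank`,
#'   `criterion`, `threshold`, `J`, `auc`, `TP`, `FP`, `TN`, `FN`,
#'   `accuracy`, `precision`, `assigned_fraction`, `n`.
#' @export
calibrate <- function(results, rank = c("order", "family"),
                      scope = c("all", "per_order"),
                      precision_levels = c(P100 = 0, P99 = 0.01, P95 = 0.05)) {
  rank <- match.arg(rank, c("order", "family"), several.ok = TRUE)
  scope <- match.arg(scope, c("all", "per_order"), several.ok = TRUE)
  subsets <- list()
  if ("all" %in% scope) subsets[["all"]] <- list(scope = "all", group = "all", data = results)
  if ("per_order" %in% scope) {
    for (g in sort(unique(results$true_order))) {
      subsets[[paste0("order:", g)]] <- list(
        scope = "per_order", group = g,
        data = results[results$true_order == g, ])
    }
  }
  rows <- purrr::map(subsets, function(sub) {
    purrr::map(rank, function(rk) calibrate_one(sub$data, rk, sub$scope, sub$group,
                                                precision_levels)) |>
      dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  structure(rows, class = c("threshold_report", class(tibble::tibble())))
}

calibrate_one <- function(results, rank, scope, group, precision_levels) {
  r <- results[!is.na(results$similarity), ]
  n <- nrow(r)
  if (n == 0) {
    return(tibble::tibble(scope = scope, group = group, rank = rank,
                          criterion = c("youden", names(precision_levels)),
                          threshold = NA_real_, J = NA_real_, auc = NA_real_,
                          TP = NA_integer_, FP = NA_integer_, TN = NA_integer_,
                          FN = NA_integer_, accuracy = NA_real_,
                          precision = NA_real_, assigned_fraction = NA_real_,
                          n = 0L))
  }
  correct <- r[[paste0("correct_", rank)]]
  degenerate <- length(unique(correct)) < 2
  roc <- roc_curve(r, rank)
  auc <- attr(roc, "auc")
  report_row <- function(criterion, t, J = NA_real_) {
    if (is.na(t)) {
      conf <- tibble::tibble(TP = NA_integer_, FP = NA_integer_,
                             TN = NA_integer_, FN = NA_integer_)
      acc <- prec <- af <- NA_real_
    } else {
      conf <- confusion_at_threshold(r, t, rank)
      acc <- (conf$TP + conf$TN) / n
      prec <- if (conf$TP + conf$FP > 0) conf$TP / (conf$TP + conf$FP) else NA_real_
      af <- (conf$TP + conf$FP) / n
    }
    tibble::tibble(scope = scope, group = group, rank = rank,
                   criterion = criterion, threshold = t, J = J, auc = auc,
                   TP = conf$TP, FP = conf$FP, TN = conf$TN, FN = conf$FN,
                   accuracy = acc, precision = prec, assigned_fraction = af, n = n)
  }
  yt <- if (degenerate) tibble::tibble(threshold = NA_real_, J = NA_real_)
        else youden_threshold(roc)
  out <- list(report_row("youden", yt$threshold, yt$J))
  for (nm in names(precision_levels)) {
    out[[nm]] <- report_row(nm, precision_threshold(r, rank, precision_levels[[nm]]))
  }
  dplyr::bind_rows(out)
}
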