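#' Per-taxon maximum-intra and minimum-inter divergences
#'
#' For each taxon at the chosen rank, reports the maximum p-distance among
#' its members (`max_intra`, absent for monotypic taxa) and the minimum
#' p-distance from any of its members to a member of any other taxon
#' (`min_inter`, absent — with a warning — when the rank has a single
#' taxon). Undefined distances are ignored. `n_members` counts the taxon's
#' records (one per BIN in a BIN-representative library).
#'
#' @param D A `pdist_matrix`.
#' @param lib The [barcode_library()] it was computed from.
#' @param rank `"order"` or `"family"`.
#' @return A `taxon_divergence` tibble: `taxon`, `rank`, `n_members`,
#'   `max_intra`, `min_inter`.
#' @export
taxon_divergences <- function(D, lib, rank = c("order", "family")) {
  rank <- match.arg(rank)
  stopifnot(identical(D$ids, lib$id))
  labels <- lib[[rank]]
  if (anyNA(labels) || any(labels == "")) {
    stop("all records must be labelled at rank ", rank, call. = FALSE)
  }
  taxa <- unique(labels)
  if (length(taxa) < 2) warning("single taxon at rank ", rank, ": min_inter is undefined")
  d <- D$d
  rows <- purrr::map(taxa, function(tx) {
    inside <- labels == tx
    max_intra <- if (sum(inside) < 2) NA_real_ else {
      block <- d[inside, inside]
      vals <- block[upper.tri(block)]
      if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
    }
    min_inter <- if (all(inside)) NA_real_ else {
      vals <- d[inside, !inside]
      if (all(is.na(vals))) NA_real_ else min(vals, na.rm = TRUE)
    }
    tibble::tibble(taxon = tx, rank = rank, n_members = sum(inside),
                   max_intra = max_intra, min_inter = min_inter)
  })
  structure(dplyr::bind_rows(rows),
            class = c("taxon_divergence", class(tibble::tibble())))
}

#' Barcode-gap table at family rank
#'
#' A family shows a barcode gap when its maximum intrafamily divergence is
#' strictly smaller than the distance to its nearest neighbour in another
#' family (the point falls above the 1:1 line of a max-intra vs min-inter
#' scatter). Monotypic families have no intrafamily divergence and are
#' excluded from the gap flag but counted separately.
#'
#' @param divs A `taxon_divergence` tibble at family rank.
#' @return A `barcode_gap` tibble (`taxon`, `n_members`, `max_intra`,
#'   `min_inter`, `gap_present`) with attribute `summary` giving counts of
#'   families with/without a gap and monotypic families.
#' @export
barcode_gap_table <- function(divs) {
  stopifnot(all(divs$rank == "family"))
  out <- divs |>
    dplyr::mutate(gap_present = dplyr::if_else(
      is.na(.data$max_intra), NA, .data$max_intra < .data$min_inter)) |>
    dplyr::select(dplyr::all_of(c("taxon", "n_members", "max_intra",
                                  "min_inter", "gap_present")))
  structure(out,
    class = c("barcode_gap", class(tibble::tibble())),
    summary = tibble::tibble(
      n_gap = sum(out$gap_present, na.rm = TRUE),
      n_no_gap = sum(!out$gap_present, na.rm = TRUE),
      n_monotypic = sum(is.na(out$gap_present))
    ))
}

#' Regression of family divergence on BIN richness
#'
#' Fits three models of maximum intrafamily divergence against the number
#' of member BINs — linear (`y ~ x`), logarithmic (`y ~ log(x)`) and
#' asymptotic (`y = A + (y0 - A) exp(-k x)`, fitted by nonlinear least
#' squares with a self-starting parameterisation and multi-start fallback) —
#' and ranks them by AIC (Gaussian profile form, `n log(RSS/n) + 2p`).
#' For the asymptotic model the report includes the BIN count at which the
#' fitted curve reaches half its asymptote.
#'
#' Monotypic families (no `max_intra`) are dropped before fitting.
#'
#' @param divs A `taxon_divergence` tibble at family rank.
#' @return A `divergence_fits` object: list with `summary` (tibble `model`,
#'   `AIC`, `RSE`, `converged`, parameter columns, `half_asymptote_x`),
#'   `fits` (the fitted model objects) and `data`.
#' @export
fit_divergence_vs_richness <- function(divs) {
  data <- divs[!is.na(divs$max_intra), ]
  if (nrow(data) < 4) {
    stop("need at least 4 non-monotypic families to fit", call. = FALSE)
  }
  df <- tibble::tibble(x = data$n_members, y = data$max_intra)
  n <- nrow(df)
  aic_of <- function(rss, p) n * log(rss / n) + 2 * p
  fits <- list()
  sum_rows <- list()

  lin <- stats::lm(y ~ x, data = df)
  fits$linear <- lin
  rss <- sum(stats::residuals(lin)^2)
  sum_rows$linear <- tibble::tibble(
    model = "linear", converged = TRUE, AIC = aic_of(rss, 2),
    RSE = sqrt(rss / (n - 2)),
    A = NA_real_, k = NA_real_, y0 = NA_real_,
    slope = stats::coef(lin)[["x"]], intercept = stats::coef(lin)[["(Intercept)"]],
    half_asymptote_x = NA_real_)

  logm <- stats::lm(y ~ log(x), data = df)
  fits$logarithmic <- logm
  rss <- sum(stats::residuals(logm)^2)
  sum_rows$logarithmic <- tibble::tibble(
    model = "logarithmic", converged = TRUE, AIC = aic_of(rss, 2),
    RSE = sqrt(rss / (n - 2)),
    A = NA_real_, k = NA_real_, y0 = NA_real_,
    slope = stats::coef(logm)[["log(x)"]], intercept = stats::coef(logm)[["(Intercept)"]],
    half_asymptote_x = NA_real_)

  asym <- fit_asymptotic(df)
  fits$asymptotic <- asym
  if (!is.null(asym)) {
    rss <- sum(stats::residuals(asym)^2)
    cf <- stats::coef(asym)
    A <- cf[["Asym"]]; y0 <- cf[["R0"]]; k <- exp(cf[["lrc"]])
    # solve A + (y0 - A) exp(-k x) = A / 2
    half_x <- if (A > 0 && A - y0 > 0) log(2 * (A - y0) / A) / k else NA_real_
    sum_rows$asymptotic <- tibble::tibble(
      model = "asymptotic", converged = TRUE, AIC = aic_of(rss, 3),
      RSE = sqrt(rss / (n - 3)),
      A = A, k = k, y0 = y0, slope = NA_real_, intercept = NA_real_,
      half_asymptote_x = half_x)
  } else {
    sum_rows$asymptotic <- tibble::tibble(
      model = "asymptotic", converged = FALSE, AIC = NA_real_, RSE = NA_real_,
      A = NA_real_, k = NA_real_, y0 = NA_real_, slope = NA_real_,
      intercept = NA_real_, half_asymptote_x = NA_real_)
  }
  summary <- dplyr::bind_rows(sum_rows) |> dplyr::arrange(.data$AIC)
  structure(list(summary = summary, fits = fits, data = df),
            class = "divergence_fits")
}

# SSasymp: y = Asym + (R0 - Asym) * exp(-exp(lrc) * x); multi-start fallback
fit_asymptotic <- function(df) {
  fit <- tryCatch(
    stats::nls(y ~ SSasymp(x, Asym, R0, lrc), data = df),
    error = function(e) NULL)
  if (!is.null(fit)) return(fit)
  starts <- expand.grid(Asym = c(0.5, 1, 2) * max(df$y),
                        R0 = c(0, min(df$y)),
                        lrc = log(c(0.02, 0.1, 0.5)))
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::nls(y ~ Asym + (R0 - Asym) * exp(-exp(lrc) * x), data = df,
                 start = as.list(starts[i, ]),
                 control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit)) return(fit)
  }
  NULL
}

#' @export
print.divergence_fits <- function(x, ...) {
  cat("# divergence ~ richness fits (best first)\n")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.divergence_fits <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.divergence_fits <- function(x, ...) {
  best <- x$summary[which.min(x$summary$AIC), ]
  tibble::tibble(best_model = best$model, AIC = best$AIC, RSE = best$RSE,
                 A = best$A, half_asymptote_x = best$half_asymptote_x,
                 n_families = nrow(x$data))
}

#' Flag outliers by the boxplot rule
#'
#' Marks values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles
#' computed by linear interpolation (`stats::quantile` type 7). `NA`s are
#' never flagged.
#'
#' @param values Numeric vector with at least 4 non-missing values.
#' @return Logical mask, `TRUE` for outliers.
#' @export
flag_outliers <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 4) stop("need at least 4 non-missing values", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  out <- values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
  out & !is.na(out)
}
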