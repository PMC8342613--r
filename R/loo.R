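#' Configuration for modified leave-one-out identification
#'
#' The modified leave-one-out design queries every sequence against the
#' library while excluding not just the query itself but every candidate
#' within `exclusion_div` of it, so that a query cannot simply match another
#' member of its own BIN (or 5%/10% divergence cluster). The conventional
#' bindings are 2%, 5% and 10% for BIN-, DIV5- and DIV10-level libraries
#' respectively. Candidates must also carry a family label and share at
#' least `min_overlap_frac` of the query's non-gap length in compared sites.
#'
#' @param exclusion_div Minimum divergence a hit must strictly exceed, in
#'   `[0, 1)`.
#' @param min_overlap_frac Minimum compared-sites fraction of the query's
#'   non-gap length, in `(0, 1]`.
#' @return A `loo_config` list.
#' @export
loo_config <- function(exclusion_div = 0.02, min_overlap_frac = 0.5) {
  stopifnot(exclusion_div >= 0, exclusion_div < 1,
            min_overlap_frac > 0, min_overlap_frac <= 1)
  structure(list(exclusion_div = exclusion_div,
                 min_overlap_frac = min_overlap_frac),
            class = "loo_config")
}

# indices of eligible candidates for query row i, under config
eligible_candidates <- function(i, lib, D, config) {
  d <- D$d[i, ]
  ov_frac <- D$overlap[i, ] / lib$effective_length[i]
  has_family <- !is.na(lib$family) & lib$family != ""
  which(seq_along(d) != i &
          !is.na(d) & d > config$exclusion_div &
          has_family &
          ov_frac >= config$min_overlap_frac)
}

#' Top hit for a single query under exclusion rules
#'
#' Among candidates strictly exceeding `exclusion_div` divergence from the
#' query, carrying a family label, and with sufficient overlap, returns the
#' one with maximal similarity (ties broken by smallest id), or `NULL` when
#' no candidate is eligible (the query is unassignable).
#'
#' @param query_id Id of the query record (must be in `lib`).
#' @param lib A [barcode_library()].
#' @param D The `pdist_matrix` of `lib`.
#' @param config A [loo_config()].
#' @return A one-row tibble (`hit_id`, `p`, `similarity`, `overlap_bp`) or
#'   `NULL`.
#' @export
top_hit <- function(query_id, lib, D, config = loo_config()) {
  i <- match(query_id, lib$id)
  if (is.na(i)) stop("unknown query id: ", query_id, call. = FALSE)
  cand <- eligible_candidates(i, lib, D, config)
  if (length(cand) == 0) return(NULL)
  d <- D$d[i, cand]
  best <- cand[order(d, id_rank(lib$id)[cand])][1]
  tibble::tibble(hit_id = lib$id[best],
                 p = D$d[i, best],
                 similarity = similarity(D$d[i, best]),
                 overlap_bp = as.integer(D$overlap[i, best]))
}

#' Leave-one-out identification of every sequence in a library
#'
#' Runs [top_hit()] for each record and scores the predicted order and
#' family labels against the truth. Queries with no eligible candidate get
#' `NA` hit fields and `FALSE` correctness flags, and are counted separately
#' by [summarize_success()] and excluded from threshold calibration.
#'
#' @param lib A [barcode_library()] with at least 2 records.
#' @param config A [loo_config()].
#' @param D Optional precomputed `pdist_matrix` of `lib`.
#' @return An `identification_results` tibble: `query_id`, `hit_id`,
#'   `similarity`, `overlap_bp`, `predicted_order`, `predicted_family`,
#'   `true_order`, `true_family`, `correct_order`, `correct_family`.
#' @export
loo_identify <- function(lib, config = loo_config(), D = NULL) {
  if (nrow(lib) < 2) stop("library must have at least 2 records", call. = FALSE)
  if (is.null(D)) D <- distance_matrix(lib)
  stopifnot(identical(D$ids, lib$id))
  rows <- purrr::map(seq_len(nrow(lib)), function(i) {
    hit <- top_hit(lib$id[i], lib, D, config)
    if (is.null(hit)) {
      tibble::tibble(query_id = lib$id[i], hit_id = NA_character_,
                     similarity = NA_real_, overlap_bp = NA_integer_,
                     predicted_order = NA_character_, predicted_family = NA_character_)
    } else {
      j <- match(hit$hit_id, lib$id)
      tibble::tibble(query_id = lib$id[i], hit_id = hit$hit_id,
                     similarity = hit$similarity, overlap_bp = hit$overlap_bp,
                     predicted_order = lib$order[j], predicted_family = lib$family[j])
    }
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      true_order = lib$order,
      true_family = lib$family,
      correct_order = !is.na(.data$predicted_order) &
        .data$predicted_order == .data$true_order,
      correct_family = !is.na(.data$predicted_family) &
        .data$predicted_family == .data$true_family
    )
  structure(out, class = c("identification_results", class(tibble::tibble())),
            config = config)
}

#' Summarise identification success
#'
#' Proportions (percent) of queries whose top hit carried the correct order
#' and family label, overall (`by = "all"`) or per true order
#' (`by = "order"`). Queries with no eligible hit are reported in
#' `n_unassignable` and excluded from the success denominators.
#'
#' @param results An `identification_results` tibble from [loo_identify()].
#' @param by `"all"` or `"order"`.
#' @return A tibble with `group`, `n_queries`, `n_assigned`,
#'   `n_unassignable`, `order_success_pct`, `family_success_pct`.
#' @export
summarize_success <- function(results, by = c("all", "order")) {
  by <- match.arg(by)
  if (nrow(results) == 0) stop("empty results", call. = FALSE)
  grouped <- if (by == "all") {
    dplyr::mutate(results, group = "all")
  } else {
    dplyr::mutate(results, group = .data$true_order)
  }
  grouped |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_queries = dplyr::n(),
      n_assigned = sum(!is.na(.data$hit_id)),
      n_unassignable = sum(is.na(.data$hit_id)),
      order_success_pct = 100 * sum(.data$correct_order) / pmax(n_assigned, 1L),
      family_success_pct = 100 * sum(.data$correct_family) / pmax(n_assigned, 1L),
      .groups = "drop"
    )
}
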