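#' Single-linkage divergence clusters at a cutoff
#'
#' Partitions sequences into the connected components of the graph with an
#' edge wherever `d < threshold`; equivalently, the single-linkage dendrogram
#' cut so that the minimum distance between any two clusters is at least
#' `threshold` ("at least 5% divergence" for `threshold = 0.05`). Pairs with
#' distance exactly equal to the threshold therefore fall in different
#' clusters. Undefined distances (zero-overlap pairs) are treated as far
#' (no edge) with a warning.
#'
#' Cluster labels are contiguous integers starting at 1, ordered by the
#' smallest member id (C-locale string order).
#'
#' @param D A `pdist_matrix` from [distance_matrix()].
#' @param threshold Divergence cutoff in `(0, 1]`.
#' @return A `cluster_partition` tibble with columns `id`, `cluster`, and
#'   attributes `threshold` and `n_clusters`.
#' @export
single_linkage_clusters <- function(D, threshold) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("domain error: threshold must lie in (0, 1]", call. = FALSE)
  }
  d <- D$d
  if (anyNA(d[upper.tri(d)])) {
    warning("undefined distance(s) treated as >= threshold (no edge)")
  }
  adj <- !is.na(d) & d < threshold
  diag(adj) <- TRUE
  n <- length(D$ids)
  comp <- integer(n)
  label <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    label <- label + 1L
    frontier <- i
    comp[i] <- label
    while (length(frontier) > 0) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- label
      frontier <- nb
    }
  }
  # relabel contiguously by smallest member id
  min_rank <- vapply(split(id_rank(D$ids), comp), min, numeric(1))
  new_label <- match(as.character(comp), names(sort(min_rank)))
  out <- tibble::tibble(id = D$ids, cluster = new_label)
  structure(out,
    class = c("cluster_partition", class(tibble::tibble())),
    threshold = threshold,
    n_clusters = max(new_label)
  )
}

#' Silhouette scores of sequences within a cluster partition
#'
#' Classic silhouette as a measure of how central a sequence is to its
#' cluster: `a(i)` is the mean distance to the other members of its own
#' cluster, `b(i)` the smallest mean distance to another cluster, and
#' `s(i) = (b - a) / max(a, b)`. Members of singleton clusters score 0 by
#' convention; if the partition has a single cluster, all scores are 0 with
#' a warning (`b` is undefined). Undefined distances are excluded from the
#' means.
#'
#' @param D A `pdist_matrix`.
#' @param partition A `cluster_partition` over the same ids.
#' @return A tibble `id`, `cluster`, `silhouette`.
#' @export
silhouette_scores <- function(D, partition) {
  if (!setequal(partition$id, D$ids)) {
    stop("partition ids do not match distance matrix ids", call. = FALSE)
  }
  cl <- partition$cluster[match(D$ids, partition$id)]
  k <- max(cl)
  if (k == 1L) {
    warning("single cluster: all silhouette scores set to 0")
    return(tibble::tibble(id = D$ids, cluster = cl, silhouette = 0))
  }
  d <- D$d
  n <- length(D$ids)
  # mean distance from each sequence to each cluster (excluding self)
  sums <- matrix(0, n, k)
  counts <- matrix(0, n, k)
  for (g in seq_len(k)) {
    cols <- which(cl == g)
    dg <- d[, cols, drop = FALSE]
    sums[, g] <- rowSums(dg, na.rm = TRUE)
    counts[, g] <- rowSums(!is.na(dg))
  }
  self <- cbind(seq_len(n), cl)
  counts[self] <- counts[self] - 1L  # self distance is 0; drop it from own-cluster mean
  means <- ifelse(counts > 0, sums / counts, NA_real_)
  a <- means[self]
  b <- vapply(seq_len(n), function(i) {
    others <- means[i, -cl[i]]
    if (all(is.na(others))) NA_real_ else min(others, na.rm = TRUE)
  }, numeric(1))
  s <- ifelse(is.na(a) | counts[self] == 0, 0,          # singleton convention
              ifelse(is.na(b), 0, (b - a) / pmax(a, b)))
  s[is.nan(s)] <- 0  # a = b = 0 (identical sequences across clusters)
  tibble::tibble(id = D$ids, cluster = cl, silhouette = as.numeric(s))
}

#' Select silhouette-optimal cluster representatives
#'
#' Per cluster, picks the member with the highest silhouette score; ties are
#' broken by longest effective length, then smallest id. Records pass into
#' the diluted library unchanged.
#'
#' @param partition A `cluster_partition`.
#' @param scores Silhouette tibble from [silhouette_scores()].
#' @param lib The [barcode_library()] the partition was computed on.
#' @return A list with `representatives` (ordered id vector, one per cluster)
#'   and `diluted_library` (a `barcode_library` of those records).
#' @export
select_representatives <- function(partition, scores, lib) {
  stopifnot(setequal(scores$id, partition$id))
  df <- dplyr::inner_join(scores, tibble::as_tibble(lib), by = "id")
  reps <- df |>
    dplyr::group_by(.data$cluster) |>
    dplyr::arrange(dplyr::desc(.data$silhouette),
                   dplyr::desc(.data$effective_length),
                   id_rank(.data$id), .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$cluster)
  keep <- lib[match(reps$id, lib$id), ]
  list(representatives = reps$id,
       diluted_library = rebuild_library(keep, lib))
}

#' Sequentially dilute a library at increasing divergence cutoffs
#'
#' Builds the divergence-diluted dataset series: at each threshold the
#' library is partitioned into single-linkage clusters computed on the
#' distance matrix of the *previous level's representative library* (not the
#' original library), and each cluster is replaced by its silhouette-optimal
#' representative. With the default thresholds this reproduces the
#' BIN -> DIV5 -> DIV10 construction. Set `sequential = FALSE` to cluster
#' every level on the input library instead (sensitivity analysis).
#'
#' @param lib A [barcode_library()] (typically one record per BIN).
#' @param thresholds Strictly increasing divergence cutoffs.
#' @param sequential Chain levels (default) or dilute each level
#'   independently from `lib`.
#' @return A named list of `barcode_library` objects, one per threshold
#'   (names like `"DIV5"`), each carrying a `membership` attribute tibble
#'   (`id`, `cluster`, `silhouette`, `is_representative`).
#' @export
dilute_series <- function(lib, thresholds = c(0.05, 0.10), sequential = TRUE) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  out <- vector("list", length(thresholds))
  names(out) <- paste0("DIV", formatC(thresholds * 100, format = "g"))
  current <- lib
  for (i in seq_along(thresholds)) {
    base <- if (sequential) current else lib
    D <- distance_matrix(base)
    part <- single_linkage_clusters(D, thresholds[i])
    sil <- suppressWarnings(silhouette_scores(D, part))
    res <- select_representatives(part, sil, base)
    membership <- dplyr::mutate(sil, is_representative = .data$id %in% res$representatives)
    attr(res$diluted_library, "membership") <- membership
    out[[i]] <- res$diluted_library
    current <- res$diluted_library
  }
  out
}
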