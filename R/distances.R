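#' Uncorrected p-distance between two aligned sequences
#'
#' Computes the proportion of differing sites under pairwise deletion:
#' alignment columns where either sequence carries a gap or an ambiguous
#' character (anything outside `{A,C,G,T}`) are excluded, and
#' `p = mismatches / compared sites`. When no sites remain the distance is
#' undefined and returned as `NA` with `overlap_bp = 0`.
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length.
#' @return A list with elements `p` (p-distance in `[0,1]` or `NA`) and
#'   `overlap_bp` (number of compared sites).
#' @examples
#' pairwise_p_distance("AAAA", "AAAT")  # p = 0.25 over 4 sites
#' pairwise_p_distance("AA-N", "AAAA")  # p = 0    over 2 sites
#' @export
pairwise_p_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) {
    stop("alignment error: sequences have unequal lengths", call. = FALSE)
  }
  use <- a %in% DNA_BASES & b %in% DNA_BASES
  overlap <- sum(use)
  p <- if (overlap == 0) NA_real_ else sum(a[use] != b[use]) / overlap
  list(p = p, overlap_bp = overlap)
}

#' All-pairs p-distance matrix with overlap counts
#'
#' Computes the full symmetric matrix of uncorrected p-distances with
#' pairwise deletion for a library, together with the per-pair count of
#' compared sites. Internally the alignment is one-hot encoded per base and
#' match/overlap counts are obtained by cross-products, so the computation is
#' vectorised but agrees exactly with the per-pair definition of
#' [pairwise_p_distance()]. Pairs with zero overlap are `NA` in `d` (never
#' silently zero).
#'
#' @param lib A [barcode_library()] with at least one record.
#' @return A `pdist_matrix`: list with `ids`, `d` (symmetric p-distance
#'   matrix, `NA` where undefined), and `overlap` (symmetric compared-site
#'   counts).
#' @export
distance_matrix <- function(lib) {
  if (nrow(lib) == 0) stop("empty library", call. = FALSE)
  m <- seq_char_matrix(lib$seq)
  valid <- matrix(m %in% DNA_BASES, nrow = nrow(m))
  overlap <- tcrossprod(valid * 1)
  matches <- matrix(0, nrow(m), nrow(m))
  for (b in DNA_BASES) {
    xb <- (m == b & valid) * 1
    matches <- matches + tcrossprod(xb)
  }
  d <- ifelse(overlap > 0, (overlap - matches) / overlap, NA_real_)
  diag(d)[overlap[cbind(seq_len(nrow(m)), seq_len(nrow(m)))] > 0] <- 0
  dimnames(d) <- dimnames(overlap) <- list(lib$id, lib$id)
  structure(list(ids = lib$id, d = d, overlap = overlap), class = "pdist_matrix")
}

#' @export
print.pdist_matrix <- function(x, ...) {
  cat(sprintf("# p-distance matrix: %d sequence(s), %d undefined pair(s)\n",
              length(x$ids), sum(is.na(x$d[upper.tri(x$d)]))))
  invisible(x)
}

#' Convert a p-distance to a percent similarity score
#'
#' The similarity analogue reported by barcode identification engines:
#' `100 * (1 - p)`, a percent in `[0, 100]`.
#'
#' @param p p-distance(s) in `[0, 1]` (`NA` allowed, propagated).
#' @return Similarity score(s) in percent.
#' @export
similarity <- function(p) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) stop("domain error: p must lie in [0, 1]", call. = FALSE)
  100 * (1 - p)
}

#' Tidy a p-distance matrix into a long pair table
#'
#' @param x A `pdist_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per unordered pair: `id_a`, `id_b`, `p`,
#'   `overlap_bp`, `similarity`.
#' @exportS3Method generics::tidy
tidy.pdist_matrix <- function(x, ...) {
  n <- length(x$ids)
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble::tibble(
    id_a = x$ids[idx[, 1]],
    id_b = x$ids[idx[, 2]],
    p = x$d[idx],
    overlap_bp = as.integer(x$overlap[idx]),
    similarity = similarity(x$d[idx])
  )
}

#' Export a p-distance matrix
#'
#' Writes either a square TSV (ids as header row and first column) or a
#' PHYLIP square-format file. Undefined distances are written as `NA` (TSV)
#' or `-1` (PHYLIP, which has no missing-value convention).
#'
#' @param D A `pdist_matrix`.
#' @param path Output path.
#' @param format `"tsv"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- tibble::as_tibble(D$d, rownames = "id")
    readr::write_tsv(df, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", length(D$ids)), con)
    d <- D$d
    d[is.na(d)] <- -1
    for (i in seq_along(D$ids)) {
      writeLines(paste(formatC(D$ids[i], width = -10),
                       paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
    }
  }
  invisible(path)
}
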