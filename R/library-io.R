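#' Build a barcode reference library from a data frame
#'
#' A barcode library is a tibble with one row per aligned sequence record and
#' columns `id`, `bin_id`, `order`, `family` and `seq` (the aligned nucleotide
#' string). The constructor validates the alignment, normalises sequences to
#' upper case, and (re)computes two per-record summaries:
#'
#' * `effective_length` — number of non-gap characters (bp);
#' * `ambiguity_fraction` — fraction of non-gap characters outside `{A,C,G,T}`
#'   (IUPAC ambiguity codes and `N` all count as ambiguous).
#'
#' The alignment width (shared sequence length) and the 1-based inclusive
#' column span of the barcode region are stored as attributes and survive the
#' trimming and filtering operations in this package.
#'
#' @param x A data frame with columns `id`, `bin_id`, `order`, `family`, `seq`.
#' @param region Optional integer vector `c(start, end)`, 1-based inclusive
#'   column span the alignment represents. Defaults to the full width.
#' @return A `barcode_library` tibble.
#' @examples
#' lib <- barcode_library(tibble::tibble(
#'   id = c("q1", "q2"), bin_id = c("B1", "B2"),
#'   order = "Sarcoptiformes", family = "Oribatulidae",
#'   seq = c("ACGTACGT", "ACGTACGA")
#' ))
#' alignment_width(lib)
#' @export
barcode_library <- function(x, region = NULL) {
  required <- c("id", "bin_id", "order", "family", "seq")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  x$id <- as.character(x$id)
  x$seq <- toupper(as.character(x$seq))
  if (anyDuplicated(x$id)) {
    dup <- unique(x$id[duplicated(x$id)])
    stop("duplicate id(s): ", paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  widths <- unique(nchar(x$seq))
  if (length(widths) > 1) {
    stop("alignment error: sequences have unequal lengths (",
         paste(sort(widths), collapse = ", "), ")", call. = FALSE)
  }
  width <- if (nrow(x) == 0) 0L else widths
  if (is.null(region)) region <- c(1L, width)
  region <- as.integer(region)
  x$effective_length <- effective_lengths(x$seq)
  x$ambiguity_fraction <- ambiguity_fractions(x$seq)
  out <- x[, c(required, "effective_length", "ambiguity_fraction")]
  structure(out,
    class = c("barcode_library", class(tibble::tibble())),
    alignment_width = as.integer(width),
    region = region
  )
}

#' @rdname barcode_library
#' @param lib A `barcode_library`.
#' @export
alignment_width <- function(lib) attr(lib, "alignment_width")

#' @rdname barcode_library
#' @export
library_region <- function(lib) attr(lib, "region")

GAP_CHARS <- c("-", ".")
DNA_BASES <- c("A", "C", "G", "T")

seq_char_matrix <- function(seqs) {
  if (length(seqs) == 0) return(matrix(character(), nrow = 0))
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}

effective_lengths <- function(seqs) {
  vapply(strsplit(seqs, "", fixed = TRUE),
         function(ch) sum(!ch %in% GAP_CHARS), integer(1))
}

ambiguity_fractions <- function(seqs) {
  vapply(strsplit(seqs, "", fixed = TRUE), function(ch) {
    nongap <- ch[!ch %in% GAP_CHARS]
    if (length(nongap) == 0) return(0)
    mean(!nongap %in% DNA_BASES)
  }, numeric(1))
}

#' Read an aligned barcode library (FASTA + taxonomy TSV)
#'
#' Sequences are read from an aligned FASTA file; taxonomy travels in a
#' sidecar TSV with header `id  bin_id  order  family`. FASTA headers are
#' parsed tolerantly: the first whitespace- or pipe-delimited token is the
#' record id (robust to BOLD-style `id|taxon|marker` headers). Records whose
#' taxonomy lacks a family label are dropped with a message reporting the
#' count.
#'
#' @param fasta_path Path to an aligned (equal-width, gapped) FASTA file.
#' @param taxonomy_path Path to the taxonomy TSV.
#' @return A [barcode_library()].
#' @export
read_library <- function(fasta_path, taxonomy_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- vapply(strsplit(names(seqs), "[|[:space:]]+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("format error: duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  tax <- readr::read_tsv(taxonomy_path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  needed <- c("id", "bin_id", "order", "family")
  if (!all(needed %in% names(tax))) {
    stop("taxonomy TSV must have columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  missing_ids <- setdiff(ids, tax$id)
  if (length(missing_ids) > 0) {
    stop("join error: id(s) in FASTA but not in taxonomy: ",
         paste(utils::head(missing_ids, 10), collapse = ", "), call. = FALSE)
  }
  df <- tibble::tibble(id = ids, seq = as.character(seqs)) |>
    dplyr::left_join(tax[, needed], by = "id") |>
    dplyr::select(dplyr::all_of(c("id", "bin_id", "order", "family", "seq")))
  no_family <- is.na(df$family) | df$family == ""
  if (any(no_family)) {
    message(sum(no_family), " record(s) dropped for lacking a family label")
    df <- df[!no_family, ]
  }
  barcode_library(df)
}

#' Write a barcode library to FASTA + taxonomy TSV
#'
#' Round-trips losslessly with [read_library()]: ids, labels and aligned
#' sequences are preserved. Ids containing whitespace or `|` would not
#' survive the tolerant header parser and are rejected.
#'
#' @param lib A [barcode_library()].
#' @param fasta_path,taxonomy_path Output paths.
#' @return `lib`, invisibly.
#' @export
write_library <- function(lib, fasta_path, taxonomy_path) {
  bad <- grepl("[|[:space:]]", lib$id)
  if (any(bad)) {
    stop("id(s) contain whitespace or '|' and cannot be written: ",
         paste(utils::head(lib$id[bad], 5), collapse = ", "), call. = FALSE)
  }
  ss <- Biostrings::BStringSet(stats::setNames(lib$seq, lib$id))
  Biostrings::writeXStringSet(ss, fasta_path)
  readr::write_tsv(lib[, c("id", "bin_id", "order", "family")], taxonomy_path)
  invisible(lib)
}

#' Filter records to barcode-compliance criteria
#'
#' Keeps records at least `min_len_bp` long (non-gap bases) with an ambiguous
#' base fraction strictly below `max_ambig`; defaults mirror the usual
#' barcode-compliance rule of >= 500 bp with < 1% ambiguous bases. Record
#' order is preserved and the operation is idempotent.
#'
#' @param lib A [barcode_library()].
#' @param min_len_bp Minimum effective length in bp.
#' @param max_ambig Maximum (exclusive) fraction of ambiguous bases.
#' @return The filtered `barcode_library`.
#' @export
filter_compliant <- function(lib, min_len_bp = 500, max_ambig = 0.01) {
  keep <- lib$effective_length >= min_len_bp & lib$ambiguity_fraction < max_ambig
  if (!any(keep)) warning("no records satisfy the compliance criteria")
  rebuild_library(lib[keep, ], lib)
}

#' Select one representative sequence per BIN
#'
#' Chooses, within each BIN, the record with maximal effective length; ties
#' are broken by fewest ambiguous characters, then by lexicographically
#' smallest id. The result has exactly one record per distinct `bin_id`,
#' ordered by first appearance of each BIN.
#'
#' @param lib A [barcode_library()].
#' @return A `barcode_library` with one record per BIN.
#' @export
select_bin_representatives <- function(lib) {
  if (nrow(lib) == 0) return(lib)
  df <- tibble::as_tibble(lib)
  df$n_ambig <- round(df$ambiguity_fraction * df$effective_length)
  picked <- df |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::arrange(dplyr::desc(.data$effective_length), .data$n_ambig,
                   id_rank(.data$id), .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row)
  rebuild_library(picked[, names(lib)], lib)
}

#' Trim a library to an alignment column span
#'
#' Slices every sequence to columns `[start_col, end_col]` (1-based,
#' inclusive) and recomputes per-record summaries. Used both to restrict
#' records to the barcode region and to simulate shorter amplicons (e.g. the
#' 463 bp metabarcoding fragment as columns 196-658 of a 658-column barcode
#' alignment).
#'
#' @param lib A [barcode_library()].
#' @param start_col,end_col 1-based inclusive column bounds.
#' @return A trimmed `barcode_library`; its `region` attribute records the
#'   span relative to the input library's coordinate system.
#' @export
trim_to_region <- function(lib, start_col, end_col) {
  width <- alignment_width(lib)
  if (start_col < 1 || end_col > width || end_col < start_col) {
    stop("bounds error: need 1 <= start_col <= end_col <= ", width, call. = FALSE)
  }
  df <- tibble::as_tibble(lib)
  df$seq <- substr(df$seq, start_col, end_col)
  offset <- library_region(lib)[1] - 1L
  barcode_library(df[, c("id", "bin_id", "order", "family", "seq")],
                  region = c(offset + start_col, offset + end_col))
}

# keep attrs when subsetting rows out of an existing library
rebuild_library <- function(rows, template) {
  structure(tibble::as_tibble(rows)[, c("id", "bin_id", "order", "family", "seq",
                                        "effective_length", "ambiguity_fraction")],
    class = class(template),
    alignment_width = attr(template, "alignment_width"),
    region = attr(template, "region")
  )
}

# locale-independent (C radix) string ranking, used for all smallest-id ties
id_rank <- function(ids) {
  match(ids, sort(unique(ids), method = "radix"))
}

#' @export
print.barcode_library <- function(x, ...) {
  cat(sprintf("# barcode library: %d record(s), alignment width %d, region %d-%d\n",
              nrow(x), alignment_width(x), library_region(x)[1], library_region(x)[2]))
  NextMethod()
}
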