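#' Configuration for the synthetic barcode-library generator
#'
#' Describes a hierarchical order -> family -> BIN taxonomy and the
#' divergence structure realised among its sequences. Divergence values are
#' expected uncorrected p-distances between the relevant ancestors; because
#' substitutions are applied as per-site uniform replacement (multiple hits
#' allowed, so realised p-distance saturates below 0.75), targets are
#' expectations rather than guarantees.
#'
#' Defaults emulate a densely sampled mite reference library: four orders,
#' ten families per order, 1-14 BINs per family (~300 BINs, including the
#' singleton families real libraries always contain), four sequences
#' per BIN (~1200 records), 658-column alignment, intra-BIN divergence up to
#' 2%, inter-BIN divergence of 4-20% within a family (so intrafamily maxima can approach saturation-era values), a 12% interfamily
#' divergence floor and an 18% interorder floor.
#'
#' @param n_orders Number of orders.
#' @param families_per_order Families per order: a single count or a
#'   `c(min, max)` range sampled per order.
#' @param bins_per_family BINs per family: count or `c(min, max)` range.
#' @param seqs_per_bin Sequences per BIN: count or `c(min, max)` range.
#' @param alignment_width Alignment width in columns.
#' @param intra_bin_max Maximum expected divergence among members of a BIN.
#' @param interbin_range Range of expected divergences between BIN ancestors
#'   within a family.
#' @param interfamily_floor Minimum expected divergence between family
#'   ancestors within an order.
#' @param interorder_floor Minimum expected divergence between order
#'   ancestors.
#' @param ambiguity_rate Per-site probability of masking a base as `N`.
#' @param truncation_fraction Fraction of records gap-masked outside
#'   `truncation_region` (emulating short metabarcoding reads).
#' @param truncation_region `c(start, end)` columns retained by truncation.
#' @param n_decoys Number of decoy outgroup records to append.
#' @param decoy_floor Minimum expected divergence of decoys from every
#'   target lineage; must exceed `interorder_floor`.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_orders = 4,
                             families_per_order = 10,
                             bins_per_family = c(1, 14),
                             seqs_per_bin = 4,
                             alignment_width = 658,
                             intra_bin_max = 0.02,
                             interbin_range = c(0.04, 0.20),
                             interfamily_floor = 0.12,
                             interorder_floor = 0.18,
                             ambiguity_rate = 0.002,
                             truncation_fraction = 0,
                             truncation_region = c(196, 658),
                             n_decoys = 0,
                             decoy_floor = 0.35,
                             seed = 1L) {
  cfg <- list(n_orders = n_orders, families_per_order = families_per_order,
              bins_per_family = bins_per_family, seqs_per_bin = seqs_per_bin,
              alignment_width = as.integer(alignment_width),
              intra_bin_max = intra_bin_max, interbin_range = interbin_range,
              interfamily_floor = interfamily_floor,
              interorder_floor = interorder_floor,
              ambiguity_rate = ambiguity_rate,
              truncation_fraction = truncation_fraction,
              truncation_region = as.integer(truncation_region),
              n_decoys = n_decoys, decoy_floor = decoy_floor,
              seed = as.integer(seed))
  rates <- c(cfg$intra_bin_max, cfg$interbin_range, cfg$interfamily_floor,
             cfg$interorder_floor, cfg$ambiguity_rate, cfg$truncation_fraction)
  if (any(rates < 0 | rates > 1)) stop("config error: rates must lie in [0, 1]", call. = FALSE)
  if (!(cfg$intra_bin_max < cfg$interfamily_floor &&
        cfg$interfamily_floor <= cfg$interorder_floor)) {
    stop("config error: need intra_bin_max < interfamily_floor <= interorder_floor",
         call. = FALSE)
  }
  if (cfg$n_decoys > 0 && cfg$decoy_floor <= cfg$interorder_floor) {
    stop("config error: decoy_floor must exceed interorder_floor", call. = FALSE)
  }
  # per-site uniform replacement saturates at p = 0.75; divergence targets
  # (floor plus generator headroom) must stay clearly below saturation
  if (divergence_target(cfg$decoy_floor) >= 0.72 ||
      divergence_target(cfg$interorder_floor) >= 0.72) {
    stop("config error: divergence floors too close to the 0.75 saturation ceiling",
         call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

# headroom above a floor so realised minima stay above it
divergence_target <- function(floor) floor * 1.15

# substitution events m so that E[p] = target between path endpoints:
# p(m) = 0.75 (1 - (1 - 1/L)^m)  (each event: uniform site, uniform base)
events_for_p <- function(p, width) {
  stopifnot(p >= 0, p < 0.75)
  as.integer(round(log(1 - p / 0.75) / log(1 - 1 / width)))
}

# exact expected p-distance between the endpoints of a path carrying m events
expected_p <- function(m, width) 0.75 * (1 - (1 - 1 / width)^m)

mutate_seq <- function(chars, n_events) {
  if (n_events <= 0) return(chars)
  sites <- sample.int(length(chars), n_events, replace = TRUE)
  chars[sites] <- sample(DNA_BASES, n_events, replace = TRUE)
  chars
}

sample_count <- function(spec) {
  if (length(spec) == 1) return(as.integer(spec))
  sample(seq.int(spec[1], spec[2]), 1L)
}

#' Generate a seeded synthetic barcode library with known truth
#'
#' Evolves sequences down the configured hierarchy from a single root:
#' order ancestors diverge beyond the interorder floor, family ancestors
#' within each order beyond the interfamily floor, BIN ancestors within the
#' configured inter-BIN range, and BIN members below `intra_bin_max`.
#' Substitutions are independent per-site uniform replacements, so deep
#' divergences naturally saturate. Ambiguities, truncation and decoys are
#' applied per the config. The same config and seed give byte-identical
#' output.
#'
#' @param config A [synthetic_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A list: `library` (a [barcode_library()]) and `truth` (a tibble
#'   `id`, `order`, `family`, `bin_id`, `is_decoy`, plus the substitution
#'   counts on each generation branch and `expected_events`, the total
#'   root-to-record event count).
#' @export
generate_library <- function(config = synthetic_config(), seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(seed)) seed <- config$seed
  withr_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(withr_seed)) assign(".Random.seed", withr_seed, envir = globalenv()))
  set.seed(seed)
  L <- config$alignment_width
  root <- sample(DNA_BASES, L, replace = TRUE)
  m_order <- events_for_p(divergence_target(config$interorder_floor), L) %/% 2L
  m_family <- events_for_p(divergence_target(config$interfamily_floor), L) %/% 2L
  rows <- list()
  for (o in seq_len(config$n_orders)) {
    order_name <- sprintf("Order%02d", o)
    order_anc <- mutate_seq(root, m_order)
    n_fam <- sample_count(config$families_per_order)
    for (f in seq_len(n_fam)) {
      family_name <- sprintf("%s_Fam%02d", order_name, f)
      family_anc <- mutate_seq(order_anc, m_family)
      n_bins <- sample_count(config$bins_per_family)
      for (b in seq_len(n_bins)) {
        bin_name <- sprintf("%s_BIN%03d", family_name, b)
        t_bin <- stats::runif(1, config$interbin_range[1], config$interbin_range[2])
        m_bin <- events_for_p(t_bin, L) %/% 2L
        bin_anc <- mutate_seq(family_anc, m_bin)
        n_seq <- sample_count(config$seqs_per_bin)
        for (s in seq_len(n_seq)) {
          t_mem <- stats::runif(1, 0.25, 1) * config$intra_bin_max
          m_mem <- events_for_p(t_mem, L) %/% 2L
          chars <- mutate_seq(bin_anc, m_mem)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            id = sprintf("%s_s%02d", bin_name, s),
            bin_id = bin_name, order = order_name, family = family_name,
            seq = paste(chars, collapse = ""), is_decoy = FALSE,
            order_events = m_order, family_events = m_family,
            bin_events = m_bin, member_events = m_mem)
        }
      }
    }
  }
  df <- dplyr::bind_rows(rows)
  # mask ambiguities
  if (config$ambiguity_rate > 0) {
    df$seq <- vapply(df$seq, function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      hit <- stats::runif(L) < config$ambiguity_rate
      ch[hit] <- "N"
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  truth <- df[, c("id", "order", "family", "bin_id", "is_decoy",
                  "order_events", "family_events", "bin_events", "member_events")]
  truth$expected_events <- truth$order_events + truth$family_events +
    truth$bin_events + truth$member_events
  lib <- barcode_library(df[, c("id", "bin_id", "order", "family", "seq")])
  if (config$truncation_fraction > 0) {
    lib <- truncate_records(lib, config$truncation_fraction,
                            config$truncation_region, seed = seed + 1L)
  }
  if (config$n_decoys > 0) {
    decoys <- make_decoys(root, config)
    lib <- inject_decoys(lib, decoys)
    truth <- dplyr::bind_rows(truth, tibble::tibble(
      id = decoys$id, order = decoys$order, family = decoys$family,
      bin_id = decoys$bin_id, is_decoy = TRUE,
      order_events = NA_integer_, family_events = NA_integer_,
      bin_events = NA_integer_, member_events = NA_integer_,
      expected_events = decoys$events))
  }
  list(library = lib, truth = truth)
}

make_decoys <- function(root, config) {
  L <- config$alignment_width
  m <- events_for_p(divergence_target(config$decoy_floor), L)
  rows <- purrr::map(seq_len(config$n_decoys), function(i) {
    chars <- mutate_seq(root, m)
    tibble::tibble(id = sprintf("DECOY_%03d", i),
                   bin_id = sprintf("DECOY_BIN%03d", i),
                   order = sprintf("OutgroupOrder%02d", (i - 1L) %% 3L + 1L),
                   family = sprintf("OutgroupFam%02d", i),
                   seq = paste(chars, collapse = ""), events = m)
  })
  dplyr::bind_rows(rows)
}

#' Append decoy outgroup records to a library
#'
#' Decoys are labelled with non-target orders/families and sit beyond the
#' configured decoy divergence floor; they emulate distant (cross-phylum)
#' reference records that can capture queries whose own lineage is missing
#' from the library. With a `synthetic_config`, decoys are generated from a
#' fresh random root; a prebuilt decoy tibble is appended as-is.
#'
#' @param lib A [barcode_library()].
#' @param decoys A `synthetic_config` (uses its `n_decoys`/`decoy_floor` and
#'   `seed`) or a tibble with columns `id`, `bin_id`, `order`, `family`,
#'   `seq`.
#' @return The augmented `barcode_library`.
#' @export
inject_decoys <- function(lib, decoys) {
  if (inherits(decoys, "synthetic_config")) {
    config <- decoys
    if (config$n_decoys == 0) return(lib)
    withr_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(withr_seed)) assign(".Random.seed", withr_seed, envir = globalenv()))
    set.seed(config$seed + 7L)
    root <- sample(DNA_BASES, config$alignment_width, replace = TRUE)
    decoys <- make_decoys(root, config)
  }
  if (nrow(decoys) == 0) return(lib)
  cols <- c("id", "bin_id", "order", "family", "seq")
  barcode_library(dplyr::bind_rows(tibble::as_tibble(lib)[, cols], decoys[, cols]),
                  region = library_region(lib))
}

#' Gap-mask a seeded subset of records outside a region
#'
#' Emulates the shorter reads of metabarcoding protocols: a deterministic
#' (seeded) random fraction of records is masked with gaps outside the given
#' column span, so their effective length drops to at most the region width
#' while the alignment width is unchanged.
#'
#' @param lib A [barcode_library()].
#' @param fraction Fraction of records to truncate, in `[0, 1]`.
#' @param region `c(start, end)` columns retained, 1-based inclusive.
#' @param seed Integer seed for the record subset.
#' @return A `barcode_library` of the same width.
#' @export
truncate_records <- function(lib, fraction, region = c(196, 658), seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0 || nrow(lib) == 0) return(lib)
  width <- alignment_width(lib)
  stopifnot(region[1] >= 1, region[2] <= width, region[1] <= region[2])
  withr_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(withr_seed)) assign(".Random.seed", withr_seed, envir = globalenv()))
  set.seed(seed)
  pick <- sample.int(nrow(lib), round(fraction * nrow(lib)))
  df <- tibble::as_tibble(lib)
  left <- strrep("-", region[1] - 1L)
  right <- strrep("-", width - region[2])
  df$seq[pick] <- paste0(left, substr(df$seq[pick], region[1], region[2]), right)
  barcode_library(df[, c("id", "bin_id", "order", "family", "seq")],
                  region = library_region(lib))
}
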