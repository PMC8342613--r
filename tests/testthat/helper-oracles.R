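# Fixture builders and independent brute-force oracles.
# Oracles are written per-definition, independent of the package internals.

make_library <- function(ids, seqs, bins = ids, orders = "O1", families = "F1") {
  barcode_library(tibble::tibble(
    id = ids, bin_id = bins, order = orders, family = families, seq = seqs))
}

# random aligned library with gaps and ambiguities sprinkled in
random_library <- function(n, width = 40, gap_rate = 0.05, ambig_rate = 0.03,
                           n_orders = 2, n_families = 4) {
  seqs <- vapply(seq_len(n), function(i) {
    ch <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
    ch[stats::runif(width) < gap_rate] <- "-"
    ch[stats::runif(width) < ambig_rate] <- sample(c("N", "R", "Y"), 1)
    paste(ch, collapse = "")
  }, character(1))
  fam <- sample(seq_len(n_families), n, replace = TRUE)
  make_library(
    ids = sprintf("s%03d", seq_len(n)), seqs = seqs,
    bins = sprintf("b%03d", seq_len(n)),
    orders = sprintf("O%d", (fam - 1) %% n_orders + 1),
    families = sprintf("F%d", fam))
}

# quadratic-time p-distance oracle, character by character
oracle_p_matrix <- function(lib) {
  n <- nrow(lib)
  chars <- strsplit(lib$seq, "", fixed = TRUE)
  d <- matrix(NA_real_, n, n)
  ov <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- chars[[i]]; b <- chars[[j]]
      mism <- 0L; comp <- 0L
      for (k in seq_along(a)) {
        if (a[k] %in% c("A", "C", "G", "T") && b[k] %in% c("A", "C", "G", "T")) {
          comp <- comp + 1L
          if (a[k] != b[k]) mism <- mism + 1L
        }
      }
      ov[i, j] <- comp
      if (comp > 0) d[i, j] <- mism / comp
    }
  }
  list(d = d, overlap = ov)
}

# transitive-closure single-linkage oracle: union-find over all edges d < t
oracle_components <- function(d, threshold) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (!is.na(d[i, j]) && d[i, j] < threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# silhouette oracle straight from the definition
oracle_silhouette <- function(d, cl) {
  n <- nrow(d)
  vapply(seq_len(n), function(i) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (length(own) == 0) return(0)
    a <- mean(d[i, own], na.rm = TRUE)
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(g) {
      mean(d[i, cl == g], na.rm = TRUE)
    }, numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

# AUC oracle: concordance over all (correct, incorrect) pairs, ties = 1/2
oracle_auc <- function(sims, correct) {
  pos <- sims[correct]; neg <- sims[!correct]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# hand-rollable identification-results fixture
make_results <- function(sims, correct, rank = "order") {
  n <- length(sims)
  tibble::tibble(
    query_id = sprintf("q%03d", seq_len(n)),
    hit_id = sprintf("h%03d", seq_len(n)),
    similarity = sims, overlap_bp = 600L,
    predicted_order = "O1", predicted_family = "F1",
    true_order = "O1", true_family = "F1",
    correct_order = if (rank == "order") correct else rep(TRUE, n),
    correct_family = if (rank == "family") correct else rep(TRUE, n))
}

random_results <- function(n) {
  make_results(sims = round(stats::runif(n, 60, 100), 1),
               correct = stats::runif(n) < 0.7)
}

# expected saturating p-distance between two generated records, from the
# truth table's per-branch substitution counts (independent of the package's
# internal helpers)
shared_path_expectation <- function(truth, lib, i, j) {
  ti <- truth[i, ]; tj <- truth[j, ]
  m <- ti$member_events + tj$member_events
  if (ti$bin_id != tj$bin_id) m <- m + ti$bin_events + tj$bin_events
  if (ti$family != tj$family) m <- m + ti$family_events + tj$family_events
  if (ti$order != tj$order) m <- m + ti$order_events + tj$order_events
  L <- alignment_width(lib)
  0.75 * (1 - (1 - 1 / L)^m)
}

# well-separated blocks: low distances within groups, high between
block_distance_matrix <- function(groups, intra = c(0.01, 0.06),
                                  inter = c(0.15, 0.30)) {
  n <- sum(groups)
  g <- rep(seq_along(groups), groups)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      rng <- if (g[i] == g[j]) intra else inter
      d[i, j] <- d[j, i] <- stats::runif(1, rng[1], rng[2])
    }
  }
  d
}
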