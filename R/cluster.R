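#' Alignment scoring parameters
#'
#' Simple edit-like scoring keeps the clustering threshold interpretable in
#' base units: with the defaults a perfect 50-mer UMI self-alignment scores
#' 50 and every error costs roughly two points. A gap of length `g` scores
#' `gap_open + g * gap_extend`.
#'
#' @param match Match score (> 0).
#' @param mismatch,gap_open,gap_extend Penalties (<= 0).
#' @param threshold Optional clustering score threshold.
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(match = 1L, mismatch = -1L, gap_open = -1L,
                           gap_extend = -1L, threshold = NULL) {
  stopifnot(match > 0L, mismatch <= 0L, gap_open <= 0L, gap_extend <= 0L)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 threshold = threshold),
            class = "scoring_params")
}

#' Local alignment score between UMIs
#'
#' Smith-Waterman local alignment score with affine gaps; symmetric in its
#' arguments. Vectorised over `b`.
#'
#' @param a A single sequence.
#' @param b One or more sequences to score against `a`.
#' @param params [scoring_params()].
#' @return Integer vector of scores, one per element of `b`.
#' @export
#' @examples
#' umi_score("ACGTACGT", c("ACGTACGT", "TTTTTTTT"))
umi_score <- function(a, b, params = scoring_params()) {
  cpp_sw_scores(a, b, params$match, params$mismatch,
                params$gap_open, params$gap_extend)
}

#' Extract UMIs from reads by probe alignment
#'
#' Locates the constant probe (and its reverse complement) in each read by
#' local alignment, orients the read so the construct reads
#' `[barcode][gene][probe][UMI]`, and takes the `umi_length` bases
#' immediately following the probe hit. Extraction fails (`ok = FALSE`) when
#' the read is shorter than probe + UMI (`"too_short"`), when the best anchor
#' score falls below `score_min` (`"no_probe"`), or when fewer than
#' `umi_length - length_tol` bases remain after the probe (`"truncated"`).
#'
#' @param reads Read tibble (`read_id`, `bases`).
#' @param probe Constant anchor sequence (>= 10 nt).
#' @param umi_length Expected UMI length.
#' @param params [scoring_params()].
#' @param score_min Minimum anchor score; default `0.7 * match * nchar(probe)`.
#' @param length_tol Tolerated UMI shortfall from indels (default 5).
#' @return Tibble `read_id`, `umi`, `anchor_score`, `ok`, `orient`
#'   (`"+"` if the read was already in construct orientation), `reason`.
#' @export
extract_umis <- function(reads, probe = default_probe(), umi_length = 50L,
                         params = scoring_params(), score_min = NULL,
                         length_tol = 5L) {
  stopifnot(umi_length >= 1L, nchar(probe) >= 10L)
  score_min <- score_min %||% 0.7 * params$match * nchar(probe)
  n <- nrow(reads)
  umi <- character(n); score <- integer(n); ok <- logical(n)
  orient <- character(n); reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    rd <- reads$bases[i]
    if (nchar(rd) < nchar(probe) + umi_length) {
      ok[i] <- FALSE; umi[i] <- ""; score[i] <- 0L; orient[i] <- "+"
      reason[i] <- "too_short"
      next
    }
    fwd <- cpp_sw_locate(probe, rd, params$match, params$mismatch,
                         params$gap_open, params$gap_extend)
    rc <- revcomp(rd)
    rev <- cpp_sw_locate(probe, rc, params$match, params$mismatch,
                         params$gap_open, params$gap_extend)
    if (fwd$score >= rev$score) {
      best <- fwd; oriented <- rd; orient[i] <- "+"
    } else {
      best <- rev; oriented <- rc; orient[i] <- "-"
    }
    score[i] <- best$score
    if (best$score < score_min) {
      ok[i] <- FALSE; umi[i] <- ""; reason[i] <- "no_probe"
      next
    }
    # when read errors clip the probe tail off the local hit, the UMI starts
    # after the unaligned probe remainder, not at the raw hit end
    start <- best$subject_end + (nchar(probe) - best$pattern_end)
    avail <- nchar(oriented) - start
    if (avail < umi_length - length_tol) {
      ok[i] <- FALSE; umi[i] <- ""; reason[i] <- "truncated"
      next
    }
    umi[i] <- substr(oriented, start + 1L, start + umi_length)
    ok[i] <- TRUE
  }
  tibble(read_id = reads$read_id, umi = umi, anchor_score = score,
         ok = ok, orient = orient, reason = reason)
}

# greedy agglomerative clustering over a vector of strings; returns integer
# cluster ids in input order. Seeds are taken in input order; every
# unassigned string scoring >= threshold against the seed joins its cluster.
# Complexity O(k * n) alignments for k clusters - never all-vs-all.
greedy_cluster_strings <- function(strings, threshold, params = scoring_params()) {
  n <- length(strings)
  cl <- integer(n)
  unassigned <- seq_len(n)
  k <- 0L
  while (length(unassigned)) {
    seed <- unassigned[1L]
    sc <- cpp_sw_scores(strings[seed], strings[unassigned], params$match,
                        params$mismatch, params$gap_open, params$gap_extend)
    hit <- sc >= threshold
    hit[1L] <- TRUE  # the seed always belongs to its own cluster
    k <- k + 1L
    cl[unassigned[hit]] <- k
    unassigned <- unassigned[!hit]
  }
  cl
}

# greedy clustering on a precomputed symmetric score matrix (threshold scans)
greedy_cluster_matrix <- function(S, threshold) {
  n <- nrow(S)
  cl <- integer(n)
  unassigned <- rep(TRUE, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!unassigned[i]) next
    k <- k + 1L
    hit <- unassigned & S[i, ] >= threshold
    hit[i] <- TRUE
    cl[hit] <- k
    unassigned[hit] <- FALSE
  }
  cl
}

#' Estimate the clustering score threshold from a UMI sample
#'
#' Clusters a sample of extracted UMIs at every candidate threshold and
#' looks for the widest plateau of the cluster-count curve: the longest run
#' of consecutive thresholds whose cluster count changes by less than 5%.
#' The chosen threshold is the upper-quartile point of that plateau —
#' conservative against false merges, which unlike false splits are not
#' repaired by downstream size filters.
#' Plateaus at the degenerate levels (one single cluster, or no merging at
#' all) are ineligible, so a threshold range lying entirely above the
#' attainable scores raises an error rather than returning a meaningless
#' value. Also reports the two diagnostic score distributions: self pairs
#' (same template when truth labels are available, otherwise each UMI
#' against a re-corrupted copy of itself) and cross pairs (random pairs of
#' distinct templates).
#'
#' @param umis Character vector of extracted UMIs (>= 200).
#' @param thresholds Candidate integer thresholds; default
#'   `seq(0.2 * L, L) * match` for UMI length `L`.
#' @param params [scoring_params()].
#' @param sample_size Sample size used for the scan (all-vs-all scores are
#'   computed once on the sample).
#' @param truth Optional template labels parallel to `umis`.
#' @param self_error Per-base error rate used to synthesise self pairs when
#'   `truth` is absent.
#' @param seed RNG seed for sampling.
#' @return An object of class `threshold_scan`: list with `threshold`
#'   (chosen), `scan` (tibble `threshold`, `n_clusters`, `eligible`),
#'   `plateau` (range of the chosen run), `self_scores`, `cross_scores`.
#' @export
estimate_threshold <- function(umis, thresholds = NULL,
                               params = scoring_params(),
                               sample_size = 500L, truth = NULL,
                               self_error = 0.1, seed = 1L) {
  if (length(umis) < 200L) {
    stop("need at least 200 UMIs to estimate a threshold (got ",
         length(umis), ")")
  }
  L <- as.integer(round(median(nchar(umis))))
  thresholds <- thresholds %||%
    seq.int(max(1L, as.integer(0.2 * L * params$match)), L * params$match)
  thresholds <- sort(unique(as.integer(thresholds)))
  set.seed(seed)
  idx <- if (length(umis) > sample_size) {
    sort(sample.int(length(umis), sample_size))
  } else seq_along(umis)
  su <- umis[idx]
  S <- cpp_sw_matrix(su, params$match, params$mismatch,
                     params$gap_open, params$gap_extend)
  n <- length(su)
  counts <- vapply(thresholds, function(th) max(greedy_cluster_matrix(S, th)),
                   integer(1L))
  eligible <- counts > 1L & counts < n
  scan <- tibble(threshold = thresholds, n_clusters = counts,
                 eligible = eligible)
  # longest run of consecutive eligible thresholds with < 5% change
  run_id <- integer(length(thresholds))
  cur <- 0L
  for (i in seq_along(thresholds)) {
    new_run <- !eligible[i] ||
      (i == 1L || !eligible[i - 1L] ||
         abs(counts[i] - counts[i - 1L]) / max(counts[i - 1L], 1L) >= 0.05)
    if (eligible[i] && new_run) cur <- cur + 1L
    run_id[i] <- if (eligible[i]) cur else 0L
  }
  lens <- table(run_id[run_id > 0L])
  if (length(lens) == 0L || max(lens) < 3L) {
    stop("no stable threshold: no plateau of length >= 3 in the cluster-",
         "count scan; consider longer UMIs")
  }
  best_run <- as.integer(names(lens)[which.max(lens)])
  in_run <- which(run_id == best_run)
  # upper-quartile point of the plateau: anywhere on the plateau leaves the
  # cluster count unchanged, but false merges (which corrupt a cluster's
  # support fractions) become rarer as the threshold rises, while false
  # splits only spawn small clusters that the min_reads filter removes
  chosen <- thresholds[in_run[ceiling(3 * length(in_run) / 4)]]

  if (!is.null(truth)) {
    st <- truth[idx]
    pairs <- which(upper.tri(S), arr.ind = TRUE)
    if (nrow(pairs) > 20000L) pairs <- pairs[sample.int(nrow(pairs), 20000L), , drop = FALSE]
    same <- st[pairs[, 1L]] == st[pairs[, 2L]]
    self_scores <- S[pairs[same, , drop = FALSE]]
    cross_scores <- S[pairs[!same, , drop = FALSE]]
  } else {
    em <- error_model(0.6 * self_error, 0.2 * self_error, 0.2 * self_error)
    reerr <- vapply(strsplit(su, "", fixed = TRUE),
                    function(ch) corrupt_chars(ch, em), "")
    self_scores <- umi_score_pairs(su, reerr, params)
    pairs <- cbind(sample.int(n, min(5000L, n * (n - 1L)), replace = TRUE),
                   sample.int(n, min(5000L, n * (n - 1L)), replace = TRUE))
    pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
    cross_scores <- S[pairs]
  }
  structure(list(threshold = chosen, scan = scan,
                 plateau = range(thresholds[in_run]),
                 self_scores = as.integer(self_scores),
                 cross_scores = as.integer(cross_scores),
                 params = params),
            class = "threshold_scan")
}

# elementwise scores of parallel string vectors
umi_score_pairs <- function(a, b, params = scoring_params()) {
  vapply(seq_along(a), function(i) {
    cpp_sw_score(a[i], b[i], params$match, params$mismatch,
                 params$gap_open, params$gap_extend)
  }, integer(1L))
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat("<threshold_scan> chosen threshold ", x$threshold, " (plateau ",
      x$plateau[1L], "..", x$plateau[2L], ")\n", sep = "")
  invisible(x)
}

#' Greedy agglomerative UMI clustering
#'
#' Assigns reads to their template of origin by clustering extracted UMIs:
#' unassigned extractions are visited in input order, each in turn seeding a
#' cluster that absorbs every unassigned UMI scoring at least `threshold`
#' against the seed. This needs `O(k n)` alignments for `k` clusters rather
#' than an all-vs-all comparison, and its output is always a partition of
#' the successfully extracted reads. Failed extractions are excluded and
#' counted.
#'
#' @param extractions Output of [extract_umis()].
#' @param threshold Integer score threshold, or `NULL` to auto-estimate via
#'   [estimate_threshold()] on a sample.
#' @param params [scoring_params()].
#' @param max_reads Per-cluster cap: consensus calling uses only the first
#'   `max_reads` members (all members remain assigned).
#' @param ... Passed to [estimate_threshold()] when `threshold` is `NULL`.
#' @return An object of class `umi_clustering`: list with `assignments`
#'   (tibble `read_id`, `umi`, `orient`, `cluster_id`, `in_consensus`),
#'   `clusters` (tibble `cluster_id`, `seed_umi`, `n_reads`), `threshold`,
#'   `n_failed`, `scan` (the [estimate_threshold()] object, if used).
#' @export
cluster_umis <- function(extractions, threshold = NULL,
                         params = scoring_params(), max_reads = 100L, ...) {
  okx <- filter(extractions, .data$ok)
  n_failed <- nrow(extractions) - nrow(okx)
  scan <- NULL
  if (is.null(threshold)) {
    threshold <- params$threshold
  }
  if (is.null(threshold)) {
    scan <- estimate_threshold(okx$umi, params = params, ...)
    threshold <- scan$threshold
  }
  cl <- greedy_cluster_strings(okx$umi, threshold, params)
  assignments <- okx |>
    select("read_id", "umi", dplyr::any_of("orient")) |>
    mutate(cluster_id = sprintf("c%05d", cl)) |>
    group_by(.data$cluster_id) |>
    mutate(in_consensus = row_number() <= max_reads) |>
    ungroup()
  clusters <- assignments |>
    group_by(.data$cluster_id) |>
    summarise(seed_umi = .data$umi[1L], n_reads = n(), .groups = "drop")
  structure(list(assignments = assignments, clusters = clusters,
                 threshold = threshold, n_failed = n_failed,
                 params = params, scan = scan),
            class = "umi_clustering")
}

#' @export
print.umi_clustering <- function(x, ...) {
  cat("<umi_clustering> ", nrow(x$clusters), " clusters over ",
      nrow(x$assignments), " reads (threshold ", x$threshold, ", ",
      x$n_failed, " failed extractions)\n", sep = "")
  invisible(x)
}

#' @rdname cluster_umis
#' @param x A `umi_clustering` object.
#' @export
tidy.umi_clustering <- function(x, ...) x$assignments

#' @rdname cluster_umis
#' @export
glance.umi_clustering <- function(x, ...) {
  tibble(n_clusters = nrow(x$clusters),
         n_reads = nrow(x$assignments),
         n_failed = x$n_failed,
         threshold = x$threshold,
         median_cluster_size = median(x$clusters$n_reads))
}
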