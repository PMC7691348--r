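#' Consensus filtering parameters
#'
#' The quality-control rules applied to candidate mutation calls: a call
#' passes only with a read-support fraction strictly greater than
#' `min_support` (ties at the threshold fail), and — when both strands
#' contribute at least `min_strand_reads` overlapping reads — with at least
#' `min_strand_support` support on each strand, which depletes errors that
#' occur consistently in one read direction. Whole consensus results with
#' more than `max_mutations` passing calls are discarded as unreliable, and
#' clusters smaller than `min_reads` are not called at all.
#'
#' @param min_support Support fraction a call must exceed (default 0.6).
#' @param max_mutations Maximum passing mutations per variant (default 16).
#' @param min_strand_support Per-strand support floor (default 0.3).
#' @param min_reads Minimum cluster size for consensus calling (default 15).
#' @param min_strand_reads Overlapping reads per strand required before the
#'   strand filter applies (default 5).
#' @param min_score_frac Alignment floor: reads scoring below
#'   `min_score_frac * match * ref_length` are excluded from the pileup.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(min_support = 0.6, max_mutations = 16L,
                          min_strand_support = 0.3, min_reads = 15L,
                          min_strand_reads = 5L, min_score_frac = 0.3) {
  stopifnot(min_support > 0, min_support <= 1, max_mutations >= 0L,
            min_strand_support >= 0, min_reads >= 1L)
  structure(list(min_support = min_support,
                 max_mutations = as.integer(max_mutations),
                 min_strand_support = min_strand_support,
                 min_reads = as.integer(min_reads),
                 min_strand_reads = as.integer(min_strand_reads),
                 min_score_frac = min_score_frac),
            class = "filter_params")
}

#' Align one read to the reference (end-gap free)
#'
#' Overlap alignment with affine gaps and deterministic traceback; end gaps
#' on both sequences are free, so construct flanks absent from the reference
#' are clipped. Indels in the returned edit table are left-aligned.
#'
#' @param bases Read sequence, already in reference orientation.
#' @param ref A [reference_gene()] (or plain sequence string).
#' @param params [scoring_params()].
#' @return List with `score`, `ref_start`, `ref_end` (0-based half-open
#'   covered span) and `edits`, a mutation-call tibble.
#' @export
align_to_reference <- function(bases, ref, params = scoring_params()) {
  ref_seq <- if (inherits(ref, "reference_gene")) ref$sequence else ref
  a <- cpp_align_overlap(bases, ref_seq, params$match, params$mismatch,
                         params$gap_open, params$gap_extend)
  kinds <- c("substitution", "insertion", "deletion")
  edits <- tibble(position = as.integer(a$pos),
                  kind = kinds[a$op],
                  ref = a$ref, alt = a$alt)
  edits <- left_align_indels(edits, ref_seq)
  list(score = a$score, ref_start = a$ref_start, ref_end = a$ref_end,
       read_start = a$read_start, read_end = a$read_end, edits = edits)
}

# pileup + filters for one cluster; bases must be oriented, strand gives the
# original read direction ("+" = was already in construct orientation)
call_cluster_impl <- function(bases, strand, ref, filters, params) {
  ref_len <- nchar(ref$sequence)
  floor_score <- filters$min_score_frac * params$match * ref_len
  n <- length(bases)
  alns <- vector("list", n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    a <- align_to_reference(bases[i], ref, params)
    if (a$score >= floor_score) {
      keep[i] <- TRUE
      alns[[i]] <- a
    }
  }
  n_aligned <- sum(keep)
  empty_calls <- mutation_calls(support = numeric(), fwd_support = numeric(),
                                rev_support = numeric())
  empty_calls$passed <- logical()
  if (n_aligned == 0L) {
    return(list(calls = empty_calls, n_reads = n, n_aligned = 0L,
                discarded = TRUE, reason = "no_alignments"))
  }
  alns <- alns[keep]
  strand <- strand[keep]
  starts <- vapply(alns, `[[`, 0L, "ref_start")
  ends <- vapply(alns, `[[`, 0L, "ref_end")

  edits <- purrr::map2_dfr(alns, seq_along(alns), function(a, i) {
    if (nrow(a$edits) == 0L) return(NULL)
    mutate(a$edits, .read = i)
  })
  if (nrow(edits) == 0L) {
    return(list(calls = empty_calls, n_reads = n, n_aligned = n_aligned,
                discarded = FALSE, reason = NA_character_))
  }
  is_fwd <- strand == "+"
  cand <- edits |>
    mutate(fwd = is_fwd[.data$.read]) |>
    group_by(.data$position, .data$kind, .data$ref, .data$alt) |>
    summarise(carriers = n(), carriers_fwd = sum(.data$fwd),
              .groups = "drop")

  denom_at <- function(pos, fwd_only = NA) {
    sel <- if (is.na(fwd_only)) rep(TRUE, length(starts)) else (is_fwd == fwd_only)
    vapply(pos, function(p) sum(sel & starts <= p & ends > p), integer(1L))
  }
  denom_ins <- function(pos, fwd_only = NA) {
    sel <- if (is.na(fwd_only)) rep(TRUE, length(starts)) else (is_fwd == fwd_only)
    vapply(pos, function(p) {
      lo <- max(p - 1L, 0L)
      hi <- min(p, ref_len - 1L)
      sum(sel & starts <= lo & ends > hi)
    }, integer(1L))
  }
  ins <- cand$kind == "insertion"
  cand$overlappers <- NA_integer_
  cand$overlappers[!ins] <- denom_at(cand$position[!ins])
  cand$overlappers[ins] <- denom_ins(cand$position[ins])
  cand$overlappers_fwd <- NA_integer_
  cand$overlappers_fwd[!ins] <- denom_at(cand$position[!ins], TRUE)
  cand$overlappers_fwd[ins] <- denom_ins(cand$position[ins], TRUE)
  cand$overlappers_rev <- cand$overlappers - cand$overlappers_fwd
  carriers_rev <- cand$carriers - cand$carriers_fwd

  cand <- cand |>
    mutate(
      support = .data$carriers / pmax(.data$overlappers, 1L),
      fwd_support = ifelse(.data$overlappers_fwd > 0L,
                           .data$carriers_fwd / .data$overlappers_fwd, NA_real_),
      rev_support = ifelse(.data$overlappers_rev > 0L,
                           carriers_rev / .data$overlappers_rev, NA_real_),
      strand_ok = !(.data$overlappers_fwd >= filters$min_strand_reads &
                      .data$overlappers_rev >= filters$min_strand_reads) |
        (.data$fwd_support >= filters$min_strand_support &
           .data$rev_support >= filters$min_strand_support),
      passed = .data$support > filters$min_support & .data$strand_ok)

  discarded <- sum(cand$passed) > filters$max_mutations
  reason <- if (discarded) "max_mutations" else NA_character_
  if (discarded) cand$passed <- FALSE
  calls <- cand |>
    select("position", "kind", "ref", "alt", "support", "fwd_support",
           "rev_support", "passed") |>
    arrange(.data$position, .data$kind, .data$alt)
  list(calls = calls, n_reads = n, n_aligned = n_aligned,
       discarded = discarded, reason = reason)
}

#' Call consensus mutations for a single read cluster
#'
#' Builds a per-position pileup from end-gap-free alignments of the
#' cluster's reads against the reference. Every non-reference allele
#' (substitution, left-aligned insertion or deletion) becomes a candidate
#' call with `support = carriers / overlapping reads`; insertions count
#' reads carrying an identical inserted sequence at the same left-aligned
#' position, and overlap denominators exclude reads whose alignment does not
#' span the position. Candidates are then filtered per [filter_params()].
#'
#' @param bases Character vector of the cluster's reads, oriented to the
#'   reference.
#' @param ref A [reference_gene()].
#' @param filters [filter_params()].
#' @param params [scoring_params()].
#' @param strand Read directions (`"+"`/`"-"`), used by the per-strand
#'   support filter; defaults to all `"+"`.
#' @return List with `calls` (all candidates, with a `passed` flag),
#'   `n_reads`, `n_aligned`, `discarded`, `reason`.
#' @export
call_cluster <- function(bases, ref, filters = filter_params(),
                         params = scoring_params(),
                         strand = rep("+", length(bases))) {
  call_cluster_impl(bases, strand, ref, filters, params)
}

#' Consensus variant calling for all clusters
#'
#' Runs [call_cluster()] for every cluster of a [cluster_umis()] result that
#' has at least `min_reads` members (smaller clusters are skipped and
#' counted). Reads are oriented using the extraction orientation before
#' alignment; only the first `max_reads` members (the `in_consensus` flag)
#' enter the pileup.
#'
#' @param clustering A [cluster_umis()] result.
#' @param reads The read tibble the clustering was computed from.
#' @param ref A [reference_gene()].
#' @param filters [filter_params()].
#' @param params [scoring_params()].
#' @return An object of class `consensus_calls`: list with `calls` (tibble
#'   `cluster_id`, `position`, `kind`, `ref`, `alt`, `support`,
#'   `fwd_support`, `rev_support`, `passed`), `summary` (tibble
#'   `cluster_id`, `n_reads`, `n_aligned`, `n_candidates`, `n_passed`,
#'   `discarded`, `reason`), plus `ref` and `filters`.
#' @export
call_consensus <- function(clustering, reads, ref,
                           filters = filter_params(),
                           params = scoring_params()) {
  members <- clustering$assignments |>
    filter(.data$in_consensus) |>
    left_join(select(reads, "read_id", "bases"), by = "read_id")
  sizes <- clustering$clusters
  eligible <- sizes$cluster_id[sizes$n_reads >= filters$min_reads]
  skipped <- setdiff(sizes$cluster_id, eligible)

  per <- members |>
    filter(.data$cluster_id %in% eligible) |>
    dplyr::group_split(.data$cluster_id)
  results <- purrr::map(per, function(d) {
    oriented <- ifelse(d$orient == "-", revcomp(d$bases), d$bases)
    r <- call_cluster_impl(oriented, d$orient, ref, filters, params)
    r$cluster_id <- d$cluster_id[1L]
    r
  })
  calls <- purrr::map_dfr(results, function(r) {
    if (nrow(r$calls) == 0L) return(NULL)
    mutate(r$calls, cluster_id = r$cluster_id, .before = 1L)
  })
  if (nrow(calls) == 0L) {
    calls <- tibble(cluster_id = character(), position = integer(),
                    kind = character(), ref = character(), alt = character(),
                    support = numeric(), fwd_support = numeric(),
                    rev_support = numeric(), passed = logical())
  }
  summary <- purrr::map_dfr(results, function(r) {
    tibble(cluster_id = r$cluster_id, n_reads = r$n_reads,
           n_aligned = r$n_aligned, n_candidates = nrow(r$calls),
           n_passed = sum(r$calls$passed), discarded = r$discarded,
           reason = r$reason)
  })
  if (length(skipped)) {
    summary <- bind_rows(summary, tibble(
      cluster_id = skipped,
      n_reads = sizes$n_reads[match(skipped, sizes$cluster_id)],
      n_aligned = 0L, n_candidates = 0L, n_passed = 0L,
      discarded = TRUE, reason = "too_few_reads"))
  }
  structure(list(calls = calls, summary = arrange(summary, .data$cluster_id),
                 ref = ref, filters = filters),
            class = "consensus_calls")
}

#' @export
print.consensus_calls <- function(x, ...) {
  cat("<consensus_calls> ", nrow(x$summary), " clusters, ",
      sum(x$calls$passed), " passed calls (", sum(x$summary$discarded),
      " discarded)\n", sep = "")
  invisible(x)
}

#' @rdname call_consensus
#' @param x A `consensus_calls` object.
#' @export
tidy.consensus_calls <- function(x, ...) x$calls

#' @rdname call_consensus
#' @export
glance.consensus_calls <- function(x, ...) {
  tibble(n_clusters = nrow(x$summary),
         n_called = sum(!x$summary$discarded),
         n_discarded = sum(x$summary$discarded),
         n_passed_calls = sum(x$calls$passed),
         mean_passed = mean(x$summary$n_passed[!x$summary$discarded]))
}

#' Apply mutation calls to a reference sequence
#'
#' Reconstructs the implied consensus sequence from a set of (passed) calls.
#'
#' @param ref A [reference_gene()] (or plain sequence string).
#' @param calls Mutation-call tibble (0-based positions).
#' @return The mutated sequence as a string.
#' @export
consensus_sequence <- function(ref, calls) {
  seq <- if (inherits(ref, "reference_gene")) ref$sequence else ref
  if (nrow(calls) == 0L) return(seq)
  # apply right-to-left so earlier positions stay valid
  calls <- arrange(calls, desc(.data$position))
  for (i in seq_len(nrow(calls))) {
    p <- calls$position[i]  # 0-based
    pre <- substr(seq, 1L, p)
    switch(calls$kind[i],
      substitution = {
        seq <- paste0(pre, calls$alt[i], substr(seq, p + 2L, nchar(seq)))
      },
      insertion = {
        seq <- paste0(pre, calls$alt[i], substr(seq, p + 1L, nchar(seq)))
      },
      deletion = {
        seq <- paste0(pre, substr(seq, p + 1L + nchar(calls$ref[i]),
                                  nchar(seq)))
      })
  }
  seq
}

#' Evaluate consensus accuracy against simulated ground truth
#'
#' Maps every called cluster to the majority template of its member reads
#' and compares the implied consensus (reference + passed calls) with the
#' true template sequence. `per_base_error` is the total edit distance
#' between implied consensus and truth divided by total true-template bases;
#' `fn_rate` is the fraction of planted mutations (over all library
#' templates) that no cluster recovered; `fp_rate` is the number of spurious
#' passed calls as a fraction of all planted mutations.
#'
#' @param consensus A [call_consensus()] result.
#' @param clustering The [cluster_umis()] result it came from.
#' @param reads Simulated reads (with `template_id` truth).
#' @param library The [generate_library()] object.
#' @return An object of class `accuracy_report` (a one-row tibble with
#'   `per_base_error`, `fn_rate`, `fp_rate`, `recovery`,
#'   `n_true_mutations`, `n_clusters_evaluated`, `n_excluded`).
#' @export
evaluate_accuracy <- function(consensus, clustering, reads, library) {
  truth_by_read <- setNames(reads$template_id, reads$read_id)
  maj <- clustering$assignments |>
    mutate(template_id = truth_by_read[.data$read_id]) |>
    group_by(.data$cluster_id) |>
    summarise(template_id = names(which.max(table(.data$template_id))),
              .groups = "drop")
  evald <- consensus$summary |>
    filter(!.data$discarded) |>
    left_join(maj, by = "cluster_id")
  n_excluded <- sum(is.na(evald$template_id))
  evald <- filter(evald, !is.na(.data$template_id))

  tpl <- library$templates
  passed <- filter(consensus$calls, .data$passed)
  err_bases <- 0
  tot_bases <- 0
  for (i in seq_len(nrow(evald))) {
    cid <- evald$cluster_id[i]
    tid <- evald$template_id[i]
    cons <- consensus_sequence(consensus$ref,
                               filter(passed, .data$cluster_id == cid))
    true_gene <- tpl$gene[tpl$template_id == tid]
    err_bases <- err_bases + as.integer(utils::adist(cons, true_gene))
    tot_bases <- tot_bases + nchar(true_gene)
  }

  truth_mut <- library$mutations |>
    mutate(key = paste0(.data$template_id, "|", .data$position, ":",
                        .data$ref, ">", .data$alt))
  called <- passed |>
    left_join(evald[, c("cluster_id", "template_id")], by = "cluster_id") |>
    filter(!is.na(.data$template_id)) |>
    mutate(key = paste0(.data$template_id, "|", .data$position, ":",
                        .data$ref, ">", .data$alt))
  n_true <- nrow(truth_mut)
  matched <- sum(truth_mut$key %in% called$key)
  spurious <- sum(!called$key %in% truth_mut$key)

  out <- tibble(
    per_base_error = if (tot_bases > 0) err_bases / tot_bases else NA_real_,
    fn_rate = if (n_true > 0) 1 - matched / n_true else NA_real_,
    fp_rate = if (n_true > 0) spurious / n_true else NA_real_,
    recovery = if (n_true > 0) matched / n_true else NA_real_,
    n_true_mutations = n_true,
    n_clusters_evaluated = nrow(evald),
    n_excluded = n_excluded)
  class(out) <- c("accuracy_report", class(out))
  out
}
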