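#' Demultiplex clusters into selection rounds by barcode
#'
#' Aligns every round barcode against the barcode-proximal window of a
#' sample of each cluster's (oriented) member reads and assigns the cluster
#' to the barcode with the highest median score, provided its margin over
#' the runner-up is at least `margin_min`; otherwise the cluster stays
#' unassigned (`round` = `NA`).
#'
#' @param clustering A [cluster_umis()] result.
#' @param reads The read tibble.
#' @param barcodes Tibble (`name`, `bases`) or named character vector; the
#'   element order defines the round index.
#' @param params [scoring_params()].
#' @param margin_min Minimum score margin between best and runner-up.
#' @param reads_per_cluster Member reads sampled per cluster (first `k`).
#' @param window Window length examined at the barcode-proximal read end;
#'   default `2 * max barcode length + 10`.
#' @return Tibble `cluster_id`, `round`, `barcode`, `barcode_score`,
#'   `margin`.
#' @export
demultiplex <- function(clustering, reads, barcodes,
                        params = scoring_params(), margin_min = 4L,
                        reads_per_cluster = 10L, window = NULL) {
  if (is.character(barcodes)) {
    barcodes <- tibble(name = names(barcodes) %||%
                         paste0("round", seq_along(barcodes)),
                       bases = unname(barcodes))
  }
  stopifnot(nrow(barcodes) >= 1L)
  window <- window %||% (2L * max(nchar(barcodes$bases)) + 10L)
  members <- clustering$assignments |>
    left_join(select(reads, "read_id", "bases"), by = "read_id") |>
    group_by(.data$cluster_id) |>
    dplyr::slice_head(n = reads_per_cluster) |>
    ungroup()
  per <- dplyr::group_split(members, .data$cluster_id)
  purrr::map_dfr(per, function(d) {
    oriented <- ifelse(d$orient == "-", revcomp(d$bases), d$bases)
    win <- substr(oriented, 1L, window)
    med <- vapply(barcodes$bases, function(bc) {
      median(cpp_sw_scores(bc, win, params$match, params$mismatch,
                           params$gap_open, params$gap_extend))
    }, numeric(1L))
    o <- order(med, decreasing = TRUE)
    margin <- if (length(med) > 1L) med[o[1L]] - med[o[2L]] else Inf
    assigned <- margin >= margin_min
    tibble(cluster_id = d$cluster_id[1L],
           round = if (assigned) o[1L] else NA_integer_,
           barcode = if (assigned) barcodes$name[o[1L]] else NA_character_,
           barcode_score = med[o[1L]], margin = margin)
  })
}

#' Deduplicate consensus results into unique variants
#'
#' Groups called clusters by identical nucleotide mutation sets; identical
#' sets collapse to one variant record with per-round counts aggregated.
#' The wild type is the record with an empty mutation set. Amino-acid
#' mutation sets are the deterministic translation of the nucleotide sets;
#' frameshifted variants are kept but flagged untranslatable.
#'
#' @param consensus A [call_consensus()] result.
#' @param ref A [reference_gene()].
#' @param rounds Optional [demultiplex()] tibble (or named vector
#'   cluster_id -> round); clusters without an assignment are dropped.
#'   Default: everything in round 1.
#' @return A tibble with one row per unique variant: `variant_id`, `label`
#'   (space-separated amino-acid mutations, `"WT"` for none),
#'   `nt_mutations` (list of call tibbles), `aa_mutations` (list of label
#'   vectors), `n_nt`, `translatable`, `first_round`, `total`, and one
#'   `round_<k>` count column per round present.
#' @export
dedupe_variants <- function(consensus, ref, rounds = NULL) {
  called <- filter(consensus$summary, !.data$discarded)
  if (is.null(rounds)) {
    rmap <- setNames(rep(1L, nrow(called)), called$cluster_id)
  } else if (is.data.frame(rounds)) {
    rmap <- setNames(rounds$round, rounds$cluster_id)
  } else {
    rmap <- rounds
  }
  called <- called |>
    mutate(round = as.integer(rmap[.data$cluster_id])) |>
    filter(!is.na(.data$round))
  all_rounds <- sort(unique(called$round))
  if (nrow(called) == 0L) {
    return(tibble(variant_id = character(), label = character(),
                  nt_mutations = list(), aa_mutations = list(),
                  n_nt = integer(), translatable = logical(),
                  first_round = integer(), total = integer()))
  }
  passed <- filter(consensus$calls, .data$passed)
  per_cluster <- called |>
    mutate(key = vapply(.data$cluster_id, function(cid) {
      mutation_key(filter(passed, .data$cluster_id == cid))
    }, ""))
  counts <- per_cluster |>
    dplyr::count(.data$key, .data$round) |>
    tidyr::pivot_wider(names_from = "round", values_from = "n",
                       names_prefix = "round_", values_fill = 0L,
                       names_sort = TRUE)
  first_seen <- per_cluster |>
    group_by(.data$key) |>
    summarise(first_round = min(.data$round), .groups = "drop")
  keys <- counts$key
  nt_list <- lapply(keys, function(k) {
    cid <- per_cluster$cluster_id[per_cluster$key == k][1L]
    filter(passed, .data$cluster_id == cid) |>
      select("position", "kind", "ref", "alt")
  })
  aa_list <- vector("list", length(keys))
  translatable <- logical(length(keys))
  for (i in seq_along(keys)) {
    aa <- translate_mutations(nt_list[[i]], ref)
    translatable[i] <- attr(aa, "translatable")
    aa_list[[i]] <- sort(aa$label)
  }
  label <- vapply(seq_along(keys), function(i) {
    if (!translatable[i]) return("frameshift")
    if (length(aa_list[[i]]) == 0L) "WT" else paste(aa_list[[i]], collapse = " ")
  }, "")
  out <- counts |>
    left_join(first_seen, by = "key") |>
    mutate(variant_id = ifelse(keys == "", "WT",
                               sprintf("v%04d", cumsum(keys != ""))),
           label = label,
           nt_mutations = nt_list,
           aa_mutations = aa_list,
           n_nt = vapply(nt_list, nrow, 0L),
           translatable = translatable,
           total = rowSums(dplyr::pick(dplyr::starts_with("round_")))) |>
    select("variant_id", "label", "nt_mutations", "aa_mutations", "n_nt",
           "translatable", "first_round", "total",
           dplyr::starts_with("round_")) |>
    arrange(.data$first_round, desc(.data$total))
  out
}

#' Distance between variants in amino-acid sequence space
#'
#' The size of the symmetric difference between two amino-acid mutation
#' sets (positions and identities both count). A metric on mutation sets.
#'
#' @param a,b Character vectors of mutation labels (e.g.
#'   `c("A64E", "R102S")`).
#' @return Integer distance.
#' @export
#' @examples
#' variant_distance(c("A64E", "R102S"), c("A64E", "R102S", "E323V"))
variant_distance <- function(a, b) {
  length(setdiff(a, b)) + length(setdiff(b, a))
}

# symmetric distance matrix over a list of label vectors
variant_distance_matrix <- function(sets) {
  n <- length(sets)
  D <- matrix(0L, n, n)
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- variant_distance(sets[[i]], sets[[j]])
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}

#' Build a variant similarity network
#'
#' Nodes are unique (translatable) variants; an edge joins every pair at
#' sequence-space distance at most `d_max`. Connected components define the
#' reproducible clustering used for founder detection; the optional 2-D
#' stochastic-neighbour embedding of the pairwise distance matrix is for
#' display only.
#'
#' @param variants A [dedupe_variants()] tibble.
#' @param d_max Maximum distance for an edge (default 2).
#' @param embed Compute 2-D embedding coordinates?
#' @param seed,perplexity Embedding parameters (deterministic under seed).
#' @return An object of class `variant_network`: list with `nodes` (the
#'   variant tibble plus `component`, `degree` and optionally `x`, `y`),
#'   `edges` (tibble `from`, `to`, `distance`), `d_max`,
#'   `n_untranslatable`.
#' @export
build_network <- function(variants, d_max = 2L, embed = FALSE, seed = 7L,
                          perplexity = 30) {
  stopifnot(nrow(variants) >= 1L)
  nodes <- filter(variants, .data$translatable)
  n_untranslatable <- nrow(variants) - nrow(nodes)
  n <- nrow(nodes)
  D <- variant_distance_matrix(nodes$aa_mutations)
  pairs <- which(upper.tri(D) & D <= d_max, arr.ind = TRUE)
  edges <- tibble(from = nodes$variant_id[pairs[, 1L]],
                  to = nodes$variant_id[pairs[, 2L]],
                  distance = D[pairs])
  # connected components by union-find
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ri <- find(pairs[k, 1L]); rj <- find(pairs[k, 2L])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), find, 0L)
  nodes$component <- match(roots, unique(roots))
  nodes$degree <- vapply(seq_len(n), function(i) sum(D[i, -i] <= d_max), 0L)
  if (embed) {
    Y <- tsne_embed(D, perplexity = perplexity, seed = seed)
    nodes$x <- Y[, 1L]
    nodes$y <- Y[, 2L]
  }
  structure(list(nodes = nodes, edges = edges, d_max = d_max,
                 n_untranslatable = n_untranslatable),
            class = "variant_network")
}

#' @export
print.variant_network <- function(x, ...) {
  cat("<variant_network> ", nrow(x$nodes), " variants, ", nrow(x$edges),
      " edges (d_max ", x$d_max, "), ",
      dplyr::n_distinct(x$nodes$component), " components\n", sep = "")
  invisible(x)
}

#' @rdname build_network
#' @param x A `variant_network` object.
#' @export
tidy.variant_network <- function(x, ...) x$nodes

#' @rdname build_network
#' @export
glance.variant_network <- function(x, ...) {
  tibble(n_variants = nrow(x$nodes), n_edges = nrow(x$edges),
         n_components = dplyr::n_distinct(x$nodes$component),
         d_max = x$d_max, n_untranslatable = x$n_untranslatable)
}

# recursive founder decomposition of one set of members (list of label sets)
founder_recurse <- function(sets, ids, parent_id, level, counter_env) {
  core <- sort(Reduce(intersect, sets))
  counter_env$n <- counter_env$n + 1L
  fid <- sprintf("f%03d", counter_env$n)
  lab <- if (length(core)) paste(core, collapse = " ") else "WT"
  rows <- tibble(
    founder_id = fid, parent_id = parent_id, level = level,
    core = list(core),
    core_label = lab,
    n_members = length(sets),
    member_ids = list(ids))
  extras <- lapply(sets, setdiff, y = core)
  keep <- lengths(extras) > 0L
  if (!any(keep)) return(rows)
  ex <- extras[keep]
  exids <- ids[keep]
  # group members that share at least one extra mutation (components of the
  # shared-mutation graph), each group founding a sub-lineage
  m <- length(ex)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (length(intersect(ex[[i]], ex[[j]]))) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(m), find, 0L)
  for (g in unique(roots)) {
    sel <- roots == g
    sub <- founder_recurse(ex[sel], exids[sel], fid, level + 1L, counter_env)
    rows <- bind_rows(rows, sub)
  }
  rows
}

#' Identify founder variants and sub-lineages
#'
#' Within each connected component of the similarity network, the founder
#' core is the set of mutations shared by every member variant. Members
#' carrying the core plus at least one shared extra mutation are recursed
#' into sub-lineages; a sub-lineage's `core_label` lists only the mutations
#' it adds to its parent.
#'
#' @param network A [build_network()] result.
#' @return Tibble `founder_id`, `parent_id` (`NA` for component roots),
#'   `component`, `level`, `core` (list of label vectors),
#'   `core_label`, `n_members`, `member_ids`.
#' @export
find_founders <- function(network) {
  nodes <- network$nodes
  env <- new.env()
  env$n <- 0L
  out <- purrr::map_dfr(sort(unique(nodes$component)), function(comp) {
    sel <- nodes$component == comp
    founder_recurse(nodes$aa_mutations[sel], nodes$variant_id[sel],
                    NA_character_, 1L, env) |>
      mutate(component = comp, .after = "parent_id")
  })
  # invariant: a core is a subset of every member's mutation set
  for (i in seq_len(nrow(out))) {
    if (out$level[i] > 1L || length(out$core[[i]]) == 0L) next
    mem <- nodes$aa_mutations[match(out$member_ids[[i]], nodes$variant_id)]
    stopifnot(all(vapply(mem, function(s) all(out$core[[i]] %in% s), TRUE)))
  }
  out
}

#' Positional enrichment of mutations between rounds
#'
#' Restricted to variants that persist into `persist_round`, computes for
#' every mutated residue the count-weighted frequency of mutation in
#' `from_round` and `to_round` and the enrichment factor
#' `(f_to + eps) / (f_from + eps)` with pseudocount
#' `eps = 1 / total qualifying count`, which keeps factors finite and
#' invariant under uniform rescaling of all counts.
#'
#' @param variants A [dedupe_variants()] tibble with round count columns.
#' @param from_round,to_round Rounds compared (defaults 1 -> 2).
#' @param persist_round Variants must have nonzero count here (default 3).
#' @param eps Pseudocount; default `1/(total qualifying count)`. Supply a
#'   fixed value where exact invariance under count rescaling matters.
#' @return Tibble `residue`, `f_from`, `f_to`, `enrichment`, sorted by
#'   decreasing enrichment.
#' @export
positional_enrichment <- function(variants, from_round = 1L, to_round = 2L,
                                  persist_round = 3L, eps = NULL) {
  cols <- paste0("round_", c(from_round, to_round, persist_round))
  missing <- cols[!cols %in% names(variants)]
  if (length(missing)) {
    stop("requested round absent from the variant table: ",
         paste(sub("round_", "", missing), collapse = ", "))
  }
  qual <- variants[variants[[cols[3L]]] > 0L & variants$translatable, ]
  if (nrow(qual) == 0L) stop("no variants persist into round ", persist_round)
  n_from <- sum(qual[[cols[1L]]])
  n_to <- sum(qual[[cols[2L]]])
  eps <- eps %||% (1 / (n_from + n_to))
  long <- tibble(
    residue = unlist(lapply(qual$aa_mutations,
                            function(x) parse_aa_mutations(x)$residue)),
    c_from = rep(qual[[cols[1L]]], lengths(qual$aa_mutations)),
    c_to = rep(qual[[cols[2L]]], lengths(qual$aa_mutations))) |>
    group_by(.data$residue) |>
    summarise(c_from = sum(.data$c_from), c_to = sum(.data$c_to),
              .groups = "drop")
  long |>
    mutate(f_from = .data$c_from / max(n_from, 1L),
           f_to = .data$c_to / max(n_to, 1L),
           enrichment = (.data$f_to + eps) / (.data$f_from + eps)) |>
    select("residue", "f_from", "f_to", "enrichment") |>
    arrange(desc(.data$enrichment))
}

#' Read a lysate-activity table
#'
#' TSV with columns `mutations` (space-separated amino-acid labels; empty,
#' `WT` or `parent` denote the non-mutated parent), `relative_activity`
#' (fraction of parent activity, parent = 1.0) and `ci95` (95% CI
#' half-width).
#'
#' @param path File path.
#' @return Tibble `mutations` (list of label vectors), `label`,
#'   `relative_activity`, `ci95`.
#' @export
read_activity_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("mutations", "relative_activity", "ci95") %in% names(raw)))
  activity_table(raw$mutations, raw$relative_activity, raw$ci95)
}

#' @rdname read_activity_table
#' @param mutations Character vector of space-separated mutation labels.
#' @param relative_activity,ci95 Numeric vectors.
#' @export
activity_table <- function(mutations, relative_activity, ci95 = 0) {
  labs <- ifelse(is.na(mutations) | mutations %in% c("", "WT", "parent"),
                 "", mutations)
  sets <- lapply(strsplit(labs, "\\s+"), function(x) sort(x[nzchar(x)]))
  tibble(mutations = sets,
         label = vapply(sets, function(s)
           if (length(s)) paste(s, collapse = " ") else "WT", ""),
         relative_activity = relative_activity,
         ci95 = rep_len(ci95, length(sets)))
}

# look up one mutation set in an activity table
activity_lookup <- function(activity, set) {
  key <- if (length(set)) paste(sort(set), collapse = " ") else "WT"
  i <- match(key, activity$label)
  if (is.na(i)) stop("no activity record for variant '", key, "'")
  list(a = activity$relative_activity[i], h = activity$ci95[i])
}

# ratio x/y with Gaussian propagation of the CI half-widths
activity_ratio <- function(x, y) {
  if (y$a == 0) stop("activity ratio undefined: background activity is 0")
  r <- x$a / y$a
  h <- abs(r) * sqrt((x$h / x$a)^2 + (y$h / y$a)^2)
  list(a = r, h = h)
}

ci_excludes_1 <- function(r) abs(r$a - 1) > r$h

#' Classify epistasis of a mutation in a background
#'
#' Compares the effect of mutation set `m` alone
#' (`act(m) / act(parent)`) with its effect inside background `B`
#' (`act(B + m) / act(B)`), with 95% CIs propagated from the activity
#' table. The interaction is classified as:
#' \describe{
#'   \item{sign}{the two effects deviate from 1 in opposite directions,
#'     each with CI excluding 1 — in either direction of the pair (the
#'     roles of `m` and `B` are exchangeable, making the pairwise case
#'     symmetric).}
#'   \item{magnitude}{same direction, but the interaction ratio
#'     `gamma = effect_in_background / effect_alone` falls outside
#'     `[1/tau, tau]`.}
#'   \item{none}{otherwise (approximately multiplicative).}
#' }
#'
#' @param activity An [activity_table()] covering parent, `m`, `B` and
#'   `B + m`.
#' @param m Focal mutation label(s).
#' @param background Background mutation label(s) (`B`).
#' @param tau Magnitude threshold (default 1.5).
#' @return A one-row tibble of class `epistasis_class` with the effects,
#'   their CI half-widths, `gamma` and `class`.
#' @export
classify_epistasis <- function(activity, m, background, tau = 1.5) {
  m <- sort(m)
  background <- sort(background)
  parent <- activity_lookup(activity, character())
  am <- activity_lookup(activity, m)
  ab <- activity_lookup(activity, background)
  amb <- activity_lookup(activity, c(m, background))

  effect_alone <- activity_ratio(am, parent)
  effect_in_b <- activity_ratio(amb, ab)
  dual_alone <- activity_ratio(ab, parent)
  dual_in_m <- activity_ratio(amb, am)

  sign_flip <- function(e1, e2) {
    sign(e1$a - 1) != sign(e2$a - 1) &&
      ci_excludes_1(e1) && ci_excludes_1(e2)
  }
  gamma <- effect_in_b$a / effect_alone$a
  cls <- if (sign_flip(effect_alone, effect_in_b) ||
             sign_flip(dual_alone, dual_in_m)) {
    "sign"
  } else if (gamma > tau || gamma < 1 / tau) {
    "magnitude"
  } else {
    "none"
  }
  ea <- effect_alone$a; eah <- effect_alone$h
  eb <- effect_in_b$a; ebh <- effect_in_b$h
  out <- tibble(
    mutation = paste(m, collapse = " "),
    background = if (length(background)) paste(background, collapse = " ")
                 else "WT",
    effect_alone = ea, effect_alone_ci = eah,
    effect_in_background = eb,
    effect_in_background_ci = ebh,
    gamma = gamma, class = cls)
  class(out) <- c("epistasis_class", class(out))
  out
}
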