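#' Per-base read error model
#'
#' Independent per-base substitution / insertion / deletion probabilities for
#' the long-read simulator. The defaults (6% / 2% / 2%) sum to a 10% per-base
#' error rate, i.e. 90% read accuracy, the middle of the 85-95% accuracy
#' regime of current nanopore basecalls. Rates are capped at a 0.2 total so
#' the model stays inside that regime.
#'
#' @param sub_rate,ins_rate,del_rate Per-base event probabilities.
#' @return An object of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.06, ins_rate = 0.02, del_rate = 0.02) {
  stopifnot(sub_rate >= 0, ins_rate >= 0, del_rate >= 0,
            sub_rate + ins_rate + del_rate <= 0.2)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate), class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("<error_model> sub %.3f + ins %.3f + del %.3f (accuracy %.1f%%)\n",
              x$sub_rate, x$ins_rate, x$del_rate,
              100 * (1 - x$sub_rate - x$ins_rate - x$del_rate)))
  invisible(x)
}

#' Default UMI-extraction probe
#'
#' The constant 20-nt anchor sequence placed between the gene and the UMI in
#' the simulated construct; UMI extraction locates it (or its reverse
#' complement) by local alignment.
#'
#' @return A 20-character DNA string.
#' @export
default_probe <- function() "TGCAGTCACGGATTCGCTAC"

#' Error-prone-PCR library configuration
#'
#' Describes one tagged amplicon library. Each template carries a Poisson
#' number of random substitutions (mean `mean_mutations`, the package default
#' matching the ~3.5 mutations/gene of a typical Mutazyme epPCR round), a
#' unique random UMI and a round barcode, assembled into the construct layout
#' `[barcode][gene][probe][UMI]`.
#'
#' @param n_templates Number of library members.
#' @param mean_mutations Mean substitutions per gene (Poisson).
#' @param umi_length UMI length in nt (default 50).
#' @param barcode Round barcode sequence; `NULL` draws a random 24-nt one.
#' @param probe Constant anchor sequence preceding the UMI.
#' @return An object of class `library_config`.
#' @export
library_config <- function(n_templates, mean_mutations = 3.5,
                           umi_length = 50L, barcode = NULL,
                           probe = default_probe()) {
  stopifnot(n_templates >= 1L, umi_length >= 1L, mean_mutations >= 0,
            nchar(probe) >= 10L)
  structure(list(n_templates = as.integer(n_templates),
                 mean_mutations = mean_mutations,
                 umi_length = as.integer(umi_length),
                 barcode = barcode, probe = probe),
            class = "library_config")
}

#' Generate a UMI-tagged error-prone-PCR library
#'
#' Draws, per template, a Poisson(`mean_mutations`) number of substitutions
#' at uniform positions without replacement over the gene, with the
#' alternative base uniform over the three non-reference bases; tags every
#' template with a distinct random UMI (regenerated on collision) and the
#' round barcode. Deterministic under `seed`.
#'
#' @param ref A [reference_gene()].
#' @param config A [library_config()].
#' @param seed Optional RNG seed.
#' @return An object of class `umi_library`: a list with
#'   \describe{
#'     \item{templates}{tibble `template_id`, `umi`, `barcode`, `gene`
#'       (mutated gene sequence), `bases` (full construct), `n_mutations`}
#'     \item{mutations}{tibble of planted truth: `template_id`, `position`
#'       (0-based on the gene), `kind`, `ref`, `alt`}
#'     \item{ref, config}{the inputs}
#'   }
#' @export
generate_library <- function(ref, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_templates
  glen <- nchar(ref$sequence)
  if (config$mean_mutations > glen) {
    stop("mean_mutations exceeds the gene length")
  }
  barcode <- config$barcode %||% random_dna(1L, 24L)

  k <- rpois(n, config$mean_mutations)
  k <- pmin(k, glen)  # truncate the (negligible) tail beyond the gene length
  rc <- strsplit(ref$sequence, "", fixed = TRUE)[[1L]]

  tid <- rep.int(seq_len(n), k)
  pos1 <- unlist(lapply(k, function(ki) sample.int(glen, ki)), use.names = FALSE)
  refb <- rc[pos1]
  oi <- match(refb, DNA_BASES)
  altb <- DNA_BASES[((oi - 1L + sample.int(3L, length(pos1), replace = TRUE)) %% 4L) + 1L]

  genes <- rep.int(ref$sequence, n)
  if (length(tid)) {
    for (i in seq_along(tid)) {
      t <- tid[i]
      substr(genes[t], pos1[i], pos1[i]) <- altb[i]
    }
  }

  umi <- random_dna(n, config$umi_length)
  while (anyDuplicated(umi)) {
    dup <- which(duplicated(umi))
    umi[dup] <- random_dna(length(dup), config$umi_length)
  }

  template_id <- sprintf("t%05d", seq_len(n))
  templates <- tibble(
    template_id = template_id, umi = umi, barcode = barcode,
    gene = genes,
    bases = paste0(barcode, genes, config$probe, umi),
    n_mutations = k)
  mutations <- tibble(
    template_id = template_id[tid],
    position = as.integer(pos1 - 1L),
    kind = "substitution", ref = refb, alt = altb)
  structure(list(templates = templates,
                 mutations = arrange(mutations, .data$template_id, .data$position),
                 ref = ref, config = config),
            class = "umi_library")
}

#' @export
print.umi_library <- function(x, ...) {
  cat(sprintf(
    "<umi_library> %d templates of %s (%d nt), %.2f mean mutations, %d nt UMIs\n",
    nrow(x$templates), x$ref$name, nchar(x$ref$sequence),
    mean(x$templates$n_mutations), x$config$umi_length))
  invisible(x)
}

# apply the i.i.d. error process to one character vector; returns a string
# carrying the number of injected events as attribute "n_ops"
corrupt_chars <- function(chars, em) {
  n <- length(chars)
  u <- runif(n)
  b <- chars
  subm <- u < em$sub_rate
  if (any(subm)) {
    oi <- match(b[subm], DNA_BASES)
    b[subm] <- DNA_BASES[((oi - 1L + sample.int(3L, sum(subm), replace = TRUE)) %% 4L) + 1L]
  }
  delm <- u >= em$sub_rate & u < em$sub_rate + em$del_rate
  insm <- runif(n) < em$ins_rate
  pieces <- b
  pieces[delm] <- ""
  if (any(insm)) {
    pieces[insm] <- paste0(pieces[insm],
                           DNA_BASES[sample.int(4L, sum(insm), replace = TRUE)])
  }
  out <- paste(pieces, collapse = "")
  attr(out, "n_ops") <- sum(subm) + sum(delm) + sum(insm)
  out
}

#' Simulate nanopore-like reads from a tagged library
#'
#' Emits exactly `coverage` reads per template. Strand is drawn uniformly;
#' reverse-strand reads are reverse complements. Each base is independently
#' substituted or deleted, and a single random base is inserted after a
#' position with probability `ins_rate`. Ground-truth columns are populated
#' from the simulator. Deterministic under `seed`.
#'
#' @param library A [generate_library()] result (or its `templates` tibble).
#' @param coverage Reads per template (>= 0).
#' @param em An [error_model()].
#' @param seed Optional RNG seed.
#' @return Tibble `read_id`, `bases`, `strand`, `template_id`, `true_umi`,
#'   `true_errors` (number of error events injected into the read).
#' @export
simulate_reads <- function(library, coverage, em = error_model(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(coverage >= 0L)
  templates <- if (inherits(library, "umi_library")) library$templates else library
  n <- nrow(templates)
  if (coverage == 0L || n == 0L) {
    return(tibble(read_id = character(), bases = character(),
                  strand = character(), template_id = character(),
                  true_umi = character()))
  }
  out_bases <- character(n * coverage)
  strands <- character(n * coverage)
  n_errors <- integer(n * coverage)
  idx <- 0L
  for (t in seq_len(n)) {
    chars <- strsplit(templates$bases[t], "", fixed = TRUE)[[1L]]
    for (r in seq_len(coverage)) {
      idx <- idx + 1L
      s <- corrupt_chars(chars, em)
      n_errors[idx] <- attr(s, "n_ops")
      if (runif(1L) < 0.5) {
        strands[idx] <- "+"
        out_bases[idx] <- as.character(s)
      } else {
        strands[idx] <- "-"
        out_bases[idx] <- revcomp(as.character(s))
      }
    }
  }
  tibble(
    read_id = sprintf("r%07d", seq_len(n * coverage)),
    bases = out_bases,
    strand = strands,
    template_id = rep(templates$template_id, each = coverage),
    true_umi = rep(templates$umi, each = coverage),
    true_errors = n_errors)
}

#' Simulate UMI clustering efficiency over a parameter grid
#'
#' For every combination of UMI length, per-base error rate and library size:
#' draws `library_size` random UMIs, emits `reads_per_umi` erroneous copies of
#' each (errors split 60/20/20 over substitution/insertion/deletion, matching
#' the read error model's default proportions), clusters the copies greedily
#' and scores the result against the known template of each copy. Used to pick
#' a UMI length that gives complete recollection and homogeneous clusters
#' under the expected error regime.
#'
#' @param umi_lengths,error_rates,library_sizes Non-empty numeric vectors
#'   spanning the grid.
#' @param reads_per_umi Erroneous copies per UMI.
#' @param seed RNG seed (each grid point derives its own sub-seed).
#' @param params [scoring_params()] for the clustering alignments.
#' @param threshold_frac Clustering threshold as a fraction of the maximal
#'   self score `umi_length * match`.
#' @return A tibble with one row per grid point: `umi_length`, `error_rate`,
#'   `library_size`, `n_clusters`, `recollection`, `homogeneity`.
#' @export
simulate_clustering_efficiency <- function(umi_lengths, error_rates,
                                           library_sizes, reads_per_umi = 5L,
                                           seed = 1L,
                                           params = scoring_params(),
                                           threshold_frac = 0.5) {
  stopifnot(length(umi_lengths) > 0L, length(error_rates) > 0L,
            length(library_sizes) > 0L, reads_per_umi >= 1L)
  grid <- tidyr::expand_grid(umi_length = as.integer(umi_lengths),
                             error_rate = error_rates,
                             library_size = as.integer(library_sizes))
  res <- purrr::pmap_dfr(grid, function(umi_length, error_rate, library_size) {
    set.seed(seed + 7901L * nrow(grid) +
               match(paste(umi_length, error_rate, library_size),
                     paste(grid$umi_length, grid$error_rate, grid$library_size)))
    em <- error_model(sub_rate = 0.6 * error_rate,
                      ins_rate = 0.2 * error_rate,
                      del_rate = 0.2 * error_rate)
    umis <- random_dna(library_size, umi_length)
    chars <- strsplit(umis, "", fixed = TRUE)
    copies <- unlist(lapply(chars, function(ch) {
      vapply(seq_len(reads_per_umi), function(i) corrupt_chars(ch, em), "")
    }), use.names = FALSE)
    truth <- rep(seq_len(library_size), each = reads_per_umi)
    threshold <- max(1L, as.integer(round(threshold_frac * umi_length * params$match)))
    cl <- greedy_cluster_strings(copies, threshold, params)
    m <- clustering_metrics(cl, truth, n_templates = library_size)
    tibble(umi_length = umi_length, error_rate = error_rate,
           library_size = library_size, n_clusters = max(cl),
           recollection = m$recollection, homogeneity = m$homogeneity)
  })
  class(res) <- c("clustering_efficiency", class(res))
  res
}

#' Clustering quality against ground truth
#'
#' Recollection is the fraction of true templates recovered as a cluster
#' whose majority label is that template; homogeneity is the mean fraction of
#' each cluster's reads sharing its majority label.
#'
#' @param cluster Integer/character vector of cluster ids, one per read.
#' @param truth Parallel vector of true template labels.
#' @param n_templates Total number of true templates (defaults to the number
#'   of distinct labels in `truth`).
#' @return A one-row tibble with `recollection` and `homogeneity`.
#' @export
clustering_metrics <- function(cluster, truth, n_templates = NULL) {
  stopifnot(length(cluster) == length(truth))
  n_templates <- n_templates %||% dplyr::n_distinct(truth)
  d <- tibble(cluster = cluster, truth = truth) |>
    dplyr::count(.data$cluster, .data$truth) |>
    group_by(.data$cluster) |>
    summarise(majority = .data$truth[which.max(.data$n)],
              frac = max(.data$n) / sum(.data$n), .groups = "drop")
  tibble(recollection = dplyr::n_distinct(d$majority) / n_templates,
         homogeneity = mean(d$frac))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
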