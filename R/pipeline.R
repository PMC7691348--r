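#' Pipeline run configuration
#'
#' One declarative object holding every stage's parameters; defaults are the
#' package's standard study conditions (50 nt UMIs, support > 0.6, at most
#' 16 mutations per variant, mean 3.5 substitutions per gene). The
#' configuration round-trips losslessly to and from a YAML file.
#'
#' @param reads Path to a FASTQ of raw reads (`NULL` when simulating).
#' @param reference Path to the reference FASTA (`NULL` to synthesise one).
#' @param barcodes Optional named character vector (or FASTA path) of round
#'   barcodes for demultiplexing.
#' @param probe Constant anchor preceding the UMI.
#' @param outdir Output directory for stage TSVs and the run report.
#' @param umi_length UMI length in nt.
#' @param threshold Clustering threshold (`"auto"` or an integer).
#' @param scoring A [scoring_params()].
#' @param filters A [filter_params()].
#' @param simulate `NULL`, or a list with `n_templates`, `coverage` and
#'   optionally `mean_mutations`, `sub_rate`, `ins_rate`, `del_rate`,
#'   `reference_length`.
#' @param evolve List with `d_max`, `embed`.
#' @param seed Integer seed used for every stochastic stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(reads = NULL, reference = NULL, barcodes = NULL,
                       probe = default_probe(), outdir = tempfile("umirun"),
                       umi_length = 50L, threshold = "auto",
                       scoring = scoring_params(), filters = filter_params(),
                       simulate = NULL, evolve = list(d_max = 2L, embed = FALSE),
                       seed = 1L) {
  structure(list(reads = reads, reference = reference, barcodes = barcodes,
                 probe = probe, outdir = outdir,
                 umi_length = as.integer(umi_length), threshold = threshold,
                 scoring = scoring, filters = filters, simulate = simulate,
                 evolve = evolve, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in intersect(names(y), c("reads", "reference", "barcodes", "probe",
                                   "outdir", "umi_length", "threshold",
                                   "simulate", "evolve", "seed"))) {
    cfg[[nm]] <- y[[nm]]
  }
  if (!is.null(y$scoring)) cfg$scoring <- do.call(scoring_params, y$scoring)
  if (!is.null(y$filters)) cfg$filters <- do.call(filter_params, y$filters)
  cfg
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  y$scoring <- unclass(y$scoring)[!vapply(unclass(y$scoring), is.null, TRUE)]
  y$filters <- unclass(y$filters)
  yaml::write_yaml(y, path)
  invisible(path)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full UMI-linked consensus pipeline
#'
#' Orchestrates simulate -> extract -> cluster -> consensus -> evolve,
#' writing every stage's table as TSV under `config$outdir` plus a
#' machine-readable JSON run report. Each reported number is re-derivable
#' from the stage TSVs. Reruns with the same config and seed produce
#' byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param stages Character vector of stages to execute.
#' @return The run report (a list, class `run_report`), invisibly
#'   containing the stage objects under `$objects`.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "extract", "cluster",
                                    "consensus", "evolve")) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed)
  obj <- list()

  # --- reference -----------------------------------------------------------
  if (!is.null(config$reference)) {
    if (!file.exists(config$reference)) {
      stop("reference file not found: ", config$reference)
    }
    ref <- read_reference(config$reference)
  } else {
    len <- config$simulate$reference_length %||% 1250L
    ref <- synthetic_reference(len, seed = config$seed)
  }
  obj$ref <- ref

  # --- simulate ------------------------------------------------------------
  if ("simulate" %in% stages && !is.null(config$simulate)) {
    s <- config$simulate
    em <- error_model(s$sub_rate %||% 0.06, s$ins_rate %||% 0.02,
                      s$del_rate %||% 0.02)
    cfg <- library_config(s$n_templates,
                          mean_mutations = s$mean_mutations %||% 3.5,
                          umi_length = config$umi_length,
                          barcode = s$barcode %||% NULL,
                          probe = config$probe)
    lib <- generate_library(ref, cfg, seed = config$seed)
    reads <- simulate_reads(lib, s$coverage, em, seed = config$seed + 1L)
    obj$library <- lib
    obj$reads <- reads
    write_fasta(setNames(lib$templates$gene, lib$templates$template_id),
                file.path(config$outdir, "templates.fasta"))
    readr::write_tsv(lib$mutations, file.path(config$outdir, "truth_mutations.tsv"))
    write_fastq(reads, file.path(config$outdir, "reads.fastq"))
    report$n_templates <- nrow(lib$templates)
    report$n_reads <- nrow(reads)
    log_stage("simulate", report$n_reads, " reads from ",
              report$n_templates, " templates")
  } else if (any(c("extract", "cluster", "consensus", "evolve") %in% stages)) {
    if (is.null(config$reads)) stop("no reads: set config$reads or simulate")
    if (!file.exists(config$reads)) {
      stop("reads file not found: ", config$reads)
    }
    obj$reads <- read_fastq(config$reads)
    if (nrow(obj$reads) == 0L) stop("reads file is empty: ", config$reads)
    report$n_reads <- nrow(obj$reads)
  }

  # --- extract -------------------------------------------------------------
  if ("extract" %in% stages) {
    ex <- extract_umis(obj$reads, probe = config$probe,
                       umi_length = config$umi_length,
                       params = config$scoring)
    obj$extractions <- ex
    readr::write_tsv(ex, file.path(config$outdir, "extractions.tsv"))
    report$n_extracted <- sum(ex$ok)
    report$extraction_rate <- mean(ex$ok)
    log_stage("extract", report$n_extracted, "/", nrow(ex), " UMIs extracted")
  }

  # --- cluster -------------------------------------------------------------
  if ("cluster" %in% stages) {
    thr <- config$threshold
    if (identical(thr, "auto")) thr <- NULL
    cl <- cluster_umis(obj$extractions, threshold = thr,
                       params = config$scoring, seed = config$seed)
    obj$clustering <- cl
    readr::write_tsv(cl$assignments, file.path(config$outdir, "clusters.tsv"))
    if (!is.null(cl$scan)) {
      readr::write_tsv(cl$scan$scan, file.path(config$outdir, "threshold_scan.tsv"))
    }
    report$threshold <- cl$threshold
    report$n_clusters <- nrow(cl$clusters)
    report$cluster_size_histogram <- as.list(table(cl$clusters$n_reads))
    log_stage("cluster", report$n_clusters, " clusters at threshold ",
              cl$threshold)
  }

  # --- consensus -----------------------------------------------------------
  if ("consensus" %in% stages) {
    cons <- call_consensus(obj$clustering, obj$reads, ref,
                           filters = config$filters, params = config$scoring)
    obj$consensus <- cons
    readr::write_tsv(cons$calls, file.path(config$outdir, "consensus_calls.tsv"))
    readr::write_tsv(cons$summary, file.path(config$outdir, "consensus_summary.tsv"))
    write_calls_vcf(cons, file.path(config$outdir, "consensus_passed.vcf"))
    report$n_called_clusters <- sum(!cons$summary$discarded)
    report$n_discarded <- as.list(table(cons$summary$reason[cons$summary$discarded]))
    report$n_passed_calls <- sum(cons$calls$passed)
    log_stage("consensus", report$n_called_clusters, " clusters called, ",
              report$n_passed_calls, " passed mutations")
    if (!is.null(obj$library)) {
      acc <- evaluate_accuracy(cons, obj$clustering, obj$reads, obj$library)
      obj$accuracy <- acc
      report$accuracy <- as.list(acc)
      log_stage("consensus", sprintf(
        "per-base error %.3g%%, recovery %.1f%%",
        100 * acc$per_base_error, 100 * acc$recovery))
    }
  }

  # --- evolve --------------------------------------------------------------
  if ("evolve" %in% stages && !is.null(obj$consensus)) {
    rounds <- NULL
    if (!is.null(config$barcodes)) {
      bc <- config$barcodes
      if (is.character(bc) && length(bc) == 1L && file.exists(bc)) {
        fa <- read_fasta(bc)
        bc <- setNames(fa$bases, fa$name)
      }
      rounds <- demultiplex(obj$clustering, obj$reads, bc,
                            params = config$scoring)
      readr::write_tsv(rounds, file.path(config$outdir, "rounds.tsv"))
      report$n_demultiplexed <- sum(!is.na(rounds$round))
      report$round_counts <- as.list(table(rounds$round))
    }
    variants <- dedupe_variants(obj$consensus, ref, rounds = rounds)
    obj$variants <- variants
    readr::write_tsv(
      select(variants, -"nt_mutations", -"aa_mutations"),
      file.path(config$outdir, "variants.tsv"))
    report$n_variants <- nrow(variants)
    if (nrow(variants) > 0L) {
      net <- build_network(variants, d_max = config$evolve$d_max %||% 2L,
                           embed = isTRUE(config$evolve$embed),
                           seed = config$seed)
      obj$network <- net
      readr::write_tsv(select(net$nodes, -"nt_mutations", -"aa_mutations"),
                       file.path(config$outdir, "network_nodes.tsv"))
      readr::write_tsv(net$edges, file.path(config$outdir, "network_edges.tsv"))
      founders <- find_founders(net)
      obj$founders <- founders
      readr::write_tsv(
        select(founders, -"core", -"member_ids"),
        file.path(config$outdir, "founders.tsv"))
      report$n_components <- dplyr::n_distinct(net$nodes$component)
      report$n_founders <- nrow(founders)
      if (all(c("round_1", "round_2", "round_3") %in% names(variants))) {
        enr <- tryCatch(positional_enrichment(variants),
                        error = function(e) NULL)
        if (!is.null(enr)) {
          readr::write_tsv(enr, file.path(config$outdir, "enrichment.tsv"))
          report$n_enriched_residues <- sum(enr$enrichment > 1)
        }
      }
    }
    log_stage("evolve", report$n_variants, " unique variants")
  }

  report_out <- report
  jsonlite::write_json(report_out, file.path(config$outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$objects <- obj
  class(report) <- "run_report"
  invisible(report)
}

#' Render passed consensus calls as a minimal VCF
#'
#' CHROM is the reference name, POS is 1-based, and indels are anchored on
#' the preceding reference base in the usual VCF convention.
#'
#' @param consensus A [call_consensus()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(consensus, path) {
  ref <- consensus$ref
  calls <- filter(consensus$calls, .data$passed)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", ref$name, ",length=",
                  nchar(ref$sequence), ">"),
           "##INFO=<ID=CLUSTER,Number=1,Type=String,Description=\"Cluster id\">",
           "##INFO=<ID=SUPPORT,Number=1,Type=Float,Description=\"Read support fraction\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    p <- calls$position[i]
    kind <- calls$kind[i]
    if (kind == "substitution") {
      pos1 <- p + 1L; refa <- calls$ref[i]; alta <- calls$alt[i]
    } else if (kind == "insertion") {
      if (p > 0L) {
        anchor <- substr(ref$sequence, p, p)
        pos1 <- p; refa <- anchor; alta <- paste0(anchor, calls$alt[i])
      } else {
        anchor <- substr(ref$sequence, 1L, 1L)
        pos1 <- 1L; refa <- anchor; alta <- paste0(calls$alt[i], anchor)
      }
    } else {
      if (p > 0L) {
        anchor <- substr(ref$sequence, p, p)
        pos1 <- p; refa <- paste0(anchor, calls$ref[i]); alta <- anchor
      } else {
        len <- nchar(calls$ref[i])
        anchor <- substr(ref$sequence, len + 1L, len + 1L)
        pos1 <- 1L; refa <- paste0(calls$ref[i], anchor); alta <- anchor
      }
    }
    rows[i] <- paste(ref$name, pos1, ".", refa, alta, ".", "PASS",
                     sprintf("CLUSTER=%s;SUPPORT=%.3f", calls$cluster_id[i],
                             calls$support[i]),
                     sep = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  flat <- x[!names(x) %in% "objects"]
  for (nm in names(flat)) {
    v <- flat[[nm]]
    if (is.list(v)) v <- paste(names(v), unlist(v), sep = "=", collapse = ", ")
    cat("  ", nm, ": ", paste(format(v), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}
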