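# Fixture builders shared across the test files. Everything is generated in
# code under fixed seeds; no data files.

# A reference realising the worked amino-acid examples: codon 64 = GCA (Ala),
# codon 102 = CGT (Arg), codon 308 = GAT (Asp), codon 323 = GAA (Glu).
make_lineage_ref <- function(seed = 42L) {
  ref <- synthetic_reference(1250L, seed = seed)
  seq <- ref$sequence
  fix <- function(seq, codon, triplet) {
    start <- 3L * (codon - 1L) + 1L
    substr(seq, start, start + 2L) <- triplet
    seq
  }
  seq <- fix(seq, 64L, "GCA")
  seq <- fix(seq, 102L, "CGT")
  seq <- fix(seq, 308L, "GAT")
  seq <- fix(seq, 323L, "GAA")
  reference_gene(ref$name, seq, ref$cds_offset, ref$cds_length)
}

# nucleotide substitutions realising the named aa mutations on that reference
lineage_subs <- list(
  A64E  = list(position = 190L, ref = "C", alt = "A"),  # GCA -> GAA
  R102S = list(position = 303L, ref = "C", alt = "A"),  # CGT -> AGT
  D308V = list(position = 922L, ref = "A", alt = "T"),  # GAT -> GTT
  E323V = list(position = 967L, ref = "A", alt = "T")   # GAA -> GTA
)

subs_for <- function(labels) {
  rows <- lineage_subs[labels]
  mutation_calls(position = vapply(rows, `[[`, 0L, "position"),
                 ref = vapply(rows, `[[`, "", "ref"),
                 alt = vapply(rows, `[[`, "", "alt"))
}

# Build a dedupe_variants-shaped tibble directly from label strings and
# per-round counts (matrix rows = variants, cols = rounds).
make_variants <- function(labels, counts) {
  counts <- as.matrix(counts)
  sets <- lapply(strsplit(labels, "\\s+"), function(x) sort(x[x != "WT" & nzchar(x)]))
  tb <- tibble::tibble(
    variant_id = ifelse(vapply(sets, length, 0L) == 0L, "WT",
                        sprintf("v%04d", seq_along(sets))),
    label = ifelse(vapply(sets, length, 0L) == 0L, "WT", labels),
    nt_mutations = rep(list(mutation_calls()), length(sets)),
    aa_mutations = sets,
    n_nt = vapply(sets, length, 0L),
    translatable = TRUE,
    first_round = apply(counts, 1L, function(x) which(x > 0L)[1L]),
    total = rowSums(counts))
  for (k in seq_len(ncol(counts))) tb[[paste0("round_", k)]] <- counts[, k]
  tb
}

# Full small-scale simulation -> extraction -> clustering -> consensus run.
run_sim_pipeline <- function(n_templates, coverage, gene_length = 300L,
                             error = error_model(), seed = 1L,
                             threshold = NULL, umi_length = 50L,
                             filters = filter_params(), barcode = NULL) {
  ref <- synthetic_reference(gene_length, seed = seed)
  lib <- generate_library(
    ref, library_config(n_templates, mean_mutations = 3.5,
                        umi_length = umi_length, barcode = barcode),
    seed = seed + 1L)
  reads <- simulate_reads(lib, coverage, error, seed = seed + 2L)
  ex <- extract_umis(reads, umi_length = umi_length)
  cl <- cluster_umis(ex, threshold = threshold, seed = seed + 3L)
  cons <- call_consensus(cl, reads, ref, filters = filters)
  list(ref = ref, lib = lib, reads = reads, extractions = ex,
       clustering = cl, consensus = cons)
}
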