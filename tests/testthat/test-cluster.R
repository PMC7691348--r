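test_that("umi_score agrees with a textbook dynamic-programming oracle", {
  p <- scoring_params()
  expect_equal(umi_score(strrep("ACGTT", 10L), strrep("ACGTT", 10L), p), 50L)
  expect_equal(umi_score("", "ACGT", p), 0L)
  expect_equal(umi_score("ACGT", "", p), 0L)

  set.seed(31)
  for (i in 1:200) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(1:20, 1L), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(1:20, 1L), replace = TRUE),
               collapse = "")
    expect_identical(umi_score(a, b, p), sw_oracle(a, b))
    # symmetry
    expect_identical(umi_score(a, b, p), umi_score(b, a, p))
  }

  # non-default scoring, cross-checked against Biostrings as a second,
  # fully independent implementation
  p2 <- scoring_params(match = 2L, mismatch = -3L, gap_open = -4L,
                       gap_extend = -2L)
  set.seed(32)
  for (i in 1:30) {
    a <- paste(sample(c("A", "C", "G", "T"), 15L, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 15L, replace = TRUE), collapse = "")
    expect_identical(umi_score(a, b, p2),
                     sw_oracle(a, b, 2L, -3L, -4L, -2L))
    bs <- Biostrings::pairwiseAlignment(
      a, b, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3, baseOnly = TRUE),
      gapOpening = 4, gapExtension = 2, scoreOnly = TRUE)
    expect_equal(umi_score(a, b, p2), as.integer(bs))
  }
})

test_that("UMIs are extracted exactly from error-free reads and fail cleanly otherwise", {
  ref <- synthetic_reference(300L, seed = 41)
  lib <- generate_library(ref, library_config(30L, umi_length = 50L), seed = 42)
  reads <- simulate_reads(lib, 2L, error_model(0, 0, 0), seed = 43)
  ex <- extract_umis(reads)
  expect_true(all(ex$ok))
  expect_identical(ex$umi, reads$true_umi)
  expect_identical(ex$orient, reads$strand)

  # random reads carry no probe
  set.seed(44)
  rnd <- tibble::tibble(read_id = sprintf("x%d", 1:20),
                        bases = umilink:::random_dna(20L, 400L))
  exr <- extract_umis(rnd)
  expect_true(all(!exr$ok))
  expect_true(all(exr$reason == "no_probe"))
  expect_true(all(exr$umi == ""))

  # too-short reads are flagged
  shrt <- tibble::tibble(read_id = "s", bases = "ACGTACGT")
  expect_equal(extract_umis(shrt)$reason, "too_short")
})

test_that("extraction from erroneous reads recovers near-true UMIs", {
  ref <- synthetic_reference(300L, seed = 45)
  lib <- generate_library(ref, library_config(100L, umi_length = 50L), seed = 46)
  reads <- simulate_reads(lib, 10L, error_model(0.06, 0.02, 0.02), seed = 47)
  ex <- extract_umis(reads)
  okx <- ex[ex$ok, ]
  truth <- setNames(reads$true_umi, reads$read_id)
  d <- mapply(function(u, t) edit_distance_oracle(u, t),
              okx$umi, truth[okx$read_id])
  # bounds calibrated on this fixture: the extracted window itself carries
  # Binomial(50, 0.1) ~ 5 +/- 2 read errors, so even a perfectly anchored
  # extraction sits within 0.15 L of the truth only ~85% of the time
  # (ppois(7, 5) = 0.87); the anchoring contributes almost nothing on top
  expect_gte(mean(d <= 0.15 * 50), 0.80)
  expect_gte(mean(d <= 0.20 * 50), 0.95)
  expect_lte(median(d), 6)
})

test_that("greedy clustering output is always a partition and is deterministic", {
  p <- scoring_params()
  # all identical UMIs -> one cluster
  same <- tibble::tibble(read_id = sprintf("r%d", 1:10),
                         umi = rep(strrep("ACGTT", 6L), 10L),
                         anchor_score = 20L, ok = TRUE, orient = "+",
                         reason = NA_character_)
  cl <- cluster_umis(same, threshold = 15L)
  expect_equal(nrow(cl$clusters), 1L)

  # threshold above the maximal self score -> all singletons
  set.seed(51)
  ex <- tibble::tibble(read_id = sprintf("r%d", 1:40),
                       umi = umilink:::random_dna(40L, 30L),
                       anchor_score = 20L, ok = TRUE, orient = "+",
                       reason = NA_character_)
  cl <- cluster_umis(ex, threshold = 31L)
  expect_equal(nrow(cl$clusters), 40L)

  # partition + monotonicity over random noisy inputs
  umis <- umilink:::random_dna(30L, 25L)
  em <- error_model(0.06, 0.02, 0.02)
  copies <- unlist(lapply(strsplit(umis, ""), function(ch) {
    vapply(1:4, function(i) umilink:::corrupt_chars(ch, em), "")
  }))
  exn <- tibble::tibble(read_id = sprintf("n%d", seq_along(copies)),
                        umi = copies, anchor_score = 20L, ok = TRUE,
                        orient = "+", reason = NA_character_)
  prev <- 0L
  for (th in c(5L, 10L, 15L, 20L, 25L)) {
    cln <- cluster_umis(exn, threshold = th)
    # partition: every ok read in exactly one cluster
    expect_setequal(cln$assignments$read_id, exn$read_id)
    expect_equal(anyDuplicated(cln$assignments$read_id), 0L)
    # raising the threshold never decreases the cluster count
    expect_gte(nrow(cln$clusters), prev)
    prev <- nrow(cln$clusters)
    # deterministic
    expect_identical(cluster_umis(exn, threshold = th)$assignments,
                     cln$assignments)
  }
})

test_that("error-free distinct UMIs give one cluster per template at any separating threshold", {
  set.seed(52)
  umis <- umilink:::random_dna(60L, 40L)
  copies <- rep(umis, each = 4L)
  ex <- tibble::tibble(read_id = sprintf("r%d", seq_along(copies)),
                       umi = copies, anchor_score = 20L, ok = TRUE,
                       orient = "+", reason = NA_character_)
  S <- umilink:::cpp_sw_matrix(umis, 1L, -1L, -1L, -1L)
  max_cross <- max(S[upper.tri(S)])
  for (th in unique(c(max_cross + 1L, 35L, 40L))) {
    cl <- cluster_umis(ex, threshold = th)
    expect_equal(nrow(cl$clusters), 60L)
    m <- clustering_metrics(cl$assignments$cluster_id,
                            rep(seq_len(60L), each = 4L), 60L)
    expect_equal(m$recollection, 1.0)
    expect_equal(m$homogeneity, 1.0)
  }
})

test_that("threshold estimation finds a plateau separating self from cross scores", {
  # noisy copies of 300 distinct UMIs at 10% per-base error
  set.seed(61)
  umis <- umilink:::random_dna(300L, 50L)
  em <- error_model(0.06, 0.02, 0.02)
  copies <- unlist(lapply(strsplit(umis, ""), function(ch) {
    vapply(1:5, function(i) umilink:::corrupt_chars(ch, em), "")
  }))
  truth <- rep(seq_len(300L), each = 5L)
  scan <- estimate_threshold(copies, truth = truth, seed = 3)
  expect_s3_class(scan, "threshold_scan")
  # the self and cross score distributions overlap by less than 1%
  rng <- range(c(scan$self_scores, scan$cross_scores))
  br <- seq(rng[1L] - 0.5, rng[2L] + 0.5, by = 1)
  p_self <- hist(scan$self_scores, breaks = br, plot = FALSE)$density
  p_cross <- hist(scan$cross_scores, breaks = br, plot = FALSE)$density
  expect_lt(sum(pmin(p_self, p_cross)), 0.01)
  # the chosen threshold clears virtually every cross pair while staying
  # below the bulk of the self-pair distribution (worst self *pairs* score
  # lower than seed-to-member links, so a modest tail below is expected)
  expect_lt(mean(scan$cross_scores >= scan$threshold), 0.001)
  expect_lt(mean(scan$self_scores < scan$threshold), 0.2)
  # and clustering at it recovers every template
  cl_ids <- umilink:::greedy_cluster_strings(copies, scan$threshold)
  m <- clustering_metrics(cl_ids, truth, 300L)
  expect_equal(m$recollection, 1.0)
  expect_equal(m$homogeneity, 1.0)
})

test_that("degenerate threshold ranges raise the no-stable-threshold error", {
  set.seed(62)
  umis <- rep(umilink:::random_dna(50L, 30L), each = 5L)
  expect_error(estimate_threshold(umis, thresholds = 40:60, seed = 1),
               "no stable threshold")
  expect_error(estimate_threshold(umilink:::random_dna(50L, 30L)),
               "at least 200")
})

test_that("simulated reads cluster perfectly at 50-bp UMIs and 10% error", {
  sim <- run_sim_pipeline(50L, 35L, gene_length = 300L, seed = 71)
  truth <- setNames(sim$reads$template_id, sim$reads$read_id)
  big <- sim$clustering$clusters$cluster_id[sim$clustering$clusters$n_reads >= 15L]
  a <- sim$clustering$assignments
  a <- a[a$cluster_id %in% big, ]
  m <- clustering_metrics(a$cluster_id, truth[a$read_id], 50L)
  expect_equal(m$recollection, 1.0)
  expect_equal(m$homogeneity, 1.0)
})
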