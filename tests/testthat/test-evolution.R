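test_that("variant_distance is the symmetric-difference metric", {
  expect_equal(variant_distance(character(), character()), 0L)
  expect_equal(variant_distance(c("A64E", "R102S"), c("A64E", "R102S")), 0L)
  # the worked lineage case: one acquired mutation is one step
  expect_equal(variant_distance(c("A64E", "R102S"),
                                c("A64E", "R102S", "E323V")), 1L)
  # brute-force oracle + metric axioms on random sets
  set.seed(120)
  pool <- paste0("M", 1:12, "A")
  rand_set <- function() sample(pool, sample(0:5, 1L))
  for (i in 1:40) {
    a <- rand_set(); b <- rand_set(); c <- rand_set()
    brute <- sum(!a %in% b) + sum(!b %in% a)
    expect_equal(variant_distance(a, b), brute)
    expect_equal(variant_distance(a, b), variant_distance(b, a))
    expect_lte(variant_distance(a, c),
               variant_distance(a, b) + variant_distance(b, c))
    expect_equal(variant_distance(a, a), 0L)
  }
})

test_that("similarity networks connect lineages and recover planted components", {
  # forced chain WT - {A64E} - {A64E,R102S} at d_max = 1
  v <- make_variants(c("WT", "A64E", "A64E R102S"),
                     matrix(1L, nrow = 3L, ncol = 1L))
  net <- build_network(v, d_max = 1L)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)
  expect_equal(dplyr::n_distinct(net$nodes$component), 1L)

  # single record
  net1 <- build_network(make_variants("A64E", matrix(1L, 1L, 1L)))
  expect_equal(nrow(net1$nodes), 1L)
  expect_equal(nrow(net1$edges), 0L)

  # 3 planted founder lineages x 20 descendants each: components at
  # d_max = 2 recover the lineages exactly
  set.seed(121)
  aa <- paste0("A", seq(10L, 400L, by = 10L), "V")
  founders <- list(aa[1:3], aa[11:13], aa[21:23])
  labels <- unlist(lapply(seq_along(founders), function(f) {
    extras <- aa[30L + (f - 1L) * 8L + (1:8)]
    vapply(1:20, function(i) {
      paste(sort(c(founders[[f]], sample(extras, sample(0:2, 1L)))),
            collapse = " ")
    }, "")
  }))
  labels <- unique(labels)
  v3 <- make_variants(labels, matrix(1L, length(labels), 1L))
  net3 <- build_network(v3, d_max = 2L)
  truth_comp <- vapply(v3$aa_mutations, function(s) {
    which(vapply(founders, function(f) all(f %in% s), TRUE))
  }, 0L)
  expect_equal(dplyr::n_distinct(net3$nodes$component), 3L)
  tab <- table(net3$nodes$component, truth_comp)
  expect_true(all(rowSums(tab > 0L) == 1L))
})

test_that("tSNE embedding is deterministic under seed and separates far lineages", {
  labels <- c("A10V A20V", "A10V A20V A30V", "A10V A20V A40V",
              "C200W C210W", "C200W C210W C220W", "C200W C210W C230W")
  v <- make_variants(labels, matrix(1L, length(labels), 1L))
  n1 <- build_network(v, d_max = 2L, embed = TRUE, seed = 7L)
  n2 <- build_network(v, d_max = 2L, embed = TRUE, seed = 7L)
  expect_identical(n1$nodes$x, n2$nodes$x)
  within <- sqrt((n1$nodes$x[1] - n1$nodes$x[2])^2 +
                   (n1$nodes$y[1] - n1$nodes$y[2])^2)
  across <- sqrt((n1$nodes$x[1] - n1$nodes$x[4])^2 +
                   (n1$nodes$y[1] - n1$nodes$y[4])^2)
  expect_lt(within, across)
})

test_that("founder cores are intersections, with the printed worked example", {
  v <- make_variants(c("A64E R102S", "A64E E323V R102S", "A64E D308V R102S"),
                     matrix(c(3L, 1L, 1L), 3L, 1L))
  net <- build_network(v, d_max = 2L)
  f <- find_founders(net)
  root <- f[f$level == 1L, ]
  expect_equal(root$core_label, "A64E R102S")
  subs <- sort(f$core_label[f$level == 2L])
  expect_equal(subs, c("D308V", "E323V"))

  # singleton cluster: core is its own set
  v1 <- make_variants("A64E R102S", matrix(1L, 1L, 1L))
  f1 <- find_founders(build_network(v1))
  expect_equal(f1$core_label, "A64E R102S")

  # a cluster containing wild type has an empty core
  v2 <- make_variants(c("WT", "A64E"), matrix(1L, 2L, 1L))
  f2 <- find_founders(build_network(v2, d_max = 1L))
  expect_equal(f2$core_label[f2$level == 1L], "WT")

  # subset invariant on simulated lineages
  set.seed(122)
  labels <- c("A10V A20V", paste("A10V A20V", paste0("B", 30:40, "C")))
  vv <- make_variants(labels, matrix(1L, length(labels), 1L))
  ff <- find_founders(build_network(vv, d_max = 2L))
  expect_equal(ff$core_label[ff$level == 1L], "A10V A20V")
})

test_that("positional enrichment matches hand arithmetic and handles pseudocounts", {
  # qualifying counts: round 1 total 100 (2 at residue 64),
  # round 2 total 100 (10 at residue 64); eps = 1/200
  v <- make_variants(
    c("A64E", "G9A"),
    cbind(round_1 = c(2L, 98L), round_2 = c(10L, 90L), round_3 = c(1L, 1L)))
  e <- positional_enrichment(v, 1L, 2L, 3L)
  expect_equal(e$enrichment[e$residue == 64L], 4.2, tolerance = 1e-12)

  # equal frequencies -> factor 1
  v_eq <- make_variants(
    c("A64E", "G9A"),
    cbind(round_1 = c(10L, 90L), round_2 = c(10L, 90L), round_3 = c(1L, 1L)))
  e_eq <- positional_enrichment(v_eq)
  expect_equal(e_eq$enrichment, c(1, 1))

  # absent in round 1, present in round 2 -> finite factor > 1
  v_new <- make_variants(
    c("A64E", "G9A"),
    cbind(round_1 = c(0L, 100L), round_2 = c(10L, 90L), round_3 = c(1L, 1L)))
  e_new <- positional_enrichment(v_new)
  f64 <- e_new$enrichment[e_new$residue == 64L]
  expect_gt(f64, 1)
  expect_true(is.finite(f64))

  # a requested round that is absent names the round in the error
  expect_error(positional_enrichment(v, 1L, 2L, 5L), "5")
})

test_that("enrichment frequencies are invariant under uniform count rescaling", {
  v <- make_variants(
    c("A64E", "R102S G9A", "G9A"),
    cbind(round_1 = c(4L, 16L, 80L), round_2 = c(30L, 20L, 50L),
          round_3 = c(2L, 1L, 3L)))
  e1 <- positional_enrichment(v)
  v10 <- v
  for (cc in c("round_1", "round_2", "round_3")) v10[[cc]] <- v10[[cc]] * 10L
  e10 <- positional_enrichment(v10)
  # the frequency components are exactly scale-free; with the adaptive
  # pseudocount the factors converge to the scale-free ratio as depth grows
  expect_equal(e10$f_from, e1$f_from)
  expect_equal(e10$f_to, e1$f_to)
  # at a fixed pseudocount the factors are exactly invariant
  ef1 <- positional_enrichment(v, eps = 0.005)
  ef10 <- positional_enrichment(v10, eps = 0.005)
  expect_equal(ef10$enrichment, ef1$enrichment)
})

test_that("epistasis classification reproduces the sign / magnitude / none cases", {
  # printed worked case: E323V alone drops activity to 15.7 +/- 1.1% of
  # parent, but raises the A64E R102S background by 1.54 +/- 0.33
  act <- activity_table(
    mutations = c("WT", "E323V", "A64E R102S", "A64E E323V R102S"),
    relative_activity = c(1.0, 0.157, 2.0, 3.08),
    ci95 = c(0, 0.011, 0.303, 0.467))
  r <- classify_epistasis(act, "E323V", c("A64E", "R102S"))
  expect_equal(r$class, "sign")
  expect_equal(r$effect_alone, 0.157)
  expect_equal(r$effect_in_background, 1.54, tolerance = 1e-12)
  expect_equal(r$effect_in_background_ci, 0.33, tolerance = 0.01)

  # multiplicative case: effect 2.0 alone and in background -> none
  act2 <- activity_table(c("WT", "M1A", "M2A", "M1A M2A"),
                         c(1, 2, 1.5, 3), 0)
  expect_equal(classify_epistasis(act2, "M1A", "M2A")$class, "none")

  # same direction, 2.0 vs 1.2 at tau 1.5 -> magnitude
  act3 <- activity_table(c("WT", "M1A", "M2A", "M1A M2A"),
                         c(1, 2, 1, 1.2), 0)
  r3 <- classify_epistasis(act3, "M1A", "M2A", tau = 1.5)
  expect_equal(r3$class, "magnitude")
  expect_equal(r3$gamma, 0.6)
})

test_that("pairwise epistasis classification is symmetric in m and background", {
  set.seed(130)
  for (i in 1:25) {
    am <- runif(1, 0.1, 3); ab <- runif(1, 0.1, 3)
    amb <- runif(1, 0.1, 3)
    act <- activity_table(c("WT", "M1A", "M2A", "M1A M2A"),
                          c(1, am, ab, amb), c(0, 0.02, 0.02, 0.02))
    r1 <- classify_epistasis(act, "M1A", "M2A")
    r2 <- classify_epistasis(act, "M2A", "M1A")
    expect_equal(r1$class, r2$class)
    expect_equal(r1$gamma, r2$gamma, tolerance = 1e-12)
  }
})

test_that("zero-activity backgrounds are flagged undefined", {
  act <- activity_table(c("WT", "M1A", "M2A", "M1A M2A"), c(1, 1, 0, 1), 0)
  expect_error(classify_epistasis(act, "M1A", "M2A"), "undefined")
})

test_that("demultiplexing assigns clusters to their round barcode", {
  set.seed(140)
  barcodes <- setNames(umilink:::random_dna(3L, 24L),
                       paste0("round", 1:3))
  ref <- synthetic_reference(300L, seed = 141)
  libs <- lapply(1:3, function(k) {
    generate_library(ref, library_config(12L, mean_mutations = 3.5,
                                         umi_length = 50L,
                                         barcode = barcodes[[k]]),
                     seed = 141L + k)
  })
  reads <- purrr::imap_dfr(libs, function(lib, k) {
    r <- simulate_reads(lib, 12L, error_model(0.06, 0.02, 0.02),
                        seed = 150L + k)
    r$read_id <- paste0("b", k, "_", r$read_id)
    r$round <- k
    r
  })
  ex <- extract_umis(reads)
  cl <- cluster_umis(ex, threshold = 22L)
  dm <- demultiplex(cl, reads, barcodes)
  truth_round <- setNames(reads$round, reads$read_id)
  maj <- cl$assignments |>
    dplyr::mutate(round = truth_round[.data$read_id]) |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(truth = .data$round[which.max(tabulate(.data$round))],
                     n = dplyr::n(), .groups = "drop")
  joined <- dplyr::left_join(dm, maj, by = "cluster_id") |>
    dplyr::filter(.data$n >= 10L)  # consensus-grade clusters
  acc <- mean(joined$round == joined$truth, na.rm = TRUE)
  expect_gte(acc, 0.99)

  # randomised barcode regions stay unassigned
  rnd <- reads
  plus <- rnd$strand == "+"
  substr(rnd$bases[plus], 1L, 24L) <- umilink:::random_dna(sum(plus), 24L)
  nn <- nchar(rnd$bases[!plus])  # reverse reads carry the barcode at the end
  substr(rnd$bases[!plus], nn - 23L, nn) <-
    umilink:::random_dna(sum(!plus), 24L)
  ex2 <- extract_umis(rnd)
  cl2 <- cluster_umis(ex2, threshold = 22L)
  dm2 <- demultiplex(cl2, rnd, barcodes)
  expect_gte(mean(is.na(dm2$round)), 0.9)
})

test_that("dedupe collapses identical mutation sets and counts rounds", {
  sim <- run_sim_pipeline(10L, 20L, gene_length = 300L,
                          error = error_model(0.04, 0.01, 0.01), seed = 160,
                          threshold = 22L)
  v <- dedupe_variants(sim$consensus, sim$ref)
  # truth-side dedup of planted variant sets (templates whose cluster was
  # actually called)
  truth_keys <- sim$lib$mutations |>
    dplyr::group_by(template_id) |>
    dplyr::summarise(key = paste(sort(paste0(position, ref, alt)),
                                 collapse = ";"), .groups = "drop")
  all_keys <- setNames(rep("", 10L), sim$lib$templates$template_id)
  all_keys[truth_keys$template_id] <- truth_keys$key
  called_tpl <- unique(all_keys)
  expect_equal(nrow(v), length(unique(all_keys)))
  expect_equal(sum(v$total), sum(!sim$consensus$summary$discarded))

  # two clusters with the same mutations in the same round -> one record
  empty_cons <- sim$consensus
  expect_equal(nrow(dedupe_variants(
    structure(list(summary = sim$consensus$summary[0, ],
                   calls = sim$consensus$calls[0, ], ref = sim$ref),
              class = "consensus_calls"), sim$ref)), 0L)
})
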