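test_that("omission plan reproduces the protocol group sizes", {
  seeds <- sprintf("GENE%02d", 1:69)
  plan <- build_omission_plan(seeds, central = "GENE01", k_max = 7,
                              draws_per_k = 30, rng_seed = 42)
  expect_equal(lengths(plan$groups), c("1" = 69, "2" = 68, "3" = 30, "4" = 30,
                                       "5" = 30, "6" = 30, "7" = 30))
  expect_equal(plan$n_configurations, 287)
  # k = 1: every seed omitted exactly once (the central one included)
  expect_setequal(unlist(plan$groups[["1"]]), seeds)
  # k = 2: the central gene paired with every other seed
  expect_true(all(vapply(plan$groups[["2"]], function(s) "GENE01" %in% s, TRUE)))
  expect_equal(length(unique(plan$groups[["2"]])), 68)
  # k >= 3: the central gene is in every configuration, sets have k members
  for (k in 3:7) {
    sets <- plan$groups[[as.character(k)]]
    expect_true(all(vapply(sets, function(s) "GENE01" %in% s, TRUE)))
    expect_true(all(lengths(sets) == k))
    expect_true(all(vapply(sets, anyDuplicated, 0L) == 0))
  }
})

test_that("omission plan handles small seed sets and bad input", {
  seeds <- paste0("S", 1:5)
  plan1 <- build_omission_plan(seeds, "S3", k_max = 1)
  expect_equal(plan1$n_configurations, 5)

  plan2 <- build_omission_plan(seeds, "S1", k_max = 2)
  expect_equal(length(plan2$groups[["2"]]), 4)
  expect_true(all(vapply(plan2$groups[["2"]], function(s) "S1" %in% s, TRUE)))

  expect_error(build_omission_plan(seeds, "NOPE"), "not among the seeds")
  expect_error(build_omission_plan(seeds, "S1", k_max = 99), "k_max")
})

test_that("identical rng_seed gives byte-identical plans, different seeds differ", {
  seeds <- sprintf("GENE%02d", 1:20)
  p1 <- build_omission_plan(seeds, "GENE05", k_max = 5, draws_per_k = 10,
                            rng_seed = 7)
  p2 <- build_omission_plan(seeds, "GENE05", k_max = 5, draws_per_k = 10,
                            rng_seed = 7)
  expect_identical(p1, p2)
  p3 <- build_omission_plan(seeds, "GENE05", k_max = 5, draws_per_k = 10,
                            rng_seed = 8)
  expect_false(identical(p1$groups[["4"]], p3$groups[["4"]]))
})

test_that("ordered omission combination counts follow the falling factorial", {
  expect_equal(omission_combination_count(69, 1), 69)
  expect_equal(omission_combination_count(5, 3), 5 * 4 * 3)
  expect_equal(omission_combination_count(5, 3, ordered = FALSE), choose(5, 3))
})

test_that("test networks score accuracy as top-M overlap with the reference", {
  cfg <- small_study_cfg()
  gen <- generate_interactome(cfg)
  seeds <- generate_seed_list(cfg, gen$truth, gen$interactions)
  giant <- decompose_components(
    build_extended_network(seeds, gen$interactions))$giant_graph
  bb <- extract_backbone(giant, fraction = 0.05)

  # omitting nothing reproduces the reference exactly
  res0 <- run_test_network(character(), seeds, gen$interactions, bb)
  expect_equal(res0$accuracy, 1.0)
  expect_equal(res0$top_bc_node, bb$members$node[1])

  # overlap arithmetic on a synthetic result
  expect_equal(length(intersect(letters[1:20], letters[8:34])) / 27, 13 / 27)

  # a disjoint reference gives accuracy 0
  fake_ref <- sprintf("FAKE%02d", seq_len(bb$cutoff_count))
  res_fake <- run_test_network(character(), seeds, gen$interactions, fake_ref)
  expect_equal(res_fake$accuracy, 0)

  # M larger than the giant triggers the degraded-denominator warning
  tiny_tab <- edge_df(c("A", "B"), c("B", "C"))
  expect_warning(
    res_small <- run_test_network(character(), c("A", "B", "C"), tiny_tab,
                                  reference_backbone = c("A", "B", "C", "D"),
                                  m = 4),
    "smaller than the top-set size")
  expect_equal(res_small$accuracy, 1.0)
})

test_that("robustness summary conserves counts and aggregates correctly", {
  cfg <- small_study_cfg()
  gen <- generate_interactome(cfg)
  seeds <- generate_seed_list(cfg, gen$truth, gen$interactions)
  plan <- build_omission_plan(seeds, central = seeds$symbol[1], k_max = 3,
                              draws_per_k = 5, rng_seed = 9)
  rob <- run_robustness(plan, seeds, gen$interactions)
  smry <- summarize_robustness(rob)

  # one result per configuration; per-row frequencies sum to the group size
  expect_equal(nrow(rob$detail), plan$n_configurations)
  node_cols <- setdiff(names(smry$per_k), c("k", "accuracy", "n_networks"))
  expect_equal(rowSums(smry$per_k[, node_cols, drop = FALSE]),
               as.numeric(smry$per_k$n_networks), ignore_attr = TRUE)
  expect_equal(sum(smry$frequency_totals), smry$n_total)
  expect_equal(smry$n_total, plan$n_configurations)
  expect_true(all(smry$per_k$accuracy >= 0 & smry$per_k$accuracy <= 1))

  # single group: the overall accuracy equals that group's mean
  one <- summarize_robustness(rob$detail[rob$detail$k == 1, ])
  expect_equal(one$overall_accuracy, mean(rob$detail$accuracy[rob$detail$k == 1]))

  # reruns with the same plan and inputs are byte-identical
  rob2 <- run_robustness(plan, seeds, gen$interactions)
  expect_identical(summarize_robustness(rob2), smry)
})

test_that("group aggregation uses the unweighted mean and column totals", {
  per_k <- data.frame(k = 1:3,
                      AAA = c(5L, 3L, 1L), BBB = c(0L, 1L, 2L),
                      accuracy = c(0.9, 0.6, 0.6),
                      n_networks = c(5L, 4L, 3L))
  agg <- aggregate_robustness_groups(per_k)
  expect_equal(agg$overall_accuracy, 0.7)                       # plain mean
  expect_equal(agg$overall_accuracy_weighted,
               (0.9 * 5 + 0.6 * 4 + 0.6 * 3) / 12)              # labelled variant
  expect_equal(unname(agg$frequency_totals), c(9, 3))
  expect_equal(agg$n_total, 12)
})
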