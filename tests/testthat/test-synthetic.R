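# The repertoire generator: determinism, structural invariants, spike
# construction, and recovery scoring.

test_that("generation is byte-reproducible for a fixed seed", {
  defs <- toy_defs()
  cfg <- simulation_config(seed = 11, n_background_clones = 60,
                           spikes = list(list(subset_id = "#S1",
                                              n_clones = 3)))
  s1 <- generate_repertoire(cfg, defs)
  s2 <- generate_repertoire(cfg, defs)
  expect_identical(s1, s2)
  p1 <- tempfile(); p2 <- tempfile()
  write_rearrangements(s1$records, p1)
  write_rearrangements(s2$records, p2)
  expect_identical(readLines(p1), readLines(p2))
  s3 <- generate_repertoire(simulation_config(seed = 12,
                                              n_background_clones = 60),
                            defs)
  expect_false(identical(s1$records$junction, s3$records$junction))
})

test_that("emitted junctions are stop-free, in-frame, and length-consistent", {
  cfg <- simulation_config(seed = 13, n_background_clones = 80)
  sim <- generate_repertoire(cfg)
  rec <- sim$records
  expect_true(all(nchar(rec$junction) %% 3 == 0))
  aa <- translate_nt(rec$junction)
  expect_false(any(grepl("*", aa, fixed = TRUE)))
  expect_identical(aa, rec$junction_aa)
  expect_identical(substr(aa, 2, nchar(aa) - 1), rec$cdr3_aa)
  expect_true(all(substr(aa, 1, 1) == "C"))
  expect_true(all(substr(aa, nchar(aa), nchar(aa)) == "W"))
  lens <- as.integer(names(default_junction_lengths()))
  expect_true(all(nchar(rec$junction) %in% lens))
  expect_true(all(rec$duplicate_count >= 1))
  expect_true(all(rec$productive))
})

test_that("planted divergence window brackets the configured thresholds", {
  cfg <- simulation_config(seed = 14, n_background_clones = 200)
  sim <- generate_repertoire(cfg)
  expect_lte(attr(sim$truth, "d1_realized"), 0.05)
  expect_gte(attr(sim$truth, "d2_realized"), 0.40)
})

test_that("spike windows hit the configured identity within discretization", {
  defs <- toy_defs()
  for (lvl in list(c(1, 1), c(0.6, 0.8), c(0.5, 0.7))) {
    cfg <- simulation_config(
      seed = 15, n_background_clones = 0,
      spikes = list(list(subset_id = "#S1", n_clones = 6,
                         identity_level = lvl[1],
                         similarity_level = lvl[2])))
    sim <- generate_repertoire(cfg, defs)
    def <- defs[[1]]
    w <- nchar(def$pattern)
    for (cdr3 in sim$records$cdr3_aa) {
      win <- substr(cdr3, def$pattern_offset + 1,
                    def$pattern_offset + w)
      expect_lte(abs(aa_identity(win, def$pattern) - lvl[1]), 1 / w + 1e-9)
      expect_lte(abs(aa_similarity(win, def$pattern) - lvl[2]), 1 / w + 1e-9)
    }
    if (lvl[1] == 1) {
      win <- substr(sim$records$cdr3_aa[1], def$pattern_offset + 1,
                    def$pattern_offset + w)
      expect_identical(win, def$pattern)
    }
  }
})

test_that("truth bookkeeping: no spikes means no subset labels", {
  sim <- generate_repertoire(simulation_config(seed = 16,
                                               n_background_clones = 30))
  expect_true(all(is.na(sim$truth$subset_id)))
  expect_true(all(is.na(sim$truth$typical)))
})

test_that("typical_fraction controls the planted typical flags", {
  defs <- toy_defs()
  cfg <- simulation_config(seed = 17, n_background_clones = 0,
                           spikes = list(list(subset_id = "#S2",
                                              n_clones = 40,
                                              typical_fraction = 0)))
  sim <- generate_repertoire(cfg, defs)
  expect_true(all(!sim$truth$typical))
  expect_false(any(sim$records$v_gene %in% defs[[2]]$typical_v_genes))

  cfg2 <- simulation_config(seed = 18, n_background_clones = 0,
                            spikes = list(list(subset_id = "#S1",
                                               n_clones = 10,
                                               typical_fraction = 1)))
  sim2 <- generate_repertoire(cfg2, defs)
  expect_true(all(sim2$truth$typical))
  expect_true(all(sim2$records$v_gene == "IGHV1-69"))
})

test_that("evaluate_recovery scores perfect, null and permuted predictions", {
  defs <- toy_defs()
  cfg <- simulation_config(seed = 19, n_background_clones = 50,
                           spikes = list(list(subset_id = "#S1",
                                              n_clones = 3)))
  sim <- generate_repertoire(cfg, defs)
  perfect <- sim$records
  perfect$subset_id <- sim$truth$subset_id
  perfect$clone_id <- sim$truth$clone_id
  ev <- evaluate_recovery(perfect, sim$truth, threshold = 0.2)
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(ev$specificity, 1.0)
  expect_equal(ev$ari, 1.0)
  expect_true(ev$threshold_in_window)

  null_pred <- perfect
  null_pred$subset_id <- NA_character_
  ev0 <- evaluate_recovery(null_pred, sim$truth)
  expect_equal(ev0$sensitivity, 0)
  expect_equal(ev0$specificity, 1.0)

  relabel <- perfect
  map <- setNames(sample(unique(perfect$clone_id)),
                  unique(perfect$clone_id))
  relabel$clone_id <- unname(map[perfect$clone_id])
  expect_equal(evaluate_recovery(relabel, sim$truth)$ari, 1.0)

  expect_error(evaluate_recovery(perfect[-1, ], sim$truth), "differ")
})

test_that("adjusted_rand_index behaves at the reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 1, 2)),
               adjusted_rand_index(c(2, 2, 1, 1), c(1, 1, 1, 2)))
  expect_lt(abs(adjusted_rand_index(rep(1:2, 50),
                                    rep(c(1, 1, 2, 2), 25))), 0.2)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(within_clone_divergence = 0.5,
                                 between_clone_min_divergence = 0.4), "d1")
  expect_error(simulation_config(spikes = list(list(subset_id = "#S1",
                                                    n_clones = 1,
                                                    identity_level = 0.9,
                                                    similarity_level = 0.5))),
               "identity_level")
  expect_error(generate_repertoire(
    simulation_config(spikes = list(list(subset_id = "#NOPE",
                                         n_clones = 1))),
    toy_defs()), "definition")
})
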