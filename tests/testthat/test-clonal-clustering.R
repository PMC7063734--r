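# Partitioning, distance-to-nearest, threshold detection, single-linkage
# clone inference and representative selection.

test_that("normalized_hamming matches hand counts and rejects mismatches", {
  expect_equal(normalized_hamming("ACGT", "ACGT"), 0.0)
  expect_equal(normalized_hamming("ACGT", "ACGA"), 0.25)
  expect_equal(normalized_hamming("AAAA", "TTTT"), 1.0)
  expect_error(normalized_hamming("ACG", "ACGT"), "partition")
})

test_that("partition_records keys on gene-level calls and junction length", {
  rec <- toy_records(c("TGTGCTAGAGATTGG", "TGTGCTAGAGATTGG",
                       "TGTGCTAGAGATAAATGG"),
                     v_call = c("IGHV1-69*01", "IGHV1-69*02", "IGHV1-69*01"))
  parts <- partition_records(rec)
  expect_equal(length(parts), 2L)
  sizes <- sort(vapply(parts, nrow, integer(1)))
  expect_equal(unname(sizes), c(1L, 2L))
  expect_equal(length(partition_records(rec[0, ])), 0L)
})

test_that("nearest-neighbor distances are per-record minima within partitions", {
  rec <- toy_records(c("AAAA", "AAAT", "TTTT"))
  d <- nearest_neighbor_distances(partition_records(rec))
  expect_equal(sort(d), c(0.25, 0.25, 0.75))

  same <- toy_records(rep("ACGT", 4))
  expect_equal(nearest_neighbor_distances(partition_records(same)),
               rep(0, 4))

  singletons <- toy_records(c("AAAA", "AAATTT"))
  expect_warning(d0 <- nearest_neighbor_distances(
    partition_records(singletons)), "2 members")
  expect_length(d0, 0L)
})

test_that("find_threshold locates the valley between planted modes", {
  set.seed(101)
  d <- c(pmin(pmax(rnorm(250, 0.05, 0.02), 0), 1),
         pmin(pmax(rnorm(250, 0.40, 0.05), 0), 1))
  th <- find_threshold(d)
  expect_equal(th$method, "density_valley")
  expect_gt(th$value, 0.10)
  expect_lt(th$value, 0.35)
})

test_that("find_threshold falls back on unimodal or degenerate input", {
  set.seed(102)
  uni <- pmin(pmax(rnorm(300, 0.3, 0.04), 0), 1)
  th <- find_threshold(uni, fallback = 0.11)
  expect_equal(th$method, "fixed")
  expect_equal(th$value, 0.11)

  th0 <- find_threshold(rep(0, 100), fallback = 0.15)
  expect_equal(th0$method, "fixed")
  expect_equal(th0$value, 0.15)

  expect_error(find_threshold(runif(10)), "fixed threshold")
})

test_that("cluster_clones reproduces the hand-worked example and limit cases", {
  rec <- toy_records(c("AAAA", "AAAT", "TTTT"))
  parts <- partition_records(rec)
  fams <- cluster_clones(parts, 0.30)
  members <- lapply(fams, `[[`, "member_ids")
  expect_equal(length(fams), 2L)
  expect_setequal(vapply(members, paste, character(1), collapse = "+"),
                  c("s001+s002", "s003"))
  # threshold 0: groups of exactly identical junctions
  rec2 <- toy_records(c("AAAA", "AAAA", "AAAT"))
  expect_equal(length(cluster_clones(partition_records(rec2), 0)), 2L)
  # threshold 1: one family per partition
  expect_equal(length(cluster_clones(parts, 1)), 1L)
})

test_that("clone ids are deterministic and order-independent", {
  set.seed(21)
  junctions <- vapply(1:30, function(i) random_nt_string(12), character(1))
  rec <- toy_records(junctions)
  fams1 <- cluster_clones(partition_records(rec), 0.25)
  shuffled <- rec[sample(nrow(rec)), ]
  fams2 <- cluster_clones(partition_records(shuffled), 0.25)
  expect_identical(lapply(fams1, `[[`, "member_ids"),
                   lapply(fams2, `[[`, "member_ids"))
  expect_identical(vapply(fams1, `[[`, character(1), "clone_id"),
                   vapply(fams2, `[[`, character(1), "clone_id"))
})

test_that("single linkage agrees with the transitive-closure oracle", {
  set.seed(31)
  for (i in 1:25) {
    m <- sample(5:60, 1)
    L <- 3 * sample(4:8, 1)
    # seed a few founders, then mutate to create linkage structure
    founders <- vapply(1:sample(2:5, 1), function(k) random_nt_string(L),
                       character(1))
    seqs <- vapply(1:m, function(k) {
      f <- strsplit(sample(founders, 1), "")[[1]]
      nmut <- sample(0:4, 1)
      if (nmut > 0) {
        pos <- sample(L, nmut)
        f[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
      }
      paste(f, collapse = "")
    }, character(1))
    threshold <- runif(1, 0.05, 0.5)
    rec <- toy_records(seqs)
    fams <- cluster_clones(partition_records(rec), threshold)
    got <- lapply(fams, `[[`, "member_ids")
    comp <- oracle_components(seqs, threshold)
    want <- membership_sets(rec$sequence_id, comp)
    expect_identical(got[order(vapply(got, `[`, character(1), 1))], want)
  }
})

test_that("number of families is non-increasing in the threshold", {
  set.seed(41)
  seqs <- vapply(1:40, function(i) random_nt_string(15), character(1))
  parts <- partition_records(toy_records(seqs))
  n_fams <- vapply(seq(0, 1, by = 0.1), function(t)
    length(cluster_clones(parts, t)), integer(1))
  expect_true(all(diff(n_fams) <= 0))
})

test_that("select_representative maximizes duplicate_count with id tie-break", {
  rec <- toy_records(c("AAAA", "AAAT"), duplicate_count = c(5L, 9L))
  fam <- list(member_ids = c("s001", "s002"))
  expect_equal(select_representative(fam, rec), "s002")
  tie <- toy_records(c("AAAA", "AAAT"), duplicate_count = c(5L, 5L))
  expect_equal(select_representative(fam, tie), "s001")
  expect_equal(select_representative(list(member_ids = "s001"), rec), "s001")
})

test_that("planted clones are recovered exactly for thresholds in the window", {
  defs <- toy_defs()
  cfg <- simulation_config(seed = 5, n_background_clones = 120,
                           spikes = list(list(subset_id = "#S1",
                                              n_clones = 4)))
  sim <- generate_repertoire(cfg, defs)
  d1 <- attr(sim$truth, "d1_realized")
  d2 <- attr(sim$truth, "d2_realized")
  expect_lt(d1, d2)
  for (t in c(d1 + 0.02, (d1 + d2) / 2, d2 - 0.02)) {
    cl <- infer_clones(sim$records, threshold = t)
    expect_equal(adjusted_rand_index(cl$clone_id, sim$truth$clone_id), 1.0)
  }
  # exactly one representative per clone
  cl <- infer_clones(sim$records, threshold = (d1 + d2) / 2)
  expect_equal(sum(cl$is_representative),
               length(unique(sim$truth$clone_id)))
})
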