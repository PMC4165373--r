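test_that("pair_distance implements 1 - R_ab / min(R_a, R_b) with test override", {
  d <- design2x1()
  # fully nested sharing: R_a = 100, R_b = 50, R_ab = 50 -> distance 0
  st <- store_of(list(list(ids = "a", counts = c(25, 25)),
                      list(ids = c("a", "b"), counts = c(25, 25))),
                 c("s1", "s2"))
  expect_equal(pair_distance(st, "a", "b", d), 0)
  # R_a = 100, R_b = 80, R_ab = 40 -> 0.5
  st2 <- store_of(list(list(ids = "a", counts = c(30, 30)),
                       list(ids = c("a", "b"), counts = c(20, 20)),
                       list(ids = "b", counts = c(20, 20))),
                  c("s1", "s2"))
  expect_equal(pair_distance(st2, "a", "b", d), 0.5)
  # no sharing -> 1
  st3 <- store_of(list(list(ids = "a", counts = c(5, 5)),
                       list(ids = "b", counts = c(5, 5))), c("s1", "s2"))
  expect_equal(pair_distance(st3, "a", "b", d), 1)
  # ratio-test rejection forces distance 1 despite heavy sharing
  st4 <- store_of(list(list(ids = "a", counts = c(300, 3)),
                       list(ids = c("a", "b"), counts = c(100, 100)),
                       list(ids = "b", counts = c(3, 300))),
                  c("s1", "s2"))
  expect_equal(pair_distance(st4, "a", "b", d, test_enabled = TRUE), 1)
  expect_lt(pair_distance(st4, "a", "b", d, test_enabled = FALSE), 1)
})

test_that("stopping rule: pairs above the distance threshold never merge", {
  d <- design2x1()
  # distance 0.5 > default 0.3 -> two singletons
  st <- store_of(list(list(ids = "a", counts = c(30, 30)),
                      list(ids = c("a", "b"), counts = c(20, 20)),
                      list(ids = "b", counts = c(20, 20))),
                 c("s1", "s2"))
  part <- cluster_supercluster(c("a", "b"), st, d,
                               cclust_params(min_fragments = 0))
  expect_equal(canonical_partition(part), list("a", "b"))
  # a pair at exactly the threshold merges (stop is strictly greater)
  part2 <- cluster_supercluster(c("a", "b"), st, d,
                                cclust_params(d_threshold = 0.5, min_fragments = 0))
  expect_equal(canonical_partition(part2), list(c("a", "b")))
  # identical read sets -> distance 0 -> merged
  st5 <- store_of(list(list(ids = c("a", "b"), counts = c(10, 10))), c("s1", "s2"))
  part3 <- cluster_supercluster(c("a", "b"), st5, d, cclust_params(min_fragments = 0))
  expect_equal(canonical_partition(part3), list(c("a", "b")))
})

test_that("threshold extremes behave as documented", {
  d <- design2x1()
  # d_threshold ~ 0: only fully redundant pairs (distance exactly 0) merge
  p0 <- cclust_params(d_threshold = 1e-12, test_enabled = FALSE, min_fragments = 0)
  st_half <- store_of(list(list(ids = "a", counts = c(5, 5)),
                           list(ids = c("a", "b"), counts = c(5, 5)),
                           list(ids = "b", counts = c(5, 5))), c("s1", "s2"))
  expect_equal(canonical_partition(cluster_supercluster(c("a", "b"), st_half, d, p0)),
               list("a", "b"))
  st_red <- store_of(list(list(ids = c("a", "b"), counts = c(5, 5))), c("s1", "s2"))
  expect_equal(canonical_partition(cluster_supercluster(c("a", "b"), st_red, d, p0)),
               list(c("a", "b")))
  # test off, threshold near 1: a supercluster collapses when all pairwise
  # distances are < 1 at every step
  p1 <- cclust_params(d_threshold = 1 - 1e-9, test_enabled = FALSE, min_fragments = 0)
  st_conn <- store_of(list(list(ids = c("a", "b"), counts = 5),
                           list(ids = c("b", "c"), counts = 5),
                           list(ids = c("c", "d"), counts = 5)), "s1")
  part <- cluster_supercluster(c("a", "b", "c", "d"), st_conn,
                               make_design("s1", "A"), p1)
  expect_equal(canonical_partition(part), list(c("a", "b", "c", "d")))
})

test_that("small random instances match the naive full-recompute oracle", {
  set.seed(81)
  d4 <- make_design(c("s1", "s2", "s3", "s4"), c("A", "A", "B", "B"))
  for (i in 1:40) {
    cls <- random_classes(sample(2:6, 1), sample(3:9, 1), 4, max_count = 50)
    st <- store_of(cls, d4$samples)
    test_on <- i %% 2 == 0
    params <- cclust_params(d_threshold = sample(c(0.3, 0.5, 0.8), 1),
                            test_enabled = test_on, min_fragments = 0)
    D_thr <- d_threshold(d4$n_conditions, params$p_value)
    got <- canonical_partition(run_all(st, d4, params))
    # oracle: within each union-find component, naive reclustering
    want <- list()
    for (sc in oracle_components(cls))
      want <- c(want, oracle_cluster(cls, sc, d4$group, params$d_threshold,
                                     test_on, D_thr))
    expect_equal(got, canonical_partition(want), info = paste("instance", i))
  }
})

test_that("transitive rescue: a rejected pair can co-cluster via an intermediate", {
  d <- design2x1()
  st <- store_of(rescue_classes(), c("s1", "s2"))
  D_thr <- d_threshold(2)
  # (a,b) rejects up front -> distance forced to 1
  r_ab <- lrt_statistic(pair_counts_from_store(st, "a", "b", d), D_thr)
  expect_true(r_ab$reject)
  expect_equal(pair_distance(st, "a", "b", d), 1)
  # but (a,c) accepts and merges; the merged pair no longer rejects
  m <- merge_clusters(st, "a", "c", "m")
  r_mb <- lrt_statistic(pair_counts_from_store(m, "m", "b", d), D_thr)
  expect_false(r_mb$reject)
  part <- run_all(st, d, cclust_params(d_threshold = 0.5, min_fragments = 0))
  expect_equal(canonical_partition(part), list(c("a", "b", "c")))
})

test_that("run_all respects super-cluster boundaries and empty stores", {
  d <- make_design("s1", "A")
  st <- store_of(list(list(ids = c("a", "b"), counts = 20),
                      list(ids = c("b", "c"), counts = 20),
                      list(ids = "z", counts = 20)), "s1")
  part <- run_all(st, d, cclust_params(min_fragments = 0))
  blocks <- canonical_partition(part)
  # z never co-clusters with a/b/c
  for (blk in blocks)
    expect_true(!("z" %in% blk) || length(blk) == 1)
  expect_setequal(unlist(blocks), c("a", "b", "c", "z"))
  # names are the deterministic supercluster.cluster scheme
  expect_true(all(grepl("^Cluster-\\d+\\.\\d+$", names(part))))
  empty <- eq_store(list(), matrix(numeric(0), 0, 1), "s1")
  expect_equal(run_all(empty, d, cclust_params()), list())
})

test_that("distances are symmetric and bounded (property)", {
  set.seed(91)
  d <- design2x1()
  for (i in 1:20) {
    cls <- random_classes(4, 6, 2)
    st <- store_of(cls, c("s1", "s2"))
    ids <- live_ids(st)
    if (length(ids) < 2) next
    ab <- sample(ids, 2)
    d1 <- pair_distance(st, ab[1], ab[2], d)
    d2 <- pair_distance(st, ab[2], ab[1], d)
    expect_identical(d1, d2)
    expect_gte(d1, 0); expect_lte(d1, 1)
  }
})
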