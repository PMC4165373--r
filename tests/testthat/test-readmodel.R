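test_that("build_eqclasses aggregates fragments into per-sample class counts", {
  d <- make_design(c("S1", "S2"), c("A", "B"))
  frags <- data.table::data.table(
    fragment = c("r1", "r2", "r3", "r4", "r5"),
    sample = c("S1", "S1", "S1", "S2", "S2"),
    contigs = list("c1", "c1", c("c1", "c2"), c("c1", "c2"), "c2"))
  st <- build_eqclasses(frags, d)
  expect_equal(st$kstr, c("c1", "c1,c2", "c2"))
  expect_equal(unname(st$counts), rbind(c(2, 0), c(1, 1), c(0, 1)))
  expect_equal(total_fragments(st), 5)
  expect_error(build_eqclasses(
    data.table::data.table(fragment = "x", sample = "nope", contigs = list("c1")), d),
    "unknown sample")
})

test_that("shared_count sums over superset keys; monotone and zero for disjoint", {
  st <- store_of(list(list(ids = "a", counts = 4),
                      list(ids = c("a", "b"), counts = 3),
                      list(ids = "d", counts = 9)), "s1")
  expect_equal(shared_count(st, "a"), 7)
  expect_equal(shared_count(st, c("a", "b")), 3)
  expect_equal(shared_count(st, c("a", "d")), 0)
  expect_error(shared_count(st, "nope"), "unknown")
  set.seed(21)
  for (i in 1:20) {
    cls <- random_classes(5, 8, 2)
    st <- store_of(cls, c("s1", "s2"))
    ids <- live_ids(st)
    if (length(ids) < 2) next
    ab <- sample(ids, 2)
    expect_lte(shared_count(st, ab),
               min(shared_count(st, ab[1]), shared_count(st, ab[2])))
    # agreement with the independent intersection-count oracle
    expect_equal(shared_count(st, ab[1]), oracle_count(cls, ab[1]))
    expect_equal(shared_count(st, ab), oracle_count(cls, ab[1], ab[2]))
  }
})

test_that("filter_low_coverage removes weak contigs, trims keys, is idempotent", {
  # c_low has 5 fragments in total -> removed at the default threshold of 10
  cls <- list(list(ids = "c_keep", counts = c(8, 4)),
              list(ids = c("c_keep", "c_low"), counts = c(3, 0)),
              list(ids = "c_low", counts = c(2, 0)))
  st <- store_of(cls, c("s1", "s2"))
  fl <- filter_low_coverage(st)
  expect_equal(fl$removed, "c_low")
  expect_equal(live_ids(fl$store), "c_keep")
  # the mixed class keeps its counts under the trimmed key
  expect_equal(shared_count(fl$store, "c_keep"), 15)
  # fragments of dropped-only classes are discarded
  expect_equal(total_fragments(fl$store), 15)
  # min_fragments = 0 disables filtering
  expect_identical(filter_low_coverage(st, 0)$store, st)
  # idempotence
  fl2 <- filter_low_coverage(fl$store)
  expect_equal(fl2$removed, character(0))
  expect_equal(fl2$store$kstr, fl$store$kstr)
  expect_equal(fl2$store$counts, fl$store$counts)
})

test_that("retention boundary: exactly min_fragments is kept", {
  st <- store_of(list(list(ids = "ten", counts = 10),
                      list(ids = "nine", counts = 9)), "s1")
  fl <- filter_low_coverage(st, 10)
  expect_equal(fl$removed, "nine")
  expect_equal(live_ids(fl$store), "ten")
})

test_that("super-clusters are connected components of read sharing", {
  st <- store_of(list(list(ids = c("a", "b"), counts = 1),
                      list(ids = c("b", "c"), counts = 1),
                      list(ids = "d", counts = 1)), "s1")
  expect_equal(build_superclusters(st), list(c("a", "b", "c"), "d"))
  # no multi-contig class -> all singletons
  st2 <- store_of(list(list(ids = "x", counts = 1),
                       list(ids = "y", counts = 2)), "s1")
  expect_equal(build_superclusters(st2), list("x", "y"))
  # random sharing graphs match the union-find oracle
  set.seed(31)
  for (i in 1:25) {
    cls <- random_classes(8, 10, 1)
    st <- store_of(cls, "s1")
    expect_equal(build_superclusters(st), oracle_components(cls))
  }
})

test_that("condition_counts matches a brute-force recount from fragments", {
  d <- make_design(c("S1", "S2", "S3", "S4"), c("A", "A", "B", "B"))
  set.seed(41)
  # raw fragments, then both routes: store vs direct recount
  n <- 200
  frags <- data.table::data.table(
    fragment = sprintf("f%03d", 1:n),
    sample = sample(d$samples, n, replace = TRUE),
    contigs = lapply(1:n, function(i)
      sort(sample(c("a", "b", "c"), sample(1:3, 1)))))
  st <- build_eqclasses(frags, d)
  cc <- condition_counts(st, "a", "b", d)
  has <- function(ctg) vapply(frags$contigs, function(s) ctg %in% s, logical(1))
  for (s in d$samples) {
    in_s <- frags$sample == s
    expect_equal(unname(cc$r_a[s]), sum(in_s & has("a")))
    expect_equal(unname(cc$r_b[s]), sum(in_s & has("b")))
    expect_equal(unname(cc$r_ab[s]), sum(in_s & has("a") & has("b")))
  }
  expect_true(all(cc$r_ab <= pmin(cc$r_a, cc$r_b)))
  expect_equal(unname(cc$condition), c("A", "A", "B", "B"))
})

test_that("merge_clusters obeys the printed linkage equations", {
  # R_a = 10, R_b = 8, R_ab = 3 -> R_a' = 15; R_ac = 4, R_bc = 2, R_abc = 1 -> R_a'c = 5
  cls <- list(list(ids = "a", counts = 4),
              list(ids = c("a", "b"), counts = 2),
              list(ids = c("a", "b", "c"), counts = 1),
              list(ids = c("a", "c"), counts = 3),
              list(ids = c("b", "c"), counts = 1),
              list(ids = "b", counts = 4))
  st <- store_of(cls, "s1")
  expect_equal(shared_count(st, "a"), 10)
  expect_equal(shared_count(st, "b"), 8)
  expect_equal(shared_count(st, c("a", "b")), 3)
  expect_equal(shared_count(st, c("a", "c")), 4)
  expect_equal(shared_count(st, c("b", "c")), 2)
  expect_equal(shared_count(st, c("a", "b", "c")), 1)
  m <- merge_clusters(st, "a", "b", "ab")
  expect_equal(shared_count(m, "ab"), 15)          # R_a + R_b - R_ab
  expect_equal(shared_count(m, c("ab", "c")), 5)   # R_ac + R_bc - R_abc
})

test_that("disjoint merge adds totals and conservation holds", {
  st <- store_of(list(list(ids = "a", counts = 6),
                      list(ids = "b", counts = 5)), "s1")
  m <- merge_clusters(st, "a", "b", "ab")
  expect_equal(shared_count(m, "ab"), 11)
  expect_equal(total_fragments(m), total_fragments(st))
  expect_error(merge_clusters(st, "a", "zz", "w"), "unknown")
})

test_that("linkage equations hold exactly on random stores (property)", {
  set.seed(51)
  for (i in 1:100) {
    cls <- random_classes(5, 7, 2)
    st <- store_of(cls, c("s1", "s2"))
    ids <- live_ids(st)
    if (length(ids) < 3) next
    ab <- sample(ids, 2); a <- ab[1]; b <- ab[2]
    R_a <- shared_count(st, a); R_b <- shared_count(st, b)
    R_ab <- shared_count(st, c(a, b))
    others <- setdiff(ids, ab)
    R_ac <- vapply(others, function(c) shared_count(st, c(a, c)), numeric(1))
    R_bc <- vapply(others, function(c) shared_count(st, c(b, c)), numeric(1))
    R_abc <- vapply(others, function(c) shared_count(st, c(a, b, c)), numeric(1))
    m <- merge_clusters(st, a, b, "\x01new")
    expect_identical(shared_count(m, "\x01new"), R_a + R_b - R_ab)
    for (k in seq_along(others))
      expect_identical(shared_count(m, c("\x01new", others[k])),
                       unname(R_ac[k] + R_bc[k] - R_abc[k]))
    expect_identical(total_fragments(m), total_fragments(st))
  }
})
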