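# shared fixture builders (all in-code; no binary files)

make_design <- function(samples, groups) {
  experiment_design(character(0), samples = samples, groups = groups)
}

design2x1 <- function() make_design(c("s1", "s2"), c("A", "B"))

store_of <- function(classes, samples) classes_to_store(classes, samples)

# hand-written SAM with paired-end, multi-mapped and unmapped records
write_fixture_sam <- function(path) {
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:c1\tLN:500",
    "@SQ\tSN:c2\tLN:400",
    # r1: first mate hits c1 and c2, second mate hits c1 only
    "r1\t65\tc1\t10\t0\t50M\t*\t0\t0\t*\t*",
    "r1\t65\tc2\t10\t0\t50M\t*\t0\t0\t*\t*",
    "r1\t129\tc1\t100\t0\t50M\t*\t0\t0\t*\t*",
    # r2: single-end read on c1 and c2
    "r2\t0\tc1\t20\t0\t50M\t*\t0\t0\t*\t*",
    "r2\t0\tc2\t20\t0\t50M\t*\t0\t0\t*\t*",
    # r3: c2 only
    "r3\t0\tc2\t30\t0\t50M\t*\t0\t0\t*\t*",
    # r4: fully unmapped -> no record
    "r4\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*")
  writeLines(lines, path)
  path
}

# random pair_counts instance for LRT tests
random_pair_counts <- function(n_conditions) {
  structure(list(X_a = 1 + stats::rpois(n_conditions, sample(c(5, 50, 300), 1)) +
                   stats::runif(n_conditions),
                 X_b = 1 + stats::rpois(n_conditions, sample(c(5, 50, 300), 1)) +
                   stats::runif(n_conditions),
                 n_conditions = n_conditions),
            class = "pair_counts")
}

# the transitive-rescue fixture: the (a,b) ratio test rejects at D = 20, but
# after (a,c) merge the re-tested pair accepts and everything co-clusters
rescue_classes <- function() list(
  list(ids = c("a", "b"), counts = c(3, 4)),
  list(ids = "b",         counts = c(25, 3)),
  list(ids = "c",         counts = c(31, 23)),
  list(ids = c("b", "c"), counts = c(28, 28)),
  list(ids = c("a", "c"), counts = c(9, 38)))
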