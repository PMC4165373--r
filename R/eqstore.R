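#' @importFrom data.table data.table := setkey setorder rbindlist fread
#' @importFrom stats qchisq rmultinom rpois rnbinom runif
NULL

# Separator used inside equivalence-class keys.  Contig IDs therefore must not
# contain commas (enforced on construction).
.KEY_SEP <- ","

# locale-independent (C collation) sort/order, so output is byte-identical
# across environments
csort <- function(x) sort(x, method = "radix")
corder <- function(...) order(..., method = "radix")

key_of <- function(ids) paste(csort(unique(ids)), collapse = .KEY_SEP)
ids_of <- function(key) strsplit(key, .KEY_SEP, fixed = TRUE)[[1L]]

#' Equivalence-class store
#'
#' The store is the single source of truth for all read-sharing quantities.
#' Each equivalence class is the set of cluster IDs that some fragments map to
#' exactly, together with the number of such fragments in every sample.  All
#' shared-read statistics (`R_a`, `R_ab`, `R_abc`, per-condition replicate
#' counts) are obtained by summing class counts over superset keys, so the
#' inclusion-exclusion linkage updates used during clustering hold exactly by
#' construction.
#'
#' @param keys list of character vectors, one non-empty set of cluster IDs per
#'   class (duplicates within a set are collapsed).
#' @param counts numeric matrix, classes x samples, non-negative fragment
#'   counts.  Classes whose total count is zero are dropped.
#' @param samples character vector of sample IDs naming the columns.
#' @return an object of class `eq_store`.
#' @export
eq_store <- function(keys, counts, samples) {
  counts <- as.matrix(counts)
  if (length(keys) != nrow(counts))
    stop("keys and counts disagree on the number of classes")
  if (ncol(counts) != length(samples))
    stop("counts and samples disagree on the number of samples")
  if (any(counts < 0)) stop("negative fragment counts")
  ids <- unlist(keys, use.names = FALSE)
  if (length(ids) && any(grepl(.KEY_SEP, ids, fixed = TRUE)))
    stop("cluster IDs must not contain '", .KEY_SEP, "'")
  kstr <- vapply(keys, key_of, character(1L))
  if (any(kstr == "")) stop("empty equivalence-class key")
  # collapse duplicate keys, drop all-zero classes
  if (anyDuplicated(kstr)) {
    counts <- rowsum(counts, kstr, reorder = FALSE)
    kstr <- rownames(counts)
  }
  if (length(kstr)) {
    o <- corder(kstr)
    kstr <- kstr[o]
    counts <- counts[o, , drop = FALSE]
  }
  keep <- rowSums(counts) > 0
  kstr <- kstr[keep]
  counts <- counts[keep, , drop = FALSE]
  dimnames(counts) <- list(NULL, samples)
  obj <- list(keys = lapply(kstr, ids_of), kstr = kstr,
              counts = counts, samples = as.character(samples))
  obj$index <- build_index(obj$keys)
  class(obj) <- "eq_store"
  obj
}

build_index <- function(keys) {
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_along(keys))
    for (id in keys[[i]])
      assign(id, c(idx[[id]], i), envir = idx)
  idx
}

#' @export
print.eq_store <- function(x, ...) {
  cat(sprintf("eq_store: %d classes, %d clusters, %d samples, %g fragments\n",
              length(x$keys), length(live_ids(x)), length(x$samples),
              sum(x$counts)))
  invisible(x)
}

#' Live cluster IDs of a store
#' @param store an `eq_store`.
#' @return sorted character vector of cluster IDs referenced by any class.
#' @export
live_ids <- function(store) csort(ls(store$index, sorted = FALSE))

#' Total fragments in a store (all classes, all samples)
#' @param store an `eq_store`.
#' @export
total_fragments <- function(store) sum(store$counts)

# rows of classes whose key contains every ID in `a` (character vector)
superset_rows <- function(store, a) {
  rows <- store$index[[a[[1L]]]]
  if (is.null(rows)) stop("unknown cluster ID: ", a[[1L]])
  for (id in a[-1L]) {
    r2 <- store$index[[id]]
    if (is.null(r2)) stop("unknown cluster ID: ", id)
    rows <- intersect(rows, r2)
    if (!length(rows)) return(integer(0))
  }
  rows
}

#' Shared fragment count over a set of clusters
#'
#' `shared_count(store, "a")` is `R_a`, the total number of fragments mapping
#' to cluster `a` over all samples; `shared_count(store, c("a","b"))` is
#' `R_ab`, fragments mapping to both, and so on for any set size.
#'
#' @param store an `eq_store`.
#' @param a non-empty character vector of live cluster IDs.
#' @return a single non-negative number.
#' @export
shared_count <- function(store, a) {
  stopifnot(length(a) >= 1L)
  rows <- superset_rows(store, unique(as.character(a)))
  if (!length(rows)) return(0)
  sum(store$counts[rows, , drop = FALSE])
}

# per-sample version (vector over samples)
shared_count_by_sample <- function(store, a) {
  rows <- superset_rows(store, unique(as.character(a)))
  if (!length(rows)) return(stats::setNames(numeric(length(store$samples)), store$samples))
  stats::setNames(colSums(store$counts[rows, , drop = FALSE]), store$samples)
}

#' Per-condition replicate counts for a pair of clusters
#'
#' Returns, for each sample, the fragments mapping to `a` (`r_a`), to `b`
#' (`r_b`) and to both (`r_ab`), together with the sample's condition label.
#' These are the replicate-level inputs of the expression-ratio test;
#' `r_ab <= min(r_a, r_b)` holds for every sample.
#'
#' @param store an `eq_store`.
#' @param a,b distinct live cluster IDs.
#' @param design an [experiment_design()].
#' @return a list with numeric vectors `r_a`, `r_b`, `r_ab` (one entry per
#'   sample, in design order) and character vector `condition`.
#' @export
condition_counts <- function(store, a, b, design) {
  stopifnot(inherits(design, "experiment_design"), a != b)
  if (!identical(store$samples, design$samples))
    stop("store samples do not match design samples")
  list(r_a  = shared_count_by_sample(store, a),
       r_b  = shared_count_by_sample(store, b),
       r_ab = shared_count_by_sample(store, c(a, b)),
       condition = design$group[design$samples])
}

#' Merge two clusters in the store
#'
#' Every class key containing `a` and/or `b` is relabelled to `new_id`;
#' classes whose keys become identical are summed.  Afterwards the linkage
#' identities hold exactly by inclusion-exclusion:
#' `R_a' = R_a + R_b - R_ab` and, for any other cluster `c`,
#' `R_a'c = R_ac + R_bc - R_abc`.
#'
#' @param store an `eq_store`.
#' @param a,b distinct live cluster IDs to merge.
#' @param new_id ID for the merged cluster (must not collide with a live ID
#'   other than `a`/`b`).
#' @return the updated `eq_store`.
#' @export
merge_clusters <- function(store, a, b, new_id) {
  stopifnot(a != b)
  if (is.null(store$index[[a]])) stop("unknown cluster ID: ", a)
  if (is.null(store$index[[b]])) stop("unknown cluster ID: ", b)
  if (!is.null(store$index[[new_id]]) && !new_id %in% c(a, b))
    stop("new_id collides with a live cluster ID: ", new_id)
  rows <- sort(unique(c(store$index[[a]], store$index[[b]])))
  keys <- store$keys
  for (i in rows) {
    k <- keys[[i]]
    keys[[i]] <- csort(unique(c(setdiff(k, c(a, b)), new_id)))
  }
  eq_store(keys, store$counts, store$samples)
}

#' Filter contigs with too few mapped fragments
#'
#' Removes every contig whose total fragment count (over all classes that
#' contain it, all samples) is below `min_fragments`; by default contigs with
#' fewer than 10 fragments are dropped.  Removed contigs are deleted from
#' class keys; classes left with an empty key are dropped and their fragments
#' discarded (they can no longer be assigned).  `min_fragments = 0` disables
#' filtering.  The operation is idempotent: surviving contigs keep their
#' totals, so a second pass removes nothing.
#'
#' @param store an `eq_store`.
#' @param min_fragments minimum total fragment count a contig needs to be
#'   retained (default 10).
#' @return list with elements `store` (filtered) and `removed` (character
#'   vector of removed contig IDs).
#' @export
filter_low_coverage <- function(store, min_fragments = 10) {
  stopifnot(min_fragments >= 0)
  if (min_fragments == 0)
    return(list(store = store, removed = character(0)))
  ids <- live_ids(store)
  totals <- vapply(ids, function(id) shared_count(store, id), numeric(1L))
  removed <- ids[totals < min_fragments]
  if (!length(removed))
    return(list(store = store, removed = character(0)))
  drop <- new.env(parent = emptyenv())
  for (id in removed) assign(id, TRUE, envir = drop)
  keys <- lapply(store$keys, function(k) k[!vapply(k, exists, logical(1L), envir = drop)])
  keep <- lengths(keys) > 0L
  st <- eq_store(keys[keep], store$counts[keep, , drop = FALSE], store$samples)
  list(store = st, removed = removed)
}

#' Build equivalence classes from fragment records
#'
#' Collapses a stream of fragment-to-contig-set records into the store: one
#' class per distinct contig set, with per-sample counts of the fragments
#' mapping to exactly that set.
#'
#' @param fragments a `data.frame`/`data.table` with columns `fragment`
#'   (fragment ID), `sample` (sample ID) and `contigs` (list column of
#'   character vectors), e.g. from [parse_alignments()].
#' @param design an [experiment_design()]; every `sample` value must appear in
#'   it.
#' @return an `eq_store` whose counts sum to the number of fragments.
#' @export
build_eqclasses <- function(fragments, design) {
  stopifnot(inherits(design, "experiment_design"))
  fragments <- data.table::as.data.table(fragments)
  if (nrow(fragments) == 0L)
    return(eq_store(list(), matrix(numeric(0), 0, length(design$samples)),
                    design$samples))
  bad <- setdiff(unique(fragments$sample), design$samples)
  if (length(bad)) stop("fragment references unknown sample: ",
                        paste(bad, collapse = ", "))
  contigs <- NULL; sample <- NULL  # NSE notes
  fragments[, key := vapply(contigs, key_of, character(1L))]
  agg <- fragments[, .N, by = .(key, sample)]
  ks <- sort(unique(agg$key))
  counts <- matrix(0, length(ks), length(design$samples),
                   dimnames = list(NULL, design$samples))
  counts[cbind(match(agg$key, ks), match(agg$sample, design$samples))] <- agg$N
  eq_store(lapply(ks, ids_of), counts, design$samples)
}

#' Group contigs into super-clusters
#'
#' A super-cluster is a connected component of the graph whose vertices are
#' the live contigs and whose edges join any two contigs co-occurring in at
#' least one equivalence class (i.e. sharing at least one fragment).
#' Clustering later runs independently within each component; contigs in
#' different components can never share reads and so are never co-clustered.
#'
#' @param store an `eq_store` (typically after [filter_low_coverage()]).
#' @return list of character vectors (sorted members), ordered by their
#'   smallest member; singletons included.
#' @export
build_superclusters <- function(store) {
  ids <- live_ids(store)
  if (!length(ids)) return(list())
  edges <- character(0)
  for (k in store$keys) {
    if (length(k) >= 2L) {
      # star around the first member is enough for connectivity
      edges <- c(edges, rbind(k[1L], k[-1L]))
    }
  }
  edges <- as.character(edges)
  g <- igraph::make_graph(edges = edges, isolates = setdiff(ids, edges),
                          directed = FALSE)
  comp <- igraph::components(g)
  parts <- split(ids, comp$membership[ids])
  parts <- lapply(parts, function(p) csort(unname(p)))
  unname(parts[corder(vapply(parts, `[`, character(1L), 1L))])
}

# restrict a store to the classes fully contained in a member set
restrict_store <- function(store, members) {
  rows <- sort(unique(unlist(lapply(members, function(id) store$index[[id]]),
                             use.names = FALSE)))
  eq_store(store$keys[rows], store$counts[rows, , drop = FALSE], store$samples)
}
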