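#' Clustering parameters
#'
#' @param d_threshold distance threshold(s) in (0, 1]; merging stops once the
#'   smallest pairwise distance strictly exceeds this.  The default 0.3 works
#'   well in practice, and results are robust over roughly 0.1--0.9 because
#'   most pairwise distances sit near 0 or 1.
#' @param test_enabled run the expression-ratio test (default TRUE).  Turn
#'   off to co-cluster differentially spliced isoforms.
#' @param D_threshold explicit threshold on the LRT statistic; overrides
#'   `p_value` when non-NULL.
#' @param p_value P-value for the ratio test (default 1e-5); converted to a
#'   D threshold via [d_threshold()].
#' @param min_fragments retention threshold for [filter_low_coverage()].
#' @param seed seed for the random assignment of ambiguous fragments.
#' @return list of class `cclust_params`.
#' @export
cclust_params <- function(d_threshold = 0.3, test_enabled = TRUE,
                          D_threshold = NULL, p_value = 1e-5,
                          min_fragments = 10, seed = 42L) {
  stopifnot(all(d_threshold > 0), all(d_threshold <= 1))
  structure(list(d_threshold = d_threshold, test_enabled = test_enabled,
                 D_threshold = D_threshold, p_value = p_value,
                 min_fragments = min_fragments, seed = as.integer(seed)),
            class = "cclust_params")
}

resolve_D_threshold <- function(params, n_conditions) {
  if (!is.null(params$D_threshold)) return(params$D_threshold)
  d_threshold(n_conditions, params$p_value)
}

#' Shared-read distance between two clusters
#'
#' `1 - R_ab / min(R_a, R_b)`: zero for a pair of redundant contigs whose
#' read sets nest, one for pairs sharing nothing.  When the ratio test is
#' enabled and rejects a constant expression ratio for the pair, the distance
#' is forced to the maximum of 1, which is what keeps paralogues and chimeric
#' contigs apart despite heavy read sharing.
#'
#' @param store an `eq_store`.
#' @param a,b distinct live cluster IDs.
#' @param design an [experiment_design()].
#' @param test_enabled whether the ratio test may override the distance.
#' @param D_thr rejection threshold on the LRT statistic.
#' @return distance in \[0, 1\].
#' @export
pair_distance <- function(store, a, b, design, test_enabled = TRUE,
                          D_thr = d_threshold(design$n_conditions)) {
  R_ab <- shared_count(store, c(a, b))
  if (R_ab == 0) return(1)
  if (test_enabled && design$n_conditions >= 2L) {
    res <- lrt_statistic(pair_counts_from_store(store, a, b, design),
                         threshold = D_thr)
    if (res$reject) return(1)
  }
  R_a <- shared_count(store, a)
  R_b <- shared_count(store, b)
  1 - R_ab / min(R_a, R_b)
}

# deterministic pair key: smaller ID first (C collation)
pair_key <- function(a, b) paste0(csort(c(a, b)), collapse = "\r")

#' Cluster the contigs of one super-cluster
#'
#' Agglomerative hierarchical clustering with the shared-read distance and a
#' linkage that lives outside the distance matrix: merging clusters a and b
#' re-labels them in the equivalence-class store, so that updated counts obey
#' `R_a' = R_a + R_b - R_ab` and `R_a'c = R_ac + R_bc - R_abc` exactly.  At
#' every step the globally smallest stored distance is found (ties broken by
#' the lexicographically first pair); if it exceeds `d_threshold`, or no
#' mergeable pair remains, clustering stops.  Pairs at distance 1 (no shared
#' reads, or ratio-test rejection) are never merged regardless of threshold.
#' Distances involving a freshly merged cluster are recomputed, including a
#' re-run of the ratio test on the merged counts -- so a pair forced apart
#' early can still end up co-clustered through an intermediate contig if the
#' merged counts no longer reject.
#'
#' @param members character vector, the super-cluster's contig IDs.
#' @param store an `eq_store` restricted to (or at least covering) those
#'   contigs.
#' @param design an [experiment_design()].
#' @param params a [cclust_params()] (single `d_threshold`).
#' @return list of character vectors: the partition of `members`, each block
#'   sorted, blocks ordered by smallest member.
#' @export
cluster_supercluster <- function(members, store, design, params = cclust_params()) {
  stopifnot(length(params$d_threshold) == 1L)
  sub <- restrict_store(store, members)
  D_thr <- resolve_D_threshold(params, design$n_conditions)
  groups <- as.list(stats::setNames(members, members))  # cluster id -> contigs
  next_id <- 1L
  # pairs with R_ab > 0: co-occurrence within classes
  dist <- new.env(parent = emptyenv(), hash = TRUE)
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  for (k in sub$keys) {
    if (length(k) < 2L) next
    for (i in seq_len(length(k) - 1L))
      for (j in seq((i + 1L), length(k)))
        assign(pair_key(k[[i]], k[[j]]), TRUE, envir = seen)
  }
  for (pk in ls(seen, sorted = FALSE)) {
    ab <- strsplit(pk, "\r", fixed = TRUE)[[1L]]
    assign(pk, pair_distance(sub, ab[[1L]], ab[[2L]], design,
                             params$test_enabled, D_thr), envir = dist)
  }
  repeat {
    pks <- ls(dist, sorted = FALSE)
    if (!length(pks)) break
    vals <- vapply(pks, function(p) dist[[p]], numeric(1L))
    mergeable <- vals < 1
    if (!any(mergeable)) break
    dmin <- min(vals[mergeable])
    if (dmin > params$d_threshold) break
    cand <- csort(pks[mergeable & vals == dmin])  # lexicographic tie-break
    ab <- strsplit(cand[[1L]], "\r", fixed = TRUE)[[1L]]
    a <- ab[[1L]]; b <- ab[[2L]]
    new_id <- paste0("\x01m", next_id); next_id <- next_id + 1L
    sub <- merge_clusters(sub, a, b, new_id)
    groups[[new_id]] <- csort(c(groups[[a]], groups[[b]]))
    groups[[a]] <- NULL; groups[[b]] <- NULL
    # drop stale pairs, recompute against the merged cluster
    for (pk in pks) {
      ab2 <- strsplit(pk, "\r", fixed = TRUE)[[1L]]
      if (a %in% ab2 || b %in% ab2) rm(list = pk, envir = dist)
    }
    for (other in setdiff(names(groups), new_id)) {
      if (shared_count(sub, c(new_id, other)) > 0)
        assign(pair_key(new_id, other),
               pair_distance(sub, new_id, other, design,
                             params$test_enabled, D_thr),
               envir = dist)
    }
  }
  part <- unname(groups)
  part[corder(vapply(part, `[`, character(1L), 1L))]
}

#' Cluster every super-cluster of a store
#'
#' Forms the super-clusters (connected components of the read-sharing graph)
#' and clusters each independently; contigs in different super-clusters are
#' never co-clustered.
#'
#' @param store a filtered `eq_store`.
#' @param design an [experiment_design()].
#' @param params a [cclust_params()] (single `d_threshold`).
#' @return named list of character vectors: cluster name ->
#'   sorted contig IDs.  Names follow
#'   `Cluster-<supercluster index>.<cluster index>` with both indices
#'   assigned in deterministic sorted order.
#' @export
run_all <- function(store, design, params = cclust_params()) {
  scs <- build_superclusters(store)
  out <- list()
  for (s in seq_along(scs)) {
    part <- cluster_supercluster(scs[[s]], store, design, params)
    for (k in seq_along(part))
      out[[sprintf("Cluster-%d.%d", s, k)]] <- part[[k]]
  }
  out
}
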