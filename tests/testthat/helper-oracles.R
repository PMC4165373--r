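# Independent oracles used by the test suite.  These deliberately avoid the
# package's own data structures and code paths: plain lists of classes,
# intersection-based counting, numeric likelihood maximisation, union-find,
# pair enumeration.

# ---- plain class representation: list of list(ids = chr, counts = numeric per sample)

# fragments mapping to at least one contig of every set in `sets`
oracle_count <- function(classes, ..., per_sample = FALSE) {
  sets <- list(...)
  tot <- NULL
  for (cl in classes) {
    if (all(vapply(sets, function(s) length(intersect(cl$ids, s)) > 0, logical(1)))) {
      tot <- if (is.null(tot)) cl$counts else tot + cl$counts
    }
  }
  if (is.null(tot)) tot <- numeric(length(classes[[1]]$counts))
  if (per_sample) tot else sum(tot)
}

classes_to_store <- function(classes, samples) {
  eq_store(lapply(classes, `[[`, "ids"),
           do.call(rbind, lapply(classes, `[[`, "counts")),
           samples)
}

random_classes <- function(n_contigs, n_classes, n_samples, max_count = 20) {
  ids <- paste0("c", seq_len(n_contigs))
  lapply(seq_len(n_classes), function(i) {
    k <- sample(seq_len(min(3, n_contigs)), 1)
    list(ids = sample(ids, k),
         counts = as.numeric(sample.int(max_count, n_samples, replace = TRUE)))
  })
}

# ---- numeric maximisation of the two Poisson likelihoods (LRT oracle)

pois_ll <- function(x, mu) sum(x * log(mu) - mu)

oracle_lrt_D <- function(X_a, X_b) {
  n <- length(X_a)
  # H1: per condition, maximise over (log mu_a, log mu_b)
  ll1 <- 0
  for (i in seq_len(n)) {
    fit <- stats::nlminb(c(log(X_a[i]), log(X_b[i]) + 0.1),
                         function(p) -(X_a[i] * p[1] - exp(p[1]) +
                                       X_b[i] * p[2] - exp(p[2])),
                         control = list(rel.tol = 1e-14, iter.max = 500))
    ll1 <- ll1 - fit$objective
  }
  # H0: maximise over (log f, log mu_b[1..n])
  negll0 <- function(p) {
    f <- exp(p[1]); mu_b <- exp(p[-1])
    -(pois_ll(X_a, f * mu_b) + pois_ll(X_b, mu_b))
  }
  fit0 <- stats::nlminb(c(0.1, log((X_a + X_b) / 2)), negll0,
                        control = list(rel.tol = 1e-14, iter.max = 1000))
  ll0 <- -fit0$objective
  -2 * (ll0 - ll1)
}

# ---- union-find super-cluster oracle

oracle_components <- function(classes) {
  ids <- sort(unique(unlist(lapply(classes, `[[`, "ids"))), method = "radix")
  parent <- stats::setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (cl in classes) {
    k <- cl$ids
    for (j in seq_along(k)[-1]) parent[[find(k[[j]])]] <- find(k[[1]])
  }
  root <- vapply(ids, find, character(1))
  parts <- split(ids, root)
  parts <- lapply(parts, function(p) sort(unname(p), method = "radix"))
  unname(parts[order(vapply(parts, `[`, character(1), 1), method = "radix")])
}

# ---- naive agglomerative clustering oracle: full distance-matrix recompute
# every iteration, counting by class intersection (no linkage equations, no
# caching).  Mirrors the documented tie-break and stopping rules.

oracle_cluster <- function(classes, members, group_of_sample, d_thr,
                           test_enabled, D_thr) {
  groups <- as.list(stats::setNames(members, members))
  nxt <- 1L
  conds <- sort(unique(group_of_sample), method = "radix")
  dist_of <- function(A, B) {
    R_ab <- oracle_count(classes, A, B)
    if (R_ab == 0) return(1)
    if (test_enabled && length(conds) >= 2) {
      r_a <- oracle_count(classes, A, per_sample = TRUE)
      r_b <- oracle_count(classes, B, per_sample = TRUE)
      r_ab <- oracle_count(classes, A, B, per_sample = TRUE)
      X_a <- X_b <- numeric(length(conds))
      for (ci in seq_along(conds)) {
        j <- group_of_sample == conds[ci]
        X_a[ci] <- 1 + sum((r_a - r_ab)[j] + 0.5 * r_ab[j])
        X_b[ci] <- 1 + sum((r_b - r_ab)[j] + 0.5 * r_ab[j])
      }
      f <- sum(X_a) / sum(X_b)
      E_b <- (X_a + X_b) / (1 + f); E_a <- f * E_b
      D <- 2 * sum(X_a * log(X_a / E_a) + X_b * log(X_b / E_b))
      if (D > D_thr) return(1)
    }
    1 - R_ab / min(oracle_count(classes, A), oracle_count(classes, B))
  }
  repeat {
    ids <- names(groups)
    if (length(ids) < 2) break
    best <- NULL
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq((i + 1), length(ids))) {
        pr <- sort(c(ids[[i]], ids[[j]]), method = "radix")
        d <- dist_of(groups[[pr[1]]], groups[[pr[2]]])
        if (d >= 1) next
        if (is.null(best) || d < best$d ||
            (d == best$d && (pr[1] < best$pr[1] ||
                             (pr[1] == best$pr[1] && pr[2] < best$pr[2]))))
          best <- list(d = d, pr = pr)
      }
    }
    if (is.null(best) || best$d > d_thr) break
    new_id <- paste0("\x01m", nxt); nxt <- nxt + 1L
    groups[[new_id]] <- sort(c(groups[[best$pr[1]]], groups[[best$pr[2]]]),
                             method = "radix")
    groups[[best$pr[1]]] <- NULL; groups[[best$pr[2]]] <- NULL
  }
  part <- unname(groups)
  part[order(vapply(part, `[`, character(1), 1), method = "radix")]
}

canonical_partition <- function(part) {
  part <- lapply(part, function(p) sort(unname(p), method = "radix"))
  unname(part[order(vapply(part, `[`, character(1), 1), method = "radix")])
}

# ---- brute-force pairwise precision/recall by pair enumeration

oracle_pair_metrics <- function(cluster_of, gene_of) {
  ctg <- intersect(names(cluster_of), names(gene_of))
  ctg <- ctg[!gene_of[ctg] %in% c(contigclust::CHIMERIC, contigclust::UNKNOWN)]
  TP <- FP <- FN <- TN <- 0
  pairs <- utils::combn(ctg, 2)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    sg <- gene_of[[a]] == gene_of[[b]]
    sc <- cluster_of[[a]] == cluster_of[[b]]
    if (sg && sc) TP <- TP + 1
    else if (!sg && sc) FP <- FP + 1
    else if (sg && !sc) FN <- FN + 1
    else TN <- TN + 1
  }
  list(TP = TP, FP = FP, FN = FN, TN = TN)
}
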