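#' Sentinel labels for contigs without a usable gene assignment
#' @export
CHIMERIC <- "__CHIMERIC__"
#' @rdname CHIMERIC
#' @export
UNKNOWN <- "__UNKNOWN__"

#' Label contigs with truth genes from annotation alignments
#'
#' Consumes a generic table of contig-versus-annotation alignment hits (one
#' row per hit) and applies the labelling rules: hits shorter than
#' `min_length` bases or below `min_identity` are dropped; a contig whose
#' surviving hits cover two or more distinct genes with any gene pair
#' overlapping fewer than `max_gene_overlap` bases on the contig is labelled
#' chimeric (treated as unknown origin downstream); otherwise the contig is
#' assigned to the gene with the longest alignment; contigs with no
#' surviving hit are labelled unknown.
#'
#' @param hits data.frame with columns `contig`, `gene`, `length` (aligned
#'   bases), `identity` (fraction in \[0,1\]), `start`, `end` (gene footprint
#'   on the contig, 0-based half-open).
#' @param min_length minimum alignment length in bases (default 200).
#' @param min_identity minimum alignment identity (default 0.98).
#' @param max_gene_overlap overlap below which two genes on one contig imply
#'   a chimera (default 100 bases).
#' @return named character vector contig -> gene ID or the [CHIMERIC] /
#'   [UNKNOWN] sentinel.
#' @export
label_contigs <- function(hits, min_length = 200, min_identity = 0.98,
                          max_gene_overlap = 100) {
  hits <- as.data.frame(hits)
  need <- c("contig", "gene", "length", "identity", "start", "end")
  if (!all(need %in% names(hits)))
    stop("hits table needs columns: ", paste(need, collapse = ", "))
  if (any(hits$start >= hits$end)) stop("malformed interval: start >= end")
  if (any(hits$identity < 0 | hits$identity > 1))
    stop("identity must be a fraction in [0, 1]")
  labels <- character(0)
  surv <- hits[hits$length >= min_length & hits$identity >= min_identity, , drop = FALSE]
  for (ctg in csort(unique(hits$contig))) {
    h <- surv[surv$contig == ctg, , drop = FALSE]
    if (nrow(h) == 0L) { labels[[ctg]] <- UNKNOWN; next }
    genes <- csort(unique(h$gene))
    if (length(genes) >= 2L) {
      # per gene, footprint = widest surviving hit span on the contig
      span <- lapply(genes, function(g) {
        hg <- h[h$gene == g, , drop = FALSE]
        c(min(hg$start), max(hg$end))
      })
      chimeric <- FALSE
      for (i in seq_len(length(genes) - 1L)) {
        for (j in seq((i + 1L), length(genes))) {
          ov <- min(span[[i]][2L], span[[j]][2L]) - max(span[[i]][1L], span[[j]][1L])
          if (ov < max_gene_overlap) chimeric <- TRUE
        }
      }
      if (chimeric) { labels[[ctg]] <- CHIMERIC; next }
    }
    labels[[ctg]] <- h$gene[[which.max(h$length)]]
  }
  labels
}

#' Label clusters by majority vote of their contigs
#'
#' @param partition named list cluster name -> contig IDs.
#' @param labels named character vector contig -> gene or sentinel, e.g. from
#'   [label_contigs()].
#' @return named character vector cluster -> gene; ties broken by the
#'   lexicographically first gene; clusters with no labelled (non-sentinel)
#'   contig map to [UNKNOWN].
#' @export
label_clusters <- function(partition, labels) {
  out <- character(0)
  for (nm in names(partition)) {
    g <- labels[intersect(partition[[nm]], names(labels))]
    g <- g[!g %in% c(CHIMERIC, UNKNOWN) & !is.na(g)]
    if (!length(g)) { out[[nm]] <- UNKNOWN; next }
    tab <- table(g)
    best <- csort(names(tab)[tab == max(tab)])
    out[[nm]] <- best[[1L]]
  }
  out
}

#' Pairwise precision and recall of a clustering
#'
#' Scores a predicted partition against gene-level truth labels over all
#' unordered pairs of labelled contigs (sentinel-labelled contigs are
#' excluded): a pair is a true positive when both contigs share a gene and a
#' cluster, a false positive when clustered together despite different
#' genes, a false negative when separated despite a shared gene, and a true
#' negative otherwise.  Precision = TP/(TP+FP), recall = TP/(TP+FN); a zero
#' denominator yields NaN.
#'
#' @param partition named list cluster name -> contig IDs.
#' @param labels named character vector contig -> gene or sentinel.  Only
#'   contigs present in both the partition and the labels, with non-sentinel
#'   labels, enter the pair enumeration.
#' @return list with `precision`, `recall`, `TP`, `FP`, `FN`, `TN`,
#'   `n_labeled`.
#' @export
pairwise_precision_recall <- function(partition, labels) {
  cl_of <- character(0)
  for (nm in names(partition)) cl_of[partition[[nm]]] <- nm
  ctg <- intersect(names(cl_of), names(labels))
  ctg <- ctg[!labels[ctg] %in% c(CHIMERIC, UNKNOWN)]
  n <- length(ctg)
  if (n < 2L) stop("need at least two labelled contigs")
  # pair counts via the gene x cluster contingency table
  tab <- table(gene = labels[ctg], cluster = cl_of[ctg])
  ch2 <- function(x) sum(x * (x - 1) / 2)
  TP <- ch2(tab)
  same_cluster <- ch2(colSums(tab))
  same_gene <- ch2(rowSums(tab))
  FP <- same_cluster - TP
  FN <- same_gene - TP
  TN <- n * (n - 1) / 2 - TP - FP - FN
  list(precision = TP / (TP + FP), recall = TP / (TP + FN),
       TP = TP, FP = FP, FN = FN, TN = TN, n_labeled = n)
}
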