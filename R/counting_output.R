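#' Uniquely assign fragments to final clusters
#'
#' Every equivalence class maps to the set of final clusters its contigs
#' belong to.  Classes touching a single cluster contribute all their counts
#' there; for classes spanning `k > 1` clusters each fragment is assigned
#' uniformly at random to one of the k (seeded, so reruns are reproducible).
#' Each fragment is counted exactly once, so per-sample column sums equal the
#' number of retained fragments of that sample.
#'
#' @param store the filtered `eq_store` (original contig IDs).
#' @param partition named list cluster name -> contig IDs, e.g. from
#'   [run_all()]; must cover every live contig of `store`.
#' @param seed integer seed for the ambiguous assignments.
#' @return list of class `cluster_result` with `contig_to_cluster` (named
#'   character vector), `counts` (integer matrix cluster x sample),
#'   `ambiguous_fraction` (fraction of fragments whose class spans more than
#'   one cluster) and `seed`.
#' @export
assign_fragments <- function(store, partition, seed = 42L) {
  cl_of <- character(0)
  for (nm in names(partition))
    cl_of[partition[[nm]]] <- nm
  missing <- setdiff(live_ids(store), names(cl_of))
  if (length(missing))
    stop("contigs missing from partition: ", paste(missing, collapse = ", "))
  cl_names <- csort(names(partition))
  counts <- matrix(0L, length(cl_names), length(store$samples),
                   dimnames = list(cl_names, store$samples))
  # preserve then restore caller RNG state; seed only our draws
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  n_amb <- 0
  for (i in seq_along(store$keys)) {       # keys are in sorted order: deterministic
    clusters <- csort(unique(cl_of[store$keys[[i]]]))
    if (length(clusters) == 1L) {
      counts[clusters, ] <- counts[clusters, ] + as.integer(store$counts[i, ])
    } else {
      n_amb <- n_amb + sum(store$counts[i, ])
      for (j in seq_along(store$samples)) {
        n <- as.integer(store$counts[i, j])
        if (n > 0) {
          draw <- stats::rmultinom(1L, n, rep(1 / length(clusters), length(clusters)))[, 1L]
          counts[clusters, j] <- counts[clusters, j] + as.integer(draw)
        }
      }
    }
  }
  tot <- total_fragments(store)
  structure(list(contig_to_cluster = cl_of[csort(names(cl_of))],
                 counts = counts,
                 ambiguous_fraction = if (tot > 0) n_amb / tot else 0,
                 seed = as.integer(seed)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d contigs in %d clusters, %d samples; %.2f%% ambiguous fragments\n",
              length(x$contig_to_cluster), nrow(x$counts), ncol(x$counts),
              100 * x$ambiguous_fraction))
  invisible(x)
}

#' Write the clusters and counts files
#'
#' `<prefix>-clusters.txt`: tab-separated contig ID, cluster name, sorted by
#' contig.  `<prefix>-counts.txt`: header `Cluster` plus sample IDs, one row
#' per cluster sorted by name.  Both plain UTF-8, LF endings, no quoting --
#' the counts file drops straight into edgeR/DESeq2 as a count matrix.
#'
#' @param result a `cluster_result`.
#' @param prefix path prefix for the two files.
#' @return character vector of the two paths, invisibly.
#' @export
write_outputs <- function(result, prefix) {
  stopifnot(inherits(result, "cluster_result"))
  f_clusters <- paste0(prefix, "-clusters.txt")
  f_counts <- paste0(prefix, "-counts.txt")
  con <- file(f_clusters, open = "wb")
  ctg <- csort(names(result$contig_to_cluster))
  writeLines(sprintf("%s\t%s", ctg, result$contig_to_cluster[ctg]), con, sep = "\n")
  close(con)
  con <- file(f_counts, open = "wb")
  writeLines(paste(c("Cluster", colnames(result$counts)), collapse = "\t"),
             con, sep = "\n")
  rn <- csort(rownames(result$counts))
  for (r in rn)
    writeLines(paste(c(r, format(result$counts[r, ], scientific = FALSE, trim = TRUE)),
                     collapse = "\t"), con, sep = "\n")
  close(con)
  invisible(c(f_clusters, f_counts))
}

#' Run the whole clustering-and-counting pipeline on a store
#'
#' Filter low-coverage contigs, form super-clusters, cluster each, and
#' uniquely assign fragments.  One result per `d_threshold` in `params`.
#'
#' @param store an unfiltered `eq_store`.
#' @param design an [experiment_design()].
#' @param params a [cclust_params()]; `d_threshold` may hold several values.
#' @param verbose log progress to stderr.
#' @return if `params$d_threshold` has one value, a `cluster_result`;
#'   otherwise a named list of them (names = thresholds).
#' @export
cluster_and_count <- function(store, design, params = cclust_params(),
                              verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("input: %d contigs, %g fragments, %d samples, %d conditions",
      length(live_ids(store)), total_fragments(store),
      length(design$samples), design$n_conditions)
  fl <- filter_low_coverage(store, params$min_fragments)
  say("filtered %d contigs below %g fragments; %d contigs, %g fragments retained",
      length(fl$removed), params$min_fragments,
      length(live_ids(fl$store)), total_fragments(fl$store))
  scs <- build_superclusters(fl$store)
  say("%d super-clusters (largest: %d contigs)",
      length(scs), if (length(scs)) max(lengths(scs)) else 0L)
  results <- list()
  for (d in params$d_threshold) {
    p1 <- params; p1$d_threshold <- d
    partition <- run_all(fl$store, design, p1)
    res <- assign_fragments(fl$store, partition, params$seed)
    say("d = %g: %d clusters; %.2f%% of fragments ambiguous",
        d, nrow(res$counts), 100 * res$ambiguous_fraction)
    results[[format(d)]] <- res
  }
  if (length(results) == 1L) results[[1L]] else results
}

#' Command-line interface
#'
#' `Rscript -e 'contigclust::cclust_cli()' aln1.bam aln2.bam -g A,B`
#'
#' Positional arguments are alignment files (or one equivalence-class table
#' with `-i eqclass`).  Per-file sample names (`-f`) default to one sample
#' per file; per-file group labels (`-g`) default to each sample being its
#' own condition group.
#'
#' @param argv character vector of command-line arguments; defaults to the
#'   actual command line.
#' @return integer exit status, invisibly (0 on success); also invisibly
#'   called for its side effect of writing `<prefix>-clusters.txt` /
#'   `<prefix>-counts.txt` per distance threshold.
#' @export
cclust_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  spec <- list(
    optparse::make_option(c("-g", "--groups"), type = "character", default = NULL,
      help = "comma-separated condition label per input file [default: one group per sample]"),
    optparse::make_option(c("-f", "--samples"), type = "character", default = NULL,
      help = "comma-separated sample name per input file [default: sample1,sample2,...]"),
    optparse::make_option(c("-m", "--min-fragments"), type = "double", default = 10,
      dest = "min_fragments",
      help = "discard contigs with fewer mapped fragments; 0 disables [default %default]"),
    optparse::make_option(c("-d", "--dist-thresholds"), type = "character", default = "0.3",
      dest = "dist", help = "comma-separated distance threshold(s) [default %default]"),
    optparse::make_option(c("-p", "--prefix"), type = "character", default = "clusters",
      help = "output file prefix [default %default]"),
    optparse::make_option(c("-D", "--D-threshold"), type = "double", default = NA,
      dest = "D_threshold", help = "explicit threshold on the LRT statistic D"),
    optparse::make_option("--pvalue", type = "double", default = 1e-5,
      help = "P-value threshold for the ratio test [default %default]"),
    optparse::make_option("--no-test", action = "store_true", default = FALSE,
      dest = "no_test", help = "disable the expression-ratio test"),
    optparse::make_option("--seed", type = "integer", default = 42L,
      help = "seed for random assignment of ambiguous fragments [default %default]"),
    optparse::make_option(c("-i", "--input-format"), type = "character", default = "auto",
      dest = "format", help = "bam|sam|eqclass|auto [default %default]"))
  parser <- optparse::OptionParser(
    usage = "%prog [options] alignment1.bam [alignment2.bam ...]",
    option_list = spec, prog = "contigclust")
  parsed <- tryCatch(
    optparse::parse_args(parser, args = argv, positional_arguments = c(1, Inf)),
    error = function(e) e)
  usage_error <- function(msg) {
    message("error: ", msg)
    optparse::print_help(parser)
    invisible(1L)
  }
  if (inherits(parsed, "error")) return(usage_error(conditionMessage(parsed)))
  opt <- parsed$options
  files <- parsed$args
  split1 <- function(x) if (is.null(x)) NULL else strsplit(x, ",", fixed = TRUE)[[1L]]
  samples <- split1(opt$samples)
  groups <- split1(opt$groups)
  dthr <- suppressWarnings(as.numeric(split1(opt$dist)))
  if (anyNA(dthr) || any(dthr <= 0) || any(dthr > 1))
    return(usage_error("-d thresholds must be numbers in (0, 1]"))
  fmt <- match.arg(opt$format, c("auto", "bam", "sam", "eqclass"))
  eqclass_in <- fmt == "eqclass" ||
    (fmt == "auto" && all(grepl("\\.(tsv|eqclass)$", files, ignore.case = TRUE)))
  if (!eqclass_in) {
    if (!is.null(samples) && length(samples) != length(files))
      return(usage_error("-f needs one sample name per input file"))
    if (!is.null(groups) && length(groups) != length(files))
      return(usage_error("-g needs one group label per input file"))
  } else if (length(files) != 1L) {
    return(usage_error("eqclass input expects exactly one table file"))
  }
  params <- cclust_params(
    d_threshold = dthr, test_enabled = !opt$no_test,
    D_threshold = if (is.na(opt$D_threshold)) NULL else opt$D_threshold,
    p_value = opt$pvalue, min_fragments = opt$min_fragments, seed = opt$seed)
  status <- tryCatch({
    if (eqclass_in) {
      # samples live in the table; -f/-g (per sample) may name and group them
      if (is.null(samples)) {
        tab <- read_eqclass_table(files[[1L]])
        samples <- sort(unique(tab$sample), method = "radix")
      }
      if (!is.null(groups) && length(groups) != length(samples))
        stop("-g needs one group label per sample for eqclass input")
      design <- experiment_design(character(0), samples = samples, groups = groups)
      store <- eqclass_store_from_table(files[[1L]], design)
    } else {
      design <- experiment_design(files, samples = samples, groups = groups)
      frags <- data.table::rbindlist(
        lapply(design$samples,
               function(s) parse_alignments(design$files[[s]], s)))
      store <- build_eqclasses(frags, design)
    }
    res <- cluster_and_count(store, design, params, verbose = TRUE)
    if (inherits(res, "cluster_result")) {
      write_outputs(res, opt$prefix)
    } else {
      for (d in names(res))
        write_outputs(res[[d]], paste0(opt$prefix, "-d", d))
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
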