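#' Experiment design: samples, files and condition groups
#'
#' @param files character vector of alignment file paths, or a list of
#'   character vectors (several files for one sample).
#' @param samples sample IDs, one per element of `files`; defaults to
#'   `sample1, sample2, ...` (one sample per file).  Repeating a sample ID is
#'   how several files are attached to one sample.
#' @param groups condition label per *sample*; defaults to each sample being
#'   its own condition, which makes the ratio test active on any multi-sample
#'   input.  May be given per file as long as files of one sample agree.
#' @return object of class `experiment_design` with fields `samples`
#'   (ordered, unique), `files` (named list per sample), `group` (named
#'   character vector per sample) and `n_conditions`.
#' @export
experiment_design <- function(files = character(0), samples = NULL, groups = NULL) {
  files <- as.list(files)
  nfile <- length(files)
  if (is.null(samples)) samples <- paste0("sample", seq_len(max(nfile, 0L)))
  samples <- as.character(samples)
  if (nfile > 0 && length(samples) != nfile)
    stop("need one sample ID per file")
  uniq <- unique(samples)
  if (is.null(groups)) {
    grp <- stats::setNames(uniq, uniq)
  } else {
    groups <- as.character(groups)
    if (length(groups) == length(samples) && nfile > 0) {
      # per-file labels: collapse to per-sample, demanding consistency
      g <- tapply(groups, factor(samples, levels = uniq), unique, simplify = FALSE)
      if (any(lengths(g) != 1L))
        stop("conflicting group labels within a sample")
      grp <- stats::setNames(as.character(unlist(g)), uniq)
    } else if (length(groups) == length(uniq)) {
      grp <- stats::setNames(groups, uniq)
    } else stop("groups must have one label per file or per sample")
  }
  fl <- if (nfile > 0) split(unlist(files), factor(samples, levels = uniq))
        else stats::setNames(rep(list(character(0)), length(uniq)), uniq)
  structure(list(samples = uniq, files = fl, group = grp,
                 n_conditions = length(unique(grp))),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("experiment_design: %d samples, %d conditions\n",
              length(x$samples), x$n_conditions))
  for (s in x$samples)
    cat(sprintf("  %s [%s]: %s\n", s, x$group[[s]],
                paste(x$files[[s]], collapse = ", ")))
  invisible(x)
}

# strip /1 /2 .1 .2 mate suffixes from read names
strip_mate_suffix <- function(qname) sub("[/.][12]$", "", qname)

#' Parse multi-mapped alignments into fragment records
#'
#' Reads one or more SAM/BAM files for a sample (unsorted, unindexed input is
#' fine) and emits one record per distinct fragment: the read name with mate
#' suffixes stripped, and the set of contig (reference) names hit by any of
#' its alignments.  For paired-end data both mates share one fragment ID, so
#' the contig set is the union over mates; the fragment -- a read pair, or a
#' single-end read -- is the counting unit throughout.  Unmapped records are
#' skipped.  Only QNAME, the unmapped flag bit and RNAME are consulted;
#' positions, CIGAR strings, mapping quality and secondary/supplementary
#' flags are ignored, as flag conventions vary between report-all aligners.
#'
#' @param files character vector of SAM (`.sam`) or BAM file paths.
#' @param sample_id sample these files belong to.
#' @return `data.table` with columns `fragment`, `sample` and list column
#'   `contigs` (character vector per fragment, sorted, unique).
#' @export
parse_alignments <- function(files, sample_id) {
  qn <- character(0); rn <- character(0)
  for (f in files) {
    if (!file.exists(f)) stop("alignment file not found: ", f)
    bam <- f
    if (grepl("\\.sam$", f, ignore.case = TRUE)) {
      bam <- tempfile(fileext = ".bam")
      on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
      Rsamtools::asBam(f, sub("\\.bam$", "", bam), indexDestination = FALSE,
                       overwrite = TRUE)
    }
    res <- Rsamtools::scanBam(
      bam, param = Rsamtools::ScanBamParam(what = c("qname", "flag", "rname")))[[1L]]
    mapped <- bitwAnd(res$flag, 4L) == 0L
    rname <- as.character(res$rname[mapped])
    if (anyNA(rname))
      stop("mapped alignment with no reference name in ", f)
    qn <- c(qn, strip_mate_suffix(res$qname[mapped]))
    rn <- c(rn, rname)
  }
  if (!length(qn))
    return(data.table::data.table(fragment = character(0),
                                  sample = character(0), contigs = list()))
  dt <- data.table::data.table(fragment = qn, contig = rn)
  fragment <- NULL; contig <- NULL  # NSE notes
  out <- dt[, .(contigs = list(csort(unique(contig)))), by = fragment]
  data.table::setorder(out, fragment)
  out[, sample := sample_id]
  out[, c("fragment", "sample", "contigs"), with = FALSE]
}

#' Read an equivalence-class table
#'
#' Plain-text dialect for storing equivalence classes: a header-less
#' tab-separated file with three columns -- comma-joined sorted contig IDs,
#' sample ID, positive integer fragment count.  Round-trips with
#' [write_eqclass_table()].
#'
#' @param path file to read.
#' @return `data.table` with columns `key` (character), `sample`, `count`.
#' @export
read_eqclass_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    # "key" is a reserved data.table() argument; rename after construction
    empty <- data.table::data.table(k = character(0), sample = character(0),
                                    count = numeric(0))
    data.table::setnames(empty, "k", "key")
    return(empty)
  }
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "character", "numeric"))
  if (ncol(dt) != 3L) stop("equivalence-class table needs 3 columns")
  data.table::setnames(dt, c("key", "sample", "count"))
  if (any(dt$key == "")) stop("empty contig set in equivalence-class table")
  if (any(!is.finite(dt$count) | dt$count <= 0 | dt$count != round(dt$count)))
    stop("counts must be positive integers")
  dt
}

#' Write an equivalence-class table
#'
#' Deterministic output: one row per (class, sample) with a positive count,
#' sorted by contig-set key then sample; UTF-8, LF line endings, no header.
#'
#' @param store an `eq_store`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_eqclass_table <- function(store, path) {
  rows <- list()
  for (i in seq_along(store$kstr)) {
    for (j in seq_along(store$samples)) {
      n <- store$counts[i, j]
      if (n > 0)
        rows[[length(rows) + 1L]] <- list(key = store$kstr[[i]],
                                          sample = store$samples[[j]],
                                          count = n)
    }
  }
  dt <- data.table::rbindlist(rows)
  if (nrow(dt)) data.table::setorder(dt, key, sample)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(dt))
    writeLines(sprintf("%s\t%s\t%d", dt$key, dt$sample, as.integer(dt$count)),
               con, sep = "\n")
  invisible(path)
}

#' Build an equivalence-class store from a table file
#'
#' @param path file in the [read_eqclass_table()] dialect.
#' @param design an [experiment_design()] listing at least the samples in the
#'   table.
#' @return an `eq_store`.
#' @export
eqclass_store_from_table <- function(path, design) {
  dt <- read_eqclass_table(path)
  bad <- setdiff(unique(dt$sample), design$samples)
  if (length(bad)) stop("table references unknown sample: ",
                        paste(bad, collapse = ", "))
  key <- NULL; count <- NULL  # NSE notes
  if (nrow(dt)) dt <- dt[, .(count = sum(count)), by = .(key, sample)]
  ks <- sort(unique(dt$key))
  counts <- matrix(0, length(ks), length(design$samples),
                   dimnames = list(NULL, design$samples))
  if (nrow(dt))
    counts[cbind(match(dt$key, ks), match(dt$sample, design$samples))] <- dt$count
  eq_store(lapply(ks, ids_of), counts, design$samples)
}
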