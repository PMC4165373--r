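#' Configuration for a synthetic assembly-and-mapping scenario
#'
#' Genes are modelled as abstract base-interval sequences (integer token
#' runs), not nucleotide strings: the clustering algorithm only ever consumes
#' read-to-contig incidence, so mapping is containment of a fragment's token
#' run within a contig's, with no aligner in the loop.  Contigs are derived
#' from genes through the artifact classes real assemblers produce:
#' redundant duplicates, fragmented (disjoint) pieces, chimeric
#' concatenations of two genes, and paralogue pairs sharing a block of
#' sequence.
#'
#' Defaults describe a desk-scale version of a typical two-group RNA-seq
#' comparison: 2 conditions x 3 replicates (6 samples), 100 expected
#' fragments per gene per sample (Poisson), genes of 1000 bases and a 200
#' base fragment span (100-bp paired-end reads with a short insert).
#'
#' @param n_genes number of genes.
#' @param gene_length gene length in bases.
#' @param isoforms_per_gene contigs per gene before artifacts (isoform k > 1
#'   is a random sub-interval of the gene).
#' @param redundant_rate probability a gene gains an identical duplicate
#'   contig.
#' @param fragmentation_rate probability a gene's full-length contig is
#'   replaced by two disjoint halves.
#' @param chimera_rate probability a gene (other than the last) gains an
#'   extra contig that concatenates its tail with the next gene's head.
#' @param n_paralogue_pairs number of leading gene pairs (1,2), (3,4), ...
#'   made paralogous.
#' @param paralogue_shared_frac fraction of the gene length shared between
#'   paralogues (identical leading block).  The default 0.75 reflects the
#'   highly homologous gene families that make clustering hard in practice;
#'   it also keeps the pair's shared-read distance below the default merge
#'   threshold of 0.3 when expression is balanced, so that any split of the
#'   pair is attributable to the expression-ratio test alone (with equal
#'   totals the distance is (1-s')/(1+s') for effective shared-start
#'   fraction s'; sharing 50% of the span gives ~0.45, which the distance
#'   rule alone already separates).
#' @param conditions,replicates experiment design (samples = conditions x
#'   replicates).
#' @param mean_fragments expected fragments per gene per sample: a scalar,
#'   or a `n_genes x conditions` matrix for differential expression.
#' @param dispersion negative-binomial dispersion; 0 means Poisson counts.
#' @param fragment_length fragment span in bases.
#' @param seed RNG seed; everything is reproducible per seed.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(n_genes = 6, gene_length = 1000,
                            isoforms_per_gene = 1, redundant_rate = 0.25,
                            fragmentation_rate = 0.25, chimera_rate = 0,
                            n_paralogue_pairs = 0, paralogue_shared_frac = 0.75,
                            conditions = 2, replicates = 3,
                            mean_fragments = 100, dispersion = 0,
                            fragment_length = 200, seed = 1L) {
  stopifnot(n_genes >= 1, gene_length >= fragment_length,
            redundant_rate >= 0, redundant_rate <= 1,
            fragmentation_rate >= 0, fragmentation_rate <= 1,
            chimera_rate >= 0, chimera_rate <= 1,
            paralogue_shared_frac >= 0, paralogue_shared_frac <= 1,
            2 * n_paralogue_pairs <= n_genes,
            conditions >= 1, replicates >= 1, dispersion >= 0,
            all(mean_fragments >= 0))
  if (is.matrix(mean_fragments)) {
    stopifnot(nrow(mean_fragments) == n_genes,
              ncol(mean_fragments) == conditions)
  } else {
    mean_fragments <- matrix(mean_fragments, n_genes, conditions)
  }
  structure(as.list(environment()), class = "scenario_config")
}

with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a synthetic scenario
#'
#' Draws per-gene per-sample fragment counts (Poisson, or negative binomial
#' when `dispersion > 0`), places each fragment uniformly within its gene,
#' and maps it to every contig that fully contains its token run -- which
#' yields realistic multi-mapping across duplicates, isoforms, chimeras and
#' paralogue shared blocks.  Fragments contained in no contig (e.g. ones
#' straddling a fragmentation breakpoint) are dropped, exactly as an aligner
#' would fail to place them.
#'
#' @param cfg a [scenario_config()].
#' @return list with `fragments` (data.table: `fragment`, `sample`, list
#'   column `contigs`), `truth` (named vector contig -> gene or [CHIMERIC]),
#'   `design` (an [experiment_design()] with no files), `contigs` (named
#'   list of token vectors), `gene_of_fragment` (named vector).
#' @export
generate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  with_seed(cfg$seed, {
    L <- as.integer(cfg$gene_length); flen <- as.integer(cfg$fragment_length)
    genes <- vector("list", cfg$n_genes)
    names(genes) <- sprintf("g%02d", seq_len(cfg$n_genes))
    tok <- 0L
    # all-token arithmetic stays integer: fragment-vs-contig matching uses
    # identical(), which is type-sensitive
    fresh <- function(n) { n <- as.integer(n); v <- tok + seq_len(n); tok <<- tok + n; v }
    for (i in seq_len(cfg$n_genes)) genes[[i]] <- fresh(L)
    if (cfg$n_paralogue_pairs > 0) {
      S <- as.integer(round(cfg$paralogue_shared_frac * L))
      for (p in seq_len(cfg$n_paralogue_pairs)) {
        a <- 2L * p - 1L; b <- 2L * p
        if (S > 0) genes[[b]][seq_len(S)] <- genes[[a]][seq_len(S)]
      }
    }
    contigs <- list(); truth <- character(0)
    add_contig <- function(name, tokens, gene) {
      contigs[[name]] <<- tokens
      truth[[name]] <<- gene
    }
    for (i in seq_len(cfg$n_genes)) {
      gn <- names(genes)[[i]]; gt <- genes[[i]]
      if (stats::runif(1) < cfg$fragmentation_rate) {
        s <- sample(seq(round(0.3 * L), round(0.7 * L)), 1L)
        add_contig(sprintf("%s_left", gn), gt[seq_len(s)], gn)
        add_contig(sprintf("%s_right", gn), gt[seq((s + 1L), L)], gn)
      } else {
        add_contig(sprintf("%s_full", gn), gt, gn)
        if (cfg$isoforms_per_gene > 1) {
          for (k in seq_len(cfg$isoforms_per_gene - 1L)) {
            len <- sample(seq(min(2L * flen, L), L), 1L)
            st <- sample(seq_len(L - len + 1L), 1L)
            add_contig(sprintf("%s_iso%d", gn, k), gt[seq(st, st + len - 1L)], gn)
          }
        }
        if (stats::runif(1) < cfg$redundant_rate)
          add_contig(sprintf("%s_dup", gn), gt, gn)
      }
      if (i < cfg$n_genes && stats::runif(1) < cfg$chimera_rate) {
        h <- round(0.4 * L)
        add_contig(sprintf("%s_chimera", gn),
                   c(gt[seq(L - h + 1L, L)], genes[[i + 1L]][seq_len(h)]),
                   CHIMERIC)
      }
    }
    # token index over contigs: token -> (contig, offset)
    idx_tok <- integer(0); idx_ctg <- character(0); idx_pos <- integer(0)
    for (nm in names(contigs)) {
      v <- contigs[[nm]]
      idx_tok <- c(idx_tok, v)
      idx_ctg <- c(idx_ctg, rep(nm, length(v)))
      idx_pos <- c(idx_pos, seq_along(v))
    }
    idx <- data.table::data.table(token = idx_tok, contig = idx_ctg, pos = idx_pos)
    data.table::setkey(idx, token)
    sample_ids <- sprintf("cond%d_rep%d",
                          rep(seq_len(cfg$conditions), each = cfg$replicates),
                          rep(seq_len(cfg$replicates), cfg$conditions))
    grp <- sprintf("cond%d", rep(seq_len(cfg$conditions), each = cfg$replicates))
    design <- experiment_design(character(0), samples = sample_ids, groups = grp)
    rows <- list(); gene_of <- character(0)
    for (si in seq_along(sample_ids)) {
      cond <- rep(seq_len(cfg$conditions), each = cfg$replicates)[[si]]
      for (i in seq_len(cfg$n_genes)) {
        mu <- cfg$mean_fragments[i, cond]
        n <- if (cfg$dispersion > 0)
          stats::rnbinom(1L, mu = mu, size = 1 / cfg$dispersion)
        else stats::rpois(1L, mu)
        if (n == 0) next
        starts <- sample.int(L - flen + 1L, n, replace = TRUE)
        for (k in seq_len(n)) {
          fr <- genes[[i]][seq(starts[[k]], starts[[k]] + flen - 1L)]
          cand <- idx[list(fr[[1L]]), nomatch = NULL]
          hit <- character(0)
          if (nrow(cand)) {
            for (r in seq_len(nrow(cand))) {
              ct <- contigs[[cand$contig[[r]]]]
              p <- cand$pos[[r]]
              if (p + flen - 1L <= length(ct) &&
                  identical(ct[seq(p, p + flen - 1L)], fr))
                hit <- c(hit, cand$contig[[r]])
            }
          }
          hit <- csort(unique(hit))
          if (!length(hit)) next
          fid <- sprintf("f_%s_%s_%05d", sample_ids[[si]], names(genes)[[i]], k)
          rows[[length(rows) + 1L]] <-
            list(fragment = fid, sample = sample_ids[[si]], contigs = list(hit))
          gene_of[[fid]] <- names(genes)[[i]]
        }
      }
    }
    fragments <- if (length(rows)) data.table::rbindlist(rows)
      else data.table::data.table(fragment = character(0),
                                  sample = character(0), contigs = list())
    list(fragments = fragments, truth = truth, design = design,
         contigs = contigs, gene_of_fragment = gene_of)
  })
}

#' Write fragment records as a minimal SAM file
#'
#' One single-end alignment record per (fragment, contig) incidence, with an
#' `@SQ` header line per contig.  Positions and CIGAR are placeholders (the
#' pipeline only reads QNAME, the unmapped bit and RNAME).  Round-trips
#' through [parse_alignments()] to the identical fragment records.
#'
#' @param fragments data.table with `fragment`, `sample`, `contigs` columns
#'   (typically one sample's rows).
#' @param contigs named list of contig token vectors (names + lengths used
#'   for the header).
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
emit_sam <- function(fragments, contigs, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con, sep = "\n")
  for (nm in names(contigs))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, length(contigs[[nm]])),
               con, sep = "\n")
  if (nrow(fragments)) {
    for (r in seq_len(nrow(fragments))) {
      for (ctg in fragments$contigs[[r]]) {
        writeLines(sprintf("%s\t0\t%s\t1\t0\t1M\t*\t0\t0\t*\t*",
                           fragments$fragment[[r]], ctg), con, sep = "\n")
      }
    }
  }
  invisible(path)
}

#' Write a whole scenario to disk as per-sample SAM files plus truth labels
#'
#' @param scenario result of [generate_scenario()].
#' @param dir output directory (created if needed).
#' @return the scenario's `experiment_design` with `files` pointing at the
#'   SAM files written under `dir`; a `truth.tsv` (contig, gene) is written
#'   alongside.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  design <- scenario$design
  for (s in design$samples) {
    f <- file.path(dir, paste0(s, ".sam"))
    emit_sam(scenario$fragments[scenario$fragments$sample == s, ],
             scenario$contigs, f)
    design$files[[s]] <- f
  }
  con <- file(file.path(dir, "truth.tsv"), open = "wb")
  writeLines(sprintf("%s\t%s", names(scenario$truth), scenario$truth),
             con, sep = "\n")
  close(con)
  design
}
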