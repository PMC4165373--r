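---
title: "Clustering de novo assembled contigs into genes: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering de novo assembled contigs into genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contigclust)
```

## The model

A *de novo* transcriptome assembly yields many contigs per gene. When the
reads are mapped back to the contigs with all alignments reported,
multi-mapping acts as a proxy for sequence similarity: two contigs
representing the same transcript attract the same reads. `contigclust`
exploits this in two steps.

**Counting model.** The unit of counting is the *fragment* — a read pair,
or one single-end read. Each fragment is reduced to the set of contigs it
maps to (union over mates); fragments with identical sets are aggregated
into equivalence classes with one count per sample. Every read-sharing
statistic is a sum over classes: $R_a$ (fragments touching contig $a$),
$R_{ab}$ (touching both $a$ and $b$), $R_{abc}$, and the per-replicate
$r_{aij}$. Keeping the classes — rather than pair tables — means that when
two clusters merge, relabelling keys and summing duplicates reproduces the
inclusion–exclusion linkage identities

$$R_{a'} = R_a + R_b - R_{ab}, \qquad R_{a'c} = R_{ac} + R_{bc} - R_{abc}$$

*exactly*, with integer arithmetic; the test suite asserts this on a
thousand random stores.

**Clustering.** Contigs sharing at least one fragment are connected; the
connected components (super-clusters) are clustered independently by
agglomerative merging under the distance
$d(a,b) = 1 - R_{ab} / \min(R_a, R_b)$, which is $0$ for nested
(redundant) read sets and $1$ for disjoint ones. Merging proceeds from the
globally smallest distance and stops when it strictly exceeds the distance
threshold; pairs at distance exactly 1 are never merged, whatever the
threshold.

**The expression-ratio test.** Read sharing cannot separate paralogues or
false chimeras from genuine redundancy — but expression can, when the
experiment has condition groups. For a candidate pair, per-condition
pseudo-counts are formed as

$$X_{ai} = 1 + \sum_j \left( r_{aij} + 0.5\, r_{abij} \right)$$

where $r_{aij}$ counts fragments unique to $a$ (replicate $j$, condition
$i$) and the shared fragments $r_{abij}$ contribute one half to each side,
avoiding double counting; the offset of one keeps all $X > 0$. The counts
are modelled as $X_{ai} \sim \mathrm{Pois}(f_i \mu_{bi})$,
$X_{bi} \sim \mathrm{Pois}(\mu_{bi})$, and $H_0\!: f_i = f$ is tested
against a free $f_i$ per condition with the likelihood-ratio statistic
$D = -2(\ln l_0 - \ln l_1)$, asymptotically $\chi^2$ on
$n_\mathrm{conditions} - 1$ degrees of freedom. Rejection forces the
pair's distance to 1.

Both likelihood maxima have closed forms: under $H_1$ the fitted means are
the observations; under $H_0$, with $\hat f = \sum_i X_{ai} / \sum_i
X_{bi}$ and $T_i = X_{ai} + X_{bi}$, the fitted means are $E_{bi} =
T_i/(1+\hat f)$ and $E_{ai} = \hat f E_{bi}$, giving

$$D = 2 \sum_i \left[ X_{ai} \ln \frac{X_{ai}}{E_{ai}} +
X_{bi} \ln \frac{X_{bi}}{E_{bi}} \right].$$

These forms are derived, not quoted; because a derivation can be wrong, the
suite gates them against brute-force numeric maximisation of both Poisson
likelihoods (`nlminb` over $(\log f, \log \mu_{bi})$), requiring agreement
to $10^{-6}$ on over a hundred random instances. The statistic is symmetric
in $(a, b)$ and is evaluated with the real-valued Poisson log-likelihood
$x\ln\mu - \mu$ (the $x$-only terms cancel in $D$), since the $X$ are
non-integer by construction.

**Unique assignment.** After clustering, every class maps to the clusters
its contigs landed in; classes touching one cluster contribute all counts
there, and fragments of classes spanning several clusters are assigned
uniformly at random with a user-visible seed. Per-sample column sums
therefore equal the retained fragment counts exactly, under any seed.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_fragments` (`-m`) | 10 | fragments per contig | removes noise contigs and shrinks the cluster list; 0 disables |
| `d_threshold` (`-d`) | 0.3 | distance in [0, 1] | stopping rule; results are robust over ~0.1–0.9 because pairwise distances concentrate near 0 and 1 |
| `p_value` | 1e-5 | tail probability | ratio-test threshold, small because every contig pair in a transcriptome is a potential test |
| `D_threshold` (`-D`) | `15 + 2.5 n_cond` | LRT statistic | cheap linear stand-in for the $\chi^2$ upper quantile at 1e-5, adequate for $2 \le n_\mathrm{cond} < 10$ (within 10% of the exact quantile); otherwise the exact quantile is used |
| `seed` | 42 | — | ambiguous-fragment assignment; fixed for reproducible pipelines |

Two boundary choices are deliberate. *Filter boundary*: "fewer than 10
fragments removed", i.e. a contig with exactly 10 is retained; the
threshold is exposed because the convention is genuinely ambiguous in the
field. *Stopping comparison*: strict — a pair at exactly the threshold
still merges.

With one condition group the test has zero degrees of freedom and is
skipped; since by default every sample is its own group, the test is active
on any multi-sample run unless groups are supplied or `--no-test` is given
(useful when differentially spliced isoforms should stay together).

## What the synthetic generator emulates — and what it does not

`scenario_config()` / `generate_scenario()` model genes as abstract integer
token runs, contigs as derived token runs (identical duplicates, disjoint
fragmented halves, tail-head chimeric concatenations, paralogue pairs with
an identical leading block), and fragments as uniformly placed sub-runs
that map to every contig *containing* them. Defaults state a desk-scale
two-group experiment: 2 conditions × 3 replicates, 100 expected fragments
per gene per sample (Poisson; negative binomial when `dispersion > 0`),
1000-base genes, 200-base fragment spans (100-bp paired-end reads with a
short insert).

Mapping-by-containment deliberately omits an aligner: no mismatches, no
partial overhangs, no quality filtering. A green test therefore establishes
the *algorithmic* behaviour — distances, the test, linkage, assignment —
not robustness to alignment artifacts. Base-level error models and
transcript-abundance ground truth are out of scope.

One generator default required analysis. With containment mapping and a
shared leading block of fraction $s$, the effective fraction of fragment
start positions inside the block is $s' = (sL - \ell + 1)/(L - \ell + 1)$
(gene length $L$, fragment span $\ell$), and for two equally expressed
paralogues the shared-read distance works out to $(1-s')/(1+s')$. At 50%
sharing this is $\approx 0.45$ — above the default threshold, so such a
pair is separated by distance alone and cannot demonstrate the ratio
test's effect. The default `paralogue_shared_frac` is therefore 0.75
(distance $\approx 0.19$), which also better matches the highly homologous
gene families that make clustering hard in practice. This was chosen once,
from the formula above, not tuned against test outcomes.

## Numerical and determinism choices

- All orderings that reach output files (class keys, cluster names,
  tie-breaks, file rows) use C-collation radix sorting, so outputs are
  byte-identical across locales and platforms.
- Ties on the minimum distance merge the pair whose (smaller member, then
  larger member) sorts first; merged clusters get fresh synthetic IDs that
  sort before all contig names.
- Distances of pairs sharing no reads are never materialised (implicitly
  1); cached distances of untouched pairs are provably unaffected by other
  merges, so only pairs involving a fresh merge are recomputed — including
  a re-run of the ratio test on the merged counts. A pair forced apart
  early can therefore still co-cluster through an intermediate contig; the
  suite asserts this on a constructed three-contig instance.
- `assign_fragments()` seeds its own RNG and restores the caller's state.
- $D$ is clamped at 0 against round-off; swap-symmetry holds to ~1e-12
  relative, and tests assert it at 1e-9.

## Truth labelling and evaluation

For benchmarking against an annotation, alignment hits (generic TSV:
contig, gene, length, identity, 0-based half-open footprint) are filtered
at length ≥ 200 and identity ≥ 0.98; a contig matching two or more genes
whose footprints overlap by fewer than 100 bases is labelled chimeric
(excluded from scoring, as is any unlabelled contig); otherwise the
longest alignment wins. With three or more genes, *any* under-overlapping
gene pair marks the contig chimeric — the strictest reading, chosen
because a single dubious junction already makes the origin unreliable.
Clusters take the majority gene of their contigs, ties broken
lexicographically. Precision and recall are computed over all unordered
pairs of labelled contigs via the gene × cluster contingency table, which
the suite checks against literal pair enumeration.

## Known limitations

- The Poisson model understates biological variability between replicates;
  the published default P-value partly compensates, but truly dispersed
  data will reject somewhat more often than nominal.
- Contigs whose fragments were all filtered with their contigs are dropped
  from counting entirely, which is correct for DE but means column sums
  reflect *retained* fragments, not sequenced ones.
- Super-clusters are processed sequentially; per-component independence
  would permit parallelism, but none is attempted.
- CRAM input, MAPQ filtering and alignment itself are out of scope.
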