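---
title: "Alignment-free read classification via eBWT clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free read classification via eBWT clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebwtax)
```

## The model

`ebwtax` assigns metagenomic sequencing reads to taxa without aligning,
mapping or assembling them. The whole method rests on one combinatorial
object: the extended Burrows–Wheeler transform (eBWT) of the joint
collection of reads and reference genomes, enhanced with the document
array (DA) and the LCP array.

Write the collection as $\mathcal{S} = \{S_1,\dots,S_r, S_{r+1},\dots,
S_{r+g}\}$ — $r$ reads followed by $g$ genomes, each terminated by its own
end marker. Sorting all suffixes of all sequences lexicographically gives:

* `ebwt[i]` — the symbol circularly preceding the $i$-th sorted suffix,
* `da[i]` — the "color" (sequence index) that suffix came from,
* `lcp[i]` — the longest common prefix length between the suffixes ranked
  $i$ and $i-1$ (`lcp[1] = lcp[N+1] = 0`), where $N = \sum_i n_i + m$.

Because sorted suffixes that share a long prefix sit next to each other,
symbols occurring before the same context cluster together in the eBWT.
The classifier exploits exactly this: if a read and a genome share many
contexts of length at least $\alpha$, their colors interleave inside the
same blocks.

**Step 1 — α-clusters.** An α-cluster is a maximal block $(p_S, p_E)$ with
`lcp[i] >= alpha` for $p_S < i \le p_E$, `lcp[pS] < alpha`,
`lcp[pE+1] < alpha`, containing at least one read color and one genome
color. Maximality is enforced; blocks whose colors all fall on one side
are discarded; no constraint is placed on cluster size. Detection is one
sequential pass over `lcp` and `da`.

**Step 2 — two similarity measures.** For a read $S_i$ and genome $S_j$,
with $\mathrm{occ}_a(i,x)$ the number of $a$-symbols of color $i$ in
cluster $x$:

$$\mathfrak{S}^{\mathrm{eBWT}}_\alpha(S_i,S_j) = \sum_{x}\Big(\sum_{a}
\min(\mathrm{occ}_a(i,x), \mathrm{occ}_a(j,x)) + \delta_{IUPAC}\Big),
\qquad
\mathfrak{S}^{\mathrm{DA}}_\alpha(S_i,S_j) = \sum_{x}
\min(\mathrm{occ}(i,x), \mathrm{occ}(j,x)).$$

$\delta_{IUPAC}$ pairs leftover degenerate-base codes (R, Y, N, ...) with
leftover concrete bases of their code sets, one-to-one. Both measures obey
$0 \le \mathfrak{S}^{\mathrm{eBWT}} \le \mathfrak{S}^{\mathrm{DA}} \le
\min(n_i,n_j)+1-\alpha$, so dividing by the right-hand bound normalizes
scores into $[0,1]$. The symbol-matching variant is the more precise
measure; the color-count variant is cheaper and slightly more sensitive.

**Step 3 — three-phase assignment.** Reads are processed with both strands
(and, for paired-end input, both mates): up to four matrices
$\mathcal{M}^{1F}, \mathcal{M}^{1RC}, \mathcal{M}^{2F}, \mathcal{M}^{2RC}$.
Phase 1 takes the overall maximum $M_i$ of a read's rows; below the
threshold $\beta$ the read stays unclassified; genomes within the
tolerance of $M_i$ in at least one matrix form the candidate set, and if
they agree on one taxonomic unit at the minimum rank the read is
classified. Otherwise phase 2 re-scores the candidates by mate-pair sums —
always the best FR strand pairing (1F with 2RC, or 1RC with 2F), never the
sum of all four, which would bias toward genomes hit on both strands.
Phase 3 repeats this over *all* genomes, so strong mate evidence can
overturn the phase-1 ranking. A read still tied across units is reported
ambiguous, or, with lineage fallback enabled, classified at the lowest
higher rank its tied set shares.

## A worked example

One read `S1 = GGCGTACCA` against genomes `S2 = GGGGCGTAT` and
`S3 = ACGARTACGAC` (note the purine code `R`):

```{r}
ex <- running_example()
idx <- build_ebwt_index(ex$collection)
cl <- detect_alpha_clusters(idx, alpha = 2)
cl
build_similarity_matrix(idx, cl, "ebwt", alpha = 2)$values
build_similarity_matrix(idx, cl, "da", alpha = 2)$values
```

The six 2-clusters yield raw similarities 5 (S1 vs S2, both measures),
2 (S1 vs S3, symbol matching — the `R` of S3 pairs with a `G`) and
3 (S1 vs S3, color counts), normalized by $\min(n_i,n_j)+1-\alpha = 8$.

## Parameters that matter

* **`alpha` (default 16)** — minimum shared-context length, in bases. Too
  small and random contexts dominate (a length-$k$ context has expected
  $\approx N/4^k$ chance matches); too large and substitution errors break
  every context. For 100-bp reads, 16 balances the two: a read with 1%
  substitutions still carries many error-free 16-mers, while $4^{16}
  \approx 4\cdot 10^9$ makes chance 16-mer sharing negligible.
* **`beta` (default 0.25)** — minimum normalized similarity for
  classification. Raising it trades sensitivity for precision; the
  classified-read set is provably non-increasing in `beta` (the gate is
  applied once, in phase 1).
* **`tolerance` (default 0.02)** — absolute slack defining "approximately
  equal to the maximum". We apply it uniformly in phases 1–3; an
  exact-maximum alternative for the re-examination phases is available via
  `strict = TRUE` (the two differ only when near-ties straddle the band).
* **`min_rank` (default species)** — the most specific rank of
  assignments; `genome` makes every leaf its own unit.

## Design choices where the design was open

* **Distinct end markers, ordered by sequence index.** This makes the
  suffix order total and the whole construction deterministic; ties
  between otherwise equal suffixes break by color. The LCP array treats
  distinct markers as unequal, so shared contexts never span a terminator.
* **End markers in cluster profiles.** For similarity counting all
  per-sequence markers collapse to the single symbol `$`, which may match
  across sequences in the exact phase — a terminal context shared by a
  read and a genome is evidence like any other. This convention is what
  reproduces the worked example's values above. `$` carries no IUPAC code
  set, so it never enters the residual matching.
* **$\delta_{IUPAC}$ as a maximum matching.** "Number of pairings" is
  computed as a maximum bipartite matching on the residual multisets
  (codes never pair with other codes; a code matches itself only through
  the exact phase). Because edges only connect codes with concrete bases,
  the problem splits into two small transportation problems solved
  exactly; greedy pairing could undercount when two codes compete for the
  same base. The result is order-independent, making the whole matrix
  independent of cluster processing order.
* **Mate pairing fixed to FR orientation** (1F with 2RC, 1RC with 2F), the
  standard Illumina layout the simulator also emits.
* **Phase 2/3 sums use normalized scores**, consistent with $M_i$;
  unnormalized sums would weight long genomes differently.
* **Unranked taxonomy nodes are transparent**: lineage walks skip
  `no_rank` entries, so intermediate unranked levels never block
  agreement at a named rank.
* **`M_i <= beta` (not `<`) leaves a read unclassified**, so `beta = 0`
  still suppresses all-zero rows.
* **Construction is in-memory prefix doubling** with the LCP array derived
  from the retained rank hierarchy. The contract is the output, not the
  algorithm: the suite checks it bit-for-bit against a naive
  enumerate-and-sort oracle. External tools producing the same structures
  can be substituted through the serialized index contract
  (`write_index()` / `read_index()`).

## What the simulator emulates — and what it does not

`simulate_reference_set()` / `simulate_paired_reads()` generate i.i.d.
uniform genomes, uniform fragment loci, FR-oriented mates of length 100,
and per-base substitutions at a fixed rate (default 1%); negative controls
are per-read symbol shuffles, preserving composition while destroying
order. Defaults: 5 genomes of 10 kb in distinct species, 500 pairs,
100 negatives.

The error model is substitution-only — no indels, no quality-dependent
error profile, no coverage bias, no shared homologous regions between
genomes. The similarity measures are context-exact, so indels would only
shorten shared contexts; for testing the computation itself they add
nothing. Consequently, passing tests demonstrate correctness of the
defined computation and recovery under substitution noise on unrelated
references; they do not demonstrate accuracy on real communities, where
inter-genome homology, repeats and indel errors make the assignment
problem genuinely harder.

Test problem sizes are chosen to exercise every code path while keeping
the suite fast: property tests use hundreds of random collections of up to
5 sequences × 30 bp (where brute-force oracles are exact and cheap), and
the end-to-end recovery scenario uses the simulator defaults above
($N \approx 10^5$ per orientation index).

## Numerical and degenerate-input conventions

* Scores are exact integer accumulators; normalization is the only
  floating-point step, so equal inputs give bit-identical matrices.
* `alpha` greater than every LCP value yields no clusters and a zero
  matrix (with a warning once `alpha` reaches the read length); a
  non-positive normalizer ($\alpha > \min(n_i,n_j)+1$) reports 0, never a
  division by zero.
* Ties surviving phase 3 with fallback off are reported `ambiguous`
  together with the tied taxa (resolved at the minimum rank) in a
  diagnostic column.
* Undefined evaluation metrics (zero denominators) are `NA`, never 0.

## Known limitations

* The index is built in memory per orientation by re-indexing reads with
  genomes; there is no incremental update or merge of precomputed
  structures, and no multi-threading.
* Genome-scale references beyond a few hundred kilobases per orientation
  index are outside the intended desk scale of this implementation.
* Abundance estimation, confidence scores beyond the normalized
  similarity, and re-assignment of ambiguous reads by priors are out of
  scope.
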