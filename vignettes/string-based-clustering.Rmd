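---
title: "String-based clustering of HT-SELEX pools: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{String-based clustering of HT-SELEX pools: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsbc)
```

## The problem

An HT-SELEX experiment reads out, per selection round, millions of short
oligonucleotide sequences. The sequences worth synthesizing are those that
share a *target-binding region* — a substring, of unknown and variable
length, necessary for binding the target. Frequency alone is a poor guide:
PCR bias and non-specific binders can dominate the most abundant
sequences. This package ranks candidate binding regions as
*over-represented strings* — substrings that occur in far more reads than
expected under the pool's base composition — and then groups sequences by
the strings they contain. One round of data (typically the final round)
suffices.

## Containment probability of a string in random text

Everything rests on one quantity: the probability $P_{s,L}$ that an
i.i.d. random sequence of length $L$, with per-base probabilities
$p_j$, $j \in \{A, C, G, T\}$, contains a given string $s$ at least once.
With $Q = \prod_j p_j^{n_{s,j}}$ (the probability of $s$ itself, where
$n_{s,j}$ counts base $j$ in $s$), $P_{s,L} = 0$ for $L < |s|$, and for
$L \ge |s|$:

$$
P_{s,L} = P_{s,L-1} + Q \left( 1 - P_{s,L-|s|}
  - \sum_{t \in \mathcal{T}} q_t^{-1}
    \left( P_{s,L-|s|+|t|} - P_{s,L-|s|+|t|-1} \right) \right),
$$

where $\mathcal{T}$ is the set of *borders* of $s$ — non-empty proper
prefixes that are also suffixes (for `ATATA`: `A` and `ATA`) — and
$q_t = \prod_j p_j^{n_{t,j}}$. The increment is the probability that a
first-time occurrence of $s$ ends exactly at position $L$; the border sum
removes occurrences that merely extend a self-overlapping earlier
occurrence, which a border-free derivation would double-count.

Because read lengths vary (around 78% of SELEX reads typically have the
expected random-region length), the per-length values are averaged over
the observed length distribution, weighted by read multiplicity:
$P_s = \frac{1}{N}\sum_{i=1}^{N} P_{s,L_i}$.

### Why we trust the recurrence

The recurrence is not taken on faith; two independent oracles recompute
the same probability in `exact_containment_oracle()`:

* **enumeration** — compiled summation of the probability of every one of
  the $4^L$ $L$-mers containing $s$ (with compensated summation; feasible
  to $L = 11$), sharing no logic with the recurrence;
* **automaton** — a dynamic program over the KMP failure automaton of $s$,
  tracking the probability mass that has not yet seen $s$ (any $L$).

The test suite checks agreement to $10^{-10}$ absolute over random
(string, probability-vector) pairs including heavily bordered strings
(`ATATA`, `AAAA`, `ATGATG`), plus hand-enumerable cases
($P_{AA,3} = 0.375$ at $p_A = 1/2$; $P_{AT,3} = 0.125$ uniform) and the
closed form $1 - (1-p)^L$ for single letters. Agreement held to machine
precision in every case we ran, so the recurrence is exact for all border
structures we exercised, not merely approximate.

```{r oracle}
p <- alphabet_probs(c(A = 0.3, C = 0.2, G = 0.3, T = 0.2))
containment_prob_table("ATATA", p, 12)[13]
exact_containment_oracle("ATATA", p, 12, method = "automaton")
```

## Scoring and selecting over-represented strings

Base probabilities are estimated from the pool itself,
$\hat p_j = n_j / \sum_i L_i$ (`estimate_base_probs()`), because the
selection process skews composition and a uniform background would
misprice strings. For a string $s$ contained in $F_s$ of the $N$ reads,

$$
Z_s = \frac{F_s/N - P_s}{\sqrt{P_s (1 - P_s) / N}},
$$

the binomially standardized excess of observed over expected containment.
$F_s$ counts *reads containing* $s$ (a read with several occurrences
counts once), with read multiplicity; the same multiplicity-weighted $N$
appears in the average for $P_s$ and in the variance. Strings with
$P_s \in \{0, 1\}$ (possible when some $\hat p_j = 0$) have no defined
score and are excluded with a message.

Enumerating all strings of lengths 5–10 would mean
$\sum_{l=5}^{10} 4^l = 1{,}397{,}760$ candidates. Instead
(`select_strings()`):

1. score all $4^{l_{min}}$ seeds; drop $Z < 0$;
2. extend each survivor by one base and keep a child only if
   $Z_{child} \ge Z_{parent}$ for at least one parent that generated it
   (ties kept — the exclusion rule is strict);
3. repeat until $l_{max}$; the selected set is the union over lengths.

Two open choices were resolved as follows. *Extension direction*: bases
are added at **both ends** by default (configurable), since binding
regions have no reason to grow only rightward and one-sided growth cannot
reach motifs whose strongest seed is interior. *Multi-parent children*:
each extension event is judged against its own parent, so one permissive
parent suffices; this is the least aggressive pruning consistent with the
rule and can only reduce the risk of missing a true motif. On the
reference synthetic pools the search scores under 2% of the exhaustive
space, and per-length exhaustive winners (computed by brute force over
all strings present in reads, lengths 5–8) were always inside the
survivor set in our tests.

## Ranking across lengths and clustering

Raw $Z$ grows with length along the extension path, so survivors of
different lengths are not comparable. Within each length class of the
*selected* strings, $Z$ is standardized:
$Z^*_s = (Z_s - \hat\mu_{|s|}) / \hat\sigma_{|s|}$, with $\hat\mu$ and
$\hat\sigma$ estimated from the selected strings of that length only.
$\hat\sigma$ is the sample ($n-1$) standard deviation; a class with a
single member (or zero spread) gets $Z^* = 0$, i.e. it sits at its class
mean rather than $\pm\infty$. Ties in $Z^*$ break by raw $Z$, then
length (longer first), then lexicographically, making the ranking fully
deterministic.

Clustering is greedy (`greedy_cluster()`): walk the strings in rank
order; all remaining sequences containing the current string form the
next cluster and are removed; an extraction that matches nothing does not
consume a rank; stop when no sequences remain. Sequences containing no
selected string stay unassigned (`NA`), and are ranked below every
cluster in evaluation. The implementation precomputes the
string-to-sequence incidence with one multi-pattern trie scan per string
width (Biostrings `PDict`), which is observationally identical to
re-scanning the remaining pool at every step.

Accuracy against known binding labels is summarized by ordering labeled
sequences by cluster rank and computing the ROC AUC
(`roc_auc_by_cluster_rank()`). Sequences sharing a cluster are genuinely
tied, so the AUC is the Mann–Whitney statistic with half credit for ties;
unassigned sequences score strictly worst. Both conventions matter: any
other tie treatment would make the AUC depend on arbitrary within-cluster
order.

## The synthetic-pool generator

`generate_pool()` provides ground-truthed inputs so every stage is
testable without external data. Its defaults are the package's reference
conditions: 10,000 reads of nominal length 30; 22% of reads off-length by
1–3 nt (uniform magnitude and sign), reflecting the commonly reported
~78% on-length fraction; skewed composition $A/C/G/T = 0.3/0.2/0.3/0.2$
to exercise the composition-aware scoring; one 10-mer motif
(`TATGGACTTC`) overwriting a uniformly placed window in 20% of reads.
A fixed seed yields byte-identical pools, and the generator restores the
caller's RNG state.

What the generator does *not* emulate — and what passing tests therefore
do not establish — includes PCR amplification bias (real pools have
highly skewed count distributions; synthetic reads are nearly all
unique), sequencing errors, correlated/secondary-structure-constrained
backgrounds, and multiple co-selected motif families. Recovery of a
planted motif at 20% prevalence in an i.i.d. background is an easier
problem than a real round-5 pool; the synthetic results validate the
machinery, not field performance.

```{r pipeline}
sp <- generate_pool(synthetic_pool_spec(n_reads = 2000, seed = 42))
res <- run_fsbc(sp$pool, min_count = 1, l_min = 5, l_max = 8,
                labels = carrier_labels(sp))
head(res$ranked[, c("string", "length", "F", "Z", "Z_star", "rank")], 3)
res$evaluation$auc
```

## Numerical and design notes

* Containment tables are memoized per profile: $P_{s,L}$ depends on $s$
  only through $|s|$, its composition, and its borders' lengths and
  compositions, so thousands of strings share a handful of recurrence
  runs. Tables are asserted to lie in $[0, 1 + 10^{-9}]$ and clipped with
  a warning only inside that margin; larger excursions are an error.
* The frequency cutoff (`min_count`, default 10 in `run_fsbc()`) is
  inclusive; cutoff 1 is the identity. Filtering recomputes $N$, the
  length distribution, and $\hat p_j$ on the retained reads.
* Reads are assumed pre-trimmed to the random region; an optional
  fixed-width trim is provided but defaults to a no-op. Reads with
  characters outside A/C/G/T/U are dropped whole (the containment model
  has no degenerate-base semantics); U maps to T; FASTQ qualities are
  ignored.
* `l_max` is enforced strictly; selecting strings longer than the
  shortest read is allowed but warned about, since such strings cannot
  occur in the short reads.
* Validation problem sizes (10,000-read pools, 20 replicates for
  recovery, lengths 5–8 for the brute-force comparison) were chosen so
  the full suite runs comfortably on a laptop core while keeping the
  binomial approximation in $Z$ well inside its validity range.
* Known limitations: no insertion/deletion- or degenerate-base-tolerant
  matching; no occurrence-count (as opposed to containment) statistics;
  no Markovian background; no multi-round trajectory information; cluster
  members are not re-ranked internally beyond their counts. Clusters are
  small, so a downstream motif refiner (e.g. MEME) can be applied per
  cluster if finer structure is needed.
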