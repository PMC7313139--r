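# fsbc — fast string-based clustering for HT-SELEX sequence pools

`fsbc` identifies candidate aptamer **target-binding regions** in a single
round of HT-SELEX sequencing data. Aptamer pools read out by
next-generation sequencing contain millions of sequences, and the most
abundant ones are often PCR-bias artifacts rather than binders. What
binders do share is a substring — of unknown, variable length — necessary
for target binding. `fsbc` finds such substrings as *over-represented
strings*, ranks them by a composition-aware Z-score, and greedily clusters
sequences by the strings they contain, so that the top-ranked clusters
collect the likely binders regardless of their raw frequency.

It is written for SELEX practitioners and sequence-analysis developers who
need cluster rankings from one (typically the final) selection round,
without multi-round data.

## The statistic at the core

For a string *s* and an i.i.d. random *L*-mer with base probabilities
*p<sub>j</sub>* estimated from the pool
(*p̂<sub>j</sub> = n<sub>j</sub> / Σ L<sub>i</sub>*), the containment
probability *P<sub>s,L</sub>* satisfies the border-corrected recurrence

    P(s,L) = P(s,L-1) + Q * ( 1 - P(s,L-|s|)
             - Σ_t 1/q_t * ( P(s,L-|s|+|t|) - P(s,L-|s|+|t|-1) ) )

with `Q = Π p_j^n(s,j)`, the sum running over the *borders* *t* of *s*
(proper prefixes that are also suffixes), and `P(s,L) = 0` for `L < |s|`.
Averaging over the observed read-length distribution gives *P<sub>s</sub>*,
and the score of *s* contained in *F<sub>s</sub>* of *N* reads is

    Z_s = (F_s/N - P_s) / sqrt( P_s (1 - P_s) / N ).

Strings of lengths `l_min..l_max` (defaults 5..10) are selected by a
Z-pruned extension search instead of enumerating all 1,397,760
possibilities; Z-scores are then standardized within each length class
(*Z\**) for cross-length ranking, and clusters are extracted greedily in
rank order. An exact enumeration/automaton oracle
(`exact_containment_oracle()`) independently validates the recurrence.

## Worked example

Generate a synthetic pool with a known planted motif — 10,000 reads of
nominal length 30, skewed composition, the 10-mer `TATGGACTTC` carried by
20% of reads — and run the full pipeline:

```r
library(fsbc)

sp  <- generate_pool(synthetic_pool_spec(seed = 1))
res <- run_fsbc(sp$pool, min_count = 1, labels = carrier_labels(sp))

print(res$selected)
#> SelectedStrings: m = 7246 strings (lengths 5-10), 24,492 Z-evaluations (1.75% of exhaustive 1,397,760)
#>   survivors per length: 5=232 6=456 7=789 8=1209 9=1737 10=2823

head(res$ranked[, c("string", "length", "F", "Z", "Z_star", "rank")], 3)
#>       string length    F        Z   Z_star rank
#> 1 TATGGACTTC     10 2034 5629.814 43.91297    1
#> 2  ATGGACTTC      9 2034 2546.880 26.53951    2
#> 3  TATGGACTT      9 2034 2459.109 25.62058    3

print(res$clusters)
#> ClusterAssignment: 2212 clusters over 10000 unique sequences (25 unassigned)
#>   top clusters (unique/reads): #1 2034/2034 #2 5/5 #3 2/2 #4 6/6 #5 6/6

res$evaluation$auc
#> [1] 1
```

Reading the output: the search scored ~24.5k strings, 1.75% of the
exhaustive space. The planted motif is the top-ranked string (its raw
Z-score, 5630, is the standardized excess of the 2034 observed carrier
reads over the fewer-than-one expected by composition alone), every one of the 2034
carrier sequences lands in cluster 1, and ordering sequences by cluster
rank separates carriers from background perfectly (AUC = 1).

With real data, point `run_fsbc()` at a FASTA/FASTQ file (gzip allowed)
of reads pre-trimmed to the random region, keep the default frequency
cutoff (`min_count = 10`) for large pools, and pass a
`sequence / binding` TSV as `labels` if binding annotations exist. A thin
command-line wrapper with `run`, `simulate` and `evaluate` subcommands is
installed at `system.file("cli", "fsbc.R", package = "fsbc")`.

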