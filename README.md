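# barcodeval

`barcodeval` is an R package for evaluating candidate **DNA barcode** regions
— single markers and concatenated ("combined") barcodes — for the
discrimination of two closely related species, the situation typical of
valuable timber or medicinal plants whose congeners are morphologically and
anatomically indistinguishable. Given per-marker multiple sequence alignments
and a sample table (id, species, genus), it runs the four evaluation methods
that the barcoding literature applies side by side:

1. **Distance-based**: pairwise Kimura two-parameter (K2P) distances
   `d = -½ ln((1 − 2P − Q) √(1 − 2Q))` (P = transition, Q = transversion
   proportion, pairwise deletion of gaps/ambiguities), summarised as mean
   interspecific distance, mean intraspecific distance, theta (θ, per-species
   mean intraspecific distance averaged over species) and coalescence depth
   (per-species maximum, averaged), each ± SE; plus the **barcoding gap**:
   present iff `min(inter) > max(intra)`, with histograms of both
   distributions. Markers are compared by the **Wilcoxon signed-rank test**
   on interspecific distances paired by sample-pair identity (exact p by the
   null distribution of W⁺ for n ≤ 25 without ties, normal approximation with
   tie and continuity correction otherwise).
2. **Similarity-based**: best-match identification against a local labeled
   reference library (leave-one-out by default), scoring each query
   *success* / *error* / *ambiguous* at species and genus level according to
   whether the top-identity hits are all conspecific, none conspecific, or
   mixed.
3. **Character-based**: induction of diagnostic logic rules — conjunctions of
   `position = nucleotide` clauses true for every sample of one species and
   no sample of the other (e.g. `196 = A`), with disjunctive alternatives —
   and leave-one-out **cc/wc/nc** (correctly / wrongly / not classified)
   percentages.
4. **Tree-based**: neighbor-joining trees from the K2P matrix with
   column-resampling bootstrap support; a species "succeeds" when its samples
   form one side of a bipartition of the unrooted tree (monophyly).

A seeded two-species simulator (`simulate_dataset()`) generates multi-marker
datasets with known planted diagnostics, so the entire pipeline is testable
end to end without any sequence download.

## Worked example

Simulate a dataset whose markers emulate the per-marker regimes reported for
a published two-species timber study (a clean-gap `trnH-psbA`-like marker, a
noisy `trnL-trnF`-like one, a weakly separated `ITS2`-like one, plus their
combination), then evaluate everything:

```r
library(barcodeval)

ds  <- simulate_dataset(dalbergia_specs(), n_per_species = c(16, 22),
                        seed = 2024)
cfg <- run_config(ds$alignments[c("trnH-psbA", "ITS2", "trnL-trnF")],
                  combinations = list(c("ITS2", "trnH-psbA")),
                  bootstrap = 200, seed = 2024)
bundle <- run_pipeline(cfg)
bundle$summary
```

```
         marker combined gap_present identification_success rules_perfect both_monophyletic all_criteria
      trnH-psbA    FALSE        TRUE                   TRUE          TRUE              TRUE         TRUE
           ITS2    FALSE       FALSE                  FALSE         FALSE             FALSE        FALSE
      trnL-trnF    FALSE       FALSE                     NA          TRUE              TRUE        FALSE
 ITS2+trnH-psbA     TRUE       FALSE                   TRUE          TRUE              TRUE        FALSE
```

Only the `trnH-psbA`-regime marker passes all four criteria (barcoding gap,
100% leave-one-out identification success, perfect diagnostic rules, both
species monophyletic) — the qualitative pattern such studies report. The
`trnL-trnF`-regime marker has an `NA` identification verdict because its
simulated divergence pushes every query below the 97% identity threshold
(logged and skipped, not fatal). Distance summaries mirror the usual
"Table 3" shape:

```r
bundle$distance_summary[, c("marker", "mean_inter", "mean_intra",
                            "theta", "coalescence_depth")]
```

```
         marker mean_inter mean_intra   theta coalescence_depth
      trnH-psbA    0.02382    0.00000 0.00000           0.00000
           ITS2    0.00486    0.00485 0.00487           0.01266
      trnL-trnF    0.06579    0.05949 0.05767           0.07876
 ITS2+trnH-psbA    0.01119    0.00372 0.00375           0.00866
```

and the rule table carries the induced logic formulae with their
leave-one-out cc/wc/nc rates, e.g. for the clean marker every diagnostic
column is reported as an alternative:

```
    marker   species  cc wc nc formula
 trnH-psbA species_A 100  0  0 1 = T OR 50 = C OR 90 = C OR ...
 trnH-psbA species_B 100  0  0 1 = G OR 50 = T OR 90 = A OR ...
```

`run_config(..., out_dir = "report")` additionally writes the full bundle:
TSV tables per stage, per-marker distance histograms, Newick trees with
bootstrap supports, `summary.json` and the run log.

## Command line

```sh
inst/cli/barcodeval simulate --n-per-species 16 --seed 1 --out sim/
inst/cli/barcodeval evaluate \
  --alignment sim/trnH-psbA.fasta --alignment sim/ITS2.fasta \
  --metadata sim/metadata.tsv --combine "ITS2+trnH-psbA" \
  --bootstrap 1000 --seed 1 --out report/
```

Subcommands `seqstats`, `distance`, `gap`, `wilcoxon`, `rules`, `identify`
and `tree` expose individual stages.

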