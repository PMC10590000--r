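# mafldtraj

Temporal disease- and death-trajectory analysis of **metabolic
dysfunction-associated fatty liver disease (MAFLD)** from ICD-10 coded
hospital diagnosis histories.

MAFLD — hepatic steatosis plus metabolic dysfunction — raises the risk of
disease across essentially every organ system. This package implements the
full trajectory-analysis design as a reusable R pipeline for
epidemiologists working with biobank-style data (a baseline participant
table, a first-diagnosis table, a death register):

1. **Phenotyping** — fatty liver index
   (FLI = 100·σ(0.953 ln TG + 0.139 BMI + 0.718 ln GGT + 0.053 WC − 15.745),
   steatosis at FLI ≥ 60), NAFLD fibrosis score (advanced fibrosis above
   −1.455), the MAFLD consensus criteria, and a normalized polygenic risk
   score over MBOAT7/GCKR/TM6SF2/PNPLA3 with range exactly [0, 8].
2. **Taxonomy** — 3-character ICD-10 truncation, collapse into combined
   disease categories, first-occurrence dating, chapter exclusions
   (pregnancy/childbirth, unclassified symptoms), and a 16-category
   cause-of-death scheme.
3. **Matching** — 1:1 propensity-score matching (age, sex, Townsend
   deprivation; greedy nearest-neighbor, exact on sex, 0.2-SD logit
   caliper) with balance diagnostics.
4. **PheWAS** — per-category Cox regression (Efron ties) on the matched
   cohort, baseline-history exclusion, incidence filter (> 1% of exposed),
   Bonferroni selection (HR > 1, p < α/n).
5. **Pair inference** — ordered disease pairs, co-occurrence filter
   (> 0.5% of exposed), exact binomial test of temporal direction
   (fraction D2-after-D1 > 1/2), logistic confirmation (OR > 1), staged
   Bonferroni denominators.
6. **Trajectory graph** — directed network of confirmed pairs, transitive
   shortcut pruning (D1→D3 deleted when D1→D2→D3 exists), original /
   intermediary / terminal layering, GraphML/JSON/TSV export.
7. **Death & genetic workflows** — decedent-vs-survivor matching within
   the exposed group, cause-of-death PheWAS, disease→death sweeps,
   per-cause graphs ending in a death node; and the same pipeline with
   exposure = highest vs lowest PRS tertile.
8. **Synthetic cohorts** — a seeded generator with a latent steatosis
   process driving the FLI inputs, planted per-category exposure hazard
   ratios, directed D1→D2 hazard amplification (ψ), and cause-specific
   death hazards, so every stage is testable without restricted data.

The real study cohorts (UK Biobank) are access-restricted; all bundled
data files are small synthetic stand-ins in the same dialects.

## Worked example

```r
library(mafldtraj)

sim <- simulate_cohort(sim_config(20000, seed = 1))   # planted effects
ph  <- phenotype_cohort(sim$participants)
p   <- merge(sim$participants, ph, by = "participant_id")
p   <- p[!is.na(p$mafld)]
ev  <- collapse_events(sim$diagnoses, default_mapping())

phe <- run_phewas(p, ev, sort(unique(default_mapping()$combined_code)), "mafld")
phe[phe$significant, c("outcome", "n_cases_exposed", "hr", "p")]
```

```
   outcome n_cases_exposed   hr         p
1      A41             351 1.51  1.05e-06
2      D50             624 1.32  4.83e-06
3      E11            4077 4.21  0.00e+00
4      F32            1168 1.56  1.08e-21
5      G47            1256 3.48 7.69e-101
...
```

The default synthetic world plants, among others, HR 4.2 on diabetes (E11)
and HR 3.7 on sleep disorders (G47) for MAFLD-exposed participants; the
sweep recovers 4.21 and 3.48 with p far below the Bonferroni cut 0.05/31.
It also plants a directed amplification ψ = 2.5 of chronic kidney disease
(N18) after diabetes:

```r
sig  <- phe$outcome[phe$significant]
prs  <- run_pair_inference(p, ev, sig, p$participant_id[p$mafld])
prs[prs$confirmed, c("d1","d2","n_both","fraction_d2_after","binom_p","or","logit_p")]
#>    d1  d2 n_both fraction_d2_after  binom_p   or  logit_p
#> 1 E11 N18    327             0.746 7.87e-20 1.64 2.66e-09
```

327 exposed participants carry both diagnoses; 74.6% received the kidney
diagnosis after the diabetes diagnosis (exact binomial p = 8e-20), and
prior diabetes multiplies the odds of incident kidney disease by 1.64 —
the pair is confirmed and becomes the edge of a two-node trajectory:

```r
g <- transitive_prune(assemble_graph(phe, prs[prs$confirmed]))
layer_nodes(g)
#>    category    layer n_direct n_descendants depth
#> 1       E11 original        1             1     0
#> 2       N18 terminal        0             0     1
export_graph(g, "out/")   # graph.graphml, graph.json, nodes.tsv, edges.tsv
```

End-to-end runs (taxonomy → phenotype → match → PheWAS → pairs → graph →
optional death/genetic workflows) with a JSON-lines audit log:

```r
cfg <- run_config(participants = "in/participants.csv",
                  diagnoses = "in/diagnoses.csv", deaths = "in/deaths.csv",
                  outdir = "out", seed = 13,
                  death_workflow = TRUE, genetic_workflow = TRUE)
run_pipeline(cfg)
```

or from the shell: `Rscript inst/cli/mafldtraj.R run-all --config cfg.json
--seed 13 --outdir out`.

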