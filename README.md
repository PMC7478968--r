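# crisprE

Gene essentiality testing from CRISPR/Cas9 clonal editing outcomes.

## The problem

When a gene is essential, no knockout clone can be recovered — which is also
what happens when the knockout simply failed. Knockout-based essentiality
calls therefore rest on negative evidence. The CRISPR essentiality
(CRISPR-E) test turns this around: target the open reading frame with
Cas9/sgRNA, genotype surviving clones, and look at *which kinds* of repair
products survived. NHEJ indels with net length 3n preserve the reading
frame; 3n+1 and 3n+2 indels inactivate the gene. Recovered in-frame indels
prove the locus was cut and repaired; the complete absence of frameshift
alleles among edited survivors is then positive evidence that frameshift
lineages died — that the gene is essential.

`crisprE` is for labs running such clonal editing experiments (the bundled
examples come from haploid *Dictyostelium discoideum*, but nothing is
organism-specific): it calls alleles from per-clone amplicon sequences,
collapses sibling clones into independent editing events, and quantifies
essentiality.

## The statistic

With `k` independent edited events of which `x` are frameshifts, and a
theoretical frameshift frequency `f_exp` (default 2/3, frame-uniform NHEJ):

- **Null probability** that all `k` events are in-frame without selection:
  `(1 − f_exp)^k = (1/3)^k`.
- **Frameshift-deficit test**: exact one-sided tail `P(X ≤ x)` for
  `X ~ Binomial(k, f_exp)`.
- **Essentiality score**: `E = (x/k) / f_exp`, with a Clopper–Pearson exact
  CI rescaled by `1/f_exp`. Bands: `E = 0` essential, `0 < E < 1` loss
  deleterious, `E = 1` neutral, `E > 1` loss beneficial.

## Worked example

Call alleles for the bundled `grlB` experiment (12 picked clones, 6 of which
failed sequencing), from reference + guide + clone FASTA:

```r
library(crisprE)
ex   <- crispr_e_example("grlB")
ref  <- read_reference(ex$reference, orf_start = 0, orf_end = 180)
site <- find_target_site(ref, ex$guide)
site
#> Target site: GGTACCTGAACGATTGCAAT + PAM AGG (plus strand)
#>   cut between positions 56 and 57; window [27, 87)

res <- run_call(reference = ref, clones = ex$clones,
                status = ex$status, guide = ex$guide)
res$summary
#> Editing summary: 12 clones (6 sequenced, 6 failed)
#>   WT 0 | edited 6 | independent events 6
#>   events by frame class: in-frame 2, 3n+1 2, 3n+2 2
```

All six sequenced clones are edited, splitting evenly (33%/33%/33%) across
the three frame classes — a non-essential readout. Contrast an experiment in
which 18 independent events were recovered and every single one is in-frame:

```r
fit <- crispr_e(collapse_events(crispr_e_example_calls("Dync1li1_combined"))$summary)
fit
#> CRISPR-E essentiality fit
#>   events: k = 18, frameshift x = 0 (f_obs = 0, f_exp = 0.6667)
#>   E = 0  [0, 0.278] (95% exact CI)
#>   P(all in-frame | no selection) = 2.581e-09;  one-sided deficit p = 2.581e-09
#>   verdict: essential (no surviving frameshift allele)
```

The chance of 18 in-frame events arising without selection is `(1/3)^18 ≈
2.6e-9`: frameshift lineages were eliminated, so the gene (`Dync1li1`,
dynein light intermediate chain) is essential. A full report with both
denominator conventions:

```r
st <- run_stats(collapse_events(crispr_e_example_calls("KIF1A"))$summary)
writeLines(st$report)
#> Clones: 19 total, 19 sequenced, 0 failed (none)
#> Sequenced clones: 2 WT, 17 edited; 17 independent events
#> Events by frame class: in-frame 9, 3n+1 7, 3n+2 1 (stop-gain in-frame: 0)
#> Editing efficiency (per sequenced clone): 17/19 = 89.5%
#> Inactivation efficiency (per sequenced clone): 8/19 = 42.1%
#> Essentiality (per independent event): x = 8 of k = 17 frameshift, f_obs = 0.4706, f_exp = 0.6667
#> E = 0.7059, 95% exact CI [0.3447, 1.083]
#> P(all in-frame | no selection) = 7.744e-09; one-sided deficit p = 0.07548
#> Verdict: deleterious -- loss is deleterious (frameshift deficit)
```

`st$json` carries the same numbers machine-readably. A clonal NHEJ simulator
(`sim_config()`, `simulate_experiment()`, `recover_parameters()`) generates
synthetic experiments with configurable indel spectra, sibling clones,
sequencing failures and frameshift survival, for power planning and
validation. A thin CLI with `call` / `stats` / `simulate` / `report`
subcommands is installed at `exec/crisprE` inside the package directory.

Input formats: single-record reference FASTA with 0-based half-open
`orf_start`/`orf_end`; per-clone multi-FASTA (ids = clone ids) with optional
`clone_id`/`status` TSV; or a pre-called variant table TSV (`clone_id`,
`kind`, `position`, `ref_allele`, `alt_allele`[, `status`]) bypassing
alignment. See the methods vignette (`vignettes/crispr-essentiality.Rmd`)
for model assumptions, conventions and limitations.

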