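---
title: "Testing gene essentiality from clonal CRISPR editing outcomes"
author: "crisprE authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing gene essentiality from clonal CRISPR editing outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprE)
```

## The idea

Targeting the open reading frame of a gene with Cas9 and a single sgRNA
produces, after non-homologous end joining (NHEJ), a mixture of unedited
(WT) alleles and small insertions, deletions and substitutions at the
double-strand break. Indels whose net length is a multiple of three (3n)
preserve the downstream reading frame; 3n+1 and 3n+2 indels scramble it and
in almost all cases inactivate the gene. If the gene is dispensable,
surviving clonal lines carry both in-frame and frameshift alleles. If the
gene is essential, every frameshift lineage dies before cloning: the
survivors show clear evidence of editing — in-frame indels, point mutations —
but not a single frameshift. That selective absence is itself the readout;
no knockout needs to be recovered to conclude essentiality, which is exactly
the situation where knockout-based approaches are uninformative.

`crisprE` implements the full path from per-clone amplicon sequences to that
inference:

1. **Target model** — locate the 20-nt protospacer and its NGG PAM on either
   strand of the reference amplicon and derive the expected blunt cut.
2. **Allele calling** — globally align each clone, extract and normalize
   edits, classify frame consequence, translate the mutant ORF segment.
3. **Event collapsing** — merge byte-identical edit signatures: sibling
   clones from one editing event must not be double-counted.
4. **Essentiality statistics** — exact binomial machinery around the score
   `E`, fitted by `crispr_e()`.
5. **Simulation** — a generative model of clonal NHEJ outcomes under
   selection, used for end-to-end validation and power planning.

## The statistical model

Let `k` be the number of *independent* edited events among sequenced clones
and `x` the number of frameshift events. Under unbiased NHEJ the three
residue classes 3n, 3n+1, 3n+2 are treated as equally likely, so a fresh
edit is a frameshift with probability `f_exp = 2/3`. With no selection,

* the probability that all `k` events are in-frame is `(1/3)^k`
  (`all_in_frame_pvalue()`);
* more generally `X ~ Binomial(k, f_exp)`, and the one-sided exact tail
  `P(X <= x)` (`frameshift_deficit_test()`) quantifies a frameshift deficit.
  The test is one-sided because viability selection can only *remove*
  frameshift lineages; a two-sided option exists for completeness.

The essentiality score is the observed frameshift frequency relative to its
theoretical value,

    E = (x / k) / f_exp,

with interpretation bands: `E = 0` essential (and only `x = 0` produces it),
`0 < E < 1` loss is deleterious, `E = 1` neutral, `E > 1` loss is
beneficial. The confidence interval is the Clopper–Pearson exact interval on
`x/k` rescaled by `1/f_exp`; exactness matters because `k` is rarely above
~20 in clonal experiments, and asymptotic intervals misbehave at `x = 0` —
the case this test is designed to detect. `min_edited_clones(alpha)` inverts
the null probability for planning: 3 independent edited events already make
an all-in-frame outcome significant at 0.05, 5 at 0.01.

`f_exp` is a parameter, not a constant. The frame-uniform value 2/3 is the
default because it is the assumption behind the `(1/3)^k` null, but sgRNA-
specific indel spectra are known to be biased; when a non-essential control
gene has been edited in the same system, its event-level frameshift fraction
can be passed as `f_exp`. Because of such spectrum bias the score is most
trustworthy near its extremes — `E = 0` with small `(1/3)^k` is strong
evidence of essentiality, while intermediate `E` values rank rather than
measure fitness effects.

Two denominator conventions coexist deliberately, and the report labels
both: *efficiencies* (editing, inactivation) are per successfully sequenced
clone, the quantity a bench scientist quotes; *class fractions and `E`* are
per independent event after sibling collapsing, the quantity the null model
applies to. Sequencing failures appear in neither denominator.

In-frame alleles that gain a premature stop codon are counted as in-frame in
the class statistics (keeping the null model clean) but flagged separately
(`stop_gain`), since they plausibly inactivate the gene; a cluster of
stop-gain in-frame alleles in an apparently "essential" outcome would
deserve a second look.

## Sequence-level conventions

* **Coordinates** are 0-based, half-open; minus-strand protospacer hits are
  reported in plus-strand coordinates.
* **Cut site**: SpCas9 blunt cut 3 bp 5′ of the PAM, i.e. between
  protospacer bases 17 and 18. Published figures mark expected cut sites
  without stating the offset; this standard convention is an explicit,
  documented assumption.
* **Guide matching** is exact and must be unique; NGG is the default PAM
  pattern (any IUPAC pattern is accepted).
* **Alignment**: global Needleman–Wunsch with affine gaps via
  `Biostrings::pairwiseAlignment`; defaults match +2, mismatch −3, gap open
  6, gap extend 1 were chosen so that deletions of a few tens of bases — the
  upper end of what clonal NHEJ data shows — are recovered as one gap rather
  than a run of mismatches. Clones under 60% alignment identity are demoted
  to sequencing failures.
* **Edit normalization**: gap runs become single indel edits, left-shifted
  to their 5′-most equivalent placement (VCF convention) so that sibling
  clones produce byte-identical signatures wherever the aligner put the gap
  inside a repeat. Frame arithmetic uses indel lengths only; substitutions
  never change frame. Multiple disjoint indels contribute their sum.
* **Analysis window**: ±30 nt around the cut by default (NHEJ errors cluster
  at the break; the window generously covers observed indel sizes). Edits
  outside the window are reported but excluded from frame classification —
  distant mismatches are more plausibly PCR or base-calling artifacts than
  Cas9 products. An edit overlapping the window boundary counts in full,
  because a deletion starting at the cut may extend past any fixed window.
  Clones whose only edits fall outside the window classify as WT-at-target.
* **Stop-gain search** spans the re-translated ORF from its start to one
  codon past the window.

A known identifiability limit: two genuinely independent events that happen
to produce the same normalized edit are indistinguishable from siblings and
are collapsed into one. This mirrors how clonal experiments are read in
practice and biases `k` slightly downward for low-complexity edits.

## The simulator

`simulate_experiment()` generates what the test consumes: for each picked
clone, a sequencing-failure coin (`p_fail`), then a genotype — sibling of an
earlier event (`p_duplicate`, copying the parent's edit byte for byte),
fresh edit (`p_edit`), or WT — then viability selection: frameshift lineages
survive with probability `s` (0 = essential, 1 = neutral), and rejected
lineages are resampled as surviving genotypes so the number of picked clones
stays fixed, matching the picked-N-clones design of real experiments.

Fresh edits mix deletions, insertions and substitution-only outcomes
(default weights 0.55/0.30/0.15, deletions dominating as in clonal NHEJ
spectra). Sizes are capped geometric by default (caps 30/12 nt, covering the
−22…+12 range seen in clonal data); a uniform-size option (`1..cap`) exists
because with cap 6 it yields a frameshift probability of exactly 2/3,
the calibration condition for recovery studies
(`spectrum_frameshift_prob()` returns the implied value for any
configuration). Substitution-only edits touch 1–3 bases at the cut.
Selection acts at clone level; population dynamics, microhomology end
joining and chromatogram noise are out of scope — so passing tests show the
statistical machinery is correct under the stated model, not that any
particular sgRNA's spectrum is frame-uniform.

Everything is reproducible from `config$seed`; the same seed yields
byte-identical clones and truth table.

## Validation strategy and problem sizes

The suite checks, among others:

* alignment scores against exhaustive enumeration of all global alignments
  on short strings, and left-normalization against brute-force enumeration
  of equivalent gap placements;
* the exact tail against brute-force multinomial enumeration over the three
  frame classes for small `k`, and Clopper–Pearson endpoints against
  `binom.test`;
* per-clone frame classes against the simulator truth table — exact
  agreement on a 3 000-clone experiment;
* parameter recovery: 100 seeded replicates at ~100 clones (k ≈ 50–65
  events) per survival level `s ∈ {0, 0.5, 1}`; `s = 0` must give `E = 0`
  exactly, and for `s > 0` the exact CI must cover the closed-form
  expectation `expected_E(s)` in at least 90% of replicates;
* coverage of the exact interval over 10⁴ binomial draws.

These sizes keep the whole suite at a few minutes on one core while leaving
the statistical margins (3σ bands, 90% coverage thresholds against ≥95%
nominal) wide enough that the checks are not seed-sensitive.

## Bundled datasets

Five published clonal editing experiments in *Dictyostelium discoideum* are
shipped as pre-called variant tables (`crispr_e_example()`): two G-protein-
coupled-receptor-family genes (`grlB`, `grlC`) demonstrating the editing
readout, the non-essential `KIF1A` (kinesin-3) and `fAR1` (folic-acid
receptor), and the dynein light intermediate chain `Dync1li1`, where three
independent experiments recover edited clones without a single frameshift —
the essential verdict. Clone compositions (net indel sizes, substitution
counts, failures, sibling pairs) follow the published per-clone tallies;
nucleotide-level sequences and positions are synthetic stand-ins since no
sequence data were deposited, and the files carrying sequence are named
accordingly. The per-clone mix of the combined `Dync1li1` experiment is
synthetic beyond its published tallies (3 WT, 18 edited, 0 frameshift).

```{r example}
fit <- crispr_e(collapse_events(crispr_e_example_calls("Dync1li1_combined"))$summary)
fit
```

## Limitations

* The all-in-frame probability assumes event independence; cross-
  contaminated clones violate it in the conservative direction only if
  siblings are collapsed, which is why collapsing is not optional.
* Haploid biology is assumed (one allele per clone); diploid targets would
  need genotype phasing, out of scope here.
* Mixed Sanger traces (TIDE/ICE-style deconvolution) and AB1 base calling
  are out of scope: inputs are clean per-clone sequences or pre-called
  variants.
* `E > 1` and intermediate values inherit any spectrum bias in `f_exp`;
  verdicts other than `essential` should be read together with the CI.
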