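---
title: "Mining candidate effectors from aphid salivary-gland ESTs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining candidate effectors from aphid salivary-gland ESTs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aphidmine)
```

## The problem

Aphids feed by threading their stylets into the plant phloem and, like
plant-pathogenic fungi and oomycetes, secrete salivary proteins
("effectors") into host tissue to suppress defenses and promote
infestation. Candidate effectors can be mined computationally from
salivary-gland expressed sequence tags (ESTs): an effector should be a
*secreted* protein (N-terminal signal peptide, no transmembrane anchor),
and — because effectors sit in a co-evolutionary arms race with host
surveillance — should show *amino-acid polymorphism* within and between
aphid species (diversifying selection). `aphidmine` implements this
mining cascade end to end for the green peach aphid (*Myzus persicae*,
"mp") cross-referenced against the pea aphid (*Acyrthosiphon pisum*,
"ap"), together with the downstream assay statistics used to screen the
resulting candidates for effects on plant immunity (ROS burst
suppression) and aphid fecundity.

ESTs are single-pass cDNA reads: they arrive on either strand, truncated
at either end, with untranslated regions attached, and the same
transcript is typically sampled several times. Every stage of the
cascade exists to deal with one of these realities.

## The cascade

Given a salivary-gland EST library, `mine_effectors()` runs:

1. **ORF calling** (`call_orfs`). All six reading frames are scanned; an
   ORF runs from an ATG to the next in-frame stop (TAA/TAG/TGA, standard
   nuclear code) or to the end of the read, and must encode at least 70
   residues (`min_orf_len`). Within a stop-free stretch the 5'-most ATG
   is reported by default — the *longest-ORF* convention. "Every possible
   ORF" is ambiguous for nested in-frame starts; we resolve it towards
   the longest ORF because the downstream full-length rule (criterion 2
   below) asks whether any supporting read shows a methionine *upstream*
   of the predicted start, which presumes that convention. The
   `all_starts = TRUE` option reports every in-frame ATG for sensitivity
   analysis. Codons containing N translate to X and never act as start
   or stop — a conservative choice that cannot fabricate ORF boundaries
   inside ambiguous sequence. Coordinates are reported 0-based half-open
   on the forward strand regardless of ORF strand, one unambiguous
   convention for all downstream bookkeeping.

2. **Secretion gate** (`predict_signal_peptide`, `detect_tm_builtin`,
   `passes_secretion_gate`). A protein passes iff its signal-peptide
   score is *strictly* greater than 0.9, the predicted cleavage site
   falls in residues 1–30, and no transmembrane segment survives in the
   mature region. The strict inequality is deliberate; the gate is
   reproduced exactly at its boundaries in the tests (0.9 fails,
   cleavage 30 passes, 31 fails). Scores can come from parsed external
   predictor reports (`read_predictor_report`, in compact
   signal-peptide and topology dialects) or from built-in heuristics.
   The built-ins are *not* reimplementations of the published
   HMM-based predictors and claim no equivalence; they are fully
   specified, deterministic stand-ins that make the pipeline buildable
   and testable without licensed binaries:

   * signal-peptide score = product of three sub-scores in [0, 1]:
     n-region charge (count of K/R minus D/E in residues 1–5 through a
     logistic centred at +1, slope 2.5 — calibrated so that a typical
     di-basic n-region can clear the 0.9 product bound when the other
     two sub-scores saturate, while a net charge of +1 or less cannot);
     h-region hydrophobicity (max mean Kyte–Doolittle hydropathy over
     8-residue windows in residues 3–25, rescaled 1.6 → 0.5, 3.0 → 1.0,
     clamped); and the classic (−3,−1) small-residue cleavage rule over
     candidate sites 16–30 (both small 1.0 / one 0.6 / none 0.2, ties
     to the smallest site).
   * transmembrane detection: 19-residue windows over the *mature*
     region with mean Kyte–Doolittle hydropathy above 1.6 seed
     segments; overlapping seeds merge. Window 19 and threshold 1.6 are
     the classic membrane-helix conventions. Only segments ending
     strictly after the cleavage site count — signal peptides are
     themselves hydrophobic and must not self-trigger the filter.

3. **Redundancy clustering** (`cluster_redundant`). The same transcript
   appears in multiple reads, so candidates are counted once: an edge
   joins two gate-passing proteins when their local alignment shows
   >95% identity at E < 1e−10 over at least 80% of the shorter
   sequence, and clusters are the connected components (single
   linkage). The original procedure inspected alignments manually
   ("throughout most of the alignment"); the 80%-of-shorter coverage
   floor is our automated replacement for that judgment and is the
   single most consequential operationalization in the package — it is
   exposed in `pipeline_config()` and every accepted edge is returned
   with its statistics so decisions can be audited. The representative
   is the longest member (ties: lexicographically smallest id), which
   naturally prefers complete reads over truncated ones.

4. **Full-length assessment** (`assess_full_length`). Candidates are
   searched (translated protein-vs-six-frame, see below) against the
   *full* same-species EST collection. Criterion 1: at least two reads
   align over the candidate's entire length with its start methionine
   matched and a stop codon conserved immediately after the aligned
   end. Criterion 2: no supporting read shows an in-frame methionine
   upstream of the predicted start (scanning the read's frame
   translation upstream until a stop). Criterion 3: some other-species
   protein annotated full-length is hit over ≥ 90% of its length. The
   source procedure lists the criteria without a logical connective; we
   default to `criterion1 OR (criterion2 AND criterion3)` — direct
   within-species evidence suffices on its own, while the absence of an
   upstream start is only corroborating and needs the cross-species
   anchor — and expose `any` / `all` in the configuration.

5. **Polymorphism filter** (`polymorphism_filter`). A candidate is
   removed when its same-species EST alignments show *no* amino-acid
   variation at all and its best other-species mature-region alignment
   differs by at most one residue: a protein identical in every read
   and nearly identical across ~100 My of aphid divergence shows no
   sign of diversifying selection. Two operationalizations are ours:
   (i) only alignments at ≥ 90% identity count as same-gene evidence —
   without that floor, weak cross-hits between unrelated secreted
   proteins (which share signal-peptide-like N-termini) masquerade as
   "variation"; (ii) candidates with *no* other-species hit are kept
   only when same-species variation exists, matching the filter's
   diversifying-selection rationale. Orphan candidates are flagged in
   the output either way.

6. **Cross-species reconciliation** (`reconcile_cross_species`). The
   second species' library is mined with the same cascade (minus the
   polymorphism filter, which the original procedure applied to the
   focal species only). Candidates of the two species pairing at
   E < 1e−5 are "shared"; each unmatched other-species candidate is
   then searched against the focal species' full EST collection, and a
   hit EST whose overlapping ORF passes the secretion gate becomes an
   *added* focal-species candidate. Two guards are our design:
   additions may not be redundant with anything already evaluated and
   rejected (otherwise the polymorphism filter could be silently
   bypassed through the other species), and additions are themselves
   subjected to the polymorphism criterion.

7. **Annotation and report**. Candidates matching the gut EST library
   at E < 1e−15 are flagged (not removed) as possible cross-tissue
   contaminants; mature regions are scanned for the chemosensory-
   protein cysteine spacing C-x6-C-x18-C-x2-C (`scan_csp_motif`); names
   are assigned serially per species (Mp1, Mp2, …) with historically
   established names supplied as an explicit mapping — the historical
   numbering encodes curation history that cannot be derived from the
   data. The stage-by-stage `funnel_report` records every count;
   filter stages can only shrink it, and the cross-species addition
   stage is the only one allowed to grow it.

## Alignment machinery

All similarity searches are exhaustive optimal local alignments
(Smith–Waterman with affine gaps, BLOSUM62, gap open 11 / extend 1 — the
standard protein-search defaults), computed by the C aligner in
Biostrings behind the package's `align_local()` /
`translated_search()` surface. At the scale of these datasets (at most
thousands of proteins) exhaustive alignment is tractable and removes
both heuristic seeding artifacts and an external binary. Significance
uses the Karlin–Altschul form `E = K m n exp(−λ S)` with the published
gapped-BLOSUM62 constants (λ = 0.267, K = 0.041). This surrogate
carries the *semantics* of the conventional E-value thresholds
(1e−5 / 1e−10 / 1e−15) rather than reproducing any particular
search engine's numbers, which is why every threshold is configurable.
Percent identity is computed over all alignment columns including gaps
(the conservative denominator), and coverage as aligned span over full
sequence length. `translated_search()` aligns a protein against all six
frame translations of a nucleotide subject with stops rendered as a
sentinel residue scoring −4 against everything, and uses the subject's
nucleotide length as the E-value search space. Tie-breaking among
equal-scoring tracebacks follows the aligner's fixed deterministic
convention, so identical inputs always give identical output; optimal
scores, which the test oracles pin, are unaffected by the convention.

## Assay statistics

The leaf-disc fecundity assay places 4 first-instar nymphs per well,
counts adults on days 6, 12 and 14 and newly produced nymphs on days
12, 14 and 17. The per-well statistic chains the interval production
rates, `R = N12/A6 + N14/A12 + N17/A14` (`production_rate`). R is
computed per well and then averaged per construct; the source
description admits either per-well or per-day averaging, and we attach
the rule to the well because that is where the first ratio is defined
(the per-day alternative would change only degenerate cases). Wells
whose denominator is zero at any count day are excluded — this covers
the stated all-four-died rule and extends it to deaths after day 6,
where the statistic is undefined anyway.

The initial screen flags a construct whose mean differs from the
empty-vector control by at least one standard error
(`initial_screen`). Whose SE is unspecified in the source; we default
to the candidate's own (the screen figure's error bars are
per-construct) with control/pooled variants available. Confirmation
testing uses a blocked one-way ANOVA (`blocked_anova`: construct as
treatment, replicate experiment as block, classic sequential sums of
squares with the block fitted first, F for treatment against residual).
The ROS assay takes each disc's maximum photon count over time,
averages the 8 discs per construct, and compares constructs to the
control with a Welch two-sample t-test (`ros_summary`) — Welch because
nothing justifies assuming equal variances across constructs.

## The synthetic benchmark

`simulate_library()` generates ground-truth-labelled inputs for every
stage. Implanted protein classes: *true candidates* (signal peptide
constructed to score > 0.9 under the built-in heuristic's own formula:
basic n-region, 8–12 residue L/I/V h-region, small residues at −1/−3
of the cleavage site), *TM decoys* (the same plus a 21-residue poly-Leu
helix near the start of the mature region, where read truncation cannot
remove it), *non-secreted decoys* (acidic N-terminus), and
*monomorphic decoys* (no within-species variation, ortholog differing
by exactly one mature residue — exactly the profile the polymorphism
filter exists to remove). Each protein is back-translated with a fixed
codon table, flanked by 40/120-nt UTRs, copied 3× into the salivary
library with 2 mature substitutions per extra copy (none for
monomorphic decoys), truncated with probability 0.3 (uniformly 10–50%
off one end), and reverse-complemented with probability 0.5. The full
whole-species collection carries 2 additional whole-body copies per
protein plus extra background — the real all-species collection is
many times the salivary library and re-samples the same transcripts,
and criterion 1 of the full-length rule depends on that depth. 60% of
true candidates receive an ortholog in the second species at 15%
mature divergence (most, but not all, focal-species proteins have a
detectable pea-aphid homolog). Background reads are random nucleotide
strings exercising the ORF-length gate stochastically.

Deliberate simplifications, and what they imply: UTRs are drawn from
A/C/T only, so no spurious upstream in-frame start can shadow an
implanted ORF — real 5' UTRs can and do contain ATGs, and the
longest-ORF convention would then pick the wrong start; back-translation
uses one codon per residue (no codon-usage model), which is irrelevant
to every stage except start/stop placement; there is no
sequencing-error model, no transcript-abundance model, and divergence
is uniform rather than phylogenetically calibrated. Passing the
benchmark therefore demonstrates that the cascade's logic is correct
under its own assumptions, not that the built-in predictors match the
published HMM predictors on real sequence — real reproductions should
feed parsed external reports, which the generator also emits (computed
with the built-ins) so that code path is exercised end to end.

`simulate_plate()` draws adult survival as independent per-interval
coin flips (default death probability 0.05 per adult per interval) and
nymph counts as Poisson with mean = surviving adults × baseline ×
construct multiplier, so `E[R] = 3 × baseline × multiplier` exactly and
recovery of implanted multipliers is a sharp test. `simulate_ros()`
uses a smooth unimodal curve (peak at 20 min) scaled per group with
truncated Gaussian noise per time point; under no suppression the two
groups are exchangeable and the Welch p-values are uniform, which the
tests verify by Kolmogorov–Smirnov.

### The screen simulation's design

The one-SE screen is *intentionally liberal* — in the original study it
passed 14 of 48 candidates forward, of which 3 confirmed. Our benchmark
design reflects two facts about such screens. First, the implanted
"real" effect is 1.5 within-construct (per-well) standard deviations —
a strong biological effect on the raw measurement scale. Effects
measured in units of the standard error of an 18-well *mean* cannot be
flagged reliably by a 1-SE rule at all: the difference of two
construct means carries at least one SE of noise itself, so a 1.5-SE
shift is flagged barely more than half the time no matter how the rule
is tuned. Second, the empty-vector control is assayed alongside every
batch of the screen, so its mean is estimated from a pool an order of
magnitude deeper than any candidate (216 wells in the benchmark); with
a noisy same-size control the rule's null flag rate would rise from
the nominal `2Φ(−1) ≈ 32%` towards 48%. Under this design the
benchmark verifies both operating characteristics: ≥ 90% of implanted
effects flagged, and roughly a third of null constructs flagged — the
liberality is the point, and the blocked ANOVA is the confirmatory
stage that controls it.

## Numerical and scale choices

Problem sizes in the tests and the acceptance script are chosen to
exercise every stage at desk scale: 1000 random sequences against the
brute-force ORF oracle; 200 random peptide pairs (length ≤ 8) against
exhaustive alignment maximization, with the dynamic-programming oracle
itself validated by true path enumeration at tiny lengths; 10 seeds ×
(20 true + 30 decoy proteins, multiplicity 3) for end-to-end recovery;
10^4 simulated wells for the null mean of R; 1000 null screens for
ANOVA type-I calibration; 500 screens for the one-SE rule's operating
characteristics. Determinism is enforced throughout: generators save
and restore the caller's RNG state and are pure functions of their
seed; the pipeline is deterministic given its inputs, so funnel reports
are byte-identical across repeated runs.

## Known limitations

* The built-in signal-peptide and topology scores are transparent
  heuristics, not the published HMM predictors; on real ESTs their
  false-positive and false-negative profiles will differ, and the
  parsed-report path is the intended route for real data.
* The E-value surrogate approximates conventional search-engine
  E-values; thresholds near a decision boundary on real data warrant
  the sensitivity analysis the configuration makes possible.
* Coverage-based operationalizations ("throughout most of the
  alignment" → 80% of the shorter sequence; mature-region identity
  floor 90%) replace manual alignment inspection and are the settings
  most worth revisiting on real libraries.
* The historical candidate numbering of the original screen (gaps at
  Mp13, Mp18, …) is supported only through an explicit legacy-name
  mapping, never inferred.
* No multiple-testing correction is applied across a screen's
  candidates (the original analysis applied none; raw p-values are
  reported).
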