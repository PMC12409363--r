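---
title: "Methods: models, parameters and design choices in trnanick"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in trnanick}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnanick)
```

## The problem

Anticodon nucleases of bacterial anti-phage defence systems, such as the
AriB Toprim effector of PARIS, inactivate translation by nicking specific
host tRNAs in the anticodon stem, between canonical positions 40 and 41.
Characterizing such an enzyme computationally involves four read-outs, each
implemented here as a module:

1. **Depletion**: full-length copies of target tRNAs disappear from a
   sequenced tRNA pool after nuclease activation.
2. **Cleavage mapping**: 5′ ends of small tRNA fragments pile up at the
   nick position in RNA-end-ligated libraries.
3. **Mass signatures**: an RNase T1 digest of a nicked versus intact
   transcript shifts a site-spanning product into two smaller products with
   diagnostic terminal chemistries.
4. **Toeprints**: ribosomes stall at codons whose cognate tRNA has been
   depleted, which a reverse-transcriptase extension assay reads out 13–14
   nt downstream of the A-site first base.

## Canonical coordinates

All biology is stated in canonical (Sprinzl-style) tRNA coordinates:
anticodon at 34–36, anticodon stem 27–31/39–43, loop 32–38, D-loop 14–21,
T-loop 54–60. Labels are text (`"17a"` is a legal position), ordered by a
fixed 76-label template with insertion slots in the D-loop (`17a`, `20a`,
`20b`) and variable loop (`e1`–`e5`). Automatic numbering is attempted only
for 74–78 nt sequences: a 76-mer maps label *i* to residue *i*; deviations
of ±1–2 nt are absorbed by deleting labels 17/20 or inserting 17a/20a in the
D-loop, the region where length variation among class-I tRNAs
concentrates. Anything else (class-II tRNAs with long variable arms) needs
an explicit sidecar map (`index0` → `label`), because arm architecture is
not inferable from length. Internally all arithmetic is 0-based half-open;
canonical labels appear only at reporting boundaries, so there is exactly
one conversion point.

## The packaged fixtures are reconstructions

The package ships sequences for the four *E. coli* nuclease targets
(Lys-UUU, Thr-UGU, Asn-GUU, Thr-CGU), a non-target Phe-GAA control and
three phage T5 escape variants, plus a modification table. These are
**synthetic reconstructions**, built to be jointly consistent with the
documented biology rather than copies of any database entry:

* site hexamers at 36–41: `UAAUCA` (Lys and Thr-UGU), `UAAUCC` (Asn),
  `UAAUGC` (Thr-CGU), all sharing the conserved `UAAU` at 36–39;
* the T5 Lys variant carries Mut1 (U39→A), Mut2 (A41→C) and the D-loop
  substitution Mut3 (U16→C), giving `UAAACC` at the site, plus two distal
  substitutions;
* a T1 digest of the Lys transcript yields a 14-nt product spanning the
  40|41 site (`ACUUUUAAUCAAUG`, positions 31–44), which the nick splits
  into 10 + 4 nt;
* the modification table gives Lys-UUU 10 modified positions of 7 distinct
  types, and 13 distinct types over the union of the four targets. The
  "13" is counted as distinct modification *types* across the union; the
  per-position placement (s4U8, D-loop dihydrouridines, wobble-34
  derivatives, position-37 adenosine hyper-modifications, Ψ39/Ψ55, m7G46,
  m5U54) follows the usual *E. coli* landscape, and the named set includes
  Ψ39, Ψ55, ct6A37 and mnm5s2U34. Mass deltas are plausible average-mass
  values; transcript-mode digests ignore them entirely.

Because the fixtures are reconstructions, tests against them validate the
*machinery* (coordinate handling, scanning, digestion, annotation), not the
identity of any natural sequence.

## Read simulation

`simulate_pool()` draws each read's tRNA from fixed abundance weights
(weights are not resampled, so expected counts are analytic and power
checks reproducible), applies a per-tRNA Bernoulli nick at a configured
between-label site, picks one of the two fragments of a nicked molecule
with equal probability, and sequences it under one of two protocol models:

* **Protocol A** (cDNA-adapter, default 150 nt paired): the apparent 5′
  end is the reverse-transcriptase stall point. Scanning modified positions
  from the fragment 3′ end towards 5′, each fires independently with
  `stall_prob`; the first that fires truncates the read immediately 3′ of
  itself. Stalling is modelled purely as truncation — no misincorporation
  or read-through mutations — because the assay reads stalls only as a
  length artefact. Stall rates per modification are free parameters, not
  measured quantities; the default 0.5 is a deliberate caricature that
  makes the protocol-A confound visible in simulations.
* **Protocol B** (RNA-end-ligated, default 50 nt single-end): the read 5′
  end is the true RNA 5′ end.

Substitution errors are applied per base at `error_rate` (default 1e-3);
there are no indels, no quality modelling and no ligation bias. Mate 2 in
paired mode is the reverse complement of the 3′-most `read_length` of the
fragment; adapters are never inserted (reads model pre-trimmed data).
All randomness derives from the integer seed in the spec; identical spec
and seed give byte-identical FASTQ and truth files.

A useful emergent property: under protocol A, stalls at anticodon-loop
modifications (e.g. position 37) generate truncated reads whose 5′ ends
fall inside the anticodon stem–loop window — exactly the artefact that
makes cleavage products hard to see in stall-limited libraries and
motivates the two-protocol design. Under protocol B, fragment 5′ ends are
faithful, so nick calling uses protocol B data.

## Mapping and classification

The built-in mapper does exact k-mer seeding with ungapped extension,
allowing `max_mismatch` substitutions (default 2) and no indels: tRNA
references are ~76 nt, and the load-bearing semantics is the uniqueness
rule, not gapped alignment. Seeds are taken at `max_mismatch + 1` disjoint
offsets with `k = floor(L / (max_mismatch + 1))` (capped at 20), so by
pigeonhole any placement within the mismatch budget has at least one exact
seed — the mapper is provably equivalent to brute-force scanning, and the
test suite checks this against an independent exhaustive oracle. Reads are
sense-strand (both library protocols are directional). Reads whose best
score ties across distinct tRNAs are dropped under `unique_only`; ties
within one tRNA keep the leftmost placement and remain unique. Reads
shorter than 15 nt are left unmapped. External aligners interoperate via
plain-text SAM import, with uniqueness inferred from equal-scoring
secondary alignments.

Classification thresholds follow the two library designs: full-length
proxies are spans ≥ 65 nt (appropriate for 150-nt libraries), anticodon
fragments are spans < 45 nt whose 5′-most residue lies at canonical
positions 27–43. Both are arguments, and for 50-nt protocol-B data the
full-length threshold must be protocol-adapted: no 50-nt read can span
65 nt, but a read running the entire read length can only derive from a
molecule intact past position 50, so `min_full = 45` (just under the read
length) is the analogous proxy. The packaged analyses use exactly that
adaptation for 50-nt pools.

## Depletion regression

Abundances are counts per million over the counted class (CPM sums to 1e6
whenever any read is counted; the normalization unit is an artifact choice,
documented as such). Depletion fits
`log10(treated + 0.5) ~ log10(control + 0.5)` by OLS — the 0.5-CPM
pseudo-count admits zero counts — and flags tRNAs whose residual falls
below −k·MAD (k = 3 by default, `stats::mad` with its standard consistency
constant). The underlying experiment identifies targets visually on the
scatter; the MAD rule is this package's explicit, config-exposed
formalization. The response/predictor orientation (treated on control) is
likewise an artifact choice. A strict `1e-9` guard on the threshold keeps
numerically-zero residual spreads (identical samples) from flagging
anything.

## Nick calling

A nick between positions p and p+1 is evidenced by fragment 5′ ends at
p+1; 3′-end pileups are computed but not required, since protocol-A
truncation corrupts apparent 3′ ends. The score is
`log2((f_t + ε)/(f_c + ε))` with per-tRNA fractions and `ε = 1/(total+1)`
keeping scores finite. Calls need treated fraction ≥ 0.05 and score ≥ 1,
inside the 27–43 window; results sort by score, ties to the smaller
position. Two degenerate-control rules matter in practice: with no control
sample at all, and equally for any tRNA with *zero* control fragment
reads, the control fraction falls back to the uniform in-window expectation
(1/17 for the default window). A clean un-nicked control typically has no
fragment-class reads whatsoever, and an `ε` of 1 for such tRNAs would
drive every score negative and make calling impossible; the uniform
fallback treats "no information" as "no positional preference", which is
the intended null. No p-values or FDR are attached — positional evidence
is reported, and direct versus indirect products (e.g. stress-induced
fragments of non-target tRNAs) are not distinguished.

Consensus scanning is anchored at label 36 by default because the site is
positionally defined; unanchored mode slides the consensus for exploratory
use. The predicted nick falls between the 5th and 6th matched residues.
Note the motif degeneracy of the natural targets: relative to `UAAUCA`,
the Asn site differs at one position (41) and the Thr-CGU site at two
(40 and 41), so anchored scans recover Lys/Thr-UGU/Asn at one allowed
mismatch but Thr-CGU only at two — mirroring its weaker cleavage.

## Mass model

Masses are average atomic masses by default (linear-mode MALDI measures
average MH⁺); a monoisotopic switch exists. The neutral mass of an oligo
with 5′-P/3′-OH termini is Σ(nucleoside-5′-monophosphate) − (n−1)·H₂O;
terminal chemistries are adjustments against that baseline (5′-OH −HPO₃,
5′-PPP +2·HPO₃, 3′-P +HPO₃, 3′-cP +HPO₃−H₂O). The test suite checks the
implementation against an independent oracle that assembles the same
molecules from nucleoside compositions plus explicit phosphodiester bonds,
to 0.01 Da on 500 random oligos. Conservation identities hold exactly in
formula terms: a hydrolytic nick adds one water; each T1 cut adds one
water in linear-phosphate mode and none in cyclic mode; ring-opening a
2′,3′-cyclic phosphate adds one water.

T1 products default to *linear* 3′-phosphate with a cyclic switch, since
both species occur experimentally and the read-out does not dictate one.
Transcript digests default to a 5′-triphosphate parent and ignore
modification deltas (in-vitro transcripts are unmodified); extracted-tRNA
digests can apply the modification table as position-wise average-mass
deltas. Peak matching assigns each observed m/z to the nearest prediction
within 1 Da and flags one-to-many collisions as ambiguous. Observed
fragment masses from the motivating experiments are not shipped; matching
is validated against self-predictions and the oracle.

## Toeprint model

A codon is depleted or not — no kinetics, no partial depletion — because
the assay is read qualitatively per codon. The first in-frame depleted
codon at or after the start becomes the A-site codon; the toeprint is
reported as the offset *pair* {13, 14} nt downstream of the A-site first
base, and consumers use the union window (±2 slack by default). The
initiation control places the A-site first base at the start codon index
with the same offsets — a documented simplification, since the exact
A-site geometry of an initiation-arrested ribosome is not specified by the
assay description. The packaged template is a reconstructed stand-in
(AUG, AAA at codon 5, ACA at codon 8, alanine codons, stop), not the
published template; its arrangement reproduces the qualitative progression:
depleting {AAA} stalls at AAA, mutating AAA to GCA and depleting
{AAA, ACA} moves the stall to ACA, mutating both removes it. Trace
quantification is plain trapezoidal integration of the piecewise-linear
electropherogram within windows, with edge interpolation.

## Problem sizes and determinism

The simulation-based checks run 20 replicate pools of 50 000 protocol-B
reads over 40 references (4 targets + 36 generated decoys; decoy hexamers
are kept ≥ 2 mismatches from the consensus so they are genuine negatives)
with nick probabilities 0.9/0.7/0.3 on Lys/Thr-UGU/Asn and log-normal
abundance skew (σ = 0.5, a ~5-fold typical spread). At these sizes every
replicate recovers all three nick positions exactly with no in-window
false positives, and the depletion flag always includes Lys and Thr-UGU;
Asn's residual is negative but, at a 0.3 nick probability, sits near the
flag boundary — which is the expected behaviour for a weak target. All
stochastic components consume an explicit integer seed and restore the
caller's RNG state, so results are platform-stably reproducible.

## What passing tests do and do not show

The simulator emulates protocol-dependent end biases, RT stalling,
abundance skew and substitution error, but not ligation bias, indels,
quality degradation, rRNA contamination or isodecoder families beyond
exact twins. Success on simulated pools therefore demonstrates that the
statistical machinery recovers truth under its own generative assumptions;
it does not certify performance on real libraries, where multi-mapping
among near-identical isodecoders and end-repair artefacts are harsher.
The package deliberately omits multi-mapping rescue/EM reallocation,
covariance-model gene finding, secondary-structure prediction, isotope
envelopes and MS/MS fragment ions.
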