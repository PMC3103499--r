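---
title: "Discovering common cis-regulatory modules in gene batteries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering common cis-regulatory modules in gene batteries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmbattery)
```

## The problem and the model

Transcription in higher eukaryotes is combinatorial: transcription
factors (TFs) act through clusters of binding sites — cis-regulatory
modules (CRMs) — on proximal promoters, not through isolated sites.
`crmbattery` searches for CRMs that are *common* to a **gene battery**,
a set of genes that are both coexpressed (same temporal expression
pattern) and functionally coherent (same pathway), under the hypothesis
that such genes are the ones likely to share a regulatory program.
Coexpression alone or pathway membership alone is deliberately not
enough; the battery is the intersection.

A promoter is represented as a **promoter profile**: the
position-sorted list of its oriented TF-family binding sites, each a
`(factor, position, orientation)` record with an inclusive extent, plus
a hash-style index from the oriented key (e.g. `+ETSF`, `-PAX6`) to the
site start positions. Sequence is discarded at this point; every
downstream question — "is this site here?", "is this module here?" —
is answered from the profile. A gene holds `K_i >= 1` alternative
promoter profiles.

A **CRM** is an ordered list of `M` oriented elements, written
`+NFKB__-CREB__-SP1F`. An *instance* on a promoter is a selection of
distinct sites matching the elements in order, each site starting
strictly after the previous one ends (non-overlap). There is **no
distance or window parameter**: a gap of ten or three hundred bases is
treated identically, because spacing can vary without functional
consequence. Geometry enters only through the post-hoc length band
described below. Repeated factors within a module are allowed
(`+E2FF__+MOKF__-E2FF`), but instance sites must be distinct.

## The alternative-promoter heuristic

Most mammalian genes have several alternative promoters, and which one
is active is usually unknown. Evaluating a battery over every
combination of promoter choices costs `prod(K_i)` searches. The
package instead uses the presence heuristic: *a module present on any
promoter of a gene is present for the gene*, and the gene-level
instance length is the minimum span over all instances on all
promoters. One search replaces the exponential sweep.

At the presence level this is exact: the set of common modules found
heuristically equals the union of the common-module sets over all
promoter combinations (for any module common in some combination, each
supporting gene has a carrying promoter, so the heuristic counts it;
conversely the heuristic's support is attained by picking a carrying
promoter per gene). The acceptance suite verifies this equality on 200
random instances against a brute-force sweep.

One caveat the package documents rather than hides: the equivalence is
a statement about **presence**, not about the length band. Because the
heuristic takes the *minimum* span per gene, a gene whose shortest
instance falls outside the band may have a longer instance on another
promoter that would fall inside it under some promoter combination.
With the band enabled the heuristic is therefore a deliberate,
deterministic policy (minimal spans), not a theorem; the lemma test
runs with the band disabled, and a constructed counterexample in the
unit tests pins down the distinction.

## Search, support, and the length band

For a battery of `N` genes with support fraction `delta` (default 0.7),
a module needs `required_support(N, delta) = ceiling(delta * N)`
supporting genes. The ceiling is computed with a small numeric guard so
that decimal products like `0.7 * 10 = 7` do not round up to 8 under
binary floating point. Consecutive sizes can share a requirement
(sizes 6 and 7 both need 5).

The search is breadth-first over ordered tuples of the battery's
*common oriented keys* (those present, gene-level, in at least the
required number of genes), sizes 2–4 by default. Raw gene-level
presence is anti-monotone under tuple extension, so a tuple whose raw
support drops below the requirement is pruned together with all its
extensions; the band-filtered count is *not* anti-monotone and is never
used for pruning.

Each candidate is then evaluated: per-gene minimal spans are collected,
their mean is the module's average length, and only instances with
span in `[0.5 * avg, 2 * avg]` (half-to-double) count toward support.
The average is computed once, before the filter — the description is
sequential, and re-averaging after exclusion would make the support set
definition circular. `avg/min/max` lengths are reported over all genes
with any instance. A gene contributes at most once regardless of how
many instances it carries.

Minimal spans are found by a greedy argument: for a fixed first site,
choosing at each subsequent element the feasible site with the smallest
end minimizes the final end (the only state the remaining elements see
is the running end), hence the span for that first site; the instance
returned is the minimum over first sites, ties broken toward the most
upstream first site, then lexicographic promoter id. The greedy matcher
is verified against a brute-force enumeration oracle in the tests, and
the compiled batch kernel against the reference R matcher.

## Significance and calibration

A module common in a battery may be common everywhere. Each common CRM
is scored against a background set of `B` genes (5,000 in the reference
setting) with the hypergeometric upper tail
`P(X >= n)`, `X ~ Hypergeom(B, b, N)`, computed in log space. Here `n`
is the band-filtered support (the number the common level reports) and
`b` is the *raw* background presence count: the battery-specific band
is not meaningful genome-wide, and presence-on-any-promoter is what the
background profiles answer directly. Battery genes need not be part of
the background; if `n > b` the upper tail is an empty sum and the
p-value is exactly 0. Filtering is strictly `p < threshold`.

Because a fixed threshold behaves very differently across battery
sizes, thresholds are calibrated by randomization: for each size `N`
(4–20 by default), draw `reps` random `N`-gene sets from the
background, run the full search, score every common CRM, record the
minimum p-value (1.0 when nothing is found — conservative, and it keeps
replicates comparable), and set the threshold to the mean of the
minima. From `N = 14` up a single floor threshold of 0.01 is used. The
reference procedure smooths the empirical curve by eye; the package
exposes the raw means plus the floor rule and accepts a user-supplied
table instead of inventing a smoother. RNG substreams are derived
deterministically per `(N, rep)`, so parallel or reordered execution
reproduces serial results exactly.

One property sometimes expected of this calibration — that a
*structured* background (many genes sharing planted sites) yields
larger thresholds than an i.i.d. background of equal site density — is
**not** robustly true, and the package does not assert it. In seeded
experiments the min-p statistic is dominated by fluke modules, and
structure amplifies flukes: when planted keys occur in every gene,
random draws keep producing reordered variants with small background
counts and hence small p-values, while the planted module itself has
`b ~ B` and `p ~ 1`. What is true, and tested, is the module-level
direction: a genome-wide shared module scored against its own
background is never significant, while the same support against an
equal-density i.i.d. background is.

## Batteries and TF inference

Batteries are built by crossing expression-pattern assignments (an
input — pattern discovery itself is out of scope) with pathway gene
sets (GMT): each (pattern, pathway) pair whose hypergeometric
enrichment beats `alpha = 0.05` contributes its overlap as a battery.
The enrichment universe defaults to the genes of the expression dataset
that carry pathway annotation — the standard conservative choice; it
is configurable. Literature-based pathway selection is irreproducible
computationally and is modeled as an optional allowlist, not a
heuristic. Batteries below 4 genes (the calibration range start) are
dropped with a warning.

Significant CRMs are decomposed into TF families with orientation
stripped (`+E2FF` and `-E2FF` are one factor, as TF tables convention-
ally list family names without strand). A factor counts once per
battery however many CRMs contain it; factors appearing in at least
`min_batteries = 3` batteries are reported as critical. The edge list
(factor x battery gene, annotated with pattern and pathway) is the
flat-file form of the regulatory network figures such analyses draw.

## The synthetic world

Every stage is testable without external data through seeded
generators with truth records. Their defaults are fixed once:

* background size `B = 5000`; promoter region −500..+100 relative to
  the TSS (the reference default promoter length); `K_i` uniform on
  1..4 alternative promoters (gene-battery promoter counts in the
  reference setting average ≈3 promoters per gene, e.g. 27 promoters
  over 8 genes);
* decoy sites: Poisson count per promoter with mean 8, positions
  uniform, orientations fair-coin, width 12 bp, vocabulary the 34
  inflammation-relevant TF family names. This density is deliberately
  far below a real matrix-scanner's output (hundreds of matches per
  promoter) so that desk-scale calibrations finish in seconds; it
  changes the absolute threshold values, which the package never
  claims to reproduce, not the mechanics;
* planted modules: default `+AP4R__-GATA__-HEAT` in a battery of
  `N = 8` at fraction 0.75 — the reference battery arithmetic
  (`8 * 0.75 = 6` carriers, exactly the round-up requirement at
  `delta = 0.7`); inter-site gaps i.i.d. uniform on 20..50 bp, which
  keeps planted instances inside the half-to-double band *by
  construction* (span ratio ≤ 1.8); span dispersion beyond the band is
  exercised through an explicit per-carrier `gap_sampler` hook;
* background leak: 1% of background genes also carry the first planted
  module, so background hit counts are non-trivial;
* planted instances never coincide exactly with a decoy record
  (collisions are redrawn), keeping truth records unambiguous.

What a green test establishes, and what it does not: the generators
emulate the *statistical structure* the method assumes — i.i.d. decoy
sites, one planted instance per carrier, independent genes. Real
promoter annotations have correlated site families, positional biases
toward the TSS, and shared regulatory architecture between paralogs;
none of that is modeled, so green tests certify the algorithmic
contracts (presence logic, band arithmetic, calibration reproducibility,
recovery of planted structure), not biological recall. In a zero-decoy
world every ordered subsequence of a planted module is necessarily
present and common, so "only planted modules are significant" is
formalized as "every significant module is an ordered subsequence of
its battery's planted module".

## Numerical and degenerate-input choices

* `ceiling(delta * N - 1e-9)` for the support requirement (decimal
  semantics under binary floating point).
* Hypergeometric tail via `lchoose` + log-sum-exp; exact 1.0 at
  `n = 0`; exact 0.0 when support exceeds background hits.
* Strict `<` against thresholds, so `p == alpha` is excluded.
* Ties in minimal-span instances: most upstream first site, then
  lexicographic promoter id; all outputs ordered by radix (C-locale)
  sort, so results are locale-independent.
* Empty promoters, empty batteries, site-free backgrounds and empty
  CRM sets are all representable and round-trip through the writers;
  a battery gene with no annotated site is a legitimate member that
  contributes no support.
* Exact duplicate site records are dropped at profile construction;
  overlapping same-factor sites at *near*-identical positions are all
  kept (no merging) — whether the original tooling merged them is
  unknowable from the description, and keeping records is lossless.
* Labels use ASCII `+`/`-`; the typographic minus (U+2212) found in
  printed tables is accepted on input and normalized.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `delta` | 0.7 | fraction of battery genes | the reference common-level threshold |
| `min/max_module_size` | 2 / 4 | sites | reported CRMs have 2–3 sites; 4 bounds the BFS |
| `length_band` | (0.5, 2) | × average span | the half-to-double rule |
| `sizes` | 4..20 | genes | calibration range |
| `reps` | 100 | draws per size | reference calibration; tests scale to 25 |
| `floor_size`, `floor_threshold` | 14, 0.01 | genes, p-value | single threshold from N = 14 up |
| `alpha` (fixed) | 1e-4 | p-value | classical single-threshold variant |
| `min_batteries` | 3 | batteries | critical-TF frequency rule |

## Known limitations

* Only proximal promoters are modeled; factors acting from distal
  enhancers (the classical P53-in-apoptosis case) are invisible by
  construction.
* Modules are strictly ordered and oriented; order-free module models
  are out of scope.
* The calibration's absolute thresholds depend on the site density of
  the background profiles; with sparse synthetic decoys most random
  draws find no common CRM and thresholds sit near 1.0. Only the
  contract (reproducibility, floor, null behavior) is asserted.
* The optional PWM scanner is a generic log-odds scorer for building
  site tables from FASTA; it does not reproduce any proprietary
  matrix-similarity score.
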