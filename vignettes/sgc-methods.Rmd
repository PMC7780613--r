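---
title: "Modeling SCRaMbLE-based genome compaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling SCRaMbLE-based genome compaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgcompact)
```

## The system being modeled

Sc2.0 synthetic yeast chromosomes carry symmetric loxPsym sites at the 3'
end of most nonessential genes. Inducing Cre recombinase (SCRaMbLE)
recombines pairs of loxPsym sites, producing deletions, inversions and
duplications of the intervening DNA. Because loxPsym is palindromic, the
outcome of a pairing is not constrained by site orientation.

SCRaMbLE-based genome compaction (SGC) turns this into a directed
minimization tool: a URA3 reporter is integrated into the synthetic region,
cells are induced, and plating on 5-FOA selects exactly those cells that
deleted the reporter-carrying segment. Strains carrying an episomal
essential-gene array (eArray) can additionally delete chromosomal units
containing essential genes, because the episome supplies a second copy.
Iterating the procedure — integrate a reporter, SCRaMbLE, select, pick the
strain with the most sequence deleted, repeat — compacts the chromosome arm
step by step.

`sgcompact` models the whole loop at the level of loxPsym units (LUs): the
segments between adjacent loxPsym sites, which are the atoms of
rearrangement. Sequence is carried along only so that strain structures can
be verified from exact contigs and in-silico PCRtags.

## The chromosome model

A `synthetic_chromosome` is an ordered list of LUs with lengths, genes
located by LU-relative coordinates, a centromere, and optional per-LU
sequence. Absolute coordinates are derived by interleaving 34-bp loxPsym
sites: one before every LU and one after the last, so both terminal LUs are
recombination-competent. Two conventions matter downstream:

* Coordinates are 0-based half-open internally; GFF3 I/O converts to
  1-based closed form.
* LU length accounting excludes the 34-bp sites. All deleted-sequence
  statistics are sums of LU lengths, so they do not depend on how many
  junction sites a rearranged molecule retains.

Gene essentiality is one of `essential`, `quasi_essential`, `nonessential`.
Quasi-essential genes (MMM1, RTT109) do not protect their LU from deletion
— their loss is viable — but any strain missing one is flagged
`slow_growth`. In the published totals the two quasi-essential genes are
counted among the 65 nonessential genes, and `lu_stats()` follows that
convention (`n_nonessential` includes them; `n_quasi` reports them
separately). Condition-specific requirements (for example growth at 37 °C
or on glycerol) are modeled as annotation tags that only matter when the
matching condition is active during selection; the default condition
imposes none.

## The synthetic fixture

The package ships no data files; `make_synxiil_fixture()` generates a
synXIIL-like arm from a seed. All published summary statistics are pinned:
46 LUs totalling exactly 170,000 bp of synthetic sequence, LU lengths
between 50 and 16,404 bp, 81 genes (16 essential / 65 nonessential), 9 LUs
carrying at least one essential gene, at most 8 genes in one LU, the
centromere in LU-37, and the named gene placements (YLL054C in LU-8, SSA2
in LU-24, the GPI13 cluster in LU-20, the PRP19–GRC3–RIX7 and SFI1–ORC3
essential runs, and so on). The ten essential genes upstream of 140 kbp
group into seven eArray loci; the remaining six sit in LU-38..LU-40 beyond
the cutoff and act as internal controls.

Only the lengths of the unpinned LUs and the random sequence depend on the
seed: lengths are drawn from a truncated log-normal (meanlog log 2600,
sdlog 0.45, truncated to 0.8–7 kbp) and rescaled to hit the 170-kbp total
exactly, with the rounding remainder absorbed by the largest unpinned unit.
The generator verifies every pinned statistic after construction and fails
loudly rather than emit a fixture that drifted. What the fixture does *not*
reproduce is the true gene order and per-LU coordinates of the real arm
(they are not in the main text); tests passing on the fixture therefore
validate the bookkeeping and the selection logic, not coordinate-level
agreement with the real chromosome.

## Recombination and selection

A `chromosome_state` is an ordered list of signed segments separated by
surviving loxPsym sites (`sites = segments + 1` always). One Cre event
between sites *i* < *j*:

* **deletion** removes the segments and interior sites, leaving one hybrid
  junction site; the excised circle carries no centromere and is discarded
  (no marker rescue from circles);
* **inversion** reverses segment order and flips orientations, keeping both
  sites;
* **duplication** tandem-duplicates the block with one new junction site.

Populations are simulated per cell with a Poisson(λ) event count, λ = 2 by
default — the induction used in the experiments is a short pulse not
quantified per cell, and λ = 2 makes multi-event strains common without
letting event chains dominate. The event-type prior is
deletion 0.45 / inversion 0.45 / duplication 0.10, reflecting that
deletions and inversions dominate observed SCRaMbLE outcomes and
duplications are rare under selection. Translocations are out of scope: the
model is single-chromosome.

Viability requires every essential gene present on the chromosome or on the
eArray, and exactly one centromere (a duplication spanning the centromere
is scored dicentric and inviable — the data is silent here, so standard
yeast dosage logic is applied). 5-FOA selection additionally requires the
URA3 reporter to be absent. `enumerate_single_deletions()` is a brute-force
oracle over all site pairs used to cross-check the stochastic simulator
wherever they must agree.

## Proximity weights and CIDs

Deletion partners are not chosen uniformly: sites close in 3D recombine
preferentially, and observed deletion boundaries track chromosomal
interacting domains (CIDs). Three weight models are provided:

* `power_law`: w = (d + d0)^(−α) on the **current** linear separation,
  recomputed after every event;
* `hic_contact`: balanced Hi-C contact counts of the sites' reference
  origins (exact only for the first event on an unrearranged strain — after
  rearrangement the origin lookup is an approximation, which is why the
  distance models are the default);
* `cid_boost`: power law times β when both sites map into the same CID.

Hi-C handling is deliberately standard: triplet text in, ICE balancing by
square-root marginal scaling (tolerance 1e-5, at most 100 iterations, bins
below the 2nd coverage percentile masked), and insulation-score domain
calling (window 5 bins at the default 2-kbp bin size, bracketing the
2–10 kbp scale of yeast CIDs; boundary prominence ≥ 0.1 in log2 units).
The published analysis called domains with a different toolchain that is
not algorithmically specified; insulation scoring is this package's stated
stand-in, and the synthetic Hi-C generator plants block-boosted power-law
matrices so the caller can be validated exactly (planted boundaries are
recovered with precision = recall = 1 at zero noise).

### Calibration of the defaults

The default weight parameters (`default_weight_params()`: α = 1.34,
d0 = 500 bp, β = 3) were calibrated once, under the package's default
study conditions — fixture arm, URA3 split into LU-24, eArray present,
10⁴ cells, λ = 2, CIDs called from the synthetic matrix whose planted
domain spans LU-23..LU-27 — so that the median span of contiguous deleted
segments among 5-FOA-selected strains lands at the observed scale of about
7 kbp. They were then frozen; they are not refit per run. The simulated
span distribution is heavier-tailed than the observed one (its mean sits
above the observed 10 kbp), which is expected from a model whose only
locality mechanisms are distance decay and a single CID boost.

## Profiling and bookkeeping

`profile_from_state()` (or replaying an event log) gives per-LU copy
number, orientation and deletion status, with maximal runs of deleted
reference LUs merged into segments. `profile_from_sequence()` reconstructs
the same profile independently by greedy exact tiling of an error-free
contig with LU sequences in either orientation, separated by loxPsym
34-mers; on simulated strains the two must agree exactly, and this
equivalence is enforced in the tests. Real-read noise, assembly and SV
calling are out of scope — the simulation produces exact contigs.

In-silico PCRtags are one convergent primer pair internal to each LU
(units shorter than ~60 bp stay untagged, as in the real tag tables);
positivity is equivalent to LU presence, and inversions keep tags positive
because the amplicon is internal to the unit. Sequence-mode screening
searches both strands, so an inverted LU still amplifies.

The `compaction_ledger` records per round the deleted LUs, bp and genes,
and maintains retained totals against the original reference. Two
conventions: deleted bp are LU-length sums (sites excluded, as above), and
a gene that was replaced by the URA3 reporter still counts among "genes
deleted" when its LU is lost, because counting follows the reference gene
content. Sub-LUs from reporter integration (LU-24-a/b/c) are attributed to
their parent: the parent counts as deleted only when its last part goes.

`run_iterative()` chains rounds: the top strain (ranked by deleted bp,
ties broken by fewer non-deletion events, then id) is collapsed into the
next round's reference — inverted blocks are re-oriented, gene strands
flipped, and the reporter marker dropped if its LU was lost. A round with
zero survivors returns a structured "no colonies" result rather than an
error, because an empty plate is diagnostic (it is the expected outcome
when the reporter sits beside an uncomplemented essential gene) and the
iteration stops there with the ledger so far.

## Numerical and design choices

* Both flanks of the synthetic region carry loxPsym sites, so terminal LUs
  are deletable (terminal deletions are observed); a model variant without
  a distal flank site would simply make LU-46 undeletable.
* The fixture's chunk-split offsets for LU-24 (7300/9300) put the reporter
  in a 2-kbp middle sub-unit clear of all genes.
* Simulation sizes in the test-suite are 10²–10⁴ cells; 10⁴ cells with
  λ = 2 runs in well under a minute and gives a few hundred selected
  strains under the default conditions, enough for stable medians.
* Degenerate inputs error early: i = j site pairs, genes crossing sites,
  all-zero weight matrices, all-masked contact matrices, unreplayable
  event logs.

## Known limitations

* Synthetic lethality among nonessential genes is not modeled: any set of
  nonessential deletions is scored viable. This is a known simplification;
  the data show individual context-dependent requirements instead via
  condition tags.
* The hic_contact weight mode uses reference-origin contacts and is only
  exact for the first event on an unrearranged strain.
* Growth rates, competition and adaptive dynamics are out of scope; strains
  carry boolean slow-growth/conditional flags only.
* The fixture reproduces printed summary statistics, not the true
  coordinates of the real arm.
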