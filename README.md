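# sgcompact

In-silico SCRaMbLE-based genome compaction (SGC) of synthetic yeast
chromosome arms.

Sc2.0 synthetic chromosomes carry palindromic loxPsym sites after most
nonessential genes; inducing Cre recombinase (SCRaMbLE) deletes, inverts
and duplicates the loxPsym units (LUs) between them. SGC directs this
randomness toward genome minimization: a URA3 reporter is integrated into
the arm, cells are SCRaMbLEd, and 5-FOA counterselection keeps exactly the
cells that deleted the reporter-carrying region. An episomal essential-gene
array (eArray) extends the reach of deletion into LUs that contain
essential genes, and iterating the whole loop compacts the arm round by
round.

`sgcompact` is a simulation and bookkeeping toolkit for this workflow,
aimed at people designing SGC experiments or reasoning about their
outcomes:

* an LU-resolution chromosome model with GFF3 / TSV / FASTA I/O, reporter
  integration (including the split of one LU into `-a/-b/-c` sub-units)
  and eArray design by the flanked-locus rule;
* a Cre event engine (deletion / inversion / duplication over site pairs)
  with population simulation, viability + 5-FOA + eArray selection, and an
  exhaustive single-deletion oracle;
* Hi-C support: triplet I/O, ICE balancing, insulation-score CID calling,
  and recombination weight models `w = (d + d0)^(-alpha)` with optional
  same-CID boost — the closer two loxPsym sites are in 3D, the more likely
  they recombine;
* strain profiling from event logs or from exact contigs, in-silico PCRtag
  screens, and a per-round compaction ledger.

A seeded generator (`make_synxiil_fixture()`) builds a synXIIL-like arm
that reproduces the published summary statistics (46 LUs / 170 kbp / 81
genes, 16 of them essential in 9 LUs / LU lengths 50–16,404 bp), so the
whole pipeline runs with no external data.

## Worked example

```r
library(sgcompact)

chrom <- make_synxiil_fixture(seed = 1)
unlist(lu_stats(chrom))[1:5]
#>           n_lus n_essential_lus         n_genes     n_essential  n_nonessential
#>              46               9              81              16              65

# eArray: essential genes from the first 140 kbp, grouped into loci
ea <- build_earray(chrom, 140000)
ea
#> eArray: 10 essential genes across 7 loci (marker HIS3)

# URA3 beside the essential gene GPI13: nothing survives 5-FOA without
# the eArray, plenty does with it
c20 <- integrate_ura3(chrom, "LU-20", "insert_between",
                      between = c("GPI13", "YLL032C"))
nrow(enumerate_single_deletions(c20, earray_present = FALSE))
#> [1] 0
nrow(enumerate_single_deletions(c20, earray = ea, earray_present = TRUE))
#> [1] 340

# one simulated SGC round: URA3 split into LU-24, CID-boosted weights
c24 <- integrate_ura3(chrom, "LU-24", "chunk_split",
                      offsets = synxiil_chunk_offsets())
hic <- make_synthetic_hic(86, 2000, boundaries = lu_cid_boundaries(c24))
cids <- insulation_cids(ice_balance(hic))
pop <- simulate_population(c24, 2000, model = "cid_boost", cids = cids,
                           episomes = "eArray", seed = 1)
surv <- select_population(pop, earray = build_earray(c24, 140000),
                          medium = "5FOA")
prof <- profile_from_state(surv[[1]])
compaction_stats(prof, c24)[1:3]
```

The first block prints the arm summary (46 units, 9 essential-flagged, 81
genes); the enumeration counts show the eArray dependency of deleting an
essential-gene LU; the final call reports how many LUs, bp and genes the
first selected strain lost.

A thin command-line front end is installed at
`system.file("cli", "sgc.R", package = "sgcompact")` with `fixture`,
`stats`, `cids` and `simulate` subcommands.

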