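# footloop

Transcription-factor footprinting and cohesin loop-extrusion analytics for
MNase HiChIP data.

## The problem

MNase HiChIP captures two signals in one library: protein footprints
(MNase spares protein-bound DNA, so fragment length reports the protector
— ~30–60 bp for CTCF, ~147 bp for a nucleosome) and 3D contacts (each
read pair is a single-cell proximity-ligation event). footloop is for
computational genomicists who want to exploit both at once: locate CTCF
binding sites at near base-pair resolution, and then use the contact side
of the same fragments to quantify cohesin extrusion — how often a bound
CTCF anchors a fully extruded convergent CTCF–CTCF loop, and how far
cohesin travels through different chromatin states.

## The statistic at the core

Short, TF-protected fragments produce a strand-specific bimodal pile-up
of read 5′ ends around a bound motif. Partitioning 5′ ends within ±w of a
candidate position into quadrants by strand × side — Q2 (`+`, upstream),
Q1 (`+`, downstream), Q3 (`−`, upstream), Q4 (`−`, downstream) — binding
enriches Q2 and Q4 and depletes Q1 and Q3. The test statistic is

    log2( min(n2, n4) / max(n1, n3) )

so that *both* flanks must pile up. Significance comes from a Monte-Carlo
multinomial null (each read equally likely in each quadrant), tabulated
as an empirical survival function per total read count N ∈ 5..500 on a
grid of statistic values 0..5 (step 0.01); N > 500 reuses the N = 500
row. No assumption is made about the count distribution beyond quadrant
exchangeability. Downstream estimators — coverage differencing for the
cohesin footprint, the occupancy-corrected convergence estimator for the
fully extruded state, mean log10 interaction length per chromatin-state
stratum for extruded loop size, and the precision-weighted per-site
cohesin effect — are described in the methods vignette
(`vignettes/footloop-methods.Rmd`).

## Worked example

Simulate a dataset with planted truth, build the null table, call peaks,
and score them against the planted motifs:

```r
library(footloop)

sim   <- simulate_dataset(sim_config(n_bound = 300, n_decoy = 300, seed = 42))
tab   <- build_null_table(n_min = 5, n_max = 150, reps = 2e5, seed = 42)
peaks <- call_peaks(sim$contacts, tab)
peaks[1:3]
#>     chrom start   end summit     stat     N pvalue qvalue
#> 1:   chrS 34766 34808  34786 4.584963    52  5e-06  5e-06
#> 2:   chrS 40310 40351  40330 5.000000    38  5e-06  5e-06
#> 3:   chrS 45121 45163  45142 5.000000    56  5e-06  5e-06

truth <- data.frame(chrom  = sim$truth$bound_motifs$chrom,
                    center = sim$truth$bound_motifs$center)
pr <- evaluate_pr(peaks, truth, match_dist = 20)
d  <- summit_distances(peaks, truth)
```

This run prints 300 peaks with **99.7% precision, 99.7% recall, and a
median summit-to-motif distance of 0 bp**: each `summit` is the midpoint
of the maximal-statistic window run, `stat` is the quadrant log2 ratio
(capped at 5 when Q1/Q3 are empty), and `pvalue` sits at the table floor
`1/reps` for clean footprints. The extrusion side of the same dataset:

```r
est <- fully_extruded_fraction(sim$contacts, sim$truth$bound_motifs,
                               sim$truth$motifs,
                               params = extrusion_params(min_frags = 20))
est
#> fully extruded state: 5.31% genome-wide (site-level 1st-99th pct: 0.00-11.52%)
#>   363 convergent / 3420 fragments; occupancy factor 0.50; 112 sites with >= 20 fragments
```

i.e. ~5% of CTCF-anchored contacts reflect the fully extruded convergent
state (the generator plants a 10% conditional capture rate; the ×0.5
occupancy correction makes the unconditional estimate 5%), with wide
site-to-site variability — matching the planted truth.

A command-line pipeline wrapping simulate → null → call → footprint →
extrusion lives at `inst/cli/ff.R`:

```sh
Rscript inst/cli/ff.R all --seed 1 --outdir ff_out/
```

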