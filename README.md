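# rcprofiler

Detection of copy-number variants (CNVs) in whole-genome sequencing data
from depth of coverage, by normalization to **Reference Coverage
Profiles** (RCPs) — per-kilobase estimates of the diploid coverage level
learned from a cohort of genomes.

The package is for people who have per-base depth (e.g. `samtools depth`
output, or a vendor coverage report) for one or many genomes and want:
compact storage of the coverage signal, a cohort-trained per-locus diploid
baseline robust to common deletions/duplications, per-genome copy-number
segments with population frequencies, and Mendelian-trio quality metrics.

## Method in brief

Depth of coverage fluctuates strongly and reproducibly from locus to
locus, far beyond what %GC explains, so a genome must be compared with a
per-locus expectation rather than its own global mean. For genome *g* and
1-kb bin *i*:

1. **Condense** — per-base depth is averaged over 20-bp windows and stored
   in one byte each (identity up to 200×; `int(sqrt(d−200)+200)` up to
   2700×; a full-resolution overflow sidecar above), roughly a 150–1000×
   reduction versus raw representations.
2. **Scale** — the genome is fingerprinted by its total autosomal coverage
   in 25 rank-based %GC buckets (its *characteristic coverage vector*
   C<sub>g</sub>); a cohort *target vector* T is the entry-wise geometric
   mean of these; scaled coverage is
   s<sub>g</sub>(i) = r<sub>g</sub>(i) · T<sub>b(i)</sub> / C<sub>g,b(i)</sub>,
   removing depth and per-bucket %GC bias at once.
3. **RCP** — per bin, the scaled coverage level corresponding to two copies,
   L(i), plus its MAD across the cohort. Usually the cohort median; where a
   CNV is common, clusters at integer multiples of a haploid level are
   fitted with a Hardy–Weinberg penalty on the implied genotype counts, so
   that even a deletion at allele frequency 0.8 (hemizygotes modal) anchors
   to the correct diploid level.
4. **NCP** — the normalized coverage profile
   NCP<sub>g</sub>(i) = 100 · s<sub>g</sub>(i) / L(i), in percent of
   diploid: 100 diploid, 50 hemizygous, 0 nullizygous.
5. **Segment** — a five-state Gaussian HMM (emission means 0, 50, 100, 150,
   200%) decoded by Viterbi; constant-state runs become segments, annotated
   with genotype and allele frequencies from a founder panel, trio
   concordance, and rare-deletion gene impact.

A first-class synthetic-cohort generator (locus effects, %GC bias, Poisson
sampling, CNV alleles in Hardy–Weinberg proportions, trio inheritance)
makes the whole chain testable end to end; see the methods vignette
(`vignettes/rcprofiler-methods.Rmd`) for the model and design choices.

## Worked example

Simulate a 25-genome cohort on a 300-kb reference with three polymorphic
CNV loci, build the RCP, and call one genome:

```r
library(rcprofiler)

ref <- simulate_reference(c(chr1 = 300), locus_sd = 0.2, seed = 4)
map <- gc_map_from_reference(ref)
spec <- data.frame(type = c("del", "del", "dup"), af = c(0.3, 0.5, 0.25),
                   len_bins = c(8, 6, 7))
coh <- simulate_cohort(ref, spec, n_trios = 0, n_extra_founders = 25,
                       gap_bins = 12, resolution = "window", seed = 5)

coh$tracks[["S001"]]
#> CondensedTrack: 1 chromosome(s), 15000 windows of 20 bp, 0 overflow site(s)

cs  <- cohort_scale(coh$tracks, map)   # fingerprints, target, scaled profiles
rcp <- build_rcp(cs$scaled)            # per-bin diploid level + MAD
calls <- call_cnvs(cs$scaled[["S001"]], rcp)
subset(calls$segments, state != 2)
#>   chrom start   end state n_bins median_ncp
#> 2  chr1  5000 13000     1      8   51.99766
#> 4  chr1 25000 31000     1      6   52.01127
```

Genome S001 carries two hemizygous deletions (state 1, NCP ≈ 52% of
diploid, i.e. one copy) of 8 kb and 6 kb; both match the planted truth
exactly:

```r
true_cnv_segments(coh, "S001")
#>   chrom start   end state
#> 1  chr1  5000 13000     1
#> 2  chr1 25000 31000     1
```

A thin command-line front end (`exec/rcptool`) exposes the same steps as
subcommands (`condense`, `query`, `gcmap`, `fingerprint`, `target`,
`scale`, `build-rcp`, `normalize`, `segment`, `event-ncp`, `autocorr`) for
shell pipelines.

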