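# twinscope

Imaging-genetics analysis of a nuclear family with twins discordant for
specific reading disability (SRD): which genetic variants and which brain
phenotypes track affection status *within* one family?

The package is built for a five-member design — two parents, dizygotic twins
of whom exactly one is affected, and an affected older sibling — and
implements four connected analyses:

1. **Genotype QC and co-segregation filtering.** Per-sample GenCall-style
   quality control (calls with confidence ≤ 0.15 are set missing), removal
   of SNPs invariant across the family, then the discordant-sibling
   pattern over a 28-gene reading panel: a SNP *co-segregates* when the two
   affected siblings share a genotype (unordered alleles — array data are
   unphased) and the unaffected twin differs. Per-gene and
   functional-class tallies, and the matching proportion among variable
   SNPs compared against a genome background processed identically.
2. **Pairwise intraclass correlations** of regional morphometry (cortical
   thickness, surface area, grey-matter volume) between each sibling pair,
   over a whole-cortex parcellation and over the reading-related subset.
   Single-measure ICC from two-way ANOVA mean squares; default form
   ICC(2,1) (absolute agreement), with ICC(1,1)/ICC(3,1) selectable.
3. **Hemispheric asymmetry indices**, `AI = (L − R) / ((L + R)/2)`
   (positive = leftward), with tolerance-based direction classification.
4. **Luminosity-composite Q–Q comparison.** Template-space ROI masks are
   sliced along each anatomical axis; slices are opacity-layered into a
   grayscale composite (`luminosity = min(255, round(255·c/alpha_ref))`,
   with `alpha_ref` standardized across subjects per ROI and axis); the
   distributions of foreground luminosities are compared through matched
   quantiles, summarised by a divergence score (mean |Δquantile| / 255),
   for the three sibling pairs per ROI and for all ROI pairs within the
   ventral, frontal and dorsal reading pathways (1, 3 and 15 pairs).

Because family genotype and MRI data of this kind are protected, the
package includes a first-class synthetic generator (`sim_config()`,
`simulate_genotypes()`, `simulate_morphometry()`, `simulate_masks()`) that
plants known ground truth — exact co-segregating SNP sets, exact
inter-sibling correlation structure, exact asymmetry indices, controlled
mask-shape similarity — so every stage is testable end to end.

## Worked example

```r
library(twinscope)

cfg <- pipeline_config(simulation = sim_config(seed = 42),
                       out_dir = "twinscope_out")
report <- run_pipeline(cfg)
print(report)
```

The run simulates the family at the default study conditions (800 panel
SNPs, 14.5% family-invariant, ~10% planted pattern SNPs, 1% missing calls),
then executes QC → co-segregation → ICC/asymmetry → luminosity Q–Q and
prints the three-section summary. Abridged output of the run above:

```
== Genetics Results ==
Pattern-matching SNPs: 75 of 658 variable (11.4%)
Genome background: 11.3%
  ATP2C2: 1 SNP(s)
  CCDC136: 3 SNP(s)
  ...

== Asymmetry Analyses ==
ICC form: ICC(2,1) | whole-cortex regions: 38
  twin-twin  thickness     whole_cortex ICC(2,1) = 0.66 (n=76)
  SRD        thickness     whole_cortex ICC(2,1) = 0.76 (n=76)
  TD-OS      thickness     whole_cortex ICC(2,1) = 0.55 (n=76)
  ...
  proband    transverse_temporal            thickness  index +0.019 (leftward)
  proband    superior_temporal              thickness  index -0.042 (rightward)
  ...

== Image Analyses ==
  inferior_occipital             sagittal  most similar: SRD        (margin 0.0006)
  inferior_occipital             coronal   most similar: twin-twin  (margin 0.0004)
  fusiform                       sagittal  most similar: TD-OS      (margin 0.0173)
  ...
```

Reading the numbers: 75 of 658 variable panel SNPs match the
affected-share/twin-differs pattern (11.4%, consistent with the genome
background — with no missing calls the defaults give exactly 79 of 684);
the thickness ICCs land on the planted similarity ordering (SRD pair most
similar, then the twins, then TD-twin/older-sibling), the structure this
design uses to flag a phenotype as tracking SRD risk; each asymmetry index
is signed laterality with its direction label; and per ROI and axis the
sibling pair with minimal Q–Q divergence is named, with its margin.

All stage artifacts are written under `out_dir`: `family.vcf` +
`family.ped.tsv`, `morphometry.tsv`, NIfTI masks, 8-bit grayscale
composite PNGs, `genetics/coseg_results.json`, `icc_results.tsv`,
`asymmetry_table.tsv`, `qq_summary.json`, `ground_truth.json` (the planted
truth), and `report.json`/`report.txt`. A thin command-line wrapper lives
at `inst/cli/twinscope.R` (`simulate`, `genetics`, `run` subcommands).

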