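# tcchart

Tumor Content chart-assisted *HER2*/CEP17 digital PCR analysis for gastric
cancer biopsies.

## The problem

*HER2* amplification status decides anti-HER2 therapy in advanced gastric
cancer and must usually be read from a small FFPE biopsy. Digital PCR
measures the bulk *HER2*/CEP17 copy-number ratio of the extracted DNA
cheaply and robustly — but a biopsy is a mixture of cancer cells and
diploid stroma, and the stroma dilutes the signal. `tcchart` is for
molecular-pathology labs and methodologists who want to correct for that
dilution in closed form and triage samples into amplified / equivocal /
non-amplified without running in situ hybridization on every case.

## The model

Positive chambers `k` of `N` on a partitioned array give the mean copies
per chamber by Poisson occupancy correction, `λ = −ln(1 − k/N)`; the ratio
of target to reference λ is the bulk ratio `r`. With tumor content ratio
`x` (fraction of nucleated cells that are cancerous), per-cell CEP17
copies `A` and *HER2* copies `B`, and diploid stroma:

    r = (B·x + 2(1 − x)) / (A·x + 2(1 − x))

Per-cell amplification is `B/A ≥ 2`. Since `A` is unknown but clinically
confined to [2, 8], the `B/A = 2` iso-curves at the bracket ends partition
the (x, r) plane — the TC chart:

* **negative** below `r = x + 1` (non-amplified for every admissible A),
* **positive** at or above `r = (7x + 1)/(3x + 1)` (amplified for every
  admissible A),
* **equivocal** in the half-open band between, where the call depends on A.

When DISH supplies the measured `A`, the model inverts exactly:
`B/A = r + 2(r − 1)(1 − x)/(A·x)`, and `B′ = r·A` under the pure-tumor
convention.

## Worked example

Quantify a diploid control line from its chamber counts (383 and 398
positive of 770 for *HER2* and CEP17):

```r
library(tcchart)
dpcr_ratio(panel_count(383, 770), panel_count(398, 770))
#> Target/reference copy-number ratio: 0.95 (95% CI 0.82-1.09)
```

The ratio 0.95 ≈ 1 says *HER2* and CEP17 are present in equal copy — no
amplification, as expected for diploid cells.

Run the full pipeline on the bundled eleven-case biopsy dataset (measured
`r`, tumor content `x`, DISH counts and IHC per case):

```r
sheet <- read_sample_sheet(system.file("extdata", "biopsy_cases.csv",
                                       package = "tcchart"))
report <- run_pipeline(sheet)
report[report$sample_id %in% c("case_25", "case_44"),
       c("sample_id", "r", "x", "tc_label", "ba_ratio", "b_prime")]
#>   sample_id     r     x  tc_label  ba_ratio b_prime
#> 2   case_44  1.49 0.264 EQUIVOCAL  2.400707    4.47
#> 9   case_25 28.25 0.414  POSITIVE 52.357035   90.40
```

case_25 sits far above the positive boundary: with only 41% tumor content
its bulk ratio 28.25 implies ~52 *HER2* copies per CEP17 copy per cancer
cell — massive amplification. case_44's bulk ratio 1.49 lands in the
equivocal band; its DISH-measured CEP17 count then resolves it: the
inverted per-cell B/A of 2.40 crosses the amplification threshold.
`render_chart(report)` draws the TC chart with both decision boundaries,
the shaded equivocal band, and the samples colored by DISH and shaped by
IHC.

A thin command-line front end for shell use lives at
`inst/cli/tcchart.R` (verbs `quantify`, `classify`, `simulate`, `chart`).

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline reference
quantities from scratch — the Poisson-corrected cell-line ratios from
their chamber counts, the closed-form per-cell B/A and B′ inversions for
the bundled biopsy cases, and the common convergence value of the decision
boundaries at pure tumor — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/tc-chart-methods.Rmd`) derives the model,
motivates every tunable default, and records the numerical and design
choices; function-level details are in the help pages.
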