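# DeNovoFA

Stable-isotope quantification of fatty acid de novo synthesis from GC/MS
selected-ion-monitoring (SIM) data, for studies of lipogenesis such as
developmental-programming models of obesity.

When body water is enriched with deuterium, or cells are cultured on
[U-¹³C]glucose, every fatty-acid molecule assembled during the labeling
window carries tracer atoms. DeNovoFA turns raw SIM ion-cluster
intensities into synthesis estimates:

* **Natural-abundance correction** — the observed cluster is the
  convolution of the tracer-only mass isotopomer distribution (MID) with
  the fragment's natural isotopologue spectrum, `y = M x` with `M` lower
  triangular; `correctMID()` solves the system exactly.
* **Deuterium (²H₂O) labeling** — new molecules carry Binomial(N, p)
  deuterium atoms (N = 21 for palmitate). Body-water enrichment from the
  consecutive ratio, `p = 2r/((N−1)+2r)` with `r = m2/m1`, and
  `FNS = ME/(pN)` where `ME = Σ i·mᵢ` is the molar enrichment; absolute
  rates in µg per mg tissue per day via heptadecanoate-d3
  internal-standard quantification.
* **¹³C MIDA** — acetyl-CoA M+2 enrichment `g` from consecutive even-peak
  ratios (M+4/M+2 for palmitate, M+6/M+4 for stearate),
  `g = (k+1)R/((n−k)+(k+1)R)`, and fractional synthesis from the light
  peaks m2/m4/m6 against their binomial expectation.
* **Lipid profiling** — percent-of-palmitate profiles, SCD1 desaturation
  indices (16:1/16:0, 18:1n-9/18:0, 18:1n-7/18:0), stearate/palmitate
  ratio, and 2^(−ΔΔCt) expression fold changes.
* **Study simulation and statistics** — a deterministic synthetic-study
  generator with known ground truth (clusters, peak areas, manifest, Ct
  values) and a pipeline producing per-group mean ± SE tables with
  unpaired t-tests.

## Worked example

Simulate a two-group deuterium study (control vs FR, the food-restricted
programmed-obesity group; n = 6/group, 14-day labeling at ~3% body-water
enrichment) and run the full pipeline:

```r
library(DeNovoFA)
design <- defaultStudyDesign("deuterium", nPerGroup = 6L)
study  <- simulateStudy(design, seed = 1)
res    <- runPipeline(study)
res$summary[res$summary$metric %in%
  c("FNS palmitate (%)", "rate palmitate (ug/mg/day)"), ]
```

```
                      metric  mean1    se1 mean2    se2        p signif
          FNS palmitate (%) 39.595 1.5440 45.21 0.9880 0.011984      *
 rate palmitate (ug/mg/day)  3.292 0.1840  4.12 0.0439 0.001386     **
```

`mean1`/`mean2` are the control and FR group means with standard errors:
the pipeline recovers the configured ground truth (40.0% vs 43.5%
palmitate FNS; control synthesis rate ≈ 3.2 µg/mg/day) from the noisy
simulated spectra, and flags the FR increase at p < 0.05. The SCD1
expression component likewise recovers the configured fold changes:

```r
res$folds
#   tissue fold_change      t         p signif
#   SC_fat       1.753 -19.53 2.701e-09     **
#    liver       0.283  26.21 1.505e-10     **
```

Single-spectrum use works without the study machinery:

```r
def <- fattyAcidDefinitions()[1, ]           # palmitate, C17H34O2, m/z 270
y   <- simulateCluster(0.4, 0.03, def, "deuterium")   # raw SIM counts
mid <- correctMID(y, def$formula)            # tracer-only MID
p   <- waterEnrichmentFromRatio(mid, N = 21)$p
fnsDeuterium(mid, p, N = 21)$fns             # ~0.40
```

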