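# spliceclip

Analysis of iCLIP reverse-transcription (RT) stop data around intronic
3′ splice sites, built for comparing a wild-type and a mutant
splicing-factor condition — the setting in which the U2AF1 S34F hotspot
mutation shifts cross-linking by a single nucleotide at the splice
acceptor and changes its CAG/TAG preference.  The package also carries
the downstream percent-spliced-in (PSI) machinery needed to connect
binding changes to alternative splicing in two-condition and cohort
(tumour-panel-style) data, and a synthetic-data generator that emulates
the statistical structure of all inputs so the entire pipeline runs and
is tested without any external download.

Intended users: computational biologists analysing protein–RNA
cross-linking (iCLIP/eCLIP) around splice sites, and anyone needing a
reproducible, tested reference implementation of this family of bespoke
analyses.

## What it computes

With junction offset 0 the first exonic nucleotide (display coordinates
shift by −3 so the acceptor AG sits at −5/−4):

- **3′SS occupancy saturation** — a 3′SS is *occupied* when any RT stop
  lies within ±20 nt of the junction.  Per-gene CLIP density is RT stops
  per 3′SS; after sorting genes by density, a rolling quantile-0.75 over
  windows of 40 genes traces the saturation curve, summarised by a
  plateau estimate (mean rolling value over the top-decile-density
  windows).
- **Metagene profile** — per-site normalised RT-stop densities over
  ±50 nt, averaged and max-scaled.
- **Binding clusters C1–C10** — each site's binding-fraction vector over
  ±25 display offsets; sites with >10 stops are assigned C1…C9 when the
  argmax falls at display −6…+2 with fraction ≥ 0.10, C10 otherwise;
  *cluster switches* are sites major in both conditions with different
  labels.
- **Hexamer Z-scores** — a resampling null (n = 50 draws of M sites,
  M = number of occupied 3′SS) gives per-hexamer (μ, σ); observed
  frequencies f count the five hexamers containing each cross-linked
  base, and z = (f − μ)/σ.  Trinucleotide sliding-window profiles over
  [RT−25, RT+25], positional base-frequency matrices, and a
  log2 preferential-binding score complete the motif layer.
- **Differential splicing** — ψ = inclusion/(inclusion+exclusion); a
  Beta(1,1)-binomial marginal-likelihood-ratio Bayes factor
  BF = B(i₁+1,e₁+1)B(i₂+1,e₂+1)/B(i₁+i₂+1,e₁+e₂+1); calls require
  |Δψ| ≥ 0.10, BF ≥ 5 and ≥ 10 supporting reads.  Cohort calls use a
  Welch t-test (p < 0.05) with |Δmedian ψ| ≥ 0.025, CAG/TAG acceptor
  co-association by Fisher's exact test, per-sample event Z-scores
  against the wild-type cohort with a 1.64 cut, and a pooled-overlap
  Fisher test.
- **Integration** — 1.5× fold-change classifications of per-gene CLIP
  and expression, binding–expression concordance (R² of log2 ratios),
  binding–splicing cluster-switch co-association (strong events:
  BF ≥ 10, |Δψ| > 0.10), co-occurrence Fisher tests from cohort margins,
  and an exact two-sided binomial hotspot test.

## Worked example

```r
library(spliceclip)

cfg <- simConfig(nGenes = 500)            # defaults emulate the study conditions
ref <- simulateReference(cfg, seed = 1, genome = FALSE)
wt  <- simulateRTStops(ref, cfg, "wt",  seed = 1)
mut <- simulateRTStops(ref, cfg, "mut", seed = 1)
wt$track
#> RTStopTrack 'wt': 18090 positions, 431791 RT stops

curveWt  <- occupancyAnalysis(wt$track,  ref$sites)
curveMut <- occupancyAnalysis(mut$track, ref$sites)
curveWt
#> OccupancyCurve: 500 genes, window 40, q 0.75, plateau 0.850
sprintf("plateau occupancy: wt %.1f%%, mut %.1f%%",
        100 * plateau(curveWt), 100 * plateau(curveMut))
#> "plateau occupancy: wt 85.0%, mut 70.0%"
```

The plateaus are the occupancy the saturation analysis reads off at high
CLIP density: with generator defaults the wild-type protein occupies
~85% of 3′ splice sites and the mutant ~70%.  The single-nucleotide
shift shows up in the cluster layer:

```r
aWt  <- clusterAssignments(wt$track,  ref$sites)
aMut <- clusterAssignments(mut$track, ref$sites)
c(wt = modalMajorPosition(aWt), mut = modalMajorPosition(aMut))
#>  wt mut
#>  -5  -4
```

— the modal cluster moves from the acceptor A (display −5, cluster C2)
to the G (display −4, C3).  On the splicing side, the cohort caller and
the acceptor co-association test recover the coupling between inclusion
direction and CAG/TAG acceptors that the generator plants:

```r
cohort <- simulatePsiCohort(ref, cfg, seed = 1)
calls  <- cohortCall(cohort$psi)          # 103 of 500 events called
acc <- setNames(cohort$truth$acceptor, cohort$truth$event_id)
res <- cohortCagTagTest(calls, acc)
res$table
#>     up down
#> CAG 43    5
#> TAG  8   31
sprintf("CAG/TAG co-association: OR %.1f, p = %.2g", res$odds_ratio, res$p)
#> "CAG/TAG co-association: OR 31.3, p = 3.2e-11"
```

Events with increased inclusion in the mutant cohort sit overwhelmingly
at CAG acceptors, decreased-inclusion events at TAG — the expected
signature of the mutant's CAG preference.

A scripted end-to-end demonstration writing TSVs for every stage is
available as `runDemo(outdir, seed)` or via the thin CLI wrapper:

```sh
Rscript inst/scripts/spliceclip.R demo --out demo_out --seed 1
```

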