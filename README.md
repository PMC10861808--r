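# cstconcord

Concordance analysis between white-matter tract segmentations and
navigated transcranial magnetic stimulation (nTMS) motor maps.

## Who this is for

Pre-operative planning around motor-eloquent brain tumours relies on
corticospinal-tract (CST) segmentations from diffusion MRI, but in tumour
patients there is no ground truth to validate them against. nTMS motor
mapping provides a non-invasive "silver standard": stimulation sites with
a motor evoked potential of at least 50 µV (latency 18–26 ms) are
causally linked to the motor system. `cstconcord` is for researchers who
want to quantify, per patient and per cohort, how well a (possibly
uncertainty-aware) tract segmentation agrees with those responses.

## What it computes

Responses are classified by positivity and primary-motor-cortex (M1)
membership into three masks — `+M1+`, `-M1+`, `-M1-` — rasterized at
1 mm³, cleaned with the intracranial mask and restricted to white matter.
A stochastic segmentation ensemble (T = 20 passes by default) is
aggregated into a mean probability map, a binary mask (strict threshold
at 0.5) and a voxelwise uncertainty map (across-pass standard deviation,
or binary entropy of the mean). Agreement is measured by

- **overlap coefficient** OC(A,B) = |A∩B| / min(|A|,|B|)
  (Szymkiewicz–Simpson; 1 when the smaller set is enclosed, 0 when
  disjoint; `NA`, never 0, when a mask is empty),
- **Dice** 2|A∩B| / (|A|+|B|) between methods,
- paired **Wilcoxon signed-rank** tests across subjects,
- the **uncertainty–distance relationship**: Euclidean distance (mm,
  anisotropy-aware exact EDT) of each response voxel to the tract mask,
  a 30-bin joint histogram, Spearman's ρ with p-value, and an OLS trend.

A synthetic phantom generator (tubular tract, boundary-concentrated
ensemble variability, three distance-ordered response classes) makes the
whole pipeline testable without clinical data. A minimal NIfTI-1
reader/writer is built in; no imaging package is required.

## Worked example

```r
library(cstconcord)

# cohort characteristics of the bundled reference table
s <- cohort_summary(reference_table("cohort"))
round(s$age_mean, 2)                     # 44.19 (range 25-69)
s$hemisphere_pct[["Left"]]               # 75

# cohort overlap aggregation and method comparison
tab <- reference_concordance()
cohort_mean_oc(tab, "uncseg", "+M1+")$mean    # 0.8263125  -> 0.83(0.14)
cohort_mean_oc(tab, "tractseg", "+M1+")$mean  # 0.8604375  -> 0.86(0.12)
x <- tab$oc[tab$method == "uncseg"   & tab$klass == "+M1+"]
y <- tab$oc[tab$method == "tractseg" & tab$klass == "+M1+"]
wilcoxon_signed_rank(x, y)$p_value            # 0.04263255

# synthetic phantom: one subject end-to-end
spec <- phantom_spec(seed = 7)
sub  <- generate_subject(spec)
res  <- analyze_subject(sub)
res$oc             #  +M1+ 0.1333333   -M1+ 0   -M1- 0
res$dice_vs_truth  #  1  (binarized ensemble mean recovers the tract)
```

The per-class OCs above show the expected monotone pattern
(`+M1+` ≥ `-M1+` ≥ `-M1-`): positive responses in M1 sit on the tract,
negative responses far from it. On a 16-subject phantom cohort the
pooled Spearman correlation between ensemble uncertainty and
response-to-tract distance is strongly negative (ρ ≈ −0.85,
p ≪ 0.01): the ensemble is uncertain near the tract boundary and
confident far from it.

## Command line

```sh
inst/cli/cstconcord simulate --out-dir cohort/ --n-subjects 16 --seed 1
inst/cli/cstconcord run      --dir cohort/
inst/cli/cstconcord report   --dir cohort/derived
```

`run` writes `concordance.csv` (per subject/class OC), `histogram.csv`
(30-bin distance histogram with per-bin mean/sd uncertainty) and
`summary.json` (cohort statistics plus every parameter and definition
used, including the OC convention and Wilcoxon zero handling).

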