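# latmseg

Location-adaptive threshold segmentation of coronary vessel cross-sections
in CT attenuation volumes, with quantification and method-agreement
statistics, validated end-to-end on a digital vessel phantom with analytic
ground truth.

## The problem

Measuring lumen and plaque along a coronary artery from contrast-enhanced
CT requires a lumen boundary and an outer vessel-wall boundary on every
cross-sectional plane perpendicular to the centerline. A fixed
Hounsfield-unit threshold cannot work: contrast attenuation varies between
patients, along a vessel, and across stenoses. This package is for image
analysts and methodologists who need (a) an open, testable implementation
of an adaptive per-plane thresholding rule, and (b) the full
method-comparison machinery used to judge such a tool against a
fine-interval reference (clinically, intravascular ultrasound pullback;
here, a phantom's analytic truth).

## The method

Per plane, with inner-point attenuation *I* (mean HU over a 0.3 mm disc at
the centerline point) and calibration attenuation *C*:

* effective base *B* = *I*, unless *I* > 1.45 *C* or *I* < 0.5 *C*, in
  which case *B* = *C* (the calibration override);
* lumen limits: lower *L* = 0.5 *B* (full-width-at-half-maximum spirit),
  upper *U* = 1.45 *B* (calcification guard);
* along each of 64 rays, the lumen radius is the first outward crossing
  below *L* (sub-step linear interpolation), capped earlier by a crossing
  above *U* (calcification onset);
* the outer wall is the strongest local maximum of |dHU/dr| beyond the
  lumen whose attenuation lies below 0.5 *B*, refined by a parabolic fit;
* plaque area = vessel area − lumen area; plaque burden = plaque / vessel,
  with burden > 0.6 defining the stenotic subgroup;
* volumes: Σ area × interval (CT software convention) and composite
  Simpson (pullback convention); agreement via Bland-Altman
  (mean ± 1.96 SD limits), Pearson *r* with Fisher-transform CI, and
  ICC(2,1) (two-way random, single measurement, absolute agreement), plus
  Fisher r-to-Z for comparing coefficients between independent groups.

See `vignettes/latm-methods.Rmd` for the full model description, phantom
design, numerical choices and known accuracy limits.

## Worked example

Generate a 12 mm phantom segment with a 50% mid-segment stenosis, segment
it at 0.25 mm plane spacing, and compare against the analytic reference:

```r
library(latmseg)
spec <- phantom_spec(segment_length = 12, stenosis_center = 6,
                     stenosis_length = 5, noise_sd = 10, seed = 7L)
ph  <- make_vessel_phantom(spec)
seg <- segment_vessel(ph$volume, ph$centerline,
                      latm_config(calibration_hu = 400), interval = 0.25)
reference <- reference_area_profile(ph$truth, 0.001)
print(evaluate_platform(seg$profile, reference))
```

```
<latm_report> 1 segment(s), stenotic threshold 0.60
  volume         lumen   n=1      bias=NA       r=NA     ICC=NA
  volume         plaque  n=1      bias=NA       r=NA     ICC=NA
  area           lumen   n=49     bias=0.554    r=0.999  ICC=0.986
  area           plaque  n=49     bias=-1.979   r=0.784  ICC=0.655
  stenotic_area  lumen   n=15     bias=0.435    r=1.000  ICC=0.985
  stenotic_area  plaque  n=15     bias=-3.073   r=0.481  ICC=0.294
```

Reading it: 49 planes were segmented and paired with the reference; the
lumen area tracks the truth tightly (r = 0.999, ICC = 0.986) with a small
positive bias (+0.55 mm², the documented threshold-offset bias of the
half-maximum rule under this contrast); plaque agreement is weaker because
a 1 mm wall sits at the resolution limit of 0.4 mm voxels with 0.25 mm
blur. The per-segment volume rows need a multi-segment cohort (pass lists
of profiles) to populate. Volumes for this segment:

```r
volume_sum(seg$profile, "lumen")   # 135.2 mm^3  (truth 125.3)
volume_sum(seg$profile, "plaque")  # 193.7 mm^3  (truth 214.0)
```

A thin CLI wraps the same functions
(`Rscript inst/cli/latm.R phantom|segment|quantify|compare|run ...`).

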