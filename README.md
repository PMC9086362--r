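# nanorodem

Automated identification and length measurement of TMV-like virus
nanorods in negative-stain transmission electron micrographs.

Tobacco mosaic virus builds rigid rods 18 nm wide whose length is set
by the encapsidated RNA: three nucleotides per coat-protein subunit,
6,395 nt for the 300 nm wild-type particle. Engineered nanorods place
the origin-of-assembly sequence on RNAs of chosen length, and checking
a preparation means measuring hundreds of rod lengths per micrograph.
`nanorodem` does this with a classical image-processing chain and
reports calibrated length distributions. It is aimed at labs producing
TMV-based nanorod preparations and at anyone benchmarking rod-particle
segmentation.

## Method

Per micrograph (MRC2014 or grayscale TIFF, calibrated in nm/px):

1. adaptive thresholding against a Gaussian local mean
   (301 px block), dark-object polarity;
2. morphological cleanup: erode once (3×3 cross), drop components
   < 2000 px, dilate five times, fill holes < 500 px;
3. seeded watershed on the distance transform (seed separation =
   one rod width) to separate close-lying rods;
4. eliminate objects with area < 500 nm² or minor axis > 40 nm;
5. per object: maximum Feret diameter *F* (exact, corner-to-corner via
   convex hull), then rod length by the Pythagorean width correction

   *L* = √(*F*² − *W*²),  *W* = 18 nm.

Reports give 10 nm-binned histograms and descriptive statistics, with
manual exclusion of mis-segmented records and classification of
end-to-end multimers (49/98/147 nm for a 49 nm monomer). A construct
geometry calculator predicts expected lengths from RNA size
(*L*(n) = n·300/6395 nm), and a synthetic micrograph generator renders
noise-degraded scenes of capsule-shaped rods with exact ground truth,
so the whole pipeline is testable without microscope data.

## Worked example

```r
library(nanorodem)

sc  <- render_scene(scene_params(n_rods = 10, rod_length_nm = 49),
                    seed = 42)                 # synthetic micrograph
seg <- segment_micrograph(sc$image)            # steps 1-4
m   <- measure_rods(seg, source_id = sc$image$source_id)  # step 5
build_report(m)
#> length_report: n = 10 rods (0 excluded), 10 nm bins
#>   mean 48.98  median 49.05  sd 0.28  min 48.44  max 49.31 nm
#>   [  40,   50) nm : 10
```

All ten 49 nm rods are recovered, the mean is within a fraction of a
nanometre of truth, and every rod falls in the [40, 50) nm bin — the
histogram class a 49 nm design should populate. Expected lengths from
construct geometry:

```r
round(expected_length(c(1045, 5479, 6395)), 1)  # RNA nt -> nm
#> [1]  49 257 300
multimer_length(1:3, 49)                        # end-to-end aggregates
#> [1]  49  98 147
```

For real data: `load_micrograph("grid3_sq12.mrc")` (pixel size is read
from the MRC header) and the same calls; `run_measure()` batches whole
image sets into per-image and pooled CSVs with a YAML run manifest.
`inst/cli/nanorodem.R` wraps measure/simulate/report/exclude/
expected-length as shell subcommands.

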