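# busecho

Three-class diagnosis of breast ultrasound images and pixel-level tumor
localization, built as a fully reproducible R package.

Breast masses are typically *hypoechoic* — darker than the surrounding
tissue on B-mode ultrasound — and computer-aided pipelines for this modality
follow a common shape: standardize the grayscale frame to 256 × 256,
extract a compact feature vector per image, classify it as normal (0),
benign (1) or malignant (2), and separately label each pixel as tumor or
not so the lesion's location and size can be reported. `busecho` implements
that entire pipeline, plus the seeded synthetic phantom generator that
makes every stage testable offline: speckle-textured images with dark
elliptical lesions (smooth for benign, spiculated for malignant) and
three-level ground-truth masks (tumor 255, normal tissue 127,
background 0).

The quantitative core:

* **Histogram features.** Each image's 256-bin intensity histogram is
  modelled as a sum of four Gaussians,
  h(b) ≈ Σⱼ aⱼ exp(−(b − mⱼ)² / 2sⱼ²), fitted by seeded multi-start
  bounded least squares; the four sorted means are the per-image feature
  vector.
* **Eigen features.** Eigenface-style: images become columns of a centered
  N² × M matrix A; the eigenpairs of the covariance AAᵀ are obtained from
  the small M × M matrix AᵀA via Uᵢ = AVᵢ, and images are projected onto
  the top-f eigenvectors Wᵀ(x − μ), the scatter-maximizing rank-f
  projection.
* **Classifiers.** Decision tree, k-nearest neighbours, SVM and Gaussian
  naive Bayes on the 4-feature vectors, plus a 16-layer / 3-convolution
  CNN classifier and an 11-layer / 3-convolution pixel-labelling CNN
  segmenter, both implemented from scratch (im2col/BLAS convolutions,
  batchnorm, Adam) with fully seeded, deterministic training.
* **Localization.** Thresholded probability maps are refined by
  morphological closing and small-component removal; the largest
  8-connected component yields centroid, pixel area and optional physical
  area (area × spacing², mm²).
* **Evaluation.** Confusion-matrix metrics (sensitivity = TP/(TP+FN),
  precision = TP/(TP+FP), accuracy = (TN+TP)/total), one-vs-rest reduction
  for the 3-class problem, ROC by threshold sweep with trapezoidal AUC
  (equal to the Mann–Whitney statistic), and per-image segmentation AUC
  with the fraction of images above an AUC cutoff (default 0.6).

## Worked example

```r
library(busecho)

# a 256x256 malignant phantom with a spiculated 25x18 px lesion
ph <- generatePhantom(phantomParams("malignant", lesion_axes = c(25, 18), seed = 42))
table(ph$mask)
#>     0   127   255
#>  2088 61992  1456

# four-Gaussian decomposition of its intensity histogram
fitFourGaussians(computeHistogram(ph$image), seed = 1)
#> HistogramModel: 4-Gaussian histogram decomposition
#>   component 1: amplitude 0.004701  mean 112.57  sigma 17.64
#>   component 2: amplitude 0.006963  mean 142.60  sigma 18.34
#>   component 3: amplitude 0.004499  mean 176.54  sigma 22.23
#>   component 4: amplitude 0.0009846  mean 242.15  sigma 255.00
#>   residual 0.0001789  converged TRUE

# localize the lesion from a binary tumor mask (here: the ground truth)
bin <- encodeMask(decodeMask(ph$mask)$tumor, matrix(FALSE, 256, 256))
ref <- morphologicalRefine(bin, radius = 5, min_size = 20)
lesionReport(ref, pixel_spacing = 0.2)
#> LesionReport: centroid (128.2, 128.2), area 1458 px (58.32 mm^2)
```

The mask tallies 1456 tumor pixels; closing fills two boundary pixels, and
the report recovers the generator's lesion center (the phantom default) to
a fraction of a pixel. The four fitted components split the speckle bulk
around the tissue mean (~150) with a low, wide fourth component absorbing
the bright tail — on phantoms the small lesion contributes only a few
percent of pixels, so the histogram features mainly describe the overall
echo structure.

End-to-end flows are one call each:

```r
cfg <- runConfig(out_dir = "runs", n_per_class = 25, seed = 1)
runClassificationPipeline(cfg)   # features, 4 classical + CNN, metrics.csv
runSegmentationPipeline(cfg)     # segmenter, per-image AUCs, lesion reports
```

Both are byte-for-byte reproducible from the config and seed, and write
into a config-hashed subdirectory so different configurations never mix. A
thin command-line wrapper with the same entry points is installed at
`inst/scripts/busecho.R`.

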