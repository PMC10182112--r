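# dlratio

How large should the ground-truth box around a tumor be? `dlratio` is an R
package for studying how the scale of square ground-truth regions of
interest (ROIs), relative to the tumor they annotate, affects the training
and evaluation of liver-tumor detectors on B-mode ultrasound images.

The central quantity is the **D/L ratio**: the maximum tumor diameter *D*
divided by the side length *L* of the square ROI. D/L = 1 means the ROI is
tangent to the tumor; D/L < 1 means a larger ROI that includes peritumoral
context (posterior enhancement or shadowing, surrounding parenchyma);
D/L > 1 means the ROI cuts into the tumor. In pooled clinical databases the
annotators' ROI habits vary, so D/L is effectively a noisy annotation
parameter — and the package provides the machinery to measure what that
noise costs a detector.

It is aimed at researchers building or auditing detection datasets and
evaluation protocols for medical ultrasound, and it works entirely from
plain annotation/prediction tables, so any external detector can be plugged
in.

## What it implements

* **Annotation geometry** — square ground-truth boxes of side L = D / (D/L)
  centered on the tumor; fixed or uniformly distributed D/L conditions;
  CSV and COCO-style JSON interchange.
* **Preprocessing** — background margin sized to 25 px in the resized
  448×448 frame, elimination of images whose ROI overflows even the padded
  frame, bilinear resize with per-axis annotation rescaling, horizontal-flip
  doubling, and case-wise 8:2 splitting into three divisions with
  pairwise-disjoint test sets.
* **Evaluation protocol** — IoU of axis-aligned boxes; one evaluated
  detection per image (highest confidence among positive-IoU detections);
  TP / FP / FN with precision = TP/(TP+FP), recall = TP/(TP+FN),
  F1 = 2PR/(P+R); IoU-threshold calibration by discriminant analysis
  (Otsu's method) over the IoU distribution with FNs entered as IoU = 0;
  best-of-3-runs reporting and test-count-weighted averaging across splits.
* **Synthetic data** — ultrasound-like phantoms (speckle, sector mask, four
  lesion appearance archetypes including posterior echo features) whose
  case/image composition is proportioned to a published 7607-image,
  1996-case multi-center liver collection, plus a detector simulator whose
  error model is conditioned on the training D/L (boxes grow as training
  D/L shrinks).
* **Experiments** — the fixed-D/L sweep (0.4–1.1) and the distributed-D/L
  range comparison ([0.6,1.0], [0.7,1.0], [0.8,1.0]), with CSV reports and
  full seed-level reproducibility.

## Worked example

```r
library(dlratio)

# a ground-truth box: D = 64 px tumor annotated at D/L = 0.8 -> side 80 px
a <- tumor_annotation("case7", "case7_img2", "cyst",
                      center_x = 210, center_y = 180, max_diameter = 64,
                      image_width = 448, image_height = 448)
make_ground_truth_box(a, dl = 0.8)
#>     image_id x_min y_min x_max y_max
#> 1 case7_img2   170   140   250   220

# full study on a 1/10-scale synthetic phantom set (~760 images, ~198 cases)
ann   <- generate_phantom_dataset(phantom_config(scale = 0.1, seed = 1))$annotations
sweep <- run_dl_sweep(ann, experiment_config(seed = 1))
tot   <- sweep$weighted[sweep$weighted$scope == "total", ]
tot[order(tot$dl), c("dl", "precision", "recall", "f1", "fn")]
#>  dl precision recall    f1   fn
#> 0.4    0.0000 0.0000    NA 31.0
#> 0.5    0.0186 0.0797 0.030 26.6
#> 0.6    0.4136 0.7420 0.529 18.4
#> 0.7    0.9559 0.8937 0.915 15.3
#> 0.8    1.0000 0.9188 0.954 12.3
#> 0.9    1.0000 0.9299 0.963 10.7
#> 1.0    1.0000 0.8932 0.944 16.3
#> 1.1    0.9975 0.8796 0.934 18.3
```

Each row is the best-of-3-runs total metric per training D/L, averaged over
the three case-disjoint splits weighted by test-image counts (`fn` is the
weighted mean of the per-split minimum FN counts). The table shows the two
signature behaviors: a collapse of precision and recall once the training
D/L drops to 0.6 and below — in the noiseless limit a detector trained at
D/L = ρ produces boxes whose IoU against the tangent test ground truth is
exactly ρ², which crosses the 0.375 threshold between 0.6 and 0.7 — and a
broad optimum for D/L in 0.8–1.0, degrading mildly at 1.1 where the box no
longer covers the tumor boundary.

`run_distributed_dl_experiment()` adds the distributed-annotation
comparison (narrower training D/L ranges give better recall and fewer FNs),
and `write_report()` emits the tables as CSV files plus a JSON metadata
record.

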