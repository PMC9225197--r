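# cardionet

Multi-class semantic segmentation of posterior–anterior chest radiographs
— lungs, heart, clavicles — with **CardioNet**, a shallow
dense-concatenation encoder–decoder, and automated **cardiothoracic-ratio
(CTR)** measurement for cardiomegaly screening.

The package is aimed at medical-image-analysis researchers who want a
fully self-contained, CPU-trainable reference implementation of this
architecture family: the declarative layer schedule with shape and
parameter audits, the deterministic flip/translate augmentation cascade,
median-frequency class-balanced training, per-class evaluation metrics,
the CTR geometry, and a synthetic chest-phantom generator with analytic
ground truth so that everything can be exercised without downloading
clinical datasets.

## The model

CardioNet is an encoder–decoder with three parts:

* a **downsample block**: four stages of paired convolutions (3×3
  standard in the shallow stages, depth-wise separable where channels are
  wide) whose outputs are depth-wise concatenated, compressed by 1×1
  bottlenecks (batch norm + ReLU), and 2×2 max-pooled;
* an **upsample block**: the mirror image, upsampling by max-unpooling
  with the indices recorded by the paired pooling layer, and
  concatenating dense skips from the encoder
  (concatenation widths 128/256/512/512 down, 512/640/320/160 up);
* a **feature-boost block** (variant "B"): six 3×3 convolutions kept at
  full input resolution with no pooling, preserving thin structures such
  as clavicles; variant "X" omits it.

Training minimizes pixel-wise cross-entropy weighted by median-frequency
balancing, `w_c = median_k(f_k) / f_c`, with Adam (lr 0.001, batch 4) and
global L2 gradient clipping.  Evaluation reports per-class accuracy,
Jaccard `J = TP/(TP+FP+FN)` and Dice `D = 2TP/(2TP+FP+FN)`.  From a
predicted mask, the screening ratio is

```
CTR = (D_L + D_R) / M
```

the maximal horizontal cardiac extent over the maximal horizontal
thoracic extent; CTR > 0.50 suggests cardiomegaly (normal range
0.42–0.50).

All network primitives (im2col+GEMM convolutions, depth-wise
convolutions, pooling/unpooling with indices, batch norm, weighted
softmax cross-entropy, the full backward pass, Adam) are implemented in
RcppArmadillo: a double-precision reference path that the test suite
holds to finite-difference gradients, and a single-precision preallocated
executor used for training and batched prediction, tested to agree with
the reference path.

## Worked example

Train the B variant on synthetic phantoms, evaluate on held-out ones, and
measure the CTR from a predicted mask:

```r
library(cardionet)

ds  <- make_phantom_dataset(40, side = 96, seed = 42)
fit <- cardionet(phantom_images(ds)[1:32], phantom_masks(ds)[1:32],
                 variant = "B",
                 control = cardionet_control(epochs = 8, seed = 1))
print(fit)
#> CardioNet-B: 4-class segmentation at 96x96
#>   trained on 32 images, 8 epochs, 64 gradient steps
#>   final epoch: loss 0.3434, training pixel accuracy 0.9618
#>   class weights: 0.222, 0.737, 1.554, 4.716

evaluate_cardionet(fit, phantom_images(ds)[33:40], phantom_masks(ds)[33:40])
#>   class  accuracy   jaccard      dice
#> 1     0 0.9638265 0.9460602 0.9722826
#> 2     1 0.9812690 0.9139135 0.9550207
#> 3     2 0.9916043 0.9196104 0.9581219
#> 4     3 0.9882948 0.7390384 0.8499391

seg  <- predict(fit, phantom_images(ds)[[33]])
meas <- compute_ctr(seg$label)
print(meas)
#> CTR = 33 / 63 = 0.5238  [cardiomegaly]
#>   midline col 48: D_L = 14, D_R = 19
ds[[33]]$expected_ctr      # analytic truth for that phantom
#> [1] 0.557377
```

The per-class rows are accuracy/Jaccard/Dice on the 8 held-out phantoms
(class 0 background, 1 lung, 2 heart, 3 clavicle — clavicles are thin and
hardest).  The class weights are the median-frequency balancing computed
from the training masks: background is down-weighted, the rare clavicle
up-weighted.  The CTR report shows the cardiac (33 px) and thoracic
(63 px) diameters measured on the *predicted* mask, their ratio and the
screening call; this phantom's analytic CTR is 0.557, so the call
(cardiomegaly, CTR > 0.50) agrees with the ground truth.  The run takes a
few minutes on one CPU core.

The schedule audit reproduces the printed architecture tables:

```r
audit_schedule(build_cardionet_schedule(4, 350, with_fbb = TRUE))
#> CardioNet-B schedule audit (input 350x350, 4 classes)
#>   3x3 convolutions:            16
#>   depth-wise separable convs:  6
#>   1x1 bottlenecks:             9
#>   pooling stages:              4 (smallest encoder map 21x21)
#>   concatenation widths:         128, 256, 512, 512, 512, 640, 320, 160
#>   parameters (ungrouped 1x1 bottlenecks): 2,112,640
#>   parameters (grouped 1x1 bottlenecks):   1,578,457
#>   ...
```

## Command-line front end

```sh
inst/cli/cardionet make-phantoms --n 64 --side 96 --seed 7 --out data/
inst/cli/cardionet train --data data/ --out run/ --epochs 5
inst/cli/cardionet predict --model run/model.rds --image data/phantom_001.png --out pred.png
inst/cli/cardionet ctr --mask pred.png --palette jsrt
inst/cli/cardionet audit-schedule --variant B
```
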