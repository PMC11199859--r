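# tffc — time-frequency fusion contrastive learning for time series

`tffc` is an R implementation of self-supervised representation learning
for windowed multichannel time series — the kind of data behind EEG sleep
staging, seizure detection, and accelerometer-based activity and gesture
recognition, where unlabeled windows are plentiful and expert labels are
scarce.

The core idea is **time-frequency fusion contrasting**: every window is
augmented twice, once in the time domain (jitter, scaling, segment
permutation, masking) and once in the frequency domain (its one-sided FFT
passes through low-pass, phase-shift, remove-frequency and add-frequency
operators and is inverse-transformed back). Each operator fires with
probability `p = 0.25`. The two augmented views are fused at the data
level with kernel PCA,

```
data_final = KernelPCA(flatten(time_view)) ⊕ KernelPCA(flatten(freq_view)),
```

and `(original window, fused view)` forms the positive pair of the
normalized temperature-scaled cross-entropy (NT-Xent) objective

```
L(i,j) = -log[ exp(sim(z_i, z_j)/τ) / Σ_{k≠i} exp(sim(z_i, z_k)/τ) ],
```

with cosine similarity `sim`, temperature `τ`, and the `2N` batch pool as
negatives. The encoder is a 3-block 1D residual network with adaptive
average pooling (so any window length maps to a fixed-size embedding) and
a BN+ReLU projection MLP; after pre-training, a 256/128-unit softmax head
with dropout 0.2 is fine-tuned on the small labeled split and evaluated
with accuracy and macro precision/recall/F1 plus a confusion matrix.

A synthetic-signal generator with class-specific spectral *and* temporal
cues makes the whole pipeline runnable and testable without any external
dataset.

## Worked example

```r
library(tffc)

cfg <- default_config(
  seed = 1,
  data     = list(n_per_class = 167L, n_classes = 3L, window = 128L, noise_sd = 1.0),
  model    = list(channels = c(8L, 16L, 32L), embed_dim = 32L, proj_dim = 16L),
  pretrain = list(epochs = 30L)
)
res <- run_experiment(cfg)
print(res$report)
```

```
<metrics_report> accuracy 0.9293 | precision 0.9355 | recall 0.9293 | F1 0.9289 (macro)
confusion (rows = truth):
     pred
truth  0  1  2
    0 33  0  0
    1  0 32  1
    2  0  6 27
```

The run generates 501 noisy synthetic windows of 3 classes (each class a
sinusoid at its own frequency plus a class-positioned pulse, noise sd 1.0),
splits them 60/20/20 into pretrain/finetune/test, fits the kernel-PCA
fusion on the augmented pretrain windows, pre-trains the encoder for 30
contrastive epochs on the ~300 unlabeled windows, fine-tunes on the ~100
labeled ones (updating the encoder), and scores the ~100 held-out test
windows: 92 of 99 are classified correctly (accuracy 0.9293), with the
confusion matrix showing class 2 occasionally mistaken for class 1. The
same fine-tuning applied to a randomly initialized encoder reaches 0.919
on this seed — the gap is the contrastive stage's contribution. The run
takes about two minutes on one CPU.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/tffc.R generate --classes 3 --per-class 100 --window 128 --seed 1 --out data.csv
Rscript inst/cli/tffc.R run    --seed 1 --out results/
Rscript inst/cli/tffc.R ablate --modes tf-fc,time-only,freq-only --seed 1 --out ablation.csv
```

(after installation the script lives at
`system.file("cli", "tffc.R", package = "tffc")`).

Checkpoints (`--out ckpt.rds`) are single RDS archives holding the whole
model object: encoder/head configurations, all weights, and the batch-norm
running statistics, so `finetune`/`evaluate` need no side files; a
per-epoch loss log is written next to each checkpoint as CSV.

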