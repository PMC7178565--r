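# segcall

Nanopore basecalling as one-dimensional instance segmentation, for people
who need not just sequences but the explicit signal-sample-to-base
correspondence: every raw current sample of a squiggle is assigned one of
eight alias nucleotide labels by a recurrent-enhanced 1D U-net, and
collapsing runs of identical labels yields the basecall *and* its per-base
signal segmentation in one step. The per-base segments feed downstream
signal analyses (re-squiggling, base-modification detection) that
CTC-style basecallers do not directly support.

## The method

For a signal window $X = (x_1, \dots, x_L)$ the network predicts labels
$y_i \in \{A_1, A_2, C_1, C_2, G_1, G_2, T_1, T_2\}$, one per sample.
The two phases per base exist so homopolymers survive run-collapse:
`AAAAA` is trained as `A1 A2 A1 A2 A1`, and collapsing maximal runs of
identical labels then decoding the aliases reproduces `AAAAA` instead of a
single `A`.

The flagship architecture (`urnet`) is a 1D U-net — CONV–BatchNorm–ReLU
encoder blocks with max pooling, nearest-neighbour up-sampling decoder with
skip concatenations — enhanced with a bidirectional GRU after every encoder
block (those recurrent outputs feed the skip connections) and three final
bidirectional GRU layers. Ablation variants `unet`, `gru3` and `unet_gru3`
are built by the same constructor. Training minimizes the interpolated
objective

$$\mathrm{loss} = \alpha \sum_i CE_i + \beta \sum_i (1 - DL_i), \qquad \alpha = \beta = 1,$$

with $CE$ the categorical cross-entropy and $DL$ the dice similarity
between predicted probabilities and one-hot gold masks, optimized with
Adam. At inference, reads are scanned with overlapping windows
($L = 300$, step $s = 290$); per-sample class probabilities of
overlapping windows are soft-merged with a linear cross-fade before the
argmax, collapse, and alias decoding. Signals are normalized per read by
median shift and (unscaled) median absolute deviation; training windows
containing normalized values above 10 are filtered.

A built-in squiggle simulator (per-k-mer current levels with Gaussian
noise, stochastic per-base dwells with translocation-speed drift, gold
per-sample label masks) makes training, inference, merging and evaluation
fully reproducible without sequencer data. Evaluation includes normalized
edit distance (NED), alignment-based read accuracy/identity (RA/RI) from a
built-in semi-global aligner, assembly identity / relative length
summaries (AI/RL), and homopolymer run-length histograms. The whole
network stack (conv/BN/GRU forward and backward passes, Adam) is
implemented in the package's RcppArmadillo kernels.

See `vignettes/segcall-methods.Rmd` for the full model description,
parameter choices, and known limits — in particular the
duration-ambiguity floor on homopolymer recovery under heavy-tailed
dwells, computed by `dwell_ambiguity_floor()`.

## Worked example

Train a tiny model on easy-regime simulated squiggles (low noise,
deterministic dwell) and basecall fresh reads end to end:

```r
library(segcall)

pore  <- pore_model(k = 1, noise_sd = 0.05)
dwell <- dwell_params(9, "fixed", drift_amplitude = 0)

train <- make_dataset(60, 400, pore = pore, dwell = dwell,
                      window_length = 300, seed = 301)
model <- build_model(urnet_config("urnet", preset = "tiny"),
                     window_length = 300, seed = 1)
fit <- train_model(model, train, epochs = 8, batch_size = 32,
                   learning_rate = 2e-3, seed = 1, verbose = TRUE)
#> epoch 1: mean window loss 360.8067
#> ...
#> epoch 8: mean window loss 10.7176

reads <- simulate_read_set(20, 400, pore = pore, dwell = dwell, seed = 777)
sigs  <- lapply(reads, function(r) normalize_signal(r$signal)$samples)
calls <- basecall_reads(fit, sigs, window_length = 300, step = 290)
truths <- vapply(reads, `[[`, character(1), "sequence")
mean(mapply(ned, calls$sequence, truths))
#> [1] 0.00725
```

A mean read NED of 0.007 means the called sequences differ from the
simulated truth by about 3 edits per 400 bases; `calls$segments` holds the
per-base sample intervals of each call. On the default heavy-tailed dwell
regime the same comparison reproduces the architecture ordering (recurrent
variants clearly beat the plain U-net in window NED)
but is bounded below by the duration-ambiguity floor (about 0.40 vs 0.63
held-out window NED for `urnet` vs `unet` in the acceptance run, against a
computed floor of 0.22) — see the vignette.

The same pipeline is scriptable from a shell via the installed `segcall`
executable (`simulate`, `train`, `basecall`, `evaluate`, `benchmark`
subcommands; run any of them with `--help`).

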