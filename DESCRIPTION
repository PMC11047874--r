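Package: ecgdnn
Title: Cycle-Consistent ECG Denoising and Temporal-Convolutional
    Arrhythmia Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale implementation of a two-stage deep-learning
    pipeline for ambulatory electrocardiogram (ECG) analysis: a
    cycle-consistent adversarial denoiser whose generators are
    denoising autoencoders (five strided 1-D convolution blocks down,
    five transposed-convolution blocks up, instance normalisation and
    tanh throughout), and a multi-label arrhythmia classifier built
    from three parallel temporal convolutional network (TCN) branches
    with dilated causal convolutions behind a 2-D convolutional
    front end and a 34-way output head.  Includes a synthetic 8-lead
    ECG simulator with controllable rhythm classes, class imbalance and
    three noise families (Gaussian white noise, baseline wander,
    impulse noise), signal I/O with the 8-to-12 lead linear derivation,
    SNR/MSE and multi-label evaluation metrics, class-weighted losses,
    and a command-line interface covering the full
    simulate/pretrain/train/denoise/classify/evaluate workflow.  The
    neural-network engine (convolutions, instance norm, Adam) is
    implemented in the package with RcppArmadillo kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
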