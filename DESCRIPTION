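Package: zivae
Title: Zero-Inflated Variational Autoencoder Embeddings for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Unsupervised dimension reduction and 2D visualization of
    single-cell RNA-seq expression matrices with a deep variational
    autoencoder whose stochastic output layer explicitly models dropout
    events. The reconstruction passes through a zero-inflation layer in
    which the dropout probability decays as a double exponential of the
    reconstructed expression, sampled with the Gumbel-softmax relaxation
    so the whole network trains end-to-end by backpropagation. Includes
    preprocessing for count and UMI matrices, a seeded RMSprop training
    loop with early stopping, clustering-based evaluation metrics (NMI,
    adjusted Rand index, homogeneity, completeness), Spearman ranking of
    genes against embedding axes, a synthetic-data generator with
    controllable dropout, dense and MatrixMarket readers, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
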