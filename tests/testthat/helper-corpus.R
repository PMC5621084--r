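# Shared fixtures, generated once per test run.

.fixtures <- new.env(parent = emptyenv())

# small corpus: 6 trials/situation at 50 Hz, cheap enough for most tests
smallCorpus <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- generateCorpus(nPerSituation = 6, seed = 7, fs = 50)
  .fixtures$small
}

smallDirect <- function() {
  if (is.null(.fixtures$direct))
    .fixtures$direct <- extractDirect(smallCorpus(), defaultLayout())
  .fixtures$direct
}

# deterministic zig-zag trajectory spanning a rectangle
zigzagTrajectory <- function(n = 200, bounds = c(43, 134), fs = 100) {
  t <- seq(0, 1, length.out = n)
  copTrajectory(cbind(bounds[1] * (0.1 + 0.8 * t),
                      bounds[2] * (0.5 + 0.4 * sin(6 * pi * t))), fs = fs)
}

# feature table from an explicit matrix, labels recycled over 1..k
toyFeatures <- function(values, labels) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  postureFeatures(values, labels, sprintf("trial%03d", seq_len(nrow(values))))
}
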