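# session-level cache so the trained stacked model and heavy simulations are
# shared between the acceptance properties that probe them
.bench <- new.env(parent = emptyenv())

cached_benchmark <- function() {
  if (is.null(.bench$qa))
    .bench$qa <- qa_benchmark(n_train = 12, n_test = 8, n_decoys = 30,
                              L = 60, seed = 1)
  .bench$qa
}
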