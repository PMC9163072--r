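# Heavy study artifacts shared across acceptance tests, computed once
# per test run and cached.

.study_cache <- new.env(parent = emptyenv())

study_memo <- function(name, fn) {
  if (!exists(name, envir = .study_cache))
    assign(name, fn(), envir = .study_cache)
  get(name, envir = .study_cache)
}

# Toy-topology recovery study: auto-parameterized reference, 125
# conditions (100 train / 25 test), trained model.
toy_study <- function() {
  study_memo("toy", function() {
    net <- toy_network()
    ref <- parameterize_reference(
      net, reference_spec(conditions_per_epoch = 100,
                          ligands_per_condition = 2, epochs = 2000,
                          seed = 3))
    cond <- sample_conditions(125, 2, net$ligands, seed = 11)
    y <- suppressWarnings(generate_dataset(ref, cond))
    fit <- train_model(net, cond[1:100, ], y[1:100, ],
                       training_config(epochs = 1000, seed = 5))
    list(net = net, ref = ref, cond = cond, y = y, fit = fit,
         test_idx = 101:125)
  })
}

# Synthetic-generalization study: 200-node fixture, 400 training and 500
# test conditions at 5 simultaneous ligands.
synth_study <- function() {
  study_memo("synth", function() {
    net <- random_network(200, 15, 30, 10, seed = 21)
    ref <- parameterize_reference(
      net, reference_spec(epochs = 1500, seed = 4))
    cond_tr <- sample_conditions(400, 5, net$ligands, seed = 9)
    cond_te <- sample_conditions(500, 5, net$ligands, seed = 10,
                                 prefix = "test")
    y_tr <- suppressWarnings(generate_dataset(ref, cond_tr))
    y_te <- suppressWarnings(generate_dataset(ref, cond_te))
    fit <- train_model(net, cond_tr, y_tr,
                       training_config(epochs = 1200, seed = 5))
    list(net = net, ref = ref, cond_tr = cond_tr, cond_te = cond_te,
         y_tr = y_tr, y_te = y_te, fit = fit)
  })
}
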