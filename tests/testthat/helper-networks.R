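# Shared fixtures built in code.

toy_paths <- function() {
  list(interactions = system.file("extdata", "toy_interactions.tsv",
                                  package = "signalnet"),
       nodes = system.file("extdata", "toy_nodes.tsv",
                           package = "signalnet"))
}

# simple two-node chain L -> T with one weight, handy for hand evaluation
chain_network <- function() {
  interactions <- tibble::tibble(
    source = "L", target = "T", moa = 1L, reversible = FALSE,
    references = list(character(0)), pubmed = list(character(0)))
  annotations <- tibble::tibble(
    id = c("L", "T"), roles = list("ligand", "TF"), synonym = c("L", "T"))
  suppressMessages(reconstruct(signaling_network(interactions, annotations)))
}

# three-node chain L -> M -> T
chain3_network <- function(moa_mid = 1L) {
  interactions <- tibble::tibble(
    source = c("L", "M"), target = c("M", "T"),
    moa = c(1L, moa_mid), reversible = FALSE,
    references = list(character(0)), pubmed = list(character(0)))
  annotations <- tibble::tibble(
    id = c("L", "M", "T"), roles = list("ligand", "signaling", "TF"),
    synonym = c("L", "M", "T"))
  reconstruct(signaling_network(interactions, annotations))
}

# model with prescribed weights on a given network
manual_model <- function(net, weights, bias = 0, input_scale = 3,
                         output_scale = 1.2) {
  signalnet:::new_sn_model(
    net, weights = rep_len(weights, nrow(net$interactions)),
    bias = rep_len(bias, length(net$nodes)),
    input_scale = rep_len(input_scale, length(net$ligands)),
    output_scale = rep_len(output_scale, length(net$tfs)))
}

# numeric loss for finite-difference checks: MSE of predictions vs obs
fd_loss <- function(model, conditions, obs, settings) {
  p <- predict(model, conditions, settings)
  mean((as.matrix(p[, -1]) - as.matrix(obs[, -1]))^2)
}

fd_gradient <- function(model, conditions, obs, settings, h = 1e-5) {
  th0 <- signalnet:::flatten_params(model)
  vapply(seq_along(th0), function(i) {
    tp <- th0; tp[i] <- tp[i] + h
    tm <- th0; tm[i] <- tm[i] - h
    (fd_loss(signalnet:::unflatten_params(model, tp), conditions, obs,
             settings) -
       fd_loss(signalnet:::unflatten_params(model, tm), conditions, obs,
               settings)) / (2 * h)
  }, numeric(1))
}

precise_settings <- function() {
  simulation_settings(max_steps = 5000, tolerance = 1e-13)
}
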