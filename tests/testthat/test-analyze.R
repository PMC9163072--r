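test_that("pearson_flat matches the textbook formula", {
  pred <- tibble::tibble(condition = c("a", "b"), T1 = c(0.1, 0.4),
                         T2 = c(0.8, 0.2))
  ref <- tibble::tibble(condition = c("a", "b"), T1 = c(0.2, 0.5),
                        T2 = c(0.9, 0.1))
  res <- pearson_flat(pred, ref)
  x <- c(0.1, 0.4, 0.8, 0.2); y <- c(0.2, 0.5, 0.9, 0.1)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, manual, tolerance = 1e-12)
  expect_equal(res$n, 4)
  # perfect and anti-perfect correlation
  expect_equal(pearson_flat(pred, pred)$r, 1)
  anti <- ref
  anti[, -1] <- 1 - pred[, -1]
  expect_equal(pearson_flat(pred, anti)$r, -1)
  # rows are aligned on condition ids, not order
  expect_equal(pearson_flat(pred, ref[c(2, 1), ])$r, manual,
               tolerance = 1e-12)
  # zero variance is flagged
  flat <- ref; flat[, -1] <- 0.5
  expect_warning(res0 <- pearson_flat(pred, flat), "zero variance")
  expect_true(is.na(res0$r))
})

test_that("knockout of a disconnected node leaves TFs unchanged", {
  # L -> M -> T plus isolated-ish node D reachable from L but feeding
  # nothing downstream of T is removed in reconstruction, so use a node
  # on a parallel branch that reaches a second TF only
  ann <- tibble::tibble(
    id = c("L", "M", "D", "T", "U"),
    roles = list("ligand", "signaling", "signaling", "TF", "TF"),
    synonym = id)
  ints <- tibble::tibble(
    source = c("L", "M", "L", "D"),
    target = c("M", "T", "D", "U"),
    moa = 1L, reversible = FALSE,
    references = list(character(0)), pubmed = list(character(0)))
  net <- reconstruct(signaling_network(ints, ann))
  model <- manual_model(net, weights = 1, bias = 0)
  cond <- tibble::tibble(condition = "c1", L = 1)
  ko <- ko_scan(model, cond, nodes = "D")
  res <- tidy(ko)
  # D does not reach T: T unchanged; D reaches U: U drops
  expect_equal(res$delta_tf[res$tf == "T"], 0)
  expect_lt(res$delta_tf[res$tf == "U"], -0.1)
})

test_that("knockout of the sole intermediary returns the TF to basal", {
  net <- chain3_network()
  model <- manual_model(net, weights = 1, bias = 0)
  cond <- tibble::tibble(condition = "c1", L = 1)
  basal <- predict(model, tibble::tibble(condition = "c0", L = 0))
  ko <- ko_scan(model, cond, nodes = "M")
  res <- tidy(ko)
  expect_equal(res$perturbed, basal$T[1], tolerance = 0.02)
  # delta = perturbed - control, elementwise
  expect_equal(res$delta_tf, res$perturbed - res$control)
  # ligands cannot be knocked out
  expect_error(ko_scan(model, cond, nodes = "L"), "ligand")
})

test_that("zero-offset scans reproduce control exactly", {
  net <- toy_network()
  model <- initialize_parameters(net, 6)
  cond <- sample_conditions(3, 2, net$ligands, seed = 9)
  ko0 <- ko_scan(model, cond, nodes = c("S1", "S2"), delta = 0)
  expect_true(all(tidy(ko0)$delta_tf == 0))
  ki0 <- knockin_scan(model, cond, nodes = "S1", delta = 0)
  expect_true(all(tidy(ki0)$delta_tf == 0))
})

test_that("knock-in through an inhibitory edge lowers the TF", {
  net <- chain3_network(moa_mid = -1L)
  model <- manual_model(net, weights = c(1, -1), bias = c(0, 0, 0.6))
  cond <- tibble::tibble(condition = "c1", L = 0.1)
  ki <- knockin_scan(model, cond, nodes = "M", delta = 5)
  expect_lt(tidy(ki)$delta_tf, -0.05)
  # knock-in of an already saturated node barely moves anything
  sat <- manual_model(chain3_network(), weights = c(5, 1),
                      bias = c(0, 5, 0))
  ki2 <- knockin_scan(sat, cond, nodes = "M", delta = 5)
  expect_lt(abs(tidy(ki2)$delta_tf), 0.02)
})

test_that("KO effects are sparse across a larger random network", {
  net <- random_network(80, 8, 12, 4, seed = 23)
  model <- initialize_parameters(net, 3)
  model$weights <- model$weights * 1.5
  cond <- sample_conditions(5, 3, net$ligands, seed = 4)
  nodes <- setdiff(net$nodes, net$ligands)[1:30]
  ko <- ko_scan(model, cond, nodes = nodes)
  d <- abs(tidy(ko)$delta_tf)
  expect_lt(median(d), max(d) / 10) # heavy mass at zero
})

test_that("sensitivity approximates the analytic derivative on a chain", {
  net <- chain3_network()
  # keep everything in the linear regime: small weights, small input
  model <- manual_model(net, weights = 0.3, bias = 0.05,
                        input_scale = 0.4, output_scale = 1)
  cond <- tibble::tibble(condition = "c1", L = 0.5)
  sens <- sensitivity_analysis(model, cond, nodes = "M", epsilon = 0.01)
  res <- tidy(sens)
  # analytic: perturbing the input of M by eps*z_M changes z_M by the
  # same amount; dT/dz_M = sigma'(z_M) * w_MT * sigma'(z_T) (chain rule),
  # so sensitivity = delta/(eps * z_M) ~ dT/dz_M (output scale 1,
  # linear regime sigma' = 1)
  expect_equal(res$sensitivity, 0.3, tolerance = 0.01)
  # first-order consistency: halving epsilon barely changes it
  s2 <- tidy(sensitivity_analysis(model, cond, nodes = "M",
                                  epsilon = 0.005))
  expect_equal(s2$sensitivity, res$sensitivity, tolerance = 0.01)
})

test_that("sensitivity is zero for nodes disconnected from a TF", {
  ann <- tibble::tibble(
    id = c("L", "M", "D", "T", "U"),
    roles = list("ligand", "signaling", "signaling", "TF", "TF"),
    synonym = id)
  ints <- tibble::tibble(
    source = c("L", "M", "L", "D"),
    target = c("M", "T", "D", "U"),
    moa = 1L, reversible = FALSE,
    references = list(character(0)), pubmed = list(character(0)))
  net <- reconstruct(signaling_network(ints, ann))
  model <- manual_model(net, weights = 1, bias = 0)
  cond <- tibble::tibble(condition = "c1", L = 1)
  sens <- sensitivity_analysis(model, cond, nodes = c("D", "M"),
                               threshold = 0.1)
  res <- tidy(sens)
  expect_equal(res$sensitivity[res$node == "D" & res$tf == "T"], 0)
  expect_gt(abs(res$sensitivity[res$node == "M" & res$tf == "T"]), 0.01)
  # strong-node summary honours the threshold
  expect_true("M" %in% sens$strong_nodes)
})
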