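test_that("toy files parse into a validated network", {
  p <- toy_paths()
  net <- load_network(p$interactions, p$nodes)
  expect_s3_class(net, "sn_network")
  expect_length(net$nodes, 7)
  expect_equal(nrow(net$interactions), 8)
  expect_equal(net$ligands, c("L1", "L2"))
  expect_equal(net$tfs, "T1")
  expect_equal(net$interactions$moa[net$interactions$source == "S2"], -1L)
})

test_that("malformed inputs are rejected with informative errors", {
  p <- toy_paths()
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tmoa\treversible",
               "A\tB\tupregulates\t0"), bad)
  expect_error(read_interactions(bad), "unrecognized moa.*line 2")
  writeLines("source\ttarget\tmoa\treversible", bad)
  expect_error(read_interactions(bad), "no rows")
  writeLines(c("id\troles", "A\tkinase"), bad)
  expect_error(read_annotations(bad), "unknown role")
  # interaction node missing from annotations
  ints <- read_interactions(p$interactions)
  ann <- read_annotations(p$nodes)
  expect_error(signaling_network(ints, ann[ann$id != "S2", ]),
               "absent from annotations.*S2")
})

test_that("duplicate edges are merged with a warning", {
  p <- toy_paths()
  ints <- read_interactions(p$interactions)
  ann <- read_annotations(p$nodes)
  expect_warning(net <- signaling_network(rbind(ints, ints[1, ]), ann),
                 "duplicate")
  expect_equal(nrow(net$interactions), 8)
})

test_that("reconstruction applies the pruning rules", {
  ann <- tibble::tibble(
    id = c("L", "R", "S", "D", "Q", "T"),
    roles = list("ligand", "receptor", "signaling", "signaling",
                 "signaling", "TF"),
    synonym = id)
  ints <- tibble::tibble(
    source = c("L", "R", "S", "R", "S", "S", "Q"),
    target = c("R", "S", "T", "D", "Q", "Q", "S"),
    moa = c(1L, 1L, 1L, 1L, 1L, -1L, 1L),
    reversible = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    references = list(character(0)), pubmed = list(character(0)))
  net <- reconstruct(signaling_network(ints, ann))
  # D is a dead end (no path to any TF) and is removed
  expect_false("D" %in% net$nodes)
  # Q only connects to and from S: redundant, removed
  expect_false("Q" %in% net$nodes)
  # reversible R-S expanded to two directed edges
  expect_true(any(net$interactions$source == "S" &
                    net$interactions$target == "R"))
  # conflicting S->Q moa would have merged to unknown had Q survived;
  # surviving edges retain their moa
  expect_equal(
    net$interactions$moa[net$interactions$source == "L"], 1L)
})

test_that("conflicting modes of action merge to unknown", {
  ann <- tibble::tibble(id = c("L", "T"), roles = list("ligand", "TF"),
                        synonym = id)
  ints <- tibble::tibble(
    source = c("L", "L"), target = c("T", "T"), moa = c(1L, -1L),
    reversible = FALSE,
    references = list("a", "b"), pubmed = list(character(0)))
  net <- reconstruct(signaling_network(ints, ann))
  expect_equal(nrow(net$interactions), 1)
  expect_equal(net$interactions$moa, 0L)
})

test_that("reconstruct is idempotent and never grows the network", {
  net <- random_network(60, 5, 8, 4, seed = 3)
  again <- reconstruct(net)
  expect_equal(again$nodes, net$nodes)
  expect_equal(again$interactions[, c("source", "target", "moa")],
               net$interactions[, c("source", "target", "moa")])
  p <- toy_paths()
  raw <- load_network(p$interactions, p$nodes)
  r1 <- reconstruct(raw)
  r2 <- reconstruct(r1)
  expect_equal(r2$nodes, r1$nodes)
  expect_lte(length(r1$nodes), length(raw$nodes))
  expect_true(all(r1$ligands %in% raw$ligands))
})

test_that("a network with no ligand-TF path is rejected", {
  ann <- tibble::tibble(id = c("L", "S", "T"),
                        roles = list("ligand", "signaling", "TF"),
                        synonym = id)
  ints <- tibble::tibble(
    source = c("L", "T"), target = c("S", "S"), moa = 1L,
    reversible = FALSE,
    references = list(character(0)), pubmed = list(character(0)))
  expect_error(reconstruct(signaling_network(ints, ann)), "empty model")
})

test_that("parameter files round-trip losslessly", {
  net <- toy_network()
  model <- initialize_parameters(net, 42)
  f <- tempfile(fileext = ".tsv")
  save_parameters(model, f)
  back <- load_parameters(f, net)
  expect_identical(back$weights, model$weights)
  expect_identical(back$bias, model$bias)
  expect_identical(back$input_scale, model$input_scale)
  expect_identical(back$output_scale, model$output_scale)
  # a second save is byte-identical (deterministic ordering)
  f2 <- tempfile(fileext = ".tsv")
  save_parameters(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("parameter loading validates coverage against the network", {
  net <- toy_network()
  model <- initialize_parameters(net, 1)
  f <- tempfile(fileext = ".tsv")
  save_parameters(model, f)
  # drop the bias entry for S1
  df <- read.delim(f, colClasses = "character")
  drop_bias <- !(df$type == "bias" & df$source == "S1")
  f3 <- tempfile(fileext = ".tsv")
  write.table(df[drop_bias, ], f3, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_parameters(f3, net), "S1")
  # weight for an edge absent from the network
  df2 <- read.delim(f, colClasses = "character")
  extra <- df2[df2$type == "weight", ][1, ]
  extra$source <- "L1"; extra$target <- "T1"
  f4 <- tempfile(fileext = ".tsv")
  write.table(rbind(df2, extra), f4, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_parameters(f4, net), "absent from the network")
})

test_that("hand-written two-edge parameter file yields the right matrix", {
  net <- chain3_network()
  lines <- c("type\tvalue\tsource\ttarget",
             "bias\t0\tL\t", "bias\t0.5\tM\t", "bias\t0\tT\t",
             "input_projection\t3\tL\t",
             "output_projection\t1\tT\t",
             "weight\t0.7\tL\tM", "weight\t-0.2\tM\tT")
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  model <- load_parameters(f, net)
  A <- as.matrix(weight_matrix(model))
  expect_equal(sum(A != 0), 2)
  expect_equal(A[match("M", net$nodes), match("L", net$nodes)], 0.7)
  expect_equal(A[match("T", net$nodes), match("M", net$nodes)], -0.2)
  expect_equal(model$bias[match("M", net$nodes)], 0.5)
})

test_that("condition tables round-trip through the TSV dialect", {
  tbl <- sample_conditions(5, 2, c("L1", "L2", "L3"), seed = 8)
  f <- tempfile(fileext = ".tsv")
  write_condition_table(tbl, f)
  back <- read_condition_table(f)
  expect_equal(back, tbl)
})
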