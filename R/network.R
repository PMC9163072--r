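#' @importFrom rlang .data
NULL

VALID_ROLES <- c("ligand", "receptor", "signaling", "TF")
MOA_LEVELS <- c(stimulation = 1L, inhibition = -1L, unknown = 0L)

#' Read a prior-knowledge interaction list
#'
#' Tab-separated file with header and columns `source`, `target`, `moa`
#' (`stimulation`/`inhibition`/`unknown`), `reversible` (0/1), and optional
#' `references` and `pubmed` (semicolon-separated). Nodes are typically
#' identified by UniProt accessions, but any identifier scheme works.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `source`, `target`, `moa` (integer, +1
#'   activating / -1 inhibiting / 0 unknown), `reversible` (logical),
#'   `references`, `pubmed` (list columns of character vectors).
#' @export
read_interactions <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("source", "target", "moa", "reversible")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("interaction file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0) stop("interaction file ", path, " contains no rows")
  bad <- which(!df$moa %in% names(MOA_LEVELS))
  if (length(bad) > 0)
    stop("unrecognized moa value '", df$moa[bad[1]], "' on line ",
         bad[1] + 1L, " of ", path)
  bad <- which(!df$reversible %in% c("0", "1"))
  if (length(bad) > 0)
    stop("reversible must be 0 or 1; offending line ", bad[1] + 1L,
         " of ", path)
  split_semi <- function(x) {
    lapply(x, function(s) {
      if (is.na(s) || s == "") character(0) else strsplit(s, ";")[[1]]
    })
  }
  tibble::tibble(
    source = df$source,
    target = df$target,
    moa = unname(MOA_LEVELS[df$moa]),
    reversible = df$reversible == "1",
    references = split_semi(if (is.null(df$references)) rep("", nrow(df))
                            else df$references),
    pubmed = split_semi(if (is.null(df$pubmed)) rep("", nrow(df))
                        else df$pubmed)
  )
}

#' Read a node-annotation table
#'
#' Tab-separated with header and columns `id`, `roles` (semicolon-separated
#' subset of ligand/receptor/signaling/TF), and optional `synonym`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `id`, `roles` (list column), `synonym`.
#' @export
read_annotations <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(c("id", "roles"), names(df))
  if (length(missing) > 0)
    stop("annotation file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  roles <- lapply(df$roles, function(s) strsplit(s, ";")[[1]])
  bad <- which(vapply(roles, function(r) any(!r %in% VALID_ROLES), logical(1)))
  if (length(bad) > 0)
    stop("unknown role '",
         setdiff(roles[[bad[1]]], VALID_ROLES)[1],
         "' for node ", df$id[bad[1]], " in ", path)
  tibble::tibble(
    id = df$id,
    roles = roles,
    synonym = if (is.null(df$synonym)) df$id else df$synonym
  )
}

#' Construct a signaling network from interaction and annotation tables
#'
#' Validates that every node referenced by an interaction is annotated,
#' deduplicates exact duplicate edges (with a warning), and establishes the
#' canonical lexicographic node and edge ordering used for all parameter
#' vectors and projections.
#'
#' @param interactions Tibble as returned by [read_interactions()].
#' @param annotations Tibble as returned by [read_annotations()].
#' @return An object of class `"sn_network"`: a list with elements
#'   `interactions`, `annotations`, `nodes`, `ligands`, `tfs`.
#' @export
signaling_network <- function(interactions, annotations) {
  if (nrow(interactions) == 0) stop("interaction table is empty")
  referenced <- unique(c(interactions$source, interactions$target))
  unannotated <- setdiff(referenced, annotations$id)
  if (length(unannotated) > 0)
    stop("node(s) referenced by interactions but absent from annotations: ",
         paste(unannotated, collapse = ", "))
  if (anyDuplicated(annotations$id) > 0)
    stop("duplicate annotation entries for: ",
         paste(unique(annotations$id[duplicated(annotations$id)]),
               collapse = ", "))
  dup <- duplicated(interactions[, c("source", "target", "moa")])
  if (any(dup)) {
    warning(sum(dup), " duplicate interaction row(s) removed")
    interactions <- interactions[!dup, , drop = FALSE]
  }
  self <- interactions$source == interactions$target
  if (any(self))
    message(sum(self), " self-interaction(s) retained: ",
            paste(unique(interactions$source[self]), collapse = ", "))
  annotations <- annotations[annotations$id %in% referenced, , drop = FALSE]
  net <- structure(list(interactions = interactions,
                        annotations = annotations),
                   class = "sn_network")
  sn_reindex(net)
}

has_role <- function(annotations, role) {
  vapply(annotations$roles, function(r) role %in% r, logical(1))
}

# Recompute canonical orderings: nodes, ligands, TFs sorted
# lexicographically; edges sorted by (source, target).
sn_reindex <- function(net) {
  ann <- net$annotations[order(net$annotations$id), , drop = FALSE]
  ints <- net$interactions[order(net$interactions$source,
                                 net$interactions$target), , drop = FALSE]
  net$annotations <- ann
  net$interactions <- ints
  net$nodes <- ann$id
  net$ligands <- ann$id[has_role(ann, "ligand")]
  net$tfs <- ann$id[has_role(ann, "TF")]
  net
}

#' @export
print.sn_network <- function(x, ...) {
  cat("<sn_network> ", length(x$nodes), " nodes (",
      length(x$ligands), " ligands, ", length(x$tfs), " TFs), ",
      nrow(x$interactions), " interactions\n", sep = "")
  invisible(x)
}

#' Load a signaling network from disk
#'
#' @param interaction_path Path to the interaction TSV.
#' @param annotation_path Path to the annotation TSV.
#' @return An `sn_network` object (not yet reconstructed; see
#'   [reconstruct()]).
#' @export
load_network <- function(interaction_path, annotation_path) {
  signaling_network(read_interactions(interaction_path),
                    read_annotations(annotation_path))
}

#' Reconstruct (prune) a signaling network
#'
#' Applies the standard model-reconstruction rules to a raw prior-knowledge
#' network: reversible interactions are duplicated and reversed; duplicate
#' directed edges are merged; edges listed with conflicting modes of action
#' (both activating and inhibiting) have their mode of action removed
#' (set to unknown); dead-end nodes -- nodes with no directed path from any
#' ligand or no directed path to any TF -- are removed iteratively until a
#' fixed point; nodes whose only source and only target are one and the
#' same node are considered redundant and removed. The operation is
#' idempotent.
#'
#' @param net An `sn_network`.
#' @return The pruned `sn_network`, with a `reconstruction` attribute
#'   recording node/edge counts before and after.
#' @export
reconstruct <- function(net) {
  stopifnot(inherits(net, "sn_network"))
  if (length(net$ligands) == 0 || length(net$tfs) == 0)
    stop("network must contain at least one ligand and one TF")
  n0 <- length(net$nodes); e0 <- nrow(net$interactions)

  ints <- net$interactions
  rev_idx <- which(ints$reversible)
  if (length(rev_idx) > 0) {
    mirrored <- ints[rev_idx, , drop = FALSE]
    tmp <- mirrored$source
    mirrored$source <- mirrored$target
    mirrored$target <- tmp
    ints$reversible <- FALSE
    mirrored$reversible <- FALSE
    ints <- dplyr::bind_rows(ints, mirrored)
  }

  # merge duplicate directed edges; conflicting moa -> unknown
  ints <- ints |>
    dplyr::group_by(.data$source, .data$target) |>
    dplyr::summarise(
      moa = {
        m <- unique(.data$moa[.data$moa != 0L])
        if (length(m) == 1L) m else 0L
      },
      reversible = FALSE,
      references = list(sort(unique(unlist(.data$references)))),
      pubmed = list(sort(unique(unlist(.data$pubmed)))),
      .groups = "drop"
    )

  # iterative dead-end and redundant-node removal
  repeat {
    nodes <- sort(unique(c(ints$source, ints$target)))
    ligs <- intersect(net$ligands, nodes)
    tfs <- intersect(net$tfs, nodes)
    if (length(ligs) == 0 || length(tfs) == 0 || nrow(ints) == 0)
      stop("reconstruction removed all ligand-to-TF paths; empty model")
    g <- igraph::graph_from_data_frame(
      ints[, c("source", "target")], directed = TRUE,
      vertices = data.frame(name = nodes))
    dist_from <- igraph::distances(g, v = ligs, to = nodes, mode = "out")
    from_lig <- apply(is.finite(dist_from), 2, any)
    dist_to <- igraph::distances(g, v = nodes, to = tfs, mode = "out")
    to_tf <- apply(is.finite(dist_to), 1, any)
    keep <- from_lig & to_tf

    # redundant: single in-neighbor == single out-neighbor == same node
    indeg_nb <- split(ints$source, ints$target)
    outdeg_nb <- split(ints$target, ints$source)
    redundant <- vapply(nodes, function(v) {
      inn <- unique(indeg_nb[[v]]); outn <- unique(outdeg_nb[[v]])
      length(inn) == 1 && length(outn) == 1 && inn == outn && inn != v
    }, logical(1))
    drop <- !keep | redundant
    if (!any(drop)) break
    dead <- nodes[drop]
    ints <- ints[!(ints$source %in% dead) & !(ints$target %in% dead), ,
                 drop = FALSE]
    if (nrow(ints) == 0)
      stop("reconstruction removed all ligand-to-TF paths; empty model")
  }

  nodes <- sort(unique(c(ints$source, ints$target)))
  net$interactions <- ints
  net$annotations <- net$annotations[net$annotations$id %in% nodes, ,
                                     drop = FALSE]
  net <- sn_reindex(net)
  attr(net, "reconstruction") <- list(nodes_before = n0, edges_before = e0,
                                      nodes_after = length(net$nodes),
                                      edges_after = nrow(net$interactions))
  net
}

#' Read or write a condition-by-variable data table
#'
#' The TSV dialect used for both ligand-concentration inputs and TF-activity
#' outputs: conditions as rows, first column `condition`, remaining columns
#' one per ligand or TF.
#'
#' @param path File path.
#' @return `read_condition_table()` returns a tibble whose first column is
#'   `condition` (character) and whose remaining columns are numeric.
#' @export
read_condition_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1] <- "condition"
  df$condition <- as.character(df$condition)
  tibble::as_tibble(df)
}

#' @rdname read_condition_table
#' @param tbl Tibble with a `condition` column followed by numeric columns.
#' @export
write_condition_table <- function(tbl, path) {
  stopifnot("condition" %in% names(tbl))
  out <- tbl[, c("condition", setdiff(names(tbl), "condition"))]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save or load model parameters in the plain-text exchange format
#'
#' Each row holds a parameter type (`bias`, `weight`, `input_projection`,
#' or `output_projection`), its value at full floating precision, and the
#' source/target node identifiers (target used only for weights). Rows are
#' ordered deterministically by (type, source, target), so saving is
#' reproducible and `save_parameters()` followed by [load_parameters()] is
#' lossless.
#'
#' @param model An `sn_model` (see [initialize_parameters()]).
#' @param path File path for the TSV.
#' @export
save_parameters <- function(model, path) {
  stopifnot(inherits(model, "sn_model"))
  net <- model$network
  rows <- dplyr::bind_rows(
    tibble::tibble(type = "bias", value = model$bias,
                   source = net$nodes, target = ""),
    tibble::tibble(type = "input_projection", value = model$input_scale,
                   source = net$ligands, target = ""),
    tibble::tibble(type = "output_projection", value = model$output_scale,
                   source = net$tfs, target = ""),
    tibble::tibble(type = "weight", value = model$weights,
                   source = net$interactions$source,
                   target = net$interactions$target)
  )
  rows <- rows[order(rows$type, rows$source, rows$target), , drop = FALSE]
  rows$value <- sprintf("%.17g", rows$value)
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname save_parameters
#' @param net The `sn_network` the parameters belong to (must match the
#'   network the file was written against).
#' @return `load_parameters()` returns an `sn_model`.
#' @export
load_parameters <- function(path, net) {
  stopifnot(file.exists(path), inherits(net, "sn_network"))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric",
                                         "character", "character"),
                          na.strings = NULL)
  pick <- function(type) df[df$type == type, , drop = FALSE]
  b <- pick("bias")
  if (!setequal(b$source, net$nodes))
    stop("bias entries do not cover the network nodes; missing: ",
         paste(setdiff(net$nodes, b$source), collapse = ", "))
  bias <- b$value[match(net$nodes, b$source)]
  ip <- pick("input_projection")
  if (!setequal(ip$source, net$ligands))
    stop("input_projection entries do not match network ligands")
  input_scale <- ip$value[match(net$ligands, ip$source)]
  op <- pick("output_projection")
  if (!setequal(op$source, net$tfs))
    stop("output_projection entries do not match network TFs")
  output_scale <- op$value[match(net$tfs, op$source)]
  w <- pick("weight")
  key_file <- paste(w$source, w$target, sep = "\r")
  key_net <- paste(net$interactions$source, net$interactions$target,
                   sep = "\r")
  extra <- setdiff(key_file, key_net)
  if (length(extra) > 0)
    stop("weight entries for edges absent from the network: ",
         paste(gsub("\r", " -> ", extra), collapse = ", "))
  if (length(setdiff(key_net, key_file)) > 0)
    stop("weight entries missing for edges: ",
         paste(gsub("\r", " -> ", setdiff(key_net, key_file)),
               collapse = ", "))
  weights <- w$value[match(key_net, key_file)]
  new_sn_model(net, weights = weights, bias = bias,
               input_scale = input_scale, output_scale = output_scale)
}
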