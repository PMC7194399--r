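# Taxonomy cladogram of the selected OTUs: a multifurcating tree built from
# the rank lineages (domain -> genus -> OTU leaf), annotated per component
# with leaf loadings and per-clade mean loadings, and exported as Newick
# plus a GraPhlAn-style annotation table.

# Sanitize a label for Newick / annotation use.
clean_label <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

#' Taxonomy cladogram with per-component loading summaries
#'
#' Builds one multifurcating taxonomy tree over the union of OTUs selected
#' in any component, so that the tree layout is shared across components and
#' the per-component pictures are directly comparable. For each component,
#' leaves selected in that component carry their loading (others are blank)
#' and every internal node carries the arithmetic mean of the loadings of
#' its selected descendant leaves.
#'
#' @param selection A `selection_result` (from [select_all_components()]).
#' @param model The [fit_cca()] model the selection derives from.
#' @param taxonomy A [taxonomy_table()]; OTUs without an entry are attached
#'   under an all-`"unknown"` lineage with a warning.
#' @return Object of class `clade_summary`: a list with `nodes` (data frame:
#'   `id`, `parent`, `label`, `rank`, `is_leaf`, `otu_id`), `leaf_values`
#'   (leaves x components loading matrix, `NA` where unselected) and
#'   `node_means` (nodes x components matrix of descendant means, `NA`
#'   where a node has no selected descendant). Empty selection gives an
#'   empty tree (zero-row tables).
#' @export
clade_summary <- function(selection, model, taxonomy) {
  stopifnot(inherits(selection, "selection_result"),
            inherits(model, "cca_model"))
  K <- ncol(model$loadings)
  comp_names <- colnames(model$loadings)
  otus <- unique(selection$otu_id)
  empty_nodes <- data.frame(id = character(), parent = character(),
                            label = character(), rank = character(),
                            is_leaf = logical(), otu_id = character(),
                            stringsAsFactors = FALSE)
  if (!length(otus)) {
    return(structure(list(nodes = empty_nodes,
                          leaf_values = matrix(NA_real_, 0, K,
                                               dimnames = list(NULL, comp_names)),
                          node_means = matrix(NA_real_, 0, K,
                                              dimnames = list(NULL, comp_names))),
                     class = "clade_summary"))
  }
  missing_tax <- setdiff(otus, rownames(taxonomy))
  if (length(missing_tax)) {
    warning(length(missing_tax),
            " selected OTU(s) missing from taxonomy; attached under an ",
            "'unknown' lineage", call. = FALSE)
  }
  tax <- matrix(UNKNOWN_RANK, nrow = length(otus),
                ncol = length(TAXONOMY_RANKS),
                dimnames = list(otus, TAXONOMY_RANKS))
  present <- intersect(otus, rownames(taxonomy))
  tax[present, ] <- unclass(taxonomy)[present, , drop = FALSE]

  # nodes are identified by their full path so that equal names at
  # different positions (e.g. repeated "unknown") stay distinct
  nodes <- list(root = list(id = "root", parent = NA_character_,
                            label = "root", rank = "root",
                            is_leaf = FALSE, otu_id = NA_character_))
  for (o in otus) {
    path <- "root"
    for (r in TAXONOMY_RANKS) {
      nm <- tax[o, r]
      child <- paste(path, nm, sep = "|")
      if (is.null(nodes[[child]])) {
        nodes[[child]] <- list(id = child, parent = path, label = nm,
                               rank = r, is_leaf = FALSE,
                               otu_id = NA_character_)
      }
      path <- child
    }
    leaf <- paste(path, o, sep = "|")
    nodes[[leaf]] <- list(id = leaf, parent = path, label = o,
                          rank = "otu", is_leaf = TRUE, otu_id = o)
  }
  nodes <- do.call(rbind, lapply(nodes, function(n)
    data.frame(n, stringsAsFactors = FALSE)))
  rownames(nodes) <- NULL

  leaf_ids <- nodes$otu_id[nodes$is_leaf]
  leaf_values <- matrix(NA_real_, length(leaf_ids), K,
                        dimnames = list(leaf_ids, comp_names))
  for (k in seq_len(K)) {
    sel_k <- selection$otu_id[selection$component == k]
    sel_k <- intersect(sel_k, rownames(model$loadings))
    leaf_values[intersect(sel_k, leaf_ids), k] <-
      model$loadings[intersect(sel_k, leaf_ids), k]
  }

  # mean loading of selected descendant leaves, per node, per component
  node_means <- matrix(NA_real_, nrow(nodes), K,
                       dimnames = list(nodes$id, comp_names))
  leaf_node_ids <- nodes$id[nodes$is_leaf]
  parent_of <- stats::setNames(nodes$parent, nodes$id)
  for (k in seq_len(K)) {
    sums <- stats::setNames(numeric(nrow(nodes)), nodes$id)
    cnts <- stats::setNames(numeric(nrow(nodes)), nodes$id)
    for (i in seq_along(leaf_node_ids)) {
      v <- leaf_values[i, k]
      if (is.na(v)) next
      node <- leaf_node_ids[i]
      while (!is.na(node)) {
        sums[node] <- sums[node] + v
        cnts[node] <- cnts[node] + 1
        node <- parent_of[[node]]
      }
    }
    node_means[cnts > 0, k] <- sums[cnts > 0] / cnts[cnts > 0]
  }
  structure(list(nodes = nodes, leaf_values = leaf_values,
                 node_means = node_means),
            class = "clade_summary")
}

# Recursive Newick construction from the node table.
newick_subtree <- function(nodes, id) {
  children <- nodes$id[!is.na(nodes$parent) & nodes$parent == id]
  row <- nodes[nodes$id == id, ]
  label <- clean_label(row$label)
  if (!length(children)) return(paste0(label, ":1"))
  inner <- paste(vapply(children, function(ch) newick_subtree(nodes, ch),
                        character(1L)), collapse = ",")
  paste0("(", inner, ")", label, ":1")
}

#' Export a cladogram as Newick plus GraPhlAn-style annotation
#'
#' Writes the shared taxonomy tree as a Newick file (internal node labels
#' kept, unit branch lengths) and one annotation table per component. The
#' annotation is the 3-column tab-separated GraPhlAn syntax
#' (`node`, `attribute`, `value`): each selected leaf gets a
#' `clade_marker_color` row (red for positive loadings, cyan for negative),
#' and each internal clade with selected descendants gets an
#' `annotation_background_color` row whose colour alpha scales linearly
#' with the magnitude of the clade's mean loading (from 0 at mean 0 to
#' opaque at the largest observed |mean|).
#'
#' @param cs A [clade_summary()].
#' @param out_dir Output directory, created if needed.
#' @param basename File stem; writes `<basename>.nwk` and
#'   `<basename>_annot_<component>.tsv`.
#' @return Invisibly, a named list with `newick` (path) and `annotations`
#'   (vector of paths, one per component).
#' @export
export_cladogram <- function(cs, out_dir, basename = "cladogram") {
  stopifnot(inherits(cs, "clade_summary"))
  if (!nrow(cs$nodes)) stop("empty cladogram: nothing to export",
                            call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir,
                                 call. = FALSE)
  nwk_path <- file.path(out_dir, paste0(basename, ".nwk"))
  writeLines(paste0(newick_subtree(cs$nodes, "root"), ";"), nwk_path)

  comp_names <- colnames(cs$leaf_values)
  annot_paths <- character(length(comp_names))
  pos_col <- "#FF0000"  # red
  neg_col <- "#00FFFF"  # cyan
  for (k in seq_along(comp_names)) {
    rows <- list()
    leaves <- cs$nodes[cs$nodes$is_leaf, ]
    vals <- cs$leaf_values[, k]
    for (i in seq_len(nrow(leaves))) {
      v <- vals[[leaves$otu_id[i]]]
      if (is.na(v)) next
      rows[[length(rows) + 1L]] <- c(clean_label(leaves$label[i]),
                                     "clade_marker_color",
                                     if (v >= 0) pos_col else neg_col)
    }
    internal <- cs$nodes[!cs$nodes$is_leaf & cs$nodes$id != "root", ]
    means <- cs$node_means[internal$id, k]
    max_abs <- if (all(is.na(means))) 0 else max(abs(means), na.rm = TRUE)
    for (i in seq_len(nrow(internal))) {
      m <- means[[i]]
      if (is.na(m)) next
      alpha <- if (max_abs > 0) abs(m) / max_abs else 0
      base <- if (m >= 0) pos_col else neg_col
      col <- paste0(base, sprintf("%02X", round(255 * alpha)))
      rows[[length(rows) + 1L]] <- c(clean_label(internal$label[i]),
                                     "annotation_background_color", col)
    }
    annot_paths[k] <- file.path(out_dir,
                                paste0(basename, "_annot_", comp_names[k],
                                       ".tsv"))
    if (length(rows)) {
      utils::write.table(do.call(rbind, rows), annot_paths[k], sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
    } else {
      file.create(annot_paths[k])
    }
  }
  invisible(list(newick = nwk_path, annotations = annot_paths))
}
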