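# CareFlow-Miner-style process discovery: a prefix tree of treatment-line
# label sequences rooted at recruitment, with per-node patient sets, anchor
# dates, branch fractions and threshold pruning.

ROOT_LABEL <- "recruitment"

#' Discover the treatment tree from an event log
#'
#' Builds the prefix tree of per-patient treatment-label sequences. The root
#' ("recruitment") holds every patient; it branches to all observed first
#' treatments, each of which branches to all second treatments observed in
#' its sub-cohort, recursively. A patient belongs to a node at depth d iff
#' the first d labels of its sequence equal the node's path. Nodes reached by
#' fewer than `min_patients` patients are omitted together with their whole
#' subtree. Children are ordered by descending patient count, ties broken by
#' label, so identical logs always yield identical trees.
#'
#' Each non-root node stores, per patient, the start date of the treatment
#' line it represents; these anchor dates drive node-level survival analysis.
#'
#' @param log an `event_log`.
#' @param min_patients non-negative pruning threshold (0 = keep everything).
#' @return an object of class `treatment_tree`: list with `nodes` (list of
#'   node records: `id, parent, depth, label, setting, type, children,
#'   patients, anchors`), `root` (= 1), `min_patients`, `n_patients`.
#' @export
discover_tree <- function(log, min_patients = 0) {
  stopifnot(inherits(log, "event_log"), min_patients >= 0)
  seqs <- patient_sequences(log)
  anchor_tab <- log$events
  # per patient, vector of start dates aligned with the label sequence
  starts <- rep(list(as.Date(character())), length(seqs))
  names(starts) <- names(seqs)
  settings <- rep(list(character(0)), length(seqs))
  names(settings) <- names(seqs)
  types <- settings
  if (nrow(anchor_tab) > 0) {
    sp <- split(seq_len(nrow(anchor_tab)), anchor_tab$patient_id)
    for (pid in names(sp)) {
      idx <- sp[[pid]]
      starts[[pid]] <- anchor_tab$start[idx]
      settings[[pid]] <- anchor_tab$setting[idx]
      types[[pid]] <- anchor_tab$type[idx]
    }
  }

  nodes <- list()
  new_node <- function(label, setting, type, depth, parent, pats, anchors) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, parent = parent, depth = depth,
                         label = label, setting = setting, type = type,
                         children = integer(0), patients = pats,
                         anchors = anchors)
    id
  }

  grow <- function(node_id, pats, depth) {
    longer <- pats[vapply(seqs[pats], length, 1L) > depth]
    if (length(longer) == 0) return(invisible())
    nxt <- vapply(seqs[longer], function(s) s[depth + 1L], "")
    counts <- table(nxt)
    labs <- names(counts)
    ord <- order(-as.integer(counts), labs)
    for (lab in labs[ord]) {
      child_pats <- longer[nxt == lab]
      if (length(child_pats) < min_patients) next
      anchors <- as.Date(vapply(child_pats, function(p)
        as.character(starts[[p]][depth + 1L]), ""))
      names(anchors) <- child_pats
      setting1 <- settings[[child_pats[1]]][depth + 1L]
      type1 <- types[[child_pats[1]]][depth + 1L]
      cid <- new_node(lab, setting1, type1, depth + 1L, node_id,
                      child_pats, anchors)
      nodes[[node_id]]$children <<- c(nodes[[node_id]]$children, cid)
      grow(cid, child_pats, depth + 1L)
    }
  }

  all_pats <- names(seqs)
  root <- new_node(ROOT_LABEL, NA_character_, NA_character_, 0L, NA_integer_,
                   all_pats, NULL)
  grow(root, all_pats, 0L)

  structure(list(nodes = nodes, root = 1L,
                 min_patients = as.integer(min_patients),
                 n_patients = length(all_pats)),
            class = "treatment_tree")
}

#' @export
print.treatment_tree <- function(x, max_depth = 3, ...) {
  cat("<treatment_tree> ", length(x$nodes), " nodes, ",
      x$n_patients, " patients, pruning threshold ", x$min_patients,
      "\n", sep = "")
  show <- function(id, indent) {
    nd <- x$nodes[[id]]
    lab <- if (nd$depth == 0) ROOT_LABEL else nd$label
    cat(strrep("  ", indent), lab, " (n=", length(nd$patients), ")\n",
        sep = "")
    if (nd$depth < max_depth)
      for (c in nd$children) show(c, indent + 1)
    else if (length(nd$children) > 0)
      cat(strrep("  ", indent + 1), "...\n", sep = "")
  }
  show(x$root, 0)
  invisible(x)
}

#' Prune a treatment tree at a higher patient threshold
#'
#' Removes every node (and its whole subtree) with fewer patients than
#' `min_patients`. Pruning can only remove nodes: a threshold below the
#' tree's current one is an error (rebuild with [discover_tree()] instead).
#' The result is identical to discovering the tree at the new threshold.
#'
#' @param tree a `treatment_tree`.
#' @param min_patients new threshold, `>= tree$min_patients`.
#' @return a `treatment_tree`.
#' @export
prune_tree <- function(tree, min_patients) {
  stopifnot(inherits(tree, "treatment_tree"))
  if (min_patients < tree$min_patients) {
    stop("pruning threshold (", min_patients,
         ") below the tree's current threshold (", tree$min_patients,
         "); rebuild with discover_tree() instead")
  }
  old <- tree$nodes
  nodes <- list()
  copy <- function(old_id, new_parent) {
    nd <- old[[old_id]]
    id <- length(nodes) + 1L
    nd$id <- id; nd$parent <- new_parent
    kids <- nd$children
    nd$children <- integer(0)
    nodes[[id]] <<- nd
    for (k in kids) {
      if (length(old[[k]]$patients) >= min_patients) {
        cid <- copy(k, id)
        nodes[[id]]$children <<- c(nodes[[id]]$children, cid)
      }
    }
    id
  }
  copy(tree$root, NA_integer_)
  structure(list(nodes = nodes, root = 1L,
                 min_patients = as.integer(min_patients),
                 n_patients = tree$n_patients),
            class = "treatment_tree")
}

#' Fraction of the parent's patients entering a node
#'
#' Drawn as branch thickness in the tree display: the share of patients from
#' the parent box undergoing this next treatment.
#'
#' @param tree a `treatment_tree`.
#' @param node_id a non-root node id.
#' @return a number in `[0, 1]`.
#' @export
branch_fraction <- function(tree, node_id) {
  nd <- tree$nodes[[node_id]]
  if (is.na(nd$parent)) stop("branch_fraction is undefined for the root")
  parent <- tree$nodes[[nd$parent]]
  length(nd$patients) / length(parent$patients)
}

#' Label path from the root to a node
#'
#' @param tree a `treatment_tree`.
#' @param node_id node id.
#' @return character vector of labels (empty for the root).
#' @export
node_path <- function(tree, node_id) {
  path <- character(0)
  id <- node_id
  while (!is.na(tree$nodes[[id]]$parent)) {
    path <- c(tree$nodes[[id]]$label, path)
    id <- tree$nodes[[id]]$parent
  }
  path
}

#' Find the node at a given label path
#'
#' @param tree a `treatment_tree`.
#' @param path character vector of labels from the root (e.g.
#'   `c("PD1", "CTLA4+PD1")`); adjuvant labels carry the `adj:` prefix.
#' @return the node id.
#' @export
find_node <- function(tree, path) {
  id <- tree$root
  for (lab in path) {
    kids <- tree$nodes[[id]]$children
    hit <- kids[vapply(kids, function(k) tree$nodes[[k]]$label == lab, TRUE)]
    if (length(hit) == 0) {
      stop("no node at path: ", paste(path, collapse = " > "))
    }
    id <- hit[1]
  }
  id
}

#' All (path, patient-count) pairs of a tree
#'
#' @param tree a `treatment_tree`.
#' @param include_root include the empty root path?
#' @return data frame `path` (labels joined by `>`), `n`.
#' @export
tree_paths <- function(tree, include_root = FALSE) {
  out <- lapply(tree$nodes, function(nd) {
    data.frame(path = paste(node_path(tree, nd$id), collapse = ">"),
               n = length(nd$patients), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  if (!include_root) df <- df[df$path != "", , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Export a treatment tree as JSON
#'
#' Nodes carry id, label, setting, depth, parent, patient count and — when an
#' event log is supplied — the best-overall-response distribution and a
#' compact OS summary; edges carry the branch fraction. Patient identifiers
#' are withheld unless explicitly requested.
#'
#' @param tree a `treatment_tree`.
#' @param log optional `event_log` for per-node statistics.
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @param include_patient_ids include per-node patient id lists (privacy
#'   default: off).
#' @return JSON string (invisibly, if written to `path`).
#' @export
tree_to_json <- function(tree, log = NULL, path = NULL,
                         include_patient_ids = FALSE) {
  nodes <- lapply(tree$nodes, function(nd) {
    rec <- list(id = nd$id,
                label = if (nd$depth == 0) ROOT_LABEL else nd$label,
                setting = nd$setting, depth = nd$depth,
                parent = if (is.na(nd$parent)) NULL else nd$parent,
                n_patients = length(nd$patients))
    if (include_patient_ids) rec$patient_ids <- as.character(nd$patients)
    if (!is.null(log) && nd$depth > 0) {
      bor <- node_bor(tree, nd$id, log)
      rec$bor <- as.list(bor$counts)
      curve <- node_os_curve(tree, nd$id, log)
      grid <- seq(0, 60, by = 6) * 30.44
      s <- vapply(grid, function(t)
        survival_rate_at(curve, t, warn_extrapolation = FALSE)$rate, 0)
      rec$os_summary <- list(t_months = seq(0, 60, by = 6), s = round(s, 4))
    }
    rec
  })
  edges <- list()
  for (nd in tree$nodes) {
    for (k in nd$children) {
      edges[[length(edges) + 1]] <-
        list(parent = nd$id, child = k,
             fraction = round(branch_fraction(tree, k), 6))
    }
  }
  json <- jsonlite::toJSON(list(min_patients = tree$min_patients,
                                n_patients = tree$n_patients,
                                nodes = nodes, edges = edges),
                           auto_unbox = TRUE, null = "null", digits = NA,
                           pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Export a treatment tree as Graphviz DOT
#'
#' Edge pen width is proportional to the branch fraction; adjuvant nodes are
#' highlighted (yellow fill), mirroring the interactive display.
#'
#' @param tree a `treatment_tree`.
#' @param path optional output file; when `NULL` the DOT string is returned.
#' @return DOT source as a character scalar (invisibly, if written).
#' @export
tree_to_dot <- function(tree, path = NULL) {
  esc <- function(s) gsub("\"", "\\\\\"", s)
  lines <- c("digraph treatment_tree {",
             "  node [shape=box, style=filled, fillcolor=white];")
  for (nd in tree$nodes) {
    lab <- if (nd$depth == 0) ROOT_LABEL else nd$label
    fill <- if (!is.na(nd$setting) && identical(nd$setting, "adjuvant"))
      "yellow" else "white"
    lines <- c(lines, sprintf("  n%d [label=\"%s\\nn=%d\", fillcolor=%s];",
                              nd$id, esc(lab), length(nd$patients), fill))
  }
  for (nd in tree$nodes) {
    for (k in nd$children) {
      f <- branch_fraction(tree, k)
      lines <- c(lines, sprintf("  n%d -> n%d [penwidth=%.2f, label=\"%d%%\"];",
                                nd$id, k, 0.5 + 5 * f, round(100 * f)))
    }
  }
  lines <- c(lines, "}")
  dot <- paste(lines, collapse = "\n")
  if (is.null(path)) return(dot)
  writeLines(dot, path)
  invisible(dot)
}
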