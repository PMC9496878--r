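#' Declared functional network labels
#'
#' The nine large-scale functional networks used for aggregating nodal
#' stability values, plus the special label `"unassigned"` for nodes that
#' belong to none of them. All node tables are validated against this set
#' (or a user-supplied replacement).
#'
#' @param include_unassigned Include the `"unassigned"` label? Default `TRUE`.
#' @return Character vector of declared labels.
#' @export
#' @examples
#' network_labels()
network_labels <- function(include_unassigned = TRUE) {
  nets <- c(
    "sensorimotor", "visual", "auditory", "default-mode", "frontoparietal",
    "cingulo-opercular", "salience", "subcortical", "attention"
  )
  if (include_unassigned) c(nets, "unassigned") else nets
}

#' Validate a node table
#'
#' A node table maps each node of the parcellation to a label and to one of
#' the declared functional networks. Node indices must be exactly
#' `0..N-1`, contiguous and without duplicates, and every network label
#' must come from the declared set.
#'
#' @param table A data frame with columns `node_index`, `node_label`,
#'   `network_label`.
#' @param networks Character vector of declared network labels.
#' @return The validated table as a tibble, invisibly classed
#'   `"dynstab_node_table"`.
#' @export
validate_node_table <- function(table, networks = network_labels()) {
  if (!is.data.frame(table)) {
    abort("`table` must be a data frame.")
  }
  needed <- c("node_index", "node_label", "network_label")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "node table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  tbl <- as_tibble(table[needed])
  tbl$node_index <- as.integer(tbl$node_index)
  tbl$node_label <- as.character(tbl$node_label)
  tbl$network_label <- as.character(tbl$network_label)

  n <- nrow(tbl)
  if (n < 1) abort("node table has no rows.")
  expected <- 0:(n - 1)
  dup <- tbl$node_index[duplicated(tbl$node_index)]
  if (length(dup) > 0) {
    abort(paste0(
      "duplicate node_index value(s): ", paste(unique(dup), collapse = ", ")
    ))
  }
  gaps <- setdiff(expected, tbl$node_index)
  extra <- setdiff(tbl$node_index, expected)
  if (length(gaps) > 0 || length(extra) > 0) {
    abort(paste0(
      "node_index must be exactly 0..", n - 1, " with no gaps;",
      if (length(gaps) > 0) paste0(" missing: ", paste(gaps, collapse = ", ")) else "",
      if (length(extra) > 0) paste0(" out of range: ", paste(extra, collapse = ", ")) else ""
    ))
  }
  bad <- setdiff(unique(tbl$network_label), networks)
  if (length(bad) > 0) {
    abort(paste0(
      "unknown network label(s): ", paste(bad, collapse = ", "),
      "; declared set is: ", paste(networks, collapse = ", ")
    ))
  }
  tbl <- tbl[order(tbl$node_index), ]
  attr(tbl, "networks") <- networks
  class(tbl) <- c("dynstab_node_table", class(tbl))
  tbl
}

#' Read a node table from a delimited file
#'
#' Reads a tab-separated file with columns `index`, `label`, `network`
#' (aliases `node_index`, `node_label`, `network_label` are accepted).
#' A directive line `#index_base=0` or `#index_base=1` before the header
#' declares whether indices are 0- or 1-based in the file; 1-based indices
#' (the common atlas convention) are shifted to the internal 0-based
#' convention. Without a directive, 0-based indices are assumed.
#'
#' @param path Path to the file.
#' @param networks Declared network label set; see [network_labels()].
#' @return A validated node-table tibble.
#' @export
read_node_table <- function(path, networks = network_labels()) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  base <- 0L
  directive <- grep("^#\\s*index_base\\s*=", lines)
  if (length(directive) > 0) {
    val <- sub("^#\\s*index_base\\s*=\\s*", "", lines[directive[1]])
    val <- trimws(val)
    if (!val %in% c("0", "1")) {
      abort(paste0("invalid #index_base directive: ", val, " (must be 0 or 1)"))
    }
    base <- as.integer(val)
  }
  body <- lines[!grepl("^#", lines)]
  tbl <- readr::read_tsv(
    I(paste(body, collapse = "\n")),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  nm <- names(tbl)
  nm[nm == "index"] <- "node_index"
  nm[nm == "label"] <- "node_label"
  nm[nm == "network"] <- "network_label"
  names(tbl) <- nm
  if (!"node_index" %in% names(tbl)) {
    abort("node table file must have an `index` column")
  }
  tbl$node_index <- suppressWarnings(as.integer(tbl$node_index)) - base
  validate_node_table(tbl, networks = networks)
}

#' Node indices belonging to one functional network
#'
#' @param table A validated node table.
#' @param network One declared network label.
#' @return Sorted integer vector of 0-based node indices. Empty only for
#'   `"unassigned"`.
#' @export
#' @examples
#' tab <- synthetic_node_table(9)
#' nodes_of_network(tab, "visual")
nodes_of_network <- function(table, network) {
  table <- validate_node_table(table, networks = node_table_networks(table))
  networks <- node_table_networks(table)
  if (!is.character(network) || length(network) != 1) {
    abort("`network` must be a single label.")
  }
  if (!network %in% networks) {
    abort(paste0(
      "undeclared network label: ", network,
      "; declared set is: ", paste(networks, collapse = ", ")
    ))
  }
  idx <- sort(unique(table$node_index[table$network_label == network]))
  if (length(idx) == 0 && network != "unassigned") {
    abort(paste0("network \"", network, "\" has no nodes in this table"))
  }
  idx
}

node_table_networks <- function(table) {
  nets <- attr(table, "networks")
  if (is.null(nets)) network_labels() else nets
}

#' Default 90-node anatomical parcellation with nine-network assignment
#'
#' A ready-made node table for the 90-region anatomical (AAL-90) cortical
#' and subcortical parcellation, with each region assigned to one of the
#' nine large-scale functional networks. The assignment is a best-effort
#' reconstruction of the network scheme commonly used with this atlas; it
#' is not authoritative, and any study should review or replace it via
#' [read_node_table()] with its own mapping file.
#'
#' @return A validated 90-row node table.
#' @export
aal90_node_table <- function() {
  path <- system.file("extdata", "aal90_network_map.tsv", package = "dynstab")
  if (!nzchar(path)) {
    # during development, before installation
    path <- file.path("inst", "extdata", "aal90_network_map.tsv")
  }
  read_node_table(path)
}

#' Proportionally partitioned node table for simulations
#'
#' Builds a node table of `n_nodes` nodes assigned in contiguous blocks to
#' the nine declared networks, for use with the synthetic-cohort generator
#' and in examples. Block sizes are proportional to the network sizes of
#' the default 90-node anatomical mapping (largest-remainder rounding,
#' minimum one node per network), so a down-scaled table keeps the same
#' relative network prominence - in particular the default-mode network
#' stays the largest system.
#'
#' @param n_nodes Number of nodes (at least 9 so every network is populated).
#' @return A validated node table.
#' @export
synthetic_node_table <- function(n_nodes = 90) {
  if (n_nodes < 9) abort("`n_nodes` must be at least 9 (one node per network).")
  nets <- network_labels(include_unassigned = FALSE)
  # network sizes of the 90-node anatomical mapping
  weights <- c(sensorimotor = 10, visual = 14, auditory = 4,
               `default-mode` = 24, frontoparietal = 8,
               `cingulo-opercular` = 8, salience = 8, subcortical = 8,
               attention = 6)[nets]
  quota <- n_nodes * weights / sum(weights)
  sizes <- pmax(floor(quota), 1)
  while (sum(sizes) < n_nodes) {
    i <- which.max(quota - sizes)
    sizes[i] <- sizes[i] + 1
  }
  while (sum(sizes) > n_nodes) {
    cand <- which(sizes > 1)
    i <- cand[which.min((quota - sizes)[cand])]
    sizes[i] <- sizes[i] - 1
  }
  assignment <- rep(nets, times = sizes)
  validate_node_table(tibble(
    node_index = 0:(n_nodes - 1),
    node_label = sprintf("node_%03d", 0:(n_nodes - 1)),
    network_label = assignment
  ))
}
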