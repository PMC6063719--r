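# Plain-text serialization: delimited matrices with a JSON sidecar.

#' Write / read a ground-truth network as delimited text + JSON sidecar
#'
#' `weights.tsv` (and `weights2.tsv` for order 2) hold the coefficient
#' matrices; `meta.json` records topology, order, rescale factor and node
#' labels.  The mask is implicit (nonzero weights).
#'
#' @param net an `mvar_network`.
#' @param dir output directory (created if missing).
#' @return `write_connectivity` returns `dir` invisibly;
#'   `read_connectivity` returns the `mvar_network`.
#' @export
write_connectivity <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(net$weights, file.path(dir, "weights.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  if (!is.null(net$weights2))
    utils::write.table(net$weights2, file.path(dir, "weights2.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- list(topology = net$topology, order = net$order,
               rescale = net$rescale, N = net$N,
               node_labels = net$node_labels)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null"),
             file.path(dir, "meta.json"))
  invisible(dir)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(dir) {
  w <- as.matrix(utils::read.table(file.path(dir, "weights.tsv"), sep = "\t"))
  dimnames(w) <- NULL
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  w2 <- NULL
  f2 <- file.path(dir, "weights2.tsv")
  if (file.exists(f2)) {
    w2 <- as.matrix(utils::read.table(f2, sep = "\t"))
    dimnames(w2) <- NULL
  }
  structure(list(weights = w, mask = w != 0, weights2 = w2,
                 mask2 = if (!is.null(w2)) w2 != 0,
                 order = as.integer(meta$order), topology = meta$topology,
                 node_labels = meta$node_labels, rescale = meta$rescale,
                 N = nrow(w), groups = NULL),
            class = "mvar_network")
}

#' Write / read a panel as delimited text (nodes x time, node-label header)
#'
#' @param x `N x T` matrix.
#' @param file path of the tab-delimited file.
#' @param labels optional node labels (header row).
#' @return `read_panel` returns the `N x T` matrix.
#' @export
write_panel <- function(x, file, labels = NULL) {
  if (is.null(labels)) labels <- paste0("node", seq_len(nrow(x)))
  m <- t(x)
  colnames(m) <- labels
  utils::write.table(m, file, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(file)
}

#' @rdname write_panel
#' @export
read_panel <- function(file) {
  m <- as.matrix(utils::read.table(file, sep = "\t", header = TRUE))
  x <- t(m)
  dimnames(x) <- NULL
  x
}

#' Serialize a detection report (JSON summary + delimited matrices)
#'
#' Writes `summary.json` (test tag, alpha, tails, counts), `decisions.tsv`
#' and `pvals.tsv` into `dir`.
#'
#' @param report an `mvar_detect`.
#' @param dir output directory.
#' @export
write_detection <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$decisions * 1L, file.path(dir, "decisions.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(report$pvals, file.path(dir, "pvals.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- list(test_tag = report$test_tag, alpha = report$alpha,
               tails = report$tails, S = report$S,
               surrogate_method = report$surrogate_method,
               n_significant = sum(report$decisions, na.rm = TRUE))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null"),
             file.path(dir, "summary.json"))
  invisible(dir)
}
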