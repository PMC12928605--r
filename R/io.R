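#' Write / read an adjacency matrix as MatrixMarket + sidecars
#'
#' Sparse matrices travel as MatrixMarket coordinate files (1-based
#' indices per the standard), with a sidecar TSV mapping row index to
#' spot_id and a JSON metadata record (kind, k, p, N, timestamp).
#'
#' @param adj A `dw_adjacency`.
#' @param dir Output directory (created if needed).
#' @param spot_id Optional character vector of spot identifiers for the
#'   sidecar; defaults to `row_00001`-style names.
#' @return `write_adjacency` returns `dir` invisibly; `read_adjacency`
#'   returns the `dw_adjacency` (with `spot_id` attribute).
#' @export
write_adjacency <- function(adj, dir, spot_id = NULL) {
  stopifnot(inherits(adj, "dw_adjacency"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(adj$matrix)
  if (is.null(spot_id)) spot_id <- sprintf("row_%05d", seq_len(n))
  stopifnot(length(spot_id) == n)
  Matrix::writeMM(methods::as(adj$matrix, "CsparseMatrix"),
                  file.path(dir, "adjacency.mtx"))
  utils::write.table(
    data.frame(row_index = seq_len(n), spot_id = spot_id),
    file.path(dir, "spots.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(kind = adj$kind, k = adj$k, p = if (is.na(adj$p)) NULL else adj$p,
               n_spots = n, created = format(Sys.time(), tz = "UTC"),
               deterministic = TRUE)
  jsonlite::write_json(meta, file.path(dir, "adjacency.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(dir) {
  mat <- methods::as(Matrix::readMM(file.path(dir, "adjacency.mtx")),
                     "CsparseMatrix")
  meta <- jsonlite::read_json(file.path(dir, "adjacency.json"))
  spots <- utils::read.delim(file.path(dir, "spots.tsv"))
  adj <- new_adjacency(mat, meta$kind, meta$k,
                       if (is.null(meta$p)) NA_real_ else meta$p)
  attr(adj, "spot_id") <- as.character(spots$spot_id)
  adj
}

#' Write a simulated dataset to a directory
#'
#' Counts as MatrixMarket (spots x genes) plus gene/barcode TSVs,
#' coordinates TSV, ground-truth labels TSV, and a manifest JSON with all
#' generator parameters and seeds sufficient to regenerate the dataset.
#'
#' @param dataset A `simulated_dataset`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(dataset$counts, sparse = TRUE),
                              "CsparseMatrix"),
                  file.path(dir, "counts.mtx"))
  writeLines(colnames(dataset$counts), file.path(dir, "genes.tsv"))
  writeLines(dataset$spots$spot_id, file.path(dir, "barcodes.tsv"))
  write_spot_table(dataset$spots, file.path(dir, "coordinates.tsv"))
  utils::write.table(
    data.frame(spot_id = dataset$spots$spot_id, domain = dataset$truth$labels),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(scenario_id = dataset$scenario_id,
                   replicate_index = dataset$replicate_index,
                   seed = dataset$seed,
                   n_spots = nrow(dataset$counts),
                   n_genes = ncol(dataset$counts),
                   n_domains = dataset$truth$n_domains,
                   pattern = dataset$truth$pattern,
                   model = unclass(dataset$model))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  genes <- readLines(file.path(dir, "genes.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(counts) <- list(barcodes, genes)
  storage.mode(counts) <- "integer"
  spots <- read_spot_table(file.path(dir, "coordinates.tsv"))
  tr <- utils::read.delim(file.path(dir, "truth.tsv"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  truth <- structure(list(labels = as.integer(tr$domain),
                          n_domains = as.integer(manifest$n_domains),
                          pattern = manifest$pattern),
                     class = "domain_map")
  structure(list(spots = spots, counts = counts, truth = truth,
                 model = do.call(expression_model, manifest$model),
                 seed = manifest$seed,
                 scenario_id = manifest$scenario_id,
                 replicate_index = manifest$replicate_index),
            class = "simulated_dataset")
}

#' Write / read run labels as TSV
#'
#' Long format with header `spot_id`, `run`, `label`.
#'
#' @param labels N x R integer label matrix.
#' @param spot_id Character vector of length N.
#' @param path Output file.
#' @return `write_labels` returns `path` invisibly; `read_labels` returns
#'   the label matrix with `spot_id` rownames.
#' @export
write_labels <- function(labels, spot_id, path) {
  labels <- as.matrix(labels)
  stopifnot(length(spot_id) == nrow(labels))
  df <- data.frame(spot_id = rep(spot_id, ncol(labels)),
                   run = rep(seq_len(ncol(labels)), each = nrow(labels)),
                   label = as.vector(labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path)
  runs <- sort(unique(df$run))
  ids <- unique(df$spot_id)
  out <- vapply(runs, function(r) {
    sub <- df[df$run == r, ]
    sub$label[match(ids, sub$spot_id)]
  }, integer(length(ids)))
  out <- matrix(as.integer(out), nrow = length(ids))
  rownames(out) <- ids
  out
}

#' Write a benchmark report as TSV + JSON
#'
#' @param report A `benchmark_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "benchmark_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$sample_level, file.path(dir, "sample_level.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$dataset_level, file.path(dir, "dataset_level.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(sample_level = report$sample_level,
                            dataset_level = report$dataset_level),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
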