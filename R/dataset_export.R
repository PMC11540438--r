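# Packaging of the graph-AI inputs: the 3D feature array X (M x n_nodes x d),
# the label vector Y, the (E, 2) edge index, deterministic k-fold splits and
# a text serialization with integrity checksums.

#' Stack per-sample feature matrices into the 3D array X
#'
#' @param graph A `mos_graph` (shared topology, per-sample features).
#' @param study The `harmonized_study` the graph was built from; fixes the
#'   sample order of the first dimension.
#' @return Numeric array of shape (M, n_nodes, d) with dimnames
#'   (sample, NULL, feature).
#' @export
stack_features <- function(graph, study) {
  samples <- study$samples
  if (!all(samples %in% names(graph$features))) {
    stop("graph lacks feature matrices for some samples")
  }
  n_nodes <- nrow(graph$nodes)
  X <- array(NA_real_, dim = c(length(samples), n_nodes, graph$d),
             dimnames = list(samples, NULL, graph$feature_names))
  for (m in seq_along(samples)) {
    f <- graph$features[[samples[m]]]
    if (!identical(dim(f), c(n_nodes, graph$d))) {
      stop("feature matrix shape mismatch for sample ", samples[m])
    }
    X[m, , ] <- f
  }
  X
}

#' Deterministic balanced k-fold assignment
#'
#' Fisher-Yates shuffle of the sample order under `seed`, then contiguous
#' chunks whose sizes differ by at most one. For each held-out fold the
#' remaining k-1 folds form the training set.
#'
#' @param M Sample count.
#' @param k Number of folds (default 5).
#' @param seed RNG seed; same seed, same assignment.
#' @return Integer vector of length M with fold ids in 0..k-1.
#' @export
make_folds <- function(M, k = 5L, seed = 42L) {
  if (k < 2L) stop("k must be >= 2")
  if (M < k) stop("cannot split ", M, " samples into ", k, " folds")
  perm <- with_seed(seed, sample.int(M))
  sizes <- rep(M %/% k, k) + c(rep(1L, M %% k), rep(0L, k - M %% k))
  fold <- integer(M)
  fold[perm] <- rep(seq_len(k) - 1L, times = sizes)
  fold
}

#' Assemble the exportable graph dataset
#'
#' @param study A `harmonized_study`.
#' @param graph A `mos_graph` built from it.
#' @param labels A `label_vector` covering every aligned sample.
#' @param k Folds (default 5).
#' @param seed Fold shuffle seed.
#' @return A `graph_dataset` with fields `X` (M x n_nodes x d), `Y` (0-based
#'   class indices, with `class_map` attribute), `edge_index` (E, 2),
#'   `genes`, `node_map`, `folds`, `counts`.
#' @export
build_graph_dataset <- function(study, graph, labels, k = 5L, seed = 42L) {
  miss <- setdiff(study$samples, labels$sample_id)
  if (length(miss)) {
    stop("labels missing for aligned sample(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  X <- stack_features(graph, study)
  Y <- labels$label[match(study$samples, labels$sample_id)]
  ei <- adjacency_to_edge_index(graph)
  folds <- make_folds(length(study$samples), k = k, seed = seed)
  counts <- study$counts
  counts$n_nodes <- nrow(graph$nodes)
  counts$d <- graph$d
  counts$E <- nrow(ei)
  counts$C <- length(attr(labels, "class_map"))
  structure(list(X = X, Y = Y, class_map = attr(labels, "class_map"),
                 edge_index = ei, genes = study$genes,
                 node_map = graph$nodes, samples = study$samples,
                 folds = folds, fold_seed = seed, counts = counts),
            class = "graph_dataset")
}

#' @export
print.graph_dataset <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("<graph_dataset> X: (M=%d, n_nodes=%d, d=%d); C=%d classes; E=%d edges; %d folds\n",
              d[1L], d[2L], d[3L], length(x$class_map), nrow(x$edge_index),
              length(unique(x$folds))))
  invisible(x)
}

#' Serialize a graph dataset to plain-text files
#'
#' Writes X (long CSV: sample_id, node_id, one column per feature), Y,
#' edge index, node map, gene list, fold assignment and a JSON manifest
#' recording shapes, fill values, the fold seed, stage counts and an md5
#' checksum per file. [read_graph_dataset()] reproduces the arrays
#' bit-exactly and refuses corrupted files.
#'
#' @param dataset A `graph_dataset`.
#' @param out_dir Output directory.
#' @return The manifest, invisibly.
#' @export
serialize_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(dataset$X)
  # X in long form: one row per (sample, node)
  xm <- matrix(aperm(dataset$X, c(2L, 1L, 3L)), nrow = d[1L] * d[2L])
  xm <- matrix(fmt_num(xm), nrow = nrow(xm))
  colnames(xm) <- dimnames(dataset$X)[[3L]]
  xdf <- data.frame(sample_id = rep(dataset$samples, each = d[2L]),
                    node_id = rep(dataset$node_map$node_id, times = d[1L]),
                    xm, check.names = FALSE, stringsAsFactors = FALSE)
  files <- list(
    X = "X.csv", Y = "Y.csv", edge_index = "edge_index.csv",
    node_map = "node_map.csv", gene_list = "gene_list.txt",
    folds = "folds.csv")
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(xdf, p(files$X), row.names = FALSE)
  utils::write.csv(data.frame(sample_id = dataset$samples, label = dataset$Y,
                              class_name = dataset$class_map[dataset$Y + 1L]),
                   p(files$Y), row.names = FALSE)
  utils::write.csv(as.data.frame(dataset$edge_index), p(files$edge_index),
                   row.names = FALSE)
  utils::write.csv(dataset$node_map, p(files$node_map), row.names = FALSE)
  writeLines(dataset$genes, p(files$gene_list))
  utils::write.csv(data.frame(sample_id = dataset$samples,
                              fold = dataset$folds),
                   p(files$folds), row.names = FALSE)
  sums <- vapply(files, function(f) unname(tools::md5sum(p(f))), character(1L))
  manifest <- list(
    shape = list(M = d[1L], n_nodes = d[2L], d = d[3L],
                 C = length(dataset$class_map), E = nrow(dataset$edge_index)),
    class_map = as.list(dataset$class_map),
    feature_names = as.list(dimnames(dataset$X)[[3L]]),
    fill_values = list(methylation = 0, rnaseq = 0, proteomics = 0,
                       variation = -1),
    fold_seed = dataset$fold_seed,
    counts = dataset$counts,
    files = files,
    md5 = as.list(sums))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Reload a serialized graph dataset, verifying integrity
#' @param dir Directory written by [serialize_dataset()].
#' @return A `graph_dataset`.
#' @export
read_graph_dataset <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  for (f in names(mf$files)) {
    path <- file.path(dir, mf$files[[f]])
    if (!file.exists(path)) stop("dataset file missing: ", path)
    if (!identical(unname(tools::md5sum(path)), mf$md5[[f]])) {
      stop("integrity error: checksum mismatch for ", mf$files[[f]])
    }
  }
  p <- function(f) file.path(dir, mf$files[[f]])
  xdf <- utils::read.csv(p("X"), check.names = FALSE,
                         stringsAsFactors = FALSE)
  ydf <- utils::read.csv(p("Y"), stringsAsFactors = FALSE,
                         colClasses = c(sample_id = "character",
                                        class_name = "character"))
  ei <- as.matrix(utils::read.csv(p("edge_index")))
  storage.mode(ei) <- "integer"
  node_map <- utils::read.csv(p("node_map"), stringsAsFactors = FALSE)
  genes <- readLines(p("gene_list"))
  folds <- utils::read.csv(p("folds"), stringsAsFactors = FALSE,
                           colClasses = c(sample_id = "character"))
  M <- mf$shape$M; n_nodes <- mf$shape$n_nodes; dd <- mf$shape$d
  fn <- unlist(mf$feature_names)
  samples <- unique(xdf$sample_id)
  xm <- as.matrix(xdf[, fn, drop = FALSE])
  X <- aperm(array(xm, dim = c(n_nodes, M, dd)), c(2L, 1L, 3L))
  dimnames(X) <- list(samples, NULL, fn)
  structure(list(X = X, Y = ydf$label, class_map = unlist(mf$class_map),
                 edge_index = ei, genes = genes, node_map = node_map,
                 samples = samples, folds = folds$fold,
                 fold_seed = mf$fold_seed, counts = mf$counts),
            class = "graph_dataset")
}
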