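#' AAL-90 region labels
#'
#' Standard abbreviated names of the 90 cortical and subcortical regions of
#' the Anatomical Automatic Labeling atlas, in the conventional order
#' (odd = left hemisphere, even = right). These are the default ROI labels
#' for 90-region connectivity matrices; any other label list of matching
#' length is accepted wherever these are used.
#'
#' @return Character vector of length 90.
#' @export
#' @examples
#' head(aal90_labels())
aal90_labels <- function() {
  base <- c(
    "PreCG", "SFGdor", "ORBsup", "MFG", "ORBmid", "IFGoperc", "IFGtriang",
    "ORBinf", "ROL", "SMA", "OLF", "SFGmed", "ORBsupmed", "REC", "INS",
    "ACG", "DCG", "PCG", "HIP", "PHG", "AMYG", "CAL", "CUN", "LING",
    "SOG", "MOG", "IOG", "FFG", "PoCG", "SPG", "IPL", "SMG", "ANG",
    "PCUN", "PCL", "CAU", "PUT", "PAL", "THA", "HES", "STG", "TPOsup",
    "MTG", "TPOmid", "ITG"
  )
  as.vector(rbind(paste0(base, ".L"), paste0(base, ".R")))
}

#' Edge index map for an N-region connectivity matrix
#'
#' Fixes the bijection between edge indices and ROI pairs. Edges are the
#' strict upper triangle taken in row-major order: (1,2), (1,3), ...,
#' (1,N), (2,3), ..., (N-1,N), giving p = N(N-1)/2 edges. Edge j of
#' `vectorize_upper_triangle()` is the pair `pairs[j, ]` here, and all
#' penalty-score and coefficient vectors in the package align with this
#' ordering.
#'
#' @param N Number of regions (>= 2).
#' @param roi_labels Optional character vector of N region names. Defaults
#'   to [aal90_labels()] when N = 90, otherwise `"ROI1"..."ROIN"`.
#' @return An object of class `edge_index_map`: a list with `N`, `pairs`
#'   (p x 2 integer matrix, column `i` < column `j`), `names`
#'   (edge names `"A--B"`), and `roi_labels`.
#' @export
#' @examples
#' em <- edge_index_map(4)
#' em$pairs
edge_index_map <- function(N, roi_labels = NULL) {
  N <- as.integer(N)
  if (N < 2L) stop("edge_index_map: N must be >= 2, got ", N)
  if (is.null(roi_labels)) {
    roi_labels <- if (N == 90L) aal90_labels() else paste0("ROI", seq_len(N))
  }
  if (length(roi_labels) != N) {
    stop("edge_index_map: roi_labels has length ", length(roi_labels),
         ", expected ", N)
  }
  i <- rep.int(seq_len(N - 1L), times = (N - 1L):1L)
  j <- unlist(lapply(seq_len(N - 1L), function(a) (a + 1L):N), use.names = FALSE)
  pairs <- cbind(i = as.integer(i), j = as.integer(j))
  nm <- paste0(roi_labels[i], "--", roi_labels[j])
  structure(
    list(N = N, pairs = pairs, names = nm, roi_labels = roi_labels),
    class = "edge_index_map"
  )
}

#' @export
print.edge_index_map <- function(x, ...) {
  cat("Edge index map: ", x$N, " regions, ", nrow(x$pairs), " edges\n",
      sep = "")
  cat("First edges:", paste(utils::head(x$names, 3), collapse = ", "), "...\n")
  invisible(x)
}

#' Convert an edge index to its (row, col) ROI pair and back
#'
#' Edge indices are 1-based and follow the row-major strict-upper-triangle
#' order of [edge_index_map()]: edge 1 is the pair (1, 2) and edge
#' N(N-1)/2 is (N-1, N).
#'
#' @param j Edge index (vectorized), in `1..N(N-1)/2`.
#' @param N Number of regions.
#' @return `edge_index_to_pair`: integer matrix with columns `i`, `j`
#'   (one row per input index). `pair_to_edge_index`: integer vector of
#'   edge indices.
#' @export
edge_index_to_pair <- function(j, N) {
  N <- as.integer(N)
  p <- (N * (N - 1L)) %/% 2L
  j <- as.integer(j)
  if (any(j < 1L | j > p)) {
    stop("edge_index_to_pair: index out of range 1..", p, ": ",
         j[which(j < 1L | j > p)[1]])
  }
  # cumulative edge count after finishing row i is i*N - i*(i+1)/2
  ends <- cumsum((N - 1L):1L)
  row <- findInterval(j - 1L, ends) + 1L
  before <- c(0L, ends)[row]
  col <- row + (j - before)
  cbind(i = as.integer(row), j = as.integer(col))
}

#' @rdname edge_index_to_pair
#' @param i Row index of the pair (`i < j` required).
#' @param jj Column index of the pair.
#' @export
pair_to_edge_index <- function(i, jj, N) {
  N <- as.integer(N)
  i <- as.integer(i); jj <- as.integer(jj)
  if (any(i >= jj) || any(i < 1L) || any(jj > N)) {
    stop("pair_to_edge_index: need 1 <= i < j <= N")
  }
  (i - 1L) * N - (i * (i + 1L)) %/% 2L + jj
}

#' Vectorize the strict upper triangle of a connectivity matrix
#'
#' Extracts the N(N-1)/2 off-diagonal connectivity values of a symmetric
#' N x N matrix in the row-major order fixed by [edge_index_map()]. The
#' diagonal (self-connectivity) is ignored, not validated. Asymmetric
#' input is rejected rather than symmetrized, so that upstream
#' preprocessing errors surface instead of being averaged away.
#'
#' @param A Symmetric numeric N x N matrix (N >= 2).
#' @param roi_labels Optional region names used to name the result.
#' @param tol Absolute symmetry tolerance (default 1e-8).
#' @return Named numeric vector of length N(N-1)/2.
#' @seealso [devectorize_edges()] for the inverse.
#' @export
#' @examples
#' A <- matrix(c(1, .3, .3, 1), 2)
#' vectorize_upper_triangle(A)
vectorize_upper_triangle <- function(A, roi_labels = NULL, tol = 1e-8) {
  if (!is.matrix(A) || !is.numeric(A)) {
    stop("vectorize_upper_triangle: A must be a numeric matrix")
  }
  N <- nrow(A)
  if (N < 2L || ncol(A) != N) {
    stop("vectorize_upper_triangle: A must be square with N >= 2 (got ",
         N, " x ", ncol(A), ")")
  }
  asym <- abs(A - t(A))
  if (any(asym > tol, na.rm = TRUE)) {
    w <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "vectorize_upper_triangle: asymmetric at entry (%d, %d): A[i,j] = %g but A[j,i] = %g (tol %g)",
      w[1], w[2], A[w[1], w[2]], A[w[2], w[1]], tol))
  }
  # lower triangle of t(A), column-major == upper triangle of A, row-major
  v <- t(A)[lower.tri(A)]
  em <- edge_index_map(N, roi_labels)
  names(v) <- em$names
  v
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_upper_triangle()] on the off-diagonal: places the
#' edge vector back into both triangles. The diagonal, which carries no
#' edge information, is filled with `diag_value` (1 by default, the
#' self-correlation of an FC matrix).
#'
#' @param v Edge vector of length N(N-1)/2.
#' @param N Number of regions.
#' @param diag_value Value for the diagonal (default 1).
#' @return Symmetric N x N numeric matrix.
#' @export
devectorize_edges <- function(v, N, diag_value = 1) {
  N <- as.integer(N)
  p <- (N * (N - 1L)) %/% 2L
  if (length(v) != p) {
    stop("devectorize_edges: edge vector has length ", length(v),
         ", expected ", p, " for N = ", N)
  }
  A <- matrix(0, N, N)
  A[lower.tri(A)] <- v   # row-major upper triangle lands here transposed
  A <- t(A)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- diag_value
  A
}

#' Construct an FC edge-feature dataset
#'
#' Bundles an n x p matrix of edge features (subjects in rows), binary
#' labels, and the edge index map that fixes which ROI pair each column
#' refers to. The label convention throughout the package is 1 = normal
#' control, 0 = patient; sensitivity is the true-positive rate with
#' positives = label 1.
#'
#' @param X Numeric n x p matrix, one row per subject.
#' @param Y Binary labels (0/1), length n.
#' @param edge_map An [edge_index_map()] with p edges.
#' @param dataset_name Optional identifier carried into reports.
#' @return Object of class `fc_dataset`: list with `X`, `Y`, `edge_map`,
#'   `dataset_name`.
#' @export
fc_dataset <- function(X, Y, edge_map, dataset_name = "dataset") {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  Y <- as.integer(Y)
  if (!inherits(edge_map, "edge_index_map")) {
    stop("fc_dataset: edge_map must be an edge_index_map")
  }
  p <- length(edge_map$names)
  if (ncol(X) != p) {
    stop("fc_dataset: X has ", ncol(X), " columns but edge_map has ", p,
         " edges")
  }
  if (nrow(X) != length(Y)) {
    stop("fc_dataset: X has ", nrow(X), " rows but Y has length ", length(Y))
  }
  if (!all(Y %in% c(0L, 1L))) {
    stop("fc_dataset: labels must be 0 (patient) or 1 (normal control)")
  }
  if (any(!is.finite(X))) stop("fc_dataset: X contains non-finite values")
  colnames(X) <- edge_map$names
  structure(
    list(X = X, Y = Y, edge_map = edge_map, dataset_name = dataset_name),
    class = "fc_dataset"
  )
}

#' @export
print.fc_dataset <- function(x, ...) {
  cat("FC dataset '", x$dataset_name, "': ", nrow(x$X), " subjects x ",
      ncol(x$X), " edges (", x$edge_map$N, " regions)\n", sep = "")
  cat("Labels: ", sum(x$Y == 1L), " NC (1), ", sum(x$Y == 0L),
      " patient (0)\n", sep = "")
  invisible(x)
}

#' Read and write FC datasets
#'
#' Two on-disk forms are supported. `"edge-table"`: a single tab-delimited
#' file, one row per subject, p edge columns named as in
#' [edge_index_map()], and a final `label` column in \{0, 1\}.
#' `"matrix-per-subject"`: a directory of tab-delimited N x N matrices
#' plus a `manifest.tsv` with columns `file` and `label`.
#'
#' @param path File (edge-table) or directory (matrix-per-subject).
#' @param format One of `"edge-table"`, `"matrix-per-subject"`.
#' @param roi_labels Optional region names (matrix-per-subject only).
#' @param dataset_name Name recorded on the returned dataset.
#' @return An [fc_dataset()].
#' @export
read_fc_dataset <- function(path,
                            format = c("edge-table", "matrix-per-subject"),
                            roi_labels = NULL,
                            dataset_name = basename(path)) {
  format <- match.arg(format)
  if (format == "edge-table") {
    df <- utils::read.delim(path, check.names = FALSE)
    if (!"label" %in% names(df)) {
      stop("read_fc_dataset: edge table ", path, " lacks a 'label' column")
    }
    lab <- df[["label"]]
    feat <- df[setdiff(names(df), "label")]
    if (!all(vapply(feat, is.numeric, logical(1)))) {
      bad <- names(feat)[!vapply(feat, is.numeric, logical(1))][1]
      stop("read_fc_dataset: non-numeric feature column '", bad, "'")
    }
    p <- ncol(feat)
    N <- (1 + sqrt(1 + 8 * p)) / 2
    if (N != round(N)) {
      stop("read_fc_dataset: ", p,
           " feature columns is not N(N-1)/2 for any integer N")
    }
    em <- edge_index_map(as.integer(N), roi_labels)
    X <- as.matrix(feat)
    fc_dataset(X, lab, em, dataset_name)
  } else {
    manifest <- file.path(path, "manifest.tsv")
    if (!file.exists(manifest)) {
      stop("read_fc_dataset: missing manifest.tsv in ", path)
    }
    man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
    if (!all(c("file", "label") %in% names(man))) {
      stop("read_fc_dataset: manifest must have 'file' and 'label' columns")
    }
    rows <- lapply(man$file, function(f) {
      A <- as.matrix(utils::read.delim(file.path(path, f), header = FALSE))
      storage.mode(A) <- "double"
      vectorize_upper_triangle(A, roi_labels)
    })
    lens <- vapply(rows, length, integer(1))
    if (length(unique(lens)) != 1L) {
      stop("read_fc_dataset: subjects have differing matrix sizes")
    }
    X <- do.call(rbind, rows)
    N <- (1 + sqrt(1 + 8 * ncol(X))) / 2
    em <- edge_index_map(as.integer(N), roi_labels)
    fc_dataset(X, man$label, em, dataset_name)
  }
}

#' @rdname read_fc_dataset
#' @param dataset An [fc_dataset()] to write (edge-table form).
#' @export
write_fc_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "fc_dataset"))
  df <- as.data.frame(dataset$X, check.names = FALSE)
  df$label <- dataset$Y
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
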