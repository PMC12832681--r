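test_that("upper-triangle vectorization has the documented order and length", {
  # N = 3: row-major order over i < j is (1,2), (1,3), (2,3)
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 0.1
  A[1, 3] <- A[3, 1] <- 0.2
  A[2, 3] <- A[3, 2] <- 0.3
  expect_equal(unname(vectorize_upper_triangle(A)), c(0.1, 0.2, 0.3))

  # N = 2: single off-diagonal element
  expect_equal(unname(vectorize_upper_triangle(matrix(c(1, .3, .3, 1), 2))),
               0.3)

  # edge names follow the ROI labels
  v <- vectorize_upper_triangle(A, roi_labels = c("a", "b", "c"))
  expect_equal(names(v), c("a--b", "a--c", "b--c"))
})

test_that("vectorize/devectorize round trip on random symmetric matrices", {
  for (N in c(2, 3, 5, 8, 13, 20)) {
    A <- random_symmetric(N, seed = N)
    v <- vectorize_upper_triangle(A)
    expect_length(v, N * (N - 1) / 2)
    B <- devectorize_edges(v, N)
    off <- !diag(TRUE, N)
    expect_equal(B[off], A[off])
  }
})

test_that("asymmetric matrices are rejected naming the offending entry", {
  A <- random_symmetric(4)
  A[2, 3] <- A[2, 3] + 1e-6
  expect_error(vectorize_upper_triangle(A),
               "asymmetric at entry \\((2, 3|3, 2)\\)")
  # within tolerance passes
  A <- random_symmetric(4)
  A[2, 3] <- A[2, 3] + 1e-10
  expect_silent(vectorize_upper_triangle(A))
})

test_that("edge index <-> pair mapping round trips and hits the endpoints", {
  expect_equal(edge_index_to_pair(1, 90), cbind(i = 1L, j = 2L))
  expect_equal(edge_index_to_pair(4005, 90), cbind(i = 89L, j = 90L))
  expect_error(edge_index_to_pair(4006, 90), "out of range")
  expect_error(edge_index_to_pair(0, 90), "out of range")

  # brute-force enumeration for N = 5: all 10 indices round trip
  em <- edge_index_map(5)
  for (j in 1:10) {
    pr <- edge_index_to_pair(j, 5)
    expect_equal(unname(pr[1, ]), unname(em$pairs[j, ]))
    expect_equal(pair_to_edge_index(pr[1, 1], pr[1, 2], 5), j)
  }
})

test_that("edge maps are consistent: sizes, unique names, distinct ROIs", {
  for (N in c(2, 4, 7, 90)) {
    em <- edge_index_map(N)
    p <- N * (N - 1) / 2
    expect_equal(nrow(em$pairs), p)
    expect_length(em$names, p)
    expect_equal(anyDuplicated(em$names), 0L)
    expect_true(all(em$pairs[, 1] < em$pairs[, 2]))
  }
  expect_equal(edge_index_map(90)$roi_labels, aal90_labels())
  expect_error(edge_index_map(1), "N must be >= 2")
})

test_that("edge-table write/read round trips a dataset", {
  d <- generate_fc_dataset(synthetic_spec(n_per_class = 5, N = 4,
                                          signal_edges = 1L, seed = 2))
  tf <- tempfile(fileext = ".tsv")
  write_fc_dataset(d, tf)
  d2 <- read_fc_dataset(tf, "edge-table", dataset_name = d$dataset_name)
  expect_equal(unname(d2$X), unname(d$X), tolerance = 1e-12)
  expect_equal(d2$Y, d$Y)
  expect_equal(d2$edge_map$names, d$edge_map$names)
})

test_that("matrix-per-subject directories are read with their manifest", {
  dir <- tempfile("subj_")
  dir.create(dir)
  mats <- lapply(1:3, function(i) random_symmetric(4, seed = i))
  for (i in 1:3) {
    utils::write.table(mats[[i]], file.path(dir, paste0("s", i, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(
    data.frame(file = paste0("s", 1:3, ".tsv"), label = c(0, 1, 1)),
    file.path(dir, "manifest.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  d <- read_fc_dataset(dir, "matrix-per-subject")
  expect_equal(dim(d$X), c(3L, 6L))
  expect_equal(d$Y, c(0L, 1L, 1L))
  expect_equal(unname(d$X[2, ]),
               unname(vectorize_upper_triangle(mats[[2]])),
               tolerance = 1e-6)
})

test_that("malformed inputs are rejected with clear messages", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("e1\te2", "0.1\t0.2"), tf)          # no label column
  expect_error(read_fc_dataset(tf, "edge-table"), "label")
  writeLines(c("e1\te2\tlabel", "0.1\tapple\t1"), tf)
  expect_error(read_fc_dataset(tf, "edge-table"), "non-numeric")
  em <- edge_index_map(3)
  expect_error(fc_dataset(matrix(0, 2, 3), c(0, 2), em), "labels")
  expect_error(fc_dataset(matrix(0, 2, 2), c(0, 1), em), "edges")
})
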