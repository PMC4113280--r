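test_that("kNN distances match hand-checkable instances", {
  ch <- search_chunk(matrix(c(0, 1, 4), ncol = 1), k = 1)
  expect_equal(knn_search(ch, "oracle"), c(1, 1, 3))
  expect_equal(knn_search(ch, "tree"), c(1, 1, 3))

  ch2 <- search_chunk(matrix(c(0, 0, 3, 1), 2, 2, byrow = TRUE), k = 1)
  expect_equal(knn_search(ch2), c(3, 3))   # max-norm, symmetric
})

test_that("range counting is strict and rejects negative radii", {
  ch <- search_chunk(matrix(c(0, 1, 4), ncol = 1), k = 1)
  expect_equal(range_count(ch, radii = c(1.5, 1.5, 1.5)), c(1L, 1L, 0L))
  expect_equal(range_count(ch, radii = c(1, 1, 3)), c(0L, 0L, 0L))  # ties out
  expect_equal(range_count(ch, radii = c(0, 0, 0)), c(0L, 0L, 0L))
  expect_error(range_count(ch, radii = c(-1, 0, 0)), "negative radius")
})

test_that("tree backend equals the brute-force oracle exactly", {
  set.seed(5)
  for (dim in c(2, 5)) {
    X <- matrix(rnorm(500 * dim), ncol = dim)
    ch <- search_chunk(X, k = 4)
    d_tree <- knn_search(ch, "tree")
    expect_identical(d_tree, knn_search(ch, "oracle"))
    expect_identical(range_count(ch, radii = d_tree, backend = "tree"),
                     range_count(ch, radii = d_tree, backend = "oracle"))
  }
})

test_that("both backends agree with an independent R implementation, with
           and without Theiler exclusion", {
  set.seed(9)
  X <- matrix(rnorm(120 * 3), ncol = 3)
  rep <- rep(1:4, each = 30)
  tim <- rep(0:29, times = 4)
  for (th in c(0L, 5L)) {
    ch <- search_chunk(X, k = 3, rep = rep, time = tim, theiler = th)
    d_ref <- oracle_knn(X, 3, rep, tim, th)
    expect_equal(knn_search(ch, "tree"), d_ref)
    expect_equal(knn_search(ch, "oracle"), d_ref)
    cnt_ref <- oracle_count(X, d_ref, rep, tim, th)
    expect_equal(range_count(ch, radii = d_ref, backend = "tree"), cnt_ref)
  }
})

test_that("count at a point's own kth distance never exceeds k", {
  set.seed(13)
  X <- matrix(runif(400 * 4), ncol = 4)
  ch <- search_chunk(X, k = 6)
  d <- knn_search(ch)
  expect_true(all(range_count(ch, radii = d) <= 6))
})

test_that("results are invariant under point re-ordering", {
  set.seed(17)
  X <- matrix(rnorm(200 * 3), ncol = 3)
  perm <- sample(nrow(X))
  d1 <- knn_search(search_chunk(X, k = 4))
  d2 <- knn_search(search_chunk(X[perm, ], k = 4))
  expect_equal(d2, d1[perm])
})

test_that("insufficient admissible neighbours raises a parameter error", {
  X <- matrix(rnorm(5), ncol = 1)
  expect_error(search_chunk(X, k = 5), "n_points > k")
  # Theiler exclusion can starve a search even when n > k
  ch <- search_chunk(matrix(rnorm(6), ncol = 1), k = 4,
                     rep = rep(1L, 6), time = 0:5, theiler = 10)
  expect_error(knn_search(ch), "fewer than k")
})

test_that("batched execution equals sequential and isolates failures", {
  set.seed(21)
  mk <- function() search_chunk(matrix(rnorm(60 * 2), ncol = 2), k = 4)
  chunks <- replicate(3, mk(), simplify = FALSE)
  batch <- batched_search(chunks)
  seq_res <- lapply(chunks, knn_search)
  expect_equal(batch, seq_res)

  expect_equal(batched_search(list()), list())

  bad <- search_chunk(matrix(rnorm(6), ncol = 1), k = 4,
                      rep = rep(1L, 6), time = 0:5, theiler = 10)
  mixed <- batched_search(list(chunks[[1]], bad, chunks[[3]]))
  expect_equal(mixed[[1]], seq_res[[1]])
  expect_s3_class(mixed[[2]], "search_error")
  expect_equal(mixed[[3]], seq_res[[3]])
})
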