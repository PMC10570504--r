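test_that("solution matrix assembly stacks and routes fields", {
  sols <- lapply(1:3, function(i)
    structure(list(mesh_id = paste0("m", i),
                   pressure = i * (1:5), wss = i * (1:2)),
              class = "flow_solution"))
  A <- assemble_solution_matrix(sols, "pressure")
  expect_equal(dim(A), c(3L, 5L))
  expect_equal(A[1, ], 1:5)
  expect_equal(attr(A, "mesh_ids"), c("m1", "m2", "m3"))
  W <- assemble_solution_matrix(sols, "wss")
  expect_equal(dim(W), c(3L, 2L))
  # inconsistent node counts are a topology error
  bad <- c(sols, list(structure(list(mesh_id = "x", pressure = 1:4, wss = 1:2),
                                class = "flow_solution")))
  expect_error(assemble_solution_matrix(bad, "pressure"), "topology")
  expect_error(assemble_solution_matrix(sols[1], "pressure"), "at least 2")
})

test_that("rank-1 matrices decompose to a single mode", {
  u <- c(1, 2, 3); v <- c(2, 0, -1, 4)
  A <- u %*% t(v)
  b <- pod_decompose(A)
  expect_equal(b$k, 1L)
  expect_gt(b$sigma[1], 0)
  expect_lt(max(b$sigma[-1]) / b$sigma[1], 1e-10)
  # mode 1 proportional to v, sign fixed so largest entry is positive
  vn <- v / sqrt(sum(v^2))
  expect_equal(as.vector(b$modes[1, ]), vn, tolerance = 1e-10)
  expect_equal(energy_fraction(b, 1), 1, tolerance = 1e-10)
  expect_equal(pod_reconstruct(b$coefficients, b), A, tolerance = 1e-10)
})

test_that("full-rank factorisation reproduces the matrix on both paths", {
  set.seed(21)
  for (dims in list(c(5L, 8L), c(8L, 5L), c(6L, 40L))) {
    A <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    for (m in c("svd", "snapshot")) {
      b <- pod_decompose(A, method = m)
      R <- pod_reconstruct(b$coefficients, b)
      expect_lt(norm(R - A, "F") / norm(A, "F"), 1e-8)
      # mode rows orthonormal
      G <- b$modes %*% t(b$modes)
      expect_lt(max(abs(G - diag(b$k))), 1e-10)
      expect_true(all(diff(b$sigma) <= 1e-12))
    }
  }
})

test_that("singular values square to the eigenvalues of A A^T", {
  set.seed(33)
  A <- matrix(rnorm(40), 5, 8)
  b <- pod_decompose(A)
  lambda <- eigen(A %*% t(A), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(b$sigma^2, lambda, tolerance = 1e-8)
})

test_that("snapshot and direct SVD agree on sigma, modes and coefficients", {
  set.seed(8)
  A <- matrix(rnorm(240), 6, 40)
  b1 <- pod_decompose(A, method = "svd")
  b2 <- pod_decompose(A, method = "snapshot")
  expect_equal(b1$sigma, b2$sigma, tolerance = 1e-8)
  expect_equal(b1$modes, b2$modes, tolerance = 1e-6)
  expect_equal(b1$coefficients, b2$coefficients, tolerance = 1e-6)
  # auto picks the snapshot path when N >> M and stays equivalent
  b3 <- pod_decompose(A, method = "auto")
  expect_equal(b3$sigma, b1$sigma, tolerance = 1e-8)
})

test_that("energy fraction follows the cumulative singular-value sum", {
  b <- pod_decompose(diag(c(4, 3, 2, 1)))
  expect_equal(b$sigma, c(4, 3, 2, 1), tolerance = 1e-12)
  expect_equal(energy_fraction(b, 2), 0.7, tolerance = 1e-12)
  expect_equal(energy_fraction(b, 4), 1, tolerance = 1e-12)
  # independent cumulative-sum oracle on a random matrix
  set.seed(4)
  br <- pod_decompose(matrix(rnorm(60), 6, 10))
  cum <- cumsum(br$sigma) / sum(br$sigma)
  for (k in seq_along(br$sigma))
    expect_equal(energy_fraction(br, k), cum[k], tolerance = 1e-12)
  expect_true(all(diff(vapply(seq_along(br$sigma), energy_fraction,
                              0, basis = br)) >= 0))
  expect_error(energy_fraction(br, 0), "out of range")
  expect_error(energy_fraction(br, 99), "out of range")
})

test_that("truncation selects the smallest k reaching the threshold", {
  b <- pod_decompose(diag(c(4, 3, 2, 1)))
  expect_equal(pod_truncate(b, energy = 1)$k, b$k)
  expect_equal(pod_truncate(b, energy = 0.7)$k, 2L)
  expect_equal(pod_truncate(b, energy = 0.71)$k, 3L)
  r1 <- pod_decompose(cbind(1:3) %*% rbind(1:4))
  expect_equal(pod_truncate(r1, energy = 0.95)$k, 1L)
  expect_error(pod_truncate(b, energy = 0), "\\(0, 1]")
  expect_error(pod_truncate(b, energy = 1.5), "\\(0, 1]")
  bt <- pod_truncate(b, k = 2L)
  expect_equal(dim(bt$modes), c(2L, 4L))
  expect_equal(dim(bt$coefficients), c(4L, 2L))
  expect_length(bt$sigma, 4L)       # full spectrum kept for energy accounting
})

test_that("truncation error decreases monotonically with k", {
  set.seed(13)
  A <- matrix(rnorm(200), 10, 20)
  b <- pod_decompose(A)
  errs <- vapply(seq_len(b$k), function(k) {
    bt <- pod_truncate(b, k = k)
    norm(pod_reconstruct(bt$coefficients, bt) - A, "F")
  }, 0)
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("projection returns principal coefficients and orthogonal residuals", {
  set.seed(5)
  A <- matrix(rnorm(80), 8, 10)
  b <- pod_truncate(pod_decompose(A), k = 4L)
  # a mode projects to a unit vector
  expect_equal(pod_project(b$modes[2, ], b), c(0, 1, 0, 0), tolerance = 1e-10)
  # a training row projects to its own coefficient row
  expect_equal(pod_project(A[3, ], b), as.vector(b$coefficients[3, ]),
               tolerance = 1e-8)
  # reconstruction of a random vector is the orthogonal projection
  f <- rnorm(10)
  res <- f - pod_reconstruct(pod_project(f, b), b)
  expect_lt(max(abs(b$modes %*% res)), 1e-8)
  expect_error(pod_project(1:3, b), "length mismatch")
  expect_error(pod_reconstruct(1:3, b), "length mismatch")
  expect_equal(pod_reconstruct(rep(0, 4L), b), rep(0, 10L))
})

test_that("optional centering is honoured in project/reconstruct", {
  set.seed(6)
  A <- matrix(rnorm(60), 6, 10) + 100
  b <- pod_decompose(A, center = TRUE)
  expect_equal(pod_reconstruct(b$coefficients, b), A, tolerance = 1e-8)
  expect_equal(pod_reconstruct(pod_project(A[2, ], b), b), A[2, ],
               tolerance = 1e-8)
})

test_that("POD ensemble solved from geometry matches expected shape", {
  cs <- coarse_solutions()
  A <- assemble_solution_matrix(cs$solutions, "pressure")
  expect_equal(dim(A), c(12L, cs$dataset[[1L]]$n_volume))
  W <- assemble_solution_matrix(cs$solutions, "wss")
  expect_equal(dim(W), c(12L, cs$dataset[[1L]]$n_surface))
  b <- pod_decompose(A)
  expect_lt(norm(pod_reconstruct(b$coefficients, b) - A, "F") /
              norm(unclass(A), "F"), 1e-8)
})

test_that("basis CSV export writes spectrum and coefficients", {
  tmp <- withr::local_tempdir()
  b <- pod_decompose(matrix(rnorm(40), 4, 10))
  write_pod_csv(b, tmp)
  sig <- read.csv(file.path(tmp, "sigma.csv"))
  expect_equal(sig$sigma, b$sigma, tolerance = 1e-12)
  expect_equal(sig$energy_cum[length(b$sigma)], 1, tolerance = 1e-12)
  co <- read.csv(file.path(tmp, "coefficients.csv"))
  expect_equal(as.matrix(co[, -1]), b$coefficients, tolerance = 1e-12,
               ignore_attr = TRUE)
})
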