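test_that("delay embedding expands lagged coordinates", {
  tr <- embed_delay(1:5, m = 2, tau = 1)
  expect_equal(unclass(tr)[, 1], 1:4, ignore_attr = TRUE)
  expect_equal(unclass(tr)[, 2], 2:5, ignore_attr = TRUE)
  expect_equal(nrow(tr), 4)

  expect_equal(nrow(embed_delay(1:10, m = 3, tau = 2)), 6)
  expect_error(embed_delay(1:4, m = 3, tau = 2), "at least")
  expect_error(embed_delay(1:10, m = 1, tau = 1), "m")
})

test_that("trajectory length N = L - (m-1) tau over random cases", {
  withr::with_seed(42, {
    for (rep in 1:30) {
      m <- sample(2:5, 1)
      tau <- sample(1:6, 1)
      L <- (m - 1) * tau + sample(2:40, 1)
      tr <- embed_delay(rnorm(L), m, tau)
      expect_equal(nrow(tr), L - (m - 1) * tau)
      expect_equal(ncol(tr), m)
    }
  })
})

test_that("k-NN thresholds match hand-computed collinear cases", {
  pts <- cbind(c(0, 1, 2, 3), c(0, 0, 0, 0))
  expect_equal(knn_epsilon(pts, 1), c(1, 1, 1, 1))
  expect_equal(knn_epsilon(pts, 3), c(3, 2, 2, 3))
  expect_equal(knn_epsilon(matrix(1, 5, 2), 2), rep(0, 5))
  expect_error(knn_epsilon(pts, 4), "k must be")
})

test_that("k-NN thresholds agree with the brute-force oracle", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      N <- sample(5:50, 1)
      m <- sample(2:3, 1)
      traj <- matrix(rnorm(N * m), N, m)
      k <- sample(seq_len(N - 1), 1)
      expect_equal(knn_epsilon(traj, k), oracle_knn_eps(traj, k))
    }
  })
})

test_that("recurrence matrix uses a strict threshold (Theta(0) = 0)", {
  pts <- matrix(1, 4, 2)  # identical points: all eps = 0, diagonal included
  R <- recurrence_matrix(pts, knn_epsilon(pts, 2))
  expect_true(all(unclass(R) == 0))

  coll <- cbind(c(0, 1, 2, 3), 0)
  R1 <- recurrence_matrix(coll, knn_epsilon(coll, 1))
  expect_equal(unclass(R1), diag(4), ignore_attr = TRUE)
})

test_that("a global epsilon gives a symmetric matrix", {
  withr::with_seed(3, {
    traj <- matrix(rnorm(60), 30, 2)
    R <- recurrence_matrix(traj, 0.8)
    expect_identical(unclass(R), t(unclass(R)))
  })
})

test_that("recurrence matrices equal the brute-force double loop", {
  withr::with_seed(11, {
    for (rep in 1:15) {
      N <- sample(5:100, 1)
      traj <- matrix(rnorm(N * 2), N, 2)
      eps_g <- runif(1, 0.1, 2)
      expect_equal(unclass(recurrence_matrix(traj, eps_g)),
                   oracle_recurrence(traj, eps_g), ignore_attr = TRUE)
      k <- sample(seq_len(min(N - 1, 8)), 1)
      # per-point thresholds: oracle uses its own eps so both routes stay
      # internally consistent at the strict k-th-neighbour boundary
      expect_equal(unclass(recurrence_matrix(traj, knn_epsilon(traj, k))),
                   oracle_recurrence(traj, oracle_knn_eps(traj, k)),
                   ignore_attr = TRUE)
    }
  })
})

test_that("per-point k-NN rows hold exactly k-1 off-diagonal recurrences", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      N <- sample(10:50, 1)
      traj <- matrix(rnorm(N * 2), N, 2)  # continuous: distances distinct
      k <- sample(2:6, 1)
      R <- unclass(recurrence_matrix(traj, knn_epsilon(traj, k)))
      expect_true(all(diag(R) == 1))
      expect_true(all(rowSums(R) == k))
    }
  })
})

test_that("rendering maps recurrences to white and preserves density", {
  ones <- matrix(1L, 64, 64)
  expect_true(all(unclass(render_rp(ones)) == 1))

  withr::with_seed(2, {
    bin <- matrix(rbinom(64 * 64, 1, 0.3), 64, 64)
    expect_equal(unclass(render_rp(bin, 64)), bin * 1.0, ignore_attr = TRUE)

    cb <- matrix(0L, 128, 128)
    cb[(row(cb) + col(cb)) %% 2 == 0] <- 1L
    expect_equal(unname(unclass(render_rp(cb, 64))),
                 matrix(0.5, 64, 64))

    # area averaging conserves mean intensity at awkward ratios too
    for (N in c(50, 97, 200)) {
      Rm <- matrix(rbinom(N * N, 1, 0.2), N, N)
      img <- render_rp(Rm, 64)
      expect_equal(mean(unclass(img)), mean(Rm), tolerance = 1e-6)
      expect_true(all(unclass(img) >= 0 & unclass(img) <= 1))
    }

    # integer-ratio upsampling is pixel replication
    m2 <- matrix(c(1, 0, 0, 1), 2, 2)
    up <- unname(unclass(render_rp(m2, 4)))
    expect_equal(up, matrix(c(1, 1, 0, 0, 1, 1, 0, 0,
                              0, 0, 1, 1, 0, 0, 1, 1), 4, 4))
  })
})

test_that("fused signal-to-image path equals the four-step composition", {
  withr::with_seed(9, {
    for (rep in 1:8) {
      u <- as.numeric(arima.sim(list(ar = 0.9), 150)) + 130
      m <- sample(2:3, 1); tau <- sample(1:3, 1); k <- sample(2:6, 1)
      fused <- signal_to_rp(u, m, tau, k, size = 64)
      tr <- embed_delay(u, m, tau)
      comp <- render_rp(recurrence_matrix(tr, knn_epsilon(tr, k)), 64)
      expect_equal(unclass(fused), unname(unclass(comp)), tolerance = 1e-12,
                   ignore_attr = TRUE)
      g_fused <- signal_to_rp(u, m, tau, k, size = 64, mode = "global")
      g_comp <- render_rp(
        recurrence_matrix(tr, mean(knn_epsilon(tr, k))), 64)
      expect_equal(unclass(g_fused), unname(unclass(g_comp)),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  })
})

test_that("a constant record renders an all-black image", {
  img <- signal_to_rp(rep(130, 100), m = 2, tau = 1, k = 6)
  expect_true(all(unclass(img) == 0))
})

test_that("any record renders a square unit-intensity image", {
  rec <- clean_record(duration_s = 90, seed = 12)
  img <- signal_to_rp(rec, m = 2, tau = 1, k = 6)
  expect_equal(dim(unclass(img)), c(64, 64))
  expect_true(all(unclass(img) >= 0 & unclass(img) <= 1))
})

test_that("the reference image fixture is reproduced", {
  rec <- clean_record(duration_s = 120, seed = 2024)
  img <- signal_to_rp(rec, m = 2, tau = 1, k = 6, size = 64)
  fix_path <- test_path("fixtures", "rp_reference.csv")
  ref <- as.matrix(utils::read.csv(fix_path, header = FALSE))
  expect_equal(unname(unclass(img)), unname(ref), tolerance = 1e-6,
               ignore_attr = TRUE)
})
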