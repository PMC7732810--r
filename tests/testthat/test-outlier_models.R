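test_that("isolation forest isolates an obvious outlier and honors contamination", {
  withr::with_seed(1, {
    X <- matrix(rnorm(99 * 4, sd = 0.05), 99, 4)
    X <- rbind(X, rep(10, 4))
  })
  res <- fit_and_flag(detector_spec("isolation_forest", contamination = 0.01),
                      X, seed = 2)
  expect_true(res$flags[100])
  expect_equal(which.max(res$scores), 100L)

  withr::with_seed(3, Xg <- matrix(rnorm(100 * 5), 100, 5))
  res2 <- fit_and_flag(detector_spec("isolation_forest", contamination = 0.1),
                       Xg, seed = 4)
  expect_equal(sum(res2$flags), 10)
})

test_that("LOF flags the density outlier and matches a direct transliteration", {
  X <- cbind(c(0, 1, 2, 100))
  scores <- occlean:::lof_scores(X, k = 2)
  expect_gt(scores[4], 5)
  expect_lt(max(scores[1:3]), 2)

  # brute-force LOF: k-distance, reachability distance, local reachability
  # density, then the neighbor-density ratio
  brute_lof <- function(X, k) {
    n <- nrow(X)
    D <- as.matrix(stats::dist(X)); diag(D) <- Inf
    kdist <- numeric(n); Nk <- vector("list", n)
    for (i in 1:n) {
      kdist[i] <- sort(D[i, ])[k]
      Nk[[i]] <- which(D[i, ] <= kdist[i])
    }
    lrd <- numeric(n)
    for (i in 1:n)
      lrd[i] <- 1 / (sum(pmax(kdist[Nk[[i]]], D[i, Nk[[i]]])) /
                       length(Nk[[i]]))
    out <- numeric(n)
    for (i in 1:n)
      out[i] <- sum(lrd[Nk[[i]]] / lrd[i]) / length(Nk[[i]])
    out
  }
  withr::with_seed(6, {
    for (rep in 1:4) {
      n <- sample(10:30, 1)
      Y <- matrix(rnorm(n * 3), n, 3)
      k <- sample(2:5, 1)
      expect_equal(occlean:::lof_scores(Y, k), brute_lof(Y, k),
                   tolerance = 1e-10)
    }
  })
})

test_that("detectors refuse undersized inputs and refit reproducibly", {
  X <- matrix(runif(5 * 7), 5, 7)
  expect_error(fit_and_flag(detector_spec("isolation_forest"), X),
               "more constraints")
  withr::with_seed(2, Xb <- matrix(runif(60 * 7), 60, 7))
  for (fam in c("isolation_forest", "ocsvm", "lof")) {
    r1 <- fit_and_flag(detector_spec(fam), Xb, seed = 9)
    r2 <- fit_and_flag(detector_spec(fam), Xb, seed = 9)
    expect_identical(r1$flags, r2$flags)
    expect_identical(r1$scores, r2$scores)
  }
})

test_that("autoencoders reconstruct constant data and expose the right latent widths", {
  X <- matrix(rep(c(0.2, 0.8, 0.5, 0.3, 0.9, 0.1, 0.6), each = 50), 50, 7)
  arch <- ae_spec(c(7, 3, 7), epochs = 500, lr = 0.3)
  m <- train_autoencoder(arch, X, seed = 1)
  expect_lt(mean(reconstruction_errors(m, X)), 0.01)
  expect_true(all(reconstruction_errors(m, X) >= 0))

  m3 <- train_autoencoder(ae_architecture("AE3", "small"), X, seed = 1)
  expect_equal(ncol(encode_latent(m3, X)), 3)
  m1 <- train_autoencoder(ae_architecture("AE1_L1", "small"), X, seed = 1)
  expect_equal(ncol(encode_latent(m1, X)), 7)
  expect_identical(encode_latent(m1, X), encode_latent(m1, X))
  expect_error(ae_spec(c(7, 3, 5)))   # asymmetric
  expect_error(train_autoencoder(ae_spec(c(7, 3, 7)), X[, 1:5]),
               "dimensionality")
})

test_that("the L1 penalty shrinks bottleneck activations", {
  withr::with_seed(5, X <- matrix(runif(300 * 7), 300, 7))
  plain <- train_autoencoder(ae_spec(c(7, 7, 7), l1 = 0, epochs = 60,
                                     lr = 0.05), X, seed = 3)
  sparse <- train_autoencoder(ae_spec(c(7, 7, 7), l1 = 1e-3, epochs = 60,
                                      lr = 0.05), X, seed = 3)
  expect_lt(mean(abs(encode_latent(sparse, X))),
            mean(abs(encode_latent(plain, X))))
})

test_that("planted far rows take the top reconstruction-error ranks", {
  withr::with_seed(7, {
    X <- matrix(runif(95 * 7, 0.4, 0.6), 95, 7)
    out <- matrix(rep(c(0, 1), length.out = 7 * 5) , 5, 7, byrow = TRUE)
  })
  Xa <- rbind(X, out)
  m <- train_autoencoder(ae_spec(c(7, 5, 3, 5, 7), epochs = 150, lr = 0.05),
                         Xa, seed = 2)
  errs <- reconstruction_errors(m, Xa)
  expect_setequal(order(-errs)[1:5], 96:100)
})

test_that("select_clean_by_error keeps the lowest errors with stable ties", {
  expect_equal(which(select_clean_by_error(c(0.1, 0.2, 0.9, 0.05), 0.75)),
               c(1L, 2L, 4L))
  expect_true(all(select_clean_by_error(runif(10), 1.0)))
  ties <- c(0.5, 0.5, 0.5, 0.5)
  expect_equal(which(select_clean_by_error(ties, 0.5)), c(1L, 2L))
  expect_length(select_clean_by_error(numeric(0), 0.9), 0)
})

test_that("training loss decreases on average and seeds reproduce fits", {
  withr::with_seed(10, X <- matrix(runif(200 * 7), 200, 7))
  m <- train_autoencoder(ae_spec(c(7, 5, 3, 5, 7), epochs = 80, lr = 0.05),
                         X, seed = 11)
  expect_lt(mean(tail(m$losses, 8)), mean(head(m$losses, 8)))
  m2 <- train_autoencoder(ae_spec(c(7, 5, 3, 5, 7), epochs = 80, lr = 0.05),
                          X, seed = 11)
  expect_identical(m$W, m2$W)
})
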