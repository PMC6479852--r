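test_that("descriptor extraction finds structure and ignores flat images", {
  uniform <- array(0.5, dim = c(80, 80, 3))
  expect_equal(nrow(extract_descriptors(uniform)$descriptors), 0L)

  d <- extract_descriptors(rot_crop())
  expect_gt(nrow(d$descriptors), 10L)
  expect_equal(ncol(d$descriptors), 128L)
  ## descriptors are L2-bounded and keypoints lie inside the crop
  expect_true(all(abs(sqrt(rowSums(d$descriptors^2)) - 1) < 1e-6))
  expect_true(all(d$keypoints$x >= 0 & d$keypoints$x < dim(rot_crop())[2]))
  expect_true(all(d$keypoints$y >= 0 & d$keypoints$y < dim(rot_crop())[1]))
})

test_that("descriptors are scale invariant under 2x upsampling", {
  crop <- rot_crop()
  d1 <- extract_descriptors(crop)
  d2 <- extract_descriptors(resize_image(crop, 2 * dim(crop)[1],
                                         2 * dim(crop)[2]))
  sims <- c()
  for (i in seq_len(nrow(d1$keypoints))) {
    k <- d1$keypoints[i, ]
    dd <- sqrt((d2$keypoints$x - 2 * k$x)^2 + (d2$keypoints$y - 2 * k$y)^2)
    sr <- d2$keypoints$scale / (2 * k$scale)
    cand <- which(dd < 4 & sr > 0.7 & sr < 1.4)
    if (length(cand)) {
      j <- cand[which.min(dd[cand])]
      sims <- c(sims, sum(d1$descriptors[i, ] * d2$descriptors[j, ]))
    }
  }
  expect_gt(length(sims), 5L)
  expect_gt(mean(sims > 0.8), 0.8)     # matched pairs agree strongly
})

test_that("vocabulary building recovers known cluster structure", {
  set.seed(21)
  centers_true <- matrix(c(rep(0, 128), rep(1, 128), rep(-1, 128)),
                         nrow = 3, byrow = TRUE)
  X <- centers_true[rep(1:3, each = 50), ] + rnorm(150 * 128, sd = 0.05)
  v <- build_vocabulary(X, k = 3, seed = 7)
  expect_s3_class(v, "bof_vocabulary")
  ## each true center has a recovered center nearby
  for (i in 1:3) {
    dists <- sqrt(rowSums((v$centers - matrix(centers_true[i, ], 3, 128,
                                              byrow = TRUE))^2))
    expect_lt(min(dists), 0.5)
  }
  ## k = 1 closed form: the mean descriptor
  v1 <- build_vocabulary(X, k = 1, seed = 7)
  expect_equal(as.vector(v1$centers), colMeans(X), tolerance = 1e-8)
  ## determinism
  v2 <- build_vocabulary(X, k = 3, seed = 7)
  expect_identical(v$centers, v2$centers)
  expect_error(build_vocabulary(X[1:2, ], k = 3), "at least")
})

test_that("BoF encoding is the exhaustive nearest-center histogram", {
  set.seed(33)
  v <- build_vocabulary(matrix(rnorm(40 * 128), 40), k = 10, seed = 2)
  D <- matrix(rnorm(20 * 128), 20)
  h <- encode_bof(D, v)
  expect_equal(sum(h), 1)
  oracle <- apply(D, 1, function(x)
    which.min(colSums((t(v$centers) - x)^2)))
  h_oracle <- tabulate(oracle, v$k) / nrow(D)
  expect_equal(h, h_oracle, tolerance = 1e-12)

  ## single descriptor exactly at a center -> one-hot
  h1 <- encode_bof(v$centers[4, , drop = FALSE], v)
  expect_equal(h1[4], 1)
  expect_equal(sum(h1), 1)

  ## no descriptors -> zero vector
  expect_equal(encode_bof(matrix(0, 0, 128), v), numeric(v$k))
  expect_error(encode_bof(matrix(0, 2, 64), v), "dimension")
})

test_that("BoF histograms are equivariant under word relabeling", {
  set.seed(44)
  v <- build_vocabulary(matrix(rnorm(30 * 128), 30), k = 6, seed = 1)
  D <- matrix(rnorm(15 * 128), 15)
  h <- encode_bof(D, v)
  perm <- sample(6)
  v2 <- v; v2$centers <- v$centers[perm, ]
  h2 <- encode_bof(D, v2)
  expect_equal(h2, h[perm], tolerance = 1e-12)
})

test_that("the backbone produces deterministic penultimate features", {
  bb <- tiny_backbone()
  expect_equal(bb$feature_dim, 128L)
  crop <- rot_crop()
  f1 <- extract_cnn_features(crop, bb)
  f2 <- extract_cnn_features(list(crop, crop), bb)
  expect_equal(dim(f1), c(1L, 128L))
  expect_equal(dim(f2), c(2L, 128L))
  expect_equal(f2[1, ], f2[2, ])             # identical images, identical features
  expect_equal(f1[1, ], f2[1, ], tolerance = 1e-12)
  expect_true(all(f1 >= 0))                  # post-ReLU activations
  expect_error(extract_cnn_features(crop, list()), "cnn_backbone")
})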