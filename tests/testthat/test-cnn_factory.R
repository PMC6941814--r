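test_that("variant specs encode the published geometry", {
  s25 <- cnn_variant("CNN-25")
  expect_equal(vapply(s25$conv_layers, `[[`, integer(1), "pool_size"),
               c(25L, 4L))
  expect_equal(vapply(s25$conv_layers, `[[`, integer(1), "filter_size"),
               c(19L, 5L))
  expect_equal(vapply(s25$conv_layers, `[[`, integer(1), "n_filters"),
               c(30L, 128L))
  # coupled pools multiply to 100
  for (v in c("CNN-1", "CNN-2", "CNN-4", "CNN-10", "CNN-25", "CNN-50",
              "CNN-100")) {
    ps <- vapply(cnn_variant(v)$conv_layers, `[[`, integer(1),
                 "pool_size")
    expect_equal(prod(ps), 100)
  }
  expect_equal(cnn_variant("CNN_9-25")$conv_layers[[1]]$filter_size, 9L)
  expect_equal(cnn_variant("CNN_3-50")$conv_layers[[1]]$filter_size, 3L)
  expect_equal(cnn_variant("CNN_19-1_-2")$conv_layers[[2]]$filter_size, 1L)
  s502 <- cnn_variant("CNN-50-2")
  expect_equal(s502$conv_layers[[1]]$pool_size, 50L)
  expect_equal(s502$conv_layers[[1]]$pool_stride, 2L)
  s3 <- cnn_variant("CNN-1-1-100")
  expect_length(s3$conv_layers, 3L)
  expect_equal(vapply(s3$conv_layers, `[[`, integer(1), "pool_size"),
               c(1L, 1L, 100L))
  expect_equal(cnn_variant("CNN-25", n_filters1 = 120)$conv_layers[[1]]$n_filters,
               120L)
  expect_equal(cnn_variant("CNN-25(90)")$conv_layers[[1]]$n_filters, 90L)
  expect_error(cnn_variant("CNN-7"), "unknown variant")
})

test_that("feature-map lengths follow the pooling arithmetic", {
  fl <- motifrep:::feature_lengths
  expect_equal(fl(cnn_variant("CNN-25"), 200), c(8L, 2L))
  expect_equal(fl(cnn_variant("CNN-2"), 200), c(100L, 2L))
  expect_equal(fl(cnn_variant("CNN-50-2"), 200), c(100L, 2L))
  expect_equal(fl(cnn_variant("CNN-1-1-100"), 200), c(200L, 200L, 2L))
})

test_that("coupled-pool variants share dense-input size and parameter count", {
  coupled <- c("CNN-1", "CNN-2", "CNN-4", "CNN-10", "CNN-25", "CNN-50",
               "CNN-100")
  models <- lapply(coupled, function(v)
    build_cnn(cnn_variant(v), 200, seed = 1))
  flats <- vapply(models, `[[`, integer(1), "flat_dim")
  expect_equal(flats, rep(flats[1], length(flats)))
  counts <- vapply(models, n_parameters, integer(1))
  expect_equal(counts, rep(counts[1], length(counts)))
  # CNN-50-2 matches CNN-2's shapes, hence the same parameter count
  expect_equal(n_parameters(build_cnn(cnn_variant("CNN-50-2"), 200)),
               counts[1])
})

test_that("conv1 weights have the stated shape", {
  m <- build_cnn(cnn_variant("CNN-25"), 200, seed = 1)
  expect_equal(dim(m$params$conv1_W), c(30L, 4L * 19L))
})

test_that("every variant forward-passes a batch of 2 with output (2, 12)", {
  set.seed(1)
  x <- array(0, c(4, 200, 2))
  for (b in 1:2) x[cbind(sample(4, 200, TRUE), 1:200, b)] <- 1
  for (v in cnn_variant_names()) {
    m <- build_cnn(cnn_variant(v), 200, seed = 2)
    p <- predict(m, x)
    expect_equal(dim(p), c(2L, 12L))
    expect_true(all(p > 0 & p < 1))
  }
})
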