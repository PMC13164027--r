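test_that("per-nucleus inverted mean DAB matches hand-computed values", {
  dab <- matrix(0.05, 6, 6)
  m <- matrix(0L, 6, 6); m[2:3, 2:3] <- 1L
  rec <- mean_inverted_dab(dab, m)
  expect_equal(rec$mu, 0.95)
  expect_equal(rec$area_px, 4L)
  # single pixel
  dab[5, 5] <- 0.2; m[5, 5] <- 2L
  rec <- mean_inverted_dab(dab, m)
  expect_equal(rec$mu[rec$id == 2], 0.8)
  # three-pixel brute force: 1 - mean(0, 0.1, 0.2)
  dab3 <- matrix(0, 3, 3); dab3[1, 1:3] <- c(0, 0.1, 0.2)
  m3 <- matrix(0L, 3, 3); m3[1, 1:3] <- 1L
  expect_equal(mean_inverted_dab(dab3, m3)$mu, 1 - 0.1)
  # contracts
  expect_error(mean_inverted_dab(matrix(0, 2, 2), matrix(0L, 3, 3)),
               "shapes differ")
  empty <- mean_inverted_dab(matrix(0, 4, 4), matrix(0L, 4, 4))
  expect_equal(nrow(empty), 0L)
  expect_error(mean_inverted_dab(matrix(2, 2, 2), matrix(1L, 2, 2)),
               "\\[0, 1\\]")
})

test_that("threshold classification is total, boundary-exact and monotone", {
  got <- classify_mu(c(0.88, 0.89, 0.94, 0.975))
  expect_equal(as.character(got),
               c("Strong", "Moderate", "Weak", "Negative"))
  expect_error(classify_mu(1.2), "\\[0, 1\\]")
  expect_error(classify_mu(-0.1), "\\[0, 1\\]")
  # every mu in [0,1] gets exactly one class, and the class ordinal
  # (Strong=1 .. Negative=4) never decreases as mu increases
  mu <- sort(runif(500))
  ord <- as.integer(classify_mu(mu))
  expect_false(anyNA(ord))
  expect_true(all(diff(ord) >= 0))
  # custom thresholds respected
  th <- class_thresholds(0.2, 0.5, 0.8)
  expect_equal(as.character(classify_mu(c(0.1, 0.3, 0.6, 0.9), th)),
               c("Strong", "Moderate", "Weak", "Negative"))
  expect_error(class_thresholds(0.9, 0.5, 0.975), "tau1 < tau2")
})

test_that("image classification composes the stages and tallies counts", {
  # tile constructed so every nucleus is Strong
  spec <- synthetic_spec(n_per_class = c(6, 0, 0, 0), height = 128,
                         width = 128, seed = 3)
  tile <- generate_tile(spec)
  res <- classify_image(tile$rgb, tile$mask)
  expect_equal(unlist(res$counts),
               c(strong = 6L, moderate = 0L, weak = 0L, negative = 0L,
                 total = 6L), ignore_attr = TRUE)
  # empty mask
  res0 <- classify_image(tile$rgb, matrix(0L, 128, 128))
  expect_equal(res0$counts$total, 0L)
  # balanced tile: five per class at band centres
  tile4 <- generate_tile(synthetic_spec(seed = 11))
  res4 <- classify_image(tile4$rgb, tile4$mask)
  expect_equal(unlist(res4$counts[c("strong", "moderate", "weak",
                                    "negative")]),
               c(strong = 5L, moderate = 5L, weak = 5L, negative = 5L),
               ignore_attr = TRUE)
  # permutation invariance of counts
  perm <- tile4$mask
  n <- max(perm)
  shuffle <- sample(n)
  perm[perm > 0] <- shuffle[perm[perm > 0]]
  resp <- classify_image(tile4$rgb, perm)
  expect_equal(unlist(resp$counts), unlist(res4$counts))
})

test_that("weakening the DAB signal drives every nucleus negative", {
  spec <- synthetic_spec(n_per_class = c(4, 4, 0, 0), height = 128,
                         width = 128, seed = 8)
  tile <- generate_tile(spec)
  dec <- deconvolve(tile$rgb)
  for (scale in c(0.25, 0.05, 0)) {
    faded <- forward_mix(dec$hematoxylin, dec$dab * scale)
    res <- classify_image(faded, tile$mask)
    if (scale == 0)
      expect_equal(res$counts$negative, res$counts$total)
  }
  # mu increases monotonically as DAB fades
  mus <- sapply(c(1, 0.5, 0.1), function(s) {
    mean(classify_image(forward_mix(dec$hematoxylin, dec$dab * s),
                        tile$mask)$records$mu)
  })
  expect_true(all(diff(mus) > 0))
})

test_that("class overlay uses the four-colour convention", {
  tile <- generate_tile(synthetic_spec(n_per_class = c(1, 1, 1, 1),
                                       height = 96, width = 96, seed = 2))
  res <- classify_image(tile$rgb, tile$mask)
  ov <- render_class_overlay(tile$mask, res$records)
  # background black
  expect_true(all(ov[tile$mask == 0] == 0))
  for (i in seq_len(4)) {
    px <- which(tile$mask == i)
    col <- c(ov[, , 1][px][1], ov[, , 2][px][1], ov[, , 3][px][1])
    expected <- switch(as.character(tile$classes[i]),
                       Strong = c(255, 0, 0), Moderate = c(255, 255, 0),
                       Weak = c(0, 255, 0), Negative = c(0, 0, 255))
    expect_equal(col, expected)
  }
  # empty mask renders all black
  ov0 <- render_class_overlay(matrix(0L, 8, 8),
                              data.frame(id = integer(0),
                                         class = character(0)))
  expect_true(all(ov0 == 0))
  # record/label mismatch is an error
  expect_error(render_class_overlay(tile$mask,
                                    res$records[res$records$id != 2, ]),
               "without a matching record")
})
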