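rot90 <- function(m) t(m)[, seq_len(nrow(m)), drop = FALSE][, nrow(m):1]

test_that("entropy matches hand-computed histogram values", {
  expect_equal(score_entropy(matrix(128L, 8, 8)), 0)
  expect_equal(score_entropy(matrix(0:255, 16, 16)), 8)
  # eight 0s and eight 255s: two equiprobable levels -> 1 bit
  expect_equal(score_entropy(matrix(c(rep(0L, 8), rep(255L, 8)), 4, 4)), 1)
  expect_error(score_entropy(matrix(integer(0), 0, 0)), "empty")
})

test_that("entropy converts RGB via the luma weights", {
  img <- array(0L, c(4, 4, 3))
  img[, , 1] <- 255L  # pure red -> gray level round(0.299*255) = 76
  expect_equal(score_entropy(img), 0)
  g <- matrix(76L, 4, 4)
  expect_equal(score_entropy(img), score_entropy(g))
})

test_that("uniformity is mean within-tile population SD", {
  expect_equal(score_uniformity(matrix(7L, 32, 32)), 0)
  # tiles internally constant but different across tiles -> still 0
  tiles <- kronecker(matrix(c(0L, 255L, 100L, 30L), 2, 2),
                     matrix(1L, 16, 16))
  expect_equal(score_uniformity(tiles), 0)
  # every 16x16 tile a 0/255 checkerboard: population SD = 127.5
  cb <- matrix(0L, 32, 32)
  cb[(row(cb) + col(cb)) %% 2 == 0] <- 255L
  expect_equal(score_uniformity(cb), 127.5)
  expect_error(score_uniformity(matrix(0L, 30, 30)), "divisible")
})

test_that("brightness is mean HSI intensity", {
  expect_equal(score_brightness(array(0L, c(4, 4, 3))), 0)
  expect_equal(score_brightness(array(255L, c(4, 4, 3))), 1)
  # half pure red, half pure blue: every pixel scores 255/765 = 1/3
  img <- array(0L, c(2, 2, 3))
  img[1, , 1] <- 255L
  img[2, , 3] <- 255L
  expect_equal(score_brightness(img), 1 / 3)
})

test_that("vehicle size is the winding-invariant shoelace area", {
  ccw <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  expect_equal(score_vehicle_size(ccw), 1)
  cw <- ccw[4:1, ]
  expect_equal(score_vehicle_size(cw), 1)
  rect <- matrix(c(0, 0, 4, 0, 4, 2, 0, 2), 4, 2, byrow = TRUE)
  expect_equal(score_vehicle_size(rect), 8)
  degen <- matrix(c(0, 0, 1, 1, 2, 2, 3, 3), 4, 2, byrow = TRUE)
  expect_error(score_vehicle_size(degen), "degenerate")
})

test_that("entropy and uniformity are rotation invariant, brightness is permutation invariant", {
  set.seed(42)
  g <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  expect_equal(score_entropy(rot90(g)), score_entropy(g))
  expect_equal(score_uniformity(rot90(g)), score_uniformity(g))
  img <- array(sample(0:255, 16 * 16 * 3, replace = TRUE), c(16, 16, 3))
  perm <- sample(16 * 16)
  shuffled <- img
  for (ch in 1:3) shuffled[, , ch] <- matrix(img[, , ch][perm], 16, 16)
  expect_equal(score_brightness(shuffled), score_brightness(img))
})

# evenly spaced scores: no IQR outliers by construction
make_scores <- function(n = 20) {
  data.frame(patch_id = sprintf("p%02d", 1:n),
             type_label = rep(c("simple-target", "simple-nontarget",
                                "complex-target", "complex-nontarget"),
                              length.out = n),
             scene = "simple", is_target = rep(c(TRUE, FALSE), length.out = n),
             entropy = seq(6.5, 7.1, length.out = n),
             uniformity = seq(30, 46, length.out = n),
             brightness = seq(0.40, 0.48, length.out = n),
             vehicle_size = ifelse(rep(c(TRUE, FALSE), length.out = n),
                                   seq(600, 680, length.out = n), NA),
             stringsAsFactors = FALSE)
}

test_that("IQR screening keeps clean sets untouched and is a fixed point", {
  sc <- make_scores()
  res <- iterative_iqr_screen(sc)
  expect_equal(res$n_passes, 1)
  expect_equal(res$kept, sc)
  expect_equal(nrow(res$removed), 0)
  again <- iterative_iqr_screen(res$kept)
  expect_equal(again$kept, res$kept)
})

test_that("IQR screening removes an injected outlier, matching brute-force fences", {
  sc <- make_scores()
  sc$entropy[7] <- 30  # far outside any plausible fence
  res <- iterative_iqr_screen(sc)
  expect_equal(nrow(res$kept), 19)
  expect_false("p07" %in% res$kept$patch_id)
  expect_equal(res$removed$patch_id, "p07")
  expect_equal(res$removed$removal_measure, "entropy")
  # brute-force oracle: fences from type-7 quartiles on the full score set
  q <- unname(stats::quantile(sc$entropy, c(0.25, 0.75)))
  fence <- c(q[1] - 1.5 * (q[2] - q[1]), q[2] + 1.5 * (q[2] - q[1]))
  expect_identical(which(sc$entropy < fence[1] | sc$entropy > fence[2]), 7L)
  # kept-set size never increases across re-screening
  expect_lte(nrow(iterative_iqr_screen(res$kept)$kept), nrow(res$kept))
})

test_that("IQR screening aborts when too few patches remain", {
  sc <- make_scores(5)
  # geometric spread peels one extreme per step until fewer than 4 are left
  sc$entropy <- 10^(1:5)
  sc$uniformity <- 1; sc$brightness <- 0.5; sc$vehicle_size <- NA
  expect_error(iterative_iqr_screen(sc), "fewer than 4")
  expect_error(iterative_iqr_screen(make_scores(20)[1:3, ]), "nrow")
})

test_that("balance_types downsamples to the minimum and is seed-deterministic", {
  sc <- make_scores(40)
  sc <- sc[-c(1, 5), ]  # unbalance two types
  bal <- balance_types(sc, seed = 3)
  expect_true(all(table(bal$type_label) == min(table(sc$type_label))))
  expect_identical(balance_types(sc, seed = 3), bal)
  expect_false(identical(balance_types(sc, seed = 4)$patch_id, bal$patch_id))
  sc0 <- sc[sc$type_label != "simple-target", ]
  expect_error(balance_types(sc0[sc0$type_label == "none", ]), "empty")
})
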