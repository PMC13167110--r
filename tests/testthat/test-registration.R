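test_that("preprocessing turns dark vessels into bright ridges", {
  img <- matrix(1, 64, 64)
  img[, 30:32] <- 0.2          # dark vertical vessel
  p <- preprocess_params(1, 20, 11)
  out <- preprocess_image(img, p)
  expect_true(all(out >= 0))
  expect_gt(mean(out[, 30:32]), mean(out[, c(10:20, 45:55)]) + 0.01)
  # constant intensity offsets do not change the features
  out2 <- preprocess_image(img + 5, p)
  expect_equal(out, out2, tolerance = 1e-6)
  expect_error(preprocess_image(matrix(2, 10, 10), p), "constant")
})

test_that("preprocessing equals its three stages applied independently", {
  img <- random_test_image(48, 11) + 2
  p <- preprocess_params(1, 10, 7)
  out <- preprocess_image(img, p)
  # stage-by-stage oracle
  den <- EBImage::gblur(img, sigma = 1, radius = 2 * ceiling(3 * 1) + 1)
  bg <- EBImage::gblur(den, sigma = 10, radius = 47)
  sub <- den - bg
  brush <- EBImage::makeBrush(7, "box")
  closed <- EBImage::erode(EBImage::dilate(sub, brush), brush)
  oracle <- pmax(as.matrix(closed - sub), 0)
  expect_equal(out, oracle, tolerance = 1e-10)
})

test_that("preprocess parameter presets satisfy their invariants", {
  expect_error(preprocess_params(5, 4, 11), "sigma_denoise")
  expect_error(preprocess_params(1, 50, 10), "blackhat_window")
  expect_equal(miniscope_preprocess_params()$sigma_denoise, 1)
  expect_equal(confocal_preprocess_params()$blackhat_window, 21)
})

test_that("correlation score matches a direct Pearson computation", {
  img <- random_test_image(40, 12)
  idt <- similarity_transform()
  expect_equal(correlation_score(img, img, idt), 1, tolerance = 1e-12)
  expect_equal(correlation_score(img, -img, idt), -1, tolerance = 1e-12)
  other <- random_test_image(40, 13)
  expect_equal(correlation_score(img, other, idt),
               cor(as.vector(img), as.vector(other)), tolerance = 1e-10)
  # affine intensity rescaling of either image leaves the score unchanged
  expect_equal(correlation_score(2 * img + 3, other, idt),
               correlation_score(img, other, idt), tolerance = 1e-10)
  # a transform throwing the moving image far away is rejected
  gone <- similarity_transform(tx = 500)
  expect_identical(correlation_score(img, other, gone), -Inf)
})

test_that("the default search grid spans the documented 21,875 nodes", {
  g <- search_grid()
  expect_equal(length(g$tx) * length(g$ty) * length(g$rot) * length(g$scale),
               25 * 25 * 7 * 5)
  expect_error(search_grid(translation = c(60, 0)), "steps")
})

test_that("coarse search recovers an on-grid warp exactly", {
  lib <- default_lib
  tt <- similarity_transform(10, -15, 5, 1.9)
  pair <- simulate_image_pair(seed = 31, lib, transform = tt,
                              render_stacks = FALSE)
  pf <- preprocess_image(pair$reference, confocal_preprocess_params())
  pm <- preprocess_image(pair$miniscope, miniscope_preprocess_params())
  g <- search_grid(translation = c(20, 5), rotation = c(10, 5),
                   scale = c(1.8, 2.0, 0.05), coarse_stride = 3)
  co <- coarse_search(pf, pm, g)
  expect_equal(co$transform$tx, 10)
  expect_equal(co$transform$ty, -15)
  expect_equal(co$transform$rotation, 5)
  expect_equal(co$transform$scale, 1.9)
})

test_that("identical images select the identity from a grid containing it", {
  img <- preprocess_image(random_test_image(48, 14) + 1,
                          preprocess_params(1, 10, 7))
  g <- search_grid(translation = c(10, 5), rotation = c(5, 5),
                   scale = c(0.9, 1.1, 0.05), coarse_stride = 1)
  co <- coarse_search(img, img, g)
  expect_equal(co$transform$tx, 0)
  expect_equal(co$transform$ty, 0)
  expect_equal(co$transform$rotation, 0)
  expect_equal(co$transform$scale, 1)
  expect_equal(co$score, 1, tolerance = 1e-9)
})

test_that("refinement never lowers the score and recovers off-grid warps", {
  lib <- default_lib
  tt <- similarity_transform(12.3, -7.6, 3.7, 1.87)
  pair <- simulate_image_pair(seed = 32, lib, transform = tt,
                              render_stacks = FALSE)
  pf <- preprocess_image(pair$reference, confocal_preprocess_params())
  pm <- preprocess_image(pair$miniscope, miniscope_preprocess_params())
  t0 <- similarity_transform(10, -10, 5, 1.85)   # nearest coarse node
  s0 <- correlation_score(pf, pm, t0)
  re <- refine_transform(pf, pm, t0)
  expect_gte(re$score, s0)
  expect_lt(abs(re$transform$tx - 12.3), 0.5)
  expect_lt(abs(re$transform$ty + 7.6), 0.5)
  expect_lt(abs(re$transform$rotation - 3.7), 0.25)
  expect_lt(abs(re$transform$scale - 1.87), 0.005)
})

test_that("apply_transform obeys its sampling contracts", {
  img <- matrix(runif(100), 10, 10)
  idt <- similarity_transform()
  expect_identical(apply_transform(img, idt, "nearest"), img)
  # pure translation moves a single-pixel mask by whole columns
  m <- roi_mask(cbind(5, 4), "px")
  shifted <- apply_transform(m, similarity_transform(tx = 5), "nearest",
                             out_dim = c(10, 10), src_dim = c(10, 10))
  expect_equal(unname(shifted$coords), cbind(5, 9))
  expect_error(similarity_transform(scale = 0), "scale")
})

test_that("masks survive a round trip through a transform and its inverse", {
  blob <- roi_mask(as.matrix(expand.grid(20:26, 30:36)), "blob")
  t <- similarity_transform(6, -4, 8, 1.25)
  fwd <- apply_transform(blob, t, "nearest", out_dim = c(64, 64),
                         src_dim = c(64, 64))
  back <- apply_transform(fwd, invert_transform(t), "nearest",
                          out_dim = c(64, 64), src_dim = c(64, 64))
  a <- matrix(FALSE, 64, 64); a[blob$coords] <- TRUE
  b <- matrix(FALSE, 64, 64); b[back$coords] <- TRUE
  jaccard <- sum(a & b) / sum(a | b)
  expect_gt(jaccard, 0.95)
})

test_that("transform composition with its inverse is the identity", {
  t <- similarity_transform(11, -3, 12, 1.9)
  ti <- invert_transform(t)
  expect_equal(ti$scale * t$scale, 1, tolerance = 1e-12)
  expect_equal(ti$rotation, -t$rotation)
  tii <- invert_transform(ti)
  expect_equal(tii$tx, t$tx, tolerance = 1e-9)
  expect_equal(tii$ty, t$ty, tolerance = 1e-9)
})

test_that("transforms serialize losslessly with their convention tag", {
  t <- similarity_transform(10.5, -15.25, 5.1, 1.905)
  path <- tempfile(fileext = ".yaml")
  write_transform(t, path, score = 0.87)
  rt <- read_transform(path)
  expect_equal(rt$transform$tx, t$tx)
  expect_equal(rt$transform$scale, t$scale)
  expect_equal(rt$score, 0.87)
})
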