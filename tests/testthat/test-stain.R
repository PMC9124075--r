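test_that("optical density transform matches its closed form and inverts exactly", {
  expect_equal(rgb_to_od(array(255, c(1, 1, 3)))[1], 0)
  expect_equal(rgb_to_od(array(0, c(1, 1, 3)))[1], log10(256), tolerance = 1e-12)
  img <- seeded_image(6, 7, seed = 2) + 0
  expect_true(all(rgb_to_od(img) >= 0))
  expect_identical(od_to_rgb(rgb_to_od(img)), img)
  # strictly decreasing in intensity
  od_vals <- rgb_to_od(array(0:255, c(256, 1, 1)))
  expect_true(all(diff(as.vector(od_vals)) < 0))
})

test_that("stain estimation recovers the generator's matrix (cosine >= 0.99 per column)", {
  p <- synth_params(image_size = 64, n_classes = 2, seed = 3)
  g <- generate_patch(p, 2, seed = 11)
  sm <- estimate_stain_model(g$image, seed = 5)
  cosines <- colSums(sm$stain_matrix * p$stain_matrix)
  expect_true(all(cosines >= 0.99))
  expect_equal(colSums(sm$stain_matrix^2), c(1, 1), tolerance = 1e-9)
  expect_true(all(sm$stain_matrix >= 0))
  # hematoxylin-like column first (larger red-channel coefficient)
  expect_gt(sm$stain_matrix[1, 1], sm$stain_matrix[1, 2])
})

test_that("a pure single-stain image yields a negligible second concentration scale", {
  p <- synth_params(seed = 1)
  set.seed(99)
  conc <- matrix(runif(64 * 64, 0.2, 1.2), 64)
  img <- od_to_rgb(array(outer(as.vector(conc), p$stain_matrix[, 1]), c(64, 64, 3)))
  sm <- estimate_stain_model(img, seed = 5)
  expect_lte(sm$concentration_scale[2], 0.01 * sm$concentration_scale[1])
})

test_that("the fit is invariant to pixel order and fails clearly on near-blank input", {
  p <- synth_params(image_size = 48, n_classes = 2, seed = 6)
  img <- generate_patch(p, 1, seed = 2)$image
  set.seed(7)
  perm <- sample(48 * 48)
  img_perm <- array(apply(img, 3, function(ch) ch[perm]), dim(img))
  m1 <- estimate_stain_model(img, seed = 5)
  m2 <- estimate_stain_model(img_perm, seed = 5)
  expect_equal(m1$stain_matrix, m2$stain_matrix)
  expect_equal(m1$concentration_scale, m2$concentration_scale)
  blank <- array(254, c(32, 32, 3))
  expect_error(estimate_stain_model(blank), "foreground")
})

test_that("normalizing to the source's own model is an identity up to rounding", {
  p <- synth_params(image_size = 48, n_classes = 2, seed = 3)
  img <- generate_patch(p, 2, seed = 17)$image
  sm <- estimate_stain_model(img, seed = 5)
  out <- normalize_image(img, sm, sm)
  expect_equal(dim(out), dim(img))
  expect_lte(mean(abs(out - img)), 2)
  white <- array(255, c(8, 8, 3))
  expect_identical(normalize_image(white, sm, sm), white + 0)
  degenerate <- ns$new_stain_model(sm$stain_matrix, c(1, 0))
  expect_error(normalize_image(img, degenerate, sm), "degenerate")
})

test_that("stain transfer moves an image onto the target's stain basis", {
  w_alt <- cbind(c(0.45, 0.80, 0.40), c(0.10, 0.85, 0.52))
  w_alt <- sweep(w_alt, 2, sqrt(colSums(w_alt^2)), "/")
  p1 <- synth_params(image_size = 64, n_classes = 2, seed = 3)
  p2 <- synth_params(image_size = 64, n_classes = 2, stain_matrix = w_alt, seed = 3)
  img_src <- generate_patch(p1, 2, seed = 5)$image
  img_tgt <- generate_patch(p2, 2, seed = 6)$image
  m_src <- estimate_stain_model(img_src, seed = 1)
  m_tgt <- estimate_stain_model(img_tgt, seed = 1)
  moved <- normalize_image(img_src, m_src, m_tgt)
  m_moved <- estimate_stain_model(moved, seed = 1)
  cosines <- colSums(m_moved$stain_matrix * m_tgt$stain_matrix)
  expect_true(all(cosines >= 0.99))
})

test_that("normalization is idempotent and preserves concentration rank order", {
  p <- synth_params(image_size = 48, n_classes = 2, seed = 8)
  img <- generate_patch(p, 2, seed = 9)$image
  src <- estimate_stain_model(img, seed = 2)
  # target = another patch's estimated appearance (the intended use)
  tgt <- estimate_stain_model(generate_patch(p, 1, seed = 30)$image, seed = 2)
  once <- normalize_image(img, src, tgt)
  model_once <- estimate_stain_model(once, seed = 2)
  twice <- normalize_image(once, model_once, tgt)
  conc_of <- function(im, model) {
    V <- t(matrix(rgb_to_od(im), ncol = 3))
    ns$solve_concentrations(V, model$stain_matrix, 0)
  }
  c1 <- conc_of(once, tgt); c2 <- conc_of(twice, tgt)
  rel_change <- abs(rowMeans(c2) - rowMeans(c1)) / rowMeans(c1)
  expect_true(all(rel_change < 0.01))
  # structure preservation: rank ordering of total concentration
  c_before <- colSums(conc_of(img, src))
  c_after <- colSums(conc_of(once, tgt))
  expect_gte(cor(c_before, c_after, method = "spearman"), 0.999)
})

test_that("stain models serialize losslessly to JSON", {
  sm <- ns$new_stain_model(ns$default_stain_matrix(), c(1.23456789, 0.87654321))
  path <- withr::local_tempfile(fileext = ".json")
  write_stain_model(sm, path)
  sm2 <- read_stain_model(path)
  expect_equal(sm2$stain_matrix, sm$stain_matrix)
  expect_equal(sm2$concentration_scale, sm$concentration_scale)
})
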