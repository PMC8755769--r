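test_that("scene generation is deterministic and validated", {
  p <- scene_params(severity = 0.7, age_proxy = 55, gender_proxy = 1,
                    nuisance = FALSE, image_size = 64, seed = 42)
  img1 <- generate_image(p)
  img2 <- generate_image(p)
  expect_identical(img1, img2)
  expect_true(all(img1 >= 0 & img1 <= 1))
  expect_equal(dim(img1), c(64, 64))

  expect_error(scene_params(severity = 1.2), "severity")
  expect_error(scene_params(severity = 0.5, age_proxy = 10), "age_proxy")
  expect_error(scene_params(severity = 0.5, gender_proxy = 2), "gender_proxy")
  expect_error(scene_params(severity = 0.5, nuisance = NA), "nuisance")
  expect_error(scene_params(severity = 0.5, image_size = 8), "image_size")
})

test_that("lung opacity is strictly increasing in severity (all seeds on a grid)", {
  grid <- seq(0, 1, length.out = 10)
  for (seed in c(1, 7, 23)) {
    readouts <- vapply(grid, function(s) {
      severity_readout(generate_image(scene_params(severity = s, seed = seed)))
    }, numeric(1))
    expect_true(all(diff(readouts) > 0))
  }
  # endpoints
  lo <- generate_image(scene_params(severity = 0, seed = 3))
  hi <- generate_image(scene_params(severity = 1, seed = 3))
  expect_gt(severity_readout(hi), severity_readout(lo))
})

test_that("severity floor gives minimal lung intensity over the severity axis", {
  r0 <- severity_readout(generate_image(scene_params(severity = 0, seed = 5)))
  for (s in c(0.2, 0.5, 0.8, 1)) {
    expect_gt(severity_readout(generate_image(scene_params(severity = s, seed = 5))), r0)
  }
})

test_that("severity_readout handles degenerate images", {
  expect_equal(severity_readout(matrix(0, 64, 64)), 0)
  expect_equal(severity_readout(matrix(1, 64, 64)), 1)
})

test_that("appearance factors leave lung opacity nearly unchanged", {
  base <- generate_image(scene_params(severity = 0.6, age_proxy = 25, seed = 9))
  old <- generate_image(scene_params(severity = 0.6, age_proxy = 85, seed = 9))
  expect_lt(abs(severity_readout(base) - severity_readout(old)), 0.02)
  m <- generate_image(scene_params(severity = 0.6, gender_proxy = 1, seed = 9))
  f <- generate_image(scene_params(severity = 0.6, gender_proxy = 0, seed = 9))
  expect_lt(abs(severity_readout(m) - severity_readout(f)), 0.02)
  # but the factors do change the image outside the lung fields
  expect_gt(mean(abs(base - old)), 0.005)
  expect_gt(mean(abs(m - f)), 0.005)
})

test_that("nuisance marker fills the top-left block with bright intensities", {
  for (size in c(32L, 64L)) {
    img <- generate_image(scene_params(severity = 0.6, nuisance = TRUE,
                                       image_size = size, seed = 2))
    block <- img[3:max(3, size %/% 8), 3:max(3, size %/% 8)]
    expect_true(all(block > 0.9))
    clean <- generate_image(scene_params(severity = 0.6, nuisance = FALSE,
                                         image_size = size, seed = 2))
    expect_false(all(clean[3:max(3, size %/% 8), 3:max(3, size %/% 8)] > 0.9))
    expect_true(all(corner_mask(size)[3:max(3, size %/% 8), 3:max(3, size %/% 8)]))
  }
})

test_that("dataset generation respects balance, policy and reproducibility", {
  ds <- generate_dataset(100, class_balance = 0.5, seed = 31, image_size = 32)
  expect_equal(dim(ds$images)[3], 100)
  expect_equal(length(ds$labels), 100)
  expect_equal(nrow(ds$attributes), 100)
  expect_equal(sum(ds$labels == "abnormal"), 50)
  expect_identical(ds$labels == "abnormal", ds$attributes$severity >= 0.5)

  ds2 <- generate_dataset(100, class_balance = 0.5, seed = 31, image_size = 32)
  expect_identical(ds$images, ds2$images)

  all_ab <- generate_dataset(20, class_balance = 1, seed = 1, image_size = 32)
  expect_true(all(all_ab$labels == "abnormal"))

  expect_error(generate_dataset(1), "n must be >= 2")
})

test_that("abnormal_only nuisance policy stamps exactly the abnormal images", {
  ds <- generate_dataset(60, class_balance = 0.5, nuisance_policy = "abnormal_only",
                         seed = 13, image_size = 32)
  reg <- 3:max(3, 32 %/% 8)
  stamped <- apply(ds$images[reg, reg, , drop = FALSE], 3, function(b) all(b > 0.9))
  expect_identical(stamped, ds$labels == "abnormal")
  expect_identical(ds$attributes$nuisance, ds$labels == "abnormal")
})

test_that("age_severity_rho plants the requested association", {
  dsc <- generate_dataset(300, seed = 3, image_size = 32, age_severity_rho = 0.7)
  dsu <- generate_dataset(300, seed = 3, image_size = 32, age_severity_rho = 0)
  expect_gt(cor(dsc$attributes$severity, dsc$attributes$age_proxy), 0.5)
  expect_lt(abs(cor(dsu$attributes$severity, dsu$attributes$age_proxy)), 0.2)
})

test_that("PNG export quantizes to 8 bits and round-trips", {
  img <- generate_image(scene_params(severity = 0.4, seed = 6, image_size = 32))
  path <- tempfile(fileext = ".png")
  write_image_png(img, path)
  back <- read_image_png(path)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255)
})
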