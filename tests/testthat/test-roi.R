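test_that("side detection matches the generator on both sides", {
  for (side in c("left", "right")) {
    ph <- generate_phantom(phantom_spec(image_size = 64, side = side), seed = 2)
    expect_equal(detect_side(ph$record$pixels), side)
    # mirroring flips the answer
    mirrored <- ph$record$pixels[, 64:1]
    expect_equal(detect_side(mirrored), setdiff(c("left", "right"), side))
  }
  expect_error(detect_side(matrix(7, 10, 10)), "constant")
})

test_that("side detection is right on 50 random phantoms and shift-invariant", {
  withr::with_seed(17, {
    sides <- sample(c("left", "right"), 50, replace = TRUE)
    seeds <- sample.int(1e6, 50)
  })
  for (i in seq_along(sides)) {
    ph <- generate_phantom(phantom_spec(image_size = 64, side = sides[i],
                                        has_lesion = i %% 2 == 0),
                           seed = seeds[i])
    expect_equal(detect_side(ph$record$pixels), sides[i])
    if (i <= 5)   # intensity-monotone safety: adding a constant changes nothing
      expect_equal(detect_side(quantize8(ph$record$pixels / 2 + 40)), sides[i])
  }
})

test_that("artifact removal zeroes exactly the far side of the dark gap", {
  ph <- generate_phantom(phantom_spec(image_size = 128), seed = 3)
  out <- remove_artifacts(ph$record$pixels, "left")
  b <- ph$truth$artifact_bounds
  expect_true(all(out[(b[1] + 1):b[2], (b[3] + 1):b[4]] == 0))
  # breast-side pixels untouched
  expect_identical(out[ph$truth$breast_mask],
                   ph$record$pixels[ph$truth$breast_mask])

  none <- generate_phantom(phantom_spec(image_size = 128, artifact = FALSE),
                           seed = 3)
  expect_identical(remove_artifacts(none$record$pixels, "left"),
                   none$record$pixels)
  zero <- matrix(0L, 20, 20)
  expect_identical(remove_artifacts(zero, "left"), zero)
})

test_that("pectoral removal recovers the exact wedge on noise-free phantoms", {
  for (side in c("left", "right")) {
    ph <- generate_phantom(phantom_spec(image_size = 128, side = side,
                                        noise_sd = 0), seed = 1)
    cleaned <- remove_artifacts(ph$record$pixels, side)
    out <- remove_pectoral(cleaned, side)
    expect_identical(unname(cleaned != out), unname(ph$truth$pectoral_mask))
  }
})

test_that("pectoral removal is conservative on noisy tissue", {
  sp <- phantom_spec(image_size = 128, noise_sd = 5, pectoral_intensity = 240,
                     breast_intensity = 150)
  ph <- generate_phantom(sp, seed = 6)
  cleaned <- remove_artifacts(ph$record$pixels, "left")
  out <- remove_pectoral(cleaned, "left")
  expect_true(all(out[ph$truth$pectoral_mask] == 0))
  expect_gte(mean(out[ph$truth$breast_mask] ==
                    cleaned[ph$truth$breast_mask]), 0.95)

  # a vanishing wedge leaves the image essentially unchanged
  tiny <- generate_phantom(phantom_spec(image_size = 128, noise_sd = 0,
                                        pectoral_fraction = 0.02), seed = 1)
  cleaned <- remove_artifacts(tiny$record$pixels, "left")
  out <- remove_pectoral(cleaned, "left")
  expect_lt(mean(out != cleaned), 0.01)
})

test_that("the initial ROI is the tight nonzero bounding box", {
  m <- matrix(0L, 100, 100)
  m[11:60, 21:50] <- 120L
  roi <- initial_roi(m)
  expect_equal(unname(roi$bounds), c(10, 60, 20, 50))
  expect_equal(roi$R, 50)          # 60 - 10 = 50 beats 50 - 20 = 30
  one <- matrix(0L, 10, 10); one[4, 7] <- 9L
  roi1 <- initial_roi(one)
  expect_equal(unname(roi1$bounds), c(3, 4, 6, 7))
  expect_equal(roi1$R, 1)
  expect_error(initial_roi(matrix(0L, 5, 5)), "empty ROI")
})

test_that("IROI always contains the planted lesion center", {
  coh <- clean_cohort()
  abnormal <- which(coh$metadata$class != "normal")
  for (i in abnormal[1:10]) {
    px <- coh$records[[i]]$pixels
    side <- detect_side(px)
    cleaned <- remove_pectoral(remove_artifacts(px, side), side)
    b <- initial_roi(cleaned)$bounds
    ctr <- coh$truth[[i]]$lesion_center - 1
    expect_true(ctr[1] >= b[["row0"]] && ctr[1] < b[["row1"]] &&
                  ctr[2] >= b[["col0"]] && ctr[2] < b[["col1"]])
  }
})

test_that("ROI refinement zooms onto the bright block", {
  # identity chromosome keeps the IROI
  ph <- generate_phantom(phantom_spec(image_size = 128), seed = 4)
  side <- detect_side(ph$record$pixels)
  cleaned <- remove_pectoral(remove_artifacts(ph$record$pixels, side), side)
  iroi <- initial_roi(cleaned)
  expect_equal(refine_roi(cleaned, iroi, chromosome(1, 1, 0))$bounds,
               iroi$bounds)

  # a lone 20x20 bright block inside a 100x100 dim field is found exactly
  m <- matrix(5L, 100, 100)
  m[41:60, 41:60] <- 200L
  iroi <- initial_roi(m)
  expect_equal(unname(iroi$bounds), c(0, 100, 0, 100))
  ref <- refine_roi(m, iroi, chromosome(0.2, 0.2, 150))
  expect_equal(unname(ref$bounds), c(40, 60, 40, 60))
  expect_equal(ref$radius, 10)
  expect_equal(ref$R, 100)

  # CutVal above every pixel falls back to the IROI with a flag
  fb <- refine_roi(m, iroi, chromosome(0.2, 0.2, 250))
  expect_true(fb$fallback)
  expect_equal(fb$bounds, iroi$bounds)
})

test_that("refined bounds always stay inside the IROI and the image", {
  ph <- generate_phantom(phantom_spec(image_size = 128, has_lesion = TRUE),
                         seed = 9)
  px <- ph$record$pixels
  side <- detect_side(px)
  cleaned <- remove_pectoral(remove_artifacts(px, side), side)
  iroi <- initial_roi(cleaned)
  withr::with_seed(5, {
    for (k in 1:20) {
      ch <- chromosome(runif(1), runif(1), runif(1, 0, 255))
      b <- refine_roi(cleaned, iroi, ch)$bounds
      expect_true(b[["row0"]] >= iroi$bounds[["row0"]] &&
                    b[["row1"]] <= iroi$bounds[["row1"]] &&
                    b[["col0"]] >= iroi$bounds[["col0"]] &&
                    b[["col1"]] <= iroi$bounds[["col1"]])
      expect_true(b[["row1"]] <= nrow(px) && b[["col1"]] <= ncol(px))
    }
  })
})

test_that("the GA recovers a known target chromosome on a convex fitness", {
  target <- c(0.6, 0.3, 120)
  fit <- function(ch) -sqrt((ch$H - target[1])^2 + (ch$W - target[2])^2 +
                              ((ch$CutVal - target[3]) / 255)^2)
  out <- ga_optimize(fit, ga_config(seed = 4))
  expect_lte(abs(out$best$H - target[1]), 0.05)
  expect_lte(abs(out$best$W - target[2]), 0.05)
  expect_lte(abs(out$best$CutVal - target[3]) / 255, 0.05)
  # deterministic under a fixed seed
  expect_identical(out, ga_optimize(fit, ga_config(seed = 4)))
  # population of one, one generation: that sole chromosome is returned
  lone <- ga_optimize(fit, ga_config(population = 1, generations = 1,
                                     seed = 2))
  expect_s3_class(lone$best, "chromosome")
  expect_equal(lone$fitness, fit(lone$best))
})

test_that("chromosome genes are bounds-checked", {
  expect_error(chromosome(0, 0.5, 10), "H and W")
  expect_error(chromosome(0.5, 1.2, 10), "H and W")
  expect_error(chromosome(0.5, 0.5, 300), "CutVal")
})
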