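test_that("thickness maps rasterize regions and overlays additively", {
  # left-half rectangle of meat
  spec <- phantom_spec(c(8L, 8L), c("meat", "bone", "skin"),
                       regions = list(list(tissue = "meat", shape = "rectangle",
                                           x = 0, y = 0, width = 4, height = 8,
                                           thickness_cm = 0.5)),
                       seed = 1)
  maps <- make_thickness_maps(spec)
  expect_equal(maps$values[, 1:4, 1], matrix(0.5, 8, 4))
  expect_equal(maps$values[, 5:8, 1], matrix(0, 8, 4))
  expect_equal(sum(maps$values[, , 2:3]), 0)

  # three disjoint blocks plus a full skin overlay
  ov <- phantom_preset("skin_overlay", frame_shape = c(16L, 16L))
  mo <- make_thickness_maps(ov)
  skin <- mo$values[, , 3]
  expect_equal(sort(unique(as.vector(skin))), c(0.1, 0.3))
  expect_equal(min(skin), 0.1)  # overlay covers the whole frame

  empty <- phantom_spec(c(4L, 4L), "meat", seed = 1)
  expect_equal(sum(make_thickness_maps(empty)$values), 0)

  expect_error(phantom_spec(c(8L, 8L), "meat",
                            regions = list(list(tissue = "fat",
                                                shape = "rectangle", x = 0, y = 0,
                                                width = 2, height = 2,
                                                thickness_cm = 0.1)),
                            seed = 1),
               "unknown tissue")
})

test_that("the Gaussian beam has the right peak, width and symmetry", {
  A <- 1000
  b <- gaussian_beam(c(21, 21), A, center = c(10, 10), sigma = 4)
  expect_equal(b[11, 11], A)                      # peak at center
  expect_equal(b[11, 15], A * exp(-0.5))          # one sigma along x
  expect_equal(b[11, 14], b[11, 8])               # radial symmetry
  expect_equal(b[7, 11], b[15, 11])
})

test_that("rendering applies the forward model, noise, clipping, quantization", {
  m1 <- attenuation_matrix(matrix(2.0), 808, "gel")
  mk_spec <- function(amp, quantize = TRUE, sigma_beam = 1e6)
    phantom_spec(c(1L, 1L), "gel",
                 regions = list(list(tissue = "gel", shape = "rectangle",
                                     x = 0, y = 0, width = 1, height = 1,
                                     thickness_cm = 0.5)),
                 beam = list(amplitude = amp, center = c(0, 0),
                             sigma = sigma_beam),
                 noise = list(speckle_sigma = 0, read_sigma = 0),
                 bit_depth = 16L, seed = 1, quantize = quantize)
  # 1000 * exp(-1) = 367.879 quantized (half away from zero) to 368
  out <- render_stack(make_thickness_maps(mk_spec(1000)), m1, mk_spec(1000))
  expect_equal(out$object_images[[1]]$pixels[1, 1], 368)

  # zero thickness, no noise, no quantization: object equals reference
  spec0 <- phantom_spec(c(4L, 4L), "gel",
                        beam = list(amplitude = 1000, center = c(1.5, 1.5),
                                    sigma = 2),
                        noise = list(speckle_sigma = 0, read_sigma = 0),
                        bit_depth = 16L, seed = 1, quantize = FALSE)
  out0 <- render_stack(make_thickness_maps(spec0), m1, spec0)
  expect_identical(out0$object_images[[1]]$pixels,
                   out0$reference_images[[1]]$pixels)

  # beam amplitude above saturation: flat-topped plateau at the threshold
  spec_sat <- phantom_spec(c(9L, 9L), "gel",
                           beam = list(amplitude = 2 * (2^16 - 1),
                                       center = c(4, 4), sigma = 3),
                           noise = list(speckle_sigma = 0, read_sigma = 0),
                           bit_depth = 16L, seed = 1)
  ref <- render_stack(make_thickness_maps(spec_sat), m1,
                      spec_sat)$reference_images[[1]]
  expect_equal(max(ref$pixels), 2^16 - 1)
  expect_gt(sum(ref$pixels == 2^16 - 1), 1)  # a plateau, not one pixel
})

test_that("identical spec and seed give bit-identical phantoms", {
  m <- chicken_mat()
  s1 <- phantom_preset("side_by_side", frame_shape = c(24L, 24L), seed = 9)
  s2 <- phantom_preset("side_by_side", frame_shape = c(24L, 24L), seed = 9)
  o1 <- simulate_phantom(s1, m)
  o2 <- simulate_phantom(s2, m)
  expect_identical(lapply(o1$object_images, `[[`, "pixels"),
                   lapply(o2$object_images, `[[`, "pixels"))
  expect_identical(lapply(o1$reference_images, `[[`, "pixels"),
                   lapply(o2$reference_images, `[[`, "pixels"))
  o3 <- simulate_phantom(phantom_preset("side_by_side",
                                        frame_shape = c(24L, 24L), seed = 10), m)
  expect_false(identical(o1$object_images[[1]]$pixels,
                         o3$object_images[[1]]$pixels))
})

test_that("noise-free unquantized rendering closes the loop with transmittance", {
  m <- chicken_mat()
  out <- simulate_phantom(exact_phantom(shape = c(16L, 16L)), m)
  st <- transmittance_stack(out$object_images, out$reference_images)
  truth <- out$ground_truth
  for (i in seq_along(m$wavelengths_nm)) {
    expected <- exp(-Reduce(`+`, lapply(1:3, function(j)
      m$values[i, j] * truth$values[, , j])))
    got <- st$values[, , i]
    expect_equal(got[st$valid_mask], expected[st$valid_mask],
                 tolerance = 1e-12)
  }
})

test_that("speckle raises the variance of the recovered maps monotonically", {
  m <- chicken_mat()
  vars <- vapply(c(0.005, 0.02, 0.1), function(s) {
    spec <- phantom_preset("side_by_side", frame_shape = c(32L, 32L), seed = 4,
                           noise = list(speckle_sigma = s, read_sigma = 0))
    out <- simulate_phantom(spec, m)
    res <- decompose_phantom(out, m)
    err <- res$thickness_maps$raw_values - out$ground_truth$values
    stats::var(as.vector(err), na.rm = TRUE)
  }, 0)
  expect_true(all(diff(vars) > 0))
})

test_that("quantization error in recovered thickness respects the one-count bound", {
  # ramp phantom, no noise, quantized: the transmittance error at any pixel
  # is at most half a count over the dimmest valid reference, which bounds
  # the thickness error through the inverse matrix norm
  m <- chicken_mat()
  spec <- phantom_preset("side_by_side", frame_shape = c(32L, 32L), seed = 2,
                         noise = list(speckle_sigma = 0, read_sigma = 0),
                         quantize = TRUE)
  out <- simulate_phantom(spec, m)
  res <- decompose_phantom(out, m)
  err <- abs(res$thickness_maps$raw_values - out$ground_truth$values)
  valid <- res$thickness_maps$valid_mask
  ref_min <- min(vapply(out$reference_images,
                        function(r) min(r$pixels[valid]), 0))
  obj_min <- min(vapply(out$object_images,
                        function(o) min(o$pixels[valid]), 0))
  # |delta lnT| <= 0.5/I + 0.5/I0 at the dimmest valid pixels
  dlnT <- 0.5 / obj_min + 0.5 / ref_min
  bound <- norm(solve(m$values), "I") * dlnT
  expect_lt(max(err[!is.na(err)]), bound)
})
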