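test_that("zero-variance free diffusion stays at the origin", {
  acq <- acquisition_params(localization_noise_sigma = 0)
  tr <- simulate_trajectory("free", n_frames = 10, D = 0, acq = acq,
                            origin = c(1.5, -2), seed = 7)
  expect_true(all(tr$positions[, "x"] == 1.5))
  expect_true(all(tr$positions[, "y"] == -2))
})

test_that("confined paths never leave the confinement disc", {
  acq <- acquisition_params(localization_noise_sigma = 0)
  for (seed in 1:20) {
    tr <- simulate_trajectory("confined", n_frames = 20, D = 0.5,
                              confinement_radius = 0.1, acq = acq,
                              origin = c(2, 3), seed = seed)
    d <- sqrt((tr$positions[, "x"] - 2)^2 + (tr$positions[, "y"] - 3)^2)
    expect_true(all(d <= 0.1 + 1e-12))
    # geometry: all points in a disc of radius R have MEC radius <= R
    expect_lte(as.numeric(radius_of_confinement(tr)), 0.1 + 1e-12)
  }
})

test_that("the origin translates a free path rigidly", {
  acq <- acquisition_params(localization_noise_sigma = 0)
  for (nf in c(2, 3, 12)) {
    at0 <- simulate_trajectory("free", n_frames = nf, D = 0.8, acq = acq,
                               origin = c(0, 0), seed = 5)
    off <- simulate_trajectory("free", n_frames = nf, D = 0.8, acq = acq,
                               origin = c(3.2, -1.7), seed = 5)
    expect_equal(sweep(off$positions, 2, c(3.2, -1.7)), at0$positions,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("generators are pure functions of (spec, seed)", {
  a <- simulate_trajectory("free", n_frames = 15, D = 0.5, seed = 42)
  b <- simulate_trajectory("free", n_frames = 15, D = 0.5, seed = 42)
  expect_identical(a$positions, b$positions)
  c <- simulate_trajectory("free", n_frames = 15, D = 0.5, seed = 43)
  expect_false(identical(a$positions, c$positions))

  spec <- demo_mask_spec()
  pops <- list(population_spec("free", D = 0.3, count = 5))
  f1 <- simulate_field(spec, pops, seed = 9)
  f2 <- simulate_field(spec, pops, seed = 9)
  expect_identical(tracks_to_df(f1$tracks), tracks_to_df(f2$tracks))
  expect_identical(f1$mask$grid, f2$mask$grid)

  # the generator restores the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulate_trajectory("free", 5, 0.5, seed = 1))
  expect_identical(runif(1), before)
})

test_that("unknown mode and bad confinement radius are rejected", {
  expect_error(simulate_trajectory("hopping", 10, seed = 1),
               "unknown mode")
  expect_error(simulate_trajectory("confined", 10, D = 0.1,
                                   confinement_radius = -1, seed = 1),
               "confinement_radius")
  expect_error(population_spec("confined", D = 0.1, count = 1),
               "confinement_radius")
})

test_that("sample MSD of free tracks matches 4*D*tau", {
  acq <- acquisition_params(localization_noise_sigma = 0)
  D_true <- 0.5
  lag1 <- unlist(lapply(1:1000, function(s) {
    tr <- simulate_trajectory("free", n_frames = 10, D = D_true,
                              acq = acq, seed = s)
    d <- diff(tr$positions)
    rowSums(d * d)
  }))
  expect_lt(abs(mean(lag1) - 4 * D_true * acq$dt),
            3 * stats::sd(lag1) / sqrt(length(lag1)))
})

test_that("simulate_field honours counts, labels and placement", {
  spec <- demo_mask_spec()
  acq <- acquisition_params(localization_noise_sigma = 0)
  pops <- list(
    population_spec("immobile", count = 10, placement = "inside_mask"),
    population_spec("free", D = 0.5, count = 5, placement = "uniform"))
  field <- simulate_field(spec, pops, acq, seed = 3)
  expect_length(field$tracks, 15L)
  labels <- vapply(field$tracks, attr, numeric(1), "population")
  expect_identical(as.integer(labels), rep(1:2, c(10L, 5L)))

  # inside-placed tracks start at a mask-true pixel centre
  for (tr in field$tracks[labels == 1]) {
    p0 <- tr$positions[1, ]
    px <- floor(p0 / acq$pixel_size)    # (x, y) -> (col, row)
    expect_true(field$mask$grid[px[2] + 1, px[1] + 1])
    ctr <- (px + 0.5) * acq$pixel_size
    expect_equal(unname(p0), unname(ctr), tolerance = 1e-12)
  }

  # zero-count population contributes nothing
  f0 <- simulate_field(spec, list(population_spec("free", count = 0)),
                       acq, seed = 1)
  expect_length(f0$tracks, 0L)
  expect_s3_class(f0$mask, "adhesion_mask")

  empty <- mask_spec(c(8, 8), list())
  expect_error(
    simulate_field(empty,
                   list(population_spec("free", D = 1, count = 1,
                                        placement = "inside_mask")),
                   acq, seed = 1),
    "empty mask")
})

test_that("noise-free renders put peak and background where specified", {
  spec <- demo_mask_spec()
  imgs <- render_two_channel_image(spec,
                                   render_spec("fill", peak_intensity = 200,
                                               background = 10),
                                   render_spec("ring", ring_width = 2,
                                               peak_intensity = 180,
                                               background = 5),
                                   seed = 1)
  # ellipse centres: fill -> peak, ring -> background
  expect_identical(imgs$A[15, 15], 200L)
  expect_identical(imgs$B[15, 15], 5L)
  # far corner is background in both
  expect_identical(imgs$A[48, 1], 10L)
  expect_identical(imgs$B[48, 1], 5L)
  # ring peaks near the boundary: along the row through a centre there are
  # peak pixels between the centre and the outside
  row_b <- imgs$B[15, ]
  expect_true(any(row_b == 180L))
  expect_true(all(imgs$A >= 0 & imgs$A <= 255))
  rs <- render_spec("fill", noise_sigma = 50)
  noisy <- render_two_channel_image(spec, rs, rs, seed = 2)
  expect_true(all(noisy$A >= 0L & noisy$A <= 255L))
  expect_true(is.integer(noisy$A))
})

test_that("peptide tables reproduce programmed enrichment structure", {
  prot <- data.frame(protein_id = sprintf("P%02d", 1:30),
                     mw_kda = seq(15, 102, by = 3))
  tabs <- generate_peptide_table(prot, c(P05 = 0), depth = 5e3, seed = 11)
  expect_identical(tabs$bait$count[5], 0L)
  expect_true(all(tabs$mock$count >= 0))
  expect_true(all(tabs$bait$count == as.integer(tabs$bait$count)))

  # null case: fold 1 everywhere, count ratios centre on 1 at large depth
  tabs1 <- generate_peptide_table(prot, depth = 1e5, seed = 2)
  ratios <- tabs1$bait$count / tabs1$mock$count
  expect_lt(abs(mean(ratios) - 1), 0.05)

  # determinism
  again <- generate_peptide_table(prot, c(P05 = 0), depth = 5e3, seed = 11)
  expect_identical(tabs, again)
  expect_error(generate_peptide_table(prot[0, ], depth = 10, seed = 1),
               "non-empty")
})
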