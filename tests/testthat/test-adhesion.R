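# A 10x10 mask (pixel_size 1 um for round areas) with mask-true block
# rows 0..3, cols 0..9 in 0-based pixel coords (40% coverage).
block_mask <- function(pixel_size = 1) {
  g <- matrix(FALSE, 10, 10)
  g[1:4, ] <- TRUE
  adhesion_mask(g, pixel_size)
}

test_that("track region assignment partitions inside/outside/discarded", {
  mask <- block_mask()
  inside <- make_traj(rbind(c(0.5, 0.5), c(3.5, 2.5)))
  outside <- make_traj(rbind(c(0.5, 6.5), c(8.2, 9.1)))
  mixed <- make_traj(rbind(c(0.5, 0.5), c(0.5, 7.5)))
  expect_identical(assign_track_region(inside, mask), "inside")
  expect_identical(assign_track_region(outside, mask), "outside")
  expect_identical(assign_track_region(mixed, mask), "discarded")
  oob <- make_traj(rbind(c(0.5, 0.5), c(11, 0.5)))
  expect_error(assign_track_region(oob, mask), "outside image bounds")

  # partition property over random tracks
  set.seed(8)
  labs <- vapply(1:100, function(i) {
    tr <- make_traj(matrix(runif(10, 0.01, 9.99), ncol = 2))
    assign_track_region(tr, mask)
  }, character(1))
  expect_true(all(labs %in% c("inside", "outside", "discarded")))
  expect_identical(sum(table(labs)), 100L)
})

test_that("points on pixel edges follow the half-open convention", {
  mask <- block_mask()
  # y = 4 is the first row OUTSIDE the block (pixel row floor(4) = 4)
  edge <- make_traj(rbind(c(0.5, 4), c(0.5, 4.5)))
  expect_identical(assign_track_region(edge, mask), "outside")
  # y just below 4 is inside
  edge_in <- make_traj(rbind(c(0.5, 3.999), c(0.5, 3.5)))
  expect_identical(assign_track_region(edge_in, mask), "inside")
})

test_that("adhesion-rich ROI rule is strict at 25% coverage", {
  g <- matrix(FALSE, 10, 10)
  g[1:3, ] <- TRUE                      # 30%
  expect_true(qualify_adhesion_rich_roi(adhesion_mask(g, 1),
                                        roi(0, 0, 10, 10)))
  g25 <- matrix(FALSE, 10, 10)
  g25[1:5, 1:5] <- TRUE                 # exactly 25%
  expect_false(qualify_adhesion_rich_roi(adhesion_mask(g25, 1),
                                         roi(0, 0, 10, 10)))
  expect_false(qualify_adhesion_rich_roi(adhesion_mask(matrix(FALSE, 5, 5),
                                                       1),
                                         roi(0, 0, 5, 5)))
  expect_error(roi(2, 2, 2, 5), "degenerate")
})

test_that("enrichment ratio reproduces hand arithmetic", {
  # 10x10 grid at 1 um/px; 10 mask pixels -> 10 um2 inside, 90 um2 outside
  g <- matrix(FALSE, 10, 10)
  g[1, ] <- TRUE
  mask <- adhesion_mask(g, 1)
  at <- function(x, y) make_traj(rbind(c(x, y), c(x, y)))
  tracks <- c(lapply(seq(0.5, 4.5), function(x) at(x, 0.5)),      # 5 inside
              lapply(seq(0.5, 8.5), function(x) at(x, 5.5)))      # 9 outside
  regions <- vapply(tracks, assign_track_region, character(1), mask = mask)
  er <- enrichment_ratio(tracks, regions, mask, roi(0, 0, 10, 10),
                         check_roi = FALSE)
  expect_equal(er$density_inside, 0.5)
  expect_equal(er$density_outside, 0.1)
  expect_equal(er$ratio, 5.0)
  expect_identical(er$n_inside, 5L)
  expect_identical(er$n_outside, 9L)

  # uniform null: equal densities give ratio 1
  g2 <- matrix(FALSE, 10, 10); g2[1:5, ] <- TRUE
  mask2 <- adhesion_mask(g2, 1)
  t2 <- c(lapply(seq(0.5, 9.5), function(x) at(x, 2.5)),
          lapply(seq(0.5, 9.5), function(x) at(x, 7.5)))
  r2 <- vapply(t2, assign_track_region, character(1), mask = mask2)
  expect_equal(enrichment_ratio(t2, r2, mask2, roi(0, 0, 10, 10))$ratio, 1)

  # no outside tracks -> explicit error, not infinity
  only_in <- tracks[1:5]
  expect_error(enrichment_ratio(only_in, regions[1:5], mask,
                                roi(0, 0, 10, 10), check_roi = FALSE),
               "undefined")
  # unqualified ROI rejected when checking
  expect_error(enrichment_ratio(tracks, regions, mask, roi(0, 0, 10, 10)),
               "adhesion-rich")
})

test_that("discarded tracks and out-of-ROI tracks are not counted", {
  g <- matrix(FALSE, 10, 10)
  g[1:4, ] <- TRUE
  mask <- adhesion_mask(g, 1)
  at <- function(x, y) make_traj(rbind(c(x, y), c(x, y)))
  tracks <- list(at(0.5, 0.5), at(0.5, 8.5), at(8.5, 8.5))
  regions <- c("inside", "outside", "outside")
  # ROI covering only the left half: the track at x=8.5 is outside the ROI
  er <- enrichment_ratio(tracks, regions, mask, roi(0, 0, 10, 5))
  expect_identical(er$n_inside, 1L)
  expect_identical(er$n_outside, 1L)
  er2 <- enrichment_ratio(tracks, c("discarded", "outside", "outside"),
                          mask, roi(0, 0, 10, 5))
  expect_identical(er2$n_inside, 0L)
})

test_that("mobility fractions count classes and sum to one", {
  f <- mobility_fractions(c("immobile", "immobile", "confined", "free"))
  expect_equal(unname(f), c(0.5, 0.25, 0.25))
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_equal(unname(mobility_fractions(rep("immobile", 3))), c(1, 0, 0))
  expect_error(mobility_fractions(character()), "no tracks")
  expect_error(mobility_fractions(c("immobile", "walking")), "unknown")
})

test_that("programmed receptor-like populations reproduce the expected orderings", {
  # receptor-I-like: immobile-rich and denser inside adhesions
  spec <- demo_mask_spec()
  acq <- acquisition_params()
  field <- simulate_field(spec, list(
    population_spec("immobile", count = 120, placement = "inside_mask",
                    frames_min = 5, frames_max = 15),
    population_spec("free", D = 1.0, count = 60, placement = "outside_mask",
                    frames_min = 5, frames_max = 15),
    population_spec("immobile", count = 20, placement = "outside_mask",
                    frames_min = 5, frames_max = 15)), acq, seed = 21)
  fit <- spt_fit(field$tracks, mask = field$mask)
  tab <- fit$table
  er <- enrichment_ratio(fit$tracks, as.character(tab$region), field$mask,
                         roi(0, 0, 24, 24), check_roi = FALSE)
  expect_gt(er$ratio, 1)
  fi <- mobility_fractions(tab$mobility[tab$region == "inside"])
  fo <- mobility_fractions(tab$mobility[tab$region == "outside"])
  expect_gt(fi["f_immobile"], fo["f_immobile"])

  # receptor-II-like: placed outside adhesions -> depleted inside
  field2 <- simulate_field(spec, list(
    population_spec("immobile", count = 150, placement = "outside_mask",
                    frames_min = 5, frames_max = 15)), acq, seed = 22)
  fit2 <- spt_fit(field2$tracks, mask = field2$mask)
  er2 <- tryCatch(
    enrichment_ratio(fit2$tracks, as.character(fit2$table$region),
                     field2$mask, roi(0, 0, 48, 48), check_roi = FALSE),
    error = function(e) NULL)
  if (!is.null(er2)) expect_lt(er2$ratio, 1)
})
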