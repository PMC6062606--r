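test_that("ILV size gates follow the 20-40 / 40-60 nm convention", {
  cfg <- morphometry_config()
  expect_equal(as.character(classify_ilv_size(50, cfg)), "escrt")
  expect_equal(as.character(classify_ilv_size(30, cfg)), "small")
  expect_equal(as.character(classify_ilv_size(40, cfg)), "escrt")
  expect_equal(as.character(classify_ilv_size(39.999, cfg)), "small")
  expect_equal(as.character(classify_ilv_size(60, cfg)), "escrt")
  expect_equal(as.character(classify_ilv_size(c(10, 65))),
               c("other", "other"))
  expect_error(classify_ilv_size(0), "positive")
  # partition: every positive diameter maps to exactly one class
  d <- seq(0.5, 120, by = 0.5)
  cls <- classify_ilv_size(d, cfg)
  expect_false(anyNA(cls))
})

test_that("section statistics summarize per-section ESCRT-ILV counts", {
  secs <- data.frame(section_id = 1:4, apparent_diameter_nm = 200)
  empty <- as_section_records(secs, data.frame(section_id = integer(),
                                               diameter_nm = numeric()))
  st <- section_statistics(empty)
  expect_equal(st$mean_escrt_per_section, 0)
  expect_equal(st$fraction_le1_escrt, 1.0)

  two_each <- as_section_records(
    secs, data.frame(section_id = rep(1:4, each = 2), diameter_nm = 50))
  st2 <- section_statistics(two_each)
  expect_equal(st2$mean_escrt_per_section, 2.0)
  expect_equal(st2$fraction_le1_escrt, 0)

  # small ILVs are tallied separately and do not enter the ESCRT mean
  mixed <- as_section_records(
    data.frame(section_id = 1:2, apparent_diameter_nm = 200),
    data.frame(section_id = c(1, 1, 2), diameter_nm = c(50, 30, 45)))
  st3 <- section_statistics(mixed)
  expect_equal(st3$mean_escrt_per_section, 1.0)
  expect_equal(unname(st3$counts_by_class["small"]), 1L)
  expect_error(section_statistics(as_section_records(secs[0, ],
    data.frame(section_id = integer(), diameter_nm = numeric()))),
    "undefined")
})

test_that("simulated default sections give about half an ILV per section", {
  recs <- simulate_sections(endosome_population(),
                            section_config(n_sections = 30000, seed = 9))
  st <- section_statistics(recs)
  expect_gt(st$mean_escrt_per_section, 0.30)
  expect_lt(st$mean_escrt_per_section, 0.55)
  expect_gt(st$fraction_le1_escrt, 0.8)
})

test_that("bud contours round-trip through classification", {
  om <- classify_bud(simulate_bud_contour("omega", width_nm = 50,
                                          neck_width_nm = 20,
                                          neck_length_nm = 15))
  expect_equal(om$category, "omega")
  expect_equal(om$neck_width_nm, 20, tolerance = 1 / 20)
  expect_equal(om$neck_length_nm, 15, tolerance = 2 / 15)

  pit <- classify_bud(simulate_bud_contour("pit", width_nm = 60,
                                           depth_nm = 10))
  expect_equal(pit$category, "pit")
  expect_equal(pit$depth_nm, 10, tolerance = 0.1)

  u <- classify_bud(simulate_bud_contour("U", width_nm = 50, depth_nm = 45,
                                         noise_nm = 2, seed = 1))
  expect_equal(u$category, "U")
  expect_equal(u$depth_nm, 45, tolerance = 5 / 45)
})

test_that("noiseless contours classify into their generating category across geometries", {
  for (w in c(40, 60, 80)) for (d in c(5, 10, 15))
    expect_equal(classify_bud(simulate_bud_contour("pit", w, d))$category,
                 "pit", info = sprintf("pit w=%g d=%g", w, d))
  for (w in c(40, 50, 60)) for (d in c(30, 45, 55))
    if (d >= w / 2)
      expect_equal(classify_bud(simulate_bud_contour("U", w, d))$category,
                   "U", info = sprintf("U w=%g d=%g", w, d))
  for (w in c(40, 50, 60)) for (nk in c(10, 18, 25)) for (ln in c(8, 15, 25))
    expect_equal(classify_bud(simulate_bud_contour("omega", w,
                                                   neck_width_nm = nk,
                                                   neck_length_nm = ln))$category,
                 "omega", info = sprintf("omega w=%g nk=%g ln=%g", w, nk, ln))
})

test_that("a U-shaped bud as deep as an ILV diameter stays unconstricted", {
  u <- classify_bud(simulate_bud_contour("U", width_nm = 50, depth_nm = 50))
  expect_equal(u$category, "U")
  expect_equal(u$depth_nm, 50, tolerance = 0.05)
})

test_that("bud classification is invariant under rigid motions and reversal", {
  bc <- simulate_bud_contour("omega", width_nm = 50, neck_width_nm = 20,
                             neck_length_nm = 15, noise_nm = 1, seed = 3)
  ref <- classify_bud(bc)
  th <- 37 * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- unclass(bc) %*% rot + matrix(c(123, -45), nrow(bc), 2, byrow = TRUE)
  for (cand in list(moved, moved[nrow(moved):1, ])) {
    got <- classify_bud(cand)
    expect_equal(got$category, ref$category)
    expect_equal(got$neck_width_nm, ref$neck_width_nm, tolerance = 0.05)
    expect_equal(got$depth_nm, ref$depth_nm, tolerance = 0.05)
  }
})

test_that("degenerate contours are reported as unclassifiable", {
  set.seed(4)
  blob <- cbind(rnorm(30, 0, 20), rnorm(30, 0, 20))
  res <- classify_bud(blob)
  expect_true(is.na(res$category))
  expect_match(res$reason, "membrane")
  expect_error(classify_bud(cbind(1:4, 1:4)), "8 vertices")
})

test_that("inconsistent bud geometries are rejected", {
  expect_error(simulate_bud_contour("omega", width_nm = 30,
                                    neck_width_nm = 40, neck_length_nm = 10),
               "neck_width < width")
  expect_error(simulate_bud_contour("pit", width_nm = 40, depth_nm = 30),
               "depth <= width / 2")
  expect_error(simulate_bud_contour("U", width_nm = 60, depth_nm = 20),
               "depth >= width / 2")
})

test_that("gold proximity uses an inclusive 40-nm membrane distance", {
  bc <- simulate_bud_contour("U", width_nm = 50, depth_nm = 40)
  on_contour <- unclass(bc)[10, ]
  expect_true(gold_near_bud(on_contour, bc))
  expect_false(gold_near_bud(c(0, -100), bc))
  # exactly 40 nm above the flat flank (flank y = 0 away from the bud)
  flank_x <- min(unclass(bc)[, 1]) + 2
  expect_true(gold_near_bud(c(flank_x, -40), bc))
  expect_false(gold_near_bud(c(flank_x, -40.001), bc))
  # vectorized over particles
  flags <- gold_near_bud(rbind(on_contour, c(0, -100)), bc)
  expect_equal(flags, c(TRUE, FALSE))
})

test_that("expected ILVs per section match the closed form and Monte Carlo", {
  pop <- endosome_population(diameter_sd_nm = 0, diameter_mean_nm = 251)
  expect_equal(expected_ilvs_per_section(1, pop), 150 / 401, tolerance = 1e-12)
  expect_equal(expected_ilvs_per_section(0, pop), 0)
  mc <- expected_ilvs_per_section(1, pop,
                                  section_config(n_sections = 100000,
                                                 seed = 11),
                                  method = "montecarlo")
  se <- sqrt(150 / 401 / 1e5)
  expect_lt(abs(mc - 150 / 401), 3 * se)
  # strictly increasing in h, saturating at the wave rate
  h <- vapply(c(50, 150, 500, 1e7), function(th)
    expected_ilvs_per_section(1, pop, section_config(thickness_nm = th)),
    numeric(1))
  expect_true(all(diff(h) > 0))
  expect_equal(h[4], 1, tolerance = 1e-3)
  # analytic form refuses a variable-diameter population
  expect_error(expected_ilvs_per_section(1, endosome_population()),
               "fixed diameter")
})
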