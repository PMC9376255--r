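test_that("Poiseuille resistance matches hand-computed values and scalings", {
  # r = 1 cm tube (area pi cm^2), 10 cm long, mu = 0.04 poise:
  # 8 * mu * L / (pi * r^4) = 1.0186 dyn.s/cm^5 = 7.640e-4 mmHg.s/mL
  expect_equal(poiseuille_resistance(pi, 10, 0.04),
               8 * 0.04 * 10 / pi / 1333.22, tolerance = 1e-12)
  expect_equal(poiseuille_resistance(pi, 10, 0.04), 7.64e-4, tolerance = 1e-3)

  # zero-length segment has zero resistance
  expect_identical(poiseuille_resistance(c(1, 2, 3), 0), 0)

  # R is proportional to 1/mean(area)^2
  r1 <- poiseuille_resistance(c(2, 2.5, 3), 5)
  r2 <- poiseuille_resistance(2 * c(2, 2.5, 3), 5)
  expect_equal(r1 / r2, 4, tolerance = 1e-12)

  # longer segments are strictly more resistive
  lens <- seq(1, 20, by = 2.5)
  rs <- vapply(lens, function(L) poiseuille_resistance(c(3, 3.2), L), numeric(1))
  expect_true(all(diff(rs) > 0))

  expect_error(poiseuille_resistance(c(1, -1), 5), "positive")
  expect_error(poiseuille_resistance(2, 5, viscosity = 0), "viscosity")
})

test_that("series split conserves the total resistance in three equal parts", {
  expect_equal(split_into_series(3), c(1, 1, 1))
  expect_equal(split_into_series(0), c(0, 0, 0))
  for (r in c(1e-6, 0.37, 12, 4041.5)) {
    expect_equal(sum(split_into_series(r)), r, tolerance = 1e-12)
  }
  expect_error(split_into_series(-1), "non-negative")
})

test_that("the shipped geometry builds a valid six-outlet tree", {
  net <- build_network(hemopulse_geometry())
  expect_s3_class(net, "cv_network")
  expect_equal(nrow(net$terminals), 6)
  expect_gte(nrow(net$segments), 8)
  expect_setequal(net$terminals$name,
                  c("right_subclavian", "right_carotid", "left_carotid",
                    "left_subclavian", "coronaries", "descending_aorta"))
  # every segment carries three series sub-resistors summing to its total
  for (i in seq_len(nrow(net$segments))) {
    sub <- net$segments$sub_resistances[[i]]
    expect_length(sub, 3)
    expect_equal(sum(sub), net$segments$resistance[i], tolerance = 1e-12)
  }
  # device insertion between the two ascending-aorta elements
  expect_equal(net$device_node,
               unname(net$segments$to_node[net$segments$name == "asc_aorta_1"]))
  # summary table covers everything
  expect_equal(nrow(network_summary(net)), nrow(net$segments) + 6)
})

test_that("malformed geometry descriptions are rejected with named errors", {
  geom <- read_geometry(hemopulse_geometry())
  drop_coro <- Filter(function(r) !identical(r$outlet, "coronaries"), geom)
  expect_error(build_network(drop_coro), "coronaries")

  unknown_field <- geom
  unknown_field[[1]]$wall_thickness <- 1
  expect_error(build_network(unknown_field), "wall_thickness")

  cyclic <- geom
  cyclic[[1]]$parent <- geom[[2]]$name
  expect_error(build_network(cyclic), "cyclic|unknown parent")
})
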