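test_that("zone classification partitions tidal volumes with inclusive green bounds", {
  z <- classify_zone(c(6, 8, 7, 5.99, 8.01, 5, 4.99, 9.6, 9.61, 11.2, 11.3, 0))
  expect_equal(as.character(z$zone),
               c("green", "green", "green", "yellow", "yellow", "yellow",
                 "orange", "yellow", "orange", "orange", "red", "red"))
  expect_equal(as.character(z$direction[1:3]), rep("in-range", 3))
  expect_equal(as.character(z$direction[4]), "under")
  expect_equal(as.character(z$direction[5]), "over")
  # every non-negative value maps to exactly one zone
  vt <- seq(0, 20, by = 0.01)
  expect_false(anyNA(classify_zone(vt)$zone))
  expect_error(classify_zone(-1), ">= 0")
})

test_that("R-E grid reproduces per-cell predictions and is monotone in E", {
  g <- build_re_grid(ref_settings, weight = 65, resolution = 50)
  expect_equal(dim(g$vt_matrix), c(50, 50))
  expect_true(all(g$vt_matrix > 0))
  # cells non-increasing along increasing E at fixed R
  expect_true(all(diff(t(g$vt_matrix)) <= 1e-12))
  # a cell placed on the index patient's mechanics matches the scalar path
  g2 <- build_re_grid(ref_settings, weight = 65, e_range = c(20, 21),
                      r_range = c(10, 11), resolution = 2)
  expect_equal(g2$vt_matrix[1, 1],
               1000 * scm_vt_closed_form(ref_cohort$P1, ref_settings) / 65,
               tolerance = 1e-10)
})

test_that("green safe area shrinks as body weight increases", {
  greens <- vapply(c(50, 75, 100), function(w) {
    g <- build_re_grid(ref_settings, weight = w, resolution = 60)
    sum(classify_zone(as.numeric(g$vt_matrix))$zone == "green")
  }, numeric(1))
  expect_true(all(diff(greens) <= 0))
  expect_lt(greens[3], greens[1])
})

test_that("candidate screening against the reference cohort selects only Patient C", {
  m <- screen_candidates(ref_cohort$P1, ref_settings, ref_candidates)
  tab <- m$candidates
  expect_equal(tab$id[tab$eligible], "C")
  expect_equal(tab$rank[tab$id == "C"], 1L)
  expect_true(all(is.na(tab$rank[tab$id != "C"])))
  # Patient A over-ventilates at 50 kg; B, D, E under-ventilate
  expect_equal(tab$direction[tab$id == "A"], "over")
  expect_true(all(tab$direction[tab$id %in% c("B", "D", "E")] == "under"))
  expect_false(tab$eligible[tab$id == "E"])
})

test_that("screening is invariant to candidate order and handles edge cases", {
  m1 <- screen_candidates(ref_cohort$P1, ref_settings, ref_candidates)
  perm <- ref_candidates[c(4, 1, 5, 3, 2)]
  m2 <- screen_candidates(ref_cohort$P1, ref_settings, perm)
  t1 <- m1$candidates[order(m1$candidates$id), ]
  t2 <- m2$candidates[order(m2$candidates$id), ]
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(t1, t2)
  # empty candidate list gives an empty report
  m0 <- screen_candidates(ref_cohort$P1, ref_settings, list())
  expect_equal(nrow(m0$candidates), 0)
  # an index patient outside the band is flagged
  expect_warning(
    screen_candidates(ref_cohort$E, ref_settings, ref_candidates["A"]),
    "outside the safe band")
})

test_that("series-resistor correction lowers an excessive VT into the band", {
  # Patient A over-ventilates at 50 kg; minimal added resistance caps VT at 8
  adj <- resistor_adjustment(ref_cohort$A, ref_settings, target = c(6, 8))
  expect_equal(adj$status, "adjusted")
  expect_gt(adj$delta_R, 0)
  expect_lte(adj$vt_after, 8 + 1e-9)
  expect_gte(adj$vt_after, 6)
  # minimality: two precision steps less resistance would overshoot the band
  less <- patient_mechanics("A-", ref_cohort$A$E,
                            ref_cohort$A$R + adj$delta_R - 0.02, 50)
  expect_gt(1000 * scm_vt_closed_form(less, ref_settings) / 50, 8)
})

test_that("resistor correction recognises no-need and infeasible cases", {
  expect_equal(resistor_adjustment(ref_cohort$C, ref_settings)$status,
               "none-needed")
  # a resistor can only lower VT, so an under-ventilated patient is infeasible
  adj_b <- resistor_adjustment(ref_cohort$B, ref_settings)
  expect_equal(adj_b$status, "infeasible")
  expect_true(is.na(adj_b$delta_R))
  # Patient C after clinical improvement (E drops to 10) over-ventilates again
  improved <- patient_mechanics("C+", E = 10, R = 9, weight = 80)
  adj_c <- resistor_adjustment(improved, ref_settings)
  expect_equal(adj_c$status, "adjusted")
  expect_gt(adj_c$delta_R, 0)
})
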