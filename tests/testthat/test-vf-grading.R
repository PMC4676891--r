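test_that("screening and threshold reliability apply their index bounds", {
  expect_true(screening_reliable(1, 1))
  expect_false(screening_reliable(2, 0))
  expect_false(screening_reliable(0, 2))
  expect_true(screening_reliable(0, 0))
  expect_true(threshold_reliable(2, 2))
  expect_false(threshold_reliable(3, 0))
  expect_true(threshold_reliable(0, 0))
  expect_error(screening_reliable(-1, 0), ">= 0")
  expect_error(threshold_reliable(0, -2), ">= 0")
})

test_that("threshold-test triggering counts deep defects cumulatively", {
  z <- fdt_c20_zones()
  expect_true(needs_threshold_test(map17(1:3, 3L)))
  expect_true(needs_threshold_test(map17(1:2, 4L)))
  expect_false(needs_threshold_test(map17()))
  expect_false(needs_threshold_test(map17(1:2, 3L)))
  # a p<0.5% defect also counts at the p<1% level
  expect_true(needs_threshold_test(map17(c(1, 2, 3), c(3L, 3L, 4L))))
})

test_that("screening normality is the complement of threshold triggering", {
  expect_true(screening_normal(map17()))
  expect_true(screening_normal(map17(1:2, 3L)))
  expect_false(screening_normal(map17(1:2, 4L)))
  expect_false(screening_normal(map17(1:3, 3L)))
  # any shallow-only map is normal at screening
  expect_true(screening_normal(map17(1:10, 1L)))
  set.seed(41)
  for (i in 1:200) {
    m <- sample(0:4, 17, replace = TRUE, prob = c(0.6, 0.1, 0.1, 0.1, 0.1))
    if (needs_threshold_test(m)) expect_false(screening_normal(m))
  }
})

test_that("threshold normality rule variants behave as documented", {
  expect_true(threshold_normal(map17()))
  expect_false(threshold_normal(map17(1, 3L)))
  expect_false(threshold_normal(map17(c(1, 9), 4L), rule = "strict"))
  # lenient: up to 2 non-adjacent deep defects
  expect_true(threshold_normal(map17(c(1, 9), 4L), rule = "lenient"))
  expect_false(threshold_normal(map17(c(1, 2), 4L), rule = "lenient"))
})

test_that("defect maps grade by the most severe satisfied row", {
  z <- fdt_c20_zones()
  # 4 defects at p<5% scattered across both hemifields
  expect_equal(grade_defect_map(map17(c(1, 4, 13, 16), 1L)), "definite")
  # a single p<0.5% defect anywhere is definite (deepest row)
  expect_equal(grade_defect_map(map17(6, 4L)), "definite")
  # one non-edge defect at p<1% in one hemifield
  expect_equal(grade_defect_map(map17(6, 3L)), "probable")
  # one edge defect at p<1% counts cumulatively at p<2%: possible
  expect_equal(grade_defect_map(map17(1, 3L)), "possible")
  # two adjacent defects at p<5% in one hemifield
  expect_equal(grade_defect_map(map17(c(1, 2), 1L)), "possible")
  # two non-adjacent shallow defects: normal
  expect_equal(grade_defect_map(map17(c(1, 4), 1L)), "normal")
  # one defect at p<2%: possible
  expect_equal(grade_defect_map(map17(3, 2L)), "possible")
  # three defects at p<5% in one hemifield: probable
  expect_equal(grade_defect_map(map17(c(1, 3, 6), 1L)), "probable")
  # empty map
  expect_equal(grade_defect_map(map17()), "normal")
})

test_that("non-glaucomatous patterns grade unlikely", {
  # heavily shaded TDP with a clean PDP: diffuse loss
  expect_equal(grade_defect_map(map17(), map17(1:12, 1L)), "unlikely")
  # TDP strictly better than a defective PDP
  expect_equal(grade_defect_map(map17(c(1, 2), 2L), map17(c(1, 2), 1L)),
               "unlikely")
  # defects hugging the vertical meridian in both hemifields
  z <- fdt_c20_zones()
  mer_col2 <- which(z$col == 2)
  sup <- mer_col2[z$hemifield[mer_col2] == "superior"][1]
  inf <- mer_col2[z$hemifield[mer_col2] == "inferior"][1]
  expect_equal(grade_defect_map(map17(c(sup, inf), 2L)), "unlikely")
})

test_that("raising a defect level never lowers the severity rank", {
  z <- fdt_c20_zones()
  set.seed(99)
  for (i in 1:300) {
    m <- sample(0:4, 17, replace = TRUE, prob = c(0.7, 0.1, 0.08, 0.07, 0.05))
    m[1] <- 1L  # keep a defect off the meridian columns
    g0 <- vf_grade_rank(grade_defect_map(m, m))
    j <- sample.int(17, 1)
    m2 <- m
    m2[j] <- min(4L, m[j] + 1L)
    expect_gte(vf_grade_rank(grade_defect_map(m2, m2)), g0)
  }
})

test_that("threshold results take precedence and unusable tests drop out", {
  thr <- vf_record("threshold", 1, 1, pdp = map17(6, 4L))
  scr <- vf_record("screening", 0, 0, pdp = map17(3, 2L))
  expect_equal(as.character(interpret_vf(scr, thr)), "definite")
  # unreliable screening alone is not usable
  bad_scr <- vf_record("screening", 2, 0, pdp = map17(6, 4L))
  expect_equal(interpret_vf(bad_scr, NULL), "not_usable")
  expect_equal(interpret_vf(NULL, NULL), "not_usable")
  # lid artefact spoils the test
  lid <- vf_record("screening", 0, 0, pdp = map17(6, 4L),
                   lid_artefact = TRUE)
  expect_equal(interpret_vf(lid, NULL), "not_usable")
  # untestable records carry no maps
  expect_error(vf_record("screening", 0, 0, pdp = map17(),
                         untestable_reason = "cataract"), "untestable")
  unt <- vf_record("screening", 0, 0, untestable_reason = "cataract")
  expect_equal(interpret_vf(unt, NULL), "not_usable")
  # repeatability is noted when both tests are usable
  g <- interpret_vf(vf_record("screening", 0, 0, pdp = map17(6, 3L)), thr)
  expect_true(attr(g, "repeatable"))
})

test_that("the vectorized grader matches the exhaustive oracle on a sample", {
  z <- reduced_zones()
  set.seed(7)
  m <- matrix(sample(0:4, 8 * 500, replace = TRUE), ncol = 8)
  got <- grade_defect_maps(m, m, zones = z)
  want <- vapply(seq_len(nrow(m)),
                 function(i) oracle_grade(m[i, ], m[i, ], z), character(1))
  expect_equal(got, want)
})
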