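# Canonical satisfying vectors for each published system
la <- function() ind_from(0.70, 0.30, 0.05, 0.10, er_ki = 3)
lb <- function() ind_from(0.40, 0.10, 0.05, 0.30, er_ki = 3, her2_ki = 1)
bh <- function() ind_from(0.05, 0.05, 0.05, 0.10, her2_ki = 1, ki67_ki = 2)
bz <- function() ind_from(0.05, 0.05, 0.05, 0.30, ki67_ki = 3)

test_that("Luminal A system evaluates its five printed conditions", {
  v <- is_luminal_a(la())
  expect_length(v, 5L)
  expect_true(all(v))
  # strict boundary: 0.66 exactly fails the first condition
  expect_false(is_luminal_a(ind_from(0.66, 0.30, 0.05, 0.10, er_ki = 3))[1])
  expect_false(is_luminal_a(ind_from(0.70, 0.30, 0.05, 0.10, er_ki = 2))[2])
  # NA intensity (no positive cells) never satisfies an equality condition
  expect_false(is_luminal_a(ind_from(0.70, 0.30, 0.05, 0.10))[2])
})

test_that("Luminal B system evaluates its six printed conditions", {
  v <- is_luminal_b(lb())
  expect_length(v, 6L)
  expect_true(all(v))
  expect_false(is_luminal_b(ind_from(0.40, 0.10, 0.05, 0.20,
                                     er_ki = 3, her2_ki = 1))[6])  # 0.2 strict
  # the unqualified KI = 1 binds to HER2 by default
  expect_false(is_luminal_b(ind_from(0.40, 0.10, 0.05, 0.30,
                                     er_ki = 3, her2_ki = 2))[5])
  cfg <- ihc_config(list(bcb_ki_binding = "KI67"))
  v2 <- is_luminal_b(ind_from(0.40, 0.10, 0.05, 0.30, er_ki = 3,
                              her2_ki = 2, ki67_ki = 1), cfg)
  expect_true(v2[5])
  expect_named(v2[5], "ki67_ki_eq_1")
})

test_that("HER2-amplified system evaluates its four printed conditions", {
  v <- is_her2_amplified(bh())
  expect_length(v, 4L)
  expect_true(all(v))
  expect_false(is_her2_amplified(ind_from(0.05, 0.05, 0.15, 0.10,
                                          her2_ki = 1))[1])
  expect_false(is_her2_amplified(ind_from(0.10, 0.05, 0.05, 0.10,
                                          her2_ki = 1))[3])  # 0.1 strict
  # configurable inversion of the (biologically suspect) printed direction
  cfg <- ihc_config(list(her2_amplified_area_direction = "gt"))
  expect_true(is_her2_amplified(ind_from(0.05, 0.05, 0.4, 0.1,
                                         her2_ki = 1), cfg)[1])
})

test_that("basal-like system evaluates its four printed conditions", {
  v <- is_basal_like(bz())
  expect_length(v, 4L)
  expect_true(all(v))
  expect_false(is_basal_like(ind_from(0.05, 0.05, 0.05, 0.30, ki67_ki = 2))[4])
  v0 <- is_basal_like(ind_from(0, 0, 0, 0))
  expect_true(all(v0[1:3]))
})

test_that("classify picks the unique satisfied system", {
  for (case in list(list(la(), "LuminalA"), list(lb(), "LuminalB"),
                    list(bh(), "HER2Amplified"), list(bz(), "BasalLike"))) {
    res <- classify(case[[1]])
    expect_identical(res$subtype, case[[2]])
    expect_identical(res$matched_systems, case[[2]])
  }
  expect_identical(vapply(classify(la())$satisfied, length, integer(1)),
                   c(LuminalA = 5L, LuminalB = 6L, HER2Amplified = 4L,
                     BasalLike = 4L))
})

test_that("zero or several satisfied systems give Indeterminate", {
  none <- ind_from(0.5, 0.5, 0.5, 0.5, er_ki = 2, her2_ki = 2, ki67_ki = 2)
  expect_identical(classify(none)$subtype, "Indeterminate")
  # solving BCH and BCZ simultaneously: all areas < 0.1, HER2 KI = 1,
  # KI67 KI = 3
  both <- ind_from(0.05, 0.05, 0.05, 0.05, her2_ki = 1, ki67_ki = 3)
  res <- classify(both)
  expect_identical(res$subtype, "Indeterminate")
  expect_setequal(res$matched_systems, c("HER2Amplified", "BasalLike"))
})

test_that("grade triggers warnings only, never changes the subtype", {
  expect_length(classify(la(), grade = "G1")$grade_warnings, 0L)
  expect_length(classify(la(), grade = "G2")$grade_warnings, 0L)
  r <- classify(la(), grade = "G3")
  expect_identical(r$subtype, "LuminalA")
  expect_match(r$grade_warnings, "G1/G2")
  expect_length(classify(lb(), grade = "G2")$grade_warnings, 0L)
  expect_match(classify(lb(), grade = "G1")$grade_warnings, "G2/G3")
  expect_match(classify(bh(), grade = "G1")$grade_warnings, "G3")
  # no published association for basal-like
  expect_length(classify(bz(), grade = "G1")$grade_warnings, 0L)
})

test_that("Luminal A and B are mutually exclusive on random indicator sets", {
  set.seed(99)
  for (k in 1:500) {
    ind <- random_indicator_set()
    expect_false(all(is_luminal_a(ind)) && all(is_luminal_b(ind)))
  }
})
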