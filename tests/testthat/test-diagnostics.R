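test_that("ratio maps divide pixelwise and pin the pixelwise-first order", {
  n <- 41; pitch <- 20
  mask <- matrix(TRUE, n, n)
  a3 <- matrix(2, n, n)
  expect_equal(ratio_map(a3, a3, mask, pitch)$roi, 1)
  expect_equal(ratio_map(2 * a3, a3, mask, pitch)$roi, 2)

  # heterogeneous images: mean of ratios differs from ratio of means
  set.seed(5)
  a9 <- matrix(runif(n^2, 0.5, 2), n, n)
  a3 <- matrix(runif(n^2, 0.5, 2), n, n)
  rm_ <- ratio_map(a9, a3, mask, pitch, roi_diameter_um = 2 * n * pitch)
  expect_equal(rm_$roi, mean(a9 / a3))
  expect_gt(abs(rm_$roi - mean(a9) / mean(a3)), 1e-3)

  a3[5, 5] <- 0
  expect_warning(ratio_map(a9, a3, mask, pitch), "denominator")
})

test_that("case referencing centres BS at one and removes case factors", {
  one <- data.frame(case = 1, category = "BS", R3 = c(2, 4), R6 = 1,
                    R9 = 1, R15 = 1, ratio = c(0.4, 0.6))
  out <- case_reference(one, "reflectance")
  expect_equal(mean(out$R3), 1)
  outr <- case_reference(one, "ratio")
  expect_equal(mean(outr$ratio), 1)

  # scaling a case's raw values leaves normalised values unchanged
  s <- 5.5
  scaled <- one
  for (v in c("R3", "R6", "R9", "R15")) scaled[[v]] <- one[[v]] * s
  expect_equal(case_reference(scaled, "reflectance"),
               case_reference(one, "reflectance"))

  # two cases with known offsets collapse onto each other
  two <- rbind(
    data.frame(case = 1, category = c("BS", "CIN3"), R3 = c(1, 2),
               R6 = 1, R9 = 1, R15 = 1, ratio = c(0.4, 0.8)),
    data.frame(case = 2, category = c("BS", "CIN3"), R3 = 7 * c(1, 2),
               R6 = 1, R9 = 1, R15 = 1, ratio = c(0.4, 0.8)))
  out2 <- case_reference(two, "reflectance")
  expect_equal(out2$R3[out2$case == 1], out2$R3[out2$case == 2])

  # idempotence in reflectance mode
  expect_equal(case_reference(out2, "reflectance"), out2)

  # cases without BS are dropped with a warning
  nob <- rbind(two, data.frame(case = 3, category = "CIN2", R3 = 1, R6 = 1,
                               R9 = 1, R15 = 1, ratio = 1))
  expect_warning(out3 <- case_reference(nob, "reflectance"), "without BS")
  expect_false(3 %in% out3$case)
})

test_that("group summaries use type-7 quartiles and min/max whiskers", {
  one <- data.frame(category = "BS", ratio = 2.5)
  s1 <- summarize_groups(one)
  expect_equal(unlist(s1[c("min", "q1", "median", "q3", "max")]),
               rep(2.5, 5), ignore_attr = TRUE)

  d <- data.frame(category = "CIN2", ratio = c(1, 2, 3, 4, 5))
  s <- summarize_groups(d)
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)

  set.seed(6)
  big <- data.frame(category = sample(c("BS", "CIN3"), 200, TRUE),
                    ratio = rlnorm(200))
  sm <- summarize_groups(big)
  for (cat in sm$category) {
    x <- sort(big$ratio[big$category == cat])
    n <- length(x)
    # type-7 quantile by hand: linear interpolation at 1 + (n-1)p
    byhand <- function(p) {
      h <- 1 + (n - 1) * p
      x[floor(h)] + (h - floor(h)) * (x[ceiling(h)] - x[floor(h)])
    }
    row <- sm[sm$category == cat, ]
    expect_equal(row$q1, byhand(0.25))
    expect_equal(row$median, byhand(0.5))
    expect_equal(row$q3, byhand(0.75))
    expect_equal(row$min, x[1])
    expect_equal(row$max, x[n])
  }
  expect_null(summarize_groups(big[0, ]))
})

test_that("linear classification counts the confusion matrix correctly", {
  d <- data.frame(category = rep(c("CIN3", "CIN2", "BS", "CIN1"), each = 5),
                  R3 = rep(1, 20),
                  ratio = c(runif(10, 0.8, 1), runif(10, 0.1, 0.3)))
  cl <- classify_linear(d, slope = 0, intercept = 0.5)
  expect_equal(cl$sensitivity, 1)
  expect_equal(cl$specificity, 1)

  # line at infinity: nothing called positive
  cl0 <- classify_linear(d, slope = 0, intercept = Inf)
  expect_equal(cl0$sensitivity, 0)
  expect_equal(cl0$specificity, 1)

  # BC/AIS are excluded from the squamous task
  d2 <- rbind(d, data.frame(category = c("BC", "AIS"), R3 = 1, ratio = 10))
  cl2 <- classify_linear(d2, slope = 0, intercept = 0.5)
  expect_equal(cl2$confusion, cl$confusion)
  expect_equal(nrow(cl2$scans), 20)

  expect_error(classify_linear(d[d$category == "BS", ], 0, 0.5),
               "degenerate")
})

test_that("sensitivity and specificity survive consistent monotone rescaling", {
  study <- make_study(synth_study_config(), seed = 4)
  sl <- 0.05; ic <- 0.45
  base <- classify_linear(study, sl, ic)
  # rescale both axes by positive factors and transform the line with them
  ax <- 3; ay <- 0.25
  resc <- study
  resc$R3 <- study$R3 * ax
  resc$ratio <- study$ratio * ay
  resc_cl <- classify_linear(resc, slope = sl * ay / ax, intercept = ic * ay)
  expect_equal(resc_cl$sensitivity, base$sensitivity)
  expect_equal(resc_cl$specificity, base$specificity)
})

test_that("the packaged study table sums per category and in total", {
  st <- load_study_table()
  expect_equal(st$grand_total, 102)
  expect_equal(unname(st$category_totals),
               c(19, 5, 47, 5, 10, 16))
  expect_equal(names(st$category_totals),
               c("BC", "AIS", "BS", "CIN1", "CIN2", "CIN3"))
  expect_equal(nrow(st$table), 13)

  tmp <- tempfile(fileext = ".csv")
  writeLines("case,BC,AIS,BS,CIN1,CIN2,CIN3", tmp)
  empty <- load_study_table(tmp)
  expect_equal(empty$grand_total, 0)

  writeLines("nope,really", tmp)
  expect_error(load_study_table(tmp), "malformed")
  expect_error(load_study_table("/nonexistent/file.csv"), "not found")
})
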