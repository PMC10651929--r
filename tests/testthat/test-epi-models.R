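test_that("exclusions are sequential and never recount a record", {
  d <- data.frame(id = 1:10,
                  neighborhood_id = c(NA, NA, "N01", "N01", "N01", "N01",
                                      "N01", "N01", "N01", "N01"),
                  tract_id = c(NA, NA, rep("T1", 8)),
                  rural = c(NA, NA, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                            FALSE, FALSE),
                  age_group = c("18-24", NA, NA, "18-24", NA, NA, "18-24",
                                "18-24", "18-24", "18-24"),
                  gender = "Female", race_ethnicity = "White",
                  education = "High school", income = "Low",
                  ff_intake = "never", obesity = 0L, diabetes = 0L)
  ex <- apply_exclusions(d)
  # rows 1-2 leave by residence (despite other missingness), 3-4 by rural
  # (despite row 3's missing age), 5-6 by missing variables
  expect_equal(unname(ex$counts[1:3]), c(2L, 2L, 2L))
  expect_equal(nrow(ex$analytic), 4L)
  expect_equal(unname(ex$counts["analytic_n"]), 4L)

  none <- apply_exclusions(d[7:10, ])
  expect_equal(nrow(none$analytic), 4L)
  all_res <- d; all_res$neighborhood_id <- NA
  ex2 <- apply_exclusions(all_res)
  expect_equal(nrow(ex2$analytic), 0L)
  expect_equal(unname(ex2$counts[1:3]), c(10L, 0L, 0L))
})

test_that("identical samples compare with zero chi-square", {
  fx <- survey_fixture(n = 500)
  cmp <- compare_samples(fx$data, fx$data)
  expect_true(all(cmp$p_value > 0.999, na.rm = TRUE))
  expect_equal(cmp$pct_full, cmp$pct_analytic)
  # percentages are over non-missing counts and sum to 100 per variable
  for (v in unique(cmp$variable))
    expect_equal(sum(cmp$pct_analytic[cmp$variable == v]), 100)
})

test_that("a constant exposure is rejected as inestimable", {
  fx <- survey_fixture(n = 300)
  fx$data$flat <- 1.7
  expect_error(fit_multinomial(fx$data, "flat"), "constant")
  expect_error(fit_binary(fx$data, "obesity", "flat"), "constant")
})

test_that("a single-level outcome is rejected", {
  fx <- survey_fixture(n = 300)
  fx$data$obesity <- 0L
  expect_error(fit_binary(fx$data, "obesity", "exposure"), "single")
})

test_that("a two-category multinomial collapse matches the binary logit", {
  fx <- survey_fixture(n = 2000, seed = 72)
  d <- fx$data[fx$data$ff_intake %in% c("never", "frequent"), ]
  mn <- fit_multinomial(d, "exposure", adjusted = FALSE)
  d$freq01 <- as.integer(d$ff_intake == "frequent")
  bl <- fit_binary(d, "freq01", "exposure", adjusted = FALSE)
  expect_equal(mn$terms$estimate[mn$terms$term == "exposure"],
               bl$terms$estimate[bl$terms$term == "exposure"],
               tolerance = 1e-3)
  expect_equal(mn$terms$se[mn$terms$term == "exposure"],
               bl$terms$se[bl$terms$term == "exposure"], tolerance = 1e-3)
})

test_that("unadjusted AOR matches the closed-form 2x2 odds ratio", {
  # hand-built 2x2 table: exposure x outcome counts (a=40, b=60, c=25, d=75)
  d <- data.frame(y = rep(c(1L, 0L, 1L, 0L), c(40, 60, 25, 75)),
                  x = rep(c(1, 0), c(100, 100)))
  f <- fit_binary(d, "y", "x", adjusted = FALSE)
  expect_equal(f$terms$or, (40 * 75) / (60 * 25), tolerance = 1e-6)
})

test_that("adjusted and unadjusted estimates agree when covariates are clean", {
  # demographics are independent of exposure by construction, and the intake
  # model plants no demographic effects, so adjustment moves the OR < 10%
  fx <- survey_fixture(n = 4000, seed = 73)
  un <- fit_multinomial(fx$data, "exposure", adjusted = FALSE)
  ad <- fit_multinomial(fx$data, "exposure", adjusted = TRUE)
  for (cat in c("infrequent", "moderate", "frequent")) {
    o_u <- un$terms$or[un$terms$category == cat & un$terms$term == "exposure"]
    o_a <- ad$terms$or[ad$terms$category == cat & ad$terms$term == "exposure"]
    expect_lt(abs(100 * (o_a - o_u) / o_u), 10)
  }
})

test_that("the multinomial fit recovers a planted exposure effect", {
  fx <- survey_fixture(n = 5000, seed = 74)
  f <- fit_multinomial(fx$data, "exposure", adjusted = FALSE)
  row <- f$terms[f$terms$category == "frequent" & f$terms$term == "exposure", ]
  expect_equal(row$estimate, log(1.35), tolerance = 0.25)
  expect_true(row$ci_lo < 1.35 & 1.35 < row$ci_hi)
  expect_equal(f$aic, -2 * f$loglik + 2 * f$k)
})

test_that("Akaike weights are correct, stable, and shift invariant", {
  w <- akaike_weights(c(a = 100, b = 100, c = 100))
  expect_equal(w$weight, rep(1 / 3, 3))
  expect_equal(sum(w$weight), 1)

  w2 <- akaike_weights(c(10, 12, 30))
  w3 <- akaike_weights(c(10, 12, 30) + 1000)
  expect_equal(w2$weight, w3$weight)
  expect_equal(which.max(w2$weight), which.min(w2$aic))

  # extreme spread stays finite thanks to the min subtraction
  w4 <- akaike_weights(c(100, 2000))
  expect_equal(w4$weight[1], 1)
  expect_error(akaike_weights(numeric(0)), "AIC")
  expect_error(akaike_weights(c(1, NA)), "finite")
})
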