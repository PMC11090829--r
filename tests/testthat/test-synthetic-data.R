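test_that("synthetic images hit requested area fractions exactly and reproduce by seed", {
  spec <- synthetic_image_spec(height = 150, width = 120, k8_area_frac = 0.10,
                               k14_area_frac = 0.05, noise_sigma = 0, seed = 9)
  g <- gen_section_image(spec)
  npx <- 150 * 120
  expect_equal(sum(g$masks$k8), round(0.10 * npx))
  expect_equal(sum(g$masks$k14), round(0.05 * npx))
  expect_false(any(g$masks$k8 & g$masks$k14))  # overlap_frac = 0

  g2 <- gen_section_image(spec)
  expect_identical(g$image$pixels, g2$image$pixels)
  expect_identical(g$masks, g2$masks)

  # seeding is local: the generator must not disturb the caller's RNG stream
  set.seed(1); r1 <- runif(3)
  set.seed(1); invisible(gen_section_image(spec)); r2 <- runif(3)
  expect_identical(r1, r2)
})

test_that("requested double-positive overlap is honoured", {
  spec <- synthetic_image_spec(height = 100, width = 100, k8_area_frac = 0.2,
                               k14_area_frac = 0.15, overlap_frac = 0.05,
                               seed = 21)
  g <- gen_section_image(spec)
  expect_equal(sum(g$masks$k8 & g$masks$k14), 0.05 * 10000)
  expect_equal(sum(g$masks$k14), 0.15 * 10000)
  expect_error(synthetic_image_spec(k8_area_frac = 0.1, overlap_frac = 0.2),
               class = "jsdfidelity_config_error")
  expect_error(synthetic_image_spec(k8_area_frac = 0.8, k14_area_frac = 0.6),
               class = "jsdfidelity_config_error")
})

test_that("noisy synthetic images are recovered by the quantitation stage", {
  # recovery experiment: noise at 10% of foreground intensity
  spec <- synthetic_image_spec(height = 200, width = 200, k8_area_frac = 0.15,
                               k14_area_frac = 0.08, noise_sigma = 20,
                               foreground_intensity = 200, seed = 33)
  g <- gen_section_image(spec)
  for (role in c("k8", "k14")) {
    got <- positive_area(threshold_channel(g$image, role))
    truth <- sum(g$masks[[role]])
    expect_lt(abs(got - truth) / truth, 0.05)
  }
})

test_that("cohort generation is deterministic and patient-stable", {
  spec <- synthetic_cohort_spec("TNBC", seed = 4, n_patients = 4,
                                sections_per_patient = 30)
  expect_identical(gen_cohort(spec), gen_cohort(spec))

  # adding patients must not perturb earlier patients' sections
  bigger <- synthetic_cohort_spec("TNBC", seed = 4, n_patients = 6,
                                  sections_per_patient = 30)
  r4 <- gen_cohort(spec)
  r6 <- gen_cohort(bigger)
  expect_identical(r4$log2_ratio, r6$log2_ratio[seq_len(nrow(r4))])
})

test_that("analytic bin probabilities: symmetry, point mass, Monte-Carlo agreement", {
  sc <- fit_bin_scheme(c(-2, -1, 1, 2))  # symmetric scheme, q50 = 0
  balanced <- synthetic_cohort_spec("normal", component_means = c(0, 0),
                                    component_sds = c(1, 1), patient_sd = 0)
  p <- analytic_bin_probs(balanced, sc)
  expect_equal(sum(p), 1)
  expect_equal(p[1], p[4])
  expect_equal(p[2], p[3])

  # mean 0.5 lies above the median boundary, inside bin 3
  point <- synthetic_cohort_spec("normal", component_means = c(0.5, 0.5),
                                 component_sds = c(1e-9, 1e-9), patient_sd = 0)
  expect_equal(analytic_bin_probs(point, sc), c(0, 0, 1, 0), tolerance = 1e-9)

  # 50,000-draw empirical histogram vs the closed form
  tn <- synthetic_cohort_spec("TNBC", n_patients = 50,
                              sections_per_patient = 1000, seed = 55)
  emp <- make_distribution(gen_cohort(tn), sc, "TNBC")
  expect_lt(max(abs(emp$probs - analytic_bin_probs(tn, sc))), 0.01)
})

test_that("subtype defaults reproduce the expected distribution shapes", {
  n_spec <- synthetic_cohort_spec("normal", patient_sd = 0, seed = 61,
                                  sections_per_patient = 500)
  scheme <- fit_bin_scheme(gen_cohort(n_spec))

  tn <- synthetic_cohort_spec("TNBC", patient_sd = 0)
  er <- synthetic_cohort_spec("ER+", patient_sd = 0)
  pt <- analytic_bin_probs(tn, scheme)
  pe <- analytic_bin_probs(er, scheme)
  # TNBC is K14-rich (left-skewed), ER+ K8-rich (right-skewed)
  expect_gt(pt[1] + pt[2], pt[3] + pt[4])
  expect_gt(pe[3] + pe[4], pe[1] + pe[2])
  # empirical cohorts agree
  dt <- make_distribution(gen_cohort(tn), scheme, "TNBC")
  expect_gt(dt$probs[1] + dt$probs[2], dt$probs[3] + dt$probs[4])
})

test_that("K8-ward treatment shift moves mass into bin 4 (analytic and empirical)", {
  n_spec <- synthetic_cohort_spec("normal", patient_sd = 0, seed = 62,
                                  sections_per_patient = 500)
  scheme <- fit_bin_scheme(gen_cohort(n_spec))
  base <- synthetic_cohort_spec("TNBC", patient_sd = 0, seed = 63)
  shifted <- synthetic_cohort_spec("TNBC", patient_sd = 0, seed = 63,
                                   treatment_shift = 0.3)
  expect_gt(analytic_bin_probs(shifted, scheme)[4],
            analytic_bin_probs(base, scheme)[4])
  d0 <- make_distribution(gen_cohort(base, "organoid"), scheme, "untreated")
  d1 <- make_distribution(gen_cohort(shifted, "organoid"), scheme, "treated")
  expect_gt(d1$probs[4], d0$probs[4])
})

test_that("culture drift displaces organoid cohorts but not starting tissue", {
  spec <- synthetic_cohort_spec("normal", culture_drift = 0.8, seed = 70,
                                n_patients = 5, sections_per_patient = 200)
  st <- gen_cohort(spec, "ST")
  org <- gen_cohort(spec, "organoid")
  expect_equal(mean(org$log2_ratio) - mean(st$log2_ratio), 0.8,
               tolerance = 0.15)
  sc <- fit_bin_scheme(c(-2, -1, 1, 2))
  expect_equal(analytic_bin_probs(spec, sc, "organoid"),
               analytic_bin_probs(synthetic_cohort_spec(
                 "normal", component_means = c(-1.5, 1.5) + 0.8,
                 patient_sd = 0.3), sc, "ST"))
})

test_that("synthetic quants invert back to the generating log-ratios", {
  spec <- synthetic_cohort_spec("ER+", seed = 77, n_patients = 3,
                                sections_per_patient = 20)
  rec <- gen_cohort(spec)
  q <- cohort_as_quants(rec)
  back <- log2_ratio(q)
  expect_equal(back$log2_ratio, rec$log2_ratio, tolerance = 1e-9)
  expect_identical(back$section_id, rec$section_id)
})
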