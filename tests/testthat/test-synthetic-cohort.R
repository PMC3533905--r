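test_that("error-free cohort has one record per role and is exactly joinable", {
  coh <- make_clean_cohort(100, seed = 11)
  expect_equal(nrow(coh$birth_records), 100)
  expect_equal(nrow(coh$maternal_hospital), 100)
  expect_equal(nrow(coh$infant_hospital), 100)

  # deterministic exact-match join on hospital + MRN recovers ground truth
  br <- coh$birth_records
  ih <- coh$infant_hospital
  join <- merge(br[, c("birth_record_id", "hospital_code", "infant_mrn")],
                ih[, c("record_id", "hospital_code", "mrn")],
                by.x = c("hospital_code", "infant_mrn"),
                by.y = c("hospital_code", "mrn"))
  expect_equal(nrow(join), 100)
  got <- join[order(join$birth_record_id), c("birth_record_id", "record_id")]
  truth <- coh$ground_truth$infant_pairs
  truth <- truth[order(truth$birth_record_id), ]
  expect_equal(got$record_id, truth$hospital_record_id)

  mh <- coh$maternal_hospital
  mjoin <- merge(unique(br[, c("delivery_id", "hospital_code", "mother_mrn")]),
                 mh[, c("record_id", "hospital_code", "mrn")],
                 by.x = c("hospital_code", "mother_mrn"),
                 by.y = c("hospital_code", "mrn"))
  expect_equal(nrow(mjoin), 100)
})

test_that("stillbirths generate no infant admission unless misclassification is on", {
  coh <- generate_cohort(
    cohort_params(100, stillbirth_rate = 1,
                  stillbirth_misclassification_rate = 0,
                  other_admission_rate = 0, seed = 5),
    zero_error_model())
  expect_equal(nrow(coh$infant_hospital), 0)
  expect_true(all(!coh$birth_records$live_birth))

  coh2 <- generate_cohort(
    cohort_params(400, stillbirth_rate = 1,
                  stillbirth_misclassification_rate = 0.5,
                  other_admission_rate = 0, seed = 5),
    zero_error_model())
  expect_gt(nrow(coh2$infant_hospital), 0)
})

test_that("empirical rates at defaults track the configured parameters", {
  params <- cohort_params(10000, seed = 1)
  coh <- generate_cohort(params)
  br <- coh$birth_records
  m <- nrow(br)

  frac_still <- mean(!br$live_birth)
  sd3 <- 3 * sqrt(params$stillbirth_rate * (1 - params$stillbirth_rate) / m)
  expect_lt(abs(frac_still - params$stillbirth_rate), sd3)

  deliv <- br[!duplicated(br$delivery_id), ]
  frac_mult <- mean(deliv$plurality_n > 1)
  sd3m <- 3 * sqrt(0.016 * 0.984 / nrow(deliv))
  expect_lt(abs(frac_mult - params$multiple_pregnancy_rate), sd3m)

  frac_priv <- mean(deliv$private_hospital)
  sd3p <- 3 * sqrt(0.25 * 0.75 / nrow(deliv))
  expect_lt(abs(frac_priv - params$private_hospital_rate), sd3p)
})

test_that("generation is reproducible by seed and varies across seeds", {
  a <- generate_cohort(cohort_params(200, seed = 3))
  b <- generate_cohort(cohort_params(200, seed = 3))
  d <- generate_cohort(cohort_params(200, seed = 4))
  expect_identical(a$birth_records, b$birth_records)
  expect_identical(a$maternal_hospital, b$maternal_hospital)
  expect_false(identical(a$maternal_hospital$surname, d$maternal_hospital$surname))

  # byte-identical CSV output under the same seed
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  p1 <- write_cohort(a, d1); p2 <- write_cohort(b, d2)
  for (i in seq_along(p1))
    expect_identical(readLines(p1[i]), readLines(p2[i]))
})

test_that("record counts are consistent with the cohort structure", {
  coh <- generate_cohort(cohort_params(2000, seed = 9))
  br <- coh$birth_records
  expect_lte(sum(coh$infant_hospital$is_birth_admission), sum(br$live_birth) +
               sum(!br$live_birth))  # misclassified stillbirths allowed
  expect_lte(sum(coh$maternal_hospital$is_birth_admission),
             length(unique(br$delivery_id)))
  # group sizes: one birth record per infant; multiples share delivery id
  mult <- br[br$plurality_n > 1, ]
  for (d in unique(mult$delivery_id)) {
    fam <- mult[mult$delivery_id == d, ]
    expect_identical(fam$mother_surname, rep(fam$mother_surname[1], nrow(fam)))
    expect_identical(fam$hospital_code, rep(fam$hospital_code[1], nrow(fam)))
    expect_identical(fam$birth_date, rep(fam$birth_date[1], nrow(fam)))
    expect_identical(sort(fam$birth_order), seq_len(nrow(fam)))
  }
})

test_that("corrupt_identifiers honours degenerate and extreme error models", {
  ids <- data.frame(given_name = c("SARAH", "EMMA"), surname = c("SMITH", "JONES"),
                    alias_surname = c("BROWN", NA), dob = as.Date("1980-05-17"),
                    address = "12 HIGH ST NEWTOWN", mrn = c("1234567", "7654321"),
                    private_hospital = FALSE, stringsAsFactors = FALSE)
  expect_identical(corrupt_identifiers(ids, zero_error_model(), seed = 1), ids)

  all_missing <- error_model(typo_rate = 0, name_missing_rate_public = 1,
                             name_missing_rate_private = 1,
                             dob_digit_swap_rate = 0, alias_rate = 0,
                             address_change_rate = 0,
                             gestation_missing_knot = NULL)
  out <- corrupt_identifiers(ids, all_missing, seed = 1)
  expect_identical(out$given_name, c("", ""))
  expect_identical(out$surname, c("", ""))
  expect_identical(out$dob, ids$dob)
})

test_that("typo corruption hits the configured fraction of fields", {
  n <- 10000
  ids <- data.frame(given_name = rep("MARGARET", n), private_hospital = FALSE,
                    stringsAsFactors = FALSE)
  em <- error_model(typo_rate = 0.5, name_missing_rate_public = 0,
                    name_missing_rate_private = 0, dob_digit_swap_rate = 0,
                    alias_rate = 0, address_change_rate = 0,
                    gestation_missing_knot = NULL)
  out <- corrupt_identifiers(ids, em, seed = 123)
  frac <- mean(out$given_name != "MARGARET")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("parameter validation rejects malformed configurations", {
  expect_error(cohort_params(0), "positive")
  expect_error(cohort_params(10, stillbirth_rate = 1.5), "\\[0, 1\\]")
  bad_gd <- default_gestation_distribution() * 2
  expect_error(cohort_params(10, gestation_distribution = bad_gd), "sum to 1")
  expect_error(error_model(name_missing_rate_public = 0.5,
                           name_missing_rate_private = 0.1), ">= public")
})
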