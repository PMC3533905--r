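vocab <- load_code_vocabulary()

hosp_rec <- function(diag = "", proc = "", age = 0L, bw = NA_real_,
                     referral = "other", order = 1L) {
  data.frame(diagnosis_codes = diag, procedure_codes = proc, age_days = age,
             birthweight_g = bw, source_of_referral = referral,
             admission_order = order, stringsAsFactors = FALSE)
}

test_that("infant birth admissions follow the age/code/referral rule", {
  expect_true(identify_infant_birth_admission(hosp_rec("Z38.0", age = 0), vocab))
  expect_true(identify_infant_birth_admission(
    hosp_rec("P07.2", age = 1, bw = 900), vocab))
  expect_true(identify_infant_birth_admission(
    hosp_rec("", age = 0, referral = "born in hospital"), vocab))
  # age outside 0-1 days fails regardless of codes
  expect_false(identify_infant_birth_admission(hosp_rec("Z38.0", age = 5), vocab))
  # P code without a recorded birthweight is insufficient
  expect_false(identify_infant_birth_admission(hosp_rec("P07.3", age = 0), vocab))
  # must be the infant's first admission
  expect_false(identify_infant_birth_admission(
    hosp_rec("Z38.0", age = 0, order = 2L), vocab))
})

test_that("maternal delivery admissions match any delivery diagnosis or procedure", {
  expect_true(identify_maternal_delivery_admission(hosp_rec("Z37.0"), vocab))
  expect_true(identify_maternal_delivery_admission(hosp_rec(proc = "16520"), vocab))
  expect_true(identify_maternal_delivery_admission(hosp_rec("O60.2"), vocab))
  expect_true(identify_maternal_delivery_admission(hosp_rec("O82.1"), vocab))
  expect_true(identify_maternal_delivery_admission(hosp_rec(proc = "90466"), vocab))
  expect_false(identify_maternal_delivery_admission(hosp_rec("E11"), vocab))
  expect_false(identify_maternal_delivery_admission(hosp_rec("O21.0"), vocab))
})

test_that("cross-record date and hospital constraints are role-specific", {
  birth <- data.frame(birth_date = as.Date("2004-06-10"), hospital_code = "H01")
  inf_ok <- data.frame(admission_date = as.Date("2004-06-11"),
                       separation_date = as.Date("2004-06-14"),
                       hospital_code = "H01")
  inf_far <- within(inf_ok, admission_date <- as.Date("2004-06-12"))
  expect_true(check_link_constraints(birth, inf_ok, "infant"))
  expect_false(check_link_constraints(birth, inf_far, "infant"))

  mat_ok <- data.frame(admission_date = as.Date("2004-06-09"),
                       separation_date = as.Date("2004-06-13"),
                       hospital_code = "H01")
  expect_true(check_link_constraints(birth, mat_ok, "mother"))
  mat_wrong_hosp <- within(mat_ok, hospital_code <- "H02")
  expect_false(check_link_constraints(birth, mat_wrong_hosp, "mother"))
  mat_na <- within(mat_ok, admission_date <- as.Date(NA))
  expect_message(res <- check_link_constraints(birth, mat_na, "mother"),
                 "missing dates")
  expect_false(res)
})

test_that("derived variable flags follow the code lists hierarchically", {
  v <- derive_variables(hosp_rec("O24.4"), vocab)
  expect_true(v$diabetes)
  expect_false(v$hypertension)
  expect_true(derive_variables(hosp_rec("O44.1"), vocab)$placenta_praevia)
  expect_true(derive_variables(hosp_rec("E13"), vocab)$diabetes)
  expect_true(derive_variables(hosp_rec(proc = "16520"), vocab)$caesarean)
  expect_true(derive_variables(hosp_rec("O90.2"), vocab)$duration_lt26wk)
  expect_true(derive_variables(hosp_rec("O45.0"), vocab)$placental_abruption)
  empty <- derive_variables(hosp_rec(""), vocab)
  expect_false(any(unlist(empty)))
})

test_that("plurality and birth status classification handles conflict and absence", {
  expect_equal(unlist(classify_plurality_stillbirth(hosp_rec("Z37.1"), vocab)),
               c(plurality = "singleton", birth_status = "stillbirth"))
  expect_equal(unlist(classify_plurality_stillbirth(hosp_rec("Z38.3"), vocab)),
               c(plurality = "multiple", birth_status = "livebirth"))
  none <- classify_plurality_stillbirth(hosp_rec("E11"), vocab)
  expect_equal(none$plurality, "unclassifiable")
  expect_equal(none$birth_status, "unclassifiable")
  conflict <- classify_plurality_stillbirth(hosp_rec("Z37.0;O84"), vocab)
  expect_equal(conflict$plurality, "unclassifiable")
})

test_that("every code literal in the vocabulary matches its own rule", {
  raw <- yaml::read_yaml(system.file("extdata", "birth_admission_codes.yml",
                                     package = "perilink"))
  expand_literals <- function(x) {
    # for ranges keep both endpoints as testable literals
    unlist(lapply(x, function(item) {
      if (grepl("-", item)) strsplit(item, "-")[[1]] else item
    }))
  }
  check_list <- function(cl, diag, proc) {
    for (lit in expand_literals(diag))
      expect_true(code_matches(lit, cl), label = paste("diagnosis", lit))
    for (lit in expand_literals(proc))
      expect_true(code_matches("", cl, procedure_codes = lit),
                  label = paste("procedure", lit))
  }
  mat <- raw$maternal_delivery_admission
  check_list(vocab$maternal, unlist(mat$diagnosis), unlist(mat$procedure))
  for (nm in names(raw$variables))
    check_list(vocab$variables[[nm]], unlist(raw$variables[[nm]]$diagnosis),
               unlist(raw$variables[[nm]]$procedure))
  check_list(vocab$plurality$singleton, unlist(raw$plurality$singleton$diagnosis), NULL)
  check_list(vocab$plurality$multiple, unlist(raw$plurality$multiple$diagnosis), NULL)
  check_list(vocab$stillbirth, unlist(raw$stillbirth$diagnosis), NULL)
})

test_that("prefix matching is hierarchical and case-insensitive; malformed codes warn", {
  cl <- code_list("diab", diagnosis = "O24")
  expect_true(code_matches("o24.1", cl))
  expect_true(code_matches("O24", cl))
  expect_false(code_matches("O25", cl))
  expect_false(code_matches("O23.9", cl))
  # truncated or garbled codes are dropped with a warning, not matched
  expect_warning(expect_false(code_matches("O2", cl)), "malformed")
  expect_warning(code_matches("??bad", cl), "malformed")
})

test_that("identification exactly recovers designated admissions on clean cohorts", {
  coh <- generate_cohort(
    cohort_params(400, coding_gap_rate = 0, seed = 21), zero_error_model())
  mi <- identify_maternal_delivery_admission(coh$maternal_hospital, vocab)
  ii <- identify_infant_birth_admission(coh$infant_hospital, vocab)
  expect_identical(mi, coh$maternal_hospital$is_birth_admission)
  expect_identical(ii, coh$infant_hospital$is_birth_admission)
  # determinism
  expect_identical(mi, identify_maternal_delivery_admission(coh$maternal_hospital, vocab))
})
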