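#' Generate a synthetic perinatal cohort with ground truth
#'
#' Simulates mother-infant deliveries and their three record streams: birth
#' registrations (one per infant, carrying both maternal and infant
#' identifiers plus pregnancy and outcome variables), maternal hospital
#' admissions and infant hospital admissions with ICD-10-AM/ACHI coding.
#' Hospital-side identifiers are corrupted copies of the registration
#' identifiers, perturbed per the [error_model()]; complete ground truth
#' (entity ids and true record pairs) is returned alongside.
#'
#' Key structural features of the emulated collections: multiples share a
#' delivery id, maternal identifiers, hospital and date of birth, differing
#' in birth order (and possibly sex and name); stillbirths are recorded on
#' the mother's admission and generate no infant admission, except for a
#' small misclassification fraction coded as liveborn; private-hospital
#' records carry much more missing name information; a configurable
#' fraction of non-birth admissions (antenatal and infant readmissions) is
#' mixed into each hospital stream; and a small coding-gap fraction of true
#' birth admissions lacks identifying codes so cannot be rule-identified.
#'
#' @param params a [cohort_params()].
#' @param errors an [error_model()].
#' @return an object of class `perilink_cohort`: a list with data.frames
#'   `birth_records`, `maternal_hospital`, `infant_hospital`, a
#'   `ground_truth` list (`mother_pairs` keyed by delivery, `infant_pairs`
#'   keyed by birth record), and the `params`/`errors` used.
#' @examples
#' coh <- generate_cohort(cohort_params(200, seed = 42), zero_error_model())
#' nrow(coh$birth_records)
#' @export
generate_cohort <- function(params, errors = error_model()) {
  stopifnot(inherits(params, "cohort_params"), inherits(errors, "error_model"))
  set.seed(params$seed)
  n <- params$n_deliveries

  ## ---- deliveries ----------------------------------------------------
  delivery_id <- sprintf("D%06d", seq_len(n))
  mother_entity_id <- sprintf("M%06d", seq_len(n))
  private <- stats::runif(n) < params$private_hospital_rate
  hospital_code <- ifelse(private,
                          sprintf("P%02d", sample.int(15, n, replace = TRUE)),
                          sprintf("H%02d", sample.int(40, n, replace = TRUE)))
  birth_date <- as.Date("2001-01-01") + sample.int(2922, n, replace = TRUE) - 1L

  age_cat <- sample(1:3, n, replace = TRUE, prob = c(0.18, 0.61, 0.21))
  maternal_age <- ifelse(age_cat == 1, 16 + stats::runif(n) * 9,
                  ifelse(age_cat == 2, 25 + stats::runif(n) * 10,
                         35 + stats::runif(n) * 10))
  mother_dob <- birth_date - round(maternal_age * 365.25)

  mother_surname <- .pl_sample(.pl_surnames, n, .pl_surname_wt)
  mother_given <- .pl_sample(.pl_given_f, n)
  has_alias <- stats::runif(n) < 0.55
  alias_surname <- ifelse(has_alias, .pl_sample(.pl_surnames, n, .pl_surname_wt),
                          NA_character_)
  address <- .pl_new_address(n)
  australian_born <- stats::runif(n) < 0.71
  country <- ifelse(australian_born, "AUSTRALIA", .pl_sample(.pl_countries, n))

  multiple <- stats::runif(n) < params$multiple_pregnancy_rate
  n_infants <- ifelse(multiple,
                      ifelse(stats::runif(n) < 0.95, 2L, 3L), 1L)

  gweeks <- 20:42
  gd <- params$gestation_distribution
  g1 <- sample(gweeks, n, replace = TRUE, prob = gd)
  g2 <- sample(gweeks, n, replace = TRUE, prob = gd)
  gestation <- ifelse(multiple, pmin(g1, g2), g1)

  parity <- sample(0:3, n, replace = TRUE, prob = c(0.42, 0.33, 0.15, 0.10))
  smoking <- stats::runif(n) < 0.145
  diabetes <- stats::runif(n) < 0.052
  hypertension <- stats::runif(n) < 0.075
  antenatal_ge15wk <- stats::runif(n) < 0.25
  married <- stats::runif(n) < 0.80
  seifa_quintile <- sample(1:5, n, replace = TRUE,
                           prob = c(0.21, 0.18, 0.18, 0.19, 0.24))
  placenta_praevia <- stats::runif(n) < 0.005
  placental_abruption <- stats::runif(n) < (0.004 + 0.02 * (gestation < 32))
  caesarean <- stats::runif(n) < stats::plogis(
    stats::qlogis(0.24) + 0.45 * private + 2.5 * placenta_praevia +
      0.6 * multiple)
  induction <- stats::runif(n) < ifelse(caesarean, 0.12, 0.30)

  # globally unique MRNs for mothers and infants
  total_ids <- n + sum(n_infants)
  mrn_pool <- sprintf("%07d", sample.int(8999999L, total_ids) + 1000000L)
  mother_mrn <- mrn_pool[seq_len(n)]

  ## ---- infants (one birth record per infant) -------------------------
  del_ix <- rep(seq_len(n), n_infants)
  m <- length(del_ix)
  birth_order <- sequence(n_infants)
  birth_record_id <- sprintf("B%06d", seq_len(m))
  infant_entity_id <- sprintf("I%06d", seq_len(m))
  infant_mrn <- mrn_pool[n + seq_len(m)]
  infant_sex <- ifelse(stats::runif(m) < 0.512, "M", "F")
  infant_given <- ifelse(infant_sex == "M", .pl_sample(.pl_given_m, m),
                         .pl_sample(.pl_given_f, m))
  infant_surname <- ifelse(stats::runif(m) < 0.97, mother_surname[del_ix],
                           .pl_sample(.pl_surnames, m, .pl_surname_wt))

  # stillbirth risk concentrated at low gestation: logit-shifted so the
  # marginal stays at stillbirth_rate (the shift has unit mean odds factor),
  # and the degenerate rates 0 and 1 are exact
  g_inf <- gestation[del_ix]
  z <- -(g_inf - 20) / 6 - log(sum(gd * exp(-(gweeks - 20) / 6)))
  p_still <- stats::plogis(stats::qlogis(params$stillbirth_rate) + z)
  stillbirth <- stats::runif(m) < p_still
  live_birth <- !stillbirth

  bw_mean <- c(350, 420, 500, 590, 690, 800, 920, 1060, 1220, 1400, 1600,
               1820, 2060, 2300, 2550, 2800, 3030, 3230, 3400, 3540, 3650,
               3720, 3760)[match(g_inf, gweeks)]
  bw_mean <- bw_mean - 150 * (n_infants[del_ix] > 1) * (g_inf >= 34)
  birthweight <- pmax(round(stats::rnorm(m, bw_mean, 0.12 * bw_mean) / 5) * 5, 150)

  apgar1_lt4 <- live_birth &
    (stats::runif(m) < stats::plogis(-4.2 + 0.35 * pmax(34 - g_inf, 0)))
  scn_nicu <- live_birth &
    (stats::runif(m) < ifelse(g_inf < 37, 0.8, 0.10 + 0.3 * apgar1_lt4))
  infant_death <- live_birth &
    (stats::runif(m) < stats::plogis(-6.5 + 0.5 * pmax(32 - g_inf, 0)))

  birth_records <- data.frame(
    birth_record_id = birth_record_id,
    delivery_id = delivery_id[del_ix],
    mother_entity_id = mother_entity_id[del_ix],
    infant_entity_id = infant_entity_id,
    mother_given_name = mother_given[del_ix],
    mother_surname = mother_surname[del_ix],
    mother_alias_surname = alias_surname[del_ix],
    mother_dob = mother_dob[del_ix],
    mother_sex = "F",
    mother_address = address[del_ix],
    mother_country_of_birth = country[del_ix],
    mother_mrn = mother_mrn[del_ix],
    hospital_code = hospital_code[del_ix],
    private_hospital = private[del_ix],
    infant_given_name = infant_given,
    infant_surname = infant_surname,
    infant_sex = infant_sex,
    infant_mrn = infant_mrn,
    birth_date = birth_date[del_ix],
    plurality_n = n_infants[del_ix],
    birth_order = birth_order,
    gestation_weeks = g_inf,
    birthweight_g = birthweight,
    live_birth = live_birth,
    maternal_age = floor(maternal_age[del_ix]),
    parity = parity[del_ix],
    smoking = smoking[del_ix],
    diabetes = diabetes[del_ix],
    hypertension = hypertension[del_ix],
    antenatal_ge15wk = antenatal_ge15wk[del_ix],
    married = married[del_ix],
    australian_born = australian_born[del_ix],
    seifa_quintile = seifa_quintile[del_ix],
    placenta_praevia = placenta_praevia[del_ix],
    placental_abruption = placental_abruption[del_ix],
    caesarean = caesarean[del_ix],
    induction = induction[del_ix],
    apgar1_lt4 = apgar1_lt4,
    scn_nicu = scn_nicu,
    infant_death = infant_death,
    stringsAsFactors = FALSE
  )

  ## ---- maternal delivery admissions ----------------------------------
  # delivery-level stillbirth composition for the Z37 outcome code
  any_still <- as.vector(tapply(stillbirth, del_ix, any))
  all_still <- as.vector(tapply(stillbirth, del_ix, all))
  z37 <- ifelse(n_infants == 1,
                ifelse(all_still, "Z37.1", "Z37.0"),
         ifelse(n_infants == 2,
                ifelse(all_still, "Z37.4", ifelse(any_still, "Z37.3", "Z37.2")),
                ifelse(all_still, "Z37.7", ifelse(any_still, "Z37.6", "Z37.5"))))

  has_mat_rec <- stats::runif(n) >= params$maternal_nonadmission_rate
  pick <- function(pool, k, prob = NULL) sample(pool, k, replace = TRUE, prob = prob)
  rb <- function(p) stats::runif(n) < p

  diag_outcome <- ifelse(rb(0.92), z37, "")
  diag_delivery <- ifelse(n_infants > 1, "O84",
                   ifelse(caesarean, "O82",
                          pick(c("O80", "O81", "O83"), n, c(0.8, 0.1, 0.1))))
  diag_delivery <- ifelse(rb(0.97), diag_delivery, "")
  diag_preterm <- ifelse(gestation < 37 & !caesarean & rb(0.6),
                         pick(c("O60.1", "O60.2", "O60.3"), n), "")
  diag_diab <- ifelse(diabetes,
                      pick(c("O24.4", "E11", "E10", "E13"), n,
                           c(0.6, 0.2, 0.1, 0.1)), "")
  diag_hyp <- ifelse(hypertension,
                     pick(c("O13", "O14.0", "O10.0", "O16"), n,
                          c(0.4, 0.3, 0.15, 0.15)), "")
  diag_praevia <- ifelse(placenta_praevia, "O44.1", "")
  diag_abrupt <- ifelse(placental_abruption, "O45.0", "")
  diag_short <- ifelse(gestation < 26, pick(c("O90.1", "O90.2", "O90.3"), n), "")

  proc_caes <- ifelse(caesarean & rb(0.97), "16520", "")
  proc_ind <- ifelse(induction & rb(0.9), "90465", "")
  proc_sut <- ifelse(!caesarean & rb(0.35), pick(c("16571", "16573", "90481"), n), "")
  proc_anal <- ifelse(rb(0.45), pick(c("92506", "92507"), n), "")
  proc_deliv <- ifelse(!caesarean & rb(0.5), pick(c("90467", "90468", "90469"), n), "")
  proc_other <- ifelse(rb(0.15), pick(c("90472", "90473", "90475"), n), "")

  # a designated delivery admission always carries at least one identifying
  # code (delivery diagnosis restored if all were omitted); only an explicit
  # coding gap makes it unidentifiable
  has_ident <- nzchar(diag_outcome) | nzchar(diag_delivery) |
    nzchar(diag_preterm) | nzchar(proc_caes) | nzchar(proc_ind) |
    nzchar(proc_sut) | nzchar(proc_anal) | nzchar(proc_deliv) |
    nzchar(proc_other)
  diag_delivery[!has_ident] <- ifelse(n_infants[!has_ident] > 1, "O84", "O80")

  gap <- rb(params$coding_gap_rate)
  join_codes <- function(parts) {
    apply(parts, 1, function(r) paste(r[nzchar(r)], collapse = ";"))
  }
  mat_diag <- join_codes(cbind(
    ifelse(gap, "", diag_outcome), ifelse(gap, "", diag_delivery),
    ifelse(gap, "", diag_preterm),
    diag_diab, diag_hyp, diag_praevia, diag_abrupt, diag_short))
  mat_proc <- join_codes(cbind(
    ifelse(gap, "", proc_caes), ifelse(gap, "", proc_ind),
    ifelse(gap, "", proc_sut), ifelse(gap, "", proc_anal),
    ifelse(gap, "", proc_deliv), ifelse(gap, "", proc_other)))

  mat_ids <- data.frame(
    given_name = mother_given, surname = mother_surname,
    alias_surname = alias_surname, dob = mother_dob, address = address,
    mrn = mother_mrn, private_hospital = private,
    stringsAsFactors = FALSE
  )
  mat_ids <- corrupt_identifiers(mat_ids, errors)

  maternal_hospital <- data.frame(
    record_id = sprintf("MH%06d", seq_len(n)),
    given_name = mat_ids$given_name,
    surname = mat_ids$surname,
    alias_surname = mat_ids$alias_surname,
    dob = mat_ids$dob,
    sex = "F",
    address = mat_ids$address,
    country_of_birth = country,
    hospital_code = hospital_code,
    private_hospital = private,
    mrn = mat_ids$mrn,
    admission_date = birth_date - pick(0:2, n, c(0.7, 0.2, 0.1)),
    separation_date = birth_date + pick(1:5, n, c(0.25, 0.3, 0.2, 0.15, 0.1)),
    age_days = NA_integer_,
    birthweight_g = NA_real_,
    source_of_referral = "home",
    admission_order = 1L,
    plurality_n = NA_integer_,
    birth_order = NA_integer_,
    diagnosis_codes = mat_diag,
    procedure_codes = mat_proc,
    is_birth_admission = TRUE,
    mother_entity_id = mother_entity_id,
    delivery_id = delivery_id,
    infant_entity_id = NA_character_,
    birth_record_id = NA_character_,
    stringsAsFactors = FALSE
  )[has_mat_rec, ]

  # antenatal (non-birth) maternal admissions
  extra_ix <- which(stats::runif(n) < params$other_admission_rate)
  if (length(extra_ix)) {
    k <- length(extra_ix)
    eids <- corrupt_identifiers(mat_ids[extra_ix, , drop = FALSE], errors)
    adm <- birth_date[extra_ix] - sample(30:220, k, replace = TRUE)
    extra_mat <- data.frame(
      record_id = sprintf("MH9%05d", seq_len(k)),
      given_name = eids$given_name, surname = eids$surname,
      alias_surname = eids$alias_surname, dob = eids$dob, sex = "F",
      address = eids$address, country_of_birth = country[extra_ix],
      hospital_code = hospital_code[extra_ix],
      private_hospital = private[extra_ix],
      mrn = eids$mrn,
      admission_date = adm,
      separation_date = adm + sample(0:3, k, replace = TRUE),
      age_days = NA_integer_, birthweight_g = NA_real_,
      source_of_referral = "home", admission_order = 1L,
      plurality_n = NA_integer_, birth_order = NA_integer_,
      diagnosis_codes = pick(c("O21.0", "O47.0", "Z34.0", "R10.4"), k),
      procedure_codes = "",
      is_birth_admission = FALSE,
      mother_entity_id = mother_entity_id[extra_ix],
      delivery_id = NA_character_,
      infant_entity_id = NA_character_, birth_record_id = NA_character_,
      stringsAsFactors = FALSE
    )
    maternal_hospital <- rbind(maternal_hospital, extra_mat)
  }
  rownames(maternal_hospital) <- NULL

  ## ---- infant birth admissions ---------------------------------------
  has_inf_rec <- ifelse(live_birth,
                        stats::runif(m) >= params$infant_record_missing_rate,
                        stats::runif(m) < params$stillbirth_misclassification_rate)

  rbm <- function(p) stats::runif(m) < p
  z38 <- ifelse(n_infants[del_ix] == 1,
                pick(c("Z38.0", "Z38.1", "Z38.2"), m, c(0.97, 0.02, 0.01)),
                pick(c("Z38.3", "Z38.6"), m, c(0.95, 0.05)))
  z38 <- ifelse(rbm(0.97), z38, "")
  p07 <- ifelse(g_inf <= 27, "P07.2", ifelse(g_inf <= 36, "P07.3", ""))
  p20 <- ifelse(apgar1_lt4, "P20.1", "")
  p22 <- ifelse(g_inf < 34 & rbm(0.4), "P22.0", "")
  p59 <- ifelse(rbm(0.15), "P59.9", "")
  inf_gap <- rbm(params$coding_gap_rate)
  bw_recorded <- rbm(0.96) & !inf_gap
  born_here <- rbm(0.88) & !inf_gap
  # guarantee identifiability of designated birth admissions: restore the
  # Z38 code when neither the referral nor birthweight + P-code route holds
  has_p <- nzchar(p07) | nzchar(p20) | nzchar(p22) | nzchar(p59)
  need_z38 <- !nzchar(z38) & !born_here & !(bw_recorded & has_p)
  z38[need_z38] <- ifelse(n_infants[del_ix][need_z38] > 1, "Z38.3", "Z38.0")
  inf_diag <- join_codes(cbind(ifelse(inf_gap, "", z38), p07, p20, p22, p59))

  inf_ids <- data.frame(
    given_name = ifelse(rbm(0.20), "", infant_given),  # not yet named
    surname = infant_surname, dob = birth_date[del_ix],
    address = address[del_ix], mrn = infant_mrn,
    private_hospital = private[del_ix], gestation_weeks = g_inf,
    stringsAsFactors = FALSE
  )
  inf_ids <- corrupt_identifiers(inf_ids, errors)

  adm_delay <- ifelse(rbm(0.9), 0L, 1L)
  infant_hospital <- data.frame(
    record_id = sprintf("IH%06d", seq_len(m)),
    given_name = inf_ids$given_name,
    surname = inf_ids$surname,
    alias_surname = NA_character_,
    dob = inf_ids$dob,
    sex = infant_sex,
    address = inf_ids$address,
    country_of_birth = "AUSTRALIA",
    hospital_code = hospital_code[del_ix],
    private_hospital = private[del_ix],
    mrn = inf_ids$mrn,
    admission_date = birth_date[del_ix] + adm_delay,
    separation_date = birth_date[del_ix] + adm_delay +
      pmax(sample(1:8, m, replace = TRUE), ifelse(g_inf < 34, 14L, 1L)),
    age_days = adm_delay,
    birthweight_g = ifelse(bw_recorded, birthweight, NA_real_),
    source_of_referral = ifelse(born_here, "born in hospital", "other"),
    admission_order = 1L,
    plurality_n = n_infants[del_ix],
    birth_order = birth_order,
    diagnosis_codes = inf_diag,
    procedure_codes = "",
    is_birth_admission = TRUE,
    mother_entity_id = mother_entity_id[del_ix],
    delivery_id = delivery_id[del_ix],
    infant_entity_id = infant_entity_id,
    birth_record_id = birth_record_id,
    gestation_weeks = g_inf,
    stringsAsFactors = FALSE
  )[has_inf_rec, ]

  # infant readmissions (not birth admissions)
  re_ix <- which(live_birth & stats::runif(m) < params$other_admission_rate * 0.5)
  if (length(re_ix)) {
    k <- length(re_ix)
    rids <- corrupt_identifiers(inf_ids[re_ix, , drop = FALSE], errors)
    delay <- sample(7:90, k, replace = TRUE)
    re_inf <- data.frame(
      record_id = sprintf("IH9%05d", seq_len(k)),
      given_name = rids$given_name, surname = rids$surname,
      alias_surname = NA_character_, dob = rids$dob,
      sex = infant_sex[re_ix], address = rids$address,
      country_of_birth = "AUSTRALIA",
      hospital_code = hospital_code[del_ix][re_ix],
      private_hospital = private[del_ix][re_ix],
      mrn = rids$mrn,
      admission_date = birth_date[del_ix][re_ix] + delay,
      separation_date = birth_date[del_ix][re_ix] + delay +
        sample(1:4, k, replace = TRUE),
      age_days = delay,
      birthweight_g = NA_real_,
      source_of_referral = "emergency",
      admission_order = 2L,
      plurality_n = n_infants[del_ix][re_ix],
      birth_order = birth_order[re_ix],
      diagnosis_codes = pick(c("J21.9", "A09", "B34.9"), k),
      procedure_codes = "",
      is_birth_admission = FALSE,
      mother_entity_id = mother_entity_id[del_ix][re_ix],
      delivery_id = NA_character_,
      infant_entity_id = infant_entity_id[re_ix],
      birth_record_id = NA_character_,
      gestation_weeks = g_inf[re_ix],
      stringsAsFactors = FALSE
    )
    infant_hospital <- rbind(infant_hospital, re_inf)
  }
  rownames(infant_hospital) <- NULL

  ## ---- ground truth ---------------------------------------------------
  mat_birth <- maternal_hospital[maternal_hospital$is_birth_admission, ]
  inf_birth <- infant_hospital[infant_hospital$is_birth_admission, ]
  ground_truth <- list(
    mother_pairs = data.frame(
      delivery_id = mat_birth$delivery_id,
      hospital_record_id = mat_birth$record_id,
      stringsAsFactors = FALSE
    ),
    infant_pairs = data.frame(
      birth_record_id = inf_birth$birth_record_id,
      hospital_record_id = inf_birth$record_id,
      stringsAsFactors = FALSE
    )
  )

  structure(list(
    birth_records = birth_records,
    maternal_hospital = maternal_hospital,
    infant_hospital = infant_hospital,
    ground_truth = ground_truth,
    params = params,
    errors = errors
  ), class = "perilink_cohort")
}

#' @export
print.perilink_cohort <- function(x, ...) {
  cat("<perilink_cohort>\n")
  cat("  deliveries:        ", x$params$n_deliveries, "\n")
  cat("  birth records:     ", nrow(x$birth_records),
      sprintf(" (%d stillbirths)", sum(!x$birth_records$live_birth)), "\n")
  cat("  maternal hospital: ", nrow(x$maternal_hospital),
      sprintf(" (%d birth admissions)", sum(x$maternal_hospital$is_birth_admission)), "\n")
  cat("  infant hospital:   ", nrow(x$infant_hospital),
      sprintf(" (%d birth admissions)", sum(x$infant_hospital$is_birth_admission)), "\n")
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `birth_records.csv`, `maternal_hospital.csv`,
#' `infant_hospital.csv` and `ground_truth_pairs.csv` (both pair tables
#' stacked with a `role` column) into `dir`. Output is deterministic:
#' regenerating with the same seed produces byte-identical files.
#'
#' @param cohort a `perilink_cohort`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "perilink_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gt <- rbind(
    data.frame(role = "mother",
               key_id = cohort$ground_truth$mother_pairs$delivery_id,
               hospital_record_id = cohort$ground_truth$mother_pairs$hospital_record_id),
    data.frame(role = "infant",
               key_id = cohort$ground_truth$infant_pairs$birth_record_id,
               hospital_record_id = cohort$ground_truth$infant_pairs$hospital_record_id)
  )
  paths <- file.path(dir, c("birth_records.csv", "maternal_hospital.csv",
                            "infant_hospital.csv", "ground_truth_pairs.csv"))
  utils::write.csv(cohort$birth_records, paths[1], row.names = FALSE)
  utils::write.csv(cohort$maternal_hospital, paths[2], row.names = FALSE)
  utils::write.csv(cohort$infant_hospital, paths[3], row.names = FALSE)
  utils::write.csv(gt, paths[4], row.names = FALSE)
  invisible(paths)
}
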