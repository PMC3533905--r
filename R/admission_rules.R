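#' Identify hospital birth admissions and derive clinical variables
#'
#' Rule-based identification of birth-related hospital admissions from
#' coded records, independently of the birth registration. Infant birth
#' admissions require an age of 0-1 days plus evidence of a birth in
#' hospital (a Z38 liveborn code, a born-in-hospital source of referral, or
#' a recorded birthweight together with a perinatal-period P code), and
#' must be the infant's first admission. Maternal delivery admissions
#' require any of the delivery diagnosis or procedure codes (O80-O84, Z37,
#' O60.1-O60.3 and the associated ACHI delivery, suture, analgesia and
#' induction procedure codes).
#'
#' @param rec data.frame of hospital records with columns `age_days`,
#'   `diagnosis_codes`, `procedure_codes` (";"-separated),
#'   `source_of_referral`, `birthweight_g`, `admission_order`.
#' @param vocab code vocabulary from [load_code_vocabulary()].
#' @return logical vector, one flag per record.
#' @seealso [derive_variables()], [classify_plurality_stillbirth()]
#' @export
identify_infant_birth_admission <- function(rec, vocab = load_code_vocabulary()) {
  stopifnot(is.data.frame(rec))
  age_ok <- !is.na(rec$age_days) & rec$age_days %in% vocab$infant$age_days
  z38 <- code_matches(rec$diagnosis_codes, vocab$infant$liveborn)
  born_here <- !is.na(rec$source_of_referral) &
    normalize_text(rec$source_of_referral) == "BORN IN HOSPITAL"
  pcode <- code_matches(rec$diagnosis_codes, vocab$infant$perinatal)
  bw <- !is.na(rec$birthweight_g)
  first <- if ("admission_order" %in% names(rec)) {
    !is.na(rec$admission_order) & rec$admission_order == 1L
  } else rep(TRUE, nrow(rec))
  age_ok & first & (z38 | born_here | (bw & pcode))
}

#' @rdname identify_infant_birth_admission
#' @export
identify_maternal_delivery_admission <- function(rec, vocab = load_code_vocabulary()) {
  stopifnot(is.data.frame(rec))
  code_matches(rec$diagnosis_codes, vocab$maternal,
               procedure_codes = rec$procedure_codes)
}

#' Cross-record constraints between a birth record and a hospital record
#'
#' Role-specific date and hospital checks applied to already-linked or
#' candidate pairs. For infants the admission date must fall within one
#' calendar day of the date of birth; for mothers the date of birth must
#' fall within the admission-to-separation interval. Both roles require
#' the hospital of birth to match on the normalized hospital code.
#' Rows with missing dates fail the check (with a message giving the count).
#'
#' @param birth data.frame with columns `birth_date` and `hospital_code`
#'   (one row per pair, aligned with `rec`).
#' @param rec data.frame with `admission_date`, `separation_date`
#'   (mother role only) and `hospital_code`, aligned with `birth`.
#' @param role `"mother"` or `"infant"`.
#' @return logical vector, one flag per pair.
#' @export
check_link_constraints <- function(birth, rec, role = c("mother", "infant")) {
  role <- match.arg(role)
  stopifnot(nrow(birth) == nrow(rec))
  bd <- as.Date(birth$birth_date)
  ad <- as.Date(rec$admission_date)
  hosp_ok <- !is.na(birth$hospital_code) & !is.na(rec$hospital_code) &
    toupper(trimws(birth$hospital_code)) == toupper(trimws(rec$hospital_code))
  if (role == "infant") {
    dated <- !is.na(bd) & !is.na(ad)
    ok <- dated & abs(as.integer(ad - bd)) <= 1L & hosp_ok
  } else {
    sd <- as.Date(rec$separation_date)
    dated <- !is.na(bd) & !is.na(ad) & !is.na(sd)
    ok <- dated & ad <= bd & bd <= sd & hosp_ok
  }
  if (any(!dated)) message(sum(!dated), " pair(s) rejected for missing dates")
  ok
}

#' Derive clinical variable flags from diagnosis/procedure codes
#'
#' Applies the variable code lists (preterm, Apgar1 < 4, diabetes,
#' hypertension, induction, caesarean section, placenta praevia, placental
#' abruption, duration of pregnancy below threshold) to coded hospital
#' records. Records with no matching codes get `FALSE` for every flag.
#'
#' @inheritParams identify_infant_birth_admission
#' @return data.frame of logical columns, one per variable rule.
#' @export
derive_variables <- function(rec, vocab = load_code_vocabulary()) {
  stopifnot(is.data.frame(rec))
  out <- lapply(vocab$variables, function(cl)
    code_matches(rec$diagnosis_codes, cl, procedure_codes = rec$procedure_codes))
  as.data.frame(out, optional = TRUE)
}

#' Classify plurality and birth status from admission codes
#'
#' Plurality is singleton for Z37.0-Z37.1 / Z38.0-Z38.2 / O80-O83, multiple
#' for Z37.2-Z37.7 / Z38.3-Z38.8 / O84; conflicting or absent evidence is
#' reported as "unclassifiable", never silently defaulted. Birth status is
#' stillbirth when any stillbirth outcome code (Z37.1, Z37.3, Z37.4, Z37.6,
#' Z37.7) is present, livebirth when a liveborn outcome (Z38, or Z37.0 /
#' Z37.2 / Z37.5) is present without stillbirth evidence, otherwise
#' unclassifiable.
#'
#' @inheritParams identify_infant_birth_admission
#' @return data.frame with character columns `plurality`
#'   (singleton/multiple/unclassifiable) and `birth_status`
#'   (livebirth/stillbirth/unclassifiable).
#' @export
classify_plurality_stillbirth <- function(rec, vocab = load_code_vocabulary()) {
  stopifnot(is.data.frame(rec))
  singleton <- code_matches(rec$diagnosis_codes, vocab$plurality$singleton)
  multiple <- code_matches(rec$diagnosis_codes, vocab$plurality$multiple)
  still <- code_matches(rec$diagnosis_codes, vocab$stillbirth)
  live_cl <- code_list("liveborn", diagnosis = c("Z38", "Z37.0", "Z37.2", "Z37.5"))
  live <- code_matches(rec$diagnosis_codes, live_cl)

  plurality <- rep("unclassifiable", nrow(rec))
  plurality[singleton & !multiple] <- "singleton"
  plurality[multiple & !singleton] <- "multiple"

  birth_status <- rep("unclassifiable", nrow(rec))
  birth_status[live & !still] <- "livebirth"
  birth_status[still] <- "stillbirth"

  data.frame(plurality = plurality, birth_status = birth_status)
}
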