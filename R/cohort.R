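#' Cohort generation parameters
#'
#' Parameters of the synthetic perinatal cohort: the number of deliveries,
#' the proportion of multiple pregnancies, the per-infant stillbirth rate,
#' the proportion of births in private hospitals, and the distribution of
#' gestational age over completed weeks 20-42. Additional rates control
#' record availability: the fraction of deliveries without a maternal
#' admission record, the fraction of live births without an infant
#' admission record, the rate at which a stillbirth nonetheless generates
#' an infant admission (misclassification near the border of viability),
#' the rate of non-birth admissions added to each stream, and the rate at
#' which birth-identifying codes are omitted from an otherwise valid
#' admission (coding gaps, which produce unidentifiable records).
#'
#' @param n_deliveries positive number of deliveries.
#' @param multiple_pregnancy_rate proportion of deliveries that are
#'   multiple pregnancies (twins or triplets).
#' @param stillbirth_rate marginal per-infant stillbirth proportion;
#'   stillbirth risk is concentrated at low gestational ages but averages
#'   to this rate.
#' @param private_hospital_rate proportion of deliveries in private
#'   hospitals.
#' @param gestation_distribution named numeric vector of probabilities over
#'   completed weeks "20".."42"; must sum to 1.
#' @param maternal_nonadmission_rate fraction of deliveries without a
#'   maternal admission record.
#' @param infant_record_missing_rate fraction of live births without an
#'   infant admission record.
#' @param stillbirth_misclassification_rate fraction of stillbirths that
#'   nonetheless generate an infant admission coded as liveborn.
#' @param other_admission_rate rate of non-birth admissions per mother
#'   (infant readmissions occur at half this rate).
#' @param coding_gap_rate fraction of true birth admissions lacking all
#'   identifying codes.
#' @param seed integer RNG seed.
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(n_deliveries,
                          multiple_pregnancy_rate = 0.016,
                          stillbirth_rate = 0.006,
                          private_hospital_rate = 0.25,
                          gestation_distribution = default_gestation_distribution(),
                          maternal_nonadmission_rate = 0.004,
                          infant_record_missing_rate = 0.012,
                          stillbirth_misclassification_rate = 0.015,
                          other_admission_rate = 0.06,
                          coding_gap_rate = 0.002,
                          seed = 1L) {
  if (length(n_deliveries) != 1 || is.na(n_deliveries) || n_deliveries < 1)
    stop("n_deliveries must be a positive count")
  props <- c(multiple_pregnancy_rate, stillbirth_rate, private_hospital_rate,
             maternal_nonadmission_rate, infant_record_missing_rate,
             stillbirth_misclassification_rate, other_admission_rate,
             coding_gap_rate)
  if (any(is.na(props)) || any(props < 0) || any(props > 1))
    stop("all proportions must lie in [0, 1]")
  gd <- gestation_distribution
  if (is.null(names(gd)) || !setequal(names(gd), as.character(20:42)))
    stop("gestation_distribution must be named over weeks 20-42")
  if (abs(sum(gd) - 1) > 1e-8) stop("gestation_distribution must sum to 1")
  structure(list(
    n_deliveries = as.integer(n_deliveries),
    multiple_pregnancy_rate = multiple_pregnancy_rate,
    stillbirth_rate = stillbirth_rate,
    private_hospital_rate = private_hospital_rate,
    gestation_distribution = gd[as.character(20:42)],
    maternal_nonadmission_rate = maternal_nonadmission_rate,
    infant_record_missing_rate = infant_record_missing_rate,
    stillbirth_misclassification_rate = stillbirth_misclassification_rate,
    other_admission_rate = other_admission_rate,
    coding_gap_rate = coding_gap_rate,
    seed = as.integer(seed)
  ), class = "cohort_params")
}

#' @rdname cohort_params
#' @export
default_gestation_distribution <- function() {
  p <- c(rep(0.000625, 8),        # 20-27 weeks
         rep(0.00175, 4),         # 28-31
         rep(0.012, 5),           # 32-36
         0.062, 0.172, 0.286, 0.300, 0.110, 0.012)  # 37-42
  names(p) <- as.character(20:42)
  p / sum(p)
}

#' Identifier error model
#'
#' Per-field corruption rates applied to hospital-side identifier copies:
#' typographical errors (single-character substitution or transposition) in
#' names, address and MRN; name-field blanking with separate rates for
#' public and private hospitals (name collection is discretionary in
#' private hospitals, so their records carry much more missing name
#' information); adjacent-digit swaps in the date of birth; substitution of
#' a recorded alias (e.g. maiden name) for the surname; and wholesale
#' address change (the family moved between registration and admission).
#' Optionally, name missingness increases linearly below a gestational-age
#' knot, emulating the poorer identifier quality of very preterm and
#' peri-viable admissions.
#'
#' @param typo_rate per-field typo proportion.
#' @param name_missing_rate_public,name_missing_rate_private per-field name
#'   blanking proportions; private must be >= public.
#' @param dob_digit_swap_rate,alias_rate,address_change_rate proportions.
#' @param gestation_missing_knot completed week below which name
#'   missingness increases (NULL disables the gradient).
#' @param gestation_missing_max additional missingness reached at 20 weeks.
#' @return an object of class `error_model`.
#' @export
error_model <- function(typo_rate = 0.02,
                        name_missing_rate_public = 0.03,
                        name_missing_rate_private = 0.35,
                        dob_digit_swap_rate = 0.005,
                        alias_rate = 0.03,
                        address_change_rate = 0.10,
                        gestation_missing_knot = 30,
                        gestation_missing_max = 0.35) {
  rates <- c(typo_rate, name_missing_rate_public, name_missing_rate_private,
             dob_digit_swap_rate, alias_rate, address_change_rate)
  if (any(is.na(rates)) || any(rates < 0) || any(rates > 1))
    stop("all error rates must lie in [0, 1]")
  if (name_missing_rate_private < name_missing_rate_public)
    stop("private-hospital name missingness must be >= public")
  structure(list(
    typo_rate = typo_rate,
    name_missing_rate_public = name_missing_rate_public,
    name_missing_rate_private = name_missing_rate_private,
    dob_digit_swap_rate = dob_digit_swap_rate,
    alias_rate = alias_rate,
    address_change_rate = address_change_rate,
    gestation_missing_knot = gestation_missing_knot,
    gestation_missing_max = gestation_missing_max
  ), class = "error_model")
}

#' @rdname error_model
#' @export
zero_error_model <- function() {
  error_model(0, 0, 0, 0, 0, 0, gestation_missing_knot = NULL,
              gestation_missing_max = 0)
}

.typo_one <- function(s) {
  n <- nchar(s)
  i <- sample.int(max(n, 1), 1)
  ci <- substr(s, i, i)
  if (n >= 2 && stats::runif(1) < 0.5 && i < n &&
      ci != substr(s, i + 1, i + 1)) {
    # transpose adjacent (distinct) characters
    paste0(substr(s, 1, i - 1), substr(s, i + 1, i + 1), ci,
           substr(s, i + 2, n))
  } else {
    # substitute a different character
    pool <- setdiff(c(LETTERS, 0:9), toupper(ci))
    paste0(substr(s, 1, i - 1), sample(pool, 1), substr(s, i + 1, n))
  }
}

.swap_dob_digits <- function(d) {
  # calendar-valid date perturbation: day/month transposition when valid,
  # otherwise day-digit swap, otherwise day +/- 1
  dt <- as.POSIXlt(d)
  day <- dt$mday; mon <- dt$mon + 1L
  cand <- if (day <= 12 && day != mon) {
    as.Date(sprintf("%04d-%02d-%02d", dt$year + 1900L, day, mon),
            format = "%Y-%m-%d")
  } else NA
  if (is.na(cand)) {
    swapped <- as.integer(paste0(day %% 10, day %/% 10))
    cand <- as.Date(sprintf("%04d-%02d-%02d", dt$year + 1900L, mon, swapped),
                    format = "%Y-%m-%d")
  }
  if (is.na(cand) || cand == d) cand <- d + sample(c(-1L, 1L), 1)
  cand
}

#' Corrupt identifier fields according to an error model
#'
#' Returns a copy of the identifier table with independent per-field
#' perturbations: character substitution/transposition in names, address
#' and MRN; blanking of name fields (rate chosen per record by
#' `private_hospital`, plus the gestational gradient when `gestation_weeks`
#' is present); adjacent-digit swaps in `dob`; substitution of
#' `alias_surname` for `surname`; and replacement of `address`. Entity-id
#' and all non-identifier columns are never altered. An all-zero model
#' returns the input unchanged.
#'
#' @param ids data.frame with identifier columns (`given_name`, `surname`,
#'   `alias_surname`, `dob`, `address`, `mrn`) plus optional context
#'   columns `private_hospital` (logical) and `gestation_weeks`.
#' @param errors an [error_model()].
#' @param seed optional integer; when supplied the RNG is seeded before
#'   corruption for standalone reproducibility.
#' @return data.frame of the same shape with corrupted identifier fields.
#' @export
corrupt_identifiers <- function(ids, errors, seed = NULL) {
  stopifnot(is.data.frame(ids), inherits(errors, "error_model"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- as.data.frame(ids)
  n <- nrow(out)
  if (n == 0) return(out)

  draw <- function(rate) stats::runif(n) < rate

  # alias substitution happens before typos so an alias can itself be typoed
  if (all(c("surname", "alias_surname") %in% names(out)) && errors$alias_rate > 0) {
    hit <- draw(errors$alias_rate) & !is.na(out$alias_surname) &
      nzchar(out$alias_surname)
    out$surname[hit] <- out$alias_surname[hit]
  }

  for (fld in intersect(c("given_name", "surname", "address", "mrn"), names(out))) {
    if (errors$typo_rate > 0) {
      hit <- which(draw(errors$typo_rate) & !is.na(out[[fld]]) & nzchar(out[[fld]]))
      if (length(hit))
        out[[fld]][hit] <- vapply(out[[fld]][hit], .typo_one, character(1),
                                  USE.NAMES = FALSE)
    }
  }

  miss_rate <- rep(errors$name_missing_rate_public, n)
  if ("private_hospital" %in% names(out))
    miss_rate[isTRUE_vec(out$private_hospital)] <- errors$name_missing_rate_private
  if (!is.null(errors$gestation_missing_knot) && "gestation_weeks" %in% names(out)) {
    gw <- out$gestation_weeks
    knot <- errors$gestation_missing_knot
    frac <- pmin(pmax((knot - gw) / (knot - 20), 0), 1)
    frac[is.na(frac)] <- 0
    miss_rate <- pmin(miss_rate + errors$gestation_missing_max * frac, 0.95)
  }
  for (fld in intersect(c("given_name", "surname"), names(out))) {
    hit <- stats::runif(n) < miss_rate
    out[[fld]][hit] <- ""
  }

  if ("dob" %in% names(out) && errors$dob_digit_swap_rate > 0) {
    dob <- as.Date(out$dob)
    hit <- which(draw(errors$dob_digit_swap_rate) & !is.na(dob))
    for (i in hit) dob[i] <- .swap_dob_digits(dob[i])
    out$dob <- dob
  }

  if ("address" %in% names(out) && errors$address_change_rate > 0) {
    hit <- which(draw(errors$address_change_rate) & !is.na(out$address))
    if (length(hit)) out$address[hit] <- .pl_new_address(length(hit))
  }
  out
}

isTRUE_vec <- function(x) !is.na(x) & x
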