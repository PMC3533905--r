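#' Link one record stream pair with blocking, scoring and assignment
#'
#' Runs the full engine on one stream pair: candidate generation by
#' blocking, clue evaluation, maximum-entropy weight fitting on a labeled
#' training split, threshold tuning on the same split, scoring and
#' classification of all candidates, and one-to-one assignment resolution
#' with the chosen review policy. When stratum columns are supplied
#' (singleton vs multiple pregnancies), pairs crossing strata are removed
#' before scoring and assignment is resolved within each stratum, so the
#' strata never compete for links.
#'
#' @param stream_a,stream_b standardized record tables with `record_id`.
#' @param truth_pairs data.frame `id_a`, `id_b` of ground-truth pairs
#'   (used for training labels, threshold tuning and the oracle policy).
#' @param clues clue list (see [default_clue_set()]).
#' @param blocking a [blocking_spec()].
#' @param stratum_a,stratum_b optional character vectors aligned with the
#'   streams assigning each record to a linkage stratum.
#' @param train_fraction fraction of candidate pairs used to fit weights
#'   and tune thresholds.
#' @param thresholds fixed [threshold_config()]; if NULL, tuned with
#'   [tune_thresholds()].
#' @param target_missed_per_1000,target_false_per_1000 tuning targets.
#' @param review_policy passed to [resolve_assignments()].
#' @return list with `pairs` (scored, classified candidates), `model`,
#'   `thresholds`, `link_map`, and `blocking_missed` (true pairs with both
#'   records present that no blocking key captured).
#' @export
link_stream <- function(stream_a, stream_b, truth_pairs,
                        clues, blocking,
                        stratum_a = NULL, stratum_b = NULL,
                        train_fraction = 0.5,
                        thresholds = NULL,
                        target_missed_per_1000 = 1,
                        target_false_per_1000 = 2,
                        review_policy = c("oracle", "reject")) {
  review_policy <- match.arg(review_policy)
  pairs <- make_blocks(stream_a, stream_b, blocking)
  oversized_dropped <- attr(pairs, "oversized_dropped")

  if (!is.null(stratum_a)) {
    sa <- stratum_a[match(pairs$id_a, stream_a$record_id)]
    sb <- stratum_b[match(pairs$id_b, stream_b$record_id)]
    pairs <- pairs[sa == sb, , drop = FALSE]
  }

  tkey <- paste(truth_pairs$id_a, truth_pairs$id_b, sep = "\r")
  pkey <- paste(pairs$id_a, pairs$id_b, sep = "\r")
  in_scope <- truth_pairs$id_a %in% stream_a$record_id &
    truth_pairs$id_b %in% stream_b$record_id
  blocking_missed <- sum(in_scope & !tkey %in% pkey)

  outcomes <- evaluate_clues(pairs, stream_a, stream_b, clues)
  labels <- pkey %in% tkey

  train <- stats::runif(nrow(pairs)) < train_fraction
  if (length(unique(labels[train])) < 2) train <- rep(TRUE, nrow(pairs))
  model <- fit_maxent_weights(outcomes[train, , drop = FALSE], labels[train])
  scores <- score_pairs(outcomes, model)
  if (is.null(thresholds)) {
    thresholds <- tune_thresholds(scores[train], labels[train],
                                  target_missed_per_1000,
                                  target_false_per_1000)
  }
  pairs$probability <- scores
  pairs$decision <- classify(scores, thresholds)
  pairs$label <- labels

  strata <- if (is.null(stratum_a)) rep("all", nrow(pairs)) else
    stratum_a[match(pairs$id_a, stream_a$record_id)]
  link_map <- do.call(rbind, lapply(split(pairs, strata), function(p)
    resolve_assignments(p, review_policy, truth_pairs)))
  rownames(link_map) <- NULL

  list(pairs = pairs, model = model, thresholds = thresholds,
       link_map = link_map, blocking_missed = blocking_missed,
       oversized_dropped = oversized_dropped)
}

#' Default blocking keys for the perinatal streams
#'
#' Union of four keys: hospital + MRN (the administrative identifier),
#' surname Soundex + full date of birth, full date of birth alone, and
#' surname Soundex + hospital (which still captures pairs whose date of
#' birth was mis-keyed). On error-free records every true pair shares the
#' hospital + MRN key, so blocking is sound by construction.
#'
#' @param max_block_size maximum pairs per block.
#' @return a [blocking_spec()].
#' @export
default_blocking_spec <- function(max_block_size = 1000) {
  blocking_spec(list(
    c("hospital_code_norm", "mrn_norm"),
    c("surname_soundex", "dob"),
    "dob",
    c("surname_soundex", "hospital_code_norm")
  ), max_block_size = max_block_size)
}

.mother_stream_a <- function(birth_records) {
  deliv <- birth_records[!duplicated(birth_records$delivery_id), ]
  normalize_identifiers(data.frame(
    record_id = deliv$delivery_id,
    given_name = deliv$mother_given_name,
    surname = deliv$mother_surname,
    alias_surname = deliv$mother_alias_surname,
    dob = deliv$mother_dob,
    sex = deliv$mother_sex,
    address = deliv$mother_address,
    country_of_birth = deliv$mother_country_of_birth,
    hospital_code = deliv$hospital_code,
    mrn = deliv$mother_mrn,
    birth_date = deliv$birth_date,
    plurality_n = deliv$plurality_n,
    stringsAsFactors = FALSE
  ))
}

.infant_stream_a <- function(birth_records) {
  normalize_identifiers(data.frame(
    record_id = birth_records$birth_record_id,
    given_name = birth_records$infant_given_name,
    surname = birth_records$infant_surname,
    dob = birth_records$birth_date,
    sex = birth_records$infant_sex,
    address = birth_records$mother_address,
    hospital_code = birth_records$hospital_code,
    mrn = birth_records$infant_mrn,
    birth_date = birth_records$birth_date,
    plurality_n = birth_records$plurality_n,
    birth_order = birth_records$birth_order,
    stringsAsFactors = FALSE
  ))
}

#' Run the full perinatal linkage pipeline on a synthetic cohort
#'
#' Identifies birth admissions in both hospital streams with the
#' ICD-10-AM/ACHI rules, links mothers (birth registration vs maternal
#' delivery admissions, at delivery level) and infants (birth registration
#' vs infant birth admissions) with separate singleton/multiple passes,
#' assigns linkage groups, and computes rate tables, identification
#' coverage and ground-truth quality metrics.
#'
#' @param cohort a `perilink_cohort` from [generate_cohort()].
#' @param vocab code vocabulary.
#' @param blocking a [blocking_spec()].
#' @param train_fraction labeled fraction used for weight fitting and
#'   threshold tuning.
#' @param thresholds fixed thresholds, or NULL to tune.
#' @param target_missed_per_1000,target_false_per_1000 tuning targets.
#' @param review_policy review-band policy (see [resolve_assignments()]).
#' @param seed integer seed fixing the training split.
#' @return object of class `perilink_linkage`: list with per-stream engine
#'   results (`mother`, `infant`), the stratified `groups` table, the
#'   `rate_table`, `coverage`, and `quality` (per stream and `overall`).
#' @export
run_linkage <- function(cohort,
                        vocab = load_code_vocabulary(),
                        blocking = default_blocking_spec(),
                        train_fraction = 0.5,
                        thresholds = NULL,
                        target_missed_per_1000 = 1,
                        target_false_per_1000 = 2,
                        review_policy = c("oracle", "reject"),
                        seed = 1L) {
  review_policy <- match.arg(review_policy)
  stopifnot(inherits(cohort, "perilink_cohort"))
  set.seed(as.integer(seed))

  ## identification from the hospital streams alone
  mh <- cohort$maternal_hospital
  ih <- cohort$infant_hospital
  mat_id <- identify_maternal_delivery_admission(mh, vocab)
  inf_id <- identify_infant_birth_admission(ih, vocab)
  identified <- list(maternal = mh[mat_id, , drop = FALSE],
                     infant = ih[inf_id, , drop = FALSE])
  # stratum labels for the unlinked hospital groups and the linkage passes
  mat_cls <- classify_plurality_stillbirth(identified$maternal, vocab)
  inf_cls <- classify_plurality_stillbirth(identified$infant, vocab)
  identified$maternal$stratum <- ifelse(
    mat_cls$plurality == "unclassifiable" | mat_cls$birth_status == "unclassifiable",
    "unknown", paste(mat_cls$birth_status, mat_cls$plurality, sep = "_"))
  identified$infant$stratum <- ifelse(
    inf_cls$plurality == "unclassifiable", "unknown",
    paste("livebirth", inf_cls$plurality, sep = "_"))

  ## mother stream (delivery level)
  a_m <- .mother_stream_a(cohort$birth_records)
  b_m <- normalize_identifiers(identified$maternal)
  b_m$record_id <- identified$maternal$record_id
  # singleton/multiple pass labels; unclassifiable admissions take the
  # majority (singleton) pass so no record competes in both
  strat_a_m <- ifelse(a_m$plurality_n > 1, "multiple", "singleton")
  strat_b_m <- ifelse(mat_cls$plurality == "multiple", "multiple", "singleton")
  truth_m <- data.frame(id_a = cohort$ground_truth$mother_pairs$delivery_id,
                        id_b = cohort$ground_truth$mother_pairs$hospital_record_id)
  mother <- link_stream(a_m, b_m, truth_m, default_clue_set("mother"),
                        blocking, strat_a_m, strat_b_m, train_fraction,
                        thresholds, target_missed_per_1000,
                        target_false_per_1000, review_policy)

  ## infant stream (birth-record level)
  a_i <- .infant_stream_a(cohort$birth_records)
  b_i <- normalize_identifiers(identified$infant)
  b_i$record_id <- identified$infant$record_id
  strat_a_i <- ifelse(a_i$plurality_n > 1, "multiple", "singleton")
  strat_b_i <- ifelse(!is.na(identified$infant$plurality_n) &
                        identified$infant$plurality_n > 1,
                      "multiple", "singleton")
  truth_i <- data.frame(id_a = cohort$ground_truth$infant_pairs$birth_record_id,
                        id_b = cohort$ground_truth$infant_pairs$hospital_record_id)
  infant <- link_stream(a_i, b_i, truth_i, default_clue_set("infant"),
                        blocking, strat_a_i, strat_b_i, train_fraction,
                        thresholds, target_missed_per_1000,
                        target_false_per_1000, review_policy)

  ## groups, rates, coverage, quality
  groups <- stratify(assign_groups(cohort$birth_records, mother$link_map,
                                   infant$link_map, identified))
  rate_table <- linkage_rate_table(groups)
  coverage <- identification_coverage(identified, cohort$birth_records)

  scope <- function(truth, a, b)
    truth[truth$id_a %in% a$record_id & truth$id_b %in% b$record_id, ]
  q_m <- evaluate_quality(mother$link_map, scope(truth_m, a_m, b_m))
  q_i <- evaluate_quality(infant$link_map, scope(truth_i, a_i, b_i))
  q_all <- evaluate_quality(
    rbind(mother$link_map[, c("id_a", "id_b")],
          infant$link_map[, c("id_a", "id_b")]),
    rbind(scope(truth_m, a_m, b_m), scope(truth_i, a_i, b_i)))

  structure(list(
    mother = mother, infant = infant,
    identified = identified,
    groups = groups, rate_table = rate_table, coverage = coverage,
    quality = list(mother = q_m, infant = q_i, overall = q_all)
  ), class = "perilink_linkage")
}

#' @export
print.perilink_linkage <- function(x, ...) {
  cat("<perilink_linkage>\n")
  cat("groups:\n")
  print(table(x$groups$birth_groups$group))
  cat("\noverall quality:\n")
  print(x$quality$overall)
  invisible(x)
}
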