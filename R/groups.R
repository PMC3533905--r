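#' Assign birth records to linkage groups
#'
#' Combines the two one-to-one link maps with the identified birth
#' admissions to place every birth record in one of four mutually
#' exclusive, exhaustive groups: `complete` (both the mother's and the
#' infant's hospital birth-admission record linked), `mothers_only`,
#' `infants_only`, or `unlinked_birth` (neither). Identified hospital
#' birth admissions that linked to no birth record form the two residual
#' groups `unlinked_maternal_hospital` and `unlinked_infant_hospital`.
#'
#' The mother-side link operates at delivery level (multiples share one
#' maternal admission), so the map is keyed by `delivery_id`; group
#' assignment is still per birth record, and one delivery can contribute
#' records to different groups through its infants.
#'
#' @param birth_records birth registration table (needs `birth_record_id`,
#'   `delivery_id`, `plurality_n`, `live_birth`).
#' @param mother_links data.frame `id_a` (delivery_id), `id_b` (maternal
#'   hospital record id).
#' @param infant_links data.frame `id_a` (birth_record_id), `id_b` (infant
#'   hospital record id).
#' @param identified list with data.frames `maternal` and `infant`: the
#'   rule-identified birth admissions (need `record_id`).
#' @return object of class `linkage_group_table`: list with `birth_groups`
#'   (per birth record: group, stratum fields, linked record ids),
#'   `unlinked_maternal`, `unlinked_infant` (the residual admission sets).
#' @export
assign_groups <- function(birth_records, mother_links, infant_links,
                          identified) {
  stopifnot(is.data.frame(birth_records))
  if (nrow(mother_links) &&
      !all(mother_links$id_a %in% birth_records$delivery_id))
    stop("mother link map references unknown delivery ids")
  if (nrow(infant_links) &&
      !all(infant_links$id_a %in% birth_records$birth_record_id))
    stop("infant link map references unknown birth record ids")

  m_link <- mother_links$id_b[match(birth_records$delivery_id, mother_links$id_a)]
  i_link <- infant_links$id_b[match(birth_records$birth_record_id, infant_links$id_a)]
  has_m <- !is.na(m_link)
  has_i <- !is.na(i_link)
  group <- ifelse(has_m & has_i, "complete",
           ifelse(has_m, "mothers_only",
           ifelse(has_i, "infants_only", "unlinked_birth")))

  birth_groups <- data.frame(
    birth_record_id = birth_records$birth_record_id,
    delivery_id = birth_records$delivery_id,
    group = group,
    plurality = ifelse(is.na(birth_records$plurality_n), NA_character_,
                       ifelse(birth_records$plurality_n > 1, "multiple",
                              "singleton")),
    birth_status = ifelse(is.na(birth_records$live_birth), NA_character_,
                          ifelse(birth_records$live_birth, "livebirth",
                                 "stillbirth")),
    mother_hospital_record_id = m_link,
    infant_hospital_record_id = i_link,
    stringsAsFactors = FALSE
  )

  structure(list(
    birth_groups = birth_groups,
    unlinked_maternal = identified$maternal[
      !identified$maternal$record_id %in% mother_links$id_b, , drop = FALSE],
    unlinked_infant = identified$infant[
      !identified$infant$record_id %in% infant_links$id_b, , drop = FALSE]
  ), class = "linkage_group_table")
}

#' Stratify a linkage-group table by plurality and birth status
#'
#' Adds a `stratum` column partitioning birth records into
#' livebirth/stillbirth by singleton/multiple, with an explicit
#' `"unknown"` stratum for records whose plurality or birth status is
#' unclassifiable rather than a silently hidden remainder.
#'
#' @param table a `linkage_group_table` from [assign_groups()].
#' @return the `linkage_group_table` with `birth_groups$stratum` populated.
#' @export
stratify <- function(table) {
  stopifnot(inherits(table, "linkage_group_table"))
  bg <- table$birth_groups
  known <- !is.na(bg$plurality) & !is.na(bg$birth_status)
  bg$stratum <- ifelse(known, paste(bg$birth_status, bg$plurality, sep = "_"),
                       "unknown")
  table$birth_groups <- bg
  table
}

#' @export
print.linkage_group_table <- function(x, ...) {
  cat("<linkage_group_table>\n")
  print(table(x$birth_groups$group))
  cat("unlinked maternal hospital records:", nrow(x$unlinked_maternal), "\n")
  cat("unlinked infant hospital records:  ", nrow(x$unlinked_infant), "\n")
  invisible(x)
}
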