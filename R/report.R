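#' Percentage with half-up rounding to one decimal
#'
#' Rates are printed as a percentage of a column denominator rounded
#' half-up to one decimal (so 95.85 prints as 95.9), matching the usual
#' presentation of linkage-rate tables. Base `round()` rounds half to
#' even, which would print 2.25 as 2.2; half-up is used instead.
#'
#' @param count numerator count(s).
#' @param denom denominator.
#' @param digits decimal places.
#' @return numeric percentage(s).
#' @examples
#' rate_percent(688802, 717982)  # 95.9
#' @export
rate_percent <- function(count, denom, digits = 1) {
  if (any(denom == 0)) stop("zero denominator")
  round_half_up(100 * count / denom, digits)
}

#' @rdname rate_percent
#' @param x numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Linkage-rate table by group and stratum
#'
#' Cross-tabulates linkage groups against plurality-by-birth-status strata
#' with counts and percentages of each column's N (one decimal, half-up).
#' Residual unlinked hospital groups are appended with counts only (their
#' members are not birth records, so no percentage of birth records is
#' defined). Strata of the unlinked hospital records are taken from the
#' coded classification columns when present.
#'
#' @param table a stratified `linkage_group_table` (see [stratify()]).
#' @return data.frame with columns `group`, `stratum`, `n`, `percent`
#'   (NA for the hospital-record rows), including a `total` stratum;
#'   attribute `column_N` holds the per-stratum denominators.
#' @export
linkage_rate_table <- function(table) {
  stopifnot(inherits(table, "linkage_group_table"))
  bg <- table$birth_groups
  if (nrow(bg) == 0) stop("empty group table")
  if (is.null(bg$stratum)) stop("stratify() the table first")
  groups <- c("complete", "mothers_only", "infants_only", "unlinked_birth")
  strata <- sort(unique(bg$stratum))
  col_N <- c(vapply(strata, function(s) sum(bg$stratum == s), numeric(1)),
             total = nrow(bg))
  rows <- list()
  for (g in groups) {
    for (s in c(strata, "total")) {
      in_s <- if (s == "total") rep(TRUE, nrow(bg)) else bg$stratum == s
      n <- sum(bg$group == g & in_s)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, stratum = s, n = n,
        percent = rate_percent(n, col_N[[s]]))
    }
  }
  for (nm in c("unlinked_maternal", "unlinked_infant")) {
    rec <- table[[nm]]
    strat <- if (!is.null(rec$stratum)) rec$stratum else rep("unknown", nrow(rec))
    for (s in c(strata, "total")) {
      n <- if (s == "total") nrow(rec) else sum(strat == s)
      rows[[length(rows) + 1L]] <- data.frame(
        group = paste0(nm, "_hospital"), stratum = s, n = n, percent = NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "column_N") <- col_N
  out
}

#' Build a rate table from printed counts
#'
#' Applies the same count-to-percentage operation as
#' [linkage_rate_table()] to an externally supplied matrix of counts with
#' stated column denominators; useful for checking published tables for
#' self-consistency.
#'
#' @param counts numeric matrix (groups x strata).
#' @param column_N named numeric vector of column denominators.
#' @return data.frame `group`, `stratum`, `n`, `percent`.
#' @export
rate_table_from_counts <- function(counts, column_N) {
  stopifnot(is.matrix(counts), ncol(counts) == length(column_N))
  out <- expand.grid(group = rownames(counts), stratum = colnames(counts),
                     stringsAsFactors = FALSE)
  out$n <- as.vector(counts)
  out$percent <- rate_percent(as.vector(counts),
                              rep(column_N, each = nrow(counts)))
  out
}

#' Complete-linkage rate by gestational age or birthweight
#'
#' Per-level rate of complete linkage (both the mother's and the infant's
#' admission linked) as a percentage of birth records at that level, for
#' all births and for liveborn singletons. Levels with no records are
#' omitted with a message.
#'
#' @param table a stratified `linkage_group_table`.
#' @param birth_records the birth registration table.
#' @param strat_field `"gestation_weeks"` or `"birthweight_bins"`.
#' @param bin_width birthweight bin width in grams.
#' @return data.frame `level`, `n_all`, `rate_all`, `n_liveborn_singleton`,
#'   `rate_liveborn_singleton`.
#' @export
rate_by_stratum <- function(table, birth_records,
                            strat_field = c("gestation_weeks", "birthweight_bins"),
                            bin_width = 250) {
  strat_field <- match.arg(strat_field)
  bg <- table$birth_groups
  ix <- match(bg$birth_record_id, birth_records$birth_record_id)
  lev <- if (strat_field == "gestation_weeks") {
    birth_records$gestation_weeks[ix]
  } else {
    floor(birth_records$birthweight_g[ix] / bin_width) * bin_width
  }
  lbs <- bg$stratum == "livebirth_singleton"
  levels_all <- sort(unique(lev[!is.na(lev)]))
  rows <- lapply(levels_all, function(l) {
    sel <- !is.na(lev) & lev == l
    n_all <- sum(sel)
    n_l <- sum(sel & lbs)
    data.frame(
      level = l,
      n_all = n_all,
      rate_all = rate_percent(sum(sel & bg$group == "complete"), n_all),
      n_liveborn_singleton = n_l,
      rate_liveborn_singleton = if (n_l > 0)
        rate_percent(sum(sel & lbs & bg$group == "complete"), n_l) else NA_real_
    )
  })
  empty <- setdiff(if (strat_field == "gestation_weeks") 20:42 else numeric(0),
                   levels_all)
  if (length(empty)) message("omitting empty level(s): ",
                             paste(empty, collapse = ", "))
  do.call(rbind, rows)
}

#' Identification coverage of deliveries and births
#'
#' Percentage of deliveries, and of live births, reported in the birth
#' records that are ascertained from the hospital streams alone by the
#' admission-identification rules (one decimal, half-up).
#'
#' @param identified list with data.frames `maternal` and `infant` of
#'   rule-identified admissions (maternal records need `delivery_id` when
#'   available for deduplication; counts fall back to record counts).
#' @param birth_records the birth registration table.
#' @return list with numerator/denominator counts and `deliveries_pct`,
#'   `births_pct`.
#' @export
identification_coverage <- function(identified, birth_records) {
  n_deliv <- length(unique(birth_records$delivery_id))
  n_births <- sum(birth_records$live_birth)
  if (n_deliv == 0 || n_births == 0) stop("zero denominator")
  n_mat <- nrow(identified$maternal)
  n_inf <- nrow(identified$infant)
  list(
    deliveries_identified = n_mat,
    deliveries_reported = n_deliv,
    deliveries_pct = rate_percent(n_mat, n_deliv),
    births_identified = n_inf,
    live_births_reported = n_births,
    births_pct = rate_percent(n_inf, n_births)
  )
}

#' Characteristic comparison across linkage groups
#'
#' Counts and percentages of maternal/pregnancy characteristics per
#' linkage group, restricted to liveborn singleton birth records (the
#' comparison population used once stillbirths and multiples are set
#' aside). The four birth-record groups draw each variable from the birth
#' registration; the unlinked maternal hospital group can only report
#' variables derivable from its diagnosis/procedure codes, and the
#' remaining cells are structurally missing (NA), mirroring the "- (-)"
#' cells of published comparisons.
#'
#' @param table a stratified `linkage_group_table`.
#' @param birth_records the birth registration table.
#' @param vocab code vocabulary for deriving variables on unlinked
#'   hospital records.
#' @param variables character vector of logical birth-record columns to
#'   tabulate; the default covers the standard maternal comparison set.
#' @return data.frame `variable`, `group`, `n`, `percent` (NA when the
#'   variable is unavailable for that group), with attribute `group_N`.
#' @export
characteristics_table <- function(table, birth_records,
                                  vocab = load_code_vocabulary(),
                                  variables = c(
                                    "smoking", "diabetes", "hypertension",
                                    "induction", "caesarean",
                                    "placenta_praevia", "placental_abruption",
                                    "duration_lt26wk", "antenatal_ge15wk",
                                    "married", "australian_born",
                                    "private_hospital")) {
  bg <- table$birth_groups
  lbs <- bg$stratum == "livebirth_singleton"
  br <- birth_records[match(bg$birth_record_id, birth_records$birth_record_id), ]
  br$duration_lt26wk <- br$gestation_weeks < 26
  groups <- c("complete", "mothers_only", "infants_only", "unlinked_birth")

  # unlinked maternal hospital group: variables derived from codes only
  um <- table$unlinked_maternal
  um_lbs <- if (!is.null(um$stratum)) um$stratum == "livebirth_singleton"
            else rep(TRUE, nrow(um))
  um <- um[um_lbs, , drop = FALSE]
  um_derived <- if (nrow(um)) derive_variables(um, vocab) else NULL
  derivable <- c("diabetes", "hypertension", "induction", "caesarean",
                 "placenta_praevia", "placental_abruption", "duration_lt26wk")

  group_N <- c(vapply(groups, function(g) sum(lbs & bg$group == g), numeric(1)),
               unlinked_maternal_hospital = nrow(um))
  rows <- list()
  for (v in variables) {
    if (!v %in% names(br)) stop("variable absent from birth records: ", v)
    for (g in groups) {
      sel <- lbs & bg$group == g
      n <- sum(br[[v]][sel], na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, group = g, n = n,
        percent = if (group_N[[g]] > 0) rate_percent(n, group_N[[g]]) else NA_real_)
    }
    if (v %in% derivable && !is.null(um_derived)) {
      n <- sum(um_derived[[v]])
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, group = "unlinked_maternal_hospital", n = n,
        percent = if (nrow(um) > 0) rate_percent(n, nrow(um)) else NA_real_)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, group = "unlinked_maternal_hospital", n = NA_integer_,
        percent = NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "group_N") <- group_N
  out
}

#' Ground-truth linkage quality
#'
#' Missed links per 1,000 true pairs and false-positive links per 1,000
#' declared links, computed with exact integer counts before rate
#' conversion. The true-pair denominator is the set of ground-truth pairs
#' whose records were both available to the linkage (i.e. both present in
#' the input streams); record-availability and identification losses are
#' reported separately by [identification_coverage()].
#'
#' @param link_map data.frame `id_a`, `id_b`: declared one-to-one links.
#' @param truth_pairs data.frame `id_a`, `id_b`: true pairs in scope.
#' @return object of class `quality_report`: list with
#'   `missed_links_per_1000`, `false_positives_per_1000`, the underlying
#'   counts and denominator definitions.
#' @export
evaluate_quality <- function(link_map, truth_pairs) {
  tkey <- paste(truth_pairs$id_a, truth_pairs$id_b, sep = "\r")
  lkey <- paste(link_map$id_a, link_map$id_b, sep = "\r")
  if (anyDuplicated(tkey)) stop("duplicate truth pairs")
  n_true <- length(tkey)
  n_links <- length(lkey)
  missed <- sum(!tkey %in% lkey)
  false_pos <- sum(!lkey %in% tkey)
  structure(list(
    missed_links_per_1000 = if (n_true > 0) 1000 * missed / n_true else 0,
    false_positives_per_1000 = if (n_links > 0) 1000 * false_pos / n_links else 0,
    missed_count = missed,
    false_positive_count = false_pos,
    n_true_pairs = n_true,
    n_declared_links = n_links,
    denominators = c(
      missed = "true pairs with both records available to the linkage",
      false_positive = "declared links")
  ), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("missed links:    %.2f per 1,000 (%d of %d true pairs)\n",
              x$missed_links_per_1000, x$missed_count, x$n_true_pairs))
  cat(sprintf("false positives: %.2f per 1,000 (%d of %d declared links)\n",
              x$false_positives_per_1000, x$false_positive_count,
              x$n_declared_links))
  invisible(x)
}
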