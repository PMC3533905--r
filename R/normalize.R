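#' Standardize personal identifier fields
#'
#' Standardization and parsing of identifier fields prior to comparison:
#' names and addresses are case-folded, transliterated to ASCII,
#' punctuation-stripped and whitespace-collapsed, and phonetic codes
#' (Soundex and NYSIIS) are derived for given name and surname. The
#' transformation is idempotent: normalizing an already-normalized table
#' returns it unchanged.
#'
#' Apostrophes are deleted (so "O'Brien" becomes "OBRIEN"); all other
#' punctuation is replaced by a space before whitespace collapsing (so
#' "Smith-Jones" becomes "SMITH JONES"). Sex is standardized to
#' "M"/"F"/"U". Empty names receive the phonetic sentinel code.
#'
#' @param ids data.frame of person identifiers. Recognized columns:
#'   `given_name`, `surname`, `alias_surname`, `dob` (Date or "YYYY-MM-DD"
#'   string), `sex`, `address`, `country_of_birth`, `hospital_code`, `mrn`.
#'   Missing columns are skipped.
#' @return the input data.frame with standardized columns `given_name_norm`,
#'   `surname_norm`, `alias_surname_norm`, `given_name_soundex`,
#'   `surname_soundex`, `given_name_nysiis`, `surname_nysiis`,
#'   `address_norm`, `country_norm`, `hospital_code_norm`, `mrn_norm`,
#'   `sex_norm`, and `dob` coerced to Date.
#' @examples
#' normalize_identifiers(data.frame(given_name = " O'Brien ", surname = "del  Rio"))
#' @export
normalize_identifiers <- function(ids) {
  stopifnot(is.data.frame(ids))
  out <- as.data.frame(ids)

  has <- function(col) col %in% names(out)
  blank_to_na <- function(x) {
    x[!nzchar(x)] <- NA_character_
    x
  }

  if (has("given_name")) out$given_name_norm <- blank_to_na(normalize_text(out$given_name))
  if (has("surname")) out$surname_norm <- blank_to_na(normalize_text(out$surname))
  if (has("alias_surname")) out$alias_surname_norm <- blank_to_na(normalize_text(out$alias_surname))
  if (has("given_name_norm")) {
    gn <- out$given_name_norm
    gn[is.na(gn)] <- ""
    out$given_name_soundex <- soundex(gn)
    out$given_name_nysiis <- nysiis(gn)
  }
  if (has("surname_norm")) {
    sn <- out$surname_norm
    sn[is.na(sn)] <- ""
    out$surname_soundex <- soundex(sn)
    out$surname_nysiis <- nysiis(sn)
  }
  if (has("address")) out$address_norm <- blank_to_na(normalize_text(out$address))
  if (has("country_of_birth")) out$country_norm <- blank_to_na(normalize_text(out$country_of_birth))
  if (has("hospital_code")) out$hospital_code_norm <- blank_to_na(toupper(trimws(as.character(out$hospital_code))))
  if (has("mrn")) out$mrn_norm <- blank_to_na(toupper(gsub("[^A-Za-z0-9]", "", as.character(out$mrn))))
  if (has("sex")) {
    s <- toupper(substr(trimws(as.character(out$sex)), 1, 1))
    s[!s %in% c("M", "F")] <- "U"
    s[is.na(s)] <- "U"
    out$sex_norm <- s
  }
  if (has("dob")) out$dob <- as.Date(out$dob)
  out
}

#' Normalize free-text fields
#'
#' Uppercases, transliterates to ASCII, deletes apostrophes, replaces other
#' punctuation with spaces and collapses whitespace. Idempotent.
#'
#' @param x character vector.
#' @return normalized character vector ("" for `NA`).
#' @export
normalize_text <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- toupper(iconv(x, from = "", to = "ASCII//TRANSLIT"))
  x[is.na(x)] <- ""
  x <- gsub("'", "", x, fixed = TRUE)
  x <- gsub("[^A-Z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}
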