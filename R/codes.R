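#' Code lists and hierarchical ICD-10-AM / ACHI matching
#'
#' A `code_list` holds ICD-10-AM diagnosis prefixes/ranges and ACHI
#' procedure codes/ranges. Diagnosis matching is prefix-hierarchical and
#' case-insensitive: the prefix "O24" matches "O24.4", and the range
#' "O80-O84" matches "O82.1". Procedure codes are compared on their 5-digit
#' stem, so "16520-00" matches the entry "16520".
#'
#' @param name label for the list.
#' @param diagnosis character vector of diagnosis prefixes or "A-B" ranges.
#' @param procedure character vector of procedure codes or numeric ranges.
#' @return an object of class `code_list`.
#' @examples
#' cl <- code_list("delivery", diagnosis = c("O80-O84", "Z37"))
#' code_matches("O82.1;E11", cl)   # TRUE
#' @export
code_list <- function(name, diagnosis = character(0), procedure = character(0)) {
  parse_items <- function(x) {
    x <- toupper(trimws(as.character(x)))
    lapply(x[nzchar(x)], function(item) {
      if (grepl("-", item, fixed = TRUE)) {
        parts <- strsplit(item, "-", fixed = TRUE)[[1]]
        if (length(parts) != 2) stop("malformed code range: ", item)
        from <- .code_key(parts[1]); to <- .code_key(parts[2])
        if (substr(from, 1, 1) != substr(to, 1, 1) && grepl("^[A-Z]", from))
          stop("range spans letter classes: ", item)
        if (nchar(from) != nchar(to) || from > to)
          stop("malformed code range: ", item)
        list(kind = "range", from = from, to = to, width = nchar(from))
      } else {
        list(kind = "prefix", key = .code_key(item), width = nchar(.code_key(item)))
      }
    })
  }
  structure(
    list(name = name,
         diagnosis = parse_items(diagnosis),
         procedure = parse_items(procedure)),
    class = "code_list"
  )
}

# canonical comparison key: uppercase, dots removed; procedures keep their
# 5-digit stem (extension after "-" dropped)
.code_key <- function(code) {
  code <- toupper(trimws(code))
  code <- sub("-.*$", "", code)
  gsub(".", "", code, fixed = TRUE)
}

# split ";"-separated code strings into a list of per-record keys,
# dropping malformed entries with a single warning
.split_codes <- function(codes) {
  codes <- as.character(codes)
  codes[is.na(codes)] <- ""
  parts <- strsplit(codes, ";", fixed = TRUE)
  bad <- character(0)
  out <- lapply(parts, function(p) {
    p <- trimws(p)
    p <- p[nzchar(p)]
    keys <- vapply(p, .code_key, character(1), USE.NAMES = FALSE)
    ok <- grepl("^[A-Z][0-9]{2}", keys) | grepl("^[0-9]{5}", keys)
    if (any(!ok)) bad <<- c(bad, keys[!ok])
    keys[ok]
  })
  if (length(bad)) warning("ignoring malformed codes: ",
                           paste(unique(bad), collapse = ", "))
  out
}

.keys_match_items <- function(keys, items) {
  if (!length(keys) || !length(items)) return(FALSE)
  for (it in items) {
    trunc <- substr(keys, 1, it$width)
    if (it$kind == "prefix") {
      if (any(trunc == it$key)) return(TRUE)
    } else {
      if (any(nchar(keys) >= it$width & trunc >= it$from & trunc <= it$to))
        return(TRUE)
    }
  }
  FALSE
}

#' @rdname code_list
#' @param diagnosis_codes,procedure_codes character vectors of
#'   ";"-separated codes per record (either may be omitted).
#' @param codes shorthand: diagnosis codes for `code_matches`.
#' @param list a `code_list`.
#' @return `code_matches`: logical vector, one element per record.
#' @export
code_matches <- function(codes, list, procedure_codes = NULL) {
  stopifnot(inherits(list, "code_list"))
  diag_keys <- .split_codes(codes)
  res <- vapply(diag_keys, .keys_match_items, logical(1), items = list$diagnosis)
  if (!is.null(procedure_codes)) {
    proc_keys <- .split_codes(procedure_codes)
    res <- res | vapply(proc_keys, .keys_match_items, logical(1),
                        items = list$procedure)
  }
  res
}

#' Load the bundled birth-admission code vocabulary
#'
#' Reads the packaged YAML vocabulary of ICD-10-AM/ACHI code lists used to
#' identify infant birth admissions and maternal delivery admissions and to
#' derive clinical variables, and compiles each section into `code_list`
#' objects.
#'
#' @param path path to a vocabulary YAML file; defaults to the bundled one.
#' @return a named list with elements `infant`, `maternal`, `variables`
#'   (named list of `code_list`s), `plurality` (`singleton`, `multiple`)
#'   and `stillbirth`.
#' @export
load_code_vocabulary <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "birth_admission_codes.yml",
                        package = "perilink", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  as_cl <- function(name, node) {
    code_list(name,
              diagnosis = unlist(node$diagnosis, use.names = FALSE),
              procedure = unlist(node$procedure, use.names = FALSE))
  }
  mat <- raw$maternal_delivery_admission
  list(
    infant = list(
      liveborn = code_list("liveborn_by_place",
                           diagnosis = unlist(raw$infant_birth_admission$liveborn_by_place)),
      perinatal = code_list("perinatal_condition",
                            diagnosis = unlist(raw$infant_birth_admission$perinatal_condition)),
      age_days = unlist(raw$infant_birth_admission$age_days)
    ),
    maternal = code_list(
      "maternal_delivery_admission",
      diagnosis = unlist(mat$diagnosis, use.names = FALSE),
      procedure = unlist(mat$procedure, use.names = FALSE)
    ),
    variables = Map(as_cl, names(raw$variables), raw$variables),
    plurality = list(
      singleton = as_cl("singleton", raw$plurality$singleton),
      multiple = as_cl("multiple", raw$plurality$multiple)
    ),
    stillbirth = as_cl("stillbirth", raw$stillbirth)
  )
}
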