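#' Phonetic name encoding
#'
#' American Soundex and NYSIIS (New York State Identification and
#' Intelligence System) codes for surname/forename fields. Phonetic codes
#' map names with similar pronunciation to the same key (e.g. "Robert" and
#' "Rupert" share a Soundex code), which makes field comparisons robust to
#' minor typographical errors and spelling variants, and provides coarse
#' blocking keys.
#'
#' Both encoders are deterministic and case-insensitive. Non-ASCII letters
#' are transliterated to ASCII before encoding; characters other than A-Z
#' are ignored. An input that is empty (or empty after stripping
#' non-alphabetic characters) returns the sentinel code
#' \code{phonetic_sentinel()} rather than raising an error, so encoders can
#' be applied to fields with missing values.
#'
#' @param x character vector of words (typically normalized names).
#' @return character vector of codes, same length as `x`.
#' @examples
#' soundex(c("Robert", "Rupert"))   # both "R163"
#' nysiis("ROBERT")                 # "RABAD"
#' soundex("")                      # sentinel "#"
#' @name phonetics
NULL

#' @rdname phonetics
#' @export
phonetic_sentinel <- function() "#"

.clean_alpha <- function(x) {
  x <- toupper(iconv(as.character(x), from = "", to = "ASCII//TRANSLIT"))
  x[is.na(x)] <- ""
  gsub("[^A-Z]", "", x)
}

# American Soundex digit classes; H and W are transparent (they do not
# separate letters of the same class), vowels and Y do separate.
.soundex_digit <- c(
  B = "1", F = "1", P = "1", V = "1",
  C = "2", G = "2", J = "2", K = "2", Q = "2", S = "2", X = "2", Z = "2",
  D = "3", T = "3",
  L = "4",
  M = "5", N = "5",
  R = "6"
)

.soundex_one <- function(word) {
  if (!nzchar(word)) return(phonetic_sentinel())
  letters_vec <- strsplit(word, "", fixed = TRUE)[[1]]
  first <- letters_vec[1]
  code <- character(0)
  prev_digit <- .soundex_digit[first]
  if (is.na(prev_digit)) prev_digit <- ""
  for (ch in letters_vec[-1]) {
    d <- .soundex_digit[ch]
    if (is.na(d)) { # vowel, Y, H or W
      if (ch %in% c("H", "W")) next       # transparent: keep prev_digit
      prev_digit <- ""                    # vowel separates repeats
      next
    }
    if (!identical(unname(d), unname(prev_digit))) code <- c(code, d)
    prev_digit <- d
  }
  paste0(first, substr(paste0(paste(code, collapse = ""), "000"), 1, 3))
}

#' @rdname phonetics
#' @export
soundex <- function(x) {
  vapply(.clean_alpha(x), .soundex_one, character(1), USE.NAMES = FALSE)
}

.nysiis_vowels <- c("A", "E", "I", "O", "U")

.nysiis_one <- function(word) {
  if (!nzchar(word)) return(phonetic_sentinel())
  w <- strsplit(word, "", fixed = TRUE)[[1]]

  # leading-letter translations
  head3 <- paste(w[seq_len(min(3, length(w)))], collapse = "")
  if (startsWith(head3, "MAC")) {
    w <- c("M", "C", "C", w[-(1:3)])
  } else if (startsWith(head3, "KN")) {
    w <- c("N", "N", w[-(1:2)])
  } else if (w[1] == "K") {
    w[1] <- "C"
  } else if (startsWith(head3, "PH") || startsWith(head3, "PF")) {
    w <- c("F", "F", w[-(1:2)])
  } else if (startsWith(head3, "SCH")) {
    w <- c("S", "S", "S", w[-(1:3)])
  }

  # trailing-letter translations
  n <- length(w)
  if (n >= 2) {
    tail2 <- paste(w[(n - 1):n], collapse = "")
    if (tail2 %in% c("EE", "IE")) {
      w <- c(w[seq_len(n - 2)], "Y")
    } else if (tail2 %in% c("DT", "RT", "RD", "NT", "ND")) {
      w <- c(w[seq_len(n - 2)], "D")
    }
  }

  key <- w[1]
  i <- 2
  n <- length(w)
  while (i <= n) {
    ch <- w[i]
    step <- 1
    repl <- ch
    if (ch %in% .nysiis_vowels) {
      if (ch == "E" && i < n && w[i + 1] == "V") {
        repl <- "AF"; step <- 2
      } else repl <- "A"
    } else if (ch == "Q") repl <- "G"
    else if (ch == "Z") repl <- "S"
    else if (ch == "M") repl <- "N"
    else if (ch == "K") {
      if (i < n && w[i + 1] == "N") { repl <- "N"; step <- 2 } else repl <- "C"
    } else if (ch == "S" && i + 2 <= n && w[i + 1] == "C" && w[i + 2] == "H") {
      repl <- "SSS"; step <- 3
    } else if (ch == "P" && i < n && w[i + 1] == "H") {
      repl <- "FF"; step <- 2
    } else if (ch == "H") {
      prev <- w[i - 1]
      nxt <- if (i < n) w[i + 1] else ""
      if (!(prev %in% .nysiis_vowels) || !(nxt %in% .nysiis_vowels)) repl <- prev
    } else if (ch == "W") {
      if (w[i - 1] %in% .nysiis_vowels) repl <- w[i - 1]
    }
    for (r in strsplit(repl, "", fixed = TRUE)[[1]]) {
      if (r != substr(key, nchar(key), nchar(key))) key <- paste0(key, r)
    }
    w[i] <- substr(repl, 1, 1)  # replaced letter is what H/W rules look back at
    i <- i + step
  }

  # trailing S, terminal AY -> Y, trailing A
  if (nchar(key) > 1 && endsWith(key, "S")) key <- substr(key, 1, nchar(key) - 1)
  if (nchar(key) > 1 && endsWith(key, "AY")) key <- paste0(substr(key, 1, nchar(key) - 2), "Y")
  if (nchar(key) > 1 && endsWith(key, "A")) key <- substr(key, 1, nchar(key) - 1)
  key
}

#' @rdname phonetics
#' @export
nysiis <- function(x) {
  vapply(.clean_alpha(x), .nysiis_one, character(1), USE.NAMES = FALSE)
}
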