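# Independent oracles used across tests. These deliberately use different
# algorithmic formulations from the package implementation.

# Table-driven Soundex oracle: map the whole name to digits (vowels -> 0),
# drop H/W entirely, collapse adjacent equal digits, then strip zeros.
# Equivalent to the letter-by-letter transparency rule but structurally
# different from the package's implementation.
ref_soundex <- function(name) {
  s <- toupper(gsub("[^A-Za-z]", "", name))
  if (!nzchar(s)) return("#")
  first <- substr(s, 1, 1)
  chars <- strsplit(s, "")[[1]]
  digit_of <- function(ch) {
    if (ch %in% c("B", "F", "P", "V")) "1"
    else if (ch %in% c("C", "G", "J", "K", "Q", "S", "X", "Z")) "2"
    else if (ch %in% c("D", "T")) "3"
    else if (ch == "L") "4"
    else if (ch %in% c("M", "N")) "5"
    else if (ch == "R") "6"
    else if (ch %in% c("H", "W")) ""      # transparent
    else "0"                              # vowel separator
  }
  digs <- vapply(chars, digit_of, character(1))
  digs <- digs[digs != ""]                # drop H/W
  collapsed <- character(0)
  for (d in digs) {
    if (length(collapsed) == 0 || d != collapsed[length(collapsed)])
      collapsed <- c(collapsed, d)
    else next
  }
  # re-collapse across the removed separators is NOT done: zeros separate
  body <- collapsed
  if (length(body) && body[1] == digit_of(first) && body[1] != "0")
    body <- body[-1]
  body <- body[body != "0"]
  paste0(first, substr(paste0(paste(body, collapse = ""), "000"), 1, 3))
}

# brute-force candidate-pair oracle: all cross pairs sharing at least one
# blocking key value
brute_force_blocks <- function(a, b, keys) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      shares <- any(vapply(keys, function(k) {
        va <- paste(vapply(k, function(f) as.character(a[[f]][i]), character(1)),
                    collapse = "\r")
        vb <- paste(vapply(k, function(f) as.character(b[[f]][j]), character(1)),
                    collapse = "\r")
        miss_a <- any(vapply(k, function(f) {
          v <- a[[f]][i]; is.na(v) || identical(as.character(v), "")
        }, logical(1)))
        miss_b <- any(vapply(k, function(f) {
          v <- b[[f]][j]; is.na(v) || identical(as.character(v), "")
        }, logical(1)))
        !miss_a && !miss_b && va == vb
      }, logical(1)))
      if (shares)
        out[[length(out) + 1L]] <- data.frame(id_a = a$record_id[i],
                                              id_b = b$record_id[j])
    }
  }
  if (!length(out)) return(data.frame(id_a = character(0), id_b = character(0)))
  unique(do.call(rbind, out))
}

# exhaustive one-to-one assignment oracle: enumerate all conflict-free
# subsets and pick the one the greedy tie rules prefer (lexicographically
# largest sorted probability sequence, then id order)
brute_force_assignment <- function(pairs) {
  n <- nrow(pairs)
  stopifnot(n <= 14)
  best <- NULL
  best_key <- NULL
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel)) {
      if (anyDuplicated(pairs$id_a[sel]) || anyDuplicated(pairs$id_b[sel])) next
      # maximal only: no addable pair
      addable <- any(vapply(setdiff(seq_len(n), sel), function(i) {
        !(pairs$id_a[i] %in% pairs$id_a[sel]) &&
          !(pairs$id_b[i] %in% pairs$id_b[sel])
      }, logical(1)))
      if (addable) next
    } else if (n > 0) next
    ord <- sel[order(-pairs$probability[sel], pairs$id_a[sel], pairs$id_b[sel])]
    key <- paste(sprintf("%.10f", pairs$probability[ord]),
                 pairs$id_a[ord], pairs$id_b[ord], collapse = "|")
    if (is.null(best_key) || key > best_key) {
      best <- ord
      best_key <- key
    }
  }
  out <- pairs[best, c("id_a", "id_b", "probability")]
  rownames(out) <- NULL
  out
}

# small error-free cohort used by several structural tests
make_clean_cohort <- function(n = 100, seed = 1, stillbirth_rate = 0,
                              multiple_rate = 0) {
  generate_cohort(
    cohort_params(n,
                  multiple_pregnancy_rate = multiple_rate,
                  stillbirth_rate = stillbirth_rate,
                  maternal_nonadmission_rate = 0,
                  infant_record_missing_rate = 0,
                  stillbirth_misclassification_rate = 0,
                  other_admission_rate = 0,
                  coding_gap_rate = 0,
                  seed = seed),
    zero_error_model())
}
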