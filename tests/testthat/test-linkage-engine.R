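std <- function(df) {
  df$record_id <- df$record_id
  normalize_identifiers(df)
}

toy_streams <- function() {
  a <- std(data.frame(
    record_id = c("A1", "A2", "A3"),
    given_name = c("Robert", "Sarah", "Emma"),
    surname = c("Smith", "Jones", "Brown"),
    dob = as.Date(c("1980-01-01", "1985-06-15", "1990-03-02")),
    sex = c("M", "F", "F"),
    hospital_code = c("H01", "H01", "H02"),
    mrn = c("111", "222", "333"),
    address = "12 High St Newtown",
    birth_date = as.Date(c("1980-01-01", "1985-06-15", "1990-03-02")),
    birth_order = 1L, plurality_n = 1L,
    stringsAsFactors = FALSE))
  b <- std(data.frame(
    record_id = c("B1", "B2"),
    given_name = c("Rupert", "Sarah"),
    surname = c("Smith", "Jones"),
    dob = as.Date(c("1980-01-01", "1985-06-15")),
    sex = c("M", "F"),
    hospital_code = c("H01", "H01"),
    mrn = c("111", "999"),
    address = "12 High St Newtown",
    admission_date = as.Date(c("1980-01-01", "1985-06-15")),
    separation_date = as.Date(c("1980-01-03", "1985-06-18")),
    birth_order = 1L, plurality_n = 1L,
    stringsAsFactors = FALSE))
  list(a = a, b = b)
}

test_that("blocking produces within-key cross pairs and handles empty streams", {
  s <- toy_streams()
  spec <- blocking_spec(list(c("surname_soundex", "dob")))
  # two A records sharing a key value with one B record -> both pairs
  a2 <- s$a; a2$surname_soundex[2] <- a2$surname_soundex[1]
  a2$dob[2] <- a2$dob[1]
  pairs <- make_blocks(a2, s$b, spec)
  expect_setequal(paste(pairs$id_a, pairs$id_b),
                  c("A1 B1", "A2 B1"))
  empty <- s$a[0, ]
  expect_equal(nrow(make_blocks(empty, s$b, spec)), 0)
  expect_error(blocking_spec(list()), "at least one key")
})

test_that("blocking equals brute-force key-sharing enumeration on a 12-record fixture", {
  set.seed(7)
  mk <- function(ids) {
    std(data.frame(
      record_id = ids,
      given_name = sample(c("ANNA", "MARIA", "JOHN"), length(ids), TRUE),
      surname = sample(c("SMITH", "SMYTH", "JONES", "BROWN"), length(ids), TRUE),
      dob = sample(as.Date("1980-01-01") + 0:3, length(ids), TRUE),
      hospital_code = sample(c("H1", "H2"), length(ids), TRUE),
      mrn = sample(as.character(1:5), length(ids), TRUE),
      stringsAsFactors = FALSE))
  }
  a <- mk(sprintf("A%02d", 1:12)); b <- mk(sprintf("B%02d", 1:12))
  keys <- list(c("surname_soundex", "dob"), c("hospital_code_norm", "mrn_norm"))
  got <- make_blocks(a, b, blocking_spec(keys, max_block_size = 1e6))
  want <- brute_force_blocks(a, b, keys)
  expect_setequal(paste(got$id_a, got$id_b), paste(want$id_a, want$id_b))
})

test_that("oversized blocks are split by the secondary key and pairs stay unique", {
  n <- 40
  a <- std(data.frame(record_id = sprintf("A%02d", 1:n),
                      given_name = rep(c("ANNA", "BELLA", "CARA", "DORA"), n / 4),
                      surname = "SMITH", dob = as.Date("1980-01-01"),
                      stringsAsFactors = FALSE))
  b <- std(data.frame(record_id = sprintf("B%02d", 1:n),
                      given_name = rep(c("ANNA", "BELLA", "CARA", "DORA"), n / 4),
                      surname = "SMITH", dob = as.Date("1980-01-01"),
                      stringsAsFactors = FALSE))
  spec <- blocking_spec(list(c("surname_soundex", "dob")), max_block_size = 200)
  pairs <- make_blocks(a, b, spec)
  # full block would be 1600 pairs; secondary split by given name gives 4 x 100
  expect_equal(nrow(pairs), 400)
  expect_equal(anyDuplicated(paste(pairs$id_a, pairs$id_b)), 0)
})

test_that("clue outcomes distinguish agree, disagree and missing", {
  s <- toy_streams()
  clues <- default_clue_set("infant")
  pairs <- data.frame(id_a = c("A1", "A2"), id_b = c("B1", "B2"))
  oc <- evaluate_clues(pairs, s$a, s$b, clues)
  # Robert vs Rupert: exact name disagrees, phonetic agrees
  expect_equal(oc$given_exact[1], "disagree")
  expect_equal(oc$given_phonetic[1], "agree")
  expect_equal(oc$surname_exact[1], "agree")
  expect_equal(oc$dob_exact[1], "agree")
  expect_equal(oc$mrn[1], "agree")
  expect_equal(oc$mrn[2], "disagree")
  # identical records agree on every evaluable clue (address is absent on
  # both sides, so its clue reports missing)
  b_same <- s$b
  b_same$mrn_norm[2] <- s$a$mrn_norm[2]
  self <- evaluate_clues(data.frame(id_a = "A2", id_b = "B2"), s$a, b_same,
                         default_clue_set("infant"))
  expect_true(all(unlist(self) %in% c("agree", "missing")))
  expect_true(any(unlist(self) == "agree"))
  # blank names report missing but dob is still evaluated
  s2 <- s; s2$a$given_name_norm[1] <- NA
  oc2 <- evaluate_clues(pairs[1, ], s2$a, s$b, clues)
  expect_equal(oc2$given_exact, "missing")
  expect_equal(oc2$dob_exact, "agree")
  # unknown field errors
  bad <- list(clue_exact("nope", "no_such_column"))
  expect_error(evaluate_clues(pairs, s$a, s$b, bad), "unknown field")
})

test_that("maxent scoring has the logistic closed form and monotone behaviour", {
  oc <- data.frame(c1 = c("agree", "disagree", "missing"),
                   c2 = c("agree", "agree", "missing"),
                   stringsAsFactors = FALSE)
  w <- c("(Intercept)" = 0, "c1.agree" = 0, "c1.disagree" = 0,
         "c2.agree" = 0, "c2.disagree" = 0)
  expect_equal(score_pairs(oc, w), rep(0.5, 3))
  w2 <- c("(Intercept)" = -1, "c1.agree" = 2, "c1.disagree" = -1.5,
          "c2.agree" = 1, "c2.disagree" = -0.5)
  got <- score_pairs(oc, w2)
  expect_equal(got, plogis(c(-1 + 2 + 1, -1 - 1.5 + 1, -1)))
  expect_gt(got[1], got[2])  # all-agree above any-disagree
  expect_error(score_pairs(oc, w2[-2]), "dimension mismatch")
})

test_that("maxent fitting separates a separable toy set and rejects one-class labels", {
  oc <- data.frame(
    name = rep(c("agree", "disagree"), each = 20),
    dob = rep(c("agree", "disagree"), each = 20),
    stringsAsFactors = FALSE)
  labels <- rep(c(TRUE, FALSE), each = 20)
  fit <- fit_maxent_weights(oc, labels)
  p <- score_pairs(oc, fit)
  expect_true(all((p >= 0.5) == labels))
  expect_error(fit_maxent_weights(oc, rep(TRUE, 40)), "both matches")
})

test_that("maxent fit agrees with an independent glm fit at tiny regularization", {
  set.seed(31)
  n <- 4000
  oc <- data.frame(
    a = sample(c("agree", "disagree", "missing"), n, TRUE),
    b = sample(c("agree", "disagree", "missing"), n, TRUE),
    stringsAsFactors = FALSE)
  X <- perilink:::.clue_design(oc)
  w_true <- c(-1, 1.5, -1, 0.8, -0.6)
  y <- runif(n) < plogis(drop(X %*% w_true))
  fit <- fit_maxent_weights(oc, y, l2 = 1e-10)
  ref <- glm.fit(X, as.numeric(y), family = binomial())
  expect_lt(max(abs(fit$weights - ref$coefficients)), 1e-4)
})

test_that("dual-threshold classification follows the cut-off conventions", {
  th <- threshold_config(0.25, 0.75)
  expect_equal(classify(c(0.80, 0.50, 0.10), th),
               c("match", "review", "non_match"))
  # boundary convention: p >= upper is a match, p <= lower a non-match
  expect_equal(classify(c(0.75, 0.25), th), c("match", "non_match"))
  expect_error(threshold_config(0.8, 0.2))
  expect_error(classify(1.2, th), "\\[0, 1\\]")
  # decisions partition the pairs
  p <- runif(500)
  expect_equal(sum(table(classify(p, th))), 500)
})

test_that("threshold tuning matches an exhaustive grid oracle and collapses on separated scores", {
  set.seed(5)
  scores <- c(runif(300, 0, 0.3), runif(300, 0.7, 1))
  labels <- rep(c(FALSE, TRUE), each = 300)
  tc <- tune_thresholds(scores, labels)
  expect_true(tc$feasible)
  expect_equal(tc$review_count, 0)

  # overlapping fixture: compare against a direct double-loop oracle
  set.seed(8)
  sc <- c(rbeta(400, 2, 5), rbeta(400, 5, 2))
  lb <- rep(c(FALSE, TRUE), each = 400)
  tc2 <- tune_thresholds(sc, lb, 1, 2)
  grid <- seq(0.02, 0.98, by = 0.02)
  best <- NULL
  for (up in grid) for (lo in grid[grid < up]) {
    miss <- 1000 * sum(lb & sc <= lo) / sum(lb)
    declared <- sum(sc >= up)
    fp <- if (declared) 1000 * sum(!lb & sc >= up) / declared else 0
    if (miss > 1 || fp > 2) next
    review <- sum(sc > lo & sc < up)
    cand <- c(lo, up, review)
    if (is.null(best) || review < best[3] ||
        (review == best[3] && (up - lo) > (best[2] - best[1])) ||
        (review == best[3] && (up - lo) == (best[2] - best[1]) && up > best[2]))
      best <- cand
  }
  expect_equal(c(tc2$lower, tc2$upper, tc2$review_count), best)

  # raising the upper cut-off never increases auto-accepted false positives
  fp_at <- vapply(grid, function(u) sum(!lb & sc >= u), numeric(1))
  expect_true(all(diff(fp_at) <= 0))
  expect_error(tune_thresholds(sc, lb, target_missed_per_1000 = -1), "targets")
})

test_that("assignment resolution is greedy one-to-one with stable ties", {
  d <- data.frame(id_a = c("A1", "A1"), id_b = c("B1", "B2"),
                  probability = c(0.9, 0.8),
                  decision = c("match", "match"), stringsAsFactors = FALSE)
  got <- resolve_assignments(d, "reject")
  expect_equal(nrow(got), 1)
  expect_equal(got$id_b, "B1")
  expect_equal(nrow(resolve_assignments(d[0, ], "reject")), 0)

  set.seed(12)
  pairs <- data.frame(
    id_a = sample(sprintf("A%d", 1:6), 12, TRUE),
    id_b = sample(sprintf("B%d", 1:6), 12, TRUE),
    probability = round(runif(12), 2), stringsAsFactors = FALSE)
  pairs <- pairs[!duplicated(paste(pairs$id_a, pairs$id_b)), ]
  pairs$decision <- "match"
  got <- resolve_assignments(pairs, "reject")
  want <- brute_force_assignment(pairs)
  o <- function(x) x[order(x$id_a, x$id_b), ]
  expect_equal(o(got)$id_b, o(want)$id_b)
  expect_equal(o(got)$id_a, o(want)$id_a)
})

test_that("review pairs follow the configured policy", {
  d <- data.frame(id_a = "A1", id_b = "B1", probability = 0.5,
                  decision = "review", stringsAsFactors = FALSE)
  truth <- data.frame(id_a = "A1", id_b = "B1")
  expect_equal(nrow(resolve_assignments(d, "oracle", truth)), 1)
  expect_equal(nrow(resolve_assignments(d, "reject")), 0)
  expect_error(resolve_assignments(d, "oracle"), "truth_pairs")
})
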