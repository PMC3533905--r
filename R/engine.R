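#' Blocking specification
#'
#' Candidate pairs are generated as the union, over a list of blocking
#' keys, of all cross-stream pairs agreeing on the key. A key is a
#' character vector of standardized column names; records with a missing
#' component are excluded from that key. Blocks whose pair count would
#' exceed `max_block_size` are split by appending the secondary key (by
#' default the first letter of the normalized given name); blocks still
#' oversized after splitting are dropped and counted in the
#' `oversized_dropped` attribute of the pair set.
#'
#' @param keys list of character vectors of column names.
#' @param max_block_size maximum pairs allowed per block (>= 2).
#' @param secondary_key column name used to split oversized blocks.
#' @return an object of class `blocking_spec`.
#' @export
blocking_spec <- function(keys,
                          max_block_size = 1000,
                          secondary_key = "given_name_norm") {
  if (!is.list(keys) || length(keys) == 0)
    stop("blocking requires at least one key")
  if (max_block_size < 2) stop("max_block_size must be >= 2")
  structure(list(keys = keys, max_block_size = max_block_size,
                 secondary_key = secondary_key),
            class = "blocking_spec")
}

.block_key_values <- function(df, key) {
  miss <- Reduce(`|`, lapply(key, function(k) {
    v <- df[[k]]
    if (is.null(v)) stop("unknown blocking field: ", k)
    is.na(v) | v == ""
  }))
  vals <- do.call(paste, c(lapply(key, function(k) as.character(df[[k]])),
                           sep = "\r"))
  vals[miss] <- NA_character_
  vals
}

#' Generate candidate pairs by blocking
#'
#' @param stream_a,stream_b standardized data.frames, each with a unique
#'   `record_id` column.
#' @param spec a [blocking_spec()].
#' @return data.frame of unique candidate pairs (`id_a`, `id_b`), with an
#'   attribute `oversized_dropped` giving the number of blocks dropped.
#' @export
make_blocks <- function(stream_a, stream_b, spec) {
  stopifnot(inherits(spec, "blocking_spec"),
            "record_id" %in% names(stream_a),
            "record_id" %in% names(stream_b))
  if (nrow(stream_a) == 0 || nrow(stream_b) == 0) {
    out <- data.frame(id_a = character(0), id_b = character(0))
    attr(out, "oversized_dropped") <- 0L
    return(out)
  }
  pieces <- list()
  dropped <- 0L
  pair_block <- function(a_df, b_df, k) {
    # returns list(pairs, big): pairs for blocks within budget, plus the
    # key values of oversized blocks
    va <- .block_key_values(a_df, k)
    vb <- .block_key_values(b_df, k)
    ta <- table(va); tb <- table(vb)
    common <- intersect(names(ta), names(tb))
    if (!length(common)) return(list(pairs = NULL, big = character(0), va = va, vb = vb))
    sizes <- as.numeric(ta[common]) * as.numeric(tb[common])
    small <- common[sizes <= spec$max_block_size]
    big <- common[sizes > spec$max_block_size]
    pairs <- NULL
    if (length(small)) {
      da <- data.table::data.table(blk = va, id_a = a_df$record_id)
      db <- data.table::data.table(blk = vb, id_b = b_df$record_id)
      da <- da[da$blk %in% small, ]
      db <- db[db$blk %in% small, ]
      merged <- merge(da, db, by = "blk", allow.cartesian = TRUE)
      pairs <- data.table::data.table(id_a = merged$id_a, id_b = merged$id_b)
    }
    list(pairs = pairs, big = big, va = va, vb = vb)
  }
  has_secondary <- spec$secondary_key %in% names(stream_a) &&
    spec$secondary_key %in% names(stream_b)
  for (key in spec$keys) {
    res <- pair_block(stream_a, stream_b, key)
    if (!is.null(res$pairs)) pieces[[length(pieces) + 1L]] <- res$pairs
    if (length(res$big)) {
      if (has_secondary && !(spec$secondary_key %in% key)) {
        sub_a <- stream_a[res$va %in% res$big, , drop = FALSE]
        sub_b <- stream_b[res$vb %in% res$big, , drop = FALSE]
        res2 <- pair_block(sub_a, sub_b, c(key, spec$secondary_key))
        if (!is.null(res2$pairs)) pieces[[length(pieces) + 1L]] <- res2$pairs
        dropped <- dropped + length(res2$big)
      } else {
        dropped <- dropped + length(res$big)
      }
    }
  }
  if (!length(pieces)) {
    out <- data.frame(id_a = character(0), id_b = character(0))
  } else {
    all_pairs <- unique(data.table::rbindlist(pieces))
    data.table::setorder(all_pairs, id_a, id_b)
    out <- as.data.frame(all_pairs)
  }
  attr(out, "oversized_dropped") <- dropped
  out
}

## ---- clues -----------------------------------------------------------

.is_blank <- function(x) {
  if (is.character(x)) is.na(x) | x == "" else is.na(x)
}

.tern <- function(agree, missing) {
  out <- ifelse(missing, "missing", ifelse(agree, "agree", "disagree"))
  out
}

#' Clue constructors
#'
#' A clue is a named pairwise field comparator returning one of "agree",
#' "disagree" or "missing" for each candidate pair; the missing outcome
#' contributes neither the agreement nor the disagreement weight to the
#' match score. Constructors cover exact agreement on a standardized
#' field, cross-field agreement (e.g. surname against a recorded alias),
#' date proximity, containment of a date in an admission interval, and
#' address token overlap.
#'
#' @param name clue name (used for weight labels).
#' @param field,field_a,field_b standardized column names.
#' @param days maximum absolute day difference counted as agreement.
#' @param min_tokens minimum shared address tokens for agreement.
#' @return an object of class `perilink_clue`: a list with `name` and a
#'   comparator `fun(a, b)` over pair-aligned data.frames.
#' @name clues
NULL

#' @rdname clues
#' @export
clue <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  structure(list(name = name, fun = fun), class = "perilink_clue")
}

.get_field <- function(df, field) {
  v <- df[[field]]
  if (is.null(v)) stop("comparator references unknown field: ", field)
  v
}

#' @rdname clues
#' @export
clue_exact <- function(name, field_a, field_b = field_a) {
  clue(name, function(a, b) {
    va <- .get_field(a, field_a); vb <- .get_field(b, field_b)
    miss <- .is_blank(va) | .is_blank(vb)
    .tern(!miss & as.character(va) == as.character(vb), miss)
  })
}

#' @rdname clues
#' @export
clue_alias_surname <- function(name = "surname_alias") {
  clue(name, function(a, b) {
    asur <- a$surname_norm; bsur <- b$surname_norm
    aali <- if (!is.null(a$alias_surname_norm)) a$alias_surname_norm else NA_character_
    bali <- if (!is.null(b$alias_surname_norm)) b$alias_surname_norm else NA_character_
    hit1 <- !.is_blank(asur) & !.is_blank(bali) & asur == bali
    hit2 <- !.is_blank(aali) & !.is_blank(bsur) & aali == bsur
    comparable <- (!.is_blank(asur) & !.is_blank(bali)) |
      (!.is_blank(aali) & !.is_blank(bsur))
    .tern(hit1 | hit2, !comparable)
  })
}

#' @rdname clues
#' @export
clue_within_days <- function(name, field_a, field_b, days = 1) {
  clue(name, function(a, b) {
    da <- as.Date(.get_field(a, field_a)); db <- as.Date(.get_field(b, field_b))
    miss <- is.na(da) | is.na(db)
    .tern(!miss & abs(as.integer(db - da)) <= days, miss)
  })
}

#' @rdname clues
#' @export
clue_date_in_interval <- function(name, field_a, field_from, field_to) {
  clue(name, function(a, b) {
    da <- as.Date(.get_field(a, field_a))
    fr <- as.Date(.get_field(b, field_from))
    to <- as.Date(.get_field(b, field_to))
    miss <- is.na(da) | is.na(fr) | is.na(to)
    .tern(!miss & fr <= da & da <= to, miss)
  })
}

#' @rdname clues
#' @export
clue_dob_component <- function(name, part = c("year", "monthday")) {
  part <- match.arg(part)
  fmt <- if (part == "year") "%Y" else "%m%d"
  clue(name, function(a, b) {
    da <- as.Date(.get_field(a, "dob")); db <- as.Date(.get_field(b, "dob"))
    miss <- is.na(da) | is.na(db)
    .tern(!miss & format(da, fmt) == format(db, fmt), miss)
  })
}

#' @rdname clues
#' @export
clue_address_tokens <- function(name = "address_tokens", min_tokens = 2) {
  clue(name, function(a, b) {
    va <- .get_field(a, "address_norm"); vb <- .get_field(b, "address_norm")
    miss <- .is_blank(va) | .is_blank(vb)
    shared <- mapply(function(x, y) {
      length(intersect(strsplit(x, " ", fixed = TRUE)[[1]],
                       strsplit(y, " ", fixed = TRUE)[[1]]))
    }, ifelse(miss, "", va), ifelse(miss, "", vb))
    .tern(!miss & shared >= min_tokens, miss)
  })
}

#' Default clue sets for the mother and infant linkage streams
#'
#' The mother stream compares the maternal identifiers on the birth
#' registration with maternal admission records (names exact and phonetic,
#' alias surname, date of birth in full and by component, address tokens,
#' country of birth, hospital code, MRN, and whether the birth date falls
#' in the admission interval). The infant stream compares infant
#' identifiers with infant admission records, adding sex, admission-date
#' proximity to the birth date, and birth order and plurality for
#' distinguishing multiples.
#'
#' @param role `"mother"` or `"infant"`.
#' @return list of `perilink_clue` objects.
#' @export
default_clue_set <- function(role = c("mother", "infant")) {
  role <- match.arg(role)
  base <- list(
    clue_exact("given_exact", "given_name_norm"),
    clue_exact("given_phonetic", "given_name_soundex"),
    clue_exact("given_nysiis", "given_name_nysiis"),
    clue_exact("surname_exact", "surname_norm"),
    clue_exact("surname_phonetic", "surname_soundex"),
    clue_exact("surname_nysiis", "surname_nysiis"),
    clue_exact("dob_exact", "dob"),
    clue_dob_component("dob_year", "year"),
    clue_dob_component("dob_monthday", "monthday"),
    clue_address_tokens(),
    clue_exact("hospital", "hospital_code_norm"),
    clue_exact("mrn", "mrn_norm")
  )
  if (role == "mother") {
    c(base, list(
      clue_alias_surname(),
      clue_exact("country", "country_norm"),
      clue_date_in_interval("admission_interval", "birth_date",
                            "admission_date", "separation_date")
    ))
  } else {
    c(base, list(
      clue_exact("sex", "sex_norm"),
      clue_within_days("admission_near_birth", "birth_date",
                       "admission_date", days = 1),
      clue_exact("birth_order", "birth_order"),
      clue_exact("plurality", "plurality_n")
    ))
  }
}

#' Evaluate clues over candidate pairs
#'
#' @param pairs data.frame with `id_a`, `id_b`.
#' @param stream_a,stream_b standardized record tables with `record_id`.
#' @param clues list of `perilink_clue` objects.
#' @return data.frame of clue outcomes (one character column per clue, in
#'   \{"agree", "disagree", "missing"\}), rows aligned with `pairs`.
#' @export
evaluate_clues <- function(pairs, stream_a, stream_b, clues) {
  a <- stream_a[match(pairs$id_a, stream_a$record_id), , drop = FALSE]
  b <- stream_b[match(pairs$id_b, stream_b$record_id), , drop = FALSE]
  out <- lapply(clues, function(cl) cl$fun(a, b))
  names(out) <- vapply(clues, function(cl) cl$name, character(1))
  as.data.frame(out, optional = TRUE, stringsAsFactors = FALSE)
}

# ternary outcomes -> design matrix with agree/disagree indicator columns;
# missing is the zero-contribution reference level
.clue_design <- function(outcomes) {
  cols <- lapply(names(outcomes), function(nm) {
    v <- outcomes[[nm]]
    m <- cbind(as.numeric(v == "agree"), as.numeric(v == "disagree"))
    colnames(m) <- paste0(nm, c(".agree", ".disagree"))
    m
  })
  cbind(`(Intercept)` = 1, do.call(cbind, cols))
}

#' Fit maximum-entropy clue weights
#'
#' Learns clue weights from labeled pairs by fitting the maximum-entropy
#' model in its standard dual form: an L2-regularized binary logistic
#' model over agree/disagree indicator features (missing outcomes are the
#' zero reference). Fitting is a damped Newton iteration, deterministic
#' given the data, regularization strength and convergence tolerance; the
#' intercept is not penalized.
#'
#' @param outcomes clue-outcome data.frame from [evaluate_clues()].
#' @param labels logical vector (TRUE = true match), same length.
#' @param l2 L2 penalty strength.
#' @param tol convergence tolerance on the maximum gradient component.
#' @param max_iter Newton iteration cap.
#' @return object of class `maxent_clue_model` with elements `weights`
#'   (named vector), `converged`, `loglik`.
#' @export
fit_maxent_weights <- function(outcomes, labels, l2 = 1e-4, tol = 1e-8,
                               max_iter = 100) {
  y <- as.numeric(labels)
  if (anyNA(y)) stop("labels must not contain NA")
  if (length(unique(y)) < 2)
    stop("labels must contain both matches and non-matches")
  X <- .clue_design(outcomes)
  if (nrow(X) != length(y)) stop("outcomes/labels length mismatch")
  if (any(!is.finite(X))) stop("non-finite feature values")
  p <- ncol(X)
  pen <- rep(l2, p); pen[1] <- 0   # intercept unpenalized
  w <- numeric(p)
  obj <- function(w) {
    eta <- drop(X %*% w)
    sum(y * eta - log1p(exp(eta))) - sum(pen * w^2) / 2
  }
  f <- obj(w)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% w)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(X, y - mu)) - pen * w
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    v <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * v, X) + diag(pen + 1e-12, p)
    step <- solve(H, g)
    t_ <- 1
    repeat {
      w_new <- w + t_ * step
      f_new <- obj(w_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      t_ <- t_ / 2
      if (t_ < 1e-8) break
    }
    if (abs(f_new - f) < tol * (abs(f) + 1)) {
      w <- w_new; f <- f_new; converged <- TRUE; break
    }
    w <- w_new; f <- f_new
  }
  structure(list(weights = stats::setNames(drop(w), colnames(X)),
                 converged = converged, loglik = f, l2 = l2),
            class = "maxent_clue_model")
}

#' Score pairs under fitted clue weights
#'
#' Combines clue outcomes with their weights through the maximum-entropy
#' (logistic) link to give the probability that the two records belong to
#' the same person.
#'
#' @param outcomes clue-outcome data.frame (or one-row equivalent).
#' @param model a `maxent_clue_model`, or a named weight vector matching
#'   the design columns.
#' @return numeric vector of match probabilities in (0, 1).
#' @export
score_pairs <- function(outcomes, model) {
  w <- if (inherits(model, "maxent_clue_model")) model$weights else model
  X <- .clue_design(outcomes)
  if (!identical(colnames(X), names(w))) {
    if (!all(colnames(X) %in% names(w)))
      stop("weight/outcome dimension mismatch")
    w <- w[colnames(X)]
  }
  stats::plogis(drop(X %*% w))
}

#' Dual-threshold configuration and classification
#'
#' Pairs with probability at or above the upper cut-off are declared
#' matches, at or below the lower cut-off non-matches, and in between they
#' fall into the clerical-review band. Defaults are the conventional
#' starting cut-offs 0.25 and 0.75.
#'
#' @param lower,upper probabilities with `0 <= lower < upper <= 1`.
#' @return `threshold_config`: list with `lower`, `upper`.
#' @export
threshold_config <- function(lower = 0.25, upper = 0.75) {
  if (is.na(lower) || is.na(upper) || lower < 0 || upper > 1 || lower >= upper)
    stop("need 0 <= lower < upper <= 1")
  structure(list(lower = lower, upper = upper), class = "threshold_config")
}

#' @rdname threshold_config
#' @param probability numeric vector of match probabilities in [0, 1].
#' @param thresholds a `threshold_config`.
#' @return `classify`: character vector in \{"match", "non_match", "review"\}.
#' @export
classify <- function(probability, thresholds = threshold_config()) {
  stopifnot(inherits(thresholds, "threshold_config"))
  if (any(probability < 0 | probability > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  ifelse(probability >= thresholds$upper, "match",
         ifelse(probability <= thresholds$lower, "non_match", "review"))
}

#' Tune dual thresholds against quality targets
#'
#' Grid search over lower/upper cut-off pairs for the configuration that
#' meets both quality targets among automatically decided pairs --- missed
#' links (true pairs auto-rejected) per 1,000 true pairs, and false
#' positives (false pairs auto-accepted) per 1,000 declared matches ---
#' while minimizing the number of pairs left in the clerical-review band.
#' Ties prefer the widest band (cut-offs pushed to the edges of the empty
#' score gap, the most robust placement), then the larger upper cut-off.
#' If no grid point meets both targets the returned config carries
#' `feasible = FALSE` (with the least-violating thresholds), never a
#' silent fallback.
#'
#' @param scores numeric vector of match probabilities.
#' @param labels logical vector of ground-truth pair labels.
#' @param target_missed_per_1000,target_false_per_1000 quality targets.
#' @param grid candidate cut-off values.
#' @return a `threshold_config` with extra fields `feasible`,
#'   `missed_per_1000`, `false_per_1000`, `review_count`.
#' @export
tune_thresholds <- function(scores, labels,
                            target_missed_per_1000 = 1,
                            target_false_per_1000 = 2,
                            grid = seq(0.02, 0.98, by = 0.02)) {
  if (target_missed_per_1000 < 0 || target_missed_per_1000 > 1000 ||
      target_false_per_1000 < 0 || target_false_per_1000 > 1000)
    stop("targets must lie in [0, 1000]")
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  n_true <- sum(labels)
  grid <- sort(unique(grid))
  # counts as functions of the cut points
  true_le <- vapply(grid, function(g) sum(labels & scores <= g), numeric(1))
  false_ge <- vapply(grid, function(g) sum(!labels & scores >= g), numeric(1))
  true_ge <- vapply(grid, function(g) sum(labels & scores >= g), numeric(1))
  le_all <- vapply(grid, function(g) sum(scores <= g), numeric(1))
  ge_all <- vapply(grid, function(g) sum(scores >= g), numeric(1))
  n <- length(scores)

  best <- NULL
  for (iu in seq_along(grid)) {
    declared <- true_ge[iu] + false_ge[iu]
    fp1000 <- if (declared > 0) 1000 * false_ge[iu] / declared else 0
    for (il in seq_len(iu - 1)) {
      miss1000 <- if (n_true > 0) 1000 * true_le[il] / n_true else 0
      review <- n - ge_all[iu] - le_all[il]
      ok <- miss1000 <= target_missed_per_1000 && fp1000 <= target_false_per_1000
      viol <- max(miss1000 - target_missed_per_1000, 0) +
        max(fp1000 - target_false_per_1000, 0)
      cand <- list(lower = grid[il], upper = grid[iu], feasible = ok,
                   missed_per_1000 = miss1000, false_per_1000 = fp1000,
                   review_count = review, violation = viol)
      if (is.null(best)) { best <- cand; next }
      width <- grid[iu] - grid[il]
      better <- if (best$feasible != ok) ok else if (ok) {
        best_width <- best$upper - best$lower
        review < best$review_count ||
          (review == best$review_count &&
             (width > best_width ||
                (width == best_width && grid[iu] > best$upper)))
      } else viol < best$violation
      if (isTRUE(better)) best <- cand
    }
  }
  tc <- threshold_config(best$lower, best$upper)
  tc$feasible <- best$feasible
  tc$missed_per_1000 <- best$missed_per_1000
  tc$false_per_1000 <- best$false_per_1000
  tc$review_count <- best$review_count
  tc
}

#' Resolve match decisions to a one-to-one link map
#'
#' Review-band pairs are first resolved by the chosen policy: the
#' ground-truth oracle (emulating accurate clerical review, available in
#' the synthetic setting) or outright rejection (blind mode). Accepted
#' pairs are then assigned greedily in descending probability, each record
#' linking at most once; ties are broken by stable (`id_a`, `id_b`) order.
#'
#' @param decisions data.frame with `id_a`, `id_b`, `probability`,
#'   `decision` (from [classify()]).
#' @param review_policy `"oracle"` or `"reject"`.
#' @param truth_pairs data.frame with `id_a`, `id_b` of true pairs
#'   (required for the oracle policy).
#' @return data.frame `id_a`, `id_b`, `probability`: the one-to-one links.
#' @export
resolve_assignments <- function(decisions,
                                review_policy = c("oracle", "reject"),
                                truth_pairs = NULL) {
  review_policy <- match.arg(review_policy)
  if (nrow(decisions) == 0)
    return(data.frame(id_a = character(0), id_b = character(0),
                      probability = numeric(0)))
  dec <- decisions$decision
  if (review_policy == "oracle") {
    if (is.null(truth_pairs)) stop("oracle policy requires truth_pairs")
    truth_key <- paste(truth_pairs$id_a, truth_pairs$id_b, sep = "\r")
    in_truth <- paste(decisions$id_a, decisions$id_b, sep = "\r") %in% truth_key
    dec[dec == "review"] <- ifelse(in_truth[dec == "review"], "match", "non_match")
  } else {
    dec[dec == "review"] <- "non_match"
  }
  cand <- decisions[dec == "match", c("id_a", "id_b", "probability")]
  if (nrow(cand) == 0) return(cand)
  cand <- cand[order(-cand$probability, cand$id_a, cand$id_b), ]
  keep <- logical(nrow(cand))
  seen_a <- new.env(hash = TRUE); seen_b <- new.env(hash = TRUE)
  for (i in seq_len(nrow(cand))) {
    ia <- cand$id_a[i]; ib <- cand$id_b[i]
    if (is.null(seen_a[[ia]]) && is.null(seen_b[[ib]])) {
      keep[i] <- TRUE
      seen_a[[ia]] <- TRUE; seen_b[[ib]] <- TRUE
    }
  }
  out <- cand[keep, ]
  rownames(out) <- NULL
  out
}
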