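#' Mine the top-K classification rules by support
#'
#' TopKRules-style search for the K class-association rules of maximum
#' support whose confidence reaches `min_conf`, with at most `max_len`
#' conditions in the antecedent (each condition is one attribute interval
#' from the transaction catalogue). Support is the number of transactions
#' satisfying antecedent and consequent; confidence is that count divided by
#' the antecedent-matching count (reported as a percent, with the
#' antecedent-only count alongside for transparency).
#'
#' The search is a level-wise expansion of the antecedent lattice with
#' support-based pruning under a dynamic minimum-support threshold (raised
#' as the K-th best support grows); candidates are processed in decreasing
#' order of an antecedent-support bound so the threshold rises early. At the
#' K boundary all rules tied with the K-th support are collected, then the
#' result is truncated deterministically by (support desc, confidence desc,
#' lexicographic antecedent).
#'
#' @param transactions a `reef_transactions` object, see [discretize()].
#' @param k number of rules to return (default 1000; `Inf` returns every
#'   valid rule).
#' @param min_conf confidence floor in percent, in (0, 100\] (default 90).
#' @param max_len maximum number of antecedent conditions (default 3).
#' @param per_class mine the top K separately for each habitat consequent
#'   instead of globally?
#' @param chunk_size candidates per vectorized block (tuning only).
#' @return A data frame of class `mined_rules`, sorted by decreasing
#'   support: `antecedent`, `consequent`, `support`, `antecedent_support`,
#'   `confidence`, `n_conditions`, plus a list column `atom_idx` of atom
#'   indices into `transactions$atoms`.
#' @export
mine_topk <- function(transactions, k = 1000, min_conf = 90, max_len = 3L,
                      per_class = FALSE, chunk_size = 1024L) {
  stopifnot(inherits(transactions, "reef_transactions"))
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1) {
    stop("`k` must be a positive count (or Inf)", call. = FALSE)
  }
  if (!is.numeric(min_conf) || min_conf <= 0 || min_conf > 100) {
    stop("`min_conf` must be a percent in (0, 100]", call. = FALSE)
  }
  if (max_len < 1L) stop("`max_len` must be >= 1", call. = FALSE)
  if (nrow(transactions$matches) < 1L) {
    stop("need at least one transaction", call. = FALSE)
  }
  if (per_class) {
    classes <- sort(unique(transactions$labels))
    parts <- lapply(classes, function(cl) {
      mine_core(transactions, k, min_conf, max_len, cl, chunk_size)
    })
    out <- do.call(rbind, parts)
  } else {
    out <- mine_core(transactions, k, min_conf, max_len, NULL, chunk_size)
  }
  rownames(out) <- NULL
  class(out) <- c("mined_rules", "data.frame")
  out
}

mine_core <- function(tr, k, min_conf, max_len, consequent, chunk_size) {
  M <- tr$matches * 1
  n <- nrow(M); m <- ncol(M)
  labs <- tr$labels
  classes <- sort(unique(labs))
  out_classes <- if (is.null(consequent)) classes else {
    if (!consequent %in% classes) return(empty_rule_frame())
    consequent
  }
  Y <- vapply(out_classes, function(cl) (labs == cl) * 1, numeric(n))
  if (n == 1L) Y <- matrix(Y, nrow = 1L, dimnames = list(NULL, out_classes))
  attrs <- tr$atoms$attribute
  cntA <- colSums(M)
  conf_eps <- 1e-9

  # rule pool: keys are comma-joined sorted atom indices
  pool <- list()
  pool_sup <- numeric(0L)
  minsup <- 1
  add_rules <- function(keys, sup, ant, conf, cons, size) {
    keep <- sup >= minsup
    if (!any(keep)) return(invisible())
    pool[[length(pool) + 1L]] <<- data.frame(
      key = keys[keep], support = sup[keep], antecedent_support = ant[keep],
      confidence = conf[keep], consequent = cons[keep], n_conditions = size,
      stringsAsFactors = FALSE)
    pool_sup <<- c(pool_sup, sup[keep])
    if (length(pool_sup) >= k && is.finite(k)) {
      minsup <<- sort(pool_sup, decreasing = TRUE)[k]
    }
    invisible()
  }

  # ---- level 1 ----
  S1 <- crossprod(M, Y)                       # m x C
  for (ci in seq_along(out_classes)) {
    sup <- S1[, ci]
    conf <- ifelse(cntA > 0, 100 * sup / cntA, 0)
    valid <- sup >= 1 & conf >= min_conf - conf_eps
    if (any(valid)) {
      idx <- which(valid)
      add_rules(as.character(idx), sup[idx], cntA[idx], conf[idx],
                rep(out_classes[ci], length(idx)), 1L)
    }
  }

  surv_idx <- matrix(which(cntA >= minsup), ncol = 1L)
  surv_cnt <- cntA[surv_idx[, 1L]]

  level <- 1L
  while (level < max_len && nrow(surv_idx) > 0L) {
    level <- level + 1L
    ord <- order(surv_cnt, decreasing = TRUE)
    surv_idx <- surv_idx[ord, , drop = FALSE]
    surv_cnt <- surv_cnt[ord]
    next_idx <- list(); next_cnt <- list()
    start <- 1L
    while (start <= nrow(surv_idx)) {
      rows <- start:min(start + chunk_size - 1L, nrow(surv_idx))
      start <- start + chunk_size
      if (surv_cnt[rows[1L]] < minsup) break   # ordered desc: nothing left
      idx <- surv_idx[rows, , drop = FALSE]
      Mp <- M[, idx[, 1L], drop = FALSE]
      if (ncol(idx) > 1L) {
        for (cc in 2:ncol(idx)) Mp <- Mp * M[, idx[, cc], drop = FALSE]
      }
      Tm <- crossprod(Mp, M)                  # ch x m antecedent counts
      allow <- outer(idx[, ncol(idx)], seq_len(m), "<")
      for (cc in seq_len(ncol(idx))) {
        allow <- allow & outer(attrs[idx[, cc]], attrs, "!=")
      }
      for (ci in seq_along(out_classes)) {
        Sc <- crossprod(Mp * Y[, ci], M)      # ch x m rule supports
        conf <- 100 * Sc / pmax(Tm, 1)
        valid <- allow & Sc >= max(1, minsup) & conf >= min_conf - conf_eps
        if (any(valid)) {
          w <- which(valid, arr.ind = TRUE)
          keys <- vapply(seq_len(nrow(w)), function(r) {
            paste(c(idx[w[r, 1L], ], w[r, 2L]), collapse = ",")
          }, character(1L))
          add_rules(keys, Sc[valid], Tm[valid], conf[valid],
                    rep(out_classes[ci], sum(valid)), level)
        }
      }
      if (level < max_len) {
        grow <- allow & Tm >= minsup
        if (any(grow)) {
          w <- which(grow, arr.ind = TRUE)
          next_idx[[length(next_idx) + 1L]] <-
            cbind(idx[w[, 1L], , drop = FALSE], w[, 2L])
          next_cnt[[length(next_cnt) + 1L]] <- Tm[grow]
        }
      }
    }
    surv_idx <- if (length(next_idx)) do.call(rbind, next_idx) else
      matrix(integer(), ncol = level)
    surv_cnt <- if (length(next_cnt)) unlist(next_cnt) else numeric(0L)
  }

  if (!length(pool)) return(empty_rule_frame())
  rules <- do.call(rbind, pool)
  rules <- rules[rules$support >= minsup, , drop = FALSE]
  rules$antecedent <- vapply(strsplit(rules$key, ",", fixed = TRUE),
                             function(ii) paste(tr$atoms$id[as.integer(ii)],
                                                collapse = " AND "),
                             character(1L))
  rules <- rules[order(-rules$support, -rules$confidence, rules$antecedent,
                       rules$consequent), , drop = FALSE]
  if (is.finite(k) && nrow(rules) > k) rules <- rules[seq_len(k), , drop = FALSE]
  rules$atom_idx <- lapply(strsplit(rules$key, ",", fixed = TRUE), as.integer)
  rules$key <- NULL
  rownames(rules) <- NULL
  rules[, c("antecedent", "consequent", "support", "antecedent_support",
            "confidence", "n_conditions", "atom_idx")]
}

empty_rule_frame <- function() {
  out <- data.frame(antecedent = character(), consequent = character(),
                    support = numeric(), antecedent_support = numeric(),
                    confidence = numeric(), n_conditions = integer(),
                    stringsAsFactors = FALSE)
  out$atom_idx <- list()
  out
}

#' Exhaustive rule enumeration (test oracle)
#'
#' Enumerates every antecedent of at most `max_len` conditions on distinct
#' attributes and returns all rules meeting the confidence floor, with the
#' same support/confidence semantics and the same deterministic ordering as
#' [mine_topk()]. Intended as an independent oracle on small instances; it
#' refuses inputs beyond the guard sizes.
#'
#' @param transactions a `reef_transactions` object.
#' @param min_conf confidence floor in percent.
#' @param max_len maximum antecedent length.
#' @param max_atoms,max_transactions guard sizes (defaults 20 and 500).
#' @return Data frame in the format of [mine_topk()] (all valid rules).
#' @export
brute_force_rules <- function(transactions, min_conf = 90, max_len = 3L,
                              max_atoms = 20L, max_transactions = 500L) {
  stopifnot(inherits(transactions, "reef_transactions"))
  m <- ncol(transactions$matches); n <- nrow(transactions$matches)
  if (m > max_atoms || n > max_transactions) {
    stop("instance too large for brute force (", m, " atoms, ", n,
         " transactions; guards are ", max_atoms, " and ", max_transactions,
         ")", call. = FALSE)
  }
  M <- transactions$matches
  labs <- transactions$labels
  classes <- sort(unique(labs))
  attrs <- transactions$atoms$attribute
  rows <- list()
  for (size in seq_len(min(max_len, m))) {
    combos <- utils::combn(m, size)
    for (j in seq_len(ncol(combos))) {
      ii <- combos[, j]
      if (anyDuplicated(attrs[ii])) next
      match_vec <- rowSums(M[, ii, drop = FALSE]) == size
      ant <- sum(match_vec)
      if (ant == 0L) next
      for (cl in classes) {
        sup <- sum(match_vec & labs == cl)
        if (sup < 1L) next
        conf <- 100 * sup / ant
        if (conf < min_conf - 1e-9) next
        rows[[length(rows) + 1L]] <- data.frame(
          antecedent = paste(transactions$atoms$id[ii], collapse = " AND "),
          consequent = cl, support = sup, antecedent_support = ant,
          confidence = conf, n_conditions = size, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty_rule_frame())
  out <- do.call(rbind, rows)
  out <- out[order(-out$support, -out$confidence, out$antecedent,
                   out$consequent), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.mined_rules <- function(x, n = 10L, ...) {
  cat("Mined classification rules:", nrow(x), "rule(s)\n")
  show <- utils::head(as.data.frame(x)[, c("antecedent", "consequent",
                                           "support", "confidence")], n)
  show$confidence <- round(show$confidence, 1L)
  print(show, row.names = FALSE, right = FALSE)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more\n")
  invisible(x)
}

#' Convert mined rules to a ruleset
#'
#' Turns the atom intervals of mined rules into the condition objects of the
#' rule engine so they can be rendered in the rule grammar, evaluated with
#' [evaluate_rule()] or used for prediction.
#'
#' @param mined a `mined_rules` data frame (with its `atom_idx` column).
#' @param transactions the `reef_transactions` the rules were mined from.
#' @param name ruleset name.
#' @return A `ruleset` object.
#' @export
as_ruleset <- function(mined, transactions, name = "mined") {
  stopifnot(inherits(mined, "mined_rules"))
  rules <- lapply(seq_len(nrow(mined)), function(r) {
    ii <- mined$atom_idx[[r]]
    conds <- transactions$atoms[ii, , drop = FALSE]
    new_rule(id = sprintf("R%d", r),
             conditions = data.frame(
               attribute = conds$attribute, lo = conds$lo, lo_incl = TRUE,
               hi = conds$hi, hi_incl = FALSE, stringsAsFactors = FALSE),
             habitat = mined$consequent[r],
             conf = mined$confidence[r], n = mined$support[r])
  })
  new_ruleset(rules, name = name, version = "1.0",
              provenance = "mined from transactions")
}
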