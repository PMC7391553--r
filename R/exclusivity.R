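#' Default cover constraint set for exclusivity checking
#'
#' Linear constraints a physically possible station must satisfy: the five
#' substrate covers sum to 100 within the annotation tolerance; the five
#' biotic overlay covers sum to at
#' most `biotic_max` (set `NULL` to drop this, e.g. when overlapping layers
#' are allowed); ordinal scores lie in \[1, 5\]; depth in \[0,
#' `depth_max`\]. `eps` is the margin used to turn strict inequalities into
#' closed ones for the feasibility solver.
#'
#' @param biotic_max biotic overlay sum cap (default 100) or `NULL`.
#' @param substrate_tol slack on the substrate sum, in percentage points
#'   (default 0.5, the annotation tolerance used by [validate_stations()]).
#' @param depth_max maximum depth in meters.
#' @param eps strict-inequality margin.
#' @return A list of constraint parameters.
#' @export
default_cover_constraints <- function(biotic_max = 100, substrate_tol = 0.5,
                                      depth_max = 100, eps = 1e-3) {
  list(biotic_max = biotic_max, substrate_tol = substrate_tol,
       depth_max = depth_max, eps = eps)
}

# coefficient vector of an attribute (base or composite) over base attributes
attr_coef <- function(attribute) {
  base <- attribute_names()
  v <- stats::setNames(numeric(length(base)), base)
  comps <- composite_attributes()
  if (attribute %in% base) v[attribute] <- 1
  else v[comps[[attribute]]] <- 1
  v
}

# Interval intersection pre-check on the union of both antecedents:
# returns TRUE when some single attribute's conditions are contradictory.
intervals_empty <- function(conds, eps) {
  for (a in unique(conds$attribute)) {
    sub <- conds[conds$attribute == a, , drop = FALSE]
    lo <- sub$lo + ifelse(sub$lo_incl, 0, eps)
    hi <- sub$hi - ifelse(sub$hi_incl, 0, eps)
    if (max(lo) > min(hi)) return(TRUE)
  }
  FALSE
}

# LP feasibility for the union of two antecedents under the cover
# constraints; returns list(status, witness row or NULL).
pair_feasibility <- function(conds, constraints) {
  eps <- constraints$eps
  base <- attribute_names()
  nv <- length(base)
  A1 <- NULL; b1 <- NULL   # <=
  A2 <- NULL; b2 <- NULL   # >=
  add1 <- function(coef, b) { A1 <<- rbind(A1, coef); b1 <<- c(b1, b) }
  add2 <- function(coef, b) { A2 <<- rbind(A2, coef); b2 <<- c(b2, b) }

  for (a in c(substrate_attributes(), biotic_attributes())) {
    add1(attr_coef(a), 100)
  }
  for (a in c("topography", "complexity")) {
    add1(attr_coef(a), 5); add2(attr_coef(a), 1)
  }
  add1(attr_coef("depth"), constraints$depth_max)
  if (!is.null(constraints$biotic_max)) {
    add1(colSums(do.call(rbind, lapply(biotic_attributes(), attr_coef))),
         constraints$biotic_max)
  }
  subsum <- colSums(do.call(rbind, lapply(substrate_attributes(), attr_coef)))
  add1(subsum, 100 + constraints$substrate_tol)
  add2(subsum, 100 - constraints$substrate_tol)

  for (i in seq_len(nrow(conds))) {
    cond <- conds[i, ]
    coef <- attr_coef(cond$attribute)
    if (is.finite(cond$hi)) add1(coef, cond$hi - if (cond$hi_incl) 0 else eps)
    if (is.finite(cond$lo) && cond$lo > 0) {
      add2(coef, cond$lo + if (cond$lo_incl) 0 else eps)
    }
  }

  fit <- tryCatch(
    boot::simplex(a = rep(1, nv), A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                  maxi = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || fit$solved == 0) {
    return(list(status = "INCONCLUSIVE", witness = NULL))
  }
  if (fit$solved == -1) return(list(status = "EXCLUSIVE", witness = NULL))
  # snap to a dyadic grid: sums of multiples of 2^-20 below 2^7 are exact in
  # doubles, so the witness re-fires conditions without rounding surprises
  w <- stats::setNames(round(as.numeric(fit$soln) * 2^20) / 2^20, base)
  list(status = "SATISFIABLE", witness = witness_station(w))
}

witness_station <- function(w) {
  data.frame(station_id = "witness", site = "synthetic", zone = "coastal",
             depth_m = w[["depth"]], topography = w[["topography"]],
             complexity = w[["complexity"]], sand_pc = w[["sand"]],
             debris_pc = w[["debris"]], boulder_pc = w[["boulder"]],
             rock_pc = w[["rock"]], slab_pc = w[["slab"]],
             live_coral_pc = w[["live_coral"]],
             dead_coral_pc = w[["dead_coral"]],
             erect_algae_pc = w[["erect_algae"]],
             algal_turf_pc = w[["algal_turf"]],
             seagrass_pc = w[["seagrass"]], habitat = NA_character_,
             stringsAsFactors = FALSE)
}

# Randomized witness search fallback when the solver is inconclusive:
# condition-aware draws on the 5%-annotation grid (0.25 for ordinals), so
# that candidate values and their sums are exact in floating point. For each
# directly conditioned attribute a grid point is drawn inside its interval;
# composite conditions are repaired through their unconditioned components;
# the substrate remainder goes to unconditioned substrate covers.
random_witness <- function(rule1, rule2, n_tries = 500L) {
  conds <- rbind(rule1$conditions, rule2$conditions)
  merged <- function(a, dom_lo, dom_hi) {
    sub <- conds[conds$attribute == a, , drop = FALSE]
    lo <- dom_lo; hi <- dom_hi
    if (nrow(sub)) {
      lo <- max(lo, sub$lo + ifelse(sub$lo_incl, 0, .25))
      hi <- min(hi, sub$hi - ifelse(sub$hi_incl, 0, .25))
    }
    c(lo, hi)
  }
  grid_draw <- function(lo, hi, step) {
    from <- ceiling(lo / step) * step
    if (!is.finite(from) || !is.finite(hi) || from > hi) return(NULL)
    pts <- seq(from, hi, by = step)
    pts[sample.int(length(pts), 1L)]
  }
  conditioned <- unique(conds$attribute)
  for (i in seq_len(n_tries)) {
    step <- if (i %% 2L) 5 else 1
    w <- stats::setNames(numeric(length(attribute_names())), attribute_names())
    w["topography"] <- 1; w["complexity"] <- 1
    ok <- TRUE
    for (a in intersect(conditioned, attribute_names())) {
      dom <- if (a %in% c("topography", "complexity")) c(1, 5)
             else if (a == "depth") c(0, 100) else c(0, 100)
      rng <- merged(a, dom[1L], dom[2L])
      v <- grid_draw(rng[1L], rng[2L],
                     if (a %in% c("topography", "complexity")) .25 else step)
      if (is.null(v)) { ok <- FALSE; break }
      w[a] <- v
    }
    if (!ok) next
    # composite repair via unconditioned components
    for (cmp in intersect(conditioned, names(composite_attributes()))) {
      parts <- composite_attributes()[[cmp]]
      rng <- merged(cmp, 0, 100 * length(parts))
      tgt <- grid_draw(max(rng[1L], sum(w[parts])), rng[2L], step)
      if (is.null(tgt)) { ok <- FALSE; break }
      free <- setdiff(parts, conditioned)
      deficit <- tgt - sum(w[parts])
      if (deficit > 0 && length(free)) {
        w[free[1L]] <- w[free[1L]] + deficit
      }
    }
    if (!ok) next
    # substrate sum: assign the remainder to unconditioned substrate covers
    rem <- 100 - sum(w[substrate_attributes()])
    free <- setdiff(substrate_attributes(),
                    c(conditioned,
                      unlist(composite_attributes()[intersect(
                        conditioned, names(composite_attributes()))])))
    if (rem < 0 || (!length(free) && abs(rem) > 0.5)) next
    if (length(free)) w[free[1L]] <- w[free[1L]] + rem
    st <- witness_station(w)
    if (rule_matches(rule1, st) && rule_matches(rule2, st)) return(st)
  }
  NULL
}

#' Check pairwise mutual exclusivity of a ruleset
#'
#' For every pair of rules, decides whether a physically possible station
#' (see [default_cover_constraints()]) can satisfy both antecedents:
#' `SATISFIABLE` (a witness station exists; it is returned and re-verified
#' by firing both rules), `EXCLUSIVE` (the joint conditions are infeasible),
#' or `INCONCLUSIVE` when the interval/linear-programming check fails and a
#' randomized witness search finds nothing. Rules paired with themselves
#' are `SATISFIABLE` whenever the rule itself is feasible.
#'
#' @param ruleset a `ruleset`.
#' @param constraints see [default_cover_constraints()].
#' @param include_self include each rule paired with itself?
#' @return Data frame of class `exclusivity_report`: `rule1`, `rule2`,
#'   `status`, and a `witness` list column of one-row station frames (or
#'   `NULL`).
#' @export
check_exclusivity <- function(ruleset, constraints = default_cover_constraints(),
                              include_self = TRUE) {
  stopifnot(inherits(ruleset, "ruleset"))
  ids <- names(ruleset$rules)
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq.int(i, length(ids))) {
      if (i == j && !include_self) next
      r1 <- ruleset$rules[[i]]; r2 <- ruleset$rules[[j]]
      conds <- rbind(r1$conditions, r2$conditions)
      if (intervals_empty(conds, constraints$eps)) {
        res <- list(status = "EXCLUSIVE", witness = NULL)
      } else {
        res <- pair_feasibility(conds, constraints)
        if (res$status == "SATISFIABLE" &&
            !(rule_matches(r1, res$witness) && rule_matches(r2, res$witness))) {
          res <- list(status = "INCONCLUSIVE", witness = NULL)
        }
        if (res$status == "INCONCLUSIVE") {
          w <- random_witness(r1, r2)
          if (!is.null(w)) res <- list(status = "SATISFIABLE", witness = w)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        rule1 = ids[i], rule2 = ids[j], status = res$status,
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$witness <- list(res$witness)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("exclusivity_report", "data.frame")
  out
}

#' @export
print.exclusivity_report <- function(x, ...) {
  self <- x$rule1 == x$rule2
  tab <- table(x$status[!self])
  cat("Exclusivity report:", sum(!self), "rule pairs\n")
  for (s in names(tab)) cat(sprintf("  %-13s %d\n", s, tab[[s]]))
  sat <- x[!self & x$status == "SATISFIABLE", , drop = FALSE]
  if (nrow(sat)) {
    cat("Overlapping pairs:\n")
    for (r in seq_len(nrow(sat))) {
      cat("  ", sat$rule1[r], "+", sat$rule2[r], "\n")
    }
  }
  invisible(x)
}
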