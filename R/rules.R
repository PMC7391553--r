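#' Construct a classification rule
#'
#' A classification rule is a conjunction of threshold conditions on habitat
#' attributes (the antecedent) implying a habitat (the consequent). Each
#' condition constrains one attribute — base or composite — to an interval
#' with independently open or closed bounds, so `seagrass >= 80`,
#' `20 <= seagrass < 40` and `5 < slab_boulder_rock < 20` are all single
#' conditions. Stored confidence/support/confusion statistics are
#' provenance metadata (computed on whatever data the rule came from) and
#' are never recomputed silently; use [evaluate_rule()] to recompute them on
#' a station set.
#'
#' @param id rule identifier (e.g. `"SG1"`).
#' @param conditions data frame with columns `attribute`, `lo`, `lo_incl`,
#'   `hi`, `hi_incl` (`-Inf`/`Inf` for one-sided conditions).
#' @param habitat consequent habitat, one of [habitat_levels()].
#' @param conf,n stored confidence (percent) and support metadata.
#' @param confusion named numeric vector: percent of antecedent-matching
#'   stations per non-consequent habitat.
#' @return An object of class `class_rule`.
#' @export
new_rule <- function(id, conditions, habitat, conf = NA_real_, n = NA_real_,
                     confusion = NULL) {
  stopifnot(is.data.frame(conditions), nrow(conditions) >= 1L)
  known <- attribute_names(composites = TRUE)
  bad <- setdiff(conditions$attribute, known)
  if (length(bad)) {
    stop("rule ", id, ": unknown attribute(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!habitat %in% habitat_levels()) {
    stop("rule ", id, ": unknown habitat '", habitat, "'", call. = FALSE)
  }
  if (any(conditions$lo >= conditions$hi)) {
    stop("rule ", id, ": empty interval condition", call. = FALSE)
  }
  structure(list(id = id, conditions = conditions, habitat = habitat,
                 conf = conf, n = n, confusion = confusion),
            class = "class_rule")
}

#' @rdname new_rule
#' @param rules list of `class_rule` objects (ids must be unique).
#' @param name,version,provenance ruleset metadata.
#' @export
new_ruleset <- function(rules, name = "ruleset", version = "1.0",
                        provenance = "") {
  ids <- vapply(rules, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate rule id(s): ", paste(unique(ids[duplicated(ids)]),
                                         collapse = ", "), call. = FALSE)
  }
  names(rules) <- ids
  structure(list(name = name, version = version, provenance = provenance,
                 rules = rules), class = "ruleset")
}

fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE)

render_condition <- function(cond) {
  a <- cond$attribute
  if (is.infinite(cond$lo) && cond$lo < 0) {
    paste(a, if (cond$hi_incl) "<=" else "<", fmt_num(cond$hi))
  } else if (is.infinite(cond$hi)) {
    paste(a, if (cond$lo_incl) ">=" else ">", fmt_num(cond$lo))
  } else {
    paste(fmt_num(cond$lo), if (cond$lo_incl) "<=" else "<", a,
          if (cond$hi_incl) "<=" else "<", fmt_num(cond$hi))
  }
}

#' Render rules in the rule grammar
#'
#' One rule per line:
#' `SG4: 20 <= seagrass < 40 AND algae < 40 AND depth >= 10 => Seagrass
#' [conf=81, n=34] {Macroalgae: 12; Debris: 2; Sandy: 5}`
#' where the bracketed block holds stored confidence/support metadata and
#' the optional braced block the confusion map. `render_ruleset()` prepends
#' `# name:`, `# version:` and `# provenance:` header comments;
#' [parse_ruleset()] inverts it exactly.
#'
#' @param rule a `class_rule`.
#' @param ruleset a `ruleset`.
#' @return A character scalar (`render_rule`) or vector of lines
#'   (`render_ruleset`).
#' @export
render_rule <- function(rule) {
  ant <- paste(vapply(seq_len(nrow(rule$conditions)), function(i) {
    render_condition(rule$conditions[i, , drop = FALSE])
  }, character(1L)), collapse = " AND ")
  line <- paste0(rule$id, ": ", ant, " => ", rule$habitat)
  if (!is.na(rule$conf) || !is.na(rule$n)) {
    line <- paste0(line, " [conf=", fmt_num(rule$conf), ", n=",
                   fmt_num(rule$n), "]")
  }
  if (length(rule$confusion)) {
    line <- paste0(line, " {", paste(names(rule$confusion),
                                     fmt_num(rule$confusion),
                                     sep = ": ", collapse = "; "), "}")
  }
  line
}

#' @rdname render_rule
#' @export
render_ruleset <- function(ruleset) {
  c(paste("# name:", ruleset$name),
    paste("# version:", ruleset$version),
    paste("# provenance:", ruleset$provenance),
    vapply(ruleset$rules, render_rule, character(1L), USE.NAMES = FALSE))
}

parse_condition <- function(txt, line_no) {
  txt <- trimws(txt)
  num <- "([0-9]+\\.?[0-9]*)"
  attr_rx <- "([A-Za-z_][A-Za-z0-9_]*)"
  m <- regmatches(txt, regexec(paste0("^", num, "\\s*(<=|<)\\s*", attr_rx,
                                      "\\s*(<=|<)\\s*", num, "$"), txt))[[1L]]
  if (length(m)) {
    return(data.frame(attribute = m[4L], lo = as.numeric(m[2L]),
                      lo_incl = m[3L] == "<=", hi = as.numeric(m[6L]),
                      hi_incl = m[5L] == "<=", stringsAsFactors = FALSE))
  }
  m <- regmatches(txt, regexec(paste0("^", attr_rx, "\\s*(>=|<=|>|<)\\s*",
                                      num, "$"), txt))[[1L]]
  if (length(m)) {
    t <- as.numeric(m[4L])
    return(switch(m[3L],
      ">=" = data.frame(attribute = m[2L], lo = t, lo_incl = TRUE,
                        hi = Inf, hi_incl = FALSE, stringsAsFactors = FALSE),
      ">"  = data.frame(attribute = m[2L], lo = t, lo_incl = FALSE,
                        hi = Inf, hi_incl = FALSE, stringsAsFactors = FALSE),
      "<=" = data.frame(attribute = m[2L], lo = -Inf, lo_incl = FALSE,
                        hi = t, hi_incl = TRUE, stringsAsFactors = FALSE),
      "<"  = data.frame(attribute = m[2L], lo = -Inf, lo_incl = FALSE,
                        hi = t, hi_incl = FALSE, stringsAsFactors = FALSE)))
  }
  stop("line ", line_no, ": cannot parse condition '", txt, "'",
       call. = FALSE)
}

#' Parse a ruleset from the rule grammar
#'
#' @param text character vector of lines, a single string with newlines, or
#'   a file path (when `text` names an existing file).
#' @return A `ruleset` object; see [render_rule()] for the grammar.
#' @export
parse_ruleset <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  } else if (length(text) == 1L) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  meta <- list(name = "ruleset", version = "1.0", provenance = "")
  rules <- list()
  for (i in seq_along(text)) {
    line <- trimws(text[i])
    if (line == "") next
    if (startsWith(line, "#")) {
      h <- regmatches(line, regexec("^#\\s*(name|version|provenance):\\s*(.*)$",
                                    line))[[1L]]
      if (length(h)) meta[[h[2L]]] <- h[3L]
      next
    }
    m <- regmatches(line, regexec(
      "^([A-Za-z0-9_.-]+)\\s*:\\s*(.*?)\\s*=>\\s*([^][{}]+?)\\s*(\\[[^]]*\\])?\\s*(\\{[^}]*\\})?$",
      line))[[1L]]
    if (!length(m)) stop("line ", i, ": cannot parse rule '", line, "'",
                         call. = FALSE)
    conds <- do.call(rbind, lapply(strsplit(m[3L], "\\s+AND\\s+")[[1L]],
                                   parse_condition, line_no = i))
    conf <- NA_real_; n <- NA_real_
    if (m[5L] != "") {
      cm <- regmatches(m[5L], regexec("conf=([0-9.]+)", m[5L]))[[1L]]
      if (length(cm)) conf <- as.numeric(cm[2L])
      nm <- regmatches(m[5L], regexec("n=([0-9.]+)", m[5L]))[[1L]]
      if (length(nm)) n <- as.numeric(nm[2L])
    }
    confusion <- NULL
    if (m[6L] != "") {
      body <- sub("^\\{", "", sub("\\}$", "", m[6L]))
      parts <- strsplit(body, ";", fixed = TRUE)[[1L]]
      kv <- strsplit(trimws(parts), ":\\s*")
      confusion <- stats::setNames(
        vapply(kv, function(p) as.numeric(p[2L]), numeric(1L)),
        vapply(kv, function(p) trimws(p[1L]), character(1L)))
    }
    rules[[length(rules) + 1L]] <- new_rule(m[2L], conds, m[4L],
                                            conf = conf, n = n,
                                            confusion = confusion)
  }
  if (!length(rules)) warning("no rules found", call. = FALSE)
  new_ruleset(rules, name = meta$name, version = meta$version,
              provenance = meta$provenance)
}

#' The packaged expert ruleset
#'
#' Loads the 26 expert-selected, mutually exclusive classification rules
#' describing the five habitats (4 Macroalgae, 4 Seagrass, 5 Sandy, 6 Live
#' Coral, 7 Debris) shipped with the package as
#' `extdata/expert_rules_nc_v1.rules`. The stored confidence, support and
#' confusion values are provenance metadata from the original 3,145-station
#' New Caledonia survey; they are not recomputed on your data unless you
#' call [evaluate_rule()] or [assess_ruleset()].
#'
#' @return A `ruleset` of 26 rules.
#' @export
expert_rules <- function() {
  path <- system.file("extdata", "expert_rules_nc_v1.rules",
                      package = "reefrules", mustWork = TRUE)
  parse_ruleset(path)
}

# logical vector: which stations satisfy every condition of the rule
rule_matches <- function(rule, stations) {
  ok <- rep(TRUE, nrow(stations))
  for (i in seq_len(nrow(rule$conditions))) {
    cond <- rule$conditions[i, ]
    v <- attribute_values(stations, cond$attribute)
    ok <- ok & (if (cond$lo_incl) v >= cond$lo else v > cond$lo)
    ok <- ok & (if (cond$hi_incl) v <= cond$hi else v < cond$hi)
  }
  ok
}

#' Evaluate a rule's statistics on labeled stations
#'
#' Recomputes support (stations matching antecedent and consequent),
#' confidence (support over antecedent-matching stations, in percent) and
#' the confusion map (percent of antecedent-matching stations per
#' non-consequent habitat). Confidence plus the confusion percentages sum to
#' 100 up to rounding. A rule whose antecedent matches no station is
#' reported as not evaluable (`NA` statistics).
#'
#' @param rule a `class_rule`.
#' @param stations labeled station data frame.
#' @return The rule with `conf`, `n` (support), `antecedent_n`, `confusion`
#'   and `evaluable` filled in.
#' @export
evaluate_rule <- function(rule, stations) {
  if (!"habitat" %in% names(stations) || anyNA(stations$habitat)) {
    stop("evaluate_rule() needs labeled stations", call. = FALSE)
  }
  matched <- rule_matches(rule, stations)
  ant <- sum(matched)
  if (ant == 0L) {
    rule$conf <- NA_real_; rule$n <- 0; rule$antecedent_n <- 0
    rule$confusion <- NULL; rule$evaluable <- FALSE
    return(rule)
  }
  sup <- sum(matched & stations$habitat == rule$habitat)
  others <- setdiff(unique(stations$habitat[matched]), rule$habitat)
  confusion <- vapply(others, function(h) {
    100 * sum(matched & stations$habitat == h) / ant
  }, numeric(1L))
  rule$conf <- 100 * sup / ant
  rule$n <- sup
  rule$antecedent_n <- ant
  rule$confusion <- confusion[confusion > 0]
  rule$evaluable <- TRUE
  rule
}

#' Predict habitat for stations from a ruleset
#'
#' Evaluates every rule on every station. A station takes the habitat of
#' the unique firing rule and is `UNCLASSIFIED` when no rule fires. When
#' several rules fire the station is flagged as a conflict — the packaged
#' expert rules are designed to be mutually exclusive, so conflicts are
#' diagnostics — and the reported habitat follows `priority`:
#' `"confidence"` (default) takes the firing rule with the highest stored
#' confidence, `"none"` reports `NA` when the firing rules disagree.
#'
#' @param stations station data frame.
#' @param ruleset a `ruleset`, e.g. [expert_rules()].
#' @param priority conflict resolution mode.
#' @return Data frame of class `habitat_prediction`: `station_id`,
#'   `habitat`, `rule_id` (all firing rules, comma-separated), `confidence`
#'   (stored confidence of the reported rule), `n_fired`, `conflict`.
#' @export
predict_habitat <- function(stations, ruleset,
                            priority = c("confidence", "none")) {
  priority <- match.arg(priority)
  stopifnot(inherits(ruleset, "ruleset"))
  fired <- vapply(ruleset$rules, rule_matches, logical(nrow(stations)),
                  stations = stations)
  if (nrow(stations) == 1L) fired <- matrix(fired, nrow = 1L,
                                            dimnames = list(NULL, names(ruleset$rules)))
  confs <- vapply(ruleset$rules, `[[`, numeric(1L), "conf")
  habs <- vapply(ruleset$rules, `[[`, character(1L), "habitat")
  out <- lapply(seq_len(nrow(stations)), function(i) {
    f <- which(fired[i, ])
    if (!length(f)) {
      return(data.frame(station_id = as.character(stations$station_id[i]),
                        habitat = "UNCLASSIFIED", rule_id = NA_character_,
                        confidence = NA_real_, n_fired = 0L,
                        conflict = FALSE, stringsAsFactors = FALSE))
    }
    conflict <- length(f) > 1L
    hset <- unique(habs[f])
    if (length(hset) == 1L) {
      pick <- f[which.max(ifelse(is.na(confs[f]), -1, confs[f]))]
      hab <- hset
    } else if (priority == "confidence") {
      pick <- f[which.max(ifelse(is.na(confs[f]), -1, confs[f]))]
      hab <- habs[pick]
    } else {
      pick <- NA_integer_
      hab <- NA_character_
    }
    data.frame(station_id = as.character(stations$station_id[i]),
               habitat = hab,
               rule_id = paste(names(ruleset$rules)[f], collapse = ","),
               confidence = if (is.na(pick)) NA_real_ else confs[pick],
               n_fired = length(f), conflict = conflict,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("habitat_prediction", "data.frame")
  out
}

#' Assess a ruleset's coverage and confidence on labeled stations
#'
#' For each habitat: the percentage of its stations classified (at least
#' one rule fired) and the overall confidence — the percentage of classified
#' stations whose label matches the predicted habitat. The `Overall` row
#' pools across habitats, station-weighted by default (`weighting =
#' "habitat"` averages the per-habitat percentages instead). Habitats
#' absent from the data are omitted with a note.
#'
#' @param stations labeled station data frame.
#' @param ruleset a `ruleset`.
#' @param weighting `"station"` (pooled) or `"habitat"` (averaged) overall
#'   row.
#' @param priority conflict resolution passed to [predict_habitat()].
#' @return Data frame of class `ruleset_assessment`: `habitat`,
#'   `n_stations`, `n_classified`, `pct_classified`, `overall_confidence`.
#' @export
assess_ruleset <- function(stations, ruleset,
                           weighting = c("station", "habitat"),
                           priority = "confidence") {
  weighting <- match.arg(weighting)
  if (!"habitat" %in% names(stations) || anyNA(stations$habitat)) {
    stop("assess_ruleset() needs labeled stations", call. = FALSE)
  }
  pred <- predict_habitat(stations, ruleset, priority = priority)
  absent <- setdiff(habitat_levels(), unique(stations$habitat))
  if (length(absent)) {
    message("habitat(s) absent from the data, rows omitted: ",
            paste(absent, collapse = ", "))
  }
  habitats <- intersect(habitat_levels(), unique(stations$habitat))
  per <- lapply(habitats, function(h) {
    in_h <- stations$habitat == h
    classified <- in_h & pred$n_fired > 0L
    correct <- classified & !is.na(pred$habitat) & pred$habitat == h
    data.frame(habitat = h, n_stations = sum(in_h),
               n_classified = sum(classified),
               pct_classified = 100 * sum(classified) / sum(in_h),
               overall_confidence = if (sum(classified) == 0L) NA_real_ else
                 100 * sum(correct) / sum(classified),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  overall <- if (weighting == "station") {
    data.frame(habitat = "Overall", n_stations = sum(per$n_stations),
               n_classified = sum(per$n_classified),
               pct_classified = 100 * sum(per$n_classified) / sum(per$n_stations),
               overall_confidence = if (sum(per$n_classified) == 0L) NA_real_ else
                 100 * sum(per$n_classified * per$overall_confidence / 100,
                           na.rm = TRUE) / sum(per$n_classified),
               stringsAsFactors = FALSE)
  } else {
    data.frame(habitat = "Overall", n_stations = sum(per$n_stations),
               n_classified = sum(per$n_classified),
               pct_classified = mean(per$pct_classified),
               overall_confidence = mean(per$overall_confidence, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }
  out <- rbind(per, overall)
  rownames(out) <- NULL
  class(out) <- c("ruleset_assessment", "data.frame")
  out
}

#' @export
print.ruleset <- function(x, ...) {
  habs <- vapply(x$rules, `[[`, character(1L), "habitat")
  cat("Ruleset '", x$name, "' (v", x$version, "): ", length(x$rules),
      " rules\n", sep = "")
  tab <- table(factor(habs, levels = habitat_levels()))
  for (h in names(tab)) if (tab[[h]] > 0L) {
    cat(sprintf("  %-11s %d rule(s): %s\n", h, tab[[h]],
                paste(names(x$rules)[habs == h], collapse = ", ")))
  }
  if (nzchar(x$provenance)) cat("Provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
print.ruleset_assessment <- function(x, ...) {
  y <- as.data.frame(x)
  y$pct_classified <- round(y$pct_classified, 1L)
  y$overall_confidence <- round(y$overall_confidence, 1L)
  print(y, row.names = FALSE)
  invisible(x)
}
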