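#' Default discretization grid
#'
#' Cutpoints used to turn continuous station attributes into atomic interval
#' conditions for rule mining: \{1, 5, 15, 20, 40, 60, 80\} for every
#' percent cover (base and composite), \{1.5, 2, 3\} for complexity and
#' topography, and \{10\} for depth. These cutpoints span the thresholds
#' that appear in the packaged expert rules.
#'
#' @return Named list of numeric cutpoint vectors, one per attribute.
#' @export
default_grid <- function() {
  covers <- c(substrate_attributes(), biotic_attributes(),
              names(composite_attributes()))
  g <- c(
    stats::setNames(rep(list(c(1, 5, 15, 20, 40, 60, 80)), length(covers)),
                    covers),
    list(complexity = c(1.5, 2, 3), topography = c(1.5, 2, 3), depth = 10))
  g
}

# Atom catalogue for a grid: every interval [lo, hi) formed from consecutive
# or non-consecutive cutpoints, one-sided intervals included, the full range
# excluded. Lower bounds are inclusive, upper bounds exclusive, so an
# interval condition reads "lo <= x < hi" and one condition spans exactly
# one attribute.
grid_atoms <- function(grid) {
  rows <- list()
  for (a in names(grid)) {
    cuts <- sort(unique(grid[[a]]))
    if (!length(cuts)) stop("empty cutpoint set for ", a, call. = FALSE)
    bounds <- c(-Inf, cuts, Inf)
    nb <- length(bounds)
    for (i in seq_len(nb - 1L)) {
      for (j in seq.int(i + 1L, nb)) {
        lo <- bounds[i]; hi <- bounds[j]
        if (is.infinite(lo) && is.infinite(hi)) next
        id <- if (is.infinite(lo)) paste(a, "<", hi)
              else if (is.infinite(hi)) paste(a, ">=", lo)
              else paste(lo, "<=", a, "<", hi)
        rows[[length(rows) + 1L]] <- data.frame(
          id = id, attribute = a, lo = lo, hi = hi, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Discretize labeled stations into transactions
#'
#' Maps each labeled station to the set of atomic grid conditions it
#' satisfies. An atomic condition is a one-attribute interval `lo <= x < hi`
#' built from the grid cutpoints (one-sided conditions `x >= lo` and
#' `x < hi` included); a station's transaction contains every condition it
#' satisfies, so implied (wider) conditions are present alongside the
#' tightest one.
#'
#' @param stations labeled station data frame.
#' @param grid named list of cutpoints per attribute, see [default_grid()].
#' @return An object of class `reef_transactions`: a list with `matches`
#'   (stations x conditions logical matrix), `atoms` (condition catalogue:
#'   `id`, `attribute`, `lo`, `hi`), `labels` and `station_id`.
#' @export
discretize <- function(stations, grid = default_grid()) {
  if (!length(grid)) stop("empty discretization grid", call. = FALSE)
  if (!"habitat" %in% names(stations) || anyNA(stations$habitat)) {
    stop("discretize() needs labeled stations", call. = FALSE)
  }
  atoms <- grid_atoms(grid)
  vals <- vapply(unique(atoms$attribute), function(a) {
    attribute_values(stations, a)
  }, numeric(nrow(stations)))
  if (nrow(stations) == 1L) vals <- matrix(vals, nrow = 1L,
                                           dimnames = list(NULL, unique(atoms$attribute)))
  m <- matrix(FALSE, nrow(stations), nrow(atoms),
              dimnames = list(stations$station_id, atoms$id))
  for (q in seq_len(nrow(atoms))) {
    v <- vals[, atoms$attribute[q]]
    m[, q] <- v >= atoms$lo[q] & v < atoms$hi[q]
  }
  new_transactions(m, atoms, as.character(stations$habitat),
                   as.character(stations$station_id))
}

#' Assemble a transaction set directly
#'
#' Lower-level constructor used by the miner's tests and by callers that
#' already have a condition-match matrix (e.g. a custom discretization).
#'
#' @param matches logical matrix, stations x conditions.
#' @param atoms condition catalogue with columns `id` and `attribute` (and
#'   optionally `lo`, `hi`).
#' @param labels class label (habitat) per station.
#' @param station_id optional station ids.
#' @return A `reef_transactions` object.
#' @export
new_transactions <- function(matches, atoms, labels, station_id = NULL) {
  matches <- as.matrix(matches)
  stopifnot(nrow(atoms) == ncol(matches), length(labels) == nrow(matches))
  if (is.null(atoms$lo)) atoms$lo <- -Inf
  if (is.null(atoms$hi)) atoms$hi <- Inf
  structure(list(
    matches = matches,
    atoms = atoms,
    labels = as.character(labels),
    station_id = station_id %||% as.character(seq_len(nrow(matches)))
  ), class = "reef_transactions")
}

#' @export
print.reef_transactions <- function(x, ...) {
  cat("Transactions:", nrow(x$matches), "stations,", ncol(x$matches),
      "atomic conditions,", length(unique(x$labels)), "habitat classes\n")
  invisible(x)
}

#' Conditions satisfied by one station
#'
#' @param transactions a `reef_transactions` object.
#' @param station station index or id.
#' @return Character vector of condition ids.
#' @export
satisfied_conditions <- function(transactions, station) {
  if (is.character(station)) {
    station <- match(station, transactions$station_id)
  }
  transactions$atoms$id[transactions$matches[station, ]]
}
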