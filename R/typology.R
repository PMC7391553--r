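#' Default archetype attribute to habitat-name map
#'
#' Cluster naming assigns each cluster the habitat whose archetypical
#' attribute shows the largest standardized positive deviation of the
#' cluster mean from the global mean. Seagrass cover names Seagrass; erect
#' algae or algal turf name Macroalgae; sand names Sandy; the hard-substrate
#' components (debris, boulder, rock, slab) name Debris; live or recently
#' dead coral names Live Coral.
#'
#' @return Named character vector, attribute -> habitat.
#' @export
default_archetype_map <- function() {
  c(seagrass = "Seagrass",
    erect_algae = "Macroalgae", algal_turf = "Macroalgae",
    sand = "Sandy",
    debris = "Debris", boulder = "Debris", rock = "Debris", slab = "Debris",
    live_coral = "Live Coral", dead_coral = "Live Coral")
}

#' Build a habitat typology from labeled or unlabeled stations
#'
#' Constructs the habitat typology in the classic ordination-plus-clustering
#' idiom: station attributes are standardized to zero mean and unit
#' variance, a principal component analysis retains the leading axes
#' covering at least `var_cutoff` of the variance, stations are clustered by
#' hierarchical ascending clustering (Ward linkage on Euclidean distances in
#' the retained axis space), and each cluster is named after its
#' archetypical attribute — the attribute with the largest standardized
#' positive deviation of the cluster mean from the global mean, mapped to a
#' habitat name through `archetype_map`.
#'
#' The returned model is not yet consolidated; see [consolidate()] for the
#' supervised reassignment of low-archetype stations and the fitting of the
#' random-forest classifiers used by [predict.habitat_typology()].
#'
#' @param stations station data frame (see [read_stations()]).
#' @param n_clusters number of clusters (default 5).
#' @param var_cutoff minimum cumulative variance share retained by the
#'   ordination (default 0.8).
#' @param seed integer seed stored in the model and used by the ensemble
#'   classifiers fitted at consolidation.
#' @param archetype_map attribute -> habitat naming map; see
#'   [default_archetype_map()].
#' @param cluster_names optional manual habitat names (character vector of
#'   length `n_clusters`), bypassing archetype naming on conflicts.
#' @return An object of class `habitat_typology`.
#' @export
habitat_typology <- function(stations, n_clusters = 5L, var_cutoff = 0.8,
                             seed = 1L, archetype_map = default_archetype_map(),
                             cluster_names = NULL) {
  attrs <- station_attributes(stations)
  if (nrow(attrs) < n_clusters) {
    stop("need at least ", n_clusters, " stations", call. = FALSE)
  }
  if (anyNA(attrs)) stop("stations with incomplete attribute profiles", call. = FALSE)

  sds <- vapply(attrs, stats::sd, numeric(1L))
  if (any(sds == 0)) {
    warning("dropping constant attribute(s): ",
            paste(names(attrs)[sds == 0], collapse = ", "), call. = FALSE)
    attrs_used <- attrs[, sds > 0, drop = FALSE]
  } else attrs_used <- attrs

  pca <- stats::prcomp(attrs_used, center = TRUE, scale. = TRUE)
  cumvar <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  n_axes <- max(2L, which(cumvar >= var_cutoff)[1L])
  scores <- pca$x[, seq_len(n_axes), drop = FALSE]

  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  cluster <- stats::cutree(hc, k = n_clusters)

  # archetypical attribute: largest standardized positive deviation of the
  # cluster mean from the global mean among the mapped candidate attributes
  cand <- intersect(names(archetype_map), names(attrs_used))
  gmean <- colMeans(attrs_used[, cand, drop = FALSE])
  gsd <- vapply(attrs_used[, cand, drop = FALSE], stats::sd, numeric(1L))
  arch_attr <- character(n_clusters)
  for (k in seq_len(n_clusters)) {
    cmean <- colMeans(attrs_used[cluster == k, cand, drop = FALSE])
    dev <- (cmean - gmean) / gsd
    arch_attr[k] <- cand[which.max(dev)]
  }

  if (is.null(cluster_names)) {
    habitat_names <- unname(archetype_map[arch_attr])
    if (anyDuplicated(habitat_names)) {
      dup <- habitat_names[duplicated(habitat_names)]
      stop("archetype naming conflict: habitat '", dup[1L],
           "' claimed by more than one cluster; supply `cluster_names` ",
           "to name clusters manually", call. = FALSE)
    }
  } else {
    if (length(cluster_names) != n_clusters) {
      stop("`cluster_names` must have length ", n_clusters, call. = FALSE)
    }
    habitat_names <- cluster_names
  }

  structure(list(
    call = match.call(),
    stations = stations,
    attributes = names(attrs_used),
    pca = pca,
    n_axes = n_axes,
    variance_retained = cumvar[n_axes],
    hclust = hc,
    n_clusters = n_clusters,
    cluster = cluster,
    cluster_habitat = stats::setNames(habitat_names, seq_len(n_clusters)),
    archetype_attribute = stats::setNames(arch_attr, habitat_names),
    habitat = habitat_names[cluster],
    reassigned = rep(FALSE, nrow(stations)),
    consolidated = FALSE,
    archetype_threshold = NA_real_,
    rf_consolidation = NULL,
    rf_projection = NULL,
    seed = seed
  ), class = "habitat_typology")
}

#' Consolidate a typology with a supervised reassignment
#'
#' Stations whose own value of their cluster's archetypical attribute falls
#' below `threshold` (default 15%) are set aside; a random forest (default
#' 1,000 trees, square-root features per split) is trained on the remaining
#' labeled stations and predicts a habitat for the set-aside stations, which
#' are reassigned accordingly and flagged. A second forest — the projection
#' classifier used by [predict.habitat_typology()] — is then trained on the
#' full consolidated typology. Out-of-bag (OOB) error estimates of both
#' forests are recorded.
#'
#' Stations already reassigned by a previous consolidation are never set
#' aside again, making consolidation idempotent: a second call at the same
#' threshold returns the model unchanged.
#'
#' @param model a `habitat_typology`.
#' @param threshold archetype percent-cover threshold in (0, 100\];
#'   `threshold = 0` disables reassignment.
#' @param ntree trees per forest (default 1000).
#' @return The consolidated `habitat_typology`.
#' @export
consolidate <- function(model, threshold = 15, ntree = 1000L) {
  stopifnot(inherits(model, "habitat_typology"))
  if (threshold < 0 || threshold >= 100) {
    stop("`threshold` must be in [0, 100)", call. = FALSE)
  }
  attrs <- station_attributes(model$stations)[, model$attributes, drop = FALSE]
  arch_of_station <- model$archetype_attribute[model$habitat]
  own <- vapply(seq_len(nrow(attrs)), function(i) {
    attribute_values(model$stations[i, , drop = FALSE],
                     unname(arch_of_station[i]))
  }, numeric(1L))
  set_aside <- !model$reassigned & own < threshold

  if (model$consolidated && !any(set_aside)) return(model)

  keep <- !set_aside
  lost <- setdiff(unname(model$cluster_habitat), unique(model$habitat[keep]))
  if (length(lost)) {
    stop("consolidation would remove every station of habitat: ",
         paste(lost, collapse = ", "), call. = FALSE)
  }

  y_keep <- factor(model$habitat[keep], levels = sort(unique(model$habitat)))
  rf1 <- with_seed(model$seed, randomForest::randomForest(
    x = attrs[keep, , drop = FALSE], y = y_keep, ntree = ntree,
    mtry = floor(sqrt(ncol(attrs)))))
  habitat <- model$habitat
  if (any(set_aside)) {
    pred <- stats::predict(rf1, attrs[set_aside, , drop = FALSE])
    habitat[set_aside] <- as.character(pred)
  }

  y_all <- factor(habitat, levels = sort(unique(habitat)))
  rf2 <- with_seed(model$seed + 1L, randomForest::randomForest(
    x = attrs, y = y_all, ntree = ntree, mtry = floor(sqrt(ncol(attrs)))))

  model$habitat <- habitat
  model$reassigned <- model$reassigned | set_aside
  model$consolidated <- TRUE
  model$archetype_threshold <- threshold
  model$rf_consolidation <- rf1
  model$rf_projection <- rf2
  model$oob <- c(consolidation = unname(rf1$err.rate[ntree, "OOB"]),
                 projection = unname(rf2$err.rate[ntree, "OOB"]))
  model
}

#' Predict habitat for new stations from a consolidated typology
#'
#' Projects new stations on the typology through the projection random
#' forest fitted by [consolidate()]. Vote shares across habitats sum to 1
#' per station.
#'
#' @param object a consolidated `habitat_typology`.
#' @param newdata station data frame.
#' @param type `"habitat"` for labels plus vote shares, `"votes"` for the
#'   vote matrix only.
#' @param ... unused.
#' @return Data frame with `station_id`, `habitat` and one vote-share
#'   column per habitat.
#' @export
predict.habitat_typology <- function(object, newdata,
                                     type = c("habitat", "votes"), ...) {
  type <- match.arg(type)
  if (!object$consolidated) {
    stop("the typology must be consolidated (see consolidate()) before ",
         "projecting new stations", call. = FALSE)
  }
  attrs <- station_attributes(newdata)
  missing <- setdiff(object$attributes, names(attrs))
  if (length(missing)) {
    stop("new stations are missing attribute(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- attrs[, object$attributes, drop = FALSE]
  votes <- stats::predict(object$rf_projection, x, type = "vote",
                          norm.votes = TRUE)
  if (type == "votes") return(votes)
  lab <- colnames(votes)[max.col(votes, ties.method = "first")]
  out <- data.frame(station_id = as.character(newdata$station_id),
                    habitat = lab, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(votes, check.names = FALSE))
}

#' Characterize habitat clusters by attribute means
#'
#' For every habitat and attribute, compares the cluster mean against the
#' global mean over all stations with a two-sided Welch test, Holm-corrected
#' across attributes within the habitat. Attributes are reported by
#' decreasing significance, tiered as highly significant (adjusted p below
#' `tier`, default 1e-50) or significant (below `alpha`, default 0.05), with
#' the direction of the deviation.
#'
#' @param x a `habitat_typology` (its stations and consolidated labels are
#'   used) or a labeled station data frame.
#' @param alpha significance level (default 0.05).
#' @param tier threshold for the "highly significant" tier (default 1e-50).
#' @param ... unused.
#' @return Data frame of class `cluster_characterization`: `habitat`,
#'   `attribute`, `direction` (higher/lower), `cluster_mean`, `global_mean`,
#'   `p_adj`, `significance`.
#' @export
characterize <- function(x, ...) UseMethod("characterize")

#' @rdname characterize
#' @export
characterize.habitat_typology <- function(x, alpha = 0.05, tier = 1e-50, ...) {
  stations <- x$stations
  stations$habitat <- x$habitat
  characterize.data.frame(stations, alpha = alpha, tier = tier)
}

#' @rdname characterize
#' @export
characterize.data.frame <- function(x, alpha = 0.05, tier = 1e-50, ...) {
  if (!"habitat" %in% names(x) || all(is.na(x$habitat))) {
    stop("characterize() needs labeled stations", call. = FALSE)
  }
  attrs <- station_attributes(x)
  habitats <- unique(stats::na.omit(x$habitat))
  rows <- list()
  for (h in habitats) {
    in_h <- !is.na(x$habitat) & x$habitat == h
    if (sum(in_h) < 2L) {
      warning("habitat ", h, " has fewer than 2 stations; skipped", call. = FALSE)
      next
    }
    p <- numeric(ncol(attrs)); cm <- numeric(ncol(attrs)); gm <- numeric(ncol(attrs))
    for (j in seq_along(attrs)) {
      v <- attrs[[j]]
      cm[j] <- mean(v[in_h]); gm[j] <- mean(v)
      p[j] <- if (stats::sd(v[in_h]) == 0 && stats::sd(v) == 0) NA_real_ else
        tryCatch(stats::t.test(v[in_h], v)$p.value, error = function(e) NA_real_)
    }
    p_adj <- stats::p.adjust(p, method = "holm")
    sig <- ifelse(is.na(p_adj), "ns",
                  ifelse(p_adj < tier, "highly significant",
                         ifelse(p_adj < alpha, "significant", "ns")))
    rows[[h]] <- data.frame(
      habitat = h, attribute = names(attrs),
      direction = ifelse(cm > gm, "higher", ifelse(cm < gm, "lower", "equal")),
      cluster_mean = cm, global_mean = gm, p_adj = p_adj,
      significance = sig, stringsAsFactors = FALSE)
    rows[[h]] <- rows[[h]][order(rows[[h]]$p_adj), , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cluster_characterization", "data.frame")
  out
}

#' @export
print.habitat_typology <- function(x, ...) {
  cat("Habitat typology:", x$n_clusters, "clusters from",
      nrow(x$stations), "stations\n")
  cat(sprintf("Ordination: %d axes retained (%.1f%% variance)\n",
              x$n_axes, 100 * x$variance_retained))
  tab <- table(x$habitat)
  for (h in names(tab)) {
    attr_h <- x$archetype_attribute[h]
    cat(sprintf("  %-11s %4d stations (archetype: %s)\n", h, tab[[h]],
                if (is.na(attr_h)) "?" else attr_h))
  }
  if (x$consolidated) {
    cat(sprintf("Consolidated at threshold %g%%: %d station(s) reassigned\n",
                x$archetype_threshold, sum(x$reassigned)))
    cat(sprintf("OOB error: consolidation %.1f%%, projection %.1f%%\n",
                100 * x$oob[["consolidation"]], 100 * x$oob[["projection"]]))
  } else {
    cat("Not consolidated (run consolidate() before predicting)\n")
  }
  invisible(x)
}

#' @export
summary.habitat_typology <- function(object, ...) {
  print(object)
  cat("\nCluster characterization (top attributes per habitat):\n")
  ch <- characterize(object)
  top <- do.call(rbind, lapply(split(ch, ch$habitat), utils::head, 3L))
  print(as.data.frame(top), row.names = FALSE, digits = 3L)
  invisible(object)
}

#' @export
plot.habitat_typology <- function(x, which = c("ordination", "dendrogram"), ...) {
  which <- match.arg(which)
  if (which == "dendrogram") {
    plot(x$hclust, labels = FALSE, main = "Hierarchical ascending clustering",
         xlab = "", sub = "")
  } else {
    sc <- x$pca$x[, 1:2]
    cols <- seq_len(x$n_clusters)[x$cluster]
    plot(sc, col = cols, pch = 16, cex = 0.6,
         main = "Stations on the first two ordination axes",
         xlab = "PC1", ylab = "PC2", ...)
    graphics::legend("topright", legend = unname(x$cluster_habitat),
                     col = seq_len(x$n_clusters), pch = 16, cex = 0.8)
  }
  invisible(x)
}
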