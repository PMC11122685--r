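# Catalytic-distance extraction, k-means clustering in (d1, d2) space, and
# competence-box / threshold occupancy statistics.

#' Named catalytic distance specification
#'
#' Pairs of atom specs to be tracked per frame; the canonical set is the
#' five active-site distances (primer O3' to Mg_A, primer O3' to dNTP
#' alpha-phosphate, catalytic-aspartate OD1/OD2 to Mg_A, second-aspartate
#' to Mg_B).
#'
#' @param name Distance name (e.g. `"d1"`).
#' @param spec1,spec2 Atom specs (`"chain:resno:name"` or lists; see
#'   [atom_pair_distance()]).
#' @param role Optional free-text tag (e.g. colour or figure role).
#' @return A `distance_spec`.
#' @export
distance_spec <- function(name, spec1, spec2, role = NA_character_) {
  structure(list(name = name, spec1 = spec1, spec2 = spec2, role = role),
            class = "distance_spec")
}

#' Extract per-frame distances for a set of atom-pair specs
#'
#' @param ensemble A [conf_ensemble()].
#' @param specs A list of [distance_spec()] objects (or a single one).
#' @return Wide tibble: `frame` plus one column per spec name (Angstrom).
#' @export
extract_distances <- function(ensemble, specs) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  if (inherits(specs, "distance_spec")) specs <- list(specs)
  idx <- lapply(specs, function(s) {
    c(resolve_atom_spec(ensemble, s$spec1),
      resolve_atom_spec(ensemble, s$spec2))
  })
  nf <- n_frames(ensemble)
  out <- tibble(frame = seq_len(nf))
  for (k in seq_along(specs)) {
    i <- idx[[k]][1]; j <- idx[[k]][2]
    d <- sqrt(rowSums((ensemble$coords[, i, , drop = TRUE] -
                         ensemble$coords[, j, , drop = TRUE])^2))
    if (nf == 1L) d <- sqrt(sum((frame_coords(ensemble, 1)[i, ] -
                                   frame_coords(ensemble, 1)[j, ])^2))
    out[[specs[[k]]$name]] <- d
  }
  out
}

# k-means++ seeding (Arthur & Vassilvitskii): first centre uniform, later
# centres with probability proportional to squared distance to the nearest
# chosen centre.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in 2:k) {
    p <- d2 / sum(d2)
    centers[j, ] <- x[sample.int(n, 1L, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' k-means clustering of a 2-D distance distribution
#'
#' Lloyd iterations (via [stats::kmeans()]) from k-means++ initial centres,
#' best of `n_init` restarts by total within-cluster sum of squares;
#' deterministic given `seed`. Distances are clustered unscaled (both axes
#' are Angstrom). When `k = NULL`, k is chosen by mean silhouette width
#' over `k = 2..6` (computed on a subsample when F is large).
#'
#' @param points F x 2 matrix / data frame (or a distance tibble with `d1`,
#'   `d2` columns).
#' @param k Number of clusters, or `NULL` for silhouette-selected.
#' @param seed RNG seed (default 853).
#' @param n_init Number of k-means++ restarts.
#' @return A `competence_clusters`: `k`, `centroids` (tibble `cluster`,
#'   `d1`, `d2`, `occupancy`), `assignment` (per-frame cluster), `tot_withinss`,
#'   `seed`. Has [tidy()] and [autoplot()] methods.
#' @export
kmeans_2d <- function(points, k = NULL, seed = 853L, n_init = 10L) {
  x <- points
  if (is.data.frame(x)) {
    if (all(c("d1", "d2") %in% names(x))) {
      x <- as.matrix(x[, c("d1", "d2")])
    } else {
      x <- as.matrix(x)
    }
  }
  if (ncol(x) != 2L) abort("`points` must be F x 2.")
  nfr <- nrow(x)
  kmax <- if (is.null(k)) 6L else k
  if (nfr < kmax) abort("Need at least k points.")
  if (!is.null(k) && nrow(unique(x)) < k) {
    abort("Fewer distinct points than clusters requested.")
  }

  with_seed(seed, {
    if (is.null(k)) {
      sub <- if (nfr > 5000L) x[sample.int(nfr, 5000L), , drop = FALSE] else x
      ks <- 2:6
      sil <- vapply(ks, function(kk) {
        cl <- kmeans(sub, centers = kmeanspp_centers(sub, kk),
                     algorithm = "Lloyd", iter.max = 100L)
        mean(cluster::silhouette(cl$cluster, dist(sub))[, 3])
      }, numeric(1))
      k <- ks[which.max(sil)]
    }
    best <- NULL
    for (r in seq_len(n_init)) {
      fit <- suppressWarnings(
        kmeans(x, centers = kmeanspp_centers(x, k), algorithm = "Lloyd",
               iter.max = 200L))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    # relabel clusters by ascending d1 centroid for reproducible identity
    ord <- order(best$centers[, 1], best$centers[, 2])
    relab <- match(seq_len(k), ord)
    assignment <- relab[best$cluster]
    centers <- best$centers[ord, , drop = FALSE]
    occ <- tabulate(assignment, nbins = k) / nfr
    structure(
      list(k = k,
           centroids = tibble(cluster = seq_len(k),
                              d1 = unname(centers[, 1]),
                              d2 = unname(centers[, 2]),
                              occupancy = occ),
           assignment = assignment,
           tot_withinss = best$tot.withinss,
           seed = seed, points = x),
      class = "competence_clusters")
  })
}

#' @export
print.competence_clusters <- function(x, ...) {
  cat(sprintf("<competence_clusters> k = %d over %d frames (WSS %.2f)\n",
              x$k, length(x$assignment), x$tot_withinss))
  print(x$centroids)
  invisible(x)
}

#' @rdname kmeans_2d
#' @param x A `competence_clusters`.
#' @param ... Unused.
#' @method tidy competence_clusters
#' @export
tidy.competence_clusters <- function(x, ...) {
  x$centroids
}

#' Competence box in (d1, d2) space
#'
#' The closed rectangle within which the active site is geometrically poised
#' for phosphoryl transfer; defaults d1 in `[3.0, 3.8]`, d2 in `[2.8, 3.5]`
#' Angstrom.
#'
#' @param d1_min,d1_max,d2_min,d2_max Box edges, Angstrom.
#' @return A `competence_box`.
#' @export
competence_box <- function(d1_min = 3.0, d1_max = 3.8,
                           d2_min = 2.8, d2_max = 3.5) {
  if (d1_min >= d1_max || d2_min >= d2_max) {
    abort("Box edges must satisfy low < high on both axes.")
  }
  structure(list(d1_min = d1_min, d1_max = d1_max,
                 d2_min = d2_min, d2_max = d2_max),
            class = "competence_box")
}

#' Fraction of frames inside the competence box
#'
#' Counts frames whose (d1, d2) lie inside the closed box. When a
#' [kmeans_2d()] result is supplied, the fraction of frames belonging to
#' clusters whose centroid lies inside the box is reported as well (the two
#' counts answer slightly different questions and can differ near the box
#' edges), along with which centroids fall inside.
#'
#' @param series Tibble with `d1`, `d2` columns.
#' @param box A [competence_box()].
#' @param clusters Optional `competence_clusters` over the same frames.
#' @return One-row tibble: `occupancy`, `n_inside`, `n_frames`, and (when
#'   `clusters` given) `occupancy_by_cluster` and `clusters_inside`
#'   (list-column of cluster ids).
#' @export
box_occupancy <- function(series, box = competence_box(), clusters = NULL) {
  if (!all(c("d1", "d2") %in% names(series))) {
    abort("`series` must contain d1 and d2 columns.")
  }
  stopifnot(inherits(box, "competence_box"))
  inside <- series$d1 >= box$d1_min & series$d1 <= box$d1_max &
    series$d2 >= box$d2_min & series$d2 <= box$d2_max
  out <- tibble(occupancy = mean(inside), n_inside = sum(inside),
                n_frames = length(inside))
  if (!is.null(clusters)) {
    stopifnot(inherits(clusters, "competence_clusters"))
    if (length(clusters$assignment) != nrow(series)) {
      abort("Cluster assignment length does not match the series.")
    }
    cen <- clusters$centroids
    cin <- cen$cluster[cen$d1 >= box$d1_min & cen$d1 <= box$d1_max &
                         cen$d2 >= box$d2_min & cen$d2 <= box$d2_max]
    out$occupancy_by_cluster <- mean(clusters$assignment %in% cin)
    out$clusters_inside <- list(cin)
  }
  out
}

#' Competent / intermediate / incompetent fractions by d1 thresholds
#'
#' Strict inequalities: competent `d1 < competent_max`, incompetent
#' `d1 > incompetent_min`, intermediate otherwise; the three fractions sum
#' to 1. Defaults 3.8 / 4.0 Angstrom.
#'
#' @param series Tibble with a `d1` column (or a numeric d1 vector).
#' @param competent_max,incompetent_min Thresholds, Angstrom, with
#'   `competent_max <= incompetent_min`.
#' @return One-row tibble `f_competent`, `f_intermediate`, `f_incompetent`.
#' @export
threshold_fractions <- function(series, competent_max = 3.8,
                                incompetent_min = 4.0) {
  if (competent_max > incompetent_min) {
    abort("`competent_max` must be <= `incompetent_min`.")
  }
  d1 <- if (is.data.frame(series)) {
    if (!"d1" %in% names(series)) abort("`series` must contain d1.")
    series$d1
  } else {
    as.numeric(series)
  }
  tibble(f_competent = mean(d1 < competent_max),
         f_intermediate = mean(d1 >= competent_max & d1 <= incompetent_min),
         f_incompetent = mean(d1 > incompetent_min))
}
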