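# AGIS visual-field severity score (0-20) and its category mapping.
#
# The score is built from the total-deviation map: a nasal contribution
# (0-2) from contiguous depressed locations in the six nasal sites
# adjacent to the horizontal midline, and superior/inferior hemifield
# contributions (0-9 each) from clusters of >= 3 adjacent depressed
# locations, graded by extent and by how many sites meet increasingly
# deep dB criteria.  The exact defect criteria of the original study
# protocol are not reprinted here; a synthetic reconstruction with the
# same structure is shipped as an editable JSON table (see
# `agis_criteria()`), with the depth rule made count-based so that the
# score is monotone under pointwise depression.

#' Load the AGIS scoring criteria table
#'
#' Reads the packaged synthetic criteria table (or a user-supplied
#' file with the same schema).  All thresholds used by [agis_score()]
#' live in this one table.
#'
#' @param path JSON file; default the packaged
#'   `agis_criteria_synthetic.json`.
#' @return a list of criteria, class `agis_criteria`.
#' @export
agis_criteria <- function(path = NULL) {
  path <- path %||% system.file("extdata", "agis_criteria_synthetic.json",
                                package = "perisim", mustWork = TRUE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.matrix(obj$nasal$sites))
    obj$nasal$sites <- matrix(unlist(obj$nasal$sites), ncol = 2L, byrow = TRUE)
  class(obj) <- "agis_criteria"
  obj
}

#' Map an AGIS score to a severity category
#'
#' Categories: 0 none, 1-5 mild, 6-11 moderate, 12-17 severe, 18-20
#' end-stage.
#'
#' @param score integer score(s) in 0..20.
#' @return factor with levels none/mild/moderate/severe/end-stage.
#' @export
agis_category <- function(score) {
  if (any(score < 0 | score > 20 | score != round(score)))
    stop_perisim("AGIS scores must be integers in 0..20")
  cut(score, breaks = c(-0.5, 0.5, 5.5, 11.5, 17.5, 20.5),
      labels = c("none", "mild", "moderate", "severe", "end-stage"))
}

# Connected components of depressed sites under 8-adjacency on the
# 6-degree lattice, never crossing the horizontal midline.
depressed_clusters <- function(pts, depressed) {
  idx <- which(depressed)
  comp <- integer(0)
  if (!length(idx)) return(list())
  labels <- rep(NA_integer_, length(idx))
  nxt <- 0L
  for (s in seq_along(idx)) {
    if (!is.na(labels[s])) next
    nxt <- nxt + 1L
    queue <- s
    labels[s] <- nxt
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      i <- idx[cur]
      nb <- which(is.na(labels) &
                  abs(pts$x[idx] - pts$x[i]) <= 6 &
                  abs(pts$y[idx] - pts$y[i]) <= 6 &
                  sign(pts$y[idx]) == sign(pts$y[i]))
      labels[nb] <- nxt
      queue <- c(queue, nb)
    }
  }
  split(idx, labels)
}

hemifield_score <- function(pts, td, sites, crit) {
  if (!length(sites)) return(0L)
  ecc <- sqrt(pts$x[sites]^2 + pts$y[sites]^2)
  depth_req <- ifelse(ecc > crit$peripheral_ecc,
                      crit$depth_db_peripheral, crit$depth_db_central)
  depressed <- td[sites] <= -depth_req
  sub <- pts[sites, , drop = FALSE]
  clusters <- depressed_clusters(sub, depressed)
  clusters <- clusters[lengths(clusters) >= crit$min_cluster]
  if (!length(clusters)) return(0L)
  in_cluster <- unlist(clusters)
  n_dep <- length(in_cluster)
  extent <- max(c(0L, crit$extent_points[crit$extent_breaks <= n_dep]))
  depth_pts <- sum(vapply(crit$depth_levels, function(d)
    sum(td[sites][in_cluster] <= -d) >= crit$depth_min_sites, logical(1)))
  as.integer(extent + depth_pts)
}

#' AGIS severity score of a total-deviation map
#'
#' Scores the field on the common 66-location grid (default) or the
#' full 30-2 grid: a nasal contribution of up to 2 points (one for a
#' run of at least 3 contiguous nasal sites depressed past the nasal
#' criterion, one more for a total nasal defect with all six sites
#' deeply depressed), and up to 9 points per hemifield from clusters of
#' at least 3 adjacent depressed sites, graded by the number of
#' clustered depressed sites and by how many reach each of the deeper
#' dB levels.  Blind-spot locations are ignored.  Deterministic and
#' monotone: deepening any location never decreases the score.
#'
#' @param td total-deviation vector (reference dB; negative = loss).
#' @param grid the `perim_grid` the deviations live on; must contain
#'   the six nasal sites.
#' @param criteria an [agis_criteria()] table.
#' @return object of class `agis_result`: `score` (0-20), `category`,
#'   and the `nasal`, `superior`, `inferior` contributions.
#' @export
agis_score <- function(td, grid = build_grid("SPARK66"),
                       criteria = agis_criteria()) {
  stopifnot(inherits(grid, "perim_grid"), length(td) == grid_size(grid),
            inherits(criteria, "agis_criteria"))
  pts <- grid$points
  ns <- criteria$nasal$sites
  nasal_idx <- match(paste(ns[, 1], ns[, 2]), paste(pts$x, pts$y))
  if (anyNA(nasal_idx)) {
    miss <- which(is.na(nasal_idx))
    stop_perisim("grid is missing required nasal site(s): ",
                 paste(sprintf("(%g, %g)", ns[miss, 1], ns[miss, 2]),
                       collapse = ", "))
  }
  # nasal contribution: contiguity within the 2 x 3 nasal block
  # (4-adjacency, midline crossing allowed within the nasal area)
  dep_n <- td[nasal_idx] <= -criteria$nasal$depth_db
  nx <- pts$x[nasal_idx]; ny <- pts$y[nasal_idx]
  run_max <- 0L
  if (any(dep_n)) {
    di <- which(dep_n)
    lab <- seq_along(di)
    repeat {
      changed <- FALSE
      for (a in seq_along(di)) for (b in seq_along(di)) {
        if (lab[a] != lab[b] &&
            abs(nx[di[a]] - nx[di[b]]) + abs(ny[di[a]] - ny[di[b]]) == 6) {
          lab[lab == lab[b]] <- lab[a]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    run_max <- max(table(lab))
  }
  nasal <- as.integer(run_max >= criteria$nasal$min_contiguous) +
    as.integer(all(td[nasal_idx] <= -criteria$nasal$total_depth_db))
  eligible <- setdiff(which(!grid$blind_spot), nasal_idx)
  sup <- hemifield_score(pts, td, eligible[pts$y[eligible] > 0],
                         criteria$hemifield)
  inf <- hemifield_score(pts, td, eligible[pts$y[eligible] < 0],
                         criteria$hemifield)
  score <- min(nasal + sup + inf, criteria$score_max)
  structure(list(score = as.integer(score),
                 category = agis_category(score),
                 nasal = nasal, superior = sup, inferior = inf),
            class = "agis_result")
}

#' @export
print.agis_result <- function(x, ...) {
  cat(sprintf("<agis_result> score %d (%s): nasal %d, superior %d, inferior %d\n",
              x$score, as.character(x$category), x$nasal, x$superior,
              x$inferior))
  invisible(x)
}
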