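# Normative database construction and global visual-field indices.
#
# All index computation happens on the reference (k = 40) dB scale;
# build_normative_db() converts measured thresholds before storing
# moments so that databases from different instruments are comparable.

#' Build a normative database by simulating and measuring normals
#'
#' Simulates `n` healthy observers over the given age range, measures
#' each with the requested strategy/instrument, converts thresholds to
#' the reference scale, and stores per-location means, SDs, an age
#' slope (linear regression of threshold on age) and empirical
#' total-deviation and pattern-deviation percentile cut-offs.
#' Deterministic given the seed.
#'
#' @param n number of normal observers (>= 50).
#' @param age_range ages sampled uniformly from this range (years).
#' @param seed RNG seed (also recorded as provenance).
#' @param strategy `"staircase42"` or `"spark"`.
#' @param inst an `instrument_model`.
#' @param grid_name truth/measurement grid: `"30-2"` for the staircase,
#'   forced to `"SPARK66"` for the interpolation strategy.
#' @param regression_model seed model for the `"spark"` strategy (a
#'   default is fitted from the normals' true fields when omitted).
#' @param levels percentile levels for the deviation cut-offs.  Levels
#'   finer than `1/n` are computed anyway but flagged with a warning
#'   (too few normals for the requested tail).
#' @param gh_percentile general-height percentile used for pattern
#'   deviation (default 0.85).
#' @return object of class `normative_db`.
#' @export
build_normative_db <- function(n = 60L, age_range = c(40, 70), seed = 1L,
                               strategy = c("staircase42", "spark"),
                               inst = instrument("hfa"),
                               grid_name = "30-2",
                               regression_model = NULL,
                               levels = c(0.05, 0.02),
                               gh_percentile = 0.85) {
  strategy <- match.arg(strategy)
  if (n < 50L) stop_perisim("at least 50 normals are required (got ", n, ")")
  fine <- levels < 1 / n
  if (any(fine))
    warning("percentile level(s) ", paste(levels[fine], collapse = ", "),
            " need more than ", n, " normals; cut-offs will be coarse")
  if (strategy == "spark") grid_name <- "SPARK66"
  grid <- build_grid(grid_name)
  with_seed(seed, {
    ages <- stats::runif(n, age_range[1], age_range[2])
    obs <- lapply(seq_len(n), function(i) {
      fld <- normal_field(grid, age = ages[i], seed = derive_seed(seed, i))
      new_observer(sprintf("norm_%03d", i), "normal", ages[i], fld,
                   response_params())
    })
    if (strategy == "spark" && is.null(regression_model))
      regression_model <- fit_seed_regression(
        do.call(rbind, lapply(obs, function(o) o$field$sensitivity)))
    meas <- vapply(seq_len(n), function(i) {
      out <- if (strategy == "spark")
        run_spark(obs[[i]], inst, regression_model,
                  seed = derive_seed(seed, 10000 + i))
      else
        staircase_42(obs[[i]], inst, seed = derive_seed(seed, 10000 + i))
      out$thresholds + ref_offset(inst)   # to reference scale
    }, numeric(grid_size(grid)))
    meas <- t(meas)                       # n x L
    mean_age <- mean(ages)
    ac <- ages - mean_age
    slope <- drop(crossprod(ac, meas)) / sum(ac^2)
    mu <- colMeans(meas)
    # residual TD of the normals against their own age-corrected means
    td <- meas - outer(ac, slope) - rep(mu, each = n)
    gh <- apply(td, 1L, stats::quantile, probs = gh_percentile, names = FALSE)
    pd <- td - gh
    # type-6 quantiles: E[P(new < q_hat)] ~ p, so held-out normals are
    # flagged at close to the nominal rate
    td_cut <- apply(td, 2L, stats::quantile, probs = levels, names = FALSE,
                    type = 6)
    pd_cut <- apply(pd, 2L, stats::quantile, probs = levels, names = FALSE,
                    type = 6)
    if (length(levels) == 1L) {
      td_cut <- matrix(td_cut, nrow = 1L); pd_cut <- matrix(pd_cut, nrow = 1L)
    }
    rownames(td_cut) <- rownames(pd_cut) <- paste0("p", levels * 100)
    structure(list(grid_name = grid_name, strategy = strategy,
                   instrument = inst$name, mean = mu,
                   sd = apply(meas, 2L, stats::sd),
                   age_slope = slope, mean_age = mean_age,
                   levels = levels, td_cutoffs = td_cut,
                   pd_cutoffs = pd_cut, gh_percentile = gh_percentile,
                   provenance = list(n = n, seed = seed,
                                     age_range = age_range)),
              class = "normative_db")
  })
}

#' @export
print.normative_db <- function(x, ...) {
  cat(sprintf("<normative_db> %s / %s on %s grid: n = %d normals, mean of means %.1f dB\n",
              x$strategy, x$instrument, x$grid_name, x$provenance$n,
              mean(x$mean)))
  invisible(x)
}

#' Write / read a normative database as JSON
#'
#' @param db a `normative_db`.
#' @param path file path.
#' @return the path (write) or a `normative_db` (read).
#' @export
write_normative_json <- function(db, path) {
  stopifnot(inherits(db, "normative_db"))
  obj <- unclass(db)
  obj$td_cutoffs <- as.data.frame(t(obj$td_cutoffs))
  obj$pd_cutoffs <- as.data.frame(t(obj$pd_cutoffs))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normative_json
#' @export
read_normative_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$td_cutoffs <- t(as.matrix(obj$td_cutoffs))
  obj$pd_cutoffs <- t(as.matrix(obj$pd_cutoffs))
  class(obj) <- "normative_db"
  obj
}

#' Mean sensitivity of a measured field
#'
#' Arithmetic mean of the thresholds over non-masked locations.
#'
#' @param thresholds numeric vector of measured thresholds (dB).
#' @param mask optional logical vector, `TRUE` = exclude.
#' @return mean sensitivity in dB.
#' @export
mean_sensitivity <- function(thresholds, mask = NULL) {
  if (!is.null(mask)) thresholds <- thresholds[!mask]
  if (!length(thresholds)) stop_perisim("no locations left after masking")
  mean(thresholds)
}

#' Total deviation from age-corrected normal
#'
#' `TD = measured - (normative mean + age_slope * (age - mean_age))`
#' per location, on the reference scale.
#'
#' @param thresholds measured thresholds on the reference (k = 40)
#'   scale, same grid and order as the database.
#' @param db a `normative_db`.
#' @param age observer age in years.
#' @return numeric vector of deviations (dB; negative = loss).
#' @export
total_deviation <- function(thresholds, db, age) {
  stopifnot(inherits(db, "normative_db"))
  if (length(thresholds) != length(db$mean))
    stop_perisim("field has ", length(thresholds), " locations but the ",
                 "normative database has ", length(db$mean),
                 " (grid mismatch: ", db$grid_name, ")")
  thresholds - (db$mean + db$age_slope * (age - db$mean_age))
}

#' Pattern deviation
#'
#' Removes the general-height component: `PD = TD - GH` where GH is the
#' configured percentile (default the database's, normally the 85th) of
#' the TD distribution, so that uniform (diffuse) loss is absorbed and
#' focal loss remains.
#'
#' @param td total-deviation vector.
#' @param gh_percentile general-height percentile.
#' @return pattern-deviation vector (dB).
#' @export
pattern_deviation <- function(td, gh_percentile = 0.85) {
  td - stats::quantile(td, probs = gh_percentile, names = FALSE)
}

#' Mean deviation and pattern standard deviation
#'
#' `mean_deviation()` is the unweighted mean of the total deviations.
#' `psd()` is the root mean squared difference between TD and MD
#' (optionally weighted by inverse normative variance).
#'
#' @param td total-deviation vector.
#' @param md mean deviation (computed from `td` when omitted).
#' @param weights optional non-negative weights (e.g. inverse normative
#'   variance); default unweighted.
#' @return dB value.
#' @export
mean_deviation <- function(td, weights = NULL) {
  if (!length(td)) stop_perisim("empty total-deviation vector")
  if (is.null(weights)) mean(td) else stats::weighted.mean(td, weights)
}

#' @rdname mean_deviation
#' @export
psd <- function(td, md = NULL, weights = NULL) {
  if (!length(td)) stop_perisim("empty total-deviation vector")
  if (is.null(md)) md <- mean_deviation(td, weights)
  if (is.null(weights)) sqrt(mean((td - md)^2))
  else sqrt(stats::weighted.mean((td - md)^2, weights))
}

#' Number of abnormal pattern-deviation points
#'
#' Counts unmasked locations whose pattern deviation falls below the
#' database's 5% cut-off (at least p < 5%).
#'
#' @param pd pattern-deviation vector.
#' @param db a `normative_db` (its `p5` row of PD cut-offs is used).
#' @param mask optional logical vector, `TRUE` = exclude.
#' @param level significance level; must be one of the database's
#'   stored levels.
#' @return integer count.
#' @export
napdp <- function(pd, db, mask = NULL, level = 0.05) {
  stopifnot(inherits(db, "normative_db"))
  row <- match(level, db$levels)
  if (is.na(row))
    stop_perisim("level ", level, " not stored in the database (has: ",
                 paste(db$levels, collapse = ", "), ")")
  if (length(pd) != ncol(db$pd_cutoffs))
    stop_perisim("pattern-deviation length does not match the database grid")
  flag <- pd < db$pd_cutoffs[row, ]
  if (!is.null(mask)) flag <- flag[!mask]
  sum(flag)
}

#' All global indices for one measured field
#'
#' Convenience wrapper computing MS, MD, PSD and NAPDP on the reference
#' scale, with optional masking (e.g. restriction to the 66 matched
#' locations).
#'
#' @param thresholds_ref thresholds on the reference scale.
#' @param db a `normative_db` on the same grid.
#' @param age observer age.
#' @param mask optional logical exclusion vector.
#' @return list with `ms`, `md`, `psd`, `napdp`, `td`, `pd`.
#' @export
global_indices <- function(thresholds_ref, db, age, mask = NULL) {
  td <- total_deviation(thresholds_ref, db, age)
  keep <- if (is.null(mask)) rep(TRUE, length(td)) else !mask
  td_k <- td[keep]
  pd_k <- pattern_deviation(td_k, db$gh_percentile)
  pd_full <- rep(NA_real_, length(td)); pd_full[keep] <- pd_k
  row <- match(0.05, db$levels)
  nap <- sum(pd_k < db$pd_cutoffs[row, keep])
  list(ms = mean_sensitivity(thresholds_ref, mask = !keep),
       md = mean_deviation(td_k), psd = psd(td_k),
       napdp = nap, td = td, pd = pd_full)
}
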