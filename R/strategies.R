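# Thresholding strategies.
#
# Two strategies are implemented on top of the frequency-of-seeing
# observer model:
#
# * `staircase_42()`: a classic full-threshold 4-2 dB double-crossing
#   staircase, run independently at every grid location.  This is a
#   declared stand-in for the proprietary SITA engine; what matters for
#   the comparison is its per-location independence.
# * `run_spark()`: a four-phase interpolation strategy of the SPARK
#   Precision type.  Phase 1 directly tests only six seed locations
#   (one per functional sector, the upper and lower pairs bracketed
#   alternately) and fills the remaining 60 locations by a seed
#   regression model (or distance-weighted interpolation); phases 2-4
#   each directly test 21 locations distributed over the sectors,
#   correcting by the previous standard error, and re-interpolate the
#   rest.  The four per-location estimates are combined by discarding
#   the most extreme and averaging the closest three.
#
# Stimulus levels are handled on the instrument's own dB scale and
# converted to the reference (k = 40) scale only when querying the
# observer, so the instrument's dynamic range (and its floor plateau)
# is enforced at presentation time.

# -- presentation logging ----------------------------------------------------

new_log <- function() {
  e <- new.env(parent = emptyenv())
  e$phase <- integer(); e$location <- integer(); e$stimulus_db <- numeric()
  e$seen <- logical(); e$catch <- character()
  e
}

log_add <- function(log, phase, location, stimulus_db, seen, catch = NA_character_) {
  log$phase <- c(log$phase, phase)
  log$location <- c(log$location, location)
  log$stimulus_db <- c(log$stimulus_db, stimulus_db)
  log$seen <- c(log$seen, seen)
  log$catch <- c(log$catch, catch)
}

log_df <- function(log) {
  data.frame(phase = log$phase, location = log$location,
             stimulus_db = log$stimulus_db, seen = log$seen,
             catch = log$catch, stringsAsFactors = FALSE)
}

new_outcome <- function(strategy, instrument, grid, thresholds, saturated,
                        per_phase, log, rates) {
  n_pres <- length(log$seen)
  structure(list(strategy = strategy, instrument = instrument$name,
                 k = instrument$k, grid_name = grid$name,
                 thresholds = thresholds, saturated = saturated,
                 per_phase = per_phase, n_presentations = n_pres,
                 test_time = test_time_proxy(n_pres),
                 rates = rates, log = log_df(log)),
            class = "strategy_outcome")
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("<strategy_outcome> %s on %s (%s grid): mean %.1f dB, %d presentations, %.0f s proxy\n",
              x$strategy, x$instrument, x$grid_name, mean(x$thresholds),
              x$n_presentations, x$test_time))
  invisible(x)
}

# Presentation-count to seconds proxy; only ratios are meaningful.
test_time_proxy <- function(n_presentations, per_presentation = 1.5,
                            overhead = 20) {
  n_presentations * per_presentation + overhead
}

clamp_instr <- function(db, inst) pmin(pmax(db, inst$db_floor), inst$db_ceiling)

# reference-scale offset: ref_db = instr_db + (40 - k)
ref_offset <- function(inst) reference_instrument()$k - inst$k

# -- single-location staircases ---------------------------------------------

#' Single-location threshold staircases
#'
#' `threshold_staircase()` runs the 4-2 dB double-crossing staircase at
#' one location: step 4 dB toward dimmer after "seen" / brighter after
#' "not seen" until the first response reversal, then 2 dB steps until
#' the second reversal; the threshold estimate is the last-seen level.
#' `threshold_bracket()` is the 4-2-1 variant (three reversals) used
#' for the seed points of the interpolation strategy.  Stimuli are
#' clipped to the instrument's presentable range; an observer who never
#' sees the brightest stimulus is recorded at the floor with the
#' saturation flag set.
#'
#' @param true_sensitivity true threshold on the reference (k = 40)
#'   scale.
#' @param start starting level on the instrument's own scale.
#' @param inst an `instrument_model`.
#' @param params a [response_params()] object.
#' @param seed optional RNG seed (otherwise the current stream is used).
#' @param max_presentations safety bound.
#' @return list with `threshold` (instrument scale), `saturated`
#'   (logical), `levels`, `responses`.
#' @export
threshold_staircase <- function(true_sensitivity, start, inst = instrument("hfa"),
                                params = response_params(), seed = NULL,
                                max_presentations = 30L) {
  with_seed(seed,
    run_stair(true_sensitivity, start, inst, params,
              steps = c(4, 2), max_presentations))
}

#' @rdname threshold_staircase
#' @export
threshold_bracket <- function(true_sensitivity, start, inst = instrument("hfa"),
                              params = response_params(), seed = NULL,
                              max_presentations = 30L) {
  with_seed(seed,
    run_stair(true_sensitivity, start, inst, params,
              steps = c(4, 2, 1), max_presentations))
}

# Shared staircase engine: one step size per pending reversal.
run_stair <- function(S_ref, start, inst, params, steps, max_pres) {
  off <- ref_offset(inst)
  level <- clamp_instr(round(start), inst)
  step_i <- 1L
  prev <- NA
  last_seen <- NA_real_
  levels <- numeric(); resp <- logical()
  sat <- FALSE
  repeat {
    seen <- stats::runif(1) < p_seen(level + off, S_ref, params)
    levels <- c(levels, level); resp <- c(resp, seen)
    if (seen) last_seen <- level
    if (!is.na(prev) && seen != prev) {
      step_i <- step_i + 1L
      if (step_i > length(steps)) break
    }
    prev <- seen
    if (seen && level >= inst$db_ceiling) { last_seen <- inst$db_ceiling; break }
    if (!seen && level <= inst$db_floor) { sat <- TRUE; break }
    level <- clamp_instr(level + if (seen) steps[step_i] else -steps[step_i],
                         inst)
    if (length(levels) >= max_pres) break
  }
  thr <- if (is.na(last_seen)) { sat <- TRUE; inst$db_floor } else last_seen
  list(threshold = thr, saturated = sat, levels = levels, responses = resp)
}

# -- catch trials ------------------------------------------------------------

#' Run reliability catch trials against an observer
#'
#' Three catch types are supported: false-positive catches (a stimulus
#' no observer can see; any "seen" response is a false positive),
#' false-negative catches (a stimulus 10 dB brighter than the
#' observer's threshold at a randomly chosen location; a "not seen"
#' response is a false negative) and fixation-loss catches
#' (Heijl-Krakau: a bright stimulus in the physiological blind spot; a
#' "seen" response indicates lost fixation).  A catch type with zero
#' scheduled trials is reported as `NA` (absent), not 0.
#'
#' @param schedule named list/vector with counts `fp`, `fn`, `fl`
#'   (missing or 0 means the type is not measured; the SPARK schedule
#'   has no `fn` catches).
#' @param observer a `perim_observer`.
#' @param inst an `instrument_model`.
#' @param seed optional RNG seed.
#' @param log optional internal presentation log to append to.
#' @param phase phase tag for logged catch presentations.
#' @return list with observed rates `fp`, `fn`, `fl` (`NA` when not
#'   measured) and counts `n`.
#' @export
catch_trials <- function(schedule, observer, inst = instrument("hfa"),
                         seed = NULL, log = NULL, phase = 0L) {
  get_n <- function(type)
    if (type %in% names(schedule)) as.integer(schedule[[type]]) else 0L
  n_fp <- get_n("fp"); n_fn <- get_n("fn"); n_fl <- get_n("fl")
  p <- observer$params
  if (is.null(log)) log <- new_log()
  with_seed(seed, {
    fp_hits <- if (n_fp > 0) {
      hits <- stats::runif(n_fp) < p$fp
      for (h in hits) log_add(log, phase, NA_integer_, inst$db_ceiling, h, "fp")
      sum(hits)
    } else NA_integer_
    fn_hits <- if (n_fn > 0) {
      locs <- sample.int(grid_size(observer$field$grid), n_fn, replace = TRUE)
      hits <- logical(n_fn)
      for (i in seq_len(n_fn)) {
        s_ref <- observer$field$sensitivity[locs[i]] - 10  # 10 dB brighter
        seen <- stats::runif(1) < p_seen(s_ref, observer$field$sensitivity[locs[i]], p)
        hits[i] <- !seen
        log_add(log, phase, locs[i], s_ref - ref_offset(inst), seen, "fn")
      }
      sum(hits)
    } else NA_integer_
    fl_hits <- if (n_fl > 0) {
      # response iff fixation lost (or a guess while fixating)
      hits <- stats::runif(n_fl) < (p$fl + (1 - p$fl) * p$fp)
      for (h in hits) log_add(log, phase, NA_integer_, inst$db_floor, h, "fl")
      sum(hits)
    } else NA_integer_
    list(fp = if (n_fp > 0) fp_hits / n_fp else NA_real_,
         fn = if (n_fn > 0) fn_hits / n_fn else NA_real_,
         fl = if (n_fl > 0) fl_hits / n_fl else NA_real_,
         n = c(fp = n_fp, fn = n_fn, fl = n_fl))
  })
}

# -- 4-2 staircase strategy --------------------------------------------------

#' Full-threshold 4-2 staircase strategy over a grid
#'
#' Runs an independent 4-2 dB double-crossing staircase at every
#' location of the observer's grid (growth pattern: the four primary
#' points at (+/-9, +/-9) are tested first from age-corrected normal
#' start levels; other locations start from the mean of already
#' thresholded 6-degree neighbours).  Appends catch trials and reports
#' observed reliability rates.
#'
#' @param observer a `perim_observer`.
#' @param inst an `instrument_model` (default the k = 40 model).
#' @param seed RNG seed; identical seeds give identical outcomes.
#' @param catches catch-trial schedule (see [catch_trials()]).
#' @return a `strategy_outcome` with one threshold per grid location on
#'   the instrument's own scale.
#' @export
staircase_42 <- function(observer, inst = instrument("hfa"), seed = NULL,
                         catches = c(fp = 10, fn = 10, fl = 10)) {
  grid <- observer$field$grid
  n <- grid_size(grid)
  pts <- grid$points
  expect_ref <- normal_expectation(grid, observer$age)
  expect_instr <- clamp_instr(expect_ref - ref_offset(inst), inst)
  primary <- which(abs(pts$x) == 9 & abs(pts$y) == 9)
  ord <- c(primary, setdiff(order(grid_ecc(grid)), primary))
  thr <- rep(NA_real_, n); sat <- logical(n)
  log <- new_log()
  with_seed(seed, {
    for (i in ord) {
      nb <- which(!is.na(thr) &
                  abs(pts$x - pts$x[i]) + abs(pts$y - pts$y[i]) == 6)
      start <- if (length(nb)) mean(thr[nb]) else expect_instr[i]
      res <- run_stair(observer$field$sensitivity[i], start, inst,
                       observer$params, steps = c(4, 2), 30L)
      thr[i] <- res$threshold; sat[i] <- res$saturated
      for (j in seq_along(res$levels))
        log_add(log, 0L, i, res$levels[j], res$responses[j])
    }
    rates <- catch_trials(catches, observer, inst, seed = NULL, log = log)
    new_outcome("staircase42", inst, grid, thr, sat, per_phase = NULL,
                log = log, rates = rates)
  })
}

# -- SPARK-like strategy -----------------------------------------------------

#' Direct-test plan for the four-phase strategy
#'
#' Phase 1 tests the six seed locations.  The 60 non-seed locations are
#' ordered by a stratified round-robin over the sectors and split into
#' the phase-2 and phase-3 sets (21 each) and the phase-4 set (the
#' remaining 18 plus 3 re-tests, keeping 21 scheduled points per
#' phase).  The union of direct tests over phases 1-4 covers all 66
#' locations.
#'
#' @param sector_map a `sector_map` for the SPARK66 grid.
#' @return list with `seeds` (6 indices) and `phases` (list of three
#'   21-index vectors).
#' @export
spark_plan <- function(sector_map) {
  stopifnot(inherits(sector_map, "sector_map"))
  seeds <- sector_map$seeds$index
  by_sec <- split(setdiff(seq_along(sector_map$sector), seeds),
                  sector_map$sector[-seeds], drop = FALSE)
  # round-robin over sectors
  ordering <- integer(0)
  while (any(lengths(by_sec) > 0)) {
    for (s in names(by_sec)) {
      if (length(by_sec[[s]])) {
        ordering <- c(ordering, by_sec[[s]][1L])
        by_sec[[s]] <- by_sec[[s]][-1L]
      }
    }
  }
  list(seeds = seeds,
       phases = list(ordering[1:21], ordering[22:42],
                     c(ordering[43:60], ordering[1:3])))
}

# Inverse-distance-squared weights from location q to source points,
# with the observer's own-sector source doubled.
idw_weights <- function(pts, q, src, same_sector) {
  d2 <- (pts$x[src] - pts$x[q])^2 + (pts$y[src] - pts$y[q])^2
  w <- 1 / (d2 + 1e-9)
  w[same_sector] <- 2 * w[same_sector]
  w / sum(w)
}

#' Phase 1 of the four-phase strategy
#'
#' Directly thresholds only the six seed locations.  The upper pair and
#' the lower pair are examined with an alternating 4-2-1 bracketing
#' strategy in which each member's starting level is informed by the
#' other's running estimate; the temporal and central seeds are
#' bracketed individually.  The remaining 60 locations are filled in by
#' the seed regression model when one is supplied, otherwise by
#' sector-weighted inverse-distance interpolation of the six seed
#' estimates (with a warning).
#'
#' @param observer a `perim_observer` whose grid contains the SPARK66
#'   locations.
#' @param sector_map a `sector_map` of the SPARK66 grid.
#' @param inst an `instrument_model`.
#' @param regression_model optional model from [fit_seed_regression()].
#' @param seed RNG seed.
#' @return list with `est` and `se` (length 66, instrument scale),
#'   `log`, and `direct` (the 6 tested indices).
#' @export
spark_phase1 <- function(observer, sector_map, inst = instrument("twinfield2"),
                         regression_model = NULL, seed = NULL) {
  grid <- build_grid("SPARK66")
  truth <- truth_on_spark66(observer, grid)
  pts <- grid$points
  seeds <- sector_map$seeds
  log <- new_log()
  with_seed(seed, {
    est_seed <- rep(NA_real_, nrow(seeds))
    start0 <- clamp_instr(normal_expectation(grid, observer$age) - ref_offset(inst),
                          inst)
    pair_of <- function(labels) which(seeds$sector %in% labels)
    run_pair <- function(ii) {
      # alternating bracket: the first member starts at age-normal, the
      # second at the first member's response-adjusted level
      a <- ii[1]; b <- ii[2]
      ra <- run_stair(truth[seeds$index[a]], start0[seeds$index[a]], inst,
                      observer$params, steps = c(4, 2, 1), 30L)
      start_b <- ra$levels[min(2L, length(ra$levels))]
      rb <- run_stair(truth[seeds$index[b]], start_b, inst,
                      observer$params, steps = c(4, 2, 1), 30L)
      for (j in seq_along(ra$levels)) log_add(log, 1L, seeds$index[a], ra$levels[j], ra$responses[j])
      for (j in seq_along(rb$levels)) log_add(log, 1L, seeds$index[b], rb$levels[j], rb$responses[j])
      est_seed[a] <<- ra$threshold; est_seed[b] <<- rb$threshold
    }
    run_pair(pair_of(c("superior_nasal", "superior_temporal")))
    run_pair(pair_of(c("inferior_nasal", "inferior_temporal")))
    for (i in pair_of(c("temporal", "central"))) {
      r <- run_stair(truth[seeds$index[i]], start0[seeds$index[i]], inst,
                     observer$params, steps = c(4, 2, 1), 30L)
      for (j in seq_along(r$levels)) log_add(log, 1L, seeds$index[i], r$levels[j], r$responses[j])
      est_seed[i] <- r$threshold
    }
    n <- grid_size(grid)
    est <- numeric(n); se <- numeric(n)
    if (!is.null(regression_model)) {
      # the model lives on the reference scale; convert around it
      off <- ref_offset(inst)
      est <- predict_seed_model(regression_model, est_seed + off) - off
      se <- pmin(pmax(regression_model$resid_se, 1), 6)
    } else {
      warning("no seed regression model supplied; ",
              "falling back to pure seed interpolation")
      for (q in seq_len(n)) {
        w <- idw_weights(pts, q, seeds$index,
                         seeds$sector == as.character(sector_map$sector[q]))
        est[q] <- sum(w * est_seed)
      }
      se[] <- 3
    }
    est[seeds$index] <- est_seed
    se[seeds$index] <- 1.5
    est <- clamp_instr(est, inst)
    list(est = est, se = se, log = log, direct = seeds$index)
  })
}

#' Refinement phases 2-4 of the four-phase strategy
#'
#' Directly re-tests the 21 planned locations of the phase, starting
#' from the previous estimate and correcting with a magnitude equal to
#' the associated previous standard error (a two-presentation up/down
#' probe of size SE; the interpretation is documented in the methods
#' vignette).  Non-tested locations are re-interpolated sector-wise
#' from the corrections observed at the directly tested points.
#'
#' @param observer a `perim_observer`.
#' @param prev list with `est` and `se` from the previous phase.
#' @param phase 2, 3 or 4.
#' @param sector_map a `sector_map` of the SPARK66 grid.
#' @param plan a [spark_plan()].
#' @param inst an `instrument_model`.
#' @param seed RNG seed.
#' @return list with updated `est`, `se`, `log`, `direct`.
#' @export
spark_refine_phase <- function(observer, prev, phase, sector_map, plan,
                               inst = instrument("twinfield2"), seed = NULL) {
  if (!phase %in% 2:4) stop_perisim("phase must be 2, 3 or 4 (got ", phase, ")")
  grid <- build_grid("SPARK66")
  truth <- truth_on_spark66(observer, grid)
  pts <- grid$points
  direct <- plan$phases[[phase - 1L]]
  est <- prev$est; se <- prev$se
  log <- new_log()
  with_seed(seed, {
    new_est <- est; new_se <- se
    for (q in direct) {
      s <- max(se[q], 1)
      l1 <- clamp_instr(round(est[q]), inst)
      seen1 <- stats::runif(1) < p_seen(l1 + ref_offset(inst), truth[q],
                                        observer$params)
      log_add(log, phase, q, l1, seen1)
      l2 <- clamp_instr(round(est[q] + if (seen1) s else -s), inst)
      seen2 <- stats::runif(1) < p_seen(l2 + ref_offset(inst), truth[q],
                                        observer$params)
      log_add(log, phase, q, l2, seen2)
      # seen at the estimate and not at the dimmer probe confirms it;
      # otherwise correct by (up to) the previous standard error
      new_est[q] <- if (seen1) {
        if (seen2) est[q] + s else est[q]
      } else {
        if (seen2) est[q] - s / 2 else est[q] - s
      }
      new_se[q] <- max(s / 2, 1)
    }
    # sector-wise re-interpolation of the correction field
    corr <- new_est - est
    for (q in setdiff(seq_len(grid_size(grid)), direct)) {
      src <- direct[sector_map$sector[direct] == sector_map$sector[q]]
      if (!length(src)) src <- direct
      w <- idw_weights(pts, q, src, rep(TRUE, length(src)))
      new_est[q] <- est[q] + sum(w * corr[src])
    }
    list(est = clamp_instr(new_est, inst), se = new_se, log = log,
         direct = direct)
  })
}

#' Combine the four per-location threshold estimates
#'
#' Discards the most extreme of the four estimates and returns the mean
#' of the remaining three: of the four leave-one-out triples, the one
#' with the smallest range is kept.  Ties are broken by preferring to
#' exclude the phase-1 estimate (the least informed), then by excluding
#' the largest value.
#'
#' @param estimates numeric vector of exactly 4 finite estimates.
#' @return the combined threshold.
#' @examples
#' spark_combine(c(10, 12, 13, 30))  # 11.667: 30 is discarded
#' @export
spark_combine <- function(estimates) {
  if (length(estimates) != 4L || !all(is.finite(estimates)))
    stop_perisim("exactly 4 finite estimates are required")
  rng <- vapply(1:4, function(i) diff(range(estimates[-i])), numeric(1))
  best <- which(rng == min(rng))
  drop <- if (length(best) == 1L) best
          else if (1L %in% best) 1L
          else best[which.max(estimates[best])]
  mean(estimates[-drop])
}

#' Run the full four-phase interpolation strategy
#'
#' Phases 1-4 followed by the median-of-four combine, catch trials
#' (false-positive and fixation-loss only: the strategy does not
#' measure false negatives) and clipping to the instrument's dynamic
#' range.
#'
#' @param observer a `perim_observer` (its grid must contain the
#'   SPARK66 locations, e.g. a 30-2 or SPARK66 truth grid).
#' @param inst an `instrument_model`; default the reduced-range k = 30
#'   model.
#' @param regression_model optional [fit_seed_regression()] model for
#'   phase 1.
#' @param seed RNG seed; identical seeds give identical outcomes.
#' @param catches catch-trial schedule (no `fn` entry).
#' @return a `strategy_outcome` with 66 thresholds (instrument scale)
#'   and the 66 x 4 per-phase estimate matrix.
#' @export
run_spark <- function(observer, inst = instrument("twinfield2"),
                      regression_model = NULL, seed = NULL,
                      catches = c(fp = 10, fl = 10)) {
  grid <- build_grid("SPARK66")
  smap <- assign_sectors(grid)
  plan <- spark_plan(smap)
  with_seed(seed, {
    p1 <- spark_phase1(observer, smap, inst, regression_model, seed = NULL)
    phases <- list(p1)
    prev <- p1
    for (ph in 2:4) {
      prev <- spark_refine_phase(observer, prev, ph, smap, plan, inst,
                                 seed = NULL)
      phases <- c(phases, list(prev))
    }
    per_phase <- vapply(phases, `[[`, numeric(grid_size(grid)), "est")
    colnames(per_phase) <- paste0("phase", 1:4)
    combined <- apply(per_phase, 1L, spark_combine)
    clipped <- clip_to_range(combined, inst)
    log <- new_log()
    for (p in phases)
      for (r in seq_along(p$log$seen))
        log_add(log, p$log$phase[r], p$log$location[r],
                p$log$stimulus_db[r], p$log$seen[r], p$log$catch[r])
    rates <- catch_trials(catches, observer, inst, seed = NULL, log = log)
    new_outcome("spark", inst, grid, clipped$db,
                clipped$saturated | clipped$db <= inst$db_floor,
                per_phase = per_phase, log = log, rates = rates)
  })
}

# Truth restricted to the SPARK66 grid, whatever grid the observer
# carries (must be a superset).
truth_on_spark66 <- function(observer, grid66) {
  og <- observer$field$grid
  if (identical(og$name, "SPARK66")) return(observer$field$sensitivity)
  m <- match_locations(grid66, og)
  if (nrow(m) != grid_size(grid66))
    stop_perisim("observer grid ", og$name,
                 " does not contain all SPARK66 locations")
  observer$field$sensitivity[m$j]
}

# -- seed regression ---------------------------------------------------------

#' Fit the seed-to-field regression model
#'
#' Least-squares mapping from the six seed sensitivities to all 66
#' locations (66 regressions on a common design of seed values plus
#' intercept), emulating the stepwise regression the device vendor fit
#' on a large field bank; here the training bank is synthetic.  A
#' degenerate design matrix triggers a small ridge penalty with a
#' warning.
#'
#' @param training a numeric matrix (fields x 66) or list of
#'   `true_field`s on the SPARK66 grid (or a superset, which is
#'   subset).  At least 50 training fields are required.
#' @param seed_idx indices of the six seed locations (default from
#'   [assign_sectors()] on the SPARK66 grid).
#' @return object of class `spark_seed_model`: `coef` (7 x 66 including
#'   intercept), `resid_se` (66), `seed_idx`.
#' @export
fit_seed_regression <- function(training, seed_idx = NULL) {
  if (is.list(training) && !is.matrix(training))
    training <- do.call(rbind, lapply(training, field_on_spark66))
  stopifnot(is.matrix(training), ncol(training) == 66L)
  if (nrow(training) < 50L)
    stop_perisim("at least 50 training fields are required (got ",
                 nrow(training), ")")
  if (is.null(seed_idx))
    seed_idx <- assign_sectors(build_grid("SPARK66"))$seeds$index
  stopifnot(length(seed_idx) == 6L)
  X <- cbind(1, training[, seed_idx, drop = FALSE])
  XtX <- crossprod(X)
  B <- tryCatch(solve(XtX, crossprod(X, training)),
                error = function(e) NULL)
  if (is.null(B) || kappa(XtX) > 1e10) {
    warning("degenerate seed design matrix; using a ridge-regularised fit")
    lambda <- 1e-6 * mean(diag(XtX))
    B <- solve(XtX + diag(lambda, ncol(X)), crossprod(X, training))
  }
  resid <- training - X %*% B
  dfree <- max(nrow(training) - ncol(X), 1L)
  resid_se <- sqrt(colSums(resid^2) / dfree)
  structure(list(coef = B, resid_se = resid_se, seed_idx = seed_idx),
            class = "spark_seed_model")
}

#' @rdname fit_seed_regression
#' @param model a `spark_seed_model`.
#' @param seed_values the six measured seed sensitivities.
#' @return `predict_seed_model()`: predicted sensitivities at all 66
#'   locations.
#' @export
predict_seed_model <- function(model, seed_values) {
  stopifnot(inherits(model, "spark_seed_model"), length(seed_values) == 6L)
  drop(c(1, seed_values) %*% model$coef)
}

field_on_spark66 <- function(field) {
  stopifnot(inherits(field, "true_field"))
  g66 <- build_grid("SPARK66")
  if (identical(field$grid$name, "SPARK66")) return(field$sensitivity)
  m <- match_locations(g66, field$grid)
  field$sensitivity[m$j]
}
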