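# Synthetic observers: ground-truth sensitivity surfaces plus a
# frequency-of-seeing response model.
#
# Ground truth is always stored on the k = 40 reference scale; an
# instrument's own scale enters only at measurement time.  Sensitivities
# may go below 0 dB (residual vision no instrument can measure).

#' Psychometric response parameters
#'
#' The probability of seeing a stimulus of `s` dB given a true
#' sensitivity `S` is a cumulative-Gaussian frequency-of-seeing curve
#' with a lapse/guess floor:
#' \deqn{p = fp + (1 - fp - fn)\,\Phi((S - s)/\sigma(S))}
#' where the spread grows as sensitivity falls (Henson-style
#' variability): \eqn{\sigma(S) = \mathrm{clamp}(e^{a - bS},
#' \sigma_{min}, \sigma_{max})} dB.
#'
#' @param fp false-positive (guess) rate in \[0, 1\].
#' @param fn false-negative (lapse) rate in \[0, 1\].
#' @param fl fixation-loss probability in \[0, 1\].
#' @param slope_a,slope_b parameters of the spread model (defaults
#'   3.27 and 0.081 give about 1.5 dB at 30 dB sensitivity rising to
#'   6 dB in deep defects).
#' @param sigma_min,sigma_max clamp bounds of the spread in dB.  Setting
#'   both to 0 yields a deterministic step-function responder (seen iff
#'   stimulus is at or dimmer-equal threshold).
#' @return an object of class `response_params`.
#' @export
response_params <- function(fp = 0.03, fn = 0.03, fl = 0.05,
                            slope_a = 3.27, slope_b = 0.081,
                            sigma_min = 1, sigma_max = 6) {
  rates <- c(fp = fp, fn = fn, fl = fl)
  if (any(rates < 0 | rates > 1)) stop_perisim("fp, fn, fl must lie in [0, 1]")
  stopifnot(sigma_min >= 0, sigma_max >= sigma_min)
  structure(list(fp = fp, fn = fn, fl = fl, slope_a = slope_a,
                 slope_b = slope_b, sigma_min = sigma_min,
                 sigma_max = sigma_max),
            class = "response_params")
}

sigma_of <- function(sensitivity, params) {
  pmin(pmax(exp(params$slope_a - params$slope_b * sensitivity),
            params$sigma_min), params$sigma_max)
}

#' Probability of seeing a stimulus
#'
#' @param stimulus_db stimulus attenuation in dB on the reference
#'   (k = 40) scale; higher = dimmer.
#' @param true_sensitivity true threshold in reference dB.
#' @param params a [response_params()] object.
#' @return probability in \[`fp`, `1 - fn`\], non-increasing in
#'   `stimulus_db`.
#' @export
p_seen <- function(stimulus_db, true_sensitivity, params = response_params()) {
  stopifnot(all(is.finite(stimulus_db)), all(is.finite(true_sensitivity)))
  sig <- sigma_of(true_sensitivity, params)
  base <- ifelse(sig == 0,
                 as.numeric(stimulus_db <= true_sensitivity),
                 stats::pnorm((true_sensitivity - stimulus_db) / sig))
  params$fp + (1 - params$fp - params$fn) * base
}

new_true_field <- function(grid, sensitivity) {
  stopifnot(inherits(grid, "perim_grid"),
            length(sensitivity) == grid_size(grid),
            all(is.finite(sensitivity)))
  structure(list(grid = grid, sensitivity = as.numeric(sensitivity)),
            class = "true_field")
}

#' @export
print.true_field <- function(x, ...) {
  cat(sprintf("<true_field> %s grid, mean %.1f dB (range %.1f to %.1f, k=40 scale)\n",
              x$grid$name, mean(x$sensitivity), min(x$sensitivity),
              max(x$sensitivity)))
  invisible(x)
}

#' Generate a normal (healthy) ground-truth field
#'
#' Hill-of-vision model: sensitivity declines linearly with eccentricity
#' and with age beyond 20 years, plus spatially correlated noise
#' (a random per-sector offset shared by all locations of a bundle
#' sector) and white noise:
#' \deqn{S(x,y) = S_0 - g\,ecc - a\,\max(0, age - 20) + u_{sector} + e}
#'
#' @param grid a `perim_grid`.
#' @param age observer age in years.
#' @param seed RNG seed (deterministic field for a given seed).
#' @param s0 foveal-peak sensitivity at age 20, reference dB.
#' @param ecc_slope decline in dB per degree of eccentricity.
#' @param age_slope decline in dB per year beyond age 20.
#' @param sector_sd SD of the shared per-sector offset (dB).
#' @param noise_sd SD of the per-location white noise (dB).
#' @return a `true_field` on the reference scale.
#' @export
normal_field <- function(grid, age = 50, seed = NULL, s0 = 34,
                         ecc_slope = 0.25, age_slope = 0.07,
                         sector_sd = 0.5, noise_sd = 1) {
  stopifnot(age >= 0)
  n <- grid_size(grid)
  mu <- s0 - ecc_slope * grid_ecc(grid) - age_slope * max(0, age - 20)
  sec <- sector_rule(grid$points$x, grid$points$y)
  with_seed(seed, {
    off <- stats::rnorm(nlevels(sec), 0, sector_sd)
    e <- stats::rnorm(n, 0, noise_sd)
    new_true_field(grid, mu + off[as.integer(sec)] + e)
  })
}

# Expected normal sensitivity (no noise), used for strategy start levels
# and as a nominal fallback normative surface.
normal_expectation <- function(grid, age = 50, s0 = 34, ecc_slope = 0.25,
                               age_slope = 0.07) {
  s0 - ecc_slope * grid_ecc(grid) - age_slope * max(0, age - 20)
}

#' Add a focal (nerve-fibre-bundle) defect to a true field
#'
#' Subtracts `depth` dB at every location of the named sector(s), with a
#' Gaussian fall-off of scale `edge_sd` degrees just outside the sector
#' so that defect edges are not artificially sharp.  The fall-off never
#' crosses the horizontal midline in the nasal field (nasal steps
#' respect the raphe).  Sensitivities may go below 0 dB.
#'
#' @param field a `true_field`.
#' @param sectors character vector of sector labels (see
#'   [assign_sectors()]).
#' @param depth defect depth in dB, non-negative.
#' @param edge_sd spatial scale of the edge fall-off in degrees; 0 gives
#'   a hard-edged defect.
#' @return a new `true_field`; never increases any sensitivity.
#' @export
add_focal_defect <- function(field, sectors, depth, edge_sd = 2) {
  stopifnot(inherits(field, "true_field"), depth >= 0)
  bad <- setdiff(sectors, SECTOR_LEVELS)
  if (length(bad))
    stop_perisim("unknown sector label(s): ", paste(bad, collapse = ", "),
                 "; valid: ", paste(SECTOR_LEVELS, collapse = ", "))
  if (depth == 0) return(field)
  pts <- field$grid$points
  sec <- sector_rule(pts$x, pts$y)
  inside <- as.character(sec) %in% sectors
  w <- as.numeric(inside)
  if (any(!inside) && edge_sd > 0) {
    for (q in which(!inside)) {
      src <- which(inside)
      if (pts$x[q] < 0) {
        # nasal point: only in-sector points on its own side of the
        # horizontal midline may bleed into it
        src <- src[sign(pts$y[src]) == sign(pts$y[q])]
      }
      if (!length(src)) next
      d2 <- (pts$x[src] - pts$x[q])^2 + (pts$y[src] - pts$y[q])^2
      wq <- exp(-0.5 * min(d2) / edge_sd^2)
      w[q] <- if (wq < 1e-6) 0 else wq
    }
  }
  new_true_field(field$grid, field$sensitivity - depth * w)
}

#' Add diffuse (cataract-like) loss to a true field
#'
#' Uniform subtraction of `loss` dB at every location; shifts the mean
#' sensitivity by exactly `loss` and leaves pattern indices unchanged.
#'
#' @param field a `true_field`.
#' @param loss dB, non-negative.
#' @return a new `true_field`.
#' @export
add_diffuse_loss <- function(field, loss) {
  stopifnot(inherits(field, "true_field"), loss >= 0)
  new_true_field(field$grid, field$sensitivity - loss)
}

new_observer <- function(id, group, age, field, params) {
  structure(list(id = id, group = group, age = age, field = field,
                 params = params),
            class = "perim_observer")
}

#' @export
print.perim_observer <- function(x, ...) {
  cat(sprintf("<perim_observer> %s (%s, age %.0f), %s grid, mean truth %.1f dB\n",
              x$id, x$group, x$age, x$field$grid$name,
              mean(x$field$sensitivity)))
  invisible(x)
}

#' Draw a single yes/no response from an observer
#'
#' Bernoulli draw with probability [p_seen()] at the observer's true
#' sensitivity for the given grid location.  Uses the current RNG
#' stream.
#'
#' @param stimulus_db stimulus level in reference (k = 40) dB.
#' @param location integer index into the observer's grid.
#' @param observer a `perim_observer`.
#' @return logical: seen or not seen.
#' @export
respond <- function(stimulus_db, location, observer) {
  n <- grid_size(observer$field$grid)
  if (!is.numeric(location) || location < 1 || location > n)
    stop_perisim("location ", location, " is off the observer's ",
                 observer$field$grid$name, " grid (1..", n, ")")
  p <- p_seen(stimulus_db, observer$field$sensitivity[location],
              observer$params)
  stats::runif(1) < p
}

#' Cohort configuration for the synthetic-observer generator
#'
#' Defaults emulate the study groups: 39 glaucoma-like observers with
#' 0-3 focal bundle defects whose depths span the AGIS severity
#' spectrum, and 31 cataract-like observers with diffuse loss only.
#' Ages are drawn from the groups' reported distributions (glaucoma
#' 54.7 +/- 12.6, cataract 60.8 +/- 9.6 years).
#'
#' @param group `"glaucoma"`, `"cataract"` or `"normal"`.
#' @param n_subjects number of observers.
#' @param seed RNG seed.
#' @param age_mean,age_sd age distribution (years).
#' @param defect_prob probabilities of 0, 1, 2 and 3 focal defects
#'   (glaucoma only).
#' @param depth_range uniform range of focal defect depth in dB.
#' @param diffuse_shape,diffuse_scale gamma parameters of the diffuse
#'   loss (cataract only).  The default (mean 3.5 dB, long right tail)
#'   spans trace to dense lenticular opacity, i.e. mean deviations from
#'   about 0 down to about -10 dB.
#' @param params a [response_params()] object shared by the cohort.
#' @param grid_name grid carrying the ground truth (default `"30-2"`, a
#'   superset of the SPARK66 grid).
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(group = c("glaucoma", "cataract", "normal"),
                          n_subjects = NULL, seed = 1L,
                          age_mean = NULL, age_sd = NULL,
                          defect_prob = c(0.30, 0.30, 0.25, 0.15),
                          depth_range = c(6, 30),
                          diffuse_shape = 1.6, diffuse_scale = 2.2,
                          params = response_params(),
                          grid_name = "30-2") {
  group <- match.arg(group)
  n_subjects <- n_subjects %||% switch(group, glaucoma = 39L,
                                       cataract = 31L, normal = 60L)
  if (n_subjects <= 0) stop_perisim("n_subjects must be positive")
  age_mean <- age_mean %||% switch(group, glaucoma = 54.7, cataract = 60.8,
                                   normal = 55)
  age_sd <- age_sd %||% switch(group, glaucoma = 12.6, cataract = 9.6,
                               normal = 10)
  if (abs(sum(defect_prob) - 1) > 1e-8 || any(defect_prob < 0))
    stop_perisim("defect_prob must be a probability vector over 0..3 defects")
  if (diffuse_shape <= 0 || diffuse_scale <= 0)
    stop_perisim("diffuse loss gamma parameters must be positive")
  structure(list(group = group, n_subjects = as.integer(n_subjects),
                 seed = seed, age_mean = age_mean, age_sd = age_sd,
                 defect_prob = defect_prob, depth_range = depth_range,
                 diffuse_shape = diffuse_shape,
                 diffuse_scale = diffuse_scale,
                 params = params, grid_name = grid_name),
            class = "cohort_config")
}

# Sectors eligible for focal defects, weighted toward arcuate/nasal
# loss as seen in glaucoma.
DEFECT_SECTORS <- c("superior_nasal", "inferior_nasal",
                    "superior_temporal", "inferior_temporal", "temporal")
DEFECT_SECTOR_W <- c(0.30, 0.25, 0.20, 0.15, 0.10)

#' Simulate a cohort of synthetic observers
#'
#' Deterministic given the config seed.  Glaucoma-like observers
#' receive 0-3 focal defects in fibre-bundle sectors; cataract-like
#' observers receive diffuse loss only; normals receive neither.
#'
#' @param config a [cohort_config()].
#' @return list of `perim_observer` objects.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  grid <- build_grid(config$grid_name)
  with_seed(config$seed, {
    lapply(seq_len(config$n_subjects), function(i) {
      age <- max(20, stats::rnorm(1, config$age_mean, config$age_sd))
      fld <- normal_field(grid, age = age,
                          seed = derive_seed(config$seed, i))
      if (config$group == "glaucoma") {
        k <- sample(0:3, 1, prob = config$defect_prob)
        if (k > 0) {
          secs <- sample(DEFECT_SECTORS, k, prob = DEFECT_SECTOR_W)
          for (s in secs) {
            depth <- stats::runif(1, config$depth_range[1], config$depth_range[2])
            fld <- add_focal_defect(fld, s, depth)
          }
        }
      } else if (config$group == "cataract") {
        loss <- stats::rgamma(1, shape = config$diffuse_shape,
                              scale = config$diffuse_scale)
        fld <- add_diffuse_loss(fld, loss)
      }
      new_observer(sprintf("%s_%03d", substr(config$group, 1, 3), i),
                   config$group, age, fld, config$params)
    })
  })
}

#' Serialise an observer to JSON / read it back
#'
#' The JSON records the grid name, per-location true sensitivities
#' (reference scale), response parameters and metadata; round-trips
#' losslessly.
#'
#' @param observer a `perim_observer`.
#' @param path file path.
#' @return `write_observer_json()`: the path, invisibly;
#'   `read_observer_json()`: a `perim_observer`.
#' @export
write_observer_json <- function(observer, path) {
  stopifnot(inherits(observer, "perim_observer"))
  obj <- list(id = observer$id, group = observer$group, age = observer$age,
              grid = observer$field$grid$name,
              sensitivity = observer$field$sensitivity,
              params = unclass(observer$params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_observer_json
#' @export
read_observer_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_observer(obj$id, obj$group, obj$age,
               new_true_field(build_grid(obj$grid), obj$sensitivity),
               do.call(response_params, as.list(obj$params)))
}
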