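# Perimetric decibel scale and instrument dynamic-range models.
#
# Sensitivity in dB is attenuation relative to an instrument-specific
# maximum stimulus luminance: dB = k - 10*log10(dL) with dL in apostilb,
# so 0 dB is the brightest presentable stimulus (10^(k/10) asb) and
# higher dB means dimmer.  The constant k is 40 for the HFA-like
# instrument and 30 for the Twinfield-2-like instrument; equal physical
# luminances therefore differ by 10 dB between the two scales, and the
# smaller-k instrument cannot record defects deeper than its 0 dB floor
# (the "plateau" effect).

#' Define a perimeter instrument model
#'
#' @param name instrument identifier.
#' @param k decibel scale constant; the maximum stimulus luminance is
#'   `10^(k/10)` asb.
#' @param background_asb background luminance in apostilb.
#' @param db_floor sensitivity recorded at the maximum stimulus
#'   (default 0 dB).
#' @param db_ceiling dimmest presentable stimulus in dB (default `k`,
#'   i.e. a 1 asb stimulus).
#' @return an object of class `instrument_model`.
#' @seealso [instrument()] for the two built-in models.
#' @export
instrument_model <- function(name, k, background_asb = 31.5,
                             db_floor = 0, db_ceiling = k) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k),
            is.numeric(background_asb), background_asb > 0,
            db_ceiling > db_floor)
  structure(list(name = name, k = k,
                 background_asb = background_asb,
                 max_stimulus_asb = luminance_from_db(db_floor, k),
                 db_floor = db_floor, db_ceiling = db_ceiling),
            class = "instrument_model")
}

#' Built-in instrument models
#'
#' `"hfa"`: k = 40, maximum stimulus 10,000 asb, range 0-40 dB (the
#' reference scale used for ground truth throughout the package).
#' `"twinfield2"`: k = 30, maximum stimulus 1,000 asb, range 0-30 dB
#' (reduced dynamic range).  Both use a 31.5 asb background.
#'
#' @param name `"hfa"` or `"twinfield2"`.
#' @return an `instrument_model`.
#' @examples
#' instrument("hfa")$max_stimulus_asb        # 10000
#' instrument("twinfield2")$max_stimulus_asb # 1000
#' @export
instrument <- function(name = c("hfa", "twinfield2")) {
  name <- match.arg(name)
  switch(name,
         hfa = instrument_model("hfa", k = 40),
         twinfield2 = instrument_model("twinfield2", k = 30))
}

#' @export
print.instrument_model <- function(x, ...) {
  cat(sprintf("<instrument_model> %s: k = %g dB, background %g asb, max %g asb, range [%g, %g] dB\n",
              x$name, x$k, x$background_asb, x$max_stimulus_asb,
              x$db_floor, x$db_ceiling))
  invisible(x)
}

#' Stimulus luminance for a decibel value
#'
#' \eqn{\Delta L = 10^{(k - dB)/10}} asb; strictly decreasing in dB.
#'
#' @param db sensitivity / attenuation in dB (vectorised).
#' @param k instrument scale constant.
#' @return luminance in apostilb.
#' @export
luminance_from_db <- function(db, k) {
  stopifnot(is.numeric(db), all(is.finite(db)))
  10^((k - db) / 10)
}

#' Decibel value for a stimulus luminance
#'
#' Exact inverse of [luminance_from_db()].
#'
#' @param delta_l stimulus luminance in apostilb; must be positive.
#' @param k instrument scale constant.
#' @return dB value.
#' @export
db_from_luminance <- function(delta_l, k) {
  if (!is.numeric(delta_l) || any(delta_l <= 0))
    stop_perisim("stimulus luminance must be positive")
  k - 10 * log10(delta_l)
}

#' Convert a decibel value between instrument scales
#'
#' The same physical stimulus luminance is kept: the dB value is shifted
#' by the difference of the scale constants, `db + (k_to - k_from)`.
#' A 0 dB threshold on the k = 30 scale is thus 10 dB on the k = 40
#' scale.
#'
#' @param db dB value(s) on `from`'s scale.
#' @param from,to `instrument_model` objects.
#' @return dB value(s) on `to`'s scale.
#' @export
convert_db <- function(db, from, to) {
  stopifnot(inherits(from, "instrument_model"), inherits(to, "instrument_model"))
  if (!isTRUE(all.equal(from$background_asb, to$background_asb)))
    warning("instruments have different background luminances; ",
            "conversion is still luminance-exact but contrasts differ")
  db + (to$k - from$k)
}

#' Clip a decibel value to an instrument's dynamic range
#'
#' Values below the floor are recorded at the floor (the plateau
#' effect: residual vision beyond the brightest stimulus is invisible
#' to the instrument); values above the ceiling are recorded at the
#' ceiling.  Exact boundary values are not flagged.
#'
#' @param db dB value(s) on the instrument's own scale; may be negative.
#' @param inst an `instrument_model`.
#' @return list with `db` (recorded values) and `saturated` (logical,
#'   `TRUE` where clipping occurred).
#' @export
clip_to_range <- function(db, inst) {
  stopifnot(inherits(inst, "instrument_model"))
  rec <- pmin(pmax(db, inst$db_floor), inst$db_ceiling)
  list(db = rec, saturated = db < inst$db_floor | db > inst$db_ceiling)
}

#' Convert apostilb to candela per square metre
#'
#' 1 cd/m^2 = pi asb, so the conversion is a division by pi (31.5 asb
#' is approximately 10 cd/m^2).
#'
#' @param luminance luminance in asb, non-negative.
#' @return luminance in cd/m^2.
#' @export
asb_to_cdm2 <- function(luminance) {
  if (!is.numeric(luminance) || any(luminance < 0))
    stop_perisim("luminance must be non-negative")
  luminance / pi
}

# Reference scale for ground truth: the k = 40 instrument.
reference_instrument <- function() instrument("hfa")
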