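# Study orchestration: cohorts -> strategies on their instruments ->
# reliability filtering -> indices & AGIS -> agreement battery ->
# report.
#
# Default pairing mirrors the clinical comparison the package
# emulates: the interpolation strategy runs on the reduced-range
# k = 30 instrument and the staircase stand-in on the k = 40
# instrument.  A counterfactual mode additionally runs the
# interpolation strategy on the k = 40 instrument, separating the
# algorithm effect from the dynamic-range (plateau) effect.

#' Configuration of the in-silico study
#'
#' @param seed master RNG seed; every downstream stream is derived from
#'   it.
#' @param n_glaucoma,n_cataract cohort sizes (defaults 39 and 31).
#' @param n_normative normals per normative database.
#' @param n_training synthetic training fields for the seed regression.
#' @param reliability named vector of exclusion thresholds; a subject
#'   fails when an observed rate strictly exceeds its threshold
#'   (defaults FP 20%, FN 20%, FL 30%).
#' @param spark_instrument,staircase_instrument built-in instrument
#'   names for the strategy/instrument pairing.
#' @param levels normative percentile levels to store.
#' @param gh_percentile general-height percentile for pattern
#'   deviation.
#' @param counterfactual also run the interpolation strategy on the
#'   staircase's instrument (algorithm vs dynamic-range decomposition).
#' @param glaucoma,cataract optional [cohort_config()] overrides.
#' @return object of class `study_config`.
#' @export
study_config <- function(seed = 1L, n_glaucoma = 39L, n_cataract = 31L,
                         n_normative = 60L, n_training = 120L,
                         reliability = c(fp = 0.20, fn = 0.20, fl = 0.30),
                         spark_instrument = "twinfield2",
                         staircase_instrument = "hfa",
                         levels = c(0.05, 0.02),
                         gh_percentile = 0.85,
                         counterfactual = FALSE,
                         glaucoma = NULL, cataract = NULL) {
  stopifnot(all(c("fp", "fn", "fl") %in% names(reliability)))
  structure(list(seed = as.integer(seed), n_glaucoma = as.integer(n_glaucoma),
                 n_cataract = as.integer(n_cataract),
                 n_normative = as.integer(n_normative),
                 n_training = as.integer(n_training),
                 reliability = reliability,
                 spark_instrument = spark_instrument,
                 staircase_instrument = staircase_instrument,
                 levels = levels, gh_percentile = gh_percentile,
                 counterfactual = isTRUE(counterfactual),
                 glaucoma = glaucoma, cataract = cataract),
            class = "study_config")
}

#' Apply the reliability exclusion criteria to a strategy outcome
#'
#' A test fails when any applicable observed catch-trial rate strictly
#' exceeds its threshold; rates the strategy does not measure (`NA`,
#' e.g. false negatives for the interpolation strategy) are never
#' applied.  Boundary values pass.
#'
#' @param outcome a `strategy_outcome`.
#' @param thresholds named vector with `fp`, `fn`, `fl` maxima.
#' @return list with `pass` (logical) and `reasons` (character vector
#'   of violated criteria, empty when passing).
#' @export
reliability_filter <- function(outcome,
                               thresholds = c(fp = 0.20, fn = 0.20, fl = 0.30)) {
  stopifnot(inherits(outcome, "strategy_outcome"))
  reasons <- character(0)
  for (type in c("fp", "fn", "fl")) {
    r <- outcome$rates[[type]]
    if (!is.null(r) && !is.na(r) && r > thresholds[[type]])
      reasons <- c(reasons, sprintf("%s %.0f%% > %.0f%%", toupper(type),
                                    100 * r, 100 * thresholds[[type]]))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

# Training bank for the seed regression: normals plus fields with
# focal and diffuse loss, emulating a strategy-development field bank.
training_fields <- function(n, seed) {
  grid <- build_grid("SPARK66")
  with_seed(seed, {
    t(vapply(seq_len(n), function(i) {
      age <- stats::runif(1, 30, 80)
      fld <- normal_field(grid, age = age, seed = derive_seed(seed, i))
      u <- stats::runif(1)
      if (u < 0.3) {
        sec <- sample(DEFECT_SECTORS, 1, prob = DEFECT_SECTOR_W)
        fld <- add_focal_defect(fld, sec, stats::runif(1, 5, 25))
      } else if (u < 0.45) {
        fld <- add_diffuse_loss(fld, stats::runif(1, 1, 5))
      }
      fld$sensitivity
    }, numeric(grid_size(grid))))
  })
}

index_row <- function(id, strategy, gi, outcome) {
  data.frame(subject = id, strategy = strategy,
             ms = gi$ms, md = gi$md, psd = gi$psd, napdp = gi$napdp,
             n_presentations = outcome$n_presentations,
             test_time = outcome$test_time, stringsAsFactors = FALSE)
}

med_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  c(median = q[2], iqr_low = q[1], iqr_high = q[3])
}

agree_block <- function(st, sp) {
  ba <- bland_altman(st, sp)
  list(bland_altman = ba,
       proportional_bias = proportional_bias(st, sp),
       spearman = spearman_rho(st, sp),
       wilcoxon = wilcoxon_signed_rank(st, sp))
}

#' Run the full in-silico study
#'
#' Simulates the glaucoma-like and cataract-like cohorts, measures
#' every observer with both strategies on their assigned instruments,
#' applies the reliability filter, computes MS/MD/PSD/NAPDP on the 66
#' matched locations (reference dB scale), scores AGIS for the
#' glaucoma group, and runs the agreement battery (Bland-Altman,
#' proportional bias, Spearman, Wilcoxon, pointwise bias map) per
#' group.  Deterministic given the config seed.
#'
#' @param config a [study_config()].
#' @param progress print progress messages.
#' @return object of class `study_report`.
#' @export
run_study <- function(config = study_config(), progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed
  say <- function(...) if (progress) message(...)
  g302 <- build_grid("30-2"); g66 <- build_grid("SPARK66")
  common302 <- match_locations(g302, g66)$i
  inst_sp <- instrument(config$spark_instrument)
  inst_st <- instrument(config$staircase_instrument)

  say("fitting seed regression model...")
  model <- fit_seed_regression(training_fields(config$n_training,
                                               derive_seed(seed, 1)))
  say("building normative databases...")
  db_st <- build_normative_db(config$n_normative, seed = derive_seed(seed, 2),
                              strategy = "staircase42", inst = inst_st,
                              grid_name = "30-2", levels = config$levels,
                              gh_percentile = config$gh_percentile)
  db_sp <- build_normative_db(config$n_normative, seed = derive_seed(seed, 3),
                              strategy = "spark", inst = inst_sp,
                              regression_model = model,
                              levels = config$levels,
                              gh_percentile = config$gh_percentile)
  db_sp40 <- if (config$counterfactual)
    build_normative_db(config$n_normative, seed = derive_seed(seed, 6),
                       strategy = "spark", inst = inst_st,
                       regression_model = model, levels = config$levels,
                       gh_percentile = config$gh_percentile)

  cohorts <- list(
    glaucoma = simulate_cohort(config$glaucoma %||%
      cohort_config("glaucoma", config$n_glaucoma,
                    seed = derive_seed(seed, 4))),
    cataract = simulate_cohort(config$cataract %||%
      cohort_config("cataract", config$n_cataract,
                    seed = derive_seed(seed, 5))))

  mask302 <- !(seq_len(grid_size(g302)) %in% common302)
  groups <- list()
  exclusions <- data.frame(subject = character(), group = character(),
                           strategy = character(), reason = character(),
                           stringsAsFactors = FALSE)

  for (gname in names(cohorts)) {
    say("measuring ", gname, " cohort...")
    cohort <- cohorts[[gname]]
    rows <- list(); agis_rows <- list()
    thr_st <- list(); thr_sp <- list(); cf_rows <- list()
    for (i in seq_along(cohort)) {
      obs <- cohort[[i]]
      off <- 1000L * match(gname, names(cohorts))
      out_st <- staircase_42(obs, inst_st, seed = derive_seed(seed, off + i))
      out_sp <- run_spark(obs, inst_sp, model,
                          seed = derive_seed(seed, off + 500L + i))
      rel_st <- reliability_filter(out_st, config$reliability)
      rel_sp <- reliability_filter(out_sp, config$reliability)
      if (!rel_st$pass)
        exclusions <- rbind(exclusions, data.frame(
          subject = obs$id, group = gname, strategy = "staircase42",
          reason = paste(rel_st$reasons, collapse = "; ")))
      if (!rel_sp$pass)
        exclusions <- rbind(exclusions, data.frame(
          subject = obs$id, group = gname, strategy = "spark",
          reason = paste(rel_sp$reasons, collapse = "; ")))
      if (!rel_st$pass || !rel_sp$pass) next
      st_ref <- out_st$thresholds + ref_offset(inst_st)
      sp_ref <- out_sp$thresholds + ref_offset(inst_sp)
      gi_st <- global_indices(st_ref, db_st, obs$age, mask = mask302)
      gi_sp <- global_indices(sp_ref, db_sp, obs$age)
      rows[[length(rows) + 1L]] <- rbind(
        index_row(obs$id, "staircase42", gi_st, out_st),
        index_row(obs$id, "spark", gi_sp, out_sp))
      thr_st[[length(thr_st) + 1L]] <- st_ref[common302]
      thr_sp[[length(thr_sp) + 1L]] <- sp_ref
      if (gname == "glaucoma") {
        a_st <- agis_score(gi_st$td[common302], g66)
        a_sp <- agis_score(gi_sp$td, g66)
        agis_rows[[length(agis_rows) + 1L]] <- data.frame(
          subject = obs$id, score_staircase = a_st$score,
          score_spark = a_sp$score,
          category_staircase = as.character(a_st$category),
          category_spark = as.character(a_sp$category),
          stringsAsFactors = FALSE)
      }
      if (config$counterfactual) {
        out_cf <- run_spark(obs, inst_st, model,
                            seed = derive_seed(seed, off + 700L + i))
        gi_cf <- global_indices(out_cf$thresholds + ref_offset(inst_st),
                                db_sp40, obs$age)
        cf_rows[[length(cf_rows) + 1L]] <-
          index_row(obs$id, "spark_on_k40", gi_cf, out_cf)
      }
    }
    idx <- do.call(rbind, rows)
    st <- idx[idx$strategy == "staircase42", ]
    sp <- idx[idx$strategy == "spark", ]
    summary_tab <- do.call(rbind, lapply(
      c("ms", "md", "psd", "napdp", "test_time", "n_presentations"),
      function(v) {
        data.frame(index = v,
                   strategy = c("staircase42", "spark"),
                   rbind(med_iqr(st[[v]]), med_iqr(sp[[v]])),
                   stringsAsFactors = FALSE)
      }))
    agreement <- list(ms = agree_block(st$ms, sp$ms),
                      md = agree_block(st$md, sp$md),
                      psd = agree_block(st$psd, sp$psd))
    pointwise <- pointwise_bias_map(do.call(rbind, thr_st),
                                    do.call(rbind, thr_sp), grid = g66)
    groups[[gname]] <- list(
      n_input = length(cohort),
      n_analysed = nrow(st),
      indices = idx, summary = summary_tab, agreement = agreement,
      pointwise = pointwise,
      counterfactual = if (length(cf_rows)) do.call(rbind, cf_rows),
      agis = if (length(agis_rows)) do.call(rbind, agis_rows))
  }

  ag <- groups$glaucoma$agis
  agis_summary <- if (!is.null(ag)) {
    stats_of <- function(x) c(mean = mean(x), sd = stats::sd(x),
                              median = stats::median(x), min = min(x),
                              max = max(x))
    list(table = data.frame(strategy = c("staircase42", "spark"),
                            rbind(stats_of(ag$score_staircase),
                                  stats_of(ag$score_spark))),
         wilcoxon = wilcoxon_signed_rank(ag$score_staircase, ag$score_spark),
         spearman = if (stats::sd(ag$score_staircase) > 0 &&
                        stats::sd(ag$score_spark) > 0)
           spearman_rho(ag$score_staircase, ag$score_spark),
         crosstab = table(staircase = agis_category(ag$score_staircase),
                          spark = agis_category(ag$score_spark)))
  }

  structure(list(config = config, seed = seed, groups = groups,
                 agis = agis_summary, exclusions = exclusions,
                 normative = list(staircase = db_st$provenance,
                                  spark = db_sp$provenance),
                 scale_note = paste("all indices on the reference k=40 dB",
                                    "scale; 66 matched locations")),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> seed", x$seed, "\n")
  for (g in names(x$groups)) {
    gr <- x$groups[[g]]
    cat(sprintf("  %s: %d/%d analysed\n", g, gr$n_analysed, gr$n_input))
    md <- gr$summary[gr$summary$index == "md", ]
    cat(sprintf("    MD median: staircase %.2f, spark %.2f dB\n",
                md$median[1], md$median[2]))
  }
  if (!is.null(x$agis))
    cat(sprintf("  AGIS max: staircase %d, spark %d\n",
                x$agis$table$max[1], x$agis$table$max[2]))
  invisible(x)
}

flatten_agreement <- function(agreement, group) {
  do.call(rbind, lapply(names(agreement), function(ix) {
    a <- agreement[[ix]]
    data.frame(group = group, index = ix,
               bias = a$bland_altman$bias, sd_diff = a$bland_altman$sd_diff,
               loa_low = a$bland_altman$loa_low,
               loa_high = a$bland_altman$loa_high,
               prop_slope = a$proportional_bias$slope,
               prop_t = a$proportional_bias$t, prop_p = a$proportional_bias$p,
               rho = a$spearman$rho, rho_p = a$spearman$p,
               wilcoxon_v = a$wilcoxon$statistic, wilcoxon_p = a$wilcoxon$p,
               n = a$bland_altman$n, stringsAsFactors = FALSE)
  }))
}

#' Write a study report to disk
#'
#' Emits CSV tables (per-subject indices, group summaries, agreement,
#' pointwise maps, AGIS scores, exclusion log) plus a JSON manifest
#' recording the seed, a config fingerprint and the package version.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @param format `"csv"` (tables + manifest) or `"json"` (single JSON
#'   dump plus manifest).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir, format = c("csv", "json")) {
  stopifnot(inherits(report, "study_report"))
  format <- match.arg(format)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_perisim("cannot create output directory ", dir)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (format == "csv") {
    for (g in names(report$groups)) {
      gr <- report$groups[[g]]
      emit(gr$indices, paste0("indices_", g))
      emit(gr$summary, paste0("summary_", g))
      emit(flatten_agreement(gr$agreement, g), paste0("agreement_", g))
      emit(gr$pointwise, paste0("pointwise_", g))
      if (!is.null(gr$agis)) emit(gr$agis, paste0("agis_", g))
      if (!is.null(gr$counterfactual))
        emit(gr$counterfactual, paste0("counterfactual_", g))
    }
    emit(report$exclusions, "exclusions")
  } else {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    paths <- c(paths, p)
  }
  cfg_json <- jsonlite::toJSON(unclass(report$config), auto_unbox = TRUE,
                               force = TRUE)
  manifest <- list(seed = report$seed,
                   config_hash = fnv1a_hash(as.character(cfg_json)),
                   package = "perisim",
                   version = as.character(utils::packageVersion("perisim")),
                   files = basename(paths),
                   convention = "difference = staircase42 - spark",
                   scale = report$scale_note)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE)
  invisible(c(paths, mp))
}
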