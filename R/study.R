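#' Run a simulated distortion study over subjects and scanner conditions
#'
#' For every subject a reference recording outside the scanner room is
#' generated and averaged; every condition (location x field strength) is
#' then generated with the same subject morphology, processed through the
#' beat pipeline, and compared to the reference with the interval error
#' metric. The outside condition is compared against a repeat outside
#' recording (a different seed), mirroring repeat-reference assessment.
#' ST deviation and the contiguous-lead ischemia rule are evaluated per
#' condition, and subject-summary ST errors are compared across field
#' strengths at isocenter with Wilcoxon rank-sum tests under Bonferroni
#' correction.
#'
#' @param config study-config list (see [read_study_config()]): `subjects`
#'   (each with `id`, `seed`), `conditions` (each with `location`,
#'   `field_t`), optional `simulator` and `pipeline` override lists.
#' @return a report bundle: list with data.frames `summaries` (per
#'   subject/condition/interval max-lead error and SD), `per_lead`,
#'   `st_deviations`, `ischemia`, `group_errors`, `comparisons` (pairwise
#'   Wilcoxon between fields at isocenter), `medians` (median/IQR by
#'   condition and interval), and `provenance` (seeds and a config hash).
#'   Conditions that fail are recorded in `errors` and skipped.
#' @export
run_study <- function(config) {
  sim_over <- config$simulator %||% list()
  pipe <- config$pipeline %||% list()
  threshold <- pipe$threshold_mv %||% 0.6
  band <- c(pipe$filter_low_hz %||% 0.67, pipe$filter_high_hz %||% 150)
  margin <- pipe$margin_ms %||% 40
  settings <- alignment_settings(
    truncation_fraction = pipe$truncation_fraction %||% 0.05,
    fine_tol_ms = pipe$fine_tol_ms %||% 5)

  make_cfg <- function(seed, subject, location, field_t) {
    args <- c(list(seed = seed, subject = subject, location = location,
                   field_t = field_t), sim_over)
    do.call(synthetic_config, args)
  }
  run_one <- function(cfg, morph, mhd, truthless = FALSE) {
    g <- generate_recording(cfg, morphology = morph, mhd = mhd)
    p <- process_recording(g$recording, g$truth$marks_rel,
                           threshold_mv = threshold, truth = g$truth,
                           filter_band = band, margin_ms = margin)
    list(gen = g, proc = p)
  }

  summaries <- list(); per_lead <- list(); st_devs <- list()
  isch <- list(); gerr <- list(); errors <- list()

  for (subj in config$subjects) {
    sseed <- as.integer(subj$seed)
    # per-subject anatomy: mild amplitude and coupling variation
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(sseed)
    amp_scale <- stats::runif(1, 0.9, 1.1)
    cpl_scale <- stats::runif(1, 0.8, 1.2)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
    morph <- default_morphology(amplitude_scale = amp_scale)
    mhd <- mhd_model(coupling = cpl_scale * mhd_model()$coupling)

    ref <- run_one(make_cfg(sseed, subj$id, "outside", 0), morph, mhd)
    ref_dev <- st_deviation(ref$proc$averaged, ref$proc$marks)

    for (ci in seq_along(config$conditions)) {
      cond <- config$conditions[[ci]]
      cseed <- sseed + 7919L * ci
      res <- tryCatch({
        one <- run_one(make_cfg(cseed, subj$id, cond$location,
                                cond$field_t), morph, mhd)
        rep <- compute_error_report(one$proc$averaged, ref$proc$averaged,
                                    ref$proc$marks, settings)
        dev <- st_deviation(one$proc$averaged, one$proc$marks)
        call <- classify_ischemia(dev)
        led_err <- stats::setNames(
          rep$per_lead$max_error[rep$per_lead$interval == "ST"],
          rep$per_lead$lead[rep$per_lead$interval == "ST"])
        list(rep = rep, dev = dev, call = call,
             grp = pair_group_error(led_err))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[length(errors) + 1L]] <- data.frame(
          subject = subj$id, location = cond$location,
          field_t = cond$field_t, message = conditionMessage(res),
          stringsAsFactors = FALSE)
        next
      }
      key <- data.frame(subject = subj$id, location = cond$location,
                        field_t = cond$field_t, stringsAsFactors = FALSE)
      summaries[[length(summaries) + 1L]] <-
        cbind(key[rep(1, nrow(res$rep$summary)), ], res$rep$summary)
      per_lead[[length(per_lead) + 1L]] <-
        cbind(key[rep(1, nrow(res$rep$per_lead)), ], res$rep$per_lead)
      st_devs[[length(st_devs) + 1L]] <- cbind(
        key[rep(1, length(res$dev)), ],
        data.frame(lead = names(res$dev),
                   deviation_mv = as.numeric(res$dev),
                   reference_deviation_mv = as.numeric(ref_dev),
                   stringsAsFactors = FALSE))
      isch[[length(isch) + 1L]] <- cbind(key, data.frame(
        ischemic = res$call$ischemic, n_pairs = nrow(res$call$pairs),
        threshold_mv = res$call$threshold_mv))
      gerr[[length(gerr) + 1L]] <- cbind(
        key[rep(1, length(res$grp)), ],
        data.frame(group = names(res$grp),
                   st_error_mv = as.numeric(res$grp),
                   stringsAsFactors = FALSE))
    }
  }

  bind <- function(l) if (length(l)) do.call(rbind, l) else NULL
  summaries <- bind(summaries)

  comparisons <- NULL
  if (!is.null(summaries)) {
    iso <- summaries[summaries$location == "isocenter" &
                       summaries$interval == "ST", ]
    fields <- sort(unique(iso$field_t))
    if (length(fields) >= 2 && length(unique(iso$subject)) >= 2) {
      prs <- utils::combn(fields, 2)
      rows <- lapply(seq_len(ncol(prs)), function(k) {
        a <- iso$max_error[iso$field_t == prs[1, k]]
        b <- iso$max_error[iso$field_t == prs[2, k]]
        wt <- wilcoxon_rank_sum(a, b)
        data.frame(field_a = prs[1, k], field_b = prs[2, k],
                   median_a = stats::median(a), median_b = stats::median(b),
                   p_value = wt$p_value, stringsAsFactors = FALSE)
      })
      comparisons <- do.call(rbind, rows)
      comparisons$significant <- bonferroni_flags(
        comparisons$p_value, alpha = 0.05, m = nrow(comparisons))
    }
  }

  medians <- NULL
  if (!is.null(summaries)) {
    key <- interaction(summaries$location, summaries$field_t,
                       summaries$interval, drop = TRUE)
    medians <- do.call(rbind, lapply(split(summaries, key), function(d) {
      mi <- median_iqr(d$max_error)
      data.frame(location = d$location[1], field_t = d$field_t[1],
                 interval = d$interval[1], median_error_mv = mi["median"],
                 q1 = mi["q1"], q3 = mi["q3"], n = nrow(d),
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }

  list(summaries = summaries, per_lead = bind(per_lead),
       st_deviations = bind(st_devs), ischemia = bind(isch),
       group_errors = bind(gerr), comparisons = comparisons,
       medians = medians, errors = bind(errors),
       provenance = list(
         config_hash = config_hash(config),
         subject_seeds = vapply(config$subjects, function(s)
           as.integer(s$seed), integer(1)),
         package_version = as.character(utils::packageVersion("mriecg"))))
}

# cheap content hash of the config (hex of a 32-bit polynomial checksum)
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "\n")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write the tables of a report bundle to a directory
#'
#' Each non-null data.frame in the bundle is written as a TSV named after
#' its element; provenance goes to `provenance.txt`.
#'
#' @param bundle output of [run_study()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in setdiff(names(bundle), "provenance")) {
    if (is.null(bundle[[nm]])) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(bundle[[nm]], p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, p)
  }
  pv <- bundle$provenance
  p <- file.path(dir, "provenance.txt")
  writeLines(c(sprintf("config_hash=%s", pv$config_hash),
               sprintf("subject_seeds=%s",
                       paste(pv$subject_seeds, collapse = ",")),
               sprintf("package_version=%s", pv$package_version)), p)
  invisible(c(paths, p))
}
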