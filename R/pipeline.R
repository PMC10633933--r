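#' Run configuration
#'
#' Bundles every tunable of the pipeline so a whole run is reproducible from
#' one object; serializable to YAML via [write_config()] / [read_config()].
#'
#' @param inclusion An [inclusion_policy()].
#' @param exclusion An [exclusion_policy()].
#' @param cutoffs An [outlier_cutoffs()].
#' @param anemia An [anemia_rules()].
#' @param qc A [qc_ruleset()].
#' @param quantile_type Quantile definition id, default 7.
#' @return A list of class `run_config`.
#' @export
run_config <- function(inclusion = inclusion_policy(),
                       exclusion = exclusion_policy(),
                       cutoffs = outlier_cutoffs(),
                       anemia = anemia_rules(),
                       qc = qc_ruleset(),
                       quantile_type = 7) {
  structure(list(inclusion = inclusion, exclusion = exclusion,
                 cutoffs = cutoffs, anemia = anemia, qc = qc,
                 quantile_type = quantile_type),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path for the YAML serialization.
#' @export
write_config <- function(config, path) {
  plain <- lapply(config, function(x) {
    if (is.list(x)) lapply(unclass(x), unclass) else x
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    inclusion = do.call(inclusion_policy, lapply(y$inclusion, unlist)),
    exclusion = do.call(exclusion_policy, y$exclusion),
    cutoffs = do.call(outlier_cutoffs, lapply(y$cutoffs, unlist)),
    anemia = anemia_rules(y$anemia$child, y$anemia$wra),
    qc = qc_ruleset(
      skew_max = y$qc$skew_max, kurt_min = y$qc$kurt_min,
      sd_range_child = unlist(y$qc$sd_range_child),
      sd_range_wra = unlist(y$qc$sd_range_wra),
      flag_pct_max = y$qc$flag_pct_max,
      exclusion = do.call(exclusion_policy, y$qc$exclusion)
    ),
    quantile_type = y$quantile_type
  )
}

#' Check every survey in a record file or tibble against the QC rules
#'
#' Ingests, screens, summarizes and evaluates the corpus; optionally writes
#' one JSON report per survey plus a run log reconciling record counts.
#'
#' @param input Path to a CSV file or a records tibble.
#' @param config A [run_config()].
#' @param out_dir Optional output directory for JSON reports.
#' @return List with `reports` (QC tibble), `stats`, `inclusion`,
#'   `n_flagged` (count of `investigate` verdicts, the pipeline's exit
#'   status in automation) and `log` (count reconciliation).
#' @export
run_qc_check <- function(input, config = run_config(), out_dir = NULL) {
  records <- if (is.character(input)) read_hb_records(input) else input
  if (nrow(records) == 0) stop("no input records", call. = FALSE)
  scr <- screen_surveys(records, config$inclusion)
  stats <- summarize_surveys(scr$records, scr$inclusion,
                             exclusion = config$exclusion,
                             rules = config$anemia,
                             quantile_type = config$quantile_type)
  reports <- evaluate_qc(stats, config$qc)
  log <- list(
    n_input = nrow(records),
    n_after_dedupe = nrow(scr$records),
    n_duplicates_removed = nrow(records) - nrow(scr$records),
    n_valid = sum(scr$records$hb_valid),
    n_invalid = sum(!scr$records$hb_valid),
    n_surveys = nrow(scr$inclusion),
    n_surveys_included = sum(scr$inclusion$include),
    excluded_surveys = scr$inclusion[!scr$inclusion$include,
                                     c("survey_id", "group", "reason")]
  )
  stopifnot(log$n_valid + log$n_invalid == log$n_after_dedupe)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(reports))) {
      r <- reports[i, ]
      jsonlite::write_json(
        as.list(r),
        file.path(out_dir, sprintf("qc_%s_%s.json", r$survey_id, r$group)),
        auto_unbox = TRUE, digits = NA
      )
    }
  }
  list(reports = reports, stats = stats, inclusion = scr$inclusion,
       n_flagged = sum(reports$verdict == "investigate"), log = log)
}

#' Summarize a survey corpus: distribution tables, flags, pairing
#'
#' Produces the corpus-level summary table (per group, with an optional
#' exclusion-sensitivity variant), the outlier-flag tabulation per group,
#' the paired child/WRA comparisons for SD, skewness and kurtosis, the
#' mean-SD correlations, and a by-country/by-year census. Deterministic
#' given the input.
#'
#' @param input Path to a CSV file or a records tibble.
#' @param config A [run_config()].
#' @param exclude Optional predicate over the stats tibble (e.g.
#'   `function(s) s$country == "Uganda"`) for the sensitivity variant.
#' @param exclude_label Variant label, default `"excluded"`.
#' @param out_dir Optional directory to write the CSV tables to.
#' @return List of tibbles: `stats`, `corpus_summary`, `flags_child`,
#'   `flags_wra`, `paired`, `mean_sd_cor`, `census`.
#' @export
run_corpus_summary <- function(input, config = run_config(), exclude = NULL,
                               exclude_label = "excluded", out_dir = NULL) {
  records <- if (is.character(input)) read_hb_records(input) else input
  scr <- screen_surveys(records, config$inclusion)
  if (sum(scr$inclusion$include) < 2) {
    stop("need at least 2 included surveys to summarize", call. = FALSE)
  }
  stats <- summarize_surveys(scr$records, scr$inclusion,
                             exclusion = config$exclusion,
                             rules = config$anemia,
                             quantile_type = config$quantile_type)
  corpus <- summarize_corpus(stats, exclude = exclude,
                             exclude_label = exclude_label,
                             quantile_type = config$quantile_type)
  flags <- lapply(c(child = "child", wra = "wra"), function(g) {
    if (!any(scr$records$group == g & scr$records$hb_valid)) return(NULL)
    tabulate_flags(scr$records, group = g, cutoffs = config$cutoffs,
                   policy = config$exclusion)
  })
  paired <- NULL
  if (all(c("child", "wra") %in% stats$group) &&
      any(duplicated(stats$survey_id))) {
    paired <- dplyr::bind_rows(lapply(
      c("sd_gdl", "skewness_g1", "kurtosis_g2"),
      function(st) paired_compare(stats, st)
    ))
  }
  ms <- dplyr::bind_rows(lapply(unique(stats$group), function(g) {
    sg <- stats[stats$group == g, ]
    variants <- list(all = NULL)
    if (!is.null(exclude)) variants[[exclude_label]] <- exclude
    dplyr::bind_rows(lapply(names(variants), function(v) {
      r <- mean_sd_correlation(sg, variants[[v]])
      tibble::tibble(group = g, variant = v, rho = r$rho,
                     p_value = r$p_value, n = r$n)
    }))
  }))
  census <- dplyr::summarise(
    dplyr::group_by(scr$records[scr$records$hb_valid, ],
                    .data$country, .data$year, .data$group),
    n_surveys = dplyr::n_distinct(.data$survey_id),
    n_sites = dplyr::n_distinct(.data$site),
    n_records = dplyr::n(), .groups = "drop"
  )
  out <- list(stats = stats, corpus_summary = corpus,
              flags_child = flags$child, flags_wra = flags$wra,
              paired = paired, mean_sd_cor = ms, census = census)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      if (!is.null(out[[nm]])) {
        readr::write_csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")))
      }
    }
  }
  out
}

#' Simulate a corpus and write it as a survey CSV plus provenance sidecar
#'
#' @param spec A [corpus_spec()].
#' @param out_dir Output directory.
#' @param basename File stem, default `"corpus"`.
#' @return Invisibly, the CSV path. Alongside it a JSON sidecar records the
#'   spec, seed and R version.
#' @export
run_simulation <- function(spec, out_dir, basename = "corpus") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  corpus <- generate_corpus(spec)
  csv <- file.path(out_dir, paste0(basename, ".csv"))
  readr::write_csv(corpus$records, csv)
  readr::write_csv(corpus$targets,
                   file.path(out_dir, paste0(basename, "_targets.csv")))
  jsonlite::write_json(
    list(spec = unclass(spec), r_version = R.version.string,
         package = as.character(utils::packageVersion("hbqc"))),
    file.path(out_dir, paste0(basename, "_provenance.json")),
    auto_unbox = TRUE, digits = NA
  )
  invisible(csv)
}
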