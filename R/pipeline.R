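#' Study configuration
#'
#' Bundles everything one run of the study needs: the cohort source
#' (a [cohort_spec] to generate from, or a path to a cohort CSV), the index
#' settings, the diagnostics settings and the seed. Exactly one cohort
#' source is allowed; the seed is recorded in every output.
#'
#' @param cohort a [cohort_spec] or a path to a cohort CSV.
#' @param power_p,power_scale,log_base index settings (see
#'   [power_xpar_index()], [depth_map()]).
#' @param alpha significance level used in the report tables.
#' @param seed integer seed; when the cohort is generated, overrides the
#'   spec's seed so one value governs the whole run.
#' @return An object of class `study_config`.
#' @export
study_config <- function(cohort = cohort_spec(), power_p = 2,
                         power_scale = 10, log_base = exp(1),
                         alpha = 0.05, seed = 1L) {
  if (!(inherits(cohort, "cohort_spec") ||
        (is.character(cohort) && length(cohort) == 1L)))
    stop("'cohort' must be a cohort_spec or a CSV path", call. = FALSE)
  if (inherits(cohort, "cohort_spec")) cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, power_p = power_p,
                 power_scale = power_scale, log_base = log_base,
                 alpha = alpha, seed = as.integer(seed)),
            class = "study_config")
}

.metric_cols <- c("xpar_non_zoomed", "power_xpar_non_zoomed",
                  "pixel_count_non_zoomed", "xpar_zoomed",
                  "power_xpar_zoomed", "pixel_count_zoomed")

#' Run the full study on a cohort
#'
#' Executes generate (or load) -> measure -> compare -> model -> ROC and
#' assembles the report tables: stratified descriptives with rank-biserial
#' effect sizes, the paired zoomed vs non-zoomed comparisons, the three
#' logistic models (zoomed, non-zoomed, combined) and the ROC table
#' stratified by resolution group x condition x metric. Deterministic given
#' the config (the only randomness is the seeded cohort draw). ROC strata
#' in which either class has fewer than 3 teeth are reported as
#' not-estimable rather than dropped.
#'
#' @param config a [study_config].
#' @return An object of class `study_report`: `descriptives`,
#'   `zoom_comparison`, `logistic` (list `A1_zoomed`, `A2_non_zoomed`,
#'   `A3_combined` and a tidy `table`), `roc`, `cohort`, `config`, `log`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  log <- character(0)
  note <- function(stage, msg) {
    log <<- c(log, sprintf("[%s] %s", stage, msg))
  }

  cohort <- tryCatch({
    if (inherits(config$cohort, "cohort_spec")) {
      co <- sample_cohort(config$cohort, power_p = config$power_p,
                          power_scale = config$power_scale,
                          log_base = config$log_base)
      note("generate", sprintf("generated %d records (seed %d)",
                               nrow(co), config$seed))
      co
    } else {
      co <- read_cohort_csv(config$cohort)
      note("load", sprintf("read %d records from %s", nrow(co), config$cohort))
      co
    }
  }, error = function(e) stop("stage [cohort]: ", conditionMessage(e),
                              call. = FALSE))

  desc <- tryCatch(descriptives_table(cohort),
                   error = function(e) stop("stage [descriptives]: ",
                                            conditionMessage(e), call. = FALSE))
  note("descriptives", sprintf("%d rows", nrow(desc)))

  zoomtab <- tryCatch(zoom_comparison_table(cohort),
                      error = function(e) stop("stage [zoom_comparison]: ",
                                               conditionMessage(e), call. = FALSE))
  note("zoom_comparison", sprintf("%d rows", nrow(zoomtab)))

  logres <- tryCatch(logistic_tables(cohort),
                     error = function(e) stop("stage [logistic]: ",
                                              conditionMessage(e), call. = FALSE))
  note("logistic", sprintf("%d model(s) estimated",
                           sum(!vapply(logres$models, is.null, TRUE))))

  roctab <- tryCatch(roc_table(cohort),
                     error = function(e) stop("stage [roc]: ",
                                              conditionMessage(e), call. = FALSE))
  note("roc", sprintf("%d strata (%d estimable)", nrow(roctab),
                      sum(!is.na(roctab$auc))))

  fingerprint <- list(
    seed = config$seed, power_p = config$power_p,
    power_scale = config$power_scale, log_base = config$log_base,
    alpha = config$alpha, n_records = nrow(cohort),
    cohort_source = if (inherits(config$cohort, "cohort_spec"))
      "generated" else config$cohort)

  structure(list(descriptives = desc, zoom_comparison = zoomtab,
                 logistic = logres, roc = roctab, cohort = cohort,
                 config = fingerprint, log = log),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d teeth (seed %d)\n", x$config$n_records,
              x$config$seed))
  cat("  tables: descriptives (", nrow(x$descriptives), " rows), zoom comparison (",
      nrow(x$zoom_comparison), "), logistic (", length(x$logistic$models),
      " models), ROC (", nrow(x$roc), " strata)\n", sep = "")
  best <- x$roc[!is.na(x$roc$auc), ]
  if (nrow(best)) {
    b <- best[which.max(best$auc), ]
    cat(sprintf("  best ROC stratum: %s %s %s, AUC %.3f\n",
                b$resolution_group, b$metric, b$condition, b$auc))
  }
  invisible(x)
}

descriptives_table <- function(cohort) {
  if (nrow(cohort) == 0L) return(empty_descriptives())
  vars <- c("dentin_pulp_volume", "pulp_length", .metric_cols)
  vars <- intersect(vars, names(cohort))
  strat <- list(sex = c("female", "male"),
                age_group = c("17-39", "40-54"),
                c_shaped = c(FALSE, TRUE),
                resolution_group = c("1023x496", "1023x593"))
  rows <- list()
  for (v in vars) for (sname in names(strat)) {
    lv <- strat[[sname]]
    g1 <- cohort[[v]][cohort[[sname]] == lv[1]]
    g2 <- cohort[[v]][cohort[[sname]] == lv[2]]
    test <- if (length(g1) > 0 && length(g2) > 0) mann_whitney(g1, g2) else NULL
    for (k in 1:2) {
      g <- if (k == 1) g1 else g2
      n <- length(g)
      ci <- if (n > 1) stats::qt(0.975, n - 1) * stats::sd(g) / sqrt(n) else NA
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, stratifier = sname, group = as.character(lv[k]), n = n,
        min = if (n) min(g) else NA, max = if (n) max(g) else NA,
        mean = if (n) mean(g) else NA, median = if (n) stats::median(g) else NA,
        sd = if (n > 1) stats::sd(g) else NA,
        ci_low = if (n > 1) mean(g) - ci else NA,
        ci_high = if (n > 1) mean(g) + ci else NA,
        effect_r = if (!is.null(test)) test$effect_r else NA,
        p_value = if (!is.null(test)) test$p_value else NA,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_descriptives())
  do.call(rbind, rows)
}

empty_descriptives <- function() {
  data.frame(variable = character(0), stratifier = character(0),
             group = character(0), n = integer(0), min = numeric(0),
             max = numeric(0), mean = numeric(0), median = numeric(0),
             sd = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
             effect_r = numeric(0), p_value = numeric(0),
             stringsAsFactors = FALSE)
}

zoom_comparison_table <- function(cohort) {
  metrics <- c("xpar", "power_xpar", "pixel_count")
  rows <- list()
  for (res in c("1023x496", "1023x593")) for (lab in c(FALSE, TRUE)) {
    sel <- cohort$resolution_group == res & cohort$c_shaped == lab
    for (m in metrics) {
      z <- cohort[[paste0(m, "_zoomed")]][sel]
      nz <- cohort[[paste0(m, "_non_zoomed")]][sel]
      if (length(z) >= 1) {
        wt <- wilcoxon_signed_rank(nz, z)   # Z < 0 when zoomed values larger
        rows[[length(rows) + 1L]] <- data.frame(
          resolution_group = res, c_shaped = lab, metric = m,
          n = length(z), mean_zoomed = mean(z), mean_non_zoomed = mean(nz),
          z_statistic = wt$statistic, p_value = wt$p_value,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          resolution_group = res, c_shaped = lab, metric = m, n = 0L,
          mean_zoomed = NA_real_, mean_non_zoomed = NA_real_,
          z_statistic = NA_real_, p_value = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

logistic_tables <- function(cohort) {
  build <- function(cols, with_demo = TRUE) {
    cols <- intersect(cols, names(cohort))
    px <- cohort[, cols, drop = FALSE]
    if (with_demo) {
      px$resolution_group <- factor(cohort$resolution_group)
      px$sex <- factor(cohort$sex)
      px$age_group <- factor(cohort$age_group)
    }
    px
  }
  specs <- list(
    A1_zoomed = c("xpar_zoomed", "power_xpar_zoomed", "pixel_count_zoomed"),
    A2_non_zoomed = c("xpar_non_zoomed", "power_xpar_non_zoomed",
                      "pixel_count_non_zoomed"),
    A3_combined = .metric_cols)
  models <- list(); tab_rows <- list()
  for (nm in names(specs)) {
    fit <- tryCatch(logistic_model(build(specs[[nm]]), cohort$c_shaped),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      models[[nm]] <- NULL
      tab_rows[[nm]] <- data.frame(
        model = nm, term = NA_character_, odds_ratio = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
        note = paste("not estimable:", conditionMessage(fit)),
        stringsAsFactors = FALSE)
    } else {
      models[[nm]] <- fit
      cf <- fit$coefficients
      tab_rows[[nm]] <- data.frame(
        model = nm, term = cf$term, odds_ratio = cf$odds_ratio,
        ci_low = cf$ci_low, ci_high = cf$ci_high, p_value = cf$p_value,
        note = if (fit$separation) "separation flagged" else "",
        stringsAsFactors = FALSE)
    }
  }
  list(models = models, table = do.call(rbind, c(tab_rows,
                                                 make.row.names = FALSE)))
}

roc_table <- function(cohort) {
  metrics <- c("xpar", "power_xpar", "pixel_count")
  rows <- list()
  for (res in c("1023x496", "1023x593")) {
    sel <- cohort$resolution_group == res
    for (cond in c("zoomed", "non_zoomed")) for (m in metrics) {
      col <- paste0(m, "_", cond)
      scores <- cohort[[col]][sel]
      labs <- cohort$c_shaped[sel]
      n_pos <- sum(labs); n_neg <- sum(!labs)
      if (n_pos >= 3 && n_neg >= 3) {
        rr <- roc_with_youden(scores, labs)
        rows[[length(rows) + 1L]] <- data.frame(
          resolution_group = res, condition = cond, metric = m,
          n_pos = n_pos, n_neg = n_neg, auc = rr$auc,
          direction = rr$direction, threshold = rr$threshold,
          sensitivity = rr$sensitivity, specificity = rr$specificity,
          youden_j = rr$youden_j, note = "", stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          resolution_group = res, condition = cond, metric = m,
          n_pos = n_pos, n_neg = n_neg, auc = NA_real_,
          direction = NA_character_, threshold = NA_real_,
          sensitivity = NA_real_, specificity = NA_real_,
          youden_j = NA_real_, note = "not estimable: class with < 3 teeth",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Export a study report
#'
#' Writes one CSV per table, a JSON summary, a config echo and the stage
#' log into `out_dir`, and returns the file manifest. An exported JSON
#' summary re-exported after reading back round-trips to equal JSON.
#'
#' @param report a `study_report`.
#' @param out_dir writable output directory (created if needed).
#' @return Character vector of written files (the manifest), invisibly.
#' @export
export_report <- function(report, out_dir) {
  stopifnot(inherits(report, "study_report"))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory '", out_dir, "'", call. = FALSE)
  paths <- c(
    descriptives = file.path(out_dir, "descriptives.csv"),
    zoom_comparison = file.path(out_dir, "zoom_comparison.csv"),
    logistic = file.path(out_dir, "logistic_models.csv"),
    roc = file.path(out_dir, "roc_table.csv"),
    cohort = file.path(out_dir, "cohort.csv"),
    summary = file.path(out_dir, "summary.json"),
    config = file.path(out_dir, "config.json"),
    log = file.path(out_dir, "run.log"))
  utils::write.csv(report$descriptives, paths["descriptives"], row.names = FALSE)
  utils::write.csv(report$zoom_comparison, paths["zoom_comparison"], row.names = FALSE)
  utils::write.csv(report$logistic$table, paths["logistic"], row.names = FALSE)
  utils::write.csv(report$roc, paths["roc"], row.names = FALSE)
  write_cohort_csv(report$cohort, paths["cohort"])
  jsonlite::write_json(report_summary(report), paths["summary"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report$config, paths["config"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(report$log, paths["log"])
  manifest <- unname(paths)
  writeLines(basename(manifest), file.path(out_dir, "MANIFEST"))
  invisible(manifest)
}

report_summary <- function(report) {
  models <- report$logistic$models
  list(config = report$config,
       n_records = report$config$n_records,
       roc = report$roc[, c("resolution_group", "condition", "metric",
                            "auc", "threshold", "sensitivity",
                            "specificity", "youden_j")],
       logistic = lapply(models, function(m)
         if (is.null(m)) NULL else
           list(lr_chi2 = m$lr_chi2, df = m$df, lr_p = m$lr_p,
                in_sample_auc = m$in_sample_auc, separation = m$separation)))
}
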