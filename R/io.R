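# Delimited-text and YAML/JSON interfaces.

#' Write a choice dataset to CSV
#'
#' Columns: trial, valA..valD, choice, second_card, delta.
#'
#' @param dataset a `choice_dataset`.
#' @param path output CSV path.
#' @export
write_choices_csv <- function(dataset, path) {
  v <- dataset$task$values
  df <- data.frame(trial = seq_len(dataset$task$n_trials),
                   valA = v[, "A"], valB = v[, "B"], valC = v[, "C"],
                   valD = v[, "D"], choice = DECK_NAMES[dataset$choices],
                   second_card = dataset$outcomes$second_card,
                   delta = dataset$outcomes$delta)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a choice dataset from CSV
#'
#' Expects the [write_choices_csv()] layout; `choice`, `second_card` and
#' `delta` are optional (a stimulus-only file yields a task sequence with no
#' choices).
#'
#' @param path CSV path.
#' @param specs deck payoff schedule assumed for the file.
#' @return A `choice_dataset` (or a bare `task_sequence` when no choices
#'   are present).
#' @export
read_choices_csv <- function(path, specs = deck_specs()) {
  df <- utils::read.csv(path)
  need <- c("trial", "valA", "valB", "valC", "valD")
  if (!all(need %in% names(df)))
    stop("choices CSV must contain columns: ", paste(need, collapse = ", "))
  v <- as.matrix(df[, c("valA", "valB", "valC", "valD")])
  colnames(v) <- DECK_NAMES
  task <- structure(list(values = v, deck_specs = specs, n_trials = nrow(v),
                         seed = NULL),
                    class = "task_sequence")
  if (!"choice" %in% names(df)) return(task)
  outcomes <- NULL
  if (all(c("second_card", "delta") %in% names(df))) {
    ch <- match(df$choice, DECK_NAMES)
    first <- v[cbind(seq_len(nrow(v)), ch)]
    outcomes <- data.frame(trial = df$trial, choice = df$choice,
                           first_card = first, second_card = df$second_card,
                           won = df$delta > 0, delta = df$delta)
  }
  choice_dataset(task, match(df$choice, DECK_NAMES), outcomes)
}

#' Write a cohort directory
#'
#' Writes `subjects.csv` (id, ns_score, l_true) and one `choices_<id>.csv`
#' per subject.
#'
#' @param subjects cohort list from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(subjects, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(subject_id = vapply(subjects, `[[`, character(1),
                                       "subject_id"),
                   ns_score = vapply(subjects, `[[`, numeric(1), "ns_score"),
                   l_true = vapply(subjects, `[[`, numeric(1), "l_true"))
  utils::write.csv(df, file.path(dir, "subjects.csv"), row.names = FALSE)
  for (s in subjects)
    write_choices_csv(s$dataset,
                      file.path(dir, paste0("choices_", s$subject_id, ".csv")))
  invisible(dir)
}

# flatten a correlation_report for tabulation
.report_row <- function(label, rep) {
  data.frame(label = label, r = rep$r, p = rep$p, n = rep$n,
             adjusted_alpha = rep$adjusted_alpha,
             significant = rep$significant, stringsAsFactors = FALSE)
}

#' Write a pipeline report to disk
#'
#' Writes `subjects.csv`, `table1.csv` (when present), `correlations.csv`
#' (all Pearson/partial/connectivity correlations with adjusted alphas) and
#' `report.json` (the numeric report bundle) into `dir`.
#'
#' @param report a [run_pipeline()] report.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  if (!is.null(report$table1))
    utils::write.csv(report$table1$table, file.path(dir, "table1.csv"),
                     row.names = FALSE)
  rows <- list(.report_row("NS~l_hat", report$cor_ns_l))
  for (r in names(report$activation))
    rows <- c(rows, list(.report_row(paste0("NS~z_risk[", r, "]"),
                                     report$activation[[r]]$correlation)))
  for (r in names(report$partial))
    rows <- c(rows, list(.report_row(paste0("NS~z_risk[", r, "]|l_hat"),
                                     report$partial[[r]])))
  for (p in names(report$rsfc))
    rows <- c(rows, list(.report_row(paste0("NS~rsfc[", p, "]"),
                                     report$rsfc[[p]])))
  cors <- do.call(rbind, rows)
  utils::write.csv(cors, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  json <- list(
    seed = report$config$seed,
    achieved_rho_ns_l = report$achieved_rho_ns_l,
    cor_ns_l = report$cor_ns_l[c("r", "p", "n")],
    mediation = report$mediation[c("a", "b", "indirect", "sobel_z", "p")],
    correlations = cors,
    table1 = if (!is.null(report$table1)) report$table1$table,
    log = report$log)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Write / read a pipeline configuration as YAML
#'
#' Serializes the scalar fields of a [pipeline_config()] (cohort, search,
#' model, layout parameters and seeds); the round trip reproduces an
#' equivalent configuration.
#'
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config_yaml <- function(config, path) {
  x <- list(cohort = unclass(config$cohort),
            search = unclass(config$search),
            params = unclass(config$params),
            n_random_agents = config$n_random_agents,
            risk_beta_mean = config$risk_beta_mean,
            risk_beta_sd = config$risk_beta_sd,
            rsfc_base = config$rsfc_base, rsfc_z_sd = config$rsfc_z_sd,
            mediation_roi = config$mediation_roi, alpha = config$alpha,
            seed = config$seed)
  x$layout <- list(n_runs = config$layout$n_runs,
                   TR = config$layout$TR,
                   trial_dur = config$layout$trial_dur,
                   rest_dur = config$layout$rest_dur)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(
    cohort = do.call(cohort_config, x$cohort),
    search = do.call(search_config, x$search),
    params = do.call(model_params, x$params),
    layout = block_layout(n_runs = x$layout$n_runs, TR = x$layout$TR,
                          trial_dur = x$layout$trial_dur,
                          rest_dur = x$layout$rest_dur),
    n_random_agents = x$n_random_agents,
    risk_beta_mean = x$risk_beta_mean, risk_beta_sd = x$risk_beta_sd,
    rsfc_base = x$rsfc_base, rsfc_z_sd = x$rsfc_z_sd,
    mediation_roi = x$mediation_roi, alpha = x$alpha, seed = x$seed)
}
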