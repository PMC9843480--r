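# Orchestration of the replication analysis: feature extraction over a
# cohort, the univariate association table, reference vs radiomics-extended
# endpoint models with LRT and apparent AUC on subgroups, the 2D-vs-3D SRE
# agreement check, and report emission.

#' Analysis configuration
#'
#' Every threshold of the pipeline in one place. The endpoint/feature
#' pairing follows the replicated design: the 2D-averaged parotid SRE
#' extends the xerostomia reference model (baseline grade + mean
#' contra-lateral parotid dose); the submandibular maximum intensity extends
#' the sticky-saliva reference model (baseline grade + mean bilateral SMG
#' dose). Overridable for methodological exploration.
#'
#' @param hu_threshold artifact slice-exclusion threshold (HU).
#' @param subgroup_floor minimum evaluable subgroup size.
#' @param exclusion_cut parotid excluded-fraction cut defining the
#'   low-artifact subgroup.
#' @param alpha two-sided significance level (no multiplicity correction).
#' @param baseline_binary if `TRUE`, baseline toxicity enters models as the
#'   0/1 indicator of grade >= 3 instead of the numeric 1-4 grade.
#' @param endpoints per-endpoint model specification (outcome, baseline,
#'   dose, radiomics feature column names).
#' @param univariate named list (per endpoint) of predictor columns for the
#'   univariate table; entries listed in `normalised` are z-scored first.
#' @param normalised columns treated as radiomics features (z-scored within
#'   the analysed group before modelling).
#' @return object of class `replication_config`.
#' @export
replication_config <- function(hu_threshold = 2000,
                               subgroup_floor = 20,
                               exclusion_cut = 0.5,
                               alpha = 0.05,
                               baseline_binary = FALSE,
                               endpoints = NULL,
                               univariate = NULL,
                               normalised = NULL) {
  if (is.null(endpoints))
    endpoints <- list(
      xer12m = list(outcome = "xer12m", baseline = "baseline_xer_grade",
                    dose = "mean_dose_cl_parotid_gy",
                    feature = "cl_parotid_sre_2d"),
      ss12m = list(outcome = "ss12m", baseline = "baseline_ss_grade",
                   dose = "mean_dose_bilateral_smg_gy",
                   feature = "smg_maxhu"))
  if (is.null(univariate))
    univariate <- list(
      xer12m = c("mean_dose_cl_parotid_gy", "baseline_xer_grade",
                 "cl_parotid_sre_2d", "cl_parotid_idm_2d",
                 "cl_parotid_maxhu"),
      ss12m = c("mean_dose_bilateral_smg_gy", "baseline_ss_grade",
                "smg_maxhu", "smg_sre_2d"))
  if (is.null(normalised))
    normalised <- c("cl_parotid_sre_2d", "cl_parotid_idm_2d",
                    "cl_parotid_maxhu", "cl_parotid_sre_3d",
                    "smg_maxhu", "smg_sre_2d")
  structure(list(hu_threshold = hu_threshold,
                 subgroup_floor = subgroup_floor,
                 exclusion_cut = exclusion_cut,
                 alpha = alpha,
                 baseline_binary = baseline_binary,
                 endpoints = endpoints,
                 univariate = univariate,
                 normalised = normalised),
            class = "replication_config")
}

# deterministic polynomial hash of the deparsed config, for run metadata
.config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Extract the feature table from a cohort
#'
#' Runs artifact exclusion, discretisation and texture/intensity feature
#' computation for every patient and gland. Per-gland submandibular values
#' are averaged over intact glands into combined `smg_*` columns (with one
#' gland, that gland's value is used). Per-patient failures (unreadable
#' volume, fully artifacted gland) yield missing features and a log entry;
#' the run continues. Deterministic given its inputs.
#'
#' @param cohort a `synthetic_cohort` (from [generate_cohort()] or
#'   [read_cohort()]) or a directory path written by [write_cohort()].
#' @param config a [replication_config()].
#' @return data.frame, one row per patient; extraction log in
#'   `attr(, "log")` and the slice-exclusion report in
#'   `attr(, "exclusion_report")`.
#' @export
run_extraction <- function(cohort, config = replication_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rows <- vector("list", length(cohort$patients))
  logs <- character(0)
  selections <- list()
  for (i in seq_along(cohort$patients)) {
    pid <- names(cohort$patients)[i]
    p <- cohort$patients[[pid]]
    row <- tryCatch(
      feature_vector(p$volume, p$masks, hu_threshold = config$hu_threshold,
                     id = pid),
      error = function(e) {
        logs <<- c(logs, sprintf("%s: extraction failed: %s", pid,
                                 conditionMessage(e)))
        NULL
      })
    if (is.null(row)) next
    sel <- list()
    for (g in names(p$masks)) {
      if (is.null(p$masks[[g]])) next   # resected: no exclusion entry
      fully_artifacted <- structure(
        list(retained = integer(0), excluded_fraction = 1,
             n_bearing = length(mask_bearing_slices(p$masks[[g]]))),
        class = "slice_selection")
      sel[[g]] <- tryCatch(
        exclude_artifact_slices(p$volume, p$masks[[g]], config$hu_threshold),
        radsaliva_empty_roi = function(e) fully_artifacted)
      nmiss <- sum(is.na(unlist(row[grep(paste0("^", g), names(row))])))
      logs <- c(logs, sprintf(
        "%s %s: %s slices excluded, %d feature(s) missing", pid, g,
        if (is.null(sel[[g]])) "all"
        else sprintf("%d/%d", sel[[g]]$n_bearing - length(sel[[g]]$retained),
                     sel[[g]]$n_bearing),
        nmiss))
    }
    selections[[pid]] <- sel
    rows[[i]] <- row
  }
  tab <- do.call(rbind, rows)
  # combined submandibular features: average over intact glands present
  for (feat in c("sre_2d", "idm_2d", "maxhu")) {
    l <- tab[[paste0("smg_left_", feat)]]
    r <- tab[[paste0("smg_right_", feat)]]
    tab[[paste0("smg_", feat)]] <- rowMeans(cbind(l, r), na.rm = TRUE)
    tab[[paste0("smg_", feat)]][is.na(l) & is.na(r)] <- NA_real_
  }
  attr(tab, "log") <- logs
  attr(tab, "exclusion_report") <- slice_exclusion_report(selections)
  tab
}

#' Write the feature table to CSV
#'
#' One row per patient, `<gland>_<feature>_<mode>` columns, missing values
#' as empty cells.
#'
#' @param table feature table from [run_extraction()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Subgroup definitions
#'
#' The analysed patient strata: everyone; both submandibular glands intact;
#' fewer than half of the contra-lateral parotid slices excluded; and the
#' modal fractionation schedule (65 Gy in 30 fractions). Each predicate is a
#' pure function of the merged analysis table.
#'
#' @param config a [replication_config()] (supplies the exclusion cut).
#' @return named list of subgroup objects (`name`, `predicate`).
#' @export
subgroup_definitions <- function(config = replication_config()) {
  cut <- config$exclusion_cut
  list(
    all = list(name = "all",
               predicate = function(d) rep(TRUE, nrow(d))),
    smgs_intact = list(
      name = "smgs_intact",
      predicate = function(d) d$smg_left_intact & d$smg_right_intact),
    parotid_low_exclusion = list(
      name = "parotid_low_exclusion",
      predicate = function(d) !is.na(d$cl_parotid_excluded_fraction) &
        d$cl_parotid_excluded_fraction < cut),
    fx_65gy_30 = list(
      name = "fx_65gy_30",
      predicate = function(d) d$prescription_gy == 65 & d$n_fractions == 30)
  )
}

#' Merge clinical records with the extracted feature table
#' @param records clinical data.frame (`patient_id` key).
#' @param features feature table from [run_extraction()].
#' @return merged data.frame (row order of `records`).
#' @export
build_analysis_table <- function(records, features) {
  merge(records, features, by = "patient_id", all.x = TRUE, sort = FALSE)
}

.baseline_column <- function(tab, col, config) {
  if (config$baseline_binary) as.integer(tab[[col]] >= 3) else tab[[col]]
}

#' Reference vs radiomics-extended model comparison on one subgroup
#'
#' Selects the subgroup, drops patients with any missing model input
#' (listwise, counts logged), z-normalises the radiomics feature within the
#' subgroup, fits the reference model (baseline grade + mean dose) and the
#' extended model (+ feature), and reports apparent AUCs, the
#' likelihood-ratio test of the added feature, and the feature's univariate
#' Wald p.
#'
#' @param tab analysis table from [build_analysis_table()] (or a tabular
#'   cohort from [generate_cohort_records()]).
#' @param endpoint `"xer12m"` or `"ss12m"`.
#' @param subgroup one entry of [subgroup_definitions()] (default: all).
#' @param config a [replication_config()].
#' @return list fragment: `endpoint`, `subgroup`, `evaluable`, `reason`,
#'   `n`, `n_events`, `n_dropped`, `auc_reference`, `auc_extended`,
#'   `lrt_statistic`, `lrt_df`, `lrt_p`, `univariate_feature_p`,
#'   `coefficients`, `patient_ids`.
#' @export
run_endpoint_analysis <- function(tab, endpoint,
                                  subgroup = NULL,
                                  config = replication_config()) {
  if (is.null(subgroup)) subgroup <- subgroup_definitions(config)$all
  spec <- config$endpoints[[endpoint]]
  if (is.null(spec)) stop("unknown endpoint: ", endpoint, call. = FALSE)
  not_eval <- function(reason, n = 0L, n_dropped = 0L)
    list(endpoint = endpoint, subgroup = subgroup$name, evaluable = FALSE,
         reason = reason, n = n, n_dropped = n_dropped)
  keep <- subgroup$predicate(tab)
  keep[is.na(keep)] <- FALSE
  d <- tab[keep, , drop = FALSE]
  if (nrow(d) == 0L) return(not_eval("no patients in subgroup"))
  d$baseline <- .baseline_column(d, spec$baseline, config)
  cols <- c(spec$outcome, "baseline", spec$dose, spec$feature)
  complete <- stats::complete.cases(d[, cols])
  n_dropped <- sum(!complete)
  d <- d[complete, , drop = FALSE]
  if (nrow(d) < config$subgroup_floor)
    return(not_eval(sprintf("subgroup below floor (%d < %d)", nrow(d),
                            config$subgroup_floor), nrow(d), n_dropped))
  if (length(unique(d[[spec$outcome]])) < 2L)
    return(not_eval("single outcome class", nrow(d), n_dropped))
  d$feature_z <- zscore_normalise(d[[spec$feature]], name = spec$feature)
  ref <- fit_logistic(d, spec$outcome, c("baseline", spec$dose))
  ext <- fit_logistic(d, spec$outcome,
                      c("baseline", spec$dose, "feature_z"))
  lrt <- likelihood_ratio_test(ref, ext)
  uni <- univariate_association(d, "feature_z", spec$outcome)
  list(endpoint = endpoint, subgroup = subgroup$name, evaluable = TRUE,
       reason = NA_character_,
       n = nrow(d), n_events = sum(d[[spec$outcome]]),
       n_dropped = n_dropped,
       feature = spec$feature,
       auc_reference = auc_rank(stats::fitted(ref$glm), d[[spec$outcome]])$auc,
       auc_extended = auc_rank(stats::fitted(ext$glm), d[[spec$outcome]])$auc,
       lrt_statistic = lrt$statistic, lrt_df = lrt$df, lrt_p = lrt$p,
       univariate_feature_p = uni$p,
       coefficients = list(reference = as.list(ref$coefficients),
                           extended = as.list(ext$coefficients)),
       patient_ids = d$patient_id)
}

#' Univariate association table
#'
#' Wald p-value of each configured predictor per endpoint, one
#' single-predictor logistic model at a time; radiomics features are
#' z-normalised across the analysed patients first. Contains exactly the
#' configured predictor set -- no silent additions.
#'
#' @param tab analysis table.
#' @param config a [replication_config()].
#' @return data.frame `endpoint`, `predictor`, `n`, `coefficient`, `p`.
#' @export
univariate_table <- function(tab, config = replication_config()) {
  rows <- list()
  for (ep in names(config$univariate)) {
    outcome <- config$endpoints[[ep]]$outcome
    for (pred in config$univariate[[ep]]) {
      d <- tab[!is.na(tab[[pred]]) & !is.na(tab[[outcome]]), , drop = FALSE]
      x <- d[[pred]]
      if (pred %in% config$normalised)
        x <- zscore_normalise(x, name = pred)
      d$.x <- x
      ua <- univariate_association(d, ".x", outcome)
      rows[[length(rows) + 1L]] <- data.frame(
        endpoint = ep, predictor = pred, n = ua$n,
        coefficient = ua$coefficient, p = ua$p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' 2D-vs-3D Short Run Emphasis agreement
#'
#' Sample Pearson correlation between the slice-averaged 2D SRE and the
#' 13-direction 3D SRE over artifact-free parotids (the only glands where
#' the 3D mode is defined). Scatter data are retained for the report figure.
#'
#' @param tab analysis table with `cl_parotid_sre_2d` / `cl_parotid_sre_3d`.
#' @return list `evaluable`, `r`, `n`, `scatter` (data.frame), `reason`.
#' @export
compare_2d_3d <- function(tab) {
  ok <- !is.na(tab$cl_parotid_sre_2d) & !is.na(tab$cl_parotid_sre_3d)
  if (sum(ok) < 3L)
    return(list(evaluable = FALSE, r = NA_real_, n = sum(ok),
                scatter = NULL,
                reason = "fewer than 3 artifact-free parotids"))
  sc <- data.frame(patient_id = tab$patient_id[ok],
                   sre_2d = tab$cl_parotid_sre_2d[ok],
                   sre_3d = tab$cl_parotid_sre_3d[ok])
  list(evaluable = TRUE,
       r = stats::cor(sc$sre_2d, sc$sre_3d, method = "pearson"),
       n = nrow(sc), scatter = sc, reason = NA_character_)
}

#' Scatter plot of 2D vs 3D SRE agreement
#' @param comparison result of [compare_2d_3d()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the comparison.
#' @export
plot_sre_agreement <- function(comparison, ...) {
  if (!isTRUE(comparison$evaluable)) {
    warning("comparison not evaluable: ", comparison$reason)
    return(invisible(comparison))
  }
  graphics::plot(comparison$scatter$sre_2d, comparison$scatter$sre_3d,
                 xlab = "SRE (2D, slice-averaged)", ylab = "SRE (3D)",
                 main = sprintf("Pearson r = %.2f (n = %d)",
                                comparison$r, comparison$n), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(comparison)
}

#' Run the full replication analysis
#'
#' Feature extraction (imaging cohorts), univariate table, reference vs
#' extended endpoint models on every subgroup, and the 2D/3D agreement
#' check.
#'
#' @param cohort a `synthetic_cohort`, a directory path, or a tabular
#'   cohort data.frame from [generate_cohort_records()].
#' @param config a [replication_config()].
#' @return object of class `analysis_report`.
#' @export
run_replication <- function(cohort, config = replication_config()) {
  if (is.data.frame(cohort)) {
    tab <- cohort
    features <- NULL
  } else {
    features <- run_extraction(cohort, config)
    tab <- build_analysis_table(cohort$records, features)
  }
  uni <- univariate_table(tab, config)
  fragments <- list()
  for (ep in names(config$endpoints)) {
    for (sg in subgroup_definitions(config)) {
      fragments[[paste(ep, sg$name, sep = ".")]] <-
        run_endpoint_analysis(tab, ep, sg, config)
    }
  }
  cmp <- compare_2d_3d(tab)
  structure(list(
    meta = list(package_version = as.character(utils::packageVersion("radsaliva")),
                config_hash = .config_hash(config),
                n_patients = nrow(tab),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    univariate = uni,
    models = fragments,
    correlation_2d3d = cmp[c("evaluable", "r", "n", "reason")],
    scatter_2d3d = cmp$scatter,
    feature_table = tab),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d patients, config %s\n",
              x$meta$n_patients, x$meta$config_hash))
  ev <- Filter(function(f) isTRUE(f$evaluable), x$models)
  for (f in ev)
    cat(sprintf("  %-7s %-22s n=%3d  AUC %.3f -> %.3f  LRT p = %.3f\n",
                f$endpoint, f$subgroup, f$n, f$auc_reference,
                f$auc_extended, f$lrt_p))
  if (isTRUE(x$correlation_2d3d$evaluable))
    cat(sprintf("  2D/3D SRE Pearson r = %.3f (n = %d parotids)\n",
                x$correlation_2d3d$r, x$correlation_2d3d$n))
  invisible(x)
}

#' Write the analysis report to disk
#'
#' `report.json` (full report with run metadata), `univariate.csv`,
#' `model_comparisons.csv`, and `features.csv`. Deterministic for a fixed
#' cohort and config except for the timestamp field of the JSON.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
emit_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frag_df <- do.call(rbind, lapply(report$models, function(f) {
    data.frame(endpoint = f$endpoint, subgroup = f$subgroup,
               evaluable = f$evaluable,
               reason = if (is.null(f$reason)) NA_character_ else f$reason,
               n = f$n,
               n_events = if (is.null(f$n_events)) NA_integer_ else f$n_events,
               auc_reference = if (is.null(f$auc_reference)) NA_real_
                               else f$auc_reference,
               auc_extended = if (is.null(f$auc_extended)) NA_real_
                              else f$auc_extended,
               lrt_p = if (is.null(f$lrt_p)) NA_real_ else f$lrt_p,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(report$univariate, file.path(dir, "univariate.csv"),
                   row.names = FALSE)
  utils::write.csv(frag_df, file.path(dir, "model_comparisons.csv"),
                   row.names = FALSE)
  write_feature_table(report$feature_table, file.path(dir, "features.csv"))
  json <- report[c("meta", "univariate", "models", "correlation_2d3d",
                   "scatter_2d3d")]
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}
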