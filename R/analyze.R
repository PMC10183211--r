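#' Run the complete statistical analysis of a metrics table
#'
#' Reproduces the inference stage of the valve-gape analysis on a per-mussel
#' metrics table ([trial_metrics()] output):
#' \enumerate{
#'   \item short-term gape response: Gaussian GLM, all-subsets AICc selection
#'     over sound, crab condition, their interaction, mussel size, crab size;
#'   \item long-term gape response: same candidate set, plus Tukey pairwise
#'     contrasts between crab conditions (the contrasts are fitted on a model
#'     containing the crab factor, adding it if the selected model dropped it)
#'     and separate per-condition sound models;
#'   \item change in strong-closing-event rate: same candidate set;
#'   \item gape versus crab proximity in the crab-in-tank condition;
#'   \item crab time budgets versus sound: Gaussian GLMs for the away and
#'     close fractions, Poisson for integer seconds spent touching.
#' }
#'
#' @param metrics Metrics table from [trial_metrics()].
#' @param full_terms Term set of the full model (default sound, crab,
#'   sound:crab, mussel_size, crab_size).
#' @return A list of class \code{gape_analysis} with elements
#'   \code{short_term}, \code{long_term} (each a \code{model_selection}),
#'   \code{tukey_crab}, \code{per_condition}, \code{event_rate},
#'   \code{proximity}, \code{crab_budget}.
#' @export
analyze_experiment <- function(metrics,
                               full_terms = c("sound", "crab", "sound:crab",
                                              "mussel_size", "crab_size")) {
  stopifnot(is.data.frame(metrics))
  sel <- function(response)
    select_best(model_spec(response, full_terms), metrics)
  short_term <- sel("short_term_delta")
  long_term <- sel("long_term_delta")

  # pairwise crab contrasts need a model with the crab factor and no
  # interaction, otherwise the level differences are not a single contrast
  tukey_terms <- union(setdiff(long_term$best$spec$terms, "sound:crab"), "crab")
  tukey_fit <- fit_glm(model_spec("long_term_delta", tukey_terms), metrics)
  tukey_crab <- tukey_pairwise(tukey_fit, "crab_condition")

  per_condition <- per_condition_sound_models(metrics)
  event_rate <- if (all(is.na(metrics$delta_event_rate))) NULL
                else sel("delta_event_rate")
  proximity <- tryCatch(gape_vs_proximity(metrics), error = function(e) NULL)

  crab_budget <- NULL
  tank <- metrics[metrics$crab_condition == "crab_in_tank" &
                    !is.na(metrics$close_or_touching), , drop = FALSE]
  if (nrow(tank) >= 4) {
    tank$fraction_away <- 1 - tank$close_or_touching
    crab_budget <- list(
      away = fit_glm(model_spec("fraction_away", "sound"), tank),
      close_or_touching = fit_glm(model_spec("close_or_touching", "sound"), tank),
      touching = fit_glm(model_spec("touching_s", "sound", family = "poisson"),
                         tank))
  }
  structure(list(short_term = short_term, long_term = long_term,
                 tukey_crab = tukey_crab, per_condition = per_condition,
                 event_rate = event_rate, proximity = proximity,
                 crab_budget = crab_budget, n = nrow(metrics)),
            class = "gape_analysis")
}

#' @export
print.gape_analysis <- function(x, ...) {
  cat(sprintf("Valve-gape analysis of %d mussel records\n\n", x$n))
  cat("Short-term response, best model:\n")
  print(x$short_term$best)
  cat("\nLong-term response, best model:\n")
  print(x$long_term$best)
  cat("\nTukey contrasts between crab conditions (long-term response):\n")
  print(x$tukey_crab, row.names = FALSE, digits = 3)
  cat("\nSound effect per crab condition (long-term response):\n")
  for (cc in names(x$per_condition)) {
    co <- x$per_condition[[cc]]$coefficients
    b <- co[co$term == "treatmentboat", ]
    cat(sprintf("  %-13s boat: %+.3f (p = %.3g)\n", cc, b$estimate, b$p_value))
  }
  if (!is.null(x$proximity)) {
    cat("\nGape vs crab proximity, best model:\n")
    print(x$proximity$best)
  }
  invisible(x)
}

#' Extract a coefficient from a fitted model
#'
#' Convenience accessor: the estimate (and optionally its p-value) of a named
#' coefficient from a \code{gape_fit}.
#'
#' @param fit A \code{gape_fit}.
#' @param term Coefficient name as it appears in the design matrix, e.g.
#'   \code{"treatmentboat"} or \code{"crab_conditioncrab_in_tank"}.
#' @return Named numeric vector \code{c(estimate, p_value)}; \code{NA}s if
#'   the term is absent.
#' @export
coef_of <- function(fit, term) {
  stopifnot(inherits(fit, "gape_fit"))
  co <- fit$coefficients
  i <- match(term, co$term)
  if (is.na(i)) return(c(estimate = NA_real_, p_value = NA_real_))
  c(estimate = co$estimate[i], p_value = co$p_value[i])
}

#' Write an analysis report
#'
#' Writes the selection tables, best-model coefficients and contrasts as a
#' machine-readable JSON file plus a human-readable text rendering.
#'
#' @param analysis A [analyze_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "gape_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  as_list <- function(sel) {
    if (is.null(sel)) return(NULL)
    list(selection = sel$table, best_model = format(sel$best$spec),
         coefficients = sel$best$coefficients)
  }
  rep <- list(
    n_records = analysis$n,
    short_term = as_list(analysis$short_term),
    long_term = as_list(analysis$long_term),
    tukey_crab = analysis$tukey_crab,
    per_condition = lapply(analysis$per_condition,
                           function(f) f$coefficients),
    event_rate = as_list(analysis$event_rate),
    proximity = as_list(analysis$proximity)
  )
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  txt_path <- file.path(dir, "report.txt")
  con <- file(txt_path, "w")
  sink(con); print(analysis); sink()
  close(con)
  invisible(c(json_path, txt_path))
}
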