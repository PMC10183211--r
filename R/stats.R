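#' Model specification for the gape analysis GLMs
#'
#' A response, a set of candidate terms, and an error family. Term tokens are
#' the analysis-level names: \code{"sound"} (the playback treatment,
#' reference level ambient), \code{"crab"} (the crab stimulus condition,
#' reference level no_crab), the interaction \code{"sound:crab"},
#' \code{"mussel_size"}, \code{"crab_size"} and \code{"close_or_touching"}
#' (the crab proximity time fraction). Marginality is enforced: an
#' interaction may only appear together with both its main effects.
#'
#' @param response Response column of the metrics table (e.g.
#'   \code{"long_term_delta"}, \code{"short_term_delta"},
#'   \code{"delta_event_rate"}, \code{"touching_s"}).
#' @param terms Character vector of term tokens (possibly empty:
#'   intercept-only model).
#' @param family \code{"gaussian"} (identity link) or \code{"poisson"}
#'   (log link).
#' @return An object of class \code{model_spec}.
#' @export
model_spec <- function(response, terms = character(),
                       family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  terms <- unique(as.character(terms))
  for (tm in terms[grepl(":", terms, fixed = TRUE)]) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% terms))
      stop(sprintf("interaction %s requires both main effects in the model", tm))
  }
  structure(list(response = response, terms = terms, family = family),
            class = "model_spec")
}

term_variable <- function(term) {
  map <- c(sound = "treatment", crab = "crab_condition")
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  parts <- ifelse(parts %in% names(map), map[parts], parts)
  paste(parts, collapse = ":")
}

spec_formula <- function(spec) {
  rhs <- if (length(spec$terms))
    paste(vapply(spec$terms, term_variable, character(1)), collapse = " + ")
  else "1"
  stats::as.formula(paste(spec$response, "~", rhs))
}

#' @export
format.model_spec <- function(x, ...) {
  sprintf("%s ~ %s [%s]", x$response,
          if (length(x$terms)) paste(sort(x$terms), collapse = " + ") else "1",
          x$family)
}

#' @export
print.model_spec <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Small-sample corrected Akaike information criterion
#'
#' \deqn{AICc = -2\,\ell + 2k + \frac{2k(k+1)}{n-k-1}}
#' where \eqn{\ell} is the maximized log-likelihood, \eqn{k} the number of
#' estimated parameters (including the residual variance for Gaussian
#' models), and \eqn{n} the number of observations. Converges to the AIC as
#' \eqn{n \to \infty}.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations; must exceed \code{k + 1}.
#' @return The AICc value.
#' @examples
#' aicc(-10, 3, 20)  # 27.5
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit one GLM of the gape analysis
#'
#' Maximum-likelihood fit of a [model_spec()] on the metrics table, with
#' treatment coding and reference levels ambient (sound) and no_crab (crab
#' condition). Gaussian models use the identity link, Poisson models the log
#' link. Rank-deficient designs raise an error naming the aliased terms.
#'
#' @param spec A [model_spec()].
#' @param data Metrics table ([trial_metrics()] output or compatible).
#' @param count_dispersion Count the Gaussian residual variance as an
#'   estimated parameter in k for the AICc (default TRUE, the convention of
#'   common all-subsets selection tools).
#' @return An object of class \code{gape_fit}: list with \code{spec},
#'   \code{fit} (the \code{glm} object), \code{coefficients} (data frame with
#'   estimate, std error, statistic, p value), \code{loglik}, \code{n},
#'   \code{k}, \code{aicc}.
#' @export
fit_glm <- function(spec, data, count_dispersion = TRUE) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(data))
  vars <- unique(unlist(strsplit(vapply(spec$terms, term_variable, character(1)),
                                 ":", fixed = TRUE)))
  need <- c(spec$response, vars)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("data lacks columns: ", paste(missing_cols, collapse = ", "))
  data <- data[stats::complete.cases(data[, need, drop = FALSE]), , drop = FALSE]
  if ("treatment" %in% names(data) && !is.factor(data$treatment))
    data$treatment <- factor(data$treatment, levels = c("ambient", "boat"))
  if ("crab_condition" %in% names(data) && !is.factor(data$crab_condition))
    data$crab_condition <- factor(data$crab_condition,
                                  levels = c("no_crab", "crab_in_box", "crab_in_tank"))
  fam <- switch(spec$family,
                gaussian = stats::gaussian(link = "identity"),
                poisson = stats::poisson(link = "log"))
  if (spec$family == "poisson") {
    y <- data[[spec$response]]
    if (any(y < 0) || any(y != round(y)))
      stop("Poisson response must be nonnegative integers")
  }
  fit <- stats::glm(spec_formula(spec), family = fam, data = data)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design; aliased terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  if (spec$family == "gaussian" && !count_dispersion) k <- k - 1
  n <- stats::nobs(fit)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                      std_error = sm[, 2], statistic = sm[, 3],
                      p_value = sm[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(
    list(spec = spec, fit = fit, coefficients = coefs,
         loglik = as.numeric(ll), n = n, k = k,
         # AICc is undefined at n <= k + 1; such fits rank last in selection
         aicc = if (n > k + 1) aicc(as.numeric(ll), k, n) else Inf,
         zero_residual_df = fit$df.residual == 0),
    class = "gape_fit"
  )
}

#' @export
print.gape_fit <- function(x, ...) {
  cat(format(x$spec), sprintf(" n=%d k=%d AICc=%.2f\n", x$n, x$k, x$aicc))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Enumerate all candidate sub-models of a full model
#'
#' All subsets of the full model's terms that respect marginality (an
#' interaction only together with both main effects), including the
#' intercept-only model. The full set used for the gape responses --
#' sound, crab condition, their interaction, mussel size, crab size --
#' yields 20 candidates.
#'
#' @param full A [model_spec()] giving the full model.
#' @return List of [model_spec()] objects.
#' @examples
#' length(enumerate_candidates(model_spec("long_term_delta",
#'   c("sound", "crab", "sound:crab", "mussel_size", "crab_size"))))  # 20
#' @export
enumerate_candidates <- function(full) {
  stopifnot(inherits(full, "model_spec"))
  terms <- full$terms
  inter <- terms[grepl(":", terms, fixed = TRUE)]
  mains <- setdiff(terms, inter)
  subsets <- list(character(0))
  for (tm in mains)
    subsets <- c(subsets, lapply(subsets, function(s) c(s, tm)))
  for (tm in inter) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    subsets <- c(subsets,
                 lapply(Filter(function(s) all(parts %in% s), subsets),
                        function(s) c(s, tm)))
  }
  lapply(subsets, function(s) model_spec(full$response, s, full$family))
}

#' Fit and rank candidate models by AICc
#'
#' Fits every candidate, ranks by AICc ascending; ties are broken by fewer
#' parameters, then by the lexicographic term string, and recorded. Failed
#' fits are dropped with a warning.
#'
#' @param candidates A list of [model_spec()] objects, or a single full
#'   [model_spec()] to be expanded with [enumerate_candidates()].
#' @param data Metrics table.
#' @param count_dispersion See [fit_glm()].
#' @return An object of class \code{model_selection}: list with \code{table}
#'   (data frame: model, k, loglik, aicc, delta_aicc, tied), \code{fits}
#'   (ranked list of \code{gape_fit}), \code{best} (the top fit).
#' @export
select_best <- function(candidates, data, count_dispersion = TRUE) {
  if (inherits(candidates, "model_spec"))
    candidates <- enumerate_candidates(candidates)
  stopifnot(length(candidates) >= 1)
  fits <- list(); labels <- character()
  for (spec in candidates) {
    f <- tryCatch(fit_glm(spec, data, count_dispersion = count_dispersion),
                  error = function(e) {
                    warning(sprintf("dropping model %s: %s", format(spec),
                                    conditionMessage(e)), call. = FALSE)
                    NULL
                  })
    if (!is.null(f)) { fits <- c(fits, list(f)); labels <- c(labels, format(spec)) }
  }
  if (!length(fits)) stop("no candidate model could be fitted")
  aiccs <- vapply(fits, `[[`, numeric(1), "aicc")
  ks <- vapply(fits, `[[`, numeric(1), "k")
  o <- order(aiccs, ks, labels)
  fits <- fits[o]; labels <- labels[o]; aiccs <- aiccs[o]; ks <- ks[o]
  tied <- c(FALSE, abs(diff(aiccs)) < 1e-9)
  tab <- data.frame(model = labels, k = ks,
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                    aicc = aiccs, delta_aicc = aiccs - aiccs[1], tied = tied,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, fits = fits, best = fits[[1]]),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection by AICc (best first):\n")
  print(utils::head(x$table, 10), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tukey pairwise contrasts of a fitted factor
#'
#' All pairwise differences between the levels of a factor in a fitted
#' model, with single-step multiplicity-adjusted p-values (joint-normal
#' max-|z| adjustment via \pkg{multcomp}). With a two-level factor the
#' adjusted p-value equals the unadjusted Wald p-value.
#'
#' @param fit A \code{gape_fit} whose model contains the factor.
#' @param factor Column name of the factor (default \code{"crab_condition"}).
#' @return Data frame: \code{contrast}, \code{estimate}, \code{std_error},
#'   \code{statistic}, \code{p_adjusted}.
#' @export
tukey_pairwise <- function(fit, factor = "crab_condition") {
  stopifnot(inherits(fit, "gape_fit"))
  vars <- all.vars(stats::formula(fit$fit))
  if (!factor %in% vars)
    stop(sprintf("factor '%s' is not a term of the fitted model", factor))
  lf <- do.call(multcomp::mcp, stats::setNames(list("Tukey"), factor))
  gh <- multcomp::glht(fit$fit, linfct = lf)
  sm <- summary(gh)
  data.frame(contrast = names(sm$test$coefficients),
             estimate = as.numeric(sm$test$coefficients),
             std_error = as.numeric(sm$test$sigma),
             statistic = as.numeric(sm$test$tstat),
             p_adjusted = as.numeric(sm$test$pvalues),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sound-effect models fitted per crab condition
#'
#' The interaction between sound and crab condition may not survive model
#' selection even when the sound effect differs between conditions; fitting
#' the long-term response against sound separately within each crab condition
#' shows the per-condition effect directly. P-values are reported unadjusted.
#'
#' @param data Metrics table containing all three crab conditions.
#' @param response Response column (default \code{"long_term_delta"}).
#' @return Named list (by condition) of \code{gape_fit} objects; fits with
#'   zero residual degrees of freedom carry \code{zero_residual_df = TRUE}.
#' @export
per_condition_sound_models <- function(data, response = "long_term_delta") {
  conditions <- c("no_crab", "crab_in_box", "crab_in_tank")
  out <- list()
  for (cc in conditions) {
    sub <- data[data$crab_condition == cc, , drop = FALSE]
    if (!nrow(sub)) stop("no data for crab condition ", cc)
    f <- fit_glm(model_spec(response, "sound"), sub)
    if (f$zero_residual_df)
      warning(sprintf("condition %s: fit has zero residual degrees of freedom", cc),
              call. = FALSE)
    out[[cc]] <- f
  }
  out
}

#' Gape response versus crab proximity
#'
#' Models the long-term gape response of crab-in-tank mussels against the
#' fraction of the scoring window the crab spent close to or touching the
#' mussel. The candidate set also includes the sound treatment; the reported
#' model is the AICc-selected one, with the proximity-only and full fits
#' available in the selection table.
#'
#' @param data Metrics table; only crab-in-tank rows with a scored track are
#'   used.
#' @param response Response column (default \code{"long_term_delta"}).
#' @return A \code{model_selection} whose \code{best} fit carries the
#'   proximity slope when selected.
#' @export
gape_vs_proximity <- function(data, response = "long_term_delta") {
  sub <- data[data$crab_condition == "crab_in_tank" &
                !is.na(data$close_or_touching), , drop = FALSE]
  if (!nrow(sub)) stop("no crab-in-tank rows with proximity data")
  full <- model_spec(response, c("close_or_touching", "sound"))
  select_best(full, sub)
}
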