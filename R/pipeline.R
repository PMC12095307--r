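#' Pipeline configuration
#'
#' @param generator A [generator_config()].
#' @param coefficients An [allometric_coefficients()] object.
#' @param cutoff Vegetation height cutoff (m) for metric extraction.
#' @param extinction_k Extinction coefficient for LAI.
#' @param grid_size Ground grid size (m) for normalization.
#' @param train_fraction Training fraction of the stratified split.
#' @param alpha Significance level for Pearson screening and dummy pruning.
#' @param vif_threshold VIF threshold of the multicollinearity screen.
#' @param predictors Predictors used by the component models.
#' @param rf_trees Trees per random forest.
#' @param seed Master seed; every stage's randomness derives from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            coefficients = allometric_coefficients(),
                            cutoff = 2, extinction_k = 0.5, grid_size = 2,
                            train_fraction = 0.7, alpha = 0.05,
                            vif_threshold = 10,
                            predictors = c("AIH2", "LAI"),
                            rf_trees = 500, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1", call. = FALSE)
  }
  structure(list(generator = generator, coefficients = coefficients,
                 cutoff = cutoff, extinction_k = extinction_k,
                 grid_size = grid_size, train_fraction = train_fraction,
                 alpha = alpha, vif_threshold = vif_threshold,
                 predictors = predictors, rf_trees = rf_trees, seed = seed),
            class = "pipeline_config")
}

#' Run the full stand-biomass modelling pipeline
#'
#' End-to-end workflow on synthetic data: simulate the age-structured plot
#' set and per-plot point clouds; compute plot biomass by allometry;
#' normalize clouds and extract the 57 metrics; Pearson- and VIF-screen the
#' metrics; split 70/30 stratified by age group; fit, per component, the base
#' model of the final system, the AIC-selected nonlinear mixed-effects
#' model, the pruned dummy-variable model and a random forest; and evaluate
#' every fit on both sets.
#'
#' The per-group validation split would reject a configuration with no
#' validation plots.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `biomass_report`: nested list with elements
#'   `config_summary`, `screening`, `split`, and `models` (per component,
#'   per model family: coefficients and train/validation statistics).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  plots <- generate_plot_set(config$generator, seed = seed)
  if (!length(plots)) stop("configuration generates no plots", call. = FALSE)
  biomass <- plot_biomass_table(plots, config$coefficients)
  metrics <- extract_metrics_table(plots, config$generator, seed = seed + 1,
                                   cutoff = config$cutoff,
                                   k = config$extinction_k,
                                   grid_size = config$grid_size)

  screen <- pearson_screen(metrics, biomass[, -(1:2)], alpha = config$alpha)
  sel_metrics <- unique(screen$table$metric[screen$table$selected])
  vif <- if (length(sel_metrics) >= 2) {
    vif_screen(metrics[, sel_metrics, drop = FALSE],
               threshold = config$vif_threshold)
  } else list(retained = sel_metrics, vif = NULL, dropped = character(0))

  split <- split_data(plots, train_fraction = config$train_fraction,
                      seed = seed + 2)
  if (!any(split$assignment == "validation")) {
    stop("configuration leaves no validation plots", call. = FALSE)
  }
  tr <- split$assignment == "train"
  groups <- factor(biomass$age_group, levels = age_group_labels())
  X <- metrics[config$predictors]

  specs <- component_model_specs()
  models <- list()
  for (comp in names(specs)) {
    spec <- specs[[comp]]
    y <- biomass[[comp]]
    ev <- function(fit, pred_tr, pred_va, k, ll) {
      list(train = unclass(evaluate_predictions(y[tr], pred_tr, k, ll)),
           validation = unclass(evaluate_predictions(y[!tr], pred_va)))
    }

    base <- fit_base_model(spec, X[tr, ], y[tr])
    out <- list(base = c(
      list(coefficients = as.list(base$coefficients)),
      ev(base, predict(base, X[tr, ]), predict(base, X[!tr, ]),
         length(base$coefficients) + 1, base$loglik)))

    sel <- tryCatch(
      select_nlme_by_aic(spec, X[tr, ], y[tr], groups[tr]),
      error = function(e) e)
    out$nlme <- if (!inherits(sel, "error") && !is.null(sel$best)) {
      b <- sel$best
      c(list(converged = TRUE, coefficients = as.list(b$beta),
             random_effects = b$re_subset, aic_table = sel$table),
        ev(b, predict(b, X[tr, ], groups[tr]),
           predict(b, X[!tr, ], groups[!tr]), b$n_par, b$loglik))
    } else {
      list(converged = FALSE,
           message = if (inherits(sel, "error")) conditionMessage(sel)
                     else "degenerate grouping: base model stands")
    }

    dmy <- tryCatch(
      fit_dummy_model(spec, X[tr, ], y[tr], groups[tr], alpha = config$alpha),
      error = function(e) e)
    out$dummy <- if (!inherits(dmy, "error")) {
      c(list(converged = TRUE, coefficients = as.list(dmy$coefficients),
             retained = dmy$retained),
        ev(dmy, predict(dmy, X[tr, ], groups[tr]),
           predict(dmy, X[!tr, ], groups[!tr]),
           length(dmy$coefficients) + 1, dmy$loglik))
    } else {
      list(converged = FALSE, message = conditionMessage(dmy))
    }

    rf <- fit_random_forest(X[tr, ], y[tr], n_trees = config$rf_trees,
                            seed = seed + 3)
    out$random_forest <- ev(rf, predict(rf, X[tr, ]), predict(rf, X[!tr, ]),
                            NULL, NULL)
    models[[comp]] <- out
  }

  structure(list(
    config_summary = list(
      n_plots = length(plots),
      plots_per_group = as.list(stats::setNames(
        as.integer(table(groups)), age_group_labels())),
      point_density = config$generator$point_density,
      seed = seed),
    screening = list(
      n_metrics = sum(!names(metrics) %in% c("plot_id", "age_group")),
      n_selected_pairs = sum(screen$table$selected),
      pearson_selected = sel_metrics,
      vif_retained = vif$retained,
      predictors = config$predictors),
    split = list(
      n_train = sum(tr), n_validation = sum(!tr),
      per_group = as.data.frame(split$counts)),
    models = models
  ), class = "biomass_report")
}

#' Serialize a pipeline report to JSON
#'
#' @param report A `biomass_report`.
#' @param path Optional output path; when NULL the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "biomass_report"))
  clean <- rapply(unclass(report), function(x) {
    if (is.data.frame(x)) x else x
  }, how = "replace")
  js <- jsonlite::toJSON(clean, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @export
print.biomass_report <- function(x, ...) {
  cat(sprintf("<biomass_report> %d plots, %d metrics, %d train / %d validation\n",
              x$config_summary$n_plots, x$screening$n_metrics,
              x$split$n_train, x$split$n_validation))
  for (comp in names(x$models)) {
    m <- x$models[[comp]]
    fam <- names(m)
    lab <- vapply(fam, function(f) {
      r2 <- m[[f]]$validation$r2
      if (is.null(r2)) sprintf("%s (not converged)", f)
      else sprintf("%s %.3f", f, r2)
    }, character(1))
    cat(sprintf("  %-13s validation R2: %s\n", comp,
                paste(lab, collapse = ", ")))
  }
  invisible(x)
}
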