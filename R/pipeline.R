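# End-to-end orchestration: observation-table I/O with a pinned CSV schema,
# a validated run configuration, and the full analysis (formulation
# comparison, residual diagnostics, attribution importance, mid-canopy
# dynamics, protocol simplification) with a reproducible report bundle.

OBS_SCHEMA <- c(
  "observation_id", "experiment_id", "gdd_cd",
  "lft1", "lft2", "lft3", "lft4", "lft5",
  "dm_t_ha", "lnc_pct", "pnc_pct"
)

#' Read an observation table CSV
#'
#' Pinned schema: columns `observation_id, experiment_id, gdd_cd,
#' lft1..lft5, dm_t_ha, lnc_pct, pnc_pct`; UTF-8, decimal point, header
#' required, empty string = missing. Empty cells in the SPAD (`lft*`) and
#' response columns become `NA` and the row is retained; rows with
#' non-positive dry matter or plant N (impossible measurements) are
#' rejected with their line numbers. The NNI column is always recomputed
#' here via [nni()], never read from the file.
#'
#' @param path CSV path.
#' @return Validated observation tibble including the computed `nni`.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop_spadgdd(sprintf("file not found: %s", path), "io")
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      observation_id = readr::col_character(),
      experiment_id = readr::col_character(),
      .default = readr::col_double()
    ),
    na = c("", "NA"), progress = FALSE
  ))
  missing_cols <- setdiff(OBS_SCHEMA, names(raw))
  if (length(missing_cols) > 0L) {
    stop_spadgdd(
      paste0("observation CSV lacks column(s): ", paste(missing_cols, collapse = ", ")),
      "schema"
    )
  }
  probs <- readr::problems(raw)
  if (nrow(probs) > 0L) {
    stop_spadgdd(
      paste0(
        "non-numeric or malformed cell(s) at line(s): ",
        paste(head(unique(probs$row), 10L), collapse = ", ")
      ),
      "parse"
    )
  }
  if (anyDuplicated(raw$observation_id)) {
    dup <- raw$observation_id[duplicated(raw$observation_id)][1]
    stop_spadgdd(sprintf("duplicate observation id: %s", dup), "duplicate_id")
  }
  bad <- which(
    is.na(raw$gdd_cd) | raw$gdd_cd < 0 |
      (!is.na(raw$dm_t_ha) & raw$dm_t_ha <= 0) |
      (!is.na(raw$pnc_pct) & raw$pnc_pct <= 0) |
      (!is.na(raw$lnc_pct) & raw$lnc_pct <= 0)
  )
  if (length(bad) > 0L) {
    warn(paste0(
      "rejected ", length(bad), " row(s) failing range checks at line(s): ",
      paste(head(bad + 1L, 10L), collapse = ", ")
    ))
    raw <- raw[-bad, , drop = FALSE]
  }
  if (nrow(raw) == 0L) stop_spadgdd("no valid observation rows.", "invalid_input")
  raw$nni <- ifelse(
    is.na(raw$pnc_pct) | is.na(raw$dm_t_ha), NA_real_,
    raw$pnc_pct / critical_n(pmax(raw$dm_t_ha, .Machine$double.eps))
  )
  raw
}

#' Configure a full analysis run
#'
#' @param input Either a path to an observation CSV or a
#'   [generator_config()] (the default generates the synthetic panel).
#' @param targets Subset of `c("LNC", "PNC", "NNI")`.
#' @param models Model families to evaluate (see [model_spec()]).
#' @param formulations Formulation codes to compare (`"A"`..`"D"`).
#' @param protocols Measurement protocols to compare (`"full"`, `"A"`..`"F"`);
#'   protocols are evaluated under the first tree family in `models`.
#' @param cv_k Grouped-CV folds (default 10).
#' @param dynamics Logical: run the mid-canopy importance dynamics stage
#'   (requires a tree family among `models`).
#' @param dynamics_target,dynamics_model Target and tree family used for the
#'   dynamics stage (defaults PNC and RF).
#' @param dynamics_config A [dynamics_config()].
#' @param out_dir Output directory for the report bundle, or `NULL` to skip
#'   writing.
#' @param seed Master seed: models use it for stochastic fits and the
#'   bootstrap derives its stream from it.
#' @return A validated `run_config` list.
#' @export
run_config <- function(input = generator_config(),
                       targets = c("LNC", "PNC", "NNI"),
                       models = "RF",
                       formulations = c("A", "B", "C", "D"),
                       protocols = character(0),
                       cv_k = 10L,
                       dynamics = FALSE,
                       dynamics_target = "PNC", dynamics_model = "RF",
                       dynamics_config = spadgdd::dynamics_config(),
                       out_dir = NULL,
                       seed = 42L) {
  if (length(targets) < 1L || length(models) < 1L) {
    stop_spadgdd("at least one target and one model are required.", "config")
  }
  targets <- match.arg(toupper(targets), c("LNC", "PNC", "NNI"), several.ok = TRUE)
  models <- vapply(models, function(m) match.arg(toupper(m), c("PLS", "SVR", "RF", "XGB")), character(1))
  if (dynamics && !any(models %in% c("RF", "XGB"))) {
    stop_spadgdd("dynamics requires a tree model family (RF or XGB) among `models`.", "config")
  }
  if (dynamics && !(toupper(dynamics_model) %in% models)) {
    stop_spadgdd("`dynamics_model` must be one of the requested `models`.", "config")
  }
  for (f in formulations) formulation_columns(f)
  for (p in protocols) protocol_columns(p)
  structure(
    list(
      input = input, targets = targets, models = unname(models),
      formulations = toupper(formulations), protocols = protocols,
      cv_k = as.integer(cv_k), dynamics = dynamics,
      dynamics_target = toupper(dynamics_target),
      dynamics_model = toupper(dynamics_model),
      dynamics_config = dynamics_config,
      out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "spadgdd_stage_error")) stop(e)
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
      class = c("spadgdd_stage_error", "spadgdd_error"), parent = e
    )
  })
}

#' Run the full analysis
#'
#' Executes, for every requested target x model x formulation: grouped
#' cross-validation with leakage-safe preprocessing, pooled out-of-fold
#' residual trends against GDD (with the SPAD-only versus SPAD+GDD
#' comparison whenever formulations A and C are both present), global
#' attribution importance for tree families (on the additive feature set),
#' the mid-canopy importance dynamics with bootstrap crossover when
#' requested, and the measurement-protocol comparison. Writes the report
#' bundle to `config$out_dir` when set; identical config and seed give a
#' byte-identical bundle.
#'
#' @param config A [run_config()].
#' @return Invisibly, a `report_bundle` list: `observations`, `metrics`
#'   (per fold), `summaries`, `oof`, `trends`, `trend_comparisons`,
#'   `importance`, `protocol_metrics`, `dynamics`, `provenance`.
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))

  obs <- run_stage("input", {
    if (inherits(config$input, "generator_config")) {
      ds <- generate_dataset(config$input)
      ds$observations
    } else {
      read_observations(config$input)
    }
  })
  message(sprintf("[input] %d observations, %d experiments (seed %d)",
    nrow(obs), length(unique(obs$experiment_id)), config$seed))

  cv_runs <- list()
  run_stage("grouped_cv", {
    for (target in config$targets) {
      for (code in config$formulations) {
        fm <- build_formulation(obs, code, target)
        plan <- plan_group_folds(fm$groups, config$cv_k)
        for (family in config$models) {
          spec <- model_spec(family, seed = config$seed)
          key <- paste(target, family, code, sep = "_")
          cv_runs[[key]] <- run_grouped_cv(fm, spec, plan)
        }
      }
    }
  })
  message(sprintf("[grouped_cv] %d target x model x formulation runs", length(cv_runs)))

  trends <- list()
  comparisons <- list()
  run_stage("diagnostics", {
    for (key in names(cv_runs)) trends[[key]] <- residual_trend(cv_runs[[key]])
    if (all(c("A", "C") %in% config$formulations)) {
      for (target in config$targets) {
        for (family in config$models) {
          kb <- paste(target, family, "A", sep = "_")
          ka <- paste(target, family, "C", sep = "_")
          comparisons[[paste(target, family, sep = "_")]] <-
            compare_trends(trends[[kb]], trends[[ka]])
        }
      }
    }
  })

  importance <- list()
  tree_models <- intersect(config$models, c("RF", "XGB"))
  run_stage("attribution", {
    for (target in config$targets) {
      fm <- build_formulation(obs, "C", target)
      plan <- plan_group_folds(fm$groups, config$cv_k)
      for (family in tree_models) {
        spec <- model_spec(family, seed = config$seed)
        at <- oof_attributions(fm, spec, plan)
        importance[[paste(target, family, sep = "_")]] <- global_importance(at)
      }
    }
  })
  if (length(tree_models) > 0L) {
    message(sprintf("[attribution] importance for %d target x model combinations", length(importance)))
  }

  dynamics_out <- NULL
  if (config$dynamics) {
    dynamics_out <- run_stage("dynamics", {
      fm <- build_formulation(obs, "C", config$dynamics_target)
      plan <- plan_group_folds(fm$groups, config$cv_k)
      spec <- model_spec(config$dynamics_model, seed = config$seed)
      at <- oof_attributions(fm, spec, plan)
      shares <- midcanopy_shares(at)
      group_bootstrap(shares, config$dynamics_config)
    })
    message(sprintf("[dynamics] crossover %.1f C d (CI %.1f-%.1f)",
      dynamics_out$crossover$point_estimate,
      dynamics_out$crossover$ci_low, dynamics_out$crossover$ci_high))
  }

  protocol_runs <- list()
  if (length(config$protocols) > 0L) {
    proto_family <- if (length(tree_models) > 0L) tree_models[1] else config$models[1]
    run_stage("protocols", {
      for (target in config$targets) {
        for (code in config$protocols) {
          fm <- build_protocol(obs, code, target)
          plan <- plan_group_folds(fm$groups, config$cv_k)
          spec <- model_spec(proto_family, seed = config$seed)
          protocol_runs[[paste(target, proto_family, code, sep = "_")]] <-
            run_grouped_cv(fm, spec, plan)
        }
      }
    })
    message(sprintf("[protocols] %d protocol runs under %s", length(protocol_runs), proto_family))
  }

  bundle <- build_report_bundle(config, obs, cv_runs, trends, comparisons,
    importance, protocol_runs, dynamics_out)
  if (!is.null(config$out_dir)) {
    run_stage("write", write_report_bundle(bundle, config$out_dir))
    message(sprintf("[write] report bundle in %s", config$out_dir))
  }
  invisible(bundle)
}

cv_metric_rows <- function(runs) {
  dplyr::bind_rows(lapply(runs, function(cv) {
    dplyr::mutate(cv$fold_metrics,
      target = cv$target, model = cv$family, feature_set = cv$feature_set,
      .before = 1L
    )
  }))
}

cv_summary_rows <- function(runs) {
  dplyr::bind_rows(lapply(runs, function(cv) {
    dplyr::mutate(cv$summary,
      target = cv$target, model = cv$family, feature_set = cv$feature_set,
      .before = 1L
    )
  }))
}

build_report_bundle <- function(config, obs, cv_runs, trends, comparisons,
                                importance, protocol_runs, dynamics_out) {
  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  structure(
    list(
      observations = obs,
      metrics = cv_metric_rows(cv_runs),
      summaries = cv_summary_rows(cv_runs),
      oof = dplyr::bind_rows(lapply(names(cv_runs), function(key) {
        cv <- cv_runs[[key]]
        dplyr::mutate(cv$oof,
          target = cv$target, model = cv$family, feature_set = cv$feature_set
        )
      })),
      trends = lapply(trends, function(t) t[c("pearson_r", "slope", "intercept", "n", "zero_variance")]),
      trend_comparisons = lapply(comparisons, function(cmp) {
        list(r_ratio = cmp$r_ratio, slope_ratio = cmp$slope_ratio)
      }),
      importance = importance,
      protocol_metrics = if (length(protocol_runs) > 0L) cv_summary_rows(protocol_runs) else NULL,
      dynamics = dynamics_out,
      provenance = list(
        package = "spadgdd",
        version = as.character(packageVersion("spadgdd")),
        seed = config$seed,
        config_hash = rlang::hash(cfg_for_hash)
      )
    ),
    class = "report_bundle"
  )
}

write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$metrics, file.path(out_dir, "metrics_folds.csv"), progress = FALSE)
  readr::write_csv(bundle$summaries, file.path(out_dir, "metrics_summary.csv"), progress = FALSE)
  readr::write_csv(bundle$oof, file.path(out_dir, "oof_predictions.csv"), progress = FALSE)
  jsonlite::write_json(
    list(trends = bundle$trends, comparisons = bundle$trend_comparisons),
    file.path(out_dir, "residual_trends.json"),
    auto_unbox = TRUE, digits = NA
  )
  if (length(bundle$importance) > 0L) {
    imp <- dplyr::bind_rows(lapply(names(bundle$importance), function(key) {
      parts <- strsplit(key, "_", fixed = TRUE)[[1]]
      dplyr::mutate(bundle$importance[[key]], target = parts[1], model = parts[2], .before = 1L)
    }))
    readr::write_csv(imp, file.path(out_dir, "importance.csv"), progress = FALSE)
  }
  if (!is.null(bundle$protocol_metrics)) {
    readr::write_csv(bundle$protocol_metrics, file.path(out_dir, "protocol_metrics.csv"), progress = FALSE)
  }
  if (!is.null(bundle$dynamics)) {
    d <- bundle$dynamics
    jsonlite::write_json(
      list(
        grid = d$grid, curves = d$curves, bands = d$bands,
        crossover = unclass(d$crossover),
        n_skipped_replicates = d$n_skipped_replicates
      ),
      file.path(out_dir, "dynamics.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns"
    )
    readr::write_csv(d$curves, file.path(out_dir, "dynamics_curves.csv"), progress = FALSE)
  }
  jsonlite::write_json(
    c(bundle$provenance, list(files = list.files(out_dir))),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}
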