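#' Assemble a pipeline configuration
#'
#' Every constant the analysis depends on lives here with its documented
#' default: the preprocessing grid and filter, the Laguerre basis, the
#' principal-dynamic-mode retention rule, the index construction, and the
#' statistics battery. The configuration round-trips losslessly through
#' YAML/JSON (it is a plain named list).
#'
#' @param Ts Uniform sampling interval (s).
#' @param f_cut High-pass cut-off (Hz).
#' @param outlier_k SD multiple for outlier removal.
#' @param alpha,L,M Laguerre basis parameters.
#' @param ridge Ridge penalty for kernel estimation (0 = OLS).
#' @param variance_threshold,q_cap Mode retention rule.
#' @param step_method Physiological-index interpretation.
#' @param alpha_family,n_tests Bonferroni correction inputs.
#' @param seed Master seed; all stage randomness derives from it.
#' @param cohort A [cohort_config()] used when the pipeline simulates its
#'   own cohort.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(Ts = 1, f_cut = 0.005, outlier_k = 3,
                            alpha = 0.5, L = 4, M = 60, ridge = 0,
                            variance_threshold = 0.9, q_cap = 3,
                            step_method = "dc_gain",
                            alpha_family = 0.05, n_tests = 4,
                            seed = 20260101,
                            cohort = cohort_config(seed = seed)) {
  structure(
    list(preprocessing = list(Ts = Ts, f_cut = f_cut, outlier_k = outlier_k),
         model = list(alpha = alpha, L = L, M = M, ridge = ridge),
         pdm = list(variance_threshold = variance_threshold, q_cap = q_cap),
         indices = list(step_method = step_method),
         stats = list(alpha_family = alpha_family, n_tests = n_tests),
         seed = seed, cohort = cohort),
    class = "pipeline_config"
  )
}

# Rolling polynomial hash of a deparsed object; enough to fingerprint a
# config in the run manifest without extra dependencies.
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Executes simulate-or-ingest -> preprocess -> fit kernels -> train
#' principal dynamic modes -> score indices -> association battery, and
#' returns the per-subject indices, the statistics tables and a run
#' manifest. Identical `(config, inputs, seed)` give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param recordings Optional named list of [physio_recording()]s; when
#'   `NULL` a synthetic cohort is generated from `config$cohort`.
#' @param cohort Cohort tibble matching `recordings`; required when
#'   recordings are supplied.
#' @param out_dir Optional directory: writes `indices.csv`,
#'   `associations.csv`, `anova.csv`, `cohort.csv` and `manifest.json`.
#' @return List with `indices`, `scored_cohort`, `associations`, `anova`,
#'   `models`, `index_model` and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), recordings = NULL,
                         cohort = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            parent = e)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  if (is.null(recordings)) {
    sim <- stage("simulate", {
      cfg <- config$cohort
      cfg$seed <- config$seed
      generate_cohort(cfg, make_recordings = TRUE)
    })
    recordings <- sim$recordings
    cohort <- sim$cohort
  } else if (is.null(cohort)) {
    abort("`cohort` must be supplied together with `recordings`.")
  }

  pre <- config$preprocessing
  series <- stage("preprocess", {
    purrr::imap(recordings, function(rec, id) {
      tryCatch(
        suppressWarnings(
          preprocess_recording(rec, Ts = pre$Ts, f_cut = pre$f_cut,
                               outlier_k = pre$outlier_k)
        ),
        error = function(e) {
          abort(sprintf("subject %s: %s", id, conditionMessage(e)), parent = e)
        }
      )
    })
  })

  mc <- config$model
  models <- stage("fit-kernels", {
    purrr::imap(series, function(s, id) {
      out <- list()
      for (ch in c("CBV", "OXY")) {
        out[[ch]] <- if (ch %in% names(s)) {
          tryCatch(
            fit_kernel_model(s, ch, mc$alpha, mc$L, mc$M, mc$ridge),
            error = function(e) {
              abort(sprintf("subject %s (%s): %s", id, ch, conditionMessage(e)),
                    parent = e)
            }
          )
        } else NULL
      }
      out
    })
  })

  kernels <- pathway_kernels(models)
  labels <- tibble::tibble(
    subject_id = cohort$subject_id,
    impaired = cohort$diagnosis %in% c("MCI", "dementia"),
    apoe_e4 = cohort$apoe_e4
  )
  imodel <- stage("train-pdm", {
    suppressWarnings(train_index_model(
      kernels, labels,
      variance_threshold = config$pdm$variance_threshold,
      q_cap = config$pdm$q_cap, Ts = pre$Ts,
      step_method = config$indices$step_method
    ))
  })
  indices <- stage("score", score_indices(imodel, kernels, labels))

  scored <- dplyr::left_join(cohort, indices, by = "subject_id")
  assoc <- stage("associate", {
    suppressWarnings(association_table(
      scored,
      alpha_family = config$stats$alpha_family,
      n_tests = config$stats$n_tests
    ))
  })
  anova_tbl <- stage("anova", {
    purrr::map_dfr(c("DVR", "DCA", "COCR", "COPR", "composite_COR"), function(ix) {
      at <- anova_tukey(scored, ix, "diagnosis")
      dplyr::mutate(tidy(at), index = ix, f = at$statistic,
                    omnibus_p = at$p.value, .before = 1)
    })
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("hemodyn")),
    config_hash = fnv1a(unclass(config)),
    seed = config$seed,
    n_subjects = nrow(cohort),
    n_with_cbv = if (is.null(kernels[["ABP->CBV"]])) 0L else nrow(kernels[["ABP->CBV"]]),
    qc = purrr::map(series, ~ list(
      removed_fraction = as.list(attr(.x, "removed_fraction")),
      warnings = attr(.x, "qc_warnings")
    )),
    timings_s = timings,
    finished = format(t_start, "%Y-%m-%dT%H:%M:%S")
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(indices, file.path(out_dir, "indices.csv"))
    readr::write_csv(assoc, file.path(out_dir, "associations.csv"))
    readr::write_csv(anova_tbl, file.path(out_dir, "anova.csv"))
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(indices = indices, scored_cohort = scored, associations = assoc,
       anova = anova_tbl, models = models, index_model = imodel,
       manifest = manifest)
}
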