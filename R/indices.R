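#' Collect per-pathway kernel ensembles from fitted subject models
#'
#' @param models Named list (by subject id); each element is a list with
#'   components `CBV` and/or `OXY` holding [fit_kernel_model()] results
#'   (`NULL` when that output channel was unavailable).
#' @return Named list over the four pathways of subjects-by-lags kernel
#'   matrices (rownames = subject ids); subjects lacking the output are
#'   simply absent from that pathway's matrix.
#' @export
pathway_kernels <- function(models) {
  out <- list()
  for (p in .pathways) {
    outp <- pathway_output(p)
    rows <- purrr::compact(purrr::map(models, function(m) {
      mod <- m[[outp]]
      if (is.null(mod)) return(NULL)
      if (pathway_input(p) == "ABP") mod$k_abp else mod$k_co2
    }))
    if (length(rows)) {
      out[[p]] <- do.call(rbind, rows)
      rownames(out[[p]]) <- names(rows)
    }
  }
  out
}

#' Train the full index model on a cohort of kernels
#'
#' Fits, per pathway: the principal dynamic modes (ensemble SVD), the
#' APOE-stratified Gaussian reference distributions of the mode gains in
#' cognitively unimpaired vs impaired subjects, and the frozen regression
#' weights of each log-likelihood-ratio index (DVR, DCA, COCR, COPR, and
#' composite-COR from the concatenated oxygenation-pathway LLRs). All
#' components are frozen after training; scoring never refits.
#'
#' @param kernels Per-pathway kernel matrices from [pathway_kernels()].
#' @param labels Tibble with `subject_id`, `impaired` (logical) and
#'   `apoe_e4` (logical) for the training subjects.
#' @param variance_threshold,q_cap Passed to [train_pdms()].
#' @param min_cell Passed to [fit_reference_distributions()].
#' @param Ts Sampling interval of the kernels (s).
#' @param step_method Interpretation of the physiological index; see
#'   [physiological_index()].
#' @return An object of class `index_model`.
#' @export
train_index_model <- function(kernels, labels, variance_threshold = 0.9,
                              q_cap = 3, min_cell = 5, Ts = 1,
                              step_method = "dc_gain") {
  stopifnot(all(c("subject_id", "impaired", "apoe_e4") %in% names(labels)))
  pdms <- list()
  refs <- list()
  for (p in names(kernels)) {
    K <- kernels[[p]]
    pdms[[p]] <- train_pdms(K, variance_threshold, q_cap, pathway = p)
    g <- compute_gains(K, pdms[[p]])
    lab <- labels[match(rownames(K), labels$subject_id), ]
    keep <- !is.na(lab$impaired)
    refs[[p]] <- fit_reference_distributions(
      g[keep, , drop = FALSE], lab$impaired[keep], lab$apoe_e4[keep],
      min_cell = min_cell
    )
  }
  weights <- list()
  for (idx in names(.index_pathways)) {
    paths <- .index_pathways[[idx]]
    if (!all(paths %in% names(kernels))) next
    llrs <- index_llrs(idx, kernels, pdms, refs, labels)
    lab <- labels[match(rownames(llrs), labels$subject_id), ]
    keep <- !is.na(lab$impaired)
    weights[[idx]] <- fit_index_weights(llrs[keep, , drop = FALSE],
                                        lab$impaired[keep])
  }
  structure(
    list(pdms = pdms, refs = refs, weights = weights, Ts = Ts,
         step_method = step_method, weights_version = "v1"),
    class = "index_model"
  )
}

# LLR columns feeding one index: the gains of its pathway(s), evaluated
# against each subject's APOE stratum; rows restricted to subjects with
# all required pathways.
index_llrs <- function(index, kernels, pdms, refs, labels) {
  paths <- .index_pathways[[index]]
  ids <- Reduce(intersect, lapply(paths, function(p) rownames(kernels[[p]])))
  ids <- intersect(ids, labels$subject_id)
  blocks <- lapply(paths, function(p) {
    K <- kernels[[p]][ids, , drop = FALSE]
    g <- compute_gains(K, pdms[[p]])
    apoe <- labels$apoe_e4[match(ids, labels$subject_id)]
    ll <- llr_matrix(g, refs[[p]], apoe)
    colnames(ll) <- paste(gsub("[^A-Za-z0-9]", "", p), colnames(ll), sep = "_")
    ll
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- ids
  out
}

#' @export
print.index_model <- function(x, ...) {
  cat(sprintf(
    "<index_model> pathways: %s; indices: %s; weights %s\n",
    toString(names(x$pdms)), toString(names(x$weights)), x$weights_version
  ))
  invisible(x)
}

#' Score hemodynamic indices for a cohort of kernels
#'
#' Computes, per subject, the five log-likelihood-ratio indices (weighted
#' LLR sums against the frozen reference model) and the four physiological
#' step-response indices (kernel DC gains). Subjects lacking a pathway
#' (e.g. no usable transcranial Doppler signal) get `NA` on the indices
#' that need it; the oxygenation indices are still computed.
#'
#' @param model A trained [train_index_model()].
#' @param kernels Per-pathway kernel matrices from [pathway_kernels()].
#' @param labels Tibble with `subject_id` and `apoe_e4` for the scored
#'   subjects.
#' @return A tibble with one row per subject: `subject_id`, `DVR`, `DCA`,
#'   `COCR`, `COPR`, `composite_COR`, and `phys_DVR`, `phys_DCA`,
#'   `phys_COCR`, `phys_COPR`.
#' @export
score_indices <- function(model, kernels, labels) {
  stopifnot(inherits(model, "index_model"))
  ids <- unique(unlist(lapply(kernels, rownames)))
  out <- tibble::tibble(subject_id = ids)
  lab <- labels[match(ids, labels$subject_id), ]
  for (idx in names(.index_pathways)) {
    vals <- rep(NA_real_, length(ids))
    paths <- .index_pathways[[idx]]
    if (all(paths %in% names(kernels)) && !is.null(model$weights[[idx]])) {
      llrs <- index_llrs(idx, kernels, model$pdms, model$refs,
                         tibble::tibble(subject_id = ids, apoe_e4 = lab$apoe_e4))
      vals[match(rownames(llrs), ids)] <- compute_index(llrs, model$weights[[idx]])
    }
    out[[idx]] <- vals
  }
  phys_map <- c(phys_DVR = "CO2->CBV", phys_DCA = "ABP->CBV",
                phys_COCR = "CO2->OXY", phys_COPR = "ABP->OXY")
  for (nm in names(phys_map)) {
    p <- phys_map[[nm]]
    vals <- rep(NA_real_, length(ids))
    if (p %in% names(kernels)) {
      K <- kernels[[p]]
      vals[match(rownames(K), ids)] <- apply(K, 1, physiological_index,
                                             Ts = model$Ts,
                                             method = model$step_method)
    }
    out[[nm]] <- vals
  }
  out
}
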