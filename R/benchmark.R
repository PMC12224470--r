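#' Run the estimator benchmark
#'
#' Orchestrates the simulation study: generates (or reuses) the benchmark
#' test set, runs every requested estimator on the same noisy signals,
#' computes each estimator's Sensitivity-Specificity Matrix and writes CSV /
#' JSON reports with full provenance (seeds, sizes, package version). An
#' estimator failing on more than 20 percent of voxels is marked failed in
#' the report but the run continues.
#'
#' @param config list with optional entries: `estimators` (character subset
#'   of smi, noddi, smt, wmti, wwmti, oracle), `n`, `snr`, `seed`,
#'   `n_train` (SMI training size), `protocol_seed`.
#' @param outdir output directory (created if needed); `NULL` for no files.
#' @param test_set optionally a precomputed [make_test_set()].
#' @return List of class `sm_benchmark`: `ssm` (named list of [compute_ssm()]
#'   results), `estimates`, `test_set`, `report`.
#' @export
run_benchmark <- function(config = list(), outdir = NULL, test_set = NULL) {
  cfg <- utils::modifyList(list(estimators = c("smi", "noddi", "smt", "wmti"),
                                n = 10000, snr = 25, seed = 1,
                                n_train = 1e5, protocol_seed = 1), config)
  if (is.null(test_set)) {
    protocol <- default_protocol(seed = cfg$protocol_seed)
    test_set <- make_test_set(n = cfg$n, snr = cfg$snr, protocol = protocol,
                              seed = cfg$seed)
  }
  protocol <- test_set$protocol
  ssms <- list(); ests <- list(); status <- list()
  for (e in cfg$estimators) {
    est <- switch(e,
      oracle = sm_estimates(
        test_set$theta[SM_PARAMS[1:5]], estimator = "oracle"),
      smi = {
        model <- smi_train(sm_prior(), protocol, snr = cfg$snr,
                           n = cfg$n_train, seed = cfg$seed + 17L)
        fit_smi(test_set$signals, protocol, model)
      },
      noddi = fit_noddi(test_set$signals, protocol),
      smt = fit_smt(test_set$signals, protocol),
      wmti = fit_wmti(test_set$signals, protocol),
      wwmti = fit_wwmti(test_set$signals, protocol),
      stop("unknown estimator: ", e))
    ests[[e]] <- est
    frac_bad <- mean(est$flags)
    if (frac_bad > 0.2) {
      status[[e]] <- sprintf("failed (%.0f%% voxels flagged)", 100 * frac_bad)
      next
    }
    status[[e]] <- "ok"
    ssms[[e]] <- compute_ssm(test_set$theta, est)
  }
  report <- list(config = cfg, status = status,
                 n_voxels = nrow(test_set$theta),
                 snr = test_set$snr, seed = test_set$seed,
                 package_version = as.character(utils::packageVersion("smikit")),
                 ssm = lapply(ssms, function(s) {
                   m <- as.data.frame(s$S)
                   m$truth <- rownames(s$S)
                   m
                 }))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (e in names(ssms)) {
      utils::write.csv(ssms[[e]]$S,
                       file.path(outdir, paste0("ssm_", e, ".csv")))
    }
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    grDevices::png(file.path(outdir, "ssm_heatmaps.png"),
                   width = 400 * max(1, length(ssms)), height = 400)
    op <- graphics::par(mfrow = c(1, max(1, length(ssms))))
    for (e in names(ssms)) plot(ssms[[e]])
    graphics::par(op)
    grDevices::dev.off()
  }
  structure(list(ssm = ssms, estimates = ests, test_set = test_set,
                 report = report),
            class = "sm_benchmark")
}

#' @export
print.sm_benchmark <- function(x, ...) {
  cat("SM estimator benchmark:", nrow(x$test_set$theta), "voxels, SNR",
      x$test_set$snr, "\n\n")
  for (e in names(x$ssm)) { print(x$ssm[[e]]); cat("\n") }
  invisible(x)
}
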