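#' Assemble a machine- and human-readable results bundle
#'
#' Collects per-group therapy test results (p-values and decisions),
#' optional questionnaire effect summaries and a correlation screen into a
#' deterministic list; optionally writes it as JSON (byte-identical across
#' reruns with identical inputs) and prints a short textual summary.
#'
#' @param therapy_results List of `therapy_test_result` objects (>= 1).
#' @param effects Optional data frame from [effect_summary()].
#' @param correlations Optional `correlation_screen`.
#' @param auc Optional named list of `auc_comparison` objects.
#' @param path Optional JSON output path.
#' @return The report list, invisibly when `path` is given.
#' @export
build_report <- function(therapy_results, effects = NULL, correlations = NULL,
                         auc = NULL, path = NULL) {
  if (length(therapy_results) < 1) stop("at least one evaluated group required")
  groups <- lapply(therapy_results, function(r) {
    list(group = r$group, p = r$p,
         normality_p = as.list(r$normality_p),
         decision = r$decision, method = r$method, alpha = r$alpha)
  })
  names(groups) <- vapply(therapy_results,
                          function(r) r$group %||% "unnamed", character(1))
  report <- list(therapy_tests = groups)
  if (!is.null(effects)) report$effect_summary <- effects
  if (!is.null(auc)) {
    report$auc <- lapply(auc, function(a)
      list(auc = as.list(a$auc), auc_max = a$auc_max, auc_ch = a$auc_ch))
  }
  if (!is.null(correlations)) {
    report$correlations <- list(
      method = correlations$method,
      significant = correlations$significant,
      rho = correlations$rho)
  }
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  for (g in names(groups)) {
    cat(sprintf("%-8s p = %.4f  %s\n", g, groups[[g]]$p, groups[[g]]$decision))
  }
  if (is.null(path)) report else invisible(report)
}
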