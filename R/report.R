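# Long-run summary container shared by all dynamics backends.

#' Stationary report
#'
#' Long-run strategy abundances plus a scalar cooperation index, produced by
#' [run_imitation()], [small_mu_stationary()] or the game-specific drivers.
#'
#' @param abundances named numeric vector summing to 1 (tolerance 1e-9).
#' @param cooperation_index numeric in `[0, 1]` (or NA when no cooperation
#'   measure was supplied).
#' @param method one of "replicator", "simulation", "small_mu".
#' @param params list of parameters (including any seed) recorded as metadata.
#' @return object of class `stationary_report`.
#' @export
stationary_report <- function(abundances, cooperation_index = NA_real_,
                              method = c("simulation", "small_mu", "replicator"),
                              params = list()) {
  method <- match.arg(method)
  if (abs(sum(abundances) - 1) > 1e-9) {
    stop("abundances must sum to 1 (got ", sum(abundances), ")")
  }
  if (any(abundances < -1e-12)) stop("abundances must be non-negative")
  if (!is.na(cooperation_index) &&
      (cooperation_index < -1e-9 || cooperation_index > 1 + 1e-9)) {
    stop("cooperation_index must lie in [0, 1]")
  }
  structure(list(abundances = abundances,
                 cooperation_index = as.numeric(cooperation_index),
                 method = method,
                 params = params),
            class = "stationary_report")
}

#' @export
print.stationary_report <- function(x, ...) {
  cat("<stationary_report> method =", x$method,
      " cooperation_index =", signif(x$cooperation_index, 4), "\n")
  ab <- sort(x$abundances, decreasing = TRUE)
  k <- min(length(ab), 8L)
  cat("top strategies:\n")
  for (i in seq_len(k)) {
    cat(sprintf("  %-12s %.4f\n", names(ab)[i], ab[i]))
  }
  if (length(ab) > k) cat("  ... (", length(ab) - k, " more)\n", sep = "")
  invisible(x)
}

#' Write a stationary report to disk
#'
#' Writes `<prefix>.csv` with columns `strategy_label, abundance` and a JSON
#' sidecar `<prefix>.json` holding the method, cooperation index and all
#' recorded parameters (including the seed).
#'
#' @param report a [stationary_report()].
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_report <- function(report, prefix) {
  csv <- paste0(prefix, ".csv")
  js <- paste0(prefix, ".json")
  write.csv(data.frame(strategy_label = names(report$abundances),
                       abundance = as.numeric(report$abundances)),
            csv, row.names = FALSE)
  jsonlite::write_json(list(method = report$method,
                            cooperation_index = report$cooperation_index,
                            params = report$params),
                       js, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv = csv, json = js))
}
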