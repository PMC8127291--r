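#' Write a cost-effectiveness report to disk
#'
#' Exports the fitted model (and optionally sensitivity analyses) as
#' plain-text artifacts: classification and per-strategy outcome tables,
#' both ICER-table conventions, the frontier as JSON, PSA draws and CEAC
#' and selection probabilities, the tornado table, and a JSON manifest
#' listing every file written together with the seed and package version.
#' All CSVs use '.' as the decimal separator, UTF-8, and a header row, so a
#' rerun from the same configuration and seed reproduces their numeric
#' content exactly.
#'
#' @param fit a [sarc_cea()] object.
#' @param dir output directory (created if missing).
#' @param psa optional `sarc_psa` object.
#' @param dsa optional `sarc_dsa` object.
#' @param figures logical; also render PNG figures (cost-effectiveness
#'   plane, CEAC, tornado) for the components supplied.
#' @return invisible character vector of the files written.
#' @export
write_cea_report <- function(fit, dir, psa = NULL, dsa = NULL,
                             figures = FALSE) {
  stopifnot(inherits(fit, "sarc_cea"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
    files <<- c(files, path)
  }
  put(fit$classification, "classification.csv")
  put(fit$results, "strategy_outcomes.csv")
  put(as.data.frame(fit$table_reference), "cea_reference.csv")
  put(as.data.frame(fit$table_frontier), "cea_frontier.csv")
  frontier_path <- file.path(dir, "frontier.json")
  jsonlite::write_json(fit$frontier, frontier_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  files <- c(files, frontier_path)
  if (!is.null(psa)) {
    put(cbind(iteration = seq_len(psa$n_iter), psa$draws), "psa_draws.csv")
    put(data.frame(iteration = seq_len(psa$n_iter),
                   stats::setNames(as.data.frame(psa$cost),
                                   paste0("cost_", colnames(psa$cost))),
                   stats::setNames(as.data.frame(psa$effect),
                                   paste0("effect_", colnames(psa$effect))),
                   check.names = FALSE), "psa_outcomes.csv")
    cc <- ceac(psa)
    put(data.frame(lambda = attr(cc, "lambda"), cc, check.names = FALSE),
        "ceac.csv")
    put(data.frame(strategy = names(selection_probabilities(psa)),
                   probability = unname(selection_probabilities(psa))),
        "selection_probabilities.csv")
  }
  if (!is.null(dsa)) put(as.data.frame(dsa), "tornado.csv")
  if (figures) {
    fig <- function(name, expr) {
      path <- file.path(dir, name)
      grDevices::png(path, width = 900, height = 650)
      on.exit(grDevices::dev.off(), add = TRUE)
      force(expr)
      files <<- c(files, path)
    }
    fig("ce_plane.png", plot(fit))
    if (!is.null(psa)) fig("ceac.png", plot(psa, type = "ceac"))
    if (!is.null(dsa)) fig("tornado.png", plot(dsa))
  }
  manifest <- list(
    package = "sarcscreen",
    version = as.character(utils::packageVersion("sarcscreen")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = if (!is.null(psa)) psa$seed else NULL,
    n_iter = if (!is.null(psa)) psa$n_iter else NULL,
    wtp = fit$wtp,
    files = basename(files))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  files <- c(files, manifest_path)
  invisible(files)
}
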