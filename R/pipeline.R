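#' Run the full sutural-fusion analysis end to end
#'
#' Chains the analysis stages in order: outgroup addition, heuristic
#' parsimony search, strict and majority-rule consensus, optional bootstrap,
#' obliteration-sequence extraction, closure/interdigitation scoring
#' (specimen, category and group averages, size-closure trend fits,
#' ontogram linearity) and, when section measurements are given,
#' histomorphometry; when a second coding is given, inter-rater
#' reliability. All randomness derives from `seed`. Outputs (Newick trees,
#' TSV tables, a JSON summary and a run log) are written under `out_dir`;
#' rerunning with the same inputs and seed reproduces the summary
#' byte-for-byte.
#'
#' @param matrix a [character_matrix()] or path to a NEXUS file.
#' @param records specimen metadata data frame or path (CSV/TSV).
#' @param out_dir output directory (created if needed).
#' @param sections optional section-measurement table or path.
#' @param recoding optional second [character_matrix()] (or NEXUS path) for
#'   the reliability stage.
#' @param chardefs optional character definitions (or path) used when
#'   `matrix` is a file.
#' @param config a [search_config()]; its seed is overridden by `seed`.
#' @param seed master seed propagated to every stochastic stage.
#' @param bootstrap_replicates bootstrap replicates (0 disables).
#' @param trend_model model for the size-closure fit.
#' @return the summary list, invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(matrix, records = NULL, out_dir,
                         sections = NULL, recoding = NULL, chardefs = NULL,
                         config = search_config(), seed = config$seed,
                         bootstrap_replicates = 0,
                         trend_model = c("linear", "log")) {
  trend_model <- match.arg(trend_model)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...,
                            "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  fail <- function(stage, e) {
    writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    logf("stage ", name)
    tryCatch(expr, error = function(e) fail(name, e))
  }

  if (is.character(chardefs)) chardefs <- read_chardef_table(chardefs)
  if (is.character(matrix))
    matrix <- stage("read_matrix", read_nexus_matrix(matrix, chars = chardefs))
  if (is.character(records)) records <- stage("read_records",
                                              read_specimen_table(records))
  if (is.character(sections)) sections <- stage("read_sections",
                                                read_suture_sections(sections))
  if (is.character(recoding)) recoding <- stage("read_recoding",
                                                read_nexus_matrix(recoding))
  config$seed <- as.integer(seed)
  logf("seed ", config$seed, "; R ", as.character(getRversion()),
       "; ontogram ", as.character(utils::packageVersion("ontogram")))

  fit <- stage("ontogram", ontogram(matrix, records, config = config,
                                    bootstrap_replicates = bootstrap_replicates))
  stage("write_trees", {
    write_consensus_newick(fit$consensus,
                           file.path(out_dir, "consensus_majority.nwk"),
                           bootstrap = fit$bootstrap)
    write_consensus_newick(fit$consensus_strict,
                           file.path(out_dir, "consensus_strict.nwk"))
  })
  avgs <- stage("scoring", specimen_averages(fit$matrix))
  stage("write_scores", {
    if (!is.null(records)) {
      idx <- match(canonical_id(avgs$specimen_id),
                   canonical_id(records$specimen_id))
      avgs$category <- records$category[idx]
    }
    utils::write.table(avgs, file.path(out_dir, "specimen_averages.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })
  trend <- NULL
  if (!is.null(records))
    trend <- tryCatch(suture_trend(records, avgs, model = trend_model),
                      error = function(e) { logf("trend skipped: ",
                                                 conditionMessage(e)); NULL })
  cat_avgs <- NULL
  if (!is.null(records) && "category" %in% names(records)) {
    cats <- intersect(CATEGORY_LEVELS, unique(records$category))
    if (length(cats))
      cat_avgs <- stats::setNames(vapply(cats, function(cg)
        tryCatch(category_average(fit$matrix, records, "closure", cg),
                 error = function(e) NA_real_), numeric(1)), cats)
  }
  histo <- NULL
  if (!is.null(sections))
    histo <- stage("histomorphometry", {
      h <- histo_widths(sections)
      utils::write.table(h, file.path(out_dir, "histomorphometry.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      h
    })
  reli <- NULL
  if (!is.null(recoding))
    reli <- stage("reliability", compare_codings(matrix, recoding))

  summary <- list(
    schema = "ontogram-pipeline/1",
    seed = config$seed,
    n_specimens = length(fit$matrix$taxa) - 1L,
    n_characters = nrow(fit$matrix$chars),
    best_length = fit$search$length,
    n_mpts = length(fit$search$trees),
    truncated = fit$search$truncated,
    ci = fit$score$ci, hi = fit$score$hi, ri = fit$score$ri,
    linearity = if (!is.null(fit$linearity)) fit$linearity$rho else NULL,
    trend = if (!is.null(trend)) list(model = trend$model,
                                      pearson_r = trend$pearson_r,
                                      slope = trend$slope,
                                      intercept = trend$intercept,
                                      n = trend$n) else NULL,
    category_averages = as.list(cat_avgs),
    obliteration_sequence = fit$obliteration$sequence,
    reliability = if (!is.null(reli))
      list(kappa = reli$kappa, z = reli$z,
           n_disagreements = reli$n_disagreements,
           pearson_rho = reli$pearson_rho) else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  logf("done")
  invisible(summary)
}
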