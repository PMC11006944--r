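#' Write a session to CSV
#'
#' One file per participant, header `trial,kick,prediction,rt_seconds`,
#' 1-based trial indices, response times printed with 15 significant
#' digits.
#'
#' @param session A [session_data()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session_data"))
  df <- as.data.frame(session)
  df$rt_seconds <- sprintf("%.15g", df$rt_seconds)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a session from CSV
#'
#' Validates the file written by [write_session()]: exact column set,
#' contiguous 1-based trial index, in-alphabet symbols, strictly positive
#' response times. Violations raise errors naming the offending rows.
#'
#' @param path File to read.
#' @param participant_id Label for the session (default: file name without
#'   extension).
#' @param alphabet Admissible symbols, default `0:2`.
#' @return A [session_data()] object.
#' @export
read_session <- function(path,
                         participant_id = sub("\\.[^.]*$", "", basename(path)),
                         alphabet = 0:2) {
  if (!file.exists(path)) stop("session file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("trial", "kick", "prediction", "rt_seconds")
  if (!identical(sort(names(df)), sort(required))) {
    stop("session file ", path, " must have exactly the columns ",
         paste(required, collapse = ", "), "; found: ",
         paste(names(df), collapse = ", "))
  }
  n <- nrow(df)
  if (!identical(as.integer(df$trial), seq_len(n))) {
    bad <- which(as.integer(df$trial) != seq_len(n))[1L]
    stop("trial index must be contiguous 1..N; first violation at row ", bad)
  }
  bad_sym <- which(!(df$kick %in% alphabet) | !(df$prediction %in% alphabet))
  if (length(bad_sym)) {
    stop("out-of-alphabet symbol(s) at row(s) ",
         paste(utils::head(bad_sym, 5), collapse = ", "))
  }
  bad_rt <- which(!is.finite(df$rt_seconds) | df$rt_seconds <= 0)
  if (length(bad_rt)) {
    stop("non-positive or missing rt_seconds at row(s) ",
         paste(utils::head(bad_rt, 5), collapse = ", "))
  }
  session_data(df$kick, df$prediction, df$rt_seconds, participant_id,
               alphabet = alphabet)
}

#' Assemble a full-run configuration
#'
#' Bundles the cohort simulation settings with the estimator and analysis
#' parameters used by [run_pipeline()].
#'
#' @param cohort A [cohort_config()].
#' @param K,alpha,min_count Estimator parameters
#'   (see [estimate_context_tree()]).
#' @param contexts Contexts analysed by [run_misprediction_analysis()].
#' @param trim,q,min_n Analysis parameters.
#' @param ingest_dir Optional directory of existing session CSV files; when
#'   given, sessions are read instead of simulated.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), K = 3, alpha = 0.05,
                       min_count = 5,
                       contexts = c("0", "2", "01", "11", "21"),
                       trim = 0.2, q = 0.05, min_n = 5, ingest_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_config"), K >= 1,
            alpha > 0, alpha < 1, trim >= 0, trim < 0.5, q > 0, q < 1)
  structure(list(cohort = cohort, K = as.integer(K), alpha = alpha,
                 min_count = as.integer(min_count), contexts = contexts,
                 trim = trim, q = q, min_n = as.integer(min_n),
                 ingest_dir = ingest_dir),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Reads the scalar fields of [run_config()] and of the nested
#' [cohort_config()] (`n_participants`, `n_trials`, `epoch_boundaries`,
#' `seed`, and optional `behavior_accuracy`, `rt_log_median`, `rt_log_sd`,
#' `rt_failure_shift` maps); unlisted fields keep their defaults.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cc_args <- list()
  for (f in c("n_participants", "n_trials", "epoch_boundaries", "seed")) {
    if (!is.null(raw[[f]])) cc_args[[f]] <- raw[[f]]
  }
  if (!is.null(raw$behavior_accuracy)) {
    cc_args$behavior <- behavior_model(unlist(raw$behavior_accuracy))
  }
  rt_args <- list()
  if (!is.null(raw$rt_log_median)) rt_args$log_median <- unlist(raw$rt_log_median)
  if (!is.null(raw$rt_log_sd)) rt_args$log_sd <- raw$rt_log_sd
  if (!is.null(raw$rt_failure_shift)) {
    rt_args$failure_shift <- unlist(raw$rt_failure_shift)
  }
  if (length(rt_args)) cc_args$rt <- do.call(rt_model, rt_args)
  rc_args <- list(cohort = do.call(cohort_config, cc_args))
  for (f in c("K", "alpha", "min_count", "contexts", "trim", "q", "min_n",
              "ingest_dir")) {
    if (!is.null(raw[[f]])) rc_args[[f]] <- raw[[f]]
  }
  do.call(run_config, rc_args)
}

#' Run the full analysis pipeline
#'
#' Simulates (or ingests) a cohort, estimates a context tree per
#' participant and epoch, aggregates a mode tree per epoch, runs the
#' misprediction analysis on the full sessions, and writes every artifact
#' plus a manifest to `out_dir`. The run is a pure function of the
#' configuration: re-running with the same `config` reproduces identical
#' outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the cohort, the per-participant epoch
#'   trees, the per-epoch mode trees, the analysis and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sessions_dir <- file.path(out_dir, "sessions")
  trees_dir <- file.path(out_dir, "trees")
  dir.create(sessions_dir, showWarnings = FALSE)
  dir.create(trees_dir, showWarnings = FALSE)

  if (is.null(config$ingest_dir)) {
    message("stage simulate: ", config$cohort$n_participants,
            " participants x ", config$cohort$n_trials, " trials")
    cohort <- generate_cohort(config$cohort)
  } else {
    if (!dir.exists(config$ingest_dir)) {
      stop("ingest directory does not exist: ", config$ingest_dir)
    }
    files <- sort(list.files(config$ingest_dir, pattern = "\\.csv$",
                             full.names = TRUE))
    if (!length(files)) stop("no session files in ", config$ingest_dir)
    message("stage ingest: ", length(files), " session files")
    cohort <- lapply(files, read_session,
                     alphabet = config$cohort$tree$alphabet)
  }
  session_files <- character(0)
  for (s in cohort) {
    f <- file.path(sessions_dir, paste0(s$participant_id, ".csv"))
    write_session(s, f)
    session_files <- c(session_files, f)
  }

  boundaries <- config$cohort$epoch_boundaries
  epoch_trees <- list()
  tree_files <- character(0)
  for (s in cohort) {
    trees <- estimate_by_epoch(s, boundaries = boundaries, K = config$K,
                               alpha = config$alpha,
                               min_count = config$min_count)
    epoch_trees[[s$participant_id]] <- trees
    for (ep in names(trees)) {
      n_tests <- length(attr(trees[[ep]], "branch_tests"))
      message("stage estimate: ", s$participant_id, " ", ep, " -> ",
              length(trees[[ep]]$contexts), " contexts (", n_tests,
              " branch tests)")
      f <- file.path(trees_dir, paste0(s$participant_id, "_", ep, ".json"))
      write_context_tree(trees[[ep]], f)
      tree_files <- c(tree_files, f)
    }
  }

  n_epochs <- length(unique(unlist(lapply(epoch_trees, names))))
  mode_trees <- list()
  mode_files <- character(0)
  for (i in seq_len(n_epochs)) {
    ep <- paste0("epoch_", i)
    per_participant <- lapply(epoch_trees, `[[`, ep)
    per_participant <- Filter(Negate(is.null), per_participant)
    mode_trees[[ep]] <- mode_context_tree(per_participant, threshold = 0.5)
    f <- file.path(out_dir, paste0("mode_", ep, ".json"))
    write_context_tree(mode_trees[[ep]]$tree, f)
    mode_files <- c(mode_files, f)
  }

  message("stage analyze: ", length(config$contexts), " contexts")
  analysis <- run_misprediction_analysis(cohort, contexts = config$contexts,
                                         trim = config$trim, q = config$q,
                                         min_n = config$min_n)
  report_file <- file.path(out_dir, "report.tsv")
  utils::write.table(as.data.frame(analysis$summary), report_file,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  means_file <- file.path(out_dir, "participant_means.tsv")
  utils::write.table(as.data.frame(analysis$participant_means), means_file,
                     sep = "\t", row.names = FALSE, quote = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("rtctree")),
    config_hash = rlang::hash(config),
    seed = config$cohort$seed,
    parameters = list(K = config$K, alpha = config$alpha,
                      min_count = config$min_count, trim = config$trim,
                      q = config$q, min_n = config$min_n,
                      epoch_boundaries = boundaries,
                      contexts = config$contexts),
    files = list(sessions = basename(session_files),
                 epoch_trees = basename(tree_files),
                 mode_trees = basename(mode_files),
                 report = basename(report_file),
                 participant_means = basename(means_file)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cohort = cohort, epoch_trees = epoch_trees,
                 mode_trees = mode_trees, analysis = analysis,
                 manifest = manifest))
}
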