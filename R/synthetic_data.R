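#' Bundle one participant's session
#'
#' @param kicks Integer sequence of penalty-taker directions `X_1..X_N`.
#' @param predictions Integer sequence of goalkeeper predictions `Y_1..Y_N`.
#' @param response_times Positive numeric response times `T_1..T_N` in
#'   seconds.
#' @param participant_id Label for the participant.
#' @param alphabet Admissible symbols, default `0:2`.
#' @return An object of class `session_data`.
#' @export
session_data <- function(kicks, predictions, response_times,
                         participant_id = "P01", alphabet = 0:2) {
  kicks <- as.integer(kicks)
  predictions <- as.integer(predictions)
  response_times <- as.numeric(response_times)
  n <- length(kicks)
  if (length(predictions) != n || length(response_times) != n) {
    stop("kicks, predictions and response_times must have the same length")
  }
  if (!all(kicks %in% alphabet)) stop("kicks contain out-of-alphabet symbols")
  if (!all(predictions %in% alphabet)) {
    stop("predictions contain out-of-alphabet symbols")
  }
  if (any(!is.finite(response_times)) || any(response_times <= 0)) {
    stop("response times must be finite and strictly positive")
  }
  structure(list(kicks = kicks, predictions = predictions,
                 response_times = response_times,
                 participant_id = as.character(participant_id),
                 alphabet = sort(unique(as.integer(alphabet)))),
            class = "session_data")
}

#' @export
print.session_data <- function(x, ...) {
  cat("Session ", x$participant_id, ": ", length(x$kicks), " trials, ",
      sum(x$kicks == x$predictions), " correct predictions, median rt ",
      signif(stats::median(x$response_times), 4), " s\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.session_data <- function(x, ...) {
  data.frame(trial = seq_along(x$kicks), kick = x$kicks,
             prediction = x$predictions, rt_seconds = x$response_times)
}

#' Goalkeeper behaviour model
#'
#' The original experiment records the goalkeeper's predictions but does not
#' model how they are produced. For simulation we use a deliberately simple
#' stand-in: at each trial the prediction equals the upcoming kick with a
#' per-context accuracy, and is otherwise uniform over the remaining
#' symbols. The defaults reflect a participant who has learned the
#' deterministic transitions well while performing near the base rate on the
#' stochastic context 0.
#'
#' @param accuracy Named numeric vector in `[0, 1]`: probability that the
#'   prediction equals the realised next symbol, per generating context.
#' @return An object of class `behavior_model`.
#' @export
behavior_model <- function(accuracy = c("0" = 0.6, "2" = 0.95, "01" = 0.95,
                                        "11" = 0.9, "21" = 0.95)) {
  accuracy <- unlist(accuracy)
  if (is.null(names(accuracy)) || any(!nzchar(names(accuracy)))) {
    stop("accuracy must be named by context label")
  }
  if (any(accuracy < 0 | accuracy > 1)) stop("accuracies must lie in [0, 1]")
  structure(list(accuracy = accuracy), class = "behavior_model")
}

#' Response-time model
#'
#' Response times are generated log-normally: for trial `n + 1`,
#' `T = exp(mu_w + delta_w * fail + sigma * eps)` where `w` is the context
#' ending at step `n`, `mu_w` its log-median location, `sigma` the common
#' log-scale standard deviation, and `delta_w` an additive log-scale shift
#' applied when the goalkeeper's prediction at the most recent context-0
#' transition failed. The default locations are separated between sibling
#' contexts by at least three `log_sd`, and the default failure shifts
#' slow responses in the highly predictable contexts 2 and 21 while
#' speeding them in the rarely predicted context 01.
#'
#' @param log_median Named numeric vector: log-seconds location per context.
#' @param log_sd Positive log-scale standard deviation.
#' @param failure_shift Named numeric vector: additive log-scale effect per
#'   context, applied after a failed prediction at the last context-0
#'   transition. Contexts absent from the vector get shift 0.
#' @param baseline Log-seconds location used for trials whose past is too
#'   short to match any context (default: mean of `log_median`).
#' @param seed Optional integer seed used by [generate_response_times()].
#' @return An object of class `rt_model`.
#' @export
rt_model <- function(log_median = c("0" = -0.7, "2" = -0.2, "01" = 0.1,
                                    "11" = 0.5, "21" = -1.0),
                     log_sd = 0.125,
                     failure_shift = c("2" = 0.3, "21" = 0.15, "01" = -0.2),
                     baseline = mean(log_median),
                     seed = NULL) {
  log_median <- unlist(log_median)
  if (is.null(names(log_median)) || any(!nzchar(names(log_median)))) {
    stop("log_median must be named by context label")
  }
  if (!is.numeric(log_sd) || length(log_sd) != 1L || log_sd <= 0) {
    stop("log_sd must be a single positive number")
  }
  failure_shift <- unlist(failure_shift)
  if (length(failure_shift) &&
      (is.null(names(failure_shift)) || any(!nzchar(names(failure_shift))))) {
    stop("failure_shift must be named by context label")
  }
  if (any(!is.finite(failure_shift))) stop("failure shifts must be finite")
  structure(list(log_median = log_median, log_sd = log_sd,
                 failure_shift = failure_shift, baseline = baseline,
                 seed = seed),
            class = "rt_model")
}

#' Cohort simulation configuration
#'
#' Defaults mirror the experimental protocol: 22 participants, 1000 penalty
#' trials per session, rest intervals after trials 334 and 668.
#'
#' @param n_participants Number of sessions to simulate (default 22).
#' @param n_trials Trials per session (default 1000).
#' @param epoch_boundaries Last trials of the non-final epochs
#'   (default `c(334, 668)`).
#' @param tree Generating [probabilistic_context_tree()]
#'   (default [penalty_taker_tree()]).
#' @param behavior A [behavior_model()].
#' @param rt An [rt_model()].
#' @param seed Master integer seed; per-participant stream seeds are derived
#'   from it deterministically.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 22, n_trials = 1000,
                          epoch_boundaries = c(334, 668),
                          tree = penalty_taker_tree(),
                          behavior = behavior_model(),
                          rt = rt_model(),
                          seed = 1L) {
  problems <- character(0)
  if (!is.numeric(n_participants) || n_participants < 0 ||
      n_participants != floor(n_participants)) {
    problems <- c(problems, "n_participants must be a non-negative integer")
  }
  max_len <- if (length(tree$contexts)) max(nchar(tree$contexts)) else 0L
  if (!is.numeric(n_trials) || n_trials < max_len + 1L) {
    problems <- c(problems,
                  sprintf("n_trials must be at least %d", max_len + 1L))
  }
  if (length(epoch_boundaries)) {
    if (is.unsorted(epoch_boundaries, strictly = TRUE) ||
        any(epoch_boundaries < 1) || any(epoch_boundaries >= n_trials)) {
      problems <- c(problems,
                    "epoch_boundaries must be strictly increasing and < n_trials")
    }
  }
  if (!inherits(tree, "probabilistic_context_tree")) {
    problems <- c(problems, "tree must be a probabilistic_context_tree")
  }
  if (!inherits(behavior, "behavior_model")) {
    problems <- c(problems, "behavior must be a behavior_model")
  }
  if (!inherits(rt, "rt_model")) problems <- c(problems, "rt must be an rt_model")
  if (length(problems)) {
    stop("invalid cohort configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  structure(list(n_participants = as.integer(n_participants),
                 n_trials = as.integer(n_trials),
                 epoch_boundaries = as.integer(epoch_boundaries),
                 tree = tree, behavior = behavior, rt = rt,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a kick sequence from a probabilistic context tree
#'
#' The chain is started from the fixed admissible past `init` (default
#' `c(0, 2, 1)`, one full triplet of the goalkeeper-game chain) so that every
#' step has a defined context; `init` is not part of the returned sequence.
#'
#' @param model A [probabilistic_context_tree()].
#' @param n Number of symbols to generate.
#' @param seed Optional integer seed (same model + same seed gives the
#'   identical sequence).
#' @param init Initial past, oldest first.
#' @return Integer vector of length `n`.
#' @examples
#' x <- generate_kicks(penalty_taker_tree(), 30, seed = 1)
#' @export
generate_kicks <- function(model, n, seed = NULL, init = c(0L, 2L, 1L)) {
  stopifnot(inherits(model, "probabilistic_context_tree"), n >= 1)
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed),
                            generate_kicks(model, n, NULL, init)))
  }
  contexts <- lapply(model$contexts, as_context)
  max_len <- max(c(0L, lengths(contexts)))
  cum_rows <- apply(model$transition, 1L, cumsum)  # one column per context
  alphabet <- model$alphabet
  past <- as.integer(init)
  out <- integer(n)
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    lab <- NULL
    np <- length(past)
    for (k in seq_along(contexts)) {
      w <- contexts[[k]]
      lw <- length(w)
      if (lw > np) next
      if (lw == 0L || identical(past[(np - lw + 1L):np], w)) {
        if (is.null(lab) || lw > nchar(lab)) lab <- model$contexts[k]
      }
    }
    if (is.null(lab)) {
      stop("no context of the model matches the realised past at step ", i,
           "; the model is incomplete for this chain")
    }
    sym <- alphabet[findInterval(u[i], cum_rows[, lab],
                                 left.open = TRUE) + 1L]
    out[i] <- sym
    past <- c(past, sym)
    if (length(past) > max_len) past <- past[(length(past) - max_len + 1L):length(past)]
  }
  out
}

#' Simulate goalkeeper predictions for a kick sequence
#'
#' The prediction at trial `n` equals `X_n` with the accuracy attached to
#' the context ending at trial `n - 1`; on an error the prediction is
#' uniform over the remaining symbols. The first trial — and any trial whose
#' past matches no context of the generating tree — is predicted uniformly
#' at random.
#'
#' @param kicks Integer kick sequence.
#' @param behavior A [behavior_model()].
#' @param tree The generating `context_tree` used to read off contexts.
#' @param seed Optional integer seed.
#' @return Integer vector of predictions, same length as `kicks`.
#' @export
generate_predictions <- function(kicks, behavior, tree = penalty_taker_tree(),
                                 seed = NULL) {
  stopifnot(length(kicks) >= 1, inherits(behavior, "behavior_model"),
            inherits(tree, "context_tree"))
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed),
                            generate_predictions(kicks, behavior, tree, NULL)))
  }
  n <- length(kicks)
  alphabet <- tree$alphabet
  ctx <- context_at_each_position(kicks, tree)
  # context governing trial i is the one ending at trial i - 1
  gov <- c(NA_character_, ctx[-n])
  acc <- rep(NA_real_, n)
  known <- !is.na(gov)
  if (any(known)) {
    missing <- setdiff(unique(gov[known]), names(behavior$accuracy))
    if (length(missing)) {
      stop("behavior model lacks an accuracy for context(s): ",
           paste(sQuote(missing), collapse = ", "))
    }
    acc[known] <- behavior$accuracy[gov[known]]
  }
  preds <- integer(n)
  correct <- stats::runif(n) < acc
  err_pick <- stats::runif(n)
  unif_pick <- sample(alphabet, n, replace = TRUE)
  for (i in seq_len(n)) {
    if (is.na(acc[i])) {
      preds[i] <- unif_pick[i]
    } else if (correct[i]) {
      preds[i] <- kicks[i]
    } else {
      others <- alphabet[alphabet != kicks[i]]
      preds[i] <- others[ceiling(err_pick[i] * length(others))]
    }
  }
  preds
}

# index of the most recent strictly-prior context-0 transition for each
# trial t: m*(t) = max{m <= t - 2 : X_m = 0}, NA when none exists.
last_zero_before <- function(kicks) {
  n <- length(kicks)
  idx <- seq_len(n)
  zero_at <- ifelse(kicks == 0L, idx, NA_integer_)
  run_max <- cummax(ifelse(is.na(zero_at), 0L, zero_at))
  m_star <- c(NA_integer_, NA_integer_, run_max[seq_len(max(0L, n - 2L))])
  m_star[!is.na(m_star) & m_star == 0L] <- NA_integer_
  m_star[seq_len(n)]
}

#' Simulate response times for a session
#'
#' Implements the log-normal model of [rt_model()]: the location depends on
#' the context ending at the previous trial, and the failure shift is added
#' when the goalkeeper's prediction at the most recent context-0 transition
#' (strictly before the previous trial's end) was wrong. Trials whose past
#' matches no context receive the baseline location; their indices are
#' attached as attribute `"baseline_trials"`.
#'
#' @param kicks,predictions Aligned integer sequences.
#' @param model An [rt_model()].
#' @param seed Optional integer seed (defaults to `model$seed`).
#' @return Positive numeric vector of response times in seconds.
#' @export
generate_response_times <- function(kicks, predictions, model = rt_model(),
                                    seed = model$seed) {
  stopifnot(inherits(model, "rt_model"),
            length(kicks) == length(predictions))
  if (!is.null(seed)) {
    model2 <- model
    model2$seed <- NULL
    return(withr::with_seed(as.integer(seed),
                            generate_response_times(kicks, predictions, model2)))
  }
  n <- length(kicks)
  ctx_tree <- context_tree(names(model$log_median),
                           alphabet = sort(unique(c(0:2, kicks))))
  ctx <- context_at_each_position(kicks, ctx_tree)
  gov <- c(NA_character_, ctx[-n])          # context governing trial t
  loc <- ifelse(is.na(gov), model$baseline, model$log_median[gov])
  shift <- rep(0, n)
  if (length(model$failure_shift)) {
    m_star <- last_zero_before(kicks)
    failed <- !is.na(m_star) &
      (predictions[pmax(m_star + 1L, 1L)] != kicks[pmax(m_star + 1L, 1L)])
    has_shift <- !is.na(gov) & gov %in% names(model$failure_shift)
    shift[has_shift & failed] <- model$failure_shift[gov[has_shift & failed]]
  }
  out <- exp(loc + shift + model$log_sd * stats::rnorm(n))
  attr(out, "baseline_trials") <- which(is.na(gov))
  out
}

#' Simulate one complete session
#'
#' @param config A [cohort_config()].
#' @param participant_id Label for the session.
#' @param seed Integer seed for this session's three streams.
#' @return A [session_data()] object.
#' @export
generate_session <- function(config, participant_id = "P01",
                             seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  streams <- withr::with_seed(as.integer(seed),
                              sample.int(2147483646L, 3L))
  kicks <- generate_kicks(config$tree, config$n_trials, seed = streams[1])
  preds <- generate_predictions(kicks, config$behavior, config$tree,
                                seed = streams[2])
  rts <- generate_response_times(kicks, preds, config$rt, seed = streams[3])
  session_data(kicks, preds, as.numeric(rts), participant_id,
               alphabet = config$tree$alphabet)
}

#' Simulate a cohort of sessions
#'
#' Per-participant seeds are drawn deterministically from the master seed,
#' so the whole cohort is a pure function of its configuration.
#'
#' @param config A [cohort_config()].
#' @return A list of [session_data()] objects (length
#'   `config$n_participants`; empty list when 0).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 2, n_trials = 100))
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  if (n == 0L) return(list())
  seeds <- withr::with_seed(config$seed, sample.int(2147483646L, n))
  ids <- sprintf("P%02d", seq_len(n))
  lapply(seq_len(n), function(i) {
    generate_session(config, participant_id = ids[i], seed = seeds[i])
  })
}
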