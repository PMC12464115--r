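#' Task conditions of the intertemporal go/no-go task
#'
#' The task orthogonalizes the required instrumental action (go/no-go) against
#' the timing of the reward available for a correct response (immediate/
#' delayed), giving four cue conditions.
#'
#' @format A character vector of the four condition labels.
#' @export
gng_conditions <- c("go-immediate", "go-delayed", "nogo-immediate", "nogo-delayed")

cond_action <- function(condition) ifelse(grepl("^go-", condition), "go", "nogo")
cond_timing <- function(condition) ifelse(grepl("-immediate$", condition), "immediate", "delayed")

#' Generate a pseudorandom go/no-go task schedule
#'
#' Builds an ordered trial list in which each of the four conditions occurs
#' exactly `n_per_condition` times, no condition repeats more than `max_run`
#' times in a row, and each trial independently receives valid (outcome
#' congruent with response correctness) or invalid feedback with probability
#' `feedback_validity`. Sequences are drawn by rejection sampling (uniform
#' shuffles of the condition multiset, rejecting run-limit violations), which
#' is exactly uniform over admissible sequences. Trials are split into four
#' contiguous blocks.
#'
#' @param n_per_condition Number of occurrences of each condition (default 50,
#'   giving the standard 200-trial session).
#' @param max_run Maximum number of consecutive presentations of the same
#'   condition (default 2).
#' @param feedback_validity Probability that a trial's feedback is congruent
#'   with response correctness (default 0.8).
#' @param seed Integer seed; identical inputs and seed reproduce the schedule.
#' @return A `gng_schedule`: a data frame with columns `index`, `block`,
#'   `condition`, `required_action`, `reward_timing`, `feedback_valid`, with
#'   attributes `n_per_condition`, `max_run`, `feedback_validity`, `seed`.
#' @export
#' @examples
#' sched <- generate_schedule(5, 2, 0.8, seed = 1)
#' table(sched$condition)
generate_schedule <- function(n_per_condition = 50, max_run = 2,
                              feedback_validity = 0.8, seed = 1L) {
  if (n_per_condition < 1 || max_run < 1)
    stop("invalid configuration: n_per_condition and max_run must be >= 1")
  if (feedback_validity < 0 || feedback_validity > 1)
    stop("invalid configuration: feedback_validity must be in [0, 1]")
  n_total <- 4L * n_per_condition
  if (n_total %% 4L != 0L) stop("invalid configuration: trials not divisible into 4 blocks")
  # feasibility: a run limit of 1 with equal counts is still schedulable for 4 labels
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  # exact-uniform rejection sampling at study-scale sessions; for long
  # sequences (where whole-shuffle acceptance vanishes) fall back to
  # sequential count-weighted pseudorandomization with restart
  labels <- if (n_total <= 400L)
    cpp_generate_sequence(rep(n_per_condition, 4L), as.integer(max_run), 1000000L)
  else
    cpp_generate_sequence_seq(rep(n_per_condition, 4L), as.integer(max_run), 1000L)
  condition <- gng_conditions[labels]
  feedback_valid <- runif(n_total) < feedback_validity
  per_block <- n_total %/% 4L
  out <- data.frame(
    index = seq_len(n_total),
    block = rep(seq_len(4L), each = per_block),
    condition = condition,
    required_action = cond_action(condition),
    reward_timing = cond_timing(condition),
    feedback_valid = feedback_valid,
    stringsAsFactors = FALSE
  )
  attr(out, "n_per_condition") <- n_per_condition
  attr(out, "max_run") <- max_run
  attr(out, "feedback_validity") <- feedback_validity
  attr(out, "seed") <- seed
  class(out) <- c("gng_schedule", "data.frame")
  out
}

# save/restore .Random.seed so schedule generation is self-seeding without
# clobbering the caller's RNG stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(x) {
  if (is.null(x)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", x, envir = globalenv())
}

#' Resolve probabilistic feedback
#'
#' With valid feedback the presented outcome matches response correctness
#' (correct yields reward, incorrect yields no reward); with invalid feedback
#' the outcome is reversed.
#'
#' @param response_correct Logical (vectorized): was the response correct?
#' @param feedback_valid Logical (vectorized): is this a congruent-feedback trial?
#' @return Character vector, `"reward"` or `"no-reward"`.
#' @export
resolve_feedback <- function(response_correct, feedback_valid) {
  rewarded <- ifelse(feedback_valid, response_correct, !response_correct)
  ifelse(rewarded, "reward", "no-reward")
}

#' Validate a task schedule
#'
#' Checks the condition-count and run-length invariants and returns every
#' violation found (an empty list for a compliant schedule).
#'
#' @param schedule A `gng_schedule` (or data frame with a `condition` column).
#' @param n_per_condition,max_run Constraints to check against; defaults taken
#'   from the schedule's attributes.
#' @return A list of violation records, each with `type` (`"count"` or
#'   `"run"`), a message, and the trial indices involved.
#' @export
validate_schedule <- function(schedule,
                              n_per_condition = attr(schedule, "n_per_condition"),
                              max_run = attr(schedule, "max_run")) {
  violations <- list()
  counts <- table(factor(schedule$condition, levels = gng_conditions))
  for (cnd in gng_conditions) {
    if (counts[[cnd]] != n_per_condition) {
      violations[[length(violations) + 1L]] <- list(
        type = "count", condition = cnd,
        message = sprintf("condition %s occurs %d times, expected %d",
                          cnd, counts[[cnd]], n_per_condition),
        indices = which(schedule$condition == cnd))
    }
  }
  r <- rle(schedule$condition)
  bad <- which(r$lengths > max_run)
  ends <- cumsum(r$lengths)
  for (i in bad) {
    idx <- (ends[i] - r$lengths[i] + 1L):ends[i]
    violations[[length(violations) + 1L]] <- list(
      type = "run", condition = r$values[i],
      message = sprintf("condition %s repeated %d times at trials %d-%d (max %d)",
                        r$values[i], r$lengths[i], min(idx), max(idx), max_run),
      indices = idx)
  }
  violations
}

#' @export
print.gng_schedule <- function(x, ...) {
  cat(sprintf("Go/no-go task schedule: %d trials (%d per condition), max run %d, feedback validity %.2f\n",
              nrow(x), attr(x, "n_per_condition"), attr(x, "max_run"),
              attr(x, "feedback_validity")))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Read or write a schedule as CSV
#'
#' @param schedule A `gng_schedule`.
#' @param path File path.
#' @return `read_schedule` returns a `gng_schedule`; `write_schedule` returns
#'   `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  out$feedback_valid <- as.logical(out$feedback_valid)
  attr(out, "n_per_condition") <- nrow(out) %/% 4L
  attr(out, "max_run") <- NA_integer_
  attr(out, "feedback_validity") <- NA_real_
  class(out) <- c("gng_schedule", "data.frame")
  out
}
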