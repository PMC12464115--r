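#' The 27-item monetary choice questionnaire item bank
#'
#' Standard instrument offering 27 choices between a smaller immediate and a
#' larger delayed monetary reward. Each item implies an indifference discount
#' rate `k_indiff = (delayed/immediate - 1) / delay_days` under hyperbolic
#' discounting; the 27 items tile 9 discount-rate levels across 3 reward
#' magnitudes.
#'
#' @return Data frame with columns `item`, `immediate`, `delayed`,
#'   `delay_days`, `k_indiff`.
#' @export
mcq_item_bank <- function() {
  path <- system.file("extdata", "mcq_items.csv", package = "pavbias")
  items <- read.csv(path)
  items$k_indiff <- (items$delayed / items$immediate - 1) / items$delay_days
  items
}

#' Candidate discount-rate grid for MCQ consistency scoring
#'
#' The 9 distinct item indifference rates partition the positive axis into 10
#' consistency regions; the grid places one candidate per region: geometric
#' means of adjacent rate levels in the interior, geometrically extended
#' endpoints outside.
#'
#' @param item_bank An MCQ item bank (see [mcq_item_bank()]).
#' @return Numeric vector of 10 candidate k values (1/day), increasing.
#' @export
mcq_k_grid <- function(item_bank = mcq_item_bank()) {
  lk <- sort(log(item_bank$k_indiff))
  # items tile 9 rate levels; within-level spread is tiny next to the
  # between-level gaps, so split where consecutive log-rates jump
  grp <- cumsum(c(1, diff(lk) > 0.3))
  l <- as.numeric(tapply(lk, grp, mean))
  mid <- (l[-1] + l[-length(l)]) / 2
  exp(c(l[1] - (l[2] - l[1]) / 2, mid, l[length(l)] + diff(utils::tail(l, 2)) / 2))
}

#' Score MCQ choices into a hyperbolic discount rate
#'
#' Assigns the candidate discount rate maximizing consistency with the
#' observed choices, where a candidate `k` predicts an immediate choice on
#' items whose indifference rate lies below `k`. Ties are broken by the
#' geometric mean of the tied candidates.
#'
#' @param choices Character or logical vector of 27 choices: `"immediate"` /
#'   `"delayed"` (or `TRUE` for immediate).
#' @param item_bank MCQ item bank aligned with `choices`.
#' @return List with `k` (the estimate), `consistency` (proportion of choices
#'   matched), and `candidates` (the scored grid).
#' @export
score_mcq <- function(choices, item_bank = mcq_item_bank()) {
  if (is.logical(choices)) choices <- ifelse(choices, "immediate", "delayed")
  if (length(choices) != nrow(item_bank))
    stop("invalid input: choices and item_bank lengths differ")
  if (!all(choices %in% c("immediate", "delayed")))
    stop("invalid input: choices must be 'immediate' or 'delayed'")
  grid <- mcq_k_grid(item_bank)
  obs_imm <- choices == "immediate"
  consistency <- vapply(grid, function(k) mean((k > item_bank$k_indiff) == obs_imm),
                        numeric(1))
  best <- which(consistency == max(consistency))
  k <- exp(mean(log(grid[best])))
  list(k = k, consistency = max(consistency),
       candidates = data.frame(k = grid, consistency = consistency))
}

#' Starting amount for the adaptive choice titrator
#'
#' The hyperbolic present value of the delayed reward at discount rate `k`,
#' rounded to the nearest even integer number of euros (ties round down) and
#' clipped to the offer range.
#'
#' @param k Hyperbolic discount rate (1/day), non-negative.
#' @param delayed_amount Delayed reward in euros (default 28).
#' @param delay Delay in days (default 120).
#' @return Even integer amount in `[0, delayed_amount]`.
#' @export
#' @examples
#' starting_amount(0)    # 28: no discounting
#' starting_amount(0.1)  # 28/13 ~ 2.15 -> 2
starting_amount <- function(k, delayed_amount = 28, delay = 120) {
  if (any(k < 0)) stop("invalid input: k must be non-negative")
  pv <- delayed_amount / (1 + k * delay)
  even <- 2 * floor(pv / 2 + 0.5)          # nearest even; exact ties round down
  tie <- abs(pv / 2 - floor(pv / 2) - 0.5) < 1e-12
  even[tie] <- 2 * floor(pv[tie] / 2)
  pmin(pmax(even, 0), delayed_amount)
}

#' Run the adaptive choice-titration staircase
#'
#' Offers a choice between an immediate amount and a fixed delayed reward.
#' After an immediate choice the next offer decreases by `step`; after a
#' delayed choice it increases by `step`; offers are clipped to `[0, 28]`.
#' The staircase stops once the last `stability_window` offers span at most
#' `stability_span` euros (the matched amount is the rounded mean of that
#' window), or unconverged at `max_trials`. A participant choosing the EUR 0
#' immediate offer is asked to confirm on one identical trial; a repeated
#' EUR 0 preference marks the result as excluded (`"prefers-zero"`).
#'
#' @param choose Function of the immediate offer returning `"immediate"` or
#'   `"delayed"` (see [make_discount_agent()]).
#' @param start Even integer starting offer in `[0, 28]`.
#' @param step Offer increment/decrement in euros (default 2).
#' @param stability_window Number of trailing trials for the stability rule
#'   (default 6).
#' @param stability_span Maximum span of offers within a stable window
#'   (default 2).
#' @param max_trials Trial cap before a no-stability exclusion (default 50).
#' @return A `titration_result` list: `matched_amount`, `n_trials`,
#'   `converged`, `excluded_reason` (`"none"`, `"no-stability"`,
#'   `"prefers-zero"`), `trajectory` (data frame of trial, offer, choice).
#' @export
run_titration <- function(choose, start, step = 2, stability_window = 6,
                          stability_span = 2, max_trials = 50) {
  stopifnot(start >= 0, start <= 28, start %% 2 == 0)
  offers <- numeric(0)
  choices <- character(0)
  offer <- start
  zero_confirm <- FALSE
  matched <- NA_real_
  converged <- FALSE
  reason <- "no-stability"
  for (t in seq_len(max_trials)) {
    ch <- match.arg(choose(offer), c("immediate", "delayed"))
    offers[t] <- offer
    choices[t] <- ch
    if (offer == 0 && ch == "immediate") {
      if (zero_confirm) { reason <- "prefers-zero"; break }
      zero_confirm <- TRUE       # one confirmation trial at the same offer
      next
    }
    if (offer == 0 && ch == "delayed") zero_confirm <- FALSE
    if (t >= stability_window) {
      win <- offers[(t - stability_window + 1):t]
      if (max(win) - min(win) <= stability_span) {
        matched <- round(mean(win))
        converged <- TRUE
        reason <- "none"
        break
      }
    }
    offer <- min(max(offer + ifelse(ch == "immediate", -step, step), 0), 28)
  }
  structure(list(matched_amount = matched, n_trials = length(offers),
                 converged = converged, excluded_reason = reason,
                 trajectory = data.frame(trial = seq_along(offers),
                                         offer = offers, choice = choices)),
            class = "titration_result")
}

#' @export
print.titration_result <- function(x, ...) {
  cat(sprintf("Choice titration: %d trials, %s\n", x$n_trials,
              if (x$converged) sprintf("converged at EUR %d", x$matched_amount)
              else sprintf("not converged (%s)", x$excluded_reason)))
  invisible(x)
}

#' Impatience score from the matched immediate amount
#'
#' Reverse-codes the preference-matched immediate amount so that higher
#' scores indicate more impatience (range 1-28).
#'
#' @param matched_amount Matched immediate amount in euros, in `[1, 28]`.
#' @return Integer impatience score `29 - matched_amount`.
#' @export
impatience_score <- function(matched_amount) {
  if (any(matched_amount < 1 | matched_amount > 28, na.rm = TRUE))
    stop("invalid input: matched_amount must lie in [1, 28]")
  29 - matched_amount
}

#' Construct a hyperbolic discounting agent
#'
#' Returns a choice function over immediate offers against a fixed delayed
#' reward, discounted hyperbolically at rate `k`. With `temperature = 0` the
#' agent is deterministic (immediate iff the offer exceeds the present
#' value); otherwise choices are logistic in the offer-minus-present-value
#' difference.
#'
#' @param k Hyperbolic discount rate (1/day), non-negative.
#' @param temperature Logistic choice noise in euros (0 = deterministic).
#' @param delayed_amount,delay The fixed delayed reward (EUR 28 in 120 days).
#' @return Function `offer -> "immediate"/"delayed"`. The present value is
#'   exposed as attribute `"indifference"`.
#' @export
make_discount_agent <- function(k, temperature = 0, delayed_amount = 28,
                                delay = 120) {
  stopifnot(k >= 0, temperature >= 0)
  pv <- delayed_amount / (1 + k * delay)
  f <- function(offer) {
    if (temperature == 0) {
      if (offer > pv) "immediate" else "delayed"
    } else {
      if (runif(1) < plogis((offer - pv) / temperature)) "immediate" else "delayed"
    }
  }
  attr(f, "indifference") <- pv
  f
}

#' Simulate MCQ choices from a hyperbolic discounting agent
#'
#' @param k True discount rate (1/day).
#' @param temperature Logistic choice noise on the present-value difference in
#'   euros (0 = deterministic).
#' @param item_bank MCQ item bank.
#' @return Character vector of choices aligned with the item bank.
#' @export
simulate_mcq_choices <- function(k, temperature = 0, item_bank = mcq_item_bank()) {
  pv <- item_bank$delayed / (1 + k * item_bank$delay_days)
  diff <- item_bank$immediate - pv
  imm <- if (temperature == 0) diff > 0 else runif(nrow(item_bank)) < plogis(diff / temperature)
  ifelse(imm, "immediate", "delayed")
}
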