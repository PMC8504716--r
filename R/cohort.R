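# Individual-level synthetic cohorts with latent responder structure.
#
# Each participant carries a latent category with deterministic potential
# outcomes under control and under treatment; randomization reveals one of
# the two. This is the minimal generative model under which the
# responder decomposition is exactly identified, and it makes the
# exchangeability assumption literal: within a category, everyone is
# identical.

#' Configuration for the synthetic cohort generator
#'
#' @param N Number of participants.
#' @param p_responder Probability that a participant is a responder (event
#'   if untreated, no event if treated).
#' @param p_nonresponder Probability of a non-responder (event either way).
#'   The remainder `1 - p_responder - p_nonresponder` are non-informative
#'   (no event either way).
#' @param alloc_T_share Probability of assignment to the experimental arm;
#'   default 2/3 mirrors the seed trial's 2:1 allocation.
#' @param seed RNG seed (required: cohorts are reproducible by contract).
#' @param n_reps Replicates for recovery experiments; replicate `i` uses
#'   sub-seed `seed + i`, so `seed + n_reps` must stay below 2^31.
#' @param allocation `"bernoulli"` assigns arms independently per
#'   participant; `"exact"` fixes the experimental arm at
#'   `round(N * alloc_T_share)` and permutes assignments (useful for
#'   matching a published trial's margins).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(N, p_responder, p_nonresponder,
                          alloc_T_share = 2 / 3, seed,
                          n_reps = 200,
                          allocation = c("bernoulli", "exact")) {
  allocation <- match.arg(allocation)
  if (missing(seed)) {
    stop("a seed is required: synthetic cohorts must be reproducible",
         call. = FALSE)
  }
  stopifnot(N > 0, p_responder >= 0, p_nonresponder >= 0,
            alloc_T_share > 0, alloc_T_share < 1, n_reps >= 1)
  if (p_responder + p_nonresponder > 1) {
    stop("p_responder + p_nonresponder = ", p_responder + p_nonresponder,
         " exceeds 1", call. = FALSE)
  }
  if (seed + n_reps >= 2^31) {
    stop("seed too large: seed + n_reps must be below 2^31", call. = FALSE)
  }
  structure(list(N = as.integer(N), p_responder = p_responder,
                 p_nonresponder = p_nonresponder,
                 alloc_T_share = alloc_T_share,
                 seed = as.integer(seed), n_reps = as.integer(n_reps),
                 allocation = allocation),
            class = "cohort_config")
}

#' Generate a synthetic trial cohort
#'
#' Draws each participant's latent category independently from
#' `(p_responder, p_nonresponder, 1 - both)`, assigns arms, fills in the
#' deterministic potential outcomes per category, and realizes the outcome
#' of the assigned arm.
#'
#' @param config A [cohort_config].
#' @param seed Override the config seed (used internally for replicates).
#' @return An object of class `cohort`: list with `participants` (data
#'   frame with columns `id, category, arm, outcome_under_C,
#'   outcome_under_T, realized_outcome`) and `config`.
#' @examples
#' cfg <- cohort_config(N = 1000, p_responder = 0.05, p_nonresponder = 0.05,
#'                      seed = 1)
#' coh <- generate_cohort(cfg)
#' tabulate_cohort(coh)
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  N <- config$N
  category <- sample(c("responder", "nonresponder", "noninformative"),
                     size = N, replace = TRUE,
                     prob = c(config$p_responder, config$p_nonresponder,
                              1 - config$p_responder - config$p_nonresponder))
  arm <- if (config$allocation == "bernoulli") {
    ifelse(stats::runif(N) < config$alloc_T_share, "T", "C")
  } else {
    nT <- as.integer(round_half_away(N * config$alloc_T_share))
    sample(rep(c("T", "C"), c(nT, N - nT)))
  }
  outcome_under_C <- category %in% c("responder", "nonresponder")
  outcome_under_T <- category == "nonresponder"
  realized <- ifelse(arm == "T", outcome_under_T, outcome_under_C)
  participants <- data.frame(
    id = seq_len(N), category = category, arm = arm,
    outcome_under_C = outcome_under_C,
    outcome_under_T = outcome_under_T,
    realized_outcome = realized
  )
  structure(list(participants = participants, config = config),
            class = "cohort")
}

#' Tally a cohort into a 2x2 trial table
#'
#' @param cohort A [generate_cohort()] result, or its `participants` data
#'   frame.
#' @return A [trial_table] of realized outcomes.
#' @export
tabulate_cohort <- function(cohort) {
  p <- if (inherits(cohort, "cohort")) cohort$participants else cohort
  stopifnot(is.data.frame(p), nrow(p) > 0)
  if (!all(c("C", "T") %in% p$arm)) {
    stop("cannot tabulate: an arm is empty (event rates undefined)",
         call. = FALSE)
  }
  inC <- p$arm == "C"
  trial_table(a = sum(p$realized_outcome[inC]),
              b = sum(p$realized_outcome[!inC]),
              c = sum(!p$realized_outcome[inC]),
              d = sum(!p$realized_outcome[!inC]))
}

#' Ground-truth breakdown of a cohort from its latent labels
#'
#' The latent categories give the category counts directly, without going
#' through the observed table: used to validate [decompose_trial()] by
#' parameter recovery.
#'
#' @param cohort A [generate_cohort()] result.
#' @return A `participant_breakdown` built from latent labels.
#' @export
true_breakdown <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  p <- cohort$participants
  d1 <- sum(p$category == "responder" & p$arm == "T")
  prC <- sum(p$category == "responder" & p$arm == "C")
  nrT <- sum(p$category == "nonresponder" & p$arm == "T")
  nrC <- sum(p$category == "nonresponder" & p$arm == "C")
  ninf <- sum(p$category == "noninformative")
  N <- nrow(p)
  out <- list(
    responders_T = d1,
    potential_responders_C = prC,
    responders_total = d1 + prC,
    nonresponders_T = nrT,
    nonresponders_C = nrC,
    nonresponders_total = nrT + nrC,
    noninformative = ninf,
    unnecessary = ninf + nrT + nrC,
    ethical_losses = N - d1,
    d2 = sum(p$category == "noninformative" & p$arm == "T"),
    N = N
  )
  structure(lapply(out, as.integer), class = "participant_breakdown")
}

#' Parameter-recovery experiment for the responder decomposition
#'
#' Generates `n_reps` independent cohorts (sub-seeds `seed + 1 ... seed +
#' n_reps`), estimates on each the absolute benefit `a/Nc - b/NT` (whose
#' expectation equals `p_responder` under the latent model) and the
#' experimental-arm responder count via the decomposition, and compares
#' them with the latent truth.
#'
#' @param config A [cohort_config] with `n_reps >= 2`.
#' @return A list with, for each estimator (`ab`, `responders_T`): the
#'   per-replicate mean, the target, the bias, its Monte-Carlo standard
#'   error, and an `unbiased` verdict (|bias| <= 3 SE); plus `n_reps`,
#'   `n_clamped` (replicates where the responder estimate was clamped at
#'   0) and the config.
#' @examples
#' cfg <- cohort_config(N = 2000, p_responder = 0.05, p_nonresponder = 0.05,
#'                      seed = 7, n_reps = 50)
#' recovery_experiment(cfg)$ab$unbiased
#' @export
recovery_experiment <- function(config) {
  stopifnot(inherits(config, "cohort_config"), config$n_reps >= 2)
  n <- config$n_reps
  ab_err <- numeric(n)        # estimated AB - p_responder
  d1_est <- numeric(n)        # decomposition's responders-in-T
  d1_true <- numeric(n)       # latent responders assigned to T
  clamped <- logical(n)
  for (i in seq_len(n)) {
    coh <- generate_cohort(config, seed = config$seed + i)
    tab <- tabulate_cohort(coh)
    er <- suppressWarnings(event_rates(tab))
    ab_err[i] <- er$AB - config$p_responder
    est <- responders_in_T(tab, warn = FALSE)
    clamped[i] <- (expected_events_if_untreated(tab) - tab$b) < 0
    d1_est[i] <- est
    d1_true[i] <- sum(coh$participants$category == "responder" &
                        coh$participants$arm == "T")
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  latent_mean <- config$N * config$alloc_T_share * config$p_responder
  ab <- list(mean_error = mean(ab_err), se = se(ab_err),
             bias = mean(ab_err),
             unbiased = abs(mean(ab_err)) <= 3 * se(ab_err))
  d1_bias <- mean(d1_est - d1_true)
  d1 <- list(mean = mean(d1_est), latent_mean = latent_mean,
             bias = d1_bias, se = se(d1_est - d1_true),
             se_mean = se(d1_est),
             unbiased = abs(mean(d1_est) - latent_mean) <= 3 * se(d1_est))
  list(n_reps = n, ab = ab, responders_T = d1,
       n_clamped = sum(clamped), config = config)
}

#' Write a recovery report to JSON
#'
#' @param report A [recovery_experiment()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_recovery_json <- function(report, path) {
  report$config <- unclass(report$config)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a cohort to CSV
#'
#' @param cohort A [generate_cohort()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  p <- cohort$participants
  for (col in c("outcome_under_C", "outcome_under_T", "realized_outcome")) {
    p[[col]] <- as.integer(p[[col]])
  }
  utils::write.csv(p, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
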