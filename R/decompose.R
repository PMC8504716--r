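# Responder decomposition of a completed two-arm trial.
#
# Model: participants are exchangeable and fall into three latent categories
# with deterministic potential outcomes --
#   responder        event if untreated, no event if treated
#   non-responder    event either way
#   non-informative  no event either way
# Under superiority (Rc >= RT) the observed table identifies the category
# counts, up to rounding to whole participants.

#' Round half away from zero
#'
#' Counts of participants are rounded to the closest unit with halves going
#' away from zero (so 120.5 -> 121), unlike base [round()] which rounds
#' half to even. Applied at final counts only, never at intermediate rates.
#'
#' @param x Numeric vector.
#' @return `x` rounded to integers (as numeric).
#' @keywords internal
round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}

#' Event rates and efficacy metrics of a 2x2 trial
#'
#' @param table A [trial_table].
#' @return An object of class `event_rates`: list with
#'   `Rc` (control event rate a/Nc), `RT` (experimental event rate b/NT),
#'   `AB` (absolute benefit, Rc - RT) and `RR` (relative risk RT/Rc;
#'   `NA` with a warning when Rc = 0, where the ratio is undefined).
#' @examples
#' event_rates(empa_reg_table())
#' @export
event_rates <- function(table) {
  stopifnot(inherits(table, "trial_table"))
  Rc <- table$a / table$Nc
  RT <- table$b / table$NT
  RR <- if (Rc > 0) {
    RT / Rc
  } else {
    warning("relative risk undefined: control event rate is zero",
            call. = FALSE)
    NA_real_
  }
  structure(list(Rc = Rc, RT = RT, AB = Rc - RT, RR = RR),
            class = "event_rates")
}

#' @export
print.event_rates <- function(x, digits = 4, ...) {
  cat(sprintf("Rc = %.*f  RT = %.*f  AB = %.*f  RR = %s\n",
              digits, x$Rc, digits, x$RT, digits, x$AB,
              if (is.na(x$RR)) "undefined" else formatC(x$RR, digits = digits,
                                                       format = "f")))
  invisible(x)
}

#' Expected events in the experimental arm had it gone untreated
#'
#' Under exchangeability the experimental arm, left untreated, would have
#' presented events at the control rate: `a * NT / Nc`, rounded to the
#' closest participant. For the Empa-REG seed table this is
#' 194 * 4687 / 2333 = 390.
#'
#' @inheritParams event_rates
#' @return Integer count.
#' @export
expected_events_if_untreated <- function(table) {
  stopifnot(inherits(table, "trial_table"))
  # numeric promotion: a * NT overflows integer range on very large trials
  as.integer(round_half_away(as.numeric(table$a) * table$NT / table$Nc))
}

#' Number of responders in the experimental arm
#'
#' Responders in the experimental (T) arm are participants kept event-free
#' by the treatment: the expected untreated events minus the observed
#' events, `round(a * NT / Nc) - b`. This is the count route the worked
#' example prints (390 - 269 = 121); it agrees with the rate route
#' `round((Rc - RT) * NT)` up to where rounding is applied.
#'
#' The framework assumes the experimental treatment is at least as good as
#' control. If the observed events exceed the expected untreated events
#' (RT > Rc), the count is clamped at 0 with a warning.
#'
#' @inheritParams event_rates
#' @param warn Emit the clamping warning for apparently harmful treatments.
#' @return Integer count (>= 0).
#' @export
responders_in_T <- function(table, warn = TRUE) {
  d1 <- expected_events_if_untreated(table) - table$b
  if (d1 < 0L) {
    if (warn) {
      warning("observed events in the experimental arm exceed the expected ",
              "untreated events (RT > Rc): responder count clamped at 0",
              call. = FALSE)
    }
    d1 <- 0L
  }
  as.integer(d1)
}

#' Potential responders in the control arm
#'
#' Participants with a responder profile randomized to control; by
#' definition they present the event (they are among the `a`). Their count
#' scales the experimental-arm responders by the arm-size ratio:
#' `round(responders_in_T * Nc / NT)`.
#'
#' @inheritParams responders_in_T
#' @return Integer count (>= 0).
#' @export
potential_responders_in_C <- function(table, warn = TRUE) {
  d1 <- responders_in_T(table, warn = warn)
  as.integer(round_half_away(as.numeric(d1) * table$Nc / table$NT))
}

#' Decompose a trial into responder categories and ethical losses
#'
#' Splits the `Nc + NT` enrolled participants into responders (T-arm
#' responders plus control-arm potential responders), non-responders
#' (events in either arm not attributable to a responder profile),
#' non-informative participants (event-free in either arm, minus the T-arm
#' responders hidden among the `d`), and the derived totals:
#' unnecessary participants (non-responders + non-informative, i.e. all who
#' cannot benefit regarding the primary outcome) and ethical losses
#' (everyone except the T-arm responders, `(Nc + NT) - responders_T`).
#'
#' @inheritParams responders_in_T
#' @return An object of class `participant_breakdown`: list with fields
#'   `responders_T`, `potential_responders_C`, `responders_total`,
#'   `nonresponders_T`, `nonresponders_C`, `nonresponders_total`,
#'   `noninformative`, `unnecessary`, `ethical_losses`, `d2`
#'   (event-free T-arm participants who are not responders) and `N`.
#' @examples
#' decompose_trial(empa_reg_table())
#' @export
decompose_trial <- function(table, warn = TRUE) {
  stopifnot(inherits(table, "trial_table"))
  d1 <- responders_in_T(table, warn = warn)
  prC <- potential_responders_in_C(table, warn = FALSE)

  nonresponders_C <- table$a - prC
  if (nonresponders_C < 0L) {
    stop("structural inconsistency: control-arm non-responders negative (",
         nonresponders_C, "); potential responders (", prC,
         ") exceed the control-arm events (", table$a, ")", call. = FALSE)
  }
  noninformative <- table$c + table$d - d1
  if (noninformative < 0L) {
    stop("structural inconsistency: non-informative count negative (",
         noninformative, "); experimental-arm responders (", d1,
         ") exceed the event-free participants (", table$c + table$d, ")",
         call. = FALSE)
  }
  d2 <- table$d - d1
  if (d2 < 0L) {
    stop("structural inconsistency: d2 negative (", d2,
         "); experimental-arm responders (", d1,
         ") exceed the event-free T-arm participants (", table$d, ")",
         call. = FALSE)
  }

  N <- table$Nc + table$NT
  out <- list(
    responders_T = d1,
    potential_responders_C = prC,
    responders_total = d1 + prC,
    nonresponders_T = table$b,
    nonresponders_C = nonresponders_C,
    nonresponders_total = table$b + nonresponders_C,
    noninformative = noninformative,
    unnecessary = noninformative + table$b + nonresponders_C,
    ethical_losses = N - d1,
    d2 = d2,
    N = N
  )
  out <- lapply(out, as.integer)
  structure(out, class = "participant_breakdown")
}

#' Ethical losses as a share of enrolment
#'
#' @param breakdown A `participant_breakdown` from [decompose_trial()].
#' @param total Total enrolment; defaults to the breakdown's own `N`.
#' @return Proportion in `[0, 1]`.
#' @examples
#' b <- decompose_trial(empa_reg_table())
#' ethical_loss_fraction(b)   # 0.983 to 3 decimals
#' @export
ethical_loss_fraction <- function(breakdown, total = breakdown$N) {
  stopifnot(inherits(breakdown, "participant_breakdown"), total > 0)
  breakdown$ethical_losses / total
}

#' @export
print.participant_breakdown <- function(x, ...) {
  cat(breakdown_report(x), sep = "\n")
  invisible(x)
}

#' Format a participant breakdown as an aligned text report
#'
#' @param breakdown A `participant_breakdown`.
#' @return Character vector of report lines.
#' @export
breakdown_report <- function(breakdown) {
  b <- breakdown
  pct <- function(k) sprintf("%.1f%%", 100 * k / b$N)
  rows <- list(
    c("Responders",           b$responders_total,
      sprintf("%d (T) + %d (C)", b$responders_T, b$potential_responders_C)),
    c("Non-responders",       b$nonresponders_total,
      sprintf("%d (T) + %d (C)", b$nonresponders_T, b$nonresponders_C)),
    c("Non-informative",      b$noninformative, ""),
    c("Unnecessary (total)",  b$unnecessary,
      "non-responders + non-informative"),
    c("Ethical losses",       b$ethical_losses,
      sprintf("%s of enrolled", pct(b$ethical_losses)))
  )
  header <- sprintf("Participant breakdown (N = %d)", b$N)
  lines <- vapply(rows, function(r) {
    sprintf("  %-20s %7s   %s", r[1], r[2], r[3])
  }, character(1))
  c(header, lines)
}

#' Write a participant breakdown to JSON
#'
#' @param breakdown A `participant_breakdown`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_breakdown_json <- function(breakdown, path) {
  jsonlite::write_json(unclass(breakdown), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
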