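# Sweep over the proportion of responders.
#
# A family of trials is reconstructed on a grid of responder proportions p,
# holding fixed: the experimental-arm responder count, the allocation
# ratio, and the event probability of unnecessary participants while
# untreated. Responders and potential responders present their
# deterministic outcomes; unnecessary participants present the event at the
# fixed untreated rate in both arms (the treatment does nothing for them).

#' Configuration for the responder-proportion sweep
#'
#' Defaults reproduce the seed trial: 121 experimental-arm responders held
#' constant, arms split 4687:2333 (the 2:1 allocation of the seed trial),
#' and untreated event probability 194/2333 (the seed control death rate).
#' The control-arm potential responders are derived once from the fixed
#' experimental-arm count and the allocation ratio (60 for the defaults)
#' and held constant across grid points.
#'
#' @param responders_T_fixed Experimental-arm responders, constant across
#'   the sweep.
#' @param arm_ratio Share of the total sample allocated to the experimental
#'   arm (NT / N).
#' @param Rc_unnecessary Event probability of an unnecessary participant
#'   while untreated.
#' @param p_start,p_stop,p_step Grid of responder proportions; the default
#'   0.025 to 1 in steps of 0.025 gives 40 trials. p = 0 is excluded (the
#'   sample size diverges).
#' @return An object of class `sweep_config`.
#' @examples
#' cfg <- sweep_config()
#' cfg$potential_responders_C  # 60
#' @export
sweep_config <- function(responders_T_fixed = 121,
                         arm_ratio = 4687 / 7020,
                         Rc_unnecessary = 194 / 2333,
                         p_start = 0.025, p_stop = 1, p_step = 0.025) {
  stopifnot(responders_T_fixed > 0,
            arm_ratio > 0, arm_ratio < 1,
            Rc_unnecessary >= 0, Rc_unnecessary <= 1,
            p_step > 0, p_stop <= 1, p_step <= p_stop, p_start >= p_step)
  prC <- as.integer(round_half_away(
    responders_T_fixed * (1 - arm_ratio) / arm_ratio))
  structure(list(
    responders_T_fixed = as.integer(responders_T_fixed),
    potential_responders_C = prC,
    responders_total = as.integer(responders_T_fixed) + prC,
    arm_ratio = arm_ratio,
    Rc_unnecessary = Rc_unnecessary,
    p_start = p_start, p_stop = p_stop, p_step = p_step
  ), class = "sweep_config")
}

#' Reconstruct the trial at a given responder proportion
#'
#' Given a proportion `p` of responders among all enrolled participants,
#' the trial is rebuilt as: total `N = R / p` where `R` is the fixed
#' responder total; arms split by the allocation ratio; each arm holds its
#' fixed responder contingent, the remainder being unnecessary
#' participants who present the event at rate `Rc_unnecessary` in both
#' arms. Control-arm potential responders all present the event;
#' experimental-arm responders none.
#'
#' With `round = TRUE` (canonical) every count is rounded to whole
#' participants stage by stage (N, then NT with `Nc = N - NT`, then event
#' counts) and a [trial_table] is returned. With `round = FALSE` the
#' reconstruction is left continuous (real-valued cells), which is the
#' model the smooth trends (monotone RR, chi-square, linear ethical-loss
#' percentage) are properties of; a plain list with fields
#' `a, b, c, d, Nc, NT` is returned.
#'
#' @param p Responder proportion, in (0, 1].
#' @param config A [sweep_config].
#' @param round Round counts to whole participants (default).
#' @return A [trial_table] (`round = TRUE`) or list of real-valued cells.
#' @examples
#' reconstruct_trial(1)     # the "perfect" trial: 60 vs 121
#' reconstruct_trial(0.5)
#' @export
reconstruct_trial <- function(p, config = sweep_config(), round = TRUE) {
  stopifnot(inherits(config, "sweep_config"), length(p) == 1L, is.finite(p))
  if (p <= 0 || p > 1) {
    stop("responder proportion p must be in (0, 1], got ", p, call. = FALSE)
  }
  d1 <- config$responders_T_fixed
  # the continuous model carries the exact control-arm counterpart
  # d1 * Nc/NT; rounding it to whole participants is a count-route choice
  prC <- if (round) config$potential_responders_C else
    d1 * (1 - config$arm_ratio) / config$arm_ratio
  R <- d1 + prC

  N <- R / p
  if (round) N <- round_half_away(N)
  NT <- N * config$arm_ratio
  if (round) NT <- round_half_away(NT)
  Nc <- N - NT

  if (Nc <= 0 || NT <= 0) {
    stop("infeasible grid point p = ", p, ": an arm is empty (Nc = ", Nc,
         ", NT = ", NT, ")", call. = FALSE)
  }
  U_T <- NT - d1
  U_C <- Nc - prC
  if (U_T < 0 || U_C < 0) {
    stop("infeasible grid point p = ", p,
         ": an arm is smaller than its fixed responder contingent (U_T = ",
         U_T, ", U_C = ", U_C, ")", call. = FALSE)
  }

  b <- config$Rc_unnecessary * U_T
  a_unn <- config$Rc_unnecessary * U_C
  if (round) {
    b <- round_half_away(b)
    a_unn <- round_half_away(a_unn)
  }
  a <- prC + a_unn

  if (round) {
    trial_table(a = a, b = b, c = Nc - a, d = NT - b)
  } else {
    list(a = a, b = b, c = Nc - a, d = NT - b, Nc = Nc, NT = NT)
  }
}

# Pearson statistic on (possibly real-valued) 2x2 cells; the continuous
# sweep needs it because trial_table enforces integer counts.
pearson_chi2_cells <- function(a, b, c, d) {
  N <- a + b + c + d
  r1 <- a + b; r2 <- c + d
  cC <- a + c; cT <- b + d
  if (r1 <= 0 || r2 <= 0 || cC <= 0 || cT <= 0) return(NA_real_)
  e <- c(r1 * cC, r1 * cT, r2 * cC, r2 * cT) / N
  o <- c(a, b, c, d)
  sum((o - e)^2 / e)
}

#' Run the responder-proportion sweep
#'
#' One reconstructed trial per grid point, with its derived metrics. The
#' ethical losses of a reconstructed trial are everyone except the fixed
#' experimental-arm responders, `N - responders_T_fixed`.
#'
#' @param config A [sweep_config].
#' @param round Round counts to whole participants (default); see
#'   [reconstruct_trial()].
#' @return A data frame, one row per grid point in increasing `p`, with
#'   columns `p, N, Nc, NT, events_C, events_T, ethical_losses,
#'   ethical_loss_pct, relative_risk, chi_square`.
#' @examples
#' sw <- run_sweep()
#' nrow(sw)  # 40
#' @export
run_sweep <- function(config = sweep_config(), round = TRUE) {
  stopifnot(inherits(config, "sweep_config"))
  p_grid <- seq(config$p_start, config$p_stop, by = config$p_step)
  rows <- lapply(p_grid, function(p) {
    tab <- reconstruct_trial(p, config, round = round)
    N <- tab$Nc + tab$NT
    Rc <- tab$a / tab$Nc
    RT <- tab$b / tab$NT
    chi2 <- if (round) {
      chi_square_2x2(tab)$statistic
    } else {
      pearson_chi2_cells(tab$a, tab$b, tab$c, tab$d)
    }
    el <- N - config$responders_T_fixed
    data.frame(p = p, N = N, Nc = tab$Nc, NT = tab$NT,
               events_C = tab$a, events_T = tab$b,
               ethical_losses = el,
               ethical_loss_pct = 100 * el / N,
               relative_risk = if (Rc > 0) RT / Rc else NA_real_,
               chi_square = chi2)
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  out
}

#' Check the monotone and linear trends of a sweep
#'
#' Verdicts on the four headline trends as the responder proportion
#' increases: sample size N nonincreasing, ethical-loss percentage
#' nonincreasing, relative risk nonincreasing, chi-square nondecreasing;
#' plus the R-squared of linear fits of ethical-loss percentage and
#' chi-square against p. The trends are exact properties of the continuous
#' reconstruction (`run_sweep(round = FALSE)`); on rounded counts,
#' one-participant quantization can break strict monotonicity of the rate
#' ratios at isolated grid points.
#'
#' @param rows A sweep data frame from [run_sweep()] (>= 3 rows).
#' @return A list with logical verdicts `N_nonincreasing`,
#'   `ethical_loss_pct_nonincreasing`, `RR_nonincreasing`,
#'   `chi2_nondecreasing`, and `r_squared` (list with `ethical_loss_pct`
#'   and `chi_square`; `NA` with `degenerate = TRUE` when the response is
#'   constant).
#' @export
trend_check <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 3)
  rows <- rows[order(rows$p), ]
  eps <- 1e-9
  noninc <- function(x) all(diff(x) <= eps)
  nondec <- function(x) all(diff(x) >= -eps)
  r2 <- function(y) {
    if (stats::var(y) < .Machine$double.eps) return(NA_real_)
    # suppress the "essentially perfect fit" note on exactly linear trends
    suppressWarnings(summary(stats::lm(y ~ rows$p))$r.squared)
  }
  r2_el <- r2(rows$ethical_loss_pct)
  r2_chi <- r2(rows$chi_square)
  list(
    N_nonincreasing = noninc(rows$N),
    ethical_loss_pct_nonincreasing = noninc(rows$ethical_loss_pct),
    RR_nonincreasing = noninc(rows$relative_risk),
    chi2_nondecreasing = nondec(rows$chi_square),
    r_squared = list(ethical_loss_pct = r2_el, chi_square = r2_chi),
    degenerate = is.na(r2_el) || is.na(r2_chi)
  )
}

#' Write a sweep to CSV
#'
#' Deterministic: identical configs give byte-identical files.
#'
#' @param rows Sweep data frame from [run_sweep()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
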