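#' Construct a 2x2 trial outcome table
#'
#' Summary data of a completed two-arm randomized controlled trial with a
#' dichotomous endpoint (e.g. all-cause death). Cells follow the standard
#' layout: rows are event / no event, columns are control (C) and
#' experimental (T) arms. Arm totals `Nc = a + c` and `NT = b + d` are
#' derived, never supplied.
#'
#' @param a Events (e.g. deaths) in the control arm.
#' @param b Events in the experimental arm.
#' @param c Event-free participants in the control arm.
#' @param d Event-free participants in the experimental arm.
#'
#' @return An object of class `trial_table`: a list with integer fields
#'   `a`, `b`, `c`, `d`, `Nc`, `NT`.
#'
#' @examples
#' tab <- trial_table(a = 194, b = 269, c = 2139, d = 4418)
#' tab
#' @export
trial_table <- function(a, b, c, d) {
  counts <- list(a = a, b = b, c = c, d = d)
  for (nm in names(counts)) {
    x <- counts[[nm]]
    if (length(x) != 1L || !is.numeric(x) || is.na(x)) {
      stop("cell '", nm, "' must be a single non-missing number", call. = FALSE)
    }
    if (x < 0) {
      stop("cell '", nm, "' is negative (", x, "); counts must be >= 0",
           call. = FALSE)
    }
    if (abs(x - round(x)) > 1e-8) {
      stop("cell '", nm, "' is not an integer count (", x, ")", call. = FALSE)
    }
  }
  a <- as.integer(round(a)); b <- as.integer(round(b))
  c <- as.integer(round(c)); d <- as.integer(round(d))
  Nc <- a + c
  NT <- b + d
  if (Nc == 0L) stop("control arm is empty (a + c = 0)", call. = FALSE)
  if (NT == 0L) stop("experimental arm is empty (b + d = 0)", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, Nc = Nc, NT = NT),
            class = "trial_table")
}

#' @export
print.trial_table <- function(x, ...) {
  m <- as.matrix(x)
  m <- rbind(m, Total = colSums(m))
  m <- cbind(m, Total = rowSums(m[, 1:2, drop = FALSE]))
  cat("2x2 trial outcome table\n")
  print(m)
  invisible(x)
}

#' @export
as.matrix.trial_table <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), nrow = 2,
         dimnames = list(c("event", "no_event"),
                         c("control", "experimental")))
}

#' The simplified Empa-REG-Outcome mortality table
#'
#' All-cause mortality figures from the published Empa-REG-Outcome trial
#' (empagliflozin vs placebo in type 2 diabetes, 2:1 allocation), reduced to
#' a single dichotomous endpoint: placebo arm 194 deceased / 2139 alive
#' (Nc = 2333), treatment arm 269 deceased / 4418 alive (NT = 4687),
#' 7020 participants in total. This table seeds the worked decomposition and
#' the default sweep configuration.
#'
#' @return A [trial_table].
#' @examples
#' decompose_trial(empa_reg_table())
#' @export
empa_reg_table <- function() {
  trial_table(a = 194, b = 269, c = 2139, d = 4418)
}

#' Read a 2x2 trial table from JSON or CSV
#'
#' Two plain-text formats are accepted. JSON: an object with integer fields
#' `a`, `b`, `c`, `d` (arm totals are derived; unknown keys are rejected).
#' CSV: exactly two data rows with header `arm,events,no_events`, the arms
#' named `C`/`control` and `T`/`experimental`/`treatment` in either order.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"json"` or `"csv"`.
#' @return A [trial_table].
#' @export
read_trial_table <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") read_trial_table_json(path) else read_trial_table_csv(path)
}

read_trial_table_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  required <- c("a", "b", "c", "d")
  missing <- setdiff(required, names(obj))
  if (length(missing)) {
    stop("JSON table ", path, ": missing field(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(obj), required)
  if (length(extra)) {
    stop("JSON table ", path, ": unknown field(s) ",
         paste(extra, collapse = ", "),
         " (arm totals are derived, not supplied)", call. = FALSE)
  }
  trial_table(a = obj$a, b = obj$b, c = obj$c, d = obj$d)
}

read_trial_table_csv <- function(path) {
  df <- utils::read.csv(path, strip.white = TRUE)
  want <- c("arm", "events", "no_events")
  if (!identical(names(df), want)) {
    stop("CSV table ", path, " line 1: header must be 'arm,events,no_events', got '",
         paste(names(df), collapse = ","), "'", call. = FALSE)
  }
  if (nrow(df) != 2L) {
    stop("CSV table ", path, ": expected exactly 2 data rows, got ", nrow(df),
         call. = FALSE)
  }
  key <- tolower(trimws(as.character(df$arm)))
  ctl <- which(key %in% c("c", "control", "placebo"))
  trt <- which(key %in% c("t", "experimental", "treatment"))
  if (length(ctl) != 1L || length(trt) != 1L) {
    stop("CSV table ", path, ": arms must be one control (C) and one ",
         "experimental (T) row; got '", paste(df$arm, collapse = "', '"), "'",
         call. = FALSE)
  }
  for (col in c("events", "no_events")) {
    if (!is.numeric(df[[col]]) || anyNA(df[[col]])) {
      stop("CSV table ", path, ": column '", col, "' must be numeric counts",
           call. = FALSE)
    }
  }
  trial_table(a = df$events[ctl], b = df$events[trt],
              c = df$no_events[ctl], d = df$no_events[trt])
}
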