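#' Define the injection schedule of a mitostress run
#'
#' A mitostress assay records a block of basal readings followed by equal-sized
#' blocks of readings after each sequential inhibitor injection. The default
#' schedule is the classical nerve-fragment protocol: five basal readings at
#' 6-minute intervals, then eight readings after each of oligomycin A (Omy,
#' 5 uM), FCCP (2.5 uM) and rotenone + antimycin A (Rot/AA, 5 uM each), for
#' 29 readings in total.
#'
#' @param n_basal Number of pre-injection (basal) readings. Must be >= 1.
#' @param n_post Number of readings recorded after each injection. Must be >= 1.
#' @param interval_min Minutes between consecutive readings (> 0).
#' @param injections Named numeric vector of compound concentrations (uM), in
#'   injection order. Names are the phase labels used throughout the package.
#'
#' @return An object of class `injection_schedule`: a list with elements
#'   `n_basal`, `n_post`, `interval_min`, `injections`.
#' @examples
#' sched <- injection_schedule()
#' n_readings(sched) # 29
#' phase_windows(sched)
#' @export
injection_schedule <- function(n_basal = 5L, n_post = 8L, interval_min = 6,
                               injections = c(Omy = 5, FCCP = 2.5, RotAA = 5)) {
  n_basal <- as.integer(n_basal)
  n_post <- as.integer(n_post)
  if (is.na(n_basal) || n_basal < 1L) {
    stop("`n_basal` must be an integer >= 1.", call. = FALSE)
  }
  if (is.na(n_post) || n_post < 1L) {
    stop("`n_post` must be an integer >= 1.", call. = FALSE)
  }
  if (!is.numeric(interval_min) || length(interval_min) != 1L ||
      !is.finite(interval_min) || interval_min <= 0) {
    stop("`interval_min` must be a single positive number.", call. = FALSE)
  }
  if (length(injections) < 1L || is.null(names(injections)) ||
      any(!nzchar(names(injections))) || anyDuplicated(names(injections))) {
    stop("`injections` must be a non-empty named vector with unique labels.",
         call. = FALSE)
  }
  if ("basal" %in% names(injections)) {
    stop("\"basal\" is reserved for the pre-injection phase label.", call. = FALSE)
  }
  structure(
    list(n_basal = n_basal, n_post = n_post,
         interval_min = as.numeric(interval_min),
         injections = injections),
    class = "injection_schedule"
  )
}

#' Total number of readings implied by a schedule
#'
#' @param schedule An [injection_schedule()].
#' @return Integer: `n_basal + n_post * length(injections)`.
#' @export
n_readings <- function(schedule) {
  stopifnot(inherits(schedule, "injection_schedule"))
  schedule$n_basal + schedule$n_post * length(schedule$injections)
}

#' Phase windows of a schedule
#'
#' Maps each phase label to its inclusive 1-based range of reading indices:
#' basal occupies `[1, n_basal]` and the k-th injection occupies
#' `[n_basal + (k-1) * n_post + 1, n_basal + k * n_post]`. The windows
#' partition `[1, n_readings(schedule)]` contiguously and disjointly.
#'
#' @param schedule An [injection_schedule()].
#' @return A tibble with columns `phase`, `start`, `end`.
#' @export
phase_windows <- function(schedule) {
  stopifnot(inherits(schedule, "injection_schedule"))
  labels <- c("basal", names(schedule$injections))
  len <- c(schedule$n_basal,
           rep(schedule$n_post, length(schedule$injections)))
  end <- cumsum(len)
  tibble::tibble(phase = labels,
                 start = as.integer(end - len + 1L),
                 end = as.integer(end))
}

# Phase label for each reading index, in order.
phase_of_readings <- function(schedule) {
  w <- phase_windows(schedule)
  rep(w$phase, times = w$end - w$start + 1L)
}

# Nominal time stamp of each reading: (index - 1) * interval_min.
times_of_readings <- function(schedule) {
  (seq_len(n_readings(schedule)) - 1) * schedule$interval_min
}

#' @export
print.injection_schedule <- function(x, ...) {
  cat(sprintf(
    "<injection_schedule> %d basal + %d x %d post readings (%g min apart)\n",
    x$n_basal, length(x$injections), x$n_post, x$interval_min))
  cat("  injections:",
      paste(sprintf("%s (%g uM)", names(x$injections), x$injections),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.injection_schedule <- function(x, ...) {
  sprintf("%d+%dx%d@%gmin[%s]", x$n_basal, length(x$injections), x$n_post,
          x$interval_min, paste(names(x$injections), collapse = ","))
}
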