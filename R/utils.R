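# Shared internal helpers: classed conditions, seeded evaluation, 8-day slots.

stop_neeflux <- function(class, msg, call. = FALSE) {
  cond <- structure(
    class = c(paste0("neeflux_", class), "neeflux_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' 8-day composite slot containing a date
#'
#' The satellite product and the parameter-inversion windows share an 8-day
#' grid anchored at day-of-year 1, 9, ..., 361 of each calendar year; the last
#' slot absorbs the trailing 5 (or 6) days of the year. This maps any
#' date/time to the start date of its slot.
#'
#' @param x `Date` or `POSIXct` vector (POSIXct interpreted in its own tz).
#' @return `Date` vector of slot start dates.
#' @examples
#' slot_start(as.Date(c("2007-01-08", "2007-01-09", "2007-12-31")))
#' @export
slot_start <- function(x) {
  d <- if (inherits(x, "POSIXct")) {
    as.Date(format(x, "%Y-%m-%d"))
  } else {
    as.Date(x)
  }
  doy <- as.integer(format(d, "%j"))
  slot_doy <- pmin(((doy - 1L) %/% 8L) * 8L + 1L, 361L)
  as.Date(paste0(format(d, "%Y"), "-01-01")) + (slot_doy - 1L)
}

#' Sequence of 8-day composite slots covering a period
#'
#' @param start,end Dates (coerced with `as.Date`); the grid runs from the
#'   slot containing `start` to the slot containing `end`.
#' @return `Date` vector of slot start dates on the DOY 1, 9, ..., 361 grid.
#' @export
composite_slots <- function(start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop_neeflux("invalid_config", "end date precedes start date")
  years <- seq.int(as.integer(format(start, "%Y")), as.integer(format(end, "%Y")))
  slots <- as.Date(unlist(lapply(years, function(y) {
    as.Date(paste0(y, "-01-01")) + seq.int(0L, 360L, 8L)
  })), origin = "1970-01-01")
  slots[slots >= slot_start(start) & slots <= slot_start(end)]
}

# mid-point day-of-year of a slot (used when sampling seasonal curves)
slot_mid_doy <- function(slot) {
  as.integer(format(slot, "%j")) + 3.5
}
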