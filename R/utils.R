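# Internal helpers shared across modules.

# Named substreams off a single master seed, so that components (field,
# stations, noise, missingness, ...) can be regenerated independently and the
# whole dataset is reproducible from one integer.
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 1009L + h * 7919L) %% .Machine$integer.max)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  expr
}

# round-half-away-from-zero, so that 0.10 * 48 stations -> 5
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gridta <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}

daily_calendar <- function(date_start, date_end) {
  date_start <- as_date(date_start); date_end <- as_date(date_end)
  if (date_end < date_start) stop_gridta("date_end must be >= date_start")
  seq(date_start, date_end, by = "day")
}
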