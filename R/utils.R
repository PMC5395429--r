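# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# stream afterwards. `seed = NULL` leaves the session stream untouched.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# days in month, handling leap years
.days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%d-%02d-01", year, month))
  nxt <- if (month == 12) as.Date(sprintf("%d-01-01", year + 1)) else
    as.Date(sprintf("%d-%02d-01", year, month + 1))
  as.integer(nxt - first)
}
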