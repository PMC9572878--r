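#' Read a session log from CSV
#'
#' Expected header: `player_id,week,day,duration_min,rpe` (extra columns
#' such as a session type are carried along).
#'
#' @param path CSV file path.
#' @return Session tibble.
#' @export
read_sessions <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  check_session_cols(x)
  if (!"day" %in% names(x)) abort_invalid("session CSV is missing column: day.")
  x <- mutate(x,
    player_id = as.character(.data$player_id),
    week = as.integer(.data$week), day = as.integer(.data$day)
  )
  if (any(x$week < 1, na.rm = TRUE) || any(!x$day %in% 1:7)) {
    abort_invalid("weeks must be >= 1 and days in 1..7.")
  }
  session_load(x$duration_min, x$rpe) # validates ranges
  x
}

#' Read injury records from CSV
#'
#' Expected header: `player_id,onset_week,days_lost`.
#'
#' @param path CSV file path.
#' @return Injury tibble.
#' @export
read_injuries <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("player_id", "onset_week") %in% names(x))) {
    abort_invalid("injury CSV needs columns player_id, onset_week.")
  }
  mutate(x,
    player_id = as.character(.data$player_id),
    onset_week = as.integer(.data$onset_week)
  )
}
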