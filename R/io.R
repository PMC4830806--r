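#' Write a trajectory to CSV (plus a JSON jump sidecar)
#'
#' Columns `t`, `x1`, ... , `is_jump` (1 on post-jump rows at impulse times,
#' 0 elsewhere); numbers are written with 17 significant digits so the
#' round-trip through [read_trajectory()] is bit-exact.
#'
#' @param traj An `imp_trajectory`.
#' @param csv_path Output CSV path.
#' @param json_path Optional path for the JSON sidecar of jump records.
#' @return `csv_path`, invisibly.
#' @export
write_trajectory <- function(traj, csv_path, json_path = NULL) {
  stopifnot(inherits(traj, "imp_trajectory"))
  n <- length(traj$times)
  is_jump <- integer(n)
  if (n > 1L) is_jump[c(FALSE, diff(traj$times) == 0)] <- 1L
  df <- data.frame(t = sprintf("%.17g", traj$times))
  for (i in seq_len(traj$species))
    df[[paste0("x", i)]] <- sprintf("%.17g", traj$states[, i])
  df$is_jump <- is_jump
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(traj$jumps, json_path, digits = NA, pretty = TRUE)
  invisible(csv_path)
}

#' Read back a trajectory CSV (and optional jump sidecar)
#'
#' @param csv_path Path written by [write_trajectory()].
#' @param json_path Optional jump-record sidecar path.
#' @return List with `data` (data frame: `t`, `x1`, ..., `is_jump`) and
#'   `jumps` (data frame or `NULL`).
#' @export
read_trajectory <- function(csv_path, json_path = NULL) {
  df <- utils::read.csv(csv_path)
  jumps <- if (!is.null(json_path))
    as.data.frame(jsonlite::read_json(json_path, simplifyVector = TRUE))
  else NULL
  list(data = df, jumps = jumps)
}

# plain-list views for JSON reports
.report_list <- function(x) {
  if (inherits(x, c("permanence_bounds", "stability_report",
                    "scalar_bounds")))
    return(unclass(x))
  x
}
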