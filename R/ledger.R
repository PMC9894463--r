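# ledger CSV schema, versioned via a header comment line
LEDGER_HEADER <- "# schoolfeed ledger v1"
LEDGER_COLS <- c("day", "fish_id", "mass_g", "total_length_cm",
                 "intake_g", "pellets")

#' Write an experiment ledger to CSV
#'
#' One row per (day, fish): `day, fish_id, mass_g, total_length_cm,
#' intake_g, pellets`, preceded by a schema-version comment line.
#' Numbers are written in full precision so the growth recurrence
#' `W(d+1) = W(d) + FCE * S(d)` survives the round trip exactly.
#'
#' @param x A `feeding_experiment` or a ledger data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(x, path) {
  ledger <- if (inherits(x, "feeding_experiment")) x$ledger else x
  stopifnot(all(LEDGER_COLS %in% names(ledger)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(LEDGER_HEADER, con)
  utils::write.csv(format(ledger[LEDGER_COLS], digits = 17, trim = TRUE,
                          scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an experiment ledger from CSV
#'
#' Validates the schema and, optionally, completeness: a ledger must hold
#' exactly one row for every (day, fish) combination of its day and fish
#' ranges.  Missing rows are named in the error.
#'
#' @param path CSV path written by [write_ledger()].
#' @param check_complete Verify the (day, fish) grid is complete.
#' @return The ledger data frame.
#' @export
read_ledger <- function(path, check_complete = TRUE) {
  if (!file.exists(path)) stop("ledger file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# schoolfeed ledger"))
    stop("not a schoolfeed ledger (missing schema header): ", path,
         call. = FALSE)
  ledger <- utils::read.csv(path, comment.char = "#")
  missing_cols <- setdiff(LEDGER_COLS, names(ledger))
  if (length(missing_cols))
    stop("malformed ledger, missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (check_complete) {
    days <- sort(unique(ledger$day))
    fish <- sort(unique(ledger$fish_id))
    want <- expand.grid(day = days, fish_id = fish)
    key <- paste(ledger$day, ledger$fish_id)
    miss <- want[!paste(want$day, want$fish_id) %in% key, ]
    if (nrow(miss))
      stop("incomplete ledger; missing (day, fish) rows: ",
           paste(sprintf("(%d, %d)", miss$day, miss$fish_id)[
             seq_len(min(10L, nrow(miss)))], collapse = ", "),
           if (nrow(miss) > 10L) " ...", call. = FALSE)
    if (anyDuplicated(key))
      stop("duplicated (day, fish) rows in ledger", call. = FALSE)
  }
  ledger
}
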