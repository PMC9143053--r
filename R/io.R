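# Event-table readers/writers in the NONMEM-dialect CSV layout:
# ID, OCC, TIME, AMT, DV, EVID (1 dose / 0 observation), ROUTE (1 IV / 2 IM),
# BW, and the package's BLANK flag for pre-dose blank samples.

.event_cols <- c("ID", "OCC", "TIME", "AMT", "DV", "EVID", "ROUTE", "BW")

#' Read an event table
#'
#' Reads and validates a dosing/observation CSV. Missing `DV` entries (dose
#' rows) are coded as empty fields. Rows with negative times are rejected
#' with a report; a dose row carrying an observation value is an error.
#'
#' @param path CSV file path.
#' @return A validated `event_table` data.frame. The number of observation
#'   rows per route is reported as a message.
#' @export
read_events <- function(path) {
  tab <- utils::read.csv(path, na.strings = c("", "NA"))
  missing <- setdiff(.event_cols, names(tab))
  if (length(missing))
    stop("event table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(tab$BLANK)) tab$BLANK <- 0L
  bad_dose <- which(tab$EVID == 1 & !is.na(tab$DV))
  if (length(bad_dose))
    stop("dose rows must have empty DV; offending row(s): ",
         paste(bad_dose, collapse = ", "), call. = FALSE)
  neg <- which(tab$TIME < 0)
  if (length(neg)) {
    message("rejected ", length(neg), " row(s) with negative time: ",
            paste(neg, collapse = ", "))
    tab <- tab[-neg, , drop = FALSE]
  }
  n_iv <- sum(tab$EVID == 0 & tab$BLANK == 0 & tab$ROUTE == 1)
  n_im <- sum(tab$EVID == 0 & tab$BLANK == 0 & tab$ROUTE == 2)
  message("event table: ", n_iv, " IV + ", n_im, " IM observation rows")
  class(tab) <- c("event_table", "data.frame")
  tab
}

#' Write an event table
#'
#' @param events an `event_table`.
#' @param path destination CSV path; missing `DV` written as empty fields.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, na = "")
  invisible(path)
}
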