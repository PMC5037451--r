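#' 96-well plate layout with control and excluded wells
#'
#' Describes which wells of an 8 x 12 plate carry cells, which are unstretched
#' controls (posts omitted from the post array), and which are excluded from
#' analysis. By default the edge rows (A, H) and edge columns (1, 12) are
#' excluded to avoid edge effects, and the eight interior wells C4, D4, E4,
#' F4, C9, D9, E9, F9 are controls.
#'
#' @param control_wells character vector of control well ids (e.g. "C4").
#' @param excluded_wells character vector of excluded well ids. The default
#'   excludes rows A and H and columns 1 and 12.
#' @return An object of class \code{plate_layout}: a list with components
#'   \code{wells} (all 96 ids), \code{control_wells}, \code{excluded_wells}
#'   and \code{active_wells} (neither excluded nor control).
#' @examples
#' lay <- plate_layout()
#' length(lay$active_wells)  # 52
#' @export
plate_layout <- function(control_wells = c("C4", "D4", "E4", "F4",
                                           "C9", "D9", "E9", "F9"),
                         excluded_wells = default_excluded_wells()) {
  all_wells <- as.vector(outer(LETTERS[1:8], 1:12, paste0))
  control_wells <- as.character(control_wells)
  excluded_wells <- as.character(excluded_wells)
  bad <- setdiff(c(control_wells, excluded_wells), all_wells)
  if (length(bad))
    stop("well ids outside the 8x12 grid: ", paste(bad, collapse = ", "))
  overlap <- intersect(control_wells, excluded_wells)
  if (length(overlap))
    stop("wells cannot be both control and excluded: ",
         paste(overlap, collapse = ", "))
  structure(list(
    wells = all_wells,
    control_wells = control_wells,
    excluded_wells = excluded_wells,
    active_wells = setdiff(all_wells, c(control_wells, excluded_wells))
  ), class = "plate_layout")
}

default_excluded_wells <- function() {
  all_wells <- as.vector(outer(LETTERS[1:8], 1:12, paste0))
  rows <- substr(all_wells, 1, 1)
  cols <- as.integer(substring(all_wells, 2))
  all_wells[rows %in% c("A", "H") | cols %in% c(1, 12)]
}

#' @export
print.plate_layout <- function(x, ...) {
  cat("96-well plate layout\n")
  cat("  control wells: ", paste(x$control_wells, collapse = ", "), "\n")
  cat("  excluded wells:", length(x$excluded_wells),
      "(edge rows/columns by default)\n")
  cat("  active wells:  ", length(x$active_wells), "\n")
  invisible(x)
}

#' Row letter and column number of well ids
#' @param well character vector of well ids such as "B2".
#' @return data.frame with columns \code{row} (integer 1-8) and \code{col}.
#' @keywords internal
well_row_col <- function(well) {
  data.frame(row = match(substr(well, 1, 1), LETTERS[1:8]),
             col = as.integer(substring(well, 2)))
}
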