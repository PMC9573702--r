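#' Spot-volume tables
#'
#' A spot-volume table records, for every protein spot detected on a set of
#' 2-DE gels, the background-subtracted densitometric volume of that spot on
#' each gel. It is represented as a tibble with one row per spot: a
#' `spot_id` character column, one numeric column per gel (the column name is
#' the gel id), and optionally the per-spot gel coordinates `pI_obs`
#' (observed isoelectric point, pH units) and `Mr_obs_kDa` (observed
#' molecular mass, kDa) as trailing metadata columns.
#'
#' `NA` means the spot was not detected on that gel ("missing"), which is
#' distinct from an explicit volume of 0 (detected with zero volume, counted
#' as present). All present volumes must be non-negative and spot/gel ids
#' must be unique.
#'
#' @param x A data frame with a `spot_id` column (or spot ids in the first
#'   column), one numeric column per gel, and optional `pI_obs` /
#'   `Mr_obs_kDa` columns.
#' @return A validated `spot_table` tibble.
#' @examples
#' tbl <- as_spot_table(data.frame(
#'   spot_id = c("s1", "s2"),
#'   g1 = c(10, 5), g2 = c(12, NA)
#' ))
#' gel_ids(tbl)
#' @export
as_spot_table <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"spot_id" %in% names(x)) {
    if (ncol(x) < 1) {
      abort("A spot table needs a spot id column.", class = "gelquant_format_error")
    }
    names(x)[1] <- "spot_id"
  }
  x$spot_id <- as.character(x$spot_id)
  x <- dplyr::relocate(x, "spot_id")
  meta <- intersect(spot_meta_cols, names(x))
  x <- dplyr::relocate(x, dplyr::all_of(meta), .after = dplyr::last_col())
  validate_spot_table(structure(x, class = c("spot_table", class(tibble::tibble())))
  )
}

spot_meta_cols <- c("pI_obs", "Mr_obs_kDa")

#' @rdname as_spot_table
#' @export
gel_ids <- function(x) {
  setdiff(names(x), c("spot_id", spot_meta_cols))
}

validate_spot_table <- function(x) {
  dup <- x$spot_id[duplicated(x$spot_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate spot id(s): ", paste(unique(dup), collapse = ", ")),
          class = "gelquant_format_error")
  }
  gels <- gel_ids(x)
  for (g in gels) {
    if (!is.numeric(x[[g]])) {
      abort(paste0("Gel column '", g, "' is not numeric."),
            class = "gelquant_format_error")
    }
    bad <- which(!is.na(x[[g]]) & x[[g]] < 0)
    if (length(bad) > 0) {
      abort(paste0("Negative volume at spot '", x$spot_id[bad[1]],
                   "', gel '", g, "'."),
            class = "gelquant_validation_error")
    }
  }
  x
}

#' Extract the spots-by-gels volume matrix
#'
#' @param x A `spot_table`.
#' @return A numeric matrix (spots in rows, gels in columns) with `NA` for
#'   undetected entries; row names are spot ids.
#' @export
volume_matrix <- function(x) {
  gels <- gel_ids(x)
  m <- as.matrix(x[gels])
  rownames(m) <- x$spot_id
  m
}

#' Read and write spot-volume tables
#'
#' Files are delimited text with a header row `spot_id, <gel_1>, ...,
#' <gel_G>` plus optional trailing `pI_obs` and `Mr_obs_kDa` columns. Empty
#' cells denote spots not detected on that gel; an explicit `0` is a detected
#' zero-volume spot. Column order is not significant; gel identity is
#' carried by the header names.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` or `"tsv"`; for `read_spot_table` the default is
#'   guessed from the file extension.
#' @return `read_spot_table` returns a validated [as_spot_table()] tibble;
#'   `write_spot_table` returns `path` invisibly and writes a file that
#'   round-trips through `read_spot_table`.
#' @export
read_spot_table <- function(path, dialect = NULL) {
  dialect <- dialect %||% guess_dialect(path)
  header <- strsplit(readLines(path, n = 1L), delim_for(dialect), fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", trimws(header))
  dup <- header[duplicated(header)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate column header(s) in '", path, "': ",
                 paste(unique(dup), collapse = ", ")),
          class = "gelquant_format_error")
  }
  x <- readr::read_delim(path, delim = delim_for(dialect), na = c("", "NA"),
                         col_types = readr::cols(.default = readr::col_double(),
                                                 spot_id = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  as_spot_table(x)
}

#' @rdname read_spot_table
#' @param table A `spot_table` to write.
#' @export
write_spot_table <- function(table, path, dialect = NULL) {
  table <- as_spot_table(table)
  dialect <- dialect %||% guess_dialect(path)
  readr::write_delim(table, path, delim = delim_for(dialect), na = "")
  invisible(path)
}

guess_dialect <- function(path) {
  if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
}

delim_for <- function(dialect) {
  dialect <- match.arg(dialect, c("csv", "tsv"))
  if (dialect == "tsv") "\t" else ","
}
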