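## Packaged per-specimen reference tables and their arithmetic.
##
## Two tables ship with the package (inst/extdata): a CT table pairing each
## specimen's calcite CT number (CCN) and mean wall thickness across three
## scans (pre-treatment, post-treatment scanned as a 3-specimen stack, and
## post-treatment scanned individually), and an isotope table with treatment
## group, genetic type, d13C, d18O (both permil VPDB) and shell weight (ug).

.ct_measure_cols <- c("pre_ccn", "post1_ccn", "post2_ccn",
                      "pre_thick", "post1_thick", "post2_thick")

#' Path to a packaged fixture table
#'
#' @param table `"ct"` or `"isotope"`.
#' @return file path of the packaged CSV.
#' @export
fixture_path <- function(table = c("ct", "isotope")) {
  table <- match.arg(table)
  fn <- switch(table, ct = "table1_ct.csv", isotope = "table2_isotope.csv")
  system.file("extdata", fn, package = "calciscan", mustWork = TRUE)
}

# Unicode minus (U+2212) is normalized to ASCII hyphen-minus before parsing.
.normalize_minus <- function(x) gsub("−", "-", x)

.parse_numeric_col <- function(x, col) {
  x <- .normalize_minus(trimws(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !(x %in% c("", "NA")))
  if (length(bad)) {
    stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                 x[bad[1]], col, bad[1]), call. = FALSE)
  }
  out
}

#' Load a per-specimen CT table
#'
#' Reads a CSV holding one row per specimen with CCN and wall-thickness
#' measurements for the pre-treatment scan and the two post-treatment scans
#' (stacked and individual mounting). Row order is preserved.
#'
#' @param path CSV path; defaults to the packaged reference table.
#' @return a `ct_table` data frame with columns `specimen_id`, `pre_ccn`,
#'   `post1_ccn`, `post2_ccn` (CCN units) and `pre_thick`, `post1_thick`,
#'   `post2_thick` (um). Any extra columns (e.g. the transcribed printed
#'   difference columns) are carried through.
#' @export
load_ct_table <- function(path = fixture_path("ct")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, colClasses = "character", check.names = TRUE)
  need <- c("specimen_id", .ct_measure_cols)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("CT table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("CT table has a header but no data rows")
    out <- df
    out$specimen_id <- integer(0)
    for (cc in .ct_measure_cols) out[[cc]] <- numeric(0)
    class(out) <- c("ct_table", class(out))
    return(out)
  }
  out <- df
  out$specimen_id <- as.integer(.parse_numeric_col(df$specimen_id, "specimen_id"))
  for (cc in setdiff(names(df), "specimen_id")) {
    out[[cc]] <- .parse_numeric_col(df[[cc]], cc)
  }
  if (anyDuplicated(out$specimen_id)) stop("duplicate specimen_id in CT table")
  ccn_cols <- grep("_ccn$", .ct_measure_cols, value = TRUE)
  th_cols <- grep("_thick$", .ct_measure_cols, value = TRUE)
  ccn <- unlist(out[ccn_cols])
  th <- unlist(out[th_cols])
  if (any(ccn <= 0 | ccn >= 1200)) stop("CCN value outside (0, 1200)")
  if (any(th <= 0 | th >= 20)) stop("thickness value outside (0, 20) um")
  class(out) <- c("ct_table", class(out))
  out
}

#' Load a per-specimen isotope table
#'
#' Reads a CSV with treatment group (A/B/C), genetic type (Ia/Ib/IIa or
#' blank for untyped), d13C and d18O (permil VPDB) and shell weight (ug).
#' Specimen IDs are unique only within a group; records are keyed by
#' (group, specimen_id).
#'
#' @param path CSV path; defaults to the packaged reference table.
#' @return an `isotope_table` data frame with columns `group` (factor A/B/C),
#'   `specimen_id`, `genetic_type` (factor Ia/Ib/IIa/untyped), `d13c`,
#'   `d18o`, `weight`.
#' @export
load_isotope_table <- function(path = fixture_path("isotope")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, colClasses = "character", check.names = TRUE)
  need <- c("group", "specimen_id", "genetic_type", "d13c", "d18o", "weight")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("isotope table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  grp <- trimws(df$group)
  bad <- setdiff(unique(grp), c("A", "B", "C"))
  if (length(bad)) {
    stop("invalid treatment group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ty <- trimws(df$genetic_type)
  ty[ty == ""] <- "untyped"
  bad_ty <- setdiff(unique(ty), c("Ia", "Ib", "IIa", "untyped"))
  if (length(bad_ty)) {
    stop("invalid genetic type label(s): ", paste(bad_ty, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    group = factor(grp, levels = c("A", "B", "C")),
    specimen_id = trimws(df$specimen_id),
    genetic_type = factor(ty, levels = c("Ia", "Ib", "IIa", "untyped")),
    d13c = .parse_numeric_col(df$d13c, "d13c"),
    d18o = .parse_numeric_col(df$d18o, "d18o"),
    weight = .parse_numeric_col(df$weight, "weight"),
    stringsAsFactors = FALSE
  )
  if (any(out$weight <= 0)) stop("nonpositive shell weight")
  key <- paste(out$group, out$specimen_id)
  if (anyDuplicated(key)) stop("duplicate (group, specimen_id) pair")
  if (any(out$group == "A" & out$genetic_type != "untyped")) {
    stop("group-A records must be untyped (no DNA extraction in group A)")
  }
  class(out) <- c("isotope_table", class(out))
  out
}

#' Write a fixture table back to CSV
#'
#' Round-trips [load_ct_table()] / [load_isotope_table()] output at printed
#' precision.
#'
#' @param x a `ct_table` or `isotope_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixture_table <- function(x, path) {
  df <- as.data.frame(x)
  if (inherits(x, "isotope_table")) {
    df$genetic_type <- as.character(df$genetic_type)
    df$genetic_type[df$genetic_type == "untyped"] <- ""
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-specimen paired differences between two measurement columns
#'
#' Differences are signed first-minus-second, matching the reference table's
#' convention for its printed difference columns.
#'
#' @param records a `ct_table` (or any data frame with the named columns).
#' @param first,second column names.
#' @return a `paired_diff_summary` list: `diffs` (ordered, one per specimen),
#'   `mean_diff`, `min_diff`, `max_diff`.
#' @export
paired_differences <- function(records, first, second) {
  for (cc in c(first, second)) {
    if (!cc %in% names(records)) stop("unknown column: ", cc, call. = FALSE)
  }
  d <- records[[first]] - records[[second]]
  structure(
    list(diffs = d, mean_diff = mean(d), min_diff = min(d), max_diff = max(d),
         first = first, second = second, n = length(d)),
    class = "paired_diff_summary"
  )
}

#' @export
print.paired_diff_summary <- function(x, ...) {
  cat(sprintf("Paired differences %s - %s (n = %d)\n", x$first, x$second, x$n))
  cat(sprintf("  mean %+0.3f   min %+0.3f   max %+0.3f\n",
              x$mean_diff, x$min_diff, x$max_diff))
  invisible(x)
}
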