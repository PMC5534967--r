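# Delimited-text readers and writers for twin-pair records.

.required_cols <- c("pair_id", "zygosity_group", "age", "sex1", "sex2",
                    "status1", "status2")

#' Read twin-pair records from delimited text
#'
#' Reads a TSV (or CSV, by extension or `dialect`) of twin-pair records with
#' the columns `pair_id, zygosity_group, age, sex1, sex2, status1, status2`
#' and optional symptom-indicator columns. Malformed rows (status outside
#' 0/1/2, unknown zygosity group, non-numeric age) are rejected
#' individually and reported; missing required columns or an empty file are
#' hard errors.
#'
#' @param path file path.
#' @param dialect `"tsv"`, `"csv"`, or `NULL` to infer from the extension.
#' @return a `data.frame` of validated records; rejected rows (with their
#'   line numbers and reasons) in `attr(, "rejected")`.
#' @export
read_twin_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("read_twin_table: no such file: ", path)
  if (is.null(dialect))
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  sep <- if (dialect == "csv") "," else "\t"
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("read_twin_table: cannot parse ", path, ": ",
                             conditionMessage(e)))
  if (nrow(raw) == 0) stop("read_twin_table: ", path, " contains no records")
  missing_cols <- setdiff(.required_cols, names(raw))
  if (length(missing_cols))
    stop("read_twin_table: missing required column(s): ",
         paste(missing_cols, collapse = ", "))

  age <- suppressWarnings(as.numeric(raw$age))
  s1 <- suppressWarnings(as.integer(raw$status1))
  s2 <- suppressWarnings(as.integer(raw$status2))
  problems <- character(nrow(raw))
  bad <- function(cond, why) {
    problems[cond & problems == ""] <<- why
  }
  bad(!raw$zygosity_group %in% .zygosity_groups, "unknown zygosity_group")
  bad(is.na(age), "non-numeric age")
  bad(is.na(s1) | !s1 %in% 0:2, "status1 outside 0/1/2")
  bad(is.na(s2) | !s2 %in% 0:2, "status2 outside 0/1/2")
  bad(!raw$sex1 %in% c("F", "M") | !raw$sex2 %in% c("F", "M"),
      "sex must be F or M")
  ok <- problems == ""
  rec <- data.frame(pair_id = raw$pair_id[ok],
                    zygosity_group = raw$zygosity_group[ok],
                    age = age[ok], sex1 = raw$sex1[ok], sex2 = raw$sex2[ok],
                    status1 = s1[ok], status2 = s2[ok],
                    stringsAsFactors = FALSE)
  sym_cols <- grep("^sym[1-9]_[12]$", names(raw), value = TRUE)
  for (sc in sym_cols) rec[[sc]] <- as.integer(raw[[sc]][ok])
  if (any(!ok)) {
    rej <- data.frame(line = which(!ok) + 1L, reason = problems[!ok],
                      stringsAsFactors = FALSE)
    attr(rec, "rejected") <- rej
    message("read_twin_table: rejected ", nrow(rej), " of ", nrow(raw),
            " rows (see attr(, 'rejected'))")
  }
  if (nrow(rec) == 0) stop("read_twin_table: no valid records in ", path)
  rec
}

#' Write twin-pair records as TSV
#'
#' @param records twin-pair records.
#' @param path output path (`.csv` switches to comma-separated).
#' @return `path`, invisibly.
#' @export
write_twin_table <- function(records, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  cols <- intersect(c(.required_cols,
                      grep("^sym", names(records), value = TRUE),
                      intersect(c("liab1", "liab2"), names(records))),
                    names(records))
  utils::write.table(records[, cols], path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
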