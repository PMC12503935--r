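# Strict CSV schemas for the four datasets. Every reader validates column
# names, types and ranges and refuses missing values; writers emit plain
# UTF-8 CSV with a header row. Round-trip write -> read is the identity.

dataset_schemas <- list(
  behavior = list(
    columns = c("trial_id", "treatment", "line_id", "cross_type", "run",
                "time_index", "n_on_uninfested", "n_females"),
    integer = c("run", "time_index", "n_on_uninfested", "n_females"),
    character = c("trial_id", "treatment", "line_id", "cross_type")
  ),
  eggs = list(
    columns = c("trial_id", "treatment", "line_id", "cross_type", "run",
                "eggs_uninfested", "eggs_infested"),
    integer = c("run", "eggs_uninfested", "eggs_infested"),
    character = c("trial_id", "treatment", "line_id", "cross_type")
  ),
  beans = list(
    columns = c("duo_id", "line_id", "cross_type", "n_focal_eggs",
                "n_competitor_eggs", "n_focal_emerged"),
    integer = c("n_focal_eggs", "n_competitor_eggs", "n_focal_emerged"),
    character = c("duo_id", "line_id", "cross_type")
  ),
  fecundity = list(
    columns = c("female_id", "cross_label", "hatched_eggs"),
    integer = "hatched_eggs",
    character = c("female_id", "cross_label")
  )
)

schema_fail <- function(type, msg, row = NULL) {
  stop_cueload(paste0("invalid ", type, " table: ", msg,
                      if (!is.null(row)) paste0(" (row ", row, ")")),
               "cueload_schema_violation")
}

#' Validate a dataset against its schema
#'
#' Checks exact column presence, integer-valued count columns,
#' non-negativity, the binomial bounds (`n_on_uninfested <= n_females`,
#' `n_focal_emerged <= n_focal_eggs`) and the absence of missing values.
#' Diagnostics name the offending column and first offending row.
#'
#' @param df data frame.
#' @param type one of `"behavior"`, `"eggs"`, `"beans"`, `"fecundity"`.
#' @return the validated data frame, columns in schema order.
#' @export
validate_dataset <- function(df, type = names(dataset_schemas)) {
  type <- match.arg(type)
  sch <- dataset_schemas[[type]]
  missing <- setdiff(sch$columns, names(df))
  if (length(missing))
    schema_fail(type, paste("missing column(s):",
                            paste(missing, collapse = ", ")))
  extra <- setdiff(names(df), sch$columns)
  if (length(extra))
    schema_fail(type, paste("unexpected column(s):",
                            paste(extra, collapse = ", ")))
  df <- df[, sch$columns]
  for (col in sch$columns) {
    x <- df[[col]]
    if (anyNA(x))
      schema_fail(type, paste0("missing values in '", col, "'"),
                  row = which(is.na(x))[1])
    if (col %in% sch$integer) {
      if (!is.numeric(x) || any(x != round(x)))
        schema_fail(type, paste0("non-integer values in '", col, "'"),
                    row = which(x != round(x))[1])
      if (any(x < 0))
        schema_fail(type, paste0("negative values in '", col, "'"),
                    row = which(x < 0)[1])
      df[[col]] <- as.integer(x)
    } else {
      df[[col]] <- as.character(x)
    }
  }
  if (type == "behavior") {
    bad <- which(df$n_on_uninfested > df$n_females)
    if (length(bad))
      schema_fail(type, "n_on_uninfested exceeds n_females", row = bad[1])
    if (any(df$n_females < 1))
      schema_fail(type, "n_females must be >= 1",
                  row = which(df$n_females < 1)[1])
  }
  if (type == "beans") {
    bad <- which(df$n_focal_emerged > df$n_focal_eggs)
    if (length(bad))
      schema_fail(type, "n_focal_emerged exceeds n_focal_eggs", row = bad[1])
  }
  df
}

#' Read a dataset CSV
#'
#' @param path CSV file with a header row.
#' @param type schema name (see [validate_dataset()]).
#' @return validated data frame.
#' @export
read_dataset <- function(path, type = names(dataset_schemas)) {
  type <- match.arg(type)
  if (!file.exists(path))
    stop_cueload(paste0("file not found: ", path), "cueload_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = TRUE)
  sch <- dataset_schemas[[type]]
  if (!setequal(names(df), sch$columns))
    schema_fail(type, paste0(
      "header mismatch; expected columns ",
      paste(sch$columns, collapse = ", ")))
  for (col in sch$integer) {
    xi <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(xi))
      schema_fail(type, paste0("non-numeric values in '", col, "'"),
                  row = which(is.na(xi))[1])
    df[[col]] <- xi
  }
  validate_dataset(df, type)
}

#' Write a dataset CSV
#'
#' @param df data frame conforming to the schema.
#' @param path output path.
#' @param type schema name.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(df, path, type = names(dataset_schemas)) {
  type <- match.arg(type)
  df <- validate_dataset(df, type)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Prepare bean records for the survival analysis
#'
#' Applies the published cleaning rule - beans with more than
#' `max_focal_eggs` focal eggs are discarded - and drops beans that
#' received no focal eggs (they carry no survival information). Attaches
#' the competition covariate experienced by each focal egg,
#' `C = n_focal_eggs + n_competitor_eggs - 1`, so a lone egg on an
#' uninfested seed has `C = 0` and the design maximum (3 focal + 4
#' competitor eggs) has `C = 6`. Removed-row counts are logged by cross
#' type; `rows_in = rows_out + rows_removed` always holds.
#'
#' @param bean_table bean records (schema `"beans"`).
#' @param max_focal_eggs retention threshold (default 3).
#' @return list with `data` (cleaned table plus column `C`) and
#'   `filter_log` (data frame of removal counts by reason and cross type).
#' @export
prepare_survival <- function(bean_table, max_focal_eggs = 3) {
  df <- validate_dataset(bean_table, "beans")
  over <- df$n_focal_eggs > max_focal_eggs
  none <- df$n_focal_eggs == 0
  log_tab <- expand.grid(
    reason = c("over_max_focal_eggs", "no_focal_eggs"),
    cross_type = sort(unique(df$cross_type)),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  log_tab$removed <- mapply(function(r, ct) {
    flag <- if (r == "over_max_focal_eggs") over else none
    sum(flag & df$cross_type == ct)
  }, log_tab$reason, log_tab$cross_type)
  keep <- df[!over & !none, , drop = FALSE]
  keep$C <- keep$n_focal_eggs + keep$n_competitor_eggs - 1L
  rownames(keep) <- NULL
  list(data = keep, filter_log = log_tab,
       rows_in = nrow(df), rows_out = nrow(keep),
       rows_removed = sum(over | none))
}
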