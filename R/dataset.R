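#' Snapshot time-series datasets
#'
#' A snapshot dataset holds measurements `y_ij` of individual `i` at time
#' `t_j`, in long form: one row per (individual, time, observable) triple.
#' Individuals need not share measurement times; in the extreme every
#' individual is measured exactly once (a snapshot design). The matrix view
#' ([to_matrix()]) has one row per individual and one column per unique time,
#' with `NA` marking absent combinations; missing entries contribute nothing
#' to any likelihood.
#'
#' @param id character or coercible; individual identifiers.
#' @param time numeric, non-negative measurement times.
#' @param value numeric measurement values (finite).
#' @param observable character observable names; defaults to a single
#'   observable `"value"`.
#' @param covariate optional per-individual covariate (e.g. a cancer-variant
#'   indicator); must be constant within an individual.
#'
#' @return An object of class `snapshot_dataset`: a list with elements
#'   `records` (data.frame with columns `id`, `time`, `observable`, `value`
#'   and optionally `covariate`), `ids` (lexicographically sorted unique
#'   ids), `times` (strictly increasing unique times), `observables`, and
#'   `n_individuals`.
#' @export
snapshot_dataset <- function(id, time, value, observable = NULL,
                             covariate = NULL) {
  n <- length(value)
  if (is.null(observable)) observable <- rep("value", n)
  if (length(observable) == 1L && n > 1L) observable <- rep(observable, n)
  id <- as.character(id)
  time <- as.numeric(time)
  value <- as.numeric(value)
  stopifnot(length(id) == n, length(time) == n, length(observable) == n)

  keep <- !is.na(value)
  records <- data.frame(id = id[keep], time = time[keep],
                        observable = as.character(observable)[keep],
                        value = value[keep], stringsAsFactors = FALSE)
  if (!is.null(covariate)) {
    covariate <- covariate[keep]
    records$covariate <- covariate
  }
  validate_snapshot_records(records)
  structure(
    list(records = records,
         ids = sort(unique(records$id)),
         times = sort(unique(records$time)),
         observables = sort(unique(records$observable)),
         n_individuals = length(unique(records$id))),
    class = "snapshot_dataset")
}

validate_snapshot_records <- function(records) {
  if (nrow(records) == 0L) stop("dataset contains no measurements")
  if (any(!is.finite(records$value))) stop("non-finite measurement values")
  if (any(!is.finite(records$time)) || any(records$time < 0))
    stop("measurement times must be finite and non-negative")
  key <- paste(records$id, records$time, records$observable, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (id, time, observable) measurement rows")
  if (!is.null(records$covariate)) {
    per_id <- tapply(records$covariate, records$id,
                     function(x) length(unique(x)))
    if (any(per_id > 1L)) stop("covariate must be constant within individual")
  }
  invisible(records)
}

#' @export
print.snapshot_dataset <- function(x, ...) {
  cat(sprintf(
    "snapshot_dataset: %d measurements, %d individuals, %d time(s), %d observable(s)\n",
    nrow(x$records), x$n_individuals, length(x$times), length(x$observables)))
  invisible(x)
}

#' Read a snapshot dataset from long-format CSV
#'
#' The canonical on-disk format is a long CSV with header columns `ID`,
#' `Time`, `Value` and optionally `Observable` (required when more than one
#' observable is present) and `Covariate`. Rows with a missing `Value` are
#' skipped (they count as `NA` cells of the matrix view).
#'
#' @param path path to a CSV file.
#' @return A [snapshot_dataset()].
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L) stop("empty dataset file: ", path)
  names(df) <- tolower(names(df))
  required <- c("id", "time", "value")
  if (!all(required %in% names(df)))
    stop("CSV must have columns ID, Time, Value (Observable optional)")
  parse_num <- function(x, col, allow_missing) {
    num <- suppressWarnings(as.numeric(x))
    missing_ok <- is.na(x) | trimws(x) %in% c("", "NA", "na")
    bad <- is.na(num) & !missing_ok
    if (any(bad))
      stop("malformed numeric field in column ", col, ": '",
           x[which(bad)[1L]], "'")
    if (!allow_missing && any(missing_ok))
      stop("missing values not allowed in column ", col)
    num
  }
  time <- parse_num(df$time, "Time", allow_missing = FALSE)
  value <- parse_num(df$value, "Value", allow_missing = TRUE)
  covariate <- if ("covariate" %in% names(df))
    parse_num(df$covariate, "Covariate", allow_missing = FALSE)
  snapshot_dataset(id = df$id, time = time, value = value,
                   observable = if ("observable" %in% names(df)) df$observable,
                   covariate = covariate)
}

#' Write a snapshot dataset to long-format CSV
#'
#' @param d a [snapshot_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(d, path) {
  stopifnot(inherits(d, "snapshot_dataset"))
  out <- data.frame(ID = d$records$id, Time = d$records$time,
                    Observable = d$records$observable,
                    Value = d$records$value)
  if (!is.null(d$records$covariate)) out$Covariate <- d$records$covariate
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Matrix view of a snapshot dataset
#'
#' Arranges the measurements of one observable as an N x K matrix with rows
#' ordered by lexicographic individual id and columns by ascending time;
#' absent (id, time) combinations are `NA`.
#'
#' @param d a [snapshot_dataset()].
#' @param observable observable name; defaults to the single observable.
#' @return A list with `matrix` (N x K, dimnames id/time) and `times`.
#' @export
to_matrix <- function(d, observable = NULL) {
  stopifnot(inherits(d, "snapshot_dataset"))
  if (is.null(observable)) {
    if (length(d$observables) > 1L)
      stop("dataset has several observables; name one")
    observable <- d$observables
  }
  if (!observable %in% d$observables)
    stop("unknown observable: ", observable)
  rec <- d$records[d$records$observable == observable, , drop = FALSE]
  mat <- matrix(NA_real_, nrow = length(d$ids), ncol = length(d$times),
                dimnames = list(d$ids, as.character(d$times)))
  i <- match(rec$id, d$ids)
  j <- match(rec$time, d$times)
  mat[cbind(i, j)] <- rec$value
  list(matrix = mat, times = d$times)
}

#' Per-individual covariates of a dataset
#'
#' @param d a [snapshot_dataset()].
#' @return Named vector of covariates in `d$ids` order, or `NULL` when the
#'   dataset carries no covariate column.
#' @export
dataset_covariates <- function(d) {
  stopifnot(inherits(d, "snapshot_dataset"))
  if (is.null(d$records$covariate)) return(NULL)
  cov <- tapply(d$records$covariate, d$records$id, function(x) x[[1L]])
  cov[d$ids]
}

# Group measurement values by (time index, observable) for likelihood code.
# Returns a list indexed [[obs]][[j]] of numeric vectors (possibly empty).
dataset_by_time <- function(d) {
  out <- lapply(d$observables, function(o) {
    rec <- d$records[d$records$observable == o, , drop = FALSE]
    lapply(seq_along(d$times), function(j)
      rec$value[rec$time == d$times[j]])
  })
  names(out) <- d$observables
  out
}
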