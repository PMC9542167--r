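#' Participant-level 2x2 factorial trial data
#'
#' A `trial_data` object holds one record per participant: an identifier,
#' 0/1 indicators for treatments A and B (`z_a`, `z_b`) and the outcome `y`.
#' Treatment coding is fixed at 0/1 by design: factor-level remapping is a
#' classic source of silent sign errors in treatment contrasts, so it is
#' simply not supported.
#'
#' @param z_a,z_b integer/numeric vectors of 0/1 treatment indicators.
#' @param y numeric outcome vector; must be 0/1 when `outcome_type` is
#'   `"binary"`.
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param id optional character identifiers; generated (`"1"`, `"2"`, ...)
#'   when absent.
#'
#' @return An object of class `trial_data`: a `data.frame` with columns
#'   `id`, `z_a`, `z_b`, `y` and attribute `outcome_type`.
#' @examples
#' d <- trial_data(z_a = c(0, 1, 0, 1), z_b = c(0, 0, 1, 1),
#'                 y = c(0, 1, 1, 0), outcome_type = "binary")
#' cross_tabulate(d)
#' @export
trial_data <- function(z_a, z_b, y, outcome_type = c("binary", "continuous"),
                       id = NULL) {
  outcome_type <- match.arg(outcome_type)
  n <- length(y)
  if (length(z_a) != n || length(z_b) != n)
    stop("z_a, z_b and y must have equal length")
  if (is.null(id)) id <- as.character(seq_len(n))
  id <- as.character(id)
  bad_a <- which(!(z_a %in% c(0, 1)))
  if (length(bad_a))
    stop("z_a must be 0/1; offending row(s): ",
         paste(utils::head(bad_a, 5), collapse = ", "))
  bad_b <- which(!(z_b %in% c(0, 1)))
  if (length(bad_b))
    stop("z_b must be 0/1; offending row(s): ",
         paste(utils::head(bad_b, 5), collapse = ", "))
  if (!is.numeric(y) || any(!is.finite(y)))
    stop("y must be finite numeric (drop missing outcomes before construction)")
  if (outcome_type == "binary" && !is_binary01(y))
    stop("outcome_type = \"binary\" requires y in {0, 1}")
  out <- data.frame(id = id, z_a = as.integer(z_a), z_b = as.integer(z_b),
                    y = as.numeric(y), stringsAsFactors = FALSE)
  structure(out, outcome_type = outcome_type,
            class = c("trial_data", "data.frame"))
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("2x2 factorial trial data: %d participants, %s outcome\n",
              nrow(x), outcome_type(x)))
  print(as.data.frame(cross_tabulate(x)), row.names = FALSE)
  invisible(x)
}

#' Outcome type of a trial dataset
#' @param data a `trial_data` object.
#' @return `"binary"` or `"continuous"`.
#' @export
outcome_type <- function(data) attr(data, "outcome_type")

#' Read a factorial trial dataset from CSV
#'
#' Expects a comma-separated, UTF-8 file with a header containing columns
#' `z_a`, `z_b` and `y` (matched by name, not position); an `id` column is
#' optional.  Rows with missing `y` are dropped (complete-case analysis under
#' a treatment-policy view of the observed data) and the number dropped is
#' reported via `message()`.
#'
#' @param path path to the CSV file.
#' @param outcome_type `"binary"` or `"continuous"`.
#' @return A [trial_data] object.
#' @export
read_trial_csv <- function(path, outcome_type = c("binary", "continuous")) {
  outcome_type <- match.arg(outcome_type)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("z_a", "z_b", "y")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("CSV is missing required column(s): ", paste(miss, collapse = ", "))
  if (!"id" %in% names(raw)) raw$id <- as.character(seq_len(nrow(raw)))
  for (col in c("z_a", "z_b")) {
    v <- raw[[col]]
    bad <- which(is.na(v) | !(v %in% c(0, 1)))
    if (length(bad))
      stop(sprintf("column %s must be 0/1; offending row %d (value %s)",
                   col, bad[1], as.character(v[bad[1]])))
  }
  dropped <- sum(is.na(raw$y))
  if (dropped > 0) {
    message("dropped ", dropped, " row(s) with missing outcome")
    raw <- raw[!is.na(raw$y), , drop = FALSE]
  }
  if (outcome_type == "binary" && !is_binary01(raw$y)) {
    bad <- which(!(raw$y %in% c(0, 1)))
    stop(sprintf("binary outcome must be 0/1; offending row %d (value %s)",
                 bad[1], as.character(raw$y[bad[1]])))
  }
  trial_data(z_a = raw$z_a, z_b = raw$z_b, y = raw$y,
             outcome_type = outcome_type, id = raw$id)
}

#' Write a factorial trial dataset to CSV
#'
#' The written file round-trips through [read_trial_csv()] preserving all
#' records exactly.
#'
#' @param data a [trial_data] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  stopifnot(inherits(data, "trial_data"))
  df <- as.data.frame(data)[, c("id", "z_a", "z_b", "y")]
  df$y <- sprintf("%.17g", df$y)  # bit-exact numeric round-trip
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-tabulate a factorial trial dataset by treatment cell
#'
#' Summarizes the four (z_a, z_b) cells: sample size per cell, plus event
#' counts for binary outcomes or outcome sums and sums of squares for
#' continuous outcomes.  Invariant to record order; cells with no records
#' get a zero count.
#'
#' @param data a [trial_data] object (non-empty).
#' @return A `cell_counts` object: a `data.frame` with one row per cell
#'   `(z_a, z_b)` in the order (0,0), (1,0), (0,1), (1,1).
#' @export
cross_tabulate <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  if (nrow(data) == 0) stop("empty dataset")
  grid <- data.frame(z_a = c(0L, 1L, 0L, 1L), z_b = c(0L, 0L, 1L, 1L))
  out <- grid
  out$n <- mapply(function(a, b) sum(data$z_a == a & data$z_b == b),
                  grid$z_a, grid$z_b)
  if (outcome_type(data) == "binary") {
    out$events <- mapply(function(a, b) sum(data$y[data$z_a == a & data$z_b == b]),
                         grid$z_a, grid$z_b)
  } else {
    out$sum <- mapply(function(a, b) sum(data$y[data$z_a == a & data$z_b == b]),
                      grid$z_a, grid$z_b)
    out$sumsq <- mapply(function(a, b) sum(data$y[data$z_a == a & data$z_b == b]^2),
                        grid$z_a, grid$z_b)
  }
  structure(out, outcome_type = outcome_type(data),
            class = c("cell_counts", "data.frame"))
}

#' @export
print.cell_counts <- function(x, ...) {
  cat("Cell counts (2x2 factorial):\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Serialize cell counts to JSON
#' @param counts a `cell_counts` object from [cross_tabulate()].
#' @return A JSON string (one object per cell).
#' @export
cell_counts_json <- function(counts) {
  stopifnot(inherits(counts, "cell_counts"))
  jsonlite::toJSON(as.data.frame(counts), dataframe = "rows", digits = NA,
                   auto_unbox = TRUE)
}
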