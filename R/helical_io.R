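#' Construct a helical-parameter ensemble
#'
#' A `helical_ensemble` is a labelled sample of one helical parameter for a
#' single (base-pair step, parameter, dataset origin) triple: the atomic unit
#' all fitting and classification functions operate on.
#'
#' @param values Numeric vector of parameter values (Angstrom for shift,
#'   slide, rise; degrees for tilt, roll, twist).
#' @param step_type One of the 10 unique dinucleotide steps
#'   (`"AA"`, `"AC"`, `"AG"`, `"AT"`, `"CC"`, `"CG"`, `"GA"`, `"GC"`, `"GG"`,
#'   `"TA"`).
#' @param parameter One of `"shift"`, `"slide"`, `"rise"`, `"tilt"`,
#'   `"roll"`, `"twist"`.
#' @param origin Dataset origin: `"md"`, `"xray_naked"`, `"xray_protein"` or
#'   `"xray_intercalator"`.
#' @param time Optional numeric vector of timestamps in ns (MD series);
#'   must be non-negative and strictly increasing.
#' @param context Optional free-text tetranucleotide context label.
#' @return An object of class `helical_ensemble`: a list with elements
#'   `values`, `step_type`, `parameter`, `origin`, `time`, `context`, `n`.
#' @examples
#' ens <- helical_ensemble(rnorm(100, 34, 4), "CG", "twist", "md")
#' ens$n
#' @export
helical_ensemble <- function(values, step_type, parameter, origin,
                             time = NULL, context = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("ensemble must contain at least one value")
  if (anyNA(values) || any(!is.finite(values)))
    stop("ensemble values must be finite")
  step_type <- match.arg(step_type, HELICAL_STEPS)
  parameter <- match.arg(parameter, HELICAL_PARAMETERS)
  origin <- match.arg(origin, HELICAL_ORIGINS)
  if (!is.null(time)) {
    time <- as.numeric(time)
    if (length(time) != length(values))
      stop("time must have one entry per value")
    if (any(time < 0)) stop("time must be non-negative")
    if (any(diff(time) <= 0))
      stop("time must be strictly increasing within a series")
  }
  structure(
    list(values = values, step_type = step_type, parameter = parameter,
         origin = origin, time = time, context = context,
         n = length(values)),
    class = "helical_ensemble")
}

#' @export
print.helical_ensemble <- function(x, ...) {
  cat(sprintf("<helical_ensemble> %s/%s [%s], n = %d\n",
              x$step_type, x$parameter, x$origin, x$n))
  cat(sprintf("  mean = %.4g, sd = %.4g", mean(x$values), sd(x$values)))
  if (!is.null(x$time))
    cat(sprintf(", span = %.4g ns", diff(range(x$time))))
  cat("\n")
  invisible(x)
}

#' Read helical-parameter tables
#'
#' Reads a long-format TSV/CSV table (columns `step_type`, `parameter`,
#' `value`, `origin`, optional `context` and `time_ns`) or a Curves+-style
#' `.ser` series file (whitespace-separated matrix, one row per snapshot, one
#' column per base-pair step) and returns one [helical_ensemble()] per
#' (step_type, parameter, origin) triple found.
#'
#' Malformed numeric fields are dropped with a warning naming the offending
#' line numbers; the remaining records are loaded.
#'
#' @param path Path to the input file.
#' @param dialect `"tsv"`, `"csv"` or `"curves_ser"`.
#' @param parameter,step_types,origin For `curves_ser` only (the format
#'   carries no labels): the parameter the file holds, the step label for each
#'   column, and the dataset origin (default `"md"`).
#' @param dt For `curves_ser`: snapshot spacing in ns; when given, rows are
#'   timestamped `0, dt, 2*dt, ...`.
#' @return A list of `helical_ensemble` objects, named
#'   `"<step>/<parameter>/<origin>"`.
#' @seealso [write_helical_table()]
#' @export
read_helical_table <- function(path, dialect = c("tsv", "csv", "curves_ser"),
                               parameter = NULL, step_types = NULL,
                               origin = "md", dt = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "curves_ser")
    return(read_curves_ser(path, parameter, step_types, origin, dt))
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE, comment.char = "")
  if (nrow(df) == 0L) stop("empty input: ", path)
  required <- c("step_type", "parameter", "value", "origin")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  value <- suppressWarnings(as.numeric(df$value))
  bad <- is.na(value) | !is.finite(value)
  if (any(bad)) {
    # +1 for the header line: report file line numbers, not row indices
    warning(sprintf("dropped %d malformed value(s) at line(s) %s",
                    sum(bad),
                    paste(which(bad) + 1L, collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
    value <- value[!bad]
  }
  if (nrow(df) == 0L) stop("no valid records in ", path)
  df$value <- value
  time <- if ("time_ns" %in% names(df)) suppressWarnings(as.numeric(df$time_ns)) else NULL
  key <- interaction(df$step_type, df$parameter, df$origin, drop = TRUE)
  out <- lapply(split(seq_len(nrow(df)), key), function(i) {
    helical_ensemble(df$value[i], df$step_type[i][1L], df$parameter[i][1L],
                     df$origin[i][1L],
                     time = if (!is.null(time)) time[i] else NULL,
                     context = if ("context" %in% names(df)) df$context[i][1L] else NULL)
  })
  names(out) <- vapply(out, function(e)
    paste(e$step_type, e$parameter, e$origin, sep = "/"), character(1))
  out
}

read_curves_ser <- function(path, parameter, step_types, origin, dt) {
  if (is.null(parameter) || is.null(step_types))
    stop("curves_ser dialect needs 'parameter' and 'step_types' labels")
  mat <- as.matrix(utils::read.table(path, header = FALSE))
  if (nrow(mat) == 0L) stop("empty input: ", path)
  if (ncol(mat) == length(step_types) + 1L)
    mat <- mat[, -1L, drop = FALSE]  # leading snapshot-index column
  if (ncol(mat) != length(step_types))
    stop(sprintf("expected %d step columns, found %d",
                 length(step_types), ncol(mat)))
  time <- if (!is.null(dt)) (seq_len(nrow(mat)) - 1L) * dt else NULL
  out <- lapply(seq_along(step_types), function(j)
    helical_ensemble(mat[, j], step_types[j], parameter, origin, time = time))
  names(out) <- paste(step_types, parameter, origin, sep = "/")
  out
}

#' Write ensembles to a long-format TSV
#'
#' Values are printed with 17 significant digits so that a
#' write/[read_helical_table()] round trip reproduces every double exactly.
#'
#' @param ensembles A `helical_ensemble` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_helical_table <- function(ensembles, path) {
  if (inherits(ensembles, "helical_ensemble")) ensembles <- list(ensembles)
  has_time <- any(vapply(ensembles, function(e) !is.null(e$time), logical(1)))
  rows <- lapply(ensembles, function(e) {
    df <- data.frame(step_type = e$step_type, parameter = e$parameter,
                     value = sprintf("%.17g", e$values), origin = e$origin,
                     context = if (is.null(e$context)) "" else e$context,
                     stringsAsFactors = FALSE)
    if (has_time)
      df$time_ns <- if (is.null(e$time)) "" else sprintf("%.17g", e$time)
    df
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove anomalous records beyond k standard deviations
#'
#' Single-pass curation filter: the mean and standard deviation are computed
#' once on the input ensemble, and exactly the records with
#' `|value - mean| <= k_sd * sd` are retained. The filter is applied once; it
#' is deliberately not iterated with re-estimated moments.
#'
#' @param ens A [helical_ensemble()] with at least 2 records.
#' @param k_sd Positive cut-off in standard deviations (default 3).
#' @return A list with `ensemble` (the curated [helical_ensemble()]) and
#'   `removed_count`.
#' @examples
#' ens <- helical_ensemble(c(rnorm(50), 25), "CG", "twist", "md")
#' filter_outliers(ens)$removed_count
#' @export
filter_outliers <- function(ens, k_sd = 3) {
  stopifnot(inherits(ens, "helical_ensemble"), k_sd > 0)
  if (ens$n < 2L) stop("need at least 2 records to estimate moments")
  m <- mean(ens$values)
  s <- sd(ens$values)
  keep <- abs(ens$values - m) <= k_sd * s   # s == 0: all identical, all kept
  out <- helical_ensemble(ens$values[keep], ens$step_type, ens$parameter,
                          ens$origin,
                          time = if (!is.null(ens$time)) ens$time[keep] else NULL,
                          context = ens$context)
  list(ensemble = out, removed_count = ens$n - out$n)
}

#' Randomly subsample an ensemble without replacement
#'
#' Mirrors the random extraction of a fixed number of snapshots per base-pair
#' step from a large aggregated ensemble before the statistical tests. When
#' `m >= n` the ensemble is returned unchanged.
#'
#' @param ens A [helical_ensemble()].
#' @param m Target sample size (positive integer).
#' @param seed Integer seed; identical seeds give identical subsets.
#' @return A [helical_ensemble()] with `min(m, n)` records.
#' @export
subsample_ensemble <- function(ens, m, seed) {
  stopifnot(inherits(ens, "helical_ensemble"), m >= 1)
  if (m >= ens$n) return(ens)
  idx <- sort(with_seed(seed, sample.int(ens$n, m)))
  helical_ensemble(ens$values[idx], ens$step_type, ens$parameter, ens$origin,
                   time = if (!is.null(ens$time)) ens$time[idx] else NULL,
                   context = ens$context)
}

#' Curate a set of ensembles
#'
#' Applies the k-SD anomalous-record filter (by default to the X-ray origins
#' only, the curation the structural database receives) and an optional random
#' subsample, returning the curated ensembles plus a machine-readable log.
#'
#' @param ensembles List of [helical_ensemble()] objects.
#' @param k_sd SD cut-off for the outlier filter.
#' @param filter_origins Origins the filter applies to.
#' @param subsample_m Optional subsample size per ensemble (`NULL` = keep all).
#' @param seed Seed for subsampling.
#' @return List with `ensembles` and `log` (one entry per ensemble:
#'   `n_in`, `n_out`, `removed_count`, `k_sd`, `seed`).
#' @export
curate_ensembles <- function(ensembles, k_sd = 3,
                             filter_origins = c("xray_naked", "xray_protein",
                                                "xray_intercalator"),
                             subsample_m = NULL, seed = 1L) {
  log <- list()
  out <- lapply(seq_along(ensembles), function(i) {
    e <- ensembles[[i]]
    n_in <- e$n
    removed <- 0L
    if (e$origin %in% filter_origins && e$n >= 2L) {
      f <- filter_outliers(e, k_sd)
      e <- f$ensemble
      removed <- f$removed_count
    }
    if (!is.null(subsample_m))
      e <- subsample_ensemble(e, subsample_m, seed + i)
    log[[i]] <<- list(key = paste(e$step_type, e$parameter, e$origin, sep = "/"),
                      n_in = n_in, n_out = e$n, removed_count = removed,
                      k_sd = k_sd, seed = seed)
    e
  })
  names(out) <- names(ensembles)
  list(ensembles = out, log = log)
}
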