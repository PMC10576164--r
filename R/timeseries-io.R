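#' Construct a RhythmDataset
#'
#' @param times numeric vector of observation times in hours; need not be
#'   evenly spaced but must be strictly increasing after sorting.
#' @param values numeric vector (single replicate) or matrix with one column
#'   per replicate; `NA` marks missing observations. Rows are reordered along
#'   with `times`.
#' @param noiseVar optional per-time-point measurement variances (>= 0).
#' @param label free-text identifier.
#' @param dropEmpty drop time points at which every replicate is missing
#'   (default `TRUE`); with `FALSE` such rows raise a validity error.
#' @return a [RhythmDataset-class] object.
#' @examples
#' ds <- RhythmDataset(seq(0, 48, by = 3), sin(2 * pi * seq(0, 48, by = 3) / 24))
#' nTimePoints(ds)
#' @export
RhythmDataset <- function(times, values, noiseVar = numeric(0),
                          label = NA_character_, dropEmpty = TRUE) {
  if (!is.numeric(times)) stop("times must be numeric")
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(times))
    stop("values must have one row per time point")
  ord <- order(times)
  times <- times[ord]
  values <- values[ord, , drop = FALSE]
  if (length(noiseVar)) noiseVar <- noiseVar[ord]
  if (anyDuplicated(times))
    stop("duplicate time points; merge replicates into columns instead")
  if (dropEmpty) {
    keep <- rowSums(!is.na(values)) > 0L
    times <- times[keep]
    values <- values[keep, , drop = FALSE]
    if (length(noiseVar)) noiseVar <- noiseVar[keep]
  }
  new("RhythmDataset", times = as.numeric(times), values = values,
      noiseVar = as.numeric(noiseVar), label = as.character(label)[1L])
}

#' @describeIn RhythmDataset-accessors observation times (hours).
#' @param x a `RhythmDataset`.
#' @name RhythmDataset-accessors
#' @aliases obsTimes obsValues noiseVar datasetLabel nReplicates nTimePoints
#' @export
setMethod("obsTimes", "RhythmDataset", function(x) x@times)

#' @rdname RhythmDataset-accessors
#' @export
setMethod("obsValues", "RhythmDataset", function(x) x@values)

#' @rdname RhythmDataset-accessors
#' @export
setMethod("noiseVar", "RhythmDataset", function(x) x@noiseVar)

#' @rdname RhythmDataset-accessors
#' @export
setMethod("datasetLabel", "RhythmDataset", function(x) x@label)

#' @rdname RhythmDataset-accessors
#' @export
setMethod("nReplicates", "RhythmDataset", function(x) ncol(x@values))

#' @rdname RhythmDataset-accessors
#' @export
setMethod("nTimePoints", "RhythmDataset", function(x) length(x@times))

setMethod("show", "RhythmDataset", function(object) {
  cat(sprintf("RhythmDataset '%s': %d time points x %d replicate(s), %g-%g h%s\n",
              object@label, length(object@times), ncol(object@values),
              min(object@times), max(object@times),
              if (length(object@noiseVar)) ", with noise variances" else ""))
  nmiss <- sum(is.na(object@values))
  if (nmiss > 0L) cat(sprintf("  %d missing value(s)\n", nmiss))
})

.missing_markers <- c("", "NA", "NaN", "na", "nan")

.parse_numeric_col <- function(x, what, allowNA = TRUE) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""  # read.csv may have eaten literal NA markers already
  out <- suppressWarnings(as.numeric(x))
  isMissing <- x %in% .missing_markers
  bad <- which(is.na(out) & !isMissing)
  if (length(bad))
    stop(sprintf("non-numeric %s at row %d: '%s'", what, bad[1L], x[bad[1L]]))
  if (!allowNA && any(isMissing))
    stop(sprintf("missing value not allowed in %s (row %d)", what,
                 which(isMissing)[1L]))
  out[isMissing] <- NA_real_
  out
}

#' Read a replicated time series from a delimited text file
#'
#' Two layouts are supported. Wide: a header row, first column named `time`,
#' remaining columns one per replicate (an optional trailing `noise_var`
#' column carries per-time-point measurement variances). Long: columns
#' `time`, `replicate`, `value`. Cells that are empty, `NA` or `NaN` are
#' treated as missing. The field separator is inferred from the file
#' extension (`.tsv` = tab) unless given.
#'
#' @param path file path.
#' @param layout `"wide"` (default) or `"long"`.
#' @param sep field separator; default `","`, or `"\t"` for `.tsv` files.
#' @param label dataset label; defaults to the file name.
#' @return a validated [RhythmDataset-class]; times sorted ascending, missing
#'   cells preserved as `NA`.
#' @export
readTimeseries <- function(path, layout = c("wide", "long"), sep = NULL,
                           label = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  if (is.null(label)) label <- basename(path)
  raw <- read.csv(path, sep = sep, header = TRUE, colClasses = "character",
                  check.names = FALSE, fileEncoding = "UTF-8")
  if (layout == "wide") {
    if (ncol(raw) < 2L)
      stop("wide layout needs a time column plus at least one replicate column")
    if (tolower(names(raw)[1L]) != "time")
      stop("wide layout requires the first column to be named 'time', got '",
           names(raw)[1L], "'")
    times <- .parse_numeric_col(raw[[1L]], "time column", allowNA = FALSE)
    nv <- numeric(0)
    repCols <- seq(2L, ncol(raw))
    if (tolower(names(raw)[ncol(raw)]) == "noise_var") {
      nv <- .parse_numeric_col(raw[[ncol(raw)]], "noise_var column",
                               allowNA = FALSE)
      repCols <- repCols[-length(repCols)]
      if (length(repCols) == 0L) stop("no replicate columns found")
    }
    vals <- sapply(repCols, function(j)
      .parse_numeric_col(raw[[j]], sprintf("column '%s'", names(raw)[j])))
    vals <- matrix(vals, nrow = length(times))
    colnames(vals) <- names(raw)[repCols]
    allMissing <- colSums(!is.na(vals)) == 0L
    if (any(allMissing))
      stop("column '", colnames(vals)[which(allMissing)[1L]],
           "' contains no observed values")
  } else {
    need <- c("time", "replicate", "value")
    if (!all(need %in% tolower(names(raw))))
      stop("long layout requires columns 'time', 'replicate', 'value'")
    names(raw) <- tolower(names(raw))
    times_all <- .parse_numeric_col(raw$time, "time column", allowNA = FALSE)
    value_all <- .parse_numeric_col(raw$value, "value column")
    rep_all <- as.character(raw$replicate)
    times <- sort(unique(times_all))
    reps <- unique(rep_all)
    vals <- matrix(NA_real_, length(times), length(reps),
                   dimnames = list(NULL, reps))
    vals[cbind(match(times_all, times), match(rep_all, reps))] <- value_all
    nv <- numeric(0)
  }
  if (length(unique(times)) < 4L)
    stop("fewer than 4 distinct time points; too short to fit")
  RhythmDataset(times, vals, noiseVar = nv, label = label)
}

#' Write a RhythmDataset to a wide CSV file
#'
#' Emits the wide dialect read by [readTimeseries()]: a `time` column, one
#' column per replicate, and a trailing `noise_var` column when variances are
#' present. Values round-trip exactly (full double precision).
#'
#' @param ds a [RhythmDataset-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTimeseries <- function(ds, path) {
  stopifnot(is(ds, "RhythmDataset"))
  vals <- obsValues(ds)
  if (is.null(colnames(vals)))
    colnames(vals) <- paste0("rep", seq_len(ncol(vals)))
  df <- data.frame(time = obsTimes(ds), vals, check.names = FALSE)
  if (length(noiseVar(ds))) df$noise_var <- noiseVar(ds)
  # format() at 17 significant digits keeps the text round-trip exact
  out <- vapply(df, function(col) format(col, digits = 17, trim = TRUE,
                                         scientific = FALSE), character(nrow(df)))
  out <- matrix(out, nrow = nrow(df))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(apply(out, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Normalize a dataset
#'
#' `zscore` subtracts the grand mean of all non-missing values and divides by
#' their standard deviation (population convention, denominator n); `center`
#' subtracts the grand mean only; `none` returns the input unchanged. Any
#' measurement variances are rescaled by the squared divisor.
#'
#' @param ds a [RhythmDataset-class].
#' @param method `"zscore"` (default), `"center"` or `"none"`.
#' @return the normalized [RhythmDataset-class].
#' @export
normalizeDataset <- function(ds, method = c("zscore", "center", "none")) {
  method <- match.arg(method)
  if (method == "none") return(ds)
  v <- obsValues(ds)
  obs <- v[!is.na(v)]
  mu <- mean(obs)
  if (method == "center") {
    v <- v - mu
    return(new("RhythmDataset", times = ds@times, values = v,
               noiseVar = ds@noiseVar, label = ds@label))
  }
  sdev <- sqrt(mean((obs - mu)^2))  # population (n) denominator
  if (sdev == 0)
    stop("zero variance: zscore undefined; use method 'center' or 'none'")
  v <- (v - mu) / sdev
  nv <- if (length(ds@noiseVar)) ds@noiseVar / sdev^2 else numeric(0)
  new("RhythmDataset", times = ds@times, values = v, noiseVar = nv,
      label = ds@label)
}

#' Collapse replicates to mean plus squared standard error, or stack them
#'
#' `mean_sem` (the default downstream of detection) replaces the replicates
#' at each time point by their mean and stores the squared standard error of
#' the mean (sample sd, denominator n-1, divided by sqrt(n)) in `noiseVar`;
#' a time point with a single surviving replicate gets variance 0 and the
#' learned kernel noise absorbs its scatter. `stack` flattens replicates into
#' repeated time entries, offsetting tied times by a negligible jitter so the
#' times stay strictly increasing (the kernel's diagonal noise handles the
#' effectively duplicated inputs).
#'
#' @param ds a [RhythmDataset-class].
#' @param mode `"mean_sem"` (default) or `"stack"`.
#' @return a single-replicate [RhythmDataset-class].
#' @export
collapseReplicates <- function(ds, mode = c("mean_sem", "stack")) {
  mode <- match.arg(mode)
  v <- obsValues(ds)
  if (mode == "mean_sem") {
    m <- rowMeans(v, na.rm = TRUE)
    nobs <- rowSums(!is.na(v))
    sem2 <- ifelse(nobs >= 2L,
                   apply(v, 1L, function(r) var(r, na.rm = TRUE)) / nobs,
                   0)
    # replicate SEM adds to any pre-existing measurement variance
    nv <- if (length(ds@noiseVar)) ds@noiseVar + sem2 else sem2
    new("RhythmDataset", times = ds@times, values = matrix(m, ncol = 1L),
        noiseVar = as.numeric(nv), label = ds@label)
  } else {
    long_t <- rep(ds@times, ncol(v))
    long_v <- as.vector(v)
    keep <- !is.na(long_v)
    long_t <- long_t[keep]
    long_v <- long_v[keep]
    ord <- order(long_t)
    long_t <- long_t[ord]
    long_v <- long_v[ord]
    dup <- duplicated(long_t)
    while (any(dup)) {  # tiny strictly-increasing offsets for tied times
      long_t[dup] <- long_t[dup] + 1e-9
      ord <- order(long_t)
      long_t <- long_t[ord]
      long_v <- long_v[ord]
      dup <- duplicated(long_t)
    }
    new("RhythmDataset", times = long_t, values = matrix(long_v, ncol = 1L),
        noiseVar = numeric(0), label = ds@label)
  }
}
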