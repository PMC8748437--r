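# Body-size time series from per-locality plate measurements.
#
# The unit of analysis is the assemblage: one dated locality with its
# lateral-arm-plate areas.  A series is the age-ordered (oldest first)
# collection of assemblages; per-event change statistics Delta are taken
# between two named assemblages bounding the event.

#' Construct an assemblage
#'
#' An assemblage is a dated locality together with its plate measurements
#' (areas in mm^2).  Either raw `areas` or the summary triple
#' (`n`, `mean_area`, `sd_area`) must be supplied; the Monte Carlo test only
#' needs the summary, so a series can be built straight from a published
#' locality table.
#'
#' @param locality Locality label (unique within a series).
#' @param age_ma Age in Ma before present (> 0; larger = older).
#' @param areas Numeric vector of plate areas in mm^2, or `NULL`.
#' @param n,mean_area,sd_area Summary statistics, used when `areas` is
#'   absent.  `sd_area` uses the sample (n-1) convention and is `NA` for
#'   `n = 1`.
#' @param stage Optional geological stage label.
#' @return An object of class `"assemblage"`.
#' @export
assemblage <- function(locality, age_ma, areas = NULL, n = NULL,
                       mean_area = NULL, sd_area = NULL, stage = NA_character_) {
  stopifnot(is.character(locality), length(locality) == 1L)
  if (!is.numeric(age_ma) || length(age_ma) != 1L || is.na(age_ma) || age_ma <= 0)
    stop("age_ma must be a single positive number (Ma before present) for locality '",
         locality, "'")
  if (!is.null(areas)) {
    # non-positive values are tolerated: simulated records draw from plain
    # normal distributions, so negatives are legitimate model output
    areas <- as.numeric(areas)
    if (anyNA(areas) || any(!is.finite(areas)))
      stop("non-finite area in locality '", locality, "'")
    n <- length(areas)
    mean_area <- if (n > 0L) mean(areas) else NA_real_
    sd_area <- if (n >= 2L) stats::sd(areas) else NA_real_
  } else {
    if (is.null(n) || is.null(mean_area))
      stop("either areas or (n, mean_area, sd_area) must be given for locality '",
           locality, "'")
    n <- as.integer(n)
    if (n < 1L) stop("n must be >= 1 for locality '", locality, "'")
    if (is.null(sd_area)) sd_area <- NA_real_
    if (n == 1L) sd_area <- NA_real_
  }
  structure(list(locality = locality, age_ma = age_ma, stage = stage,
                 areas = areas, n = n, mean_area = mean_area,
                 sd_area = sd_area),
            class = "assemblage")
}

#' Construct an assemblage series
#'
#' Orders assemblages oldest to youngest by `age_ma` regardless of input
#' order, and checks that locality labels are unique.
#'
#' @param assemblages List of [assemblage()] objects.
#' @return An object of class `"assemblage_series"` (a list of assemblages).
#' @export
assemblage_series <- function(assemblages) {
  stopifnot(is.list(assemblages), length(assemblages) >= 1L)
  ok <- vapply(assemblages, inherits, logical(1), "assemblage")
  if (!all(ok)) stop("all elements must be assemblage objects")
  loc <- vapply(assemblages, `[[`, character(1), "locality")
  if (anyDuplicated(loc))
    stop("duplicate locality label: ", loc[duplicated(loc)][1L])
  age <- vapply(assemblages, `[[`, numeric(1), "age_ma")
  assemblages <- unname(assemblages[order(-age)])  # oldest (largest age) first
  structure(assemblages, class = "assemblage_series")
}

#' @export
print.assemblage_series <- function(x, ...) {
  cat("assemblage series:", length(x), "localities,",
      sum(vapply(x, `[[`, integer(1), "n")), "measurements\n")
  print(series_summary(x), row.names = FALSE)
  invisible(x)
}

#' Build a series from a per-locality summary table
#'
#' @param df Data frame with columns `locality`, `age_ma`, `n`, `mean`
#'   (or `mean_area`), `sd` (or `sd_area`) and optionally `stage`.
#' @return An `assemblage_series`.
#' @export
series_from_summary <- function(df) {
  nm <- names(df)
  mean_col <- intersect(c("mean", "mean_area"), nm)[1]
  sd_col <- intersect(c("sd", "sd_area"), nm)[1]
  for (col in c("locality", "age_ma", "n")) {
    if (!col %in% nm) stop("summary table lacks required column '", col, "'")
  }
  if (is.na(mean_col)) stop("summary table lacks required column 'mean'")
  assemblage_series(lapply(seq_len(nrow(df)), function(i) {
    assemblage(locality = as.character(df$locality[i]), age_ma = df$age_ma[i],
               n = df$n[i], mean_area = df[[mean_col]][i],
               sd_area = if (is.na(sd_col)) NA_real_ else df[[sd_col]][i],
               stage = if ("stage" %in% nm) as.character(df$stage[i]) else NA_character_)
  }))
}

#' Plate surface area from length and width
#'
#' Average lateral-arm-plate surface area is the study's body-size proxy.
#' How "area" is derived from the two graphic measurements is a convention:
#' `"rectangle"` gives `length * width`, `"ellipse"` gives
#' `pi/4 * length * width`.  Both are fixed multiplicative rescalings of the
#' same quantity, so the permutation test's p-values do not depend on the
#' choice; `"rectangle"` is the default.
#'
#' @param length,width Plate dimensions in mm (> 0).
#' @param formula `"rectangle"` or `"ellipse"`.
#' @return Area in mm^2.
#' @export
#' @examples
#' plate_area(2, 1)                      # 2
#' plate_area(2, 1, "ellipse")           # pi/2
plate_area <- function(length, width, formula = c("rectangle", "ellipse")) {
  formula <- match.arg(formula)
  if (any(!is.finite(length)) || any(!is.finite(width)) ||
      any(length <= 0) || any(width <= 0))
    stop("plate length and width must be positive")
  switch(formula,
         rectangle = length * width,
         ellipse = (pi / 4) * length * width)
}

#' Drop under-sampled assemblages
#'
#' Removes assemblages with fewer than `min_n` measurements, mirroring the
#' exclusion of singleton localities (a single plate carries no variance
#' information and cannot enter the simulation).  Removals are reported via
#' `message()`.
#'
#' @param series An `assemblage_series`.
#' @param min_n Minimum number of measurements to retain a locality.
#' @return The filtered `assemblage_series`.
#' @export
filter_assemblages <- function(series, min_n = 2L) {
  stopifnot(inherits(series, "assemblage_series"), min_n >= 1L)
  n <- vapply(series, `[[`, integer(1), "n")
  drop <- n < min_n
  if (!any(drop)) return(series)
  if (any(drop)) {
    message("excluding ", sum(drop), " assemblage(s) with n < ", min_n, ": ",
            paste(vapply(series[drop], `[[`, character(1), "locality"),
                  collapse = ", "))
  }
  kept <- unclass(series)[!drop]
  if (length(kept) == 0L)
    stop("no assemblages left after filtering at min_n = ", min_n)
  structure(kept, class = "assemblage_series")
}

#' Summarize one assemblage
#'
#' @param x An `assemblage`.
#' @return Named list with `n`, `mean_area` and `sd_area` (sample SD, n-1
#'   denominator; `NA` when `n = 1`).
#' @export
assemblage_summary <- function(x) {
  stopifnot(inherits(x, "assemblage"))
  if (x$n == 0L) stop("assemblage '", x$locality, "' has no measurements")
  list(n = x$n, mean_area = x$mean_area, sd_area = x$sd_area)
}

#' Per-locality summary table for a series
#'
#' @param series An `assemblage_series`.
#' @return Data frame (locality, age_ma, stage, n, mean, sd), oldest first.
#' @export
series_summary <- function(series) {
  stopifnot(inherits(series, "assemblage_series"))
  data.frame(
    locality = vapply(series, `[[`, character(1), "locality"),
    age_ma = vapply(series, `[[`, numeric(1), "age_ma"),
    stage = vapply(series, `[[`, character(1), "stage"),
    n = vapply(series, `[[`, integer(1), "n"),
    mean = vapply(series, `[[`, numeric(1), "mean_area"),
    sd = vapply(series, `[[`, numeric(1), "sd_area"),
    stringsAsFactors = FALSE)
}

#' Define an event window
#'
#' An event window names the oldest and youngest assemblages bracketing a
#' crisis event; which localities bound which event is explicit user input.
#'
#' @param name Event label (e.g. "Ireviken", "Mulde", "Lau").
#' @param oldest,youngest Locality labels; the oldest must be older.
#' @return An object of class `"event_window"`.
#' @export
event_window <- function(name, oldest, youngest) {
  stopifnot(is.character(name), is.character(oldest), is.character(youngest))
  structure(list(name = name, oldest = oldest, youngest = youngest),
            class = "event_window")
}

.series_get <- function(series, locality) {
  loc <- vapply(series, `[[`, character(1), "locality")
  i <- match(locality, loc)
  if (is.na(i))
    stop("locality '", locality, "' not present in the series ",
         "(absent or removed by the min_n filter)")
  series[[i]]
}

#' Per-event size change Delta
#'
#' Delta = mean area of the oldest assemblage minus mean area of the
#' youngest assemblage of the event window; positive Delta is a size
#' decrease.  Exactly two named assemblages enter the statistic (no
#' regression through intermediate localities).
#'
#' @param series An `assemblage_series` (already filtered).
#' @param event An [event_window()].
#' @return Delta in mm^2.
#' @export
event_delta <- function(series, event) {
  stopifnot(inherits(series, "assemblage_series"), inherits(event, "event_window"))
  old <- .series_get(series, event$oldest)
  yng <- .series_get(series, event$youngest)
  if (old$age_ma <= yng$age_ma)
    stop("event '", event$name, "': oldest locality '", event$oldest,
         "' is not older than '", event$youngest, "'")
  old$mean_area - yng$mean_area
}
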