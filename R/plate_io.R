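#' Write a plate table to long-format CSV
#'
#' The canonical interchange format is a long CSV with header
#' `time_h,well,channel,value`; run metadata goes to a JSON sidecar next to
#' the CSV (same stem, `.meta.json`) when present.
#'
#' @param table a `plate_table` (or data frame with the long columns).
#' @param path output CSV path.
#' @param sidecar write the metadata sidecar JSON (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(table, path, sidecar = TRUE) {
  df <- as.data.frame(table)[c("time_h", "well", "channel", "value")]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- plate_meta(table)
  if (sidecar && length(meta)) {
    jsonlite::write_json(meta, sub("\\.csv$", ".meta.json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a plate-reader time course from CSV
#'
#' Two dialects are accepted.  `long` is the canonical format
#' (`time_h,well,channel,value`).  `wide` is import-only: a time column
#' followed by one column per well/channel pair named `well.channel` or
#' `well_OD600` / `well_RLU` (the channel is taken from the suffix after
#' the last separator).  Times may be recorded in minutes or hours and are
#' always stored in hours.
#'
#' @param path CSV file path.
#' @param dialect `"long"` or `"wide"`.
#' @param time_units `"h"` or `"min"`.
#' @return a validated `plate_table`.
#' @export
read_plate_csv <- function(path, dialect = c("long", "wide"),
                           time_units = c("h", "min")) {
  dialect <- match.arg(dialect)
  time_units <- match.arg(time_units)
  if (!file.exists(path)) stop_config("plate file not found: %s", path)
  df <- tryCatch(read.csv(path, check.names = FALSE, strip.white = TRUE),
                 error = function(e) stop_config("cannot parse %s: %s",
                                                 path, conditionMessage(e)))
  if (dialect == "long") {
    need <- c("time_h", "well", "channel", "value")
    if (!all(need %in% names(df))) {
      # accept a generic time column name for minute-scale imports
      tcol <- intersect(c("time_h", "time_min", "time"), names(df))[1]
      if (is.na(tcol) || !all(c("well", "channel", "value") %in% names(df)))
        stop_config("long dialect needs columns time_h, well, channel, value")
      names(df)[names(df) == tcol] <- "time_h"
    }
    long <- df[c("time_h", "well", "channel", "value")]
  } else {
    tcol <- names(df)[1]
    if (!nrow(df) || ncol(df) < 2)
      stop_config("wide file needs a time column plus data columns")
    series <- names(df)[-1]
    parts <- regmatches(series, regexpr("[._]([^._]+)$", series))
    channels <- sub("^[._]", "", parts)
    wells <- substr(series, 1, nchar(series) - nchar(parts))
    if (any(!nzchar(wells)) || any(!nzchar(channels)))
      stop_config("wide column names must look like <well>.<channel>")
    long <- do.call(rbind, lapply(seq_along(series), function(i) {
      data.frame(time_h = df[[tcol]], well = wells[i], channel = channels[i],
                 value = df[[series[i]]])
    }))
  }
  if (time_units == "min") long$time_h <- long$time_h / 60
  validate_plate_table(long, source = path)
}

validate_plate_table <- function(long, source = NULL) {
  if (any(is.na(long$value)) || any(is.na(long$time_h))) {
    bad <- which(is.na(long$value) | is.na(long$time_h))[1]
    stop_config("missing value in plate table near record %d%s", bad,
                if (is.null(source)) "" else sprintf(" of %s", source))
  }
  key <- paste(long$time_h, long$well, long$channel)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop_config("duplicate (time, well, channel) record: t=%.4g well=%s channel=%s",
                long$time_h[d], long$well[d], long$channel[d])
  }
  for (w in unique(long$well)) for (ch in unique(long$channel[long$well == w])) {
    tt <- long$time_h[long$well == w & long$channel == ch]
    if (is.unsorted(tt, strictly = TRUE))
      stop_config("time not strictly increasing for well %s channel %s", w, ch)
  }
  new_plate_table(long, meta = list(source = source))
}

#' Extract one (well, channel) series from a plate table
#'
#' @param table a `plate_table`.
#' @param well well id.
#' @param channel channel name (`"OD600"` or `"RLU"`).
#' @return data frame with `time` (h) and `value`.
#' @export
plate_series <- function(table, well, channel) {
  df <- as.data.frame(table)
  sel <- df$well == well & df$channel == channel
  if (!any(sel)) stop_config("no records for well %s channel %s", well, channel)
  out <- df[sel, c("time_h", "value")]
  data.frame(time = out$time_h, value = out$value)
}

#' Blank-correct a plate table
#'
#' Subtracts, per channel and time point, the median reading of the blank
#' wells from every sample well.  Corrected OD values below `od_floor` are
#' clipped to the floor (with a warning reporting the count), because
#' downstream growth-rate estimation takes logs.
#'
#' @param table a `plate_table`.
#' @param blank_wells character vector of blank well ids (defaults to the
#'   metadata's `blank_wells`).
#' @param od_floor positive floor applied to corrected OD600 readings.
#' @param channels channels to correct (default OD600 only; RLU blanks are
#'   optional because published luminescence traces are not necessarily
#'   blank-subtracted).
#' @return a `plate_table` without the blank wells.
#' @export
blank_correct <- function(table, blank_wells = NULL, od_floor = 1e-4,
                          channels = "OD600") {
  meta <- plate_meta(table)
  blank_wells <- blank_wells %||% meta$blank_wells
  df <- as.data.frame(table)
  if (is.null(blank_wells) || !length(blank_wells))
    stop_config("no blank wells given and none recorded in metadata")
  if (!all(blank_wells %in% df$well))
    stop_config("blank well(s) absent: %s",
                paste(setdiff(blank_wells, df$well), collapse = ", "))
  samples <- setdiff(unique(df$well), blank_wells)
  if (!length(samples)) stop_config("table contains only blank wells")
  n_clip <- 0
  for (ch in intersect(channels, unique(df$channel))) {
    bl <- df[df$well %in% blank_wells & df$channel == ch, ]
    med <- tapply(bl$value, bl$time_h, median)
    sel <- df$well %in% samples & df$channel == ch
    df$value[sel] <- df$value[sel] - as.numeric(med[as.character(df$time_h[sel])])
    if (ch == "OD600") {
      low <- sel & df$value < od_floor
      n_clip <- sum(low)
      df$value[low] <- od_floor
    }
  }
  if (n_clip > 0)
    warning(sprintf("%d OD600 reading(s) clipped at the %.1e floor", n_clip, od_floor))
  meta$blank_corrected <- TRUE
  meta$blank_wells <- NULL
  new_plate_table(df[df$well %in% samples, ], meta = meta)
}

#' Average replicate wells and quantify their scatter
#'
#' Groups wells (e.g. duplicate wells of the same strain), then computes
#' the time-wise mean, standard deviation, and coefficient of variation per
#' group and channel.  Singleton groups get `NA` scatter with a warning.
#'
#' @param table a `plate_table`.
#' @param group_map named list `group -> character vector of wells`;
#'   defaults to grouping by the metadata's well-to-promoter map.
#' @return data frame with columns `group`, `channel`, `time`, `mean`,
#'   `sd`, `cv`.
#' @export
align_replicates <- function(table, group_map = NULL) {
  df <- as.data.frame(table)
  if (is.null(group_map)) {
    wm <- plate_meta(table)$well_map
    if (is.null(wm)) stop_config("no group_map given and no well map in metadata")
    wm <- wm[names(wm) %in% df$well]
    group_map <- split(names(wm), unlist(wm))
  }
  out <- list()
  for (g in names(group_map)) {
    wells <- intersect(group_map[[g]], unique(df$well))
    if (!length(wells)) next
    if (length(wells) < 2)
      warning(sprintf("group '%s' has a single well; CV undefined", g))
    for (ch in unique(df$channel)) {
      sub <- df[df$well %in% wells & df$channel == ch, ]
      if (!nrow(sub)) next
      mean_v <- tapply(sub$value, sub$time_h, mean)
      sd_v <- if (length(wells) >= 2) tapply(sub$value, sub$time_h, sd)
              else rep(NA_real_, length(mean_v))
      tt <- as.numeric(names(mean_v))
      o <- order(tt)
      out[[length(out) + 1]] <- data.frame(
        group = g, channel = ch, time = tt[o], mean = as.numeric(mean_v)[o],
        sd = as.numeric(sd_v)[o],
        cv = as.numeric(sd_v)[o] / ifelse(as.numeric(mean_v)[o] != 0,
                                          as.numeric(mean_v)[o], NA))
    }
  }
  do.call(rbind, out)
}

#' Fill short gaps in a series by linear interpolation
#'
#' Missing single readings (up to `max_gap` consecutive samples) are
#' linearly interpolated; longer gaps are left as `NA` so the caller can
#' split the series.
#'
#' @param time time grid.
#' @param value values with possible `NA`s.
#' @param max_gap maximum run of consecutive missing samples to fill.
#' @return the filled value vector.
#' @export
fill_gaps <- function(time, value, max_gap = 2) {
  na <- is.na(value)
  if (!any(na)) return(value)
  r <- rle(na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  filled <- value
  ok <- !na
  fa <- approxfun(time[ok], value[ok], rule = 1)
  for (j in which(r$values & r$lengths <= max_gap)) {
    i <- starts[j]:ends[j]
    if (starts[j] > 1 && ends[j] < length(value)) filled[i] <- fa(time[i])
  }
  filled
}
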