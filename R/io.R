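# Versioned tab-delimited tables: every output starts with a single
# comment line "#phenoflux_schema <version> <kind>" so readers can reject
# mismatched formats.
SCHEMA_VERSION <- 1L

write_table_v <- function(df, path, kind) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#phenoflux_schema %d %s", SCHEMA_VERSION, kind), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_table_v <- function(path, kind) {
  first <- readLines(path, n = 1L)
  parts <- strsplit(first, " ", fixed = TRUE)[[1]]
  if (length(parts) != 3L || parts[1] != "#phenoflux_schema") {
    stop("not a phenoflux table (missing schema line): ", path)
  }
  if (as.integer(parts[2]) != SCHEMA_VERSION) {
    stop("schema version mismatch in ", path, ": file has ", parts[2],
         ", reader expects ", SCHEMA_VERSION)
  }
  if (parts[3] != kind) {
    stop("table kind mismatch in ", path, ": file is '", parts[3],
         "', expected '", kind, "'")
  }
  utils::read.delim(path, skip = 1L, check.names = FALSE)
}

#' Write flashlet traces to long-form delimited text
#'
#' Columns: sample_id, wavelength_nm, timepoint_index, repeat_index, phase,
#' time_us, fluorescence. UTF-8, tab-delimited, with a schema line.
#'
#' @param traces Nested trace structure from [generate_cohort()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_traces <- function(traces, path) {
  rows <- lapply(traces, function(smp) {
    lapply(smp$wavelengths, function(wv) {
      n_tp <- dim(wv$induction)[1]
      n_rep <- dim(wv$induction)[2]
      mk <- function(arr, phase, times) {
        grid <- expand.grid(tp = seq_len(n_tp), rep = seq_len(n_rep),
                            fl = seq_along(times))
        data.frame(sample_id = smp$sample_id,
                   wavelength_nm = wv$wavelength_nm,
                   timepoint_index = grid$tp, repeat_index = grid$rep,
                   phase = phase, time_us = times[grid$fl],
                   fluorescence = as.vector(arr))
      }
      rbind(mk(wv$induction, "induction", wv$ind_schedule$times_us),
            mk(wv$relaxation, "relaxation", wv$rel_schedule$times_us))
    })
  })
  df <- do.call(rbind, unlist(rows, recursive = FALSE))
  write_table_v(df, path, "traces")
}

#' Read flashlet traces from long-form delimited text
#'
#' Inverse of [write_traces()]; rebuilds the nested per-sample structure
#' with flashlet schedules recovered from the time columns.
#'
#' @param path Input file.
#' @param dose_per_flashlet Excitation dose to attach to the rebuilt
#'   schedules (not stored in the table).
#' @return Nested trace list as produced by [generate_cohort()].
#' @export
read_traces <- function(path, dose_per_flashlet = 2.5e-4) {
  df <- read_table_v(path, "traces")
  need <- c("sample_id", "wavelength_nm", "timepoint_index", "repeat_index",
            "phase", "time_us", "fluorescence")
  if (!all(need %in% names(df))) {
    stop("trace table missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  out <- lapply(split(df, df$sample_id), function(ds) {
    per_w <- lapply(split(ds, ds$wavelength_nm), function(dw) {
      build <- function(phase) {
        dp <- dw[dw$phase == phase, ]
        times <- sort(unique(dp$time_us))
        n_tp <- max(dp$timepoint_index)
        n_rep <- max(dp$repeat_index)
        arr <- array(NA_real_, c(n_tp, n_rep, length(times)))
        arr[cbind(dp$timepoint_index, dp$repeat_index,
                  match(dp$time_us, times))] <- dp$fluorescence
        sched <- flashlet_schedule(phase, times,
                                   dose_per_flashlet = dose_per_flashlet)
        list(arr = arr, sched = sched)
      }
      ind <- build("induction")
      rel <- build("relaxation")
      list(wavelength_nm = canonical_wavelength(dw$wavelength_nm[1]),
           induction = ind$arr, relaxation = rel$arr,
           ind_schedule = ind$sched, rel_schedule = rel$sched)
    })
    names(per_w) <- vapply(per_w, function(w) as.character(w$wavelength_nm),
                           "")
    list(sample_id = ds$sample_id[1], wavelengths = per_w)
  })
  out
}

#' Write metric cubes as tidy and wide tables
#'
#' @param cubes List of `metric_cube`.
#' @param tidy_path,wide_path Output files (either may be `NULL`).
#' @param protocol Protocol for acquisition times in the tidy table.
#' @return Invisibly, the paths written.
#' @export
write_cubes <- function(cubes, tidy_path = NULL, wide_path = NULL,
                        protocol = NULL) {
  if (!is.null(tidy_path)) {
    tidy <- do.call(rbind, lapply(cubes, cube_to_tidy, protocol = protocol))
    write_table_v(tidy, tidy_path, "metrics_tidy")
  }
  if (!is.null(wide_path)) {
    wide <- cubes_to_wide(cubes)
    df <- data.frame(sample_id = rownames(wide), wide, check.names = FALSE)
    write_table_v(df, wide_path, "metrics_wide")
  }
  invisible(c(tidy_path, wide_path))
}

#' Read a wide metric table back into metric cubes
#'
#' @param path File written by [write_cubes()] (`wide_path`).
#' @return List of `metric_cube`.
#' @export
read_cubes_wide <- function(path) {
  df <- read_table_v(path, "metrics_wide")
  ids <- df$sample_id
  mat <- as.matrix(df[, setdiff(names(df), "sample_id")])
  out <- lapply(seq_along(ids), function(i) {
    unflatten_cube(stats::setNames(as.numeric(mat[i, ]), colnames(mat)),
                   sample_id = ids[i])
  })
  names(out) <- ids
  out
}
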