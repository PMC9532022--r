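# Cohorts of raw touchscreen traces: construction, canonical storage
# format, pixel-to-mm conversion and the three data-cleaning filters.
#
# Canonical on-disk format: one CSV per trace with header "t_s,x_mm,y_mm",
# plus a cohort manifest JSON listing the subjects ({subject_id, age,
# handedness, gender}), the trace files keyed by subject and template, and
# the template registry. Adapters for other deposits can map onto
# trace_record()/trace_cohort() directly.

#' Create a single trace record
#'
#' One subject's continuous touch stream for one template: strictly
#' increasing timestamps in seconds (starting near 0) and the matching 2-D
#' positions in mm.
#'
#' @param subject_id opaque subject identifier.
#' @param template_name name of the traced template.
#' @param t numeric timestamps in seconds, strictly increasing, length >= 2.
#' @param xy two-column matrix of positions in mm.
#' @return an object of class `woc_trace` with a `duration` field
#'   (last minus first timestamp).
#' @export
trace_record <- function(subject_id, template_name, t, xy) {
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  t <- as.numeric(t)
  if (length(t) < 2L) stop("a trace needs at least 2 samples")
  if (length(t) != nrow(xy)) stop("timestamps and points differ in length")
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  if (!all(is.finite(xy))) stop("trace points must be finite")
  structure(list(subject_id = as.character(subject_id),
                 template_name = as.character(template_name),
                 t = t, xy = xy,
                 duration = t[length(t)] - t[1L]),
            class = "woc_trace")
}

#' Assemble a cohort of traces
#'
#' @param subjects data frame with columns `subject_id`, `age` (years,
#'   fractional allowed, `NA` for unknown), `handedness` and `gender`.
#' @param traces list of [trace_record()] objects, at most one per
#'   (subject, template) pair.
#' @param templates named list of `woc_template` objects resolving every
#'   `template_name` used by the traces.
#' @return an object of class `woc_cohort`. Traces are stored in a named
#'   list keyed `"subject_id|template_name"`.
#' @export
trace_cohort <- function(subjects, traces = list(), templates = list()) {
  subjects <- as.data.frame(subjects)
  need <- c("subject_id", "age", "handedness", "gender")
  for (col in setdiff(need, names(subjects)))
    subjects[[col]] <- if (col == "age") NA_real_ else "unknown"
  subjects$subject_id <- as.character(subjects$subject_id)
  if (anyDuplicated(subjects$subject_id))
    stop("subject_id values must be unique within a cohort")
  bad_age <- !is.na(subjects$age) & (subjects$age < 3 | subjects$age > 99)
  if (any(bad_age)) stop("ages must lie in [3, 99] when present")
  keys <- vapply(traces, function(tr) paste(tr$subject_id, tr$template_name,
                                            sep = "|"), character(1))
  if (anyDuplicated(keys))
    stop("duplicate (subject, template) trace pairs: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  for (tr in traces) {
    if (!tr$subject_id %in% subjects$subject_id)
      stop("trace subject '", tr$subject_id, "' missing from subject table")
    if (length(templates) && !tr$template_name %in% names(templates))
      stop("trace template '", tr$template_name, "' missing from registry")
  }
  names(traces) <- keys
  structure(list(subjects = subjects, traces = traces, templates = templates),
            class = "woc_cohort")
}

#' @export
print.woc_cohort <- function(x, ...) {
  cat("Tracing cohort: ", nrow(x$subjects), " subjects, ",
      length(x$traces), " traces, ", length(x$templates),
      " template(s)\n", sep = "")
  if (any(!is.na(x$subjects$age)))
    cat(sprintf("  ages: %.1f-%.1f years\n",
                min(x$subjects$age, na.rm = TRUE),
                max(x$subjects$age, na.rm = TRUE)))
  invisible(x)
}

#' Convert touch coordinates from pixels to millimetres
#'
#' Linear scaling per axis using the physical screen size and resolution;
#' the default is the 216 x 135 mm, 1920 x 1200 px tablet display of the
#' tracing task.
#'
#' @param points_px two-column matrix of pixel coordinates.
#' @param screen_px screen resolution (width, height) in px.
#' @param screen_mm screen dimensions (width, height) in mm.
#' @return matrix of mm coordinates.
#' @export
px_to_mm <- function(points_px, screen_px = SCREEN_PX, screen_mm = SCREEN_MM) {
  if (any(screen_px <= 0) || any(screen_mm <= 0))
    stop("screen dimensions must be positive")
  points_px <- as.matrix(points_px)
  cbind(points_px[, 1L] * screen_mm[1] / screen_px[1],
        points_px[, 2L] * screen_mm[2] / screen_px[2])
}

#' Write a cohort in the canonical on-disk format
#'
#' @param cohort a `woc_cohort`.
#' @param path directory to create/populate.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "traces"), showWarnings = FALSE)
  files <- list()
  for (key in names(cohort$traces)) {
    tr <- cohort$traces[[key]]
    fn <- file.path("traces", paste0(gsub("[^A-Za-z0-9_.-]", "_", key), ".csv"))
    # 17 significant digits: doubles survive the text round-trip exactly
    d <- data.frame(t_s = sprintf("%.17g", tr$t),
                    x_mm = sprintf("%.17g", tr$xy[, 1L]),
                    y_mm = sprintf("%.17g", tr$xy[, 2L]))
    utils::write.csv(d, file.path(path, fn), row.names = FALSE,
                     quote = FALSE)
    files[[key]] <- list(subject_id = tr$subject_id,
                         template_name = tr$template_name, file = fn)
  }
  tpl_reg <- lapply(cohort$templates, function(tp) {
    fn <- file.path("traces", paste0("template_", tp$name, ".csv"))
    utils::write.csv(data.frame(x_mm = sprintf("%.17g", tp$points[, 1L]),
                                y_mm = sprintf("%.17g", tp$points[, 2L])),
                     file.path(path, fn), row.names = FALSE, quote = FALSE)
    list(name = tp$name, n_ref = tp$n_ref, file = fn)
  })
  manifest <- list(subjects = cohort$subjects, traces = unname(files),
                   templates = unname(tpl_reg))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a cohort from the canonical on-disk format
#'
#' Reads `manifest.json` plus the per-trace CSV files under `path`.
#' Unparseable or invalid trace files are skipped with a warning and
#' counted in the `n_skipped` attribute of the result. An empty directory
#' yields an empty cohort.
#'
#' @param path cohort directory (as written by [write_cohort()]).
#' @return a `woc_cohort`, with attribute `n_skipped`.
#' @export
load_cohort <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    return(trace_cohort(data.frame(subject_id = character(0),
                                   age = numeric(0),
                                   handedness = character(0),
                                   gender = character(0))))
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  subjects <- as.data.frame(manifest$subjects)
  if (!"subject_id" %in% names(subjects))
    stop("manifest subjects table lacks a subject_id column")
  templates <- list()
  if (!is.null(manifest$templates) && NROW(manifest$templates)) {
    treg <- as.data.frame(manifest$templates)
    for (i in seq_len(nrow(treg)))
      templates[[treg$name[i]]] <-
        read_template_csv(file.path(path, treg$file[i]),
                          n_ref = as.integer(treg$n_ref[i]))
  }
  traces <- list()
  n_skipped <- 0L
  tdf <- as.data.frame(manifest$traces)
  for (i in seq_len(NROW(tdf))) {
    tr <- tryCatch({
      d <- utils::read.csv(file.path(path, tdf$file[i]))
      stopifnot(all(c("t_s", "x_mm", "y_mm") %in% names(d)),
                !anyNA(d$t_s), !anyNA(d$x_mm), !anyNA(d$y_mm))
      trace_record(tdf$subject_id[i], tdf$template_name[i],
                   d$t_s, cbind(d$x_mm, d$y_mm))
    }, error = function(e) {
      warning("skipping trace ", tdf$file[i], ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(tr)) n_skipped <- n_skipped + 1L else
      traces[[length(traces) + 1L]] <- tr
  }
  out <- trace_cohort(subjects, traces, templates)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Apply the three data-cleaning filters to a cohort
#'
#' Removes anomalous traces by three independent criteria:
#' \enumerate{
#'   \item duration shorter than `min_duration` seconds (subjects not
#'     focused on the 30 s task);
#'   \item standard deviation of the trace, in either the horizontal or the
#'     vertical dimension, below `std_ratio` times the corresponding
#'     standard deviation of the template's dense points (degenerate
#'     traces);
#'   \item a jump between two consecutively recorded points larger than
#'     `jump_fraction` of the corresponding screen dimension in either
#'     axis (tablet malfunction or two-handed touches).
#' }
#' A trace may fail several criteria; the report tallies each criterion
#' independently, and `n_retained = n_input - |traces failing >= 1|`.
#'
#' @param cohort a `woc_cohort` whose templates resolve.
#' @param min_duration seconds; default 25.
#' @param std_ratio default 0.5.
#' @param jump_fraction default 0.25.
#' @param screen_mm screen dimensions for the jump criterion.
#' @return list with `cohort` (retained traces) and `report` (class
#'   `woc_cleaning`: counts plus a per-trace data frame of verdicts).
#' @export
clean_cohort <- function(cohort, min_duration = 25, std_ratio = 0.5,
                         jump_fraction = 0.25, screen_mm = SCREEN_MM) {
  stopifnot(inherits(cohort, "woc_cohort"))
  keys <- names(cohort$traces)
  n <- length(keys)
  short <- lowstd <- jump <- logical(n)
  for (i in seq_len(n)) {
    tr <- cohort$traces[[i]]
    short[i] <- tr$duration < min_duration
    tpl <- cohort$templates[[tr$template_name]]
    if (is.null(tpl))
      stop("no template '", tr$template_name, "' in the cohort registry")
    tpl_sd <- apply(tpl$points[-nrow(tpl$points), , drop = FALSE], 2L,
                    stats::sd)
    tr_sd <- apply(tr$xy, 2L, stats::sd)
    lowstd[i] <- any(tr_sd < std_ratio * tpl_sd)
    dxy <- abs(diff(tr$xy))
    jump[i] <- any(dxy[, 1L] > jump_fraction * screen_mm[1]) ||
      any(dxy[, 2L] > jump_fraction * screen_mm[2])
  }
  removed <- short | lowstd | jump
  per_trace <- data.frame(key = keys, removed_short = short,
                          removed_low_std = lowstd, removed_jump = jump,
                          retained = !removed)
  report <- structure(list(n_input = n,
                           removed_short = sum(short),
                           removed_low_std = sum(lowstd),
                           removed_jump = sum(jump),
                           n_removed = sum(removed),
                           n_retained = sum(!removed),
                           per_trace = per_trace),
                      class = "woc_cleaning")
  kept <- trace_cohort(cohort$subjects, unname(cohort$traces[!removed]),
                       cohort$templates)
  list(cohort = kept, report = report)
}

#' @export
print.woc_cleaning <- function(x, ...) {
  cat("Trace cleaning report\n")
  cat(sprintf("  input traces: %d\n", x$n_input))
  cat(sprintf("  removed: %d (short %d, low-std %d, jump %d; overlaps possible)\n",
              x$n_removed, x$removed_short, x$removed_low_std, x$removed_jump))
  cat(sprintf("  retained: %d\n", x$n_retained))
  invisible(x)
}
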