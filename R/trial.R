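#' Trial tables of stride-by-stride joint angles
#'
#' A trial table is a long tibble with one row per (participant, step)
#' observation and columns `group`, `participant`, `step`, `angle`. It is the
#' common input of every estimation function in the package. `as_gait_trials()`
#' validates an existing data frame (completeness, one group per participant,
#' consecutive unit-spaced steps) and stamps the `gait_trials` class;
#' `angle_matrix()` lays the angles out as a step-by-participant matrix.
#'
#' @param x A data frame with columns `group`, `participant`, `step`, `angle`.
#' @param truth Optional ground-truth tibble (as attached by
#'   [generate_cohort()]).
#' @param config Optional generating configuration (a [synth_config()] list).
#' @return `as_gait_trials()` returns the validated tibble with class
#'   `gait_trials`; `angle_matrix()` a numeric matrix with `T` rows (steps) and
#'   one column per participant, with `participant` and `group` attributes.
#' @examples
#' trials <- generate_cohort(synth_config(n_per_group = 3, n_steps = 40, seed = 1))
#' dim(angle_matrix(trials))
#' @export
as_gait_trials <- function(x, truth = NULL, config = NULL) {
  required <- c("group", "participant", "step", "angle")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Trial table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)
  x$group <- as.character(x$group)
  x$participant <- as.character(x$participant)
  x$step <- as.integer(x$step)
  if (anyNA(x$angle) || !is.numeric(x$angle)) {
    bad <- which(is.na(x$angle))
    abort(sprintf(
      "Trial table has %d missing/non-numeric angle(s); first at participant '%s', step %d.",
      length(bad), x$participant[bad[1]], x$step[bad[1]]
    ))
  }
  if (anyNA(x$group)) abort("Every observation must carry a group label.")
  grp_per_part <- tapply(x$group, x$participant, function(g) length(unique(g)))
  if (any(grp_per_part > 1)) {
    abort(sprintf("Participant '%s' is labelled with more than one group.",
                  names(grp_per_part)[grp_per_part > 1][1]))
  }
  steps <- sort(unique(x$step))
  if (length(steps) < 1 || any(diff(steps) != 1L)) {
    abort("Steps must form a consecutive unit-spaced sequence.")
  }
  counts <- table(x$participant)
  if (length(unique(counts)) != 1 || counts[1] != length(steps)) {
    abort("Every participant must be observed at every step exactly once.")
  }
  x <- dplyr::arrange(x, .data$group, .data$participant, .data$step)
  if (!is.null(truth)) attr(x, "truth") <- truth
  if (!is.null(config)) attr(x, "config") <- config
  class(x) <- unique(c("gait_trials", class(x)))
  x
}

#' @rdname as_gait_trials
#' @param trials A trial table (see [as_gait_trials()]).
#' @export
angle_matrix <- function(trials) {
  trials <- as_gait_trials(trials)
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(trials), "participant", "step", "angle"),
    names_from = "participant", values_from = "angle"
  )
  wide <- dplyr::arrange(wide, .data$step)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$step
  meta <- dplyr::distinct(tibble::as_tibble(trials),
                          .data$participant, .data$group)
  attr(m, "participant") <- colnames(m)
  attr(m, "group") <- meta$group[match(colnames(m), meta$participant)]
  m
}

#' Observed per-group mean angle series
#'
#' @param trials A trial table.
#' @return A tibble with columns `group`, `step`, `y_bar` (mean over the
#'   group's participants at that step).
#' @export
group_means <- function(trials) {
  trials <- as_gait_trials(trials)
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(trials), .data$group, .data$step),
    y_bar = mean(.data$angle), .groups = "drop"
  )
}

#' Read and write wide angle CSV files
#'
#' The on-disk dialect is a wide CSV: first header row holds participant ids,
#' second header row holds the matching group labels, and each subsequent row
#' holds one step's angles (step 1 first). `read_angles_csv()` validates the
#' table and by default keeps only the first `max_steps` rows, the analysis
#' window used throughout the package.
#'
#' @param path File path.
#' @param groups Optional named character vector mapping participant id to
#'   group label, overriding (or standing in for) the second header row.
#' @param max_steps Keep at most this many leading steps; `NULL` keeps all.
#' @return `read_angles_csv()` returns a validated trial table;
#'   `write_angles_csv()` returns `path` invisibly.
#' @examples
#' trials <- generate_cohort(synth_config(n_per_group = 2, n_steps = 20, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_angles_csv(trials, f)
#' identical(dim(read_angles_csv(f)), dim(tibble::as_tibble(trials)))
#' @export
read_angles_csv <- function(path, groups = NULL, max_steps = 500L) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  header <- readr::read_lines(path, n_max = 2)
  ids <- strsplit(header[1], ",", fixed = TRUE)[[1]]
  ids <- trimws(ids)
  second <- if (length(header) >= 2) trimws(strsplit(header[2], ",", fixed = TRUE)[[1]]) else character()
  second_is_groups <- length(second) == length(ids) &&
    all(suppressWarnings(is.na(as.numeric(second))))
  skip <- if (second_is_groups) 2L else 1L
  body <- readr::read_csv(path, skip = skip, col_names = ids,
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  if (is.null(groups)) {
    if (!second_is_groups) {
      abort("No group labels found: supply `groups` or a second header row of labels.")
    }
    groups <- setNames(second, ids)
  }
  unlabelled <- setdiff(ids, names(groups))
  if (length(unlabelled) > 0) {
    abort(paste0("No group label for participant(s): ",
                 paste(unlabelled, collapse = ", ")))
  }
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  vals <- matrix(vals, nrow = nrow(body),
                 dimnames = list(NULL, ids))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    abort(sprintf("Missing or non-numeric angle at data row %d, column '%s'.",
                  idx[1], ids[idx[2]]))
  }
  if (!is.null(max_steps) && nrow(vals) > max_steps) {
    vals <- vals[seq_len(max_steps), , drop = FALSE]
  }
  long <- tibble::tibble(
    group = rep(unname(groups[ids]), each = nrow(vals)),
    participant = rep(ids, each = nrow(vals)),
    step = rep(seq_len(nrow(vals)), times = length(ids)),
    angle = as.vector(vals)
  )
  as_gait_trials(long)
}

#' @rdname read_angles_csv
#' @param trials A trial table.
#' @export
write_angles_csv <- function(trials, path) {
  m <- angle_matrix(trials)
  lines <- c(
    paste(attr(m, "participant"), collapse = ","),
    paste(attr(m, "group"), collapse = ",")
  )
  readr::write_lines(lines, path)
  body <- apply(m, 1, function(r) paste(format(r, digits = 15, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = ","))
  readr::write_lines(body, path, append = TRUE)
  invisible(path)
}

#' Baseline-adjust a trial table
#'
#' Subtracts each participant's mean angle over the baseline window from that
#' participant's whole series, the convention used for baseline-adjusted
#' deposited data. After adjustment every participant's mean over
#' `baseline_steps` is zero to machine precision.
#'
#' @param trials A trial table.
#' @param baseline_steps Integer vector of steps forming the baseline window
#'   (default the first 250 steps, intersected with the available steps).
#' @return The adjusted trial table.
#' @export
baseline_adjust <- function(trials, baseline_steps = 1:250) {
  trials <- as_gait_trials(trials)
  baseline_steps <- intersect(baseline_steps, unique(trials$step))
  if (length(baseline_steps) == 0) {
    abort("`baseline_steps` does not intersect the observed step range.")
  }
  out <- dplyr::mutate(
    dplyr::group_by(tibble::as_tibble(trials), .data$participant),
    angle = .data$angle - mean(.data$angle[.data$step %in% baseline_steps])
  )
  out <- dplyr::ungroup(out)
  as_gait_trials(out,
                 truth = attr(trials, "truth"),
                 config = attr(trials, "config"))
}
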