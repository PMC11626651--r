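.GAS_FILE_COLS <- c("bottle_id", "time_d", "pressure_kPa", "temp_K", .GAS_COLS)
.EVENT_FILE_COLS <- c("bottle_id", "time_d", "kind", "volume_mL")

# delimited read: comma with dot decimals; tab accepted
.read_delim <- function(path) {
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

.check_cols <- function(df, need, what, path) {
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0(what, " table '", path, "' is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
}

#' Read the headspace gas table
#'
#' Long-format delimited table (comma or tab) with one row per measured
#' headspace state: `bottle_id`, `time_d`, `pressure_kPa`, `temp_K`, the
#' mole fractions `x_CO`, `x_CO2`, `x_H2`, `x_CH4`, `x_N2` and optionally
#' `event` (`measure`/`post_flush`). Duplicate (bottle, time, event) keys
#' are an error, reported with their keys.
#'
#' @param path file path.
#' @return a tibble.
#' @export
read_gas_table <- function(path) {
  df <- .read_delim(path)
  .check_cols(df, .GAS_FILE_COLS, "gas", path)
  if (!"event" %in% names(df)) df$event <- "measure"
  dup <- df %>%
    dplyr::count(.data$bottle_id, .data$time_d, .data$event) %>%
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0(
      "duplicated (bottle_id, time_d) in '", path, "': ",
      paste(sprintf("%s@%g", dup$bottle_id, dup$time_d), collapse = ", ")
    ))
  }
  df
}

#' Read the event log table
#'
#' Delimited table with `bottle_id`, `time_d`, `kind` (`gas_sample`,
#' `liquid_sample`, `flush`) and `volume_mL`.
#'
#' @param path file path.
#' @return a tibble.
#' @export
read_events_table <- function(path) {
  df <- .read_delim(path)
  .check_cols(df, .EVENT_FILE_COLS, "events", path)
  bad <- !df$kind %in% .EVENT_KINDS
  if (any(bad)) {
    abort(paste0("unknown event kind(s) in '", path, "': ",
                 paste(unique(df$kind[bad]), collapse = ", ")))
  }
  df
}

#' Read the liquid metabolite table
#'
#' Delimited table with `bottle_id`, `time_d` and one g/L column per
#' measured metabolite (registry names, e.g. `acetate`, `n_butyrate`).
#'
#' @param path file path.
#' @return a tibble.
#' @export
read_liquid_table <- function(path) {
  df <- .read_delim(path)
  .check_cols(df, c("bottle_id", "time_d"), "liquid", path)
  df
}

#' Read a whole experiment bundle
#'
#' Reads the gas, events and liquid tables, splits them by `bottle_id` and
#' pairs each bottle with its [bottle_spec()] from the design table (columns
#' `bottle_id`, `acetate_gL`, `pH`, `temp_C`, optionally
#' `bottle_volume_mL`, `liquid_volume_mL`, `replicate_id`).
#'
#' @param gas_path,events_path,liquid_path paths to the delimited tables.
#' @param design either a path to a delimited design table or a data frame.
#' @return named list of bottles (`gas`, `events`, `liquid`, `spec`),
#'   consumable by [analyze_experiment()].
#' @export
read_experiment <- function(gas_path, events_path, liquid_path, design) {
  gas <- read_gas_table(gas_path)
  events <- read_events_table(events_path)
  liquid <- read_liquid_table(liquid_path)
  if (is.character(design)) design <- .read_delim(design)
  .check_cols(design, c("bottle_id", "acetate_gL", "pH", "temp_C"),
              "design", "design")
  design <- as_tibble(design)

  col_or <- function(row, col, default) {
    if (col %in% names(row) && !is.na(row[[col]])) row[[col]] else default
  }
  bottles <- lapply(seq_len(nrow(design)), function(i) {
    row <- design[i, ]
    spec <- bottle_spec(
      bottle_volume_mL = col_or(row, "bottle_volume_mL", 250),
      liquid_volume_mL = col_or(row, "liquid_volume_mL", 50),
      temp_C = row$temp_C, pH = row$pH, acetate_gL = row$acetate_gL,
      replicate_id = col_or(row, "replicate_id", 1L)
    )
    list(
      gas = filter(gas, .data$bottle_id == row$bottle_id),
      events = filter(events, .data$bottle_id == row$bottle_id),
      liquid = filter(liquid, .data$bottle_id == row$bottle_id),
      spec = spec
    )
  })
  names(bottles) <- design$bottle_id
  bottles
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0 || (length(a) == 1 && is.na(a))) b else a
}

#' Write a simulated experiment as the analysis input tables
#'
#' Emits the same delimited tables [read_experiment()] consumes (gas,
#' events, liquid, design) plus a ground-truth sidecar table, all
#' comma-separated and round-trippable.
#'
#' @param sims list of `bottle_sim` objects (named or not; names become
#'   bottle ids).
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_experiment <- function(sims, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- names(sims) %||% sprintf("bottle_%03d", seq_along(sims))
  if (is.null(names(sims))) names(sims) <- ids

  tag <- function(part) {
    purrr::imap_dfr(sims, function(s, id) mutate(s[[part]], bottle_id = id,
                                                 .before = 1))
  }
  design <- purrr::imap_dfr(sims, function(s, id) {
    tibble(
      bottle_id = id, acetate_gL = s$spec$acetate_gL, pH = s$spec$pH,
      temp_C = s$spec$temp_C, bottle_volume_mL = s$spec$bottle_volume_mL,
      liquid_volume_mL = s$spec$liquid_volume_mL,
      replicate_id = s$spec$replicate_id
    )
  })
  truth <- purrr::imap_dfr(sims, function(s, id) {
    mutate(s$truth$flows, bottle_id = id, .before = 1)
  })

  paths <- c(
    gas = file.path(dir, "gas.csv"),
    events = file.path(dir, "events.csv"),
    liquid = file.path(dir, "liquid.csv"),
    design = file.path(dir, "design.csv"),
    truth = file.path(dir, "ground_truth.csv")
  )
  readr::write_csv(tag("gas"), paths[["gas"]])
  readr::write_csv(tag("events"), paths[["events"]])
  readr::write_csv(tag("liquid"), paths[["liquid"]])
  readr::write_csv(design, paths[["design"]])
  readr::write_csv(truth, paths[["truth"]])
  invisible(paths)
}
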