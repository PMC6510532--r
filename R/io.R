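# Persistence of the tidy attack-record table and of study configurations.

RECORD_COLUMNS <- c("subject_id", "experiment_id", "trial", "order",
                    "reliable_value", "reliable_polarity",
                    "unreliable_value", "profitability", "attacked")

#' Write attack records to CSV
#'
#' One row per presented prey, in the shared tidy schema.
#'
#' @param records Attack-record data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read attack records from CSV
#'
#' Accepts an optional column mapping so that externally deposited data
#' with different headers can be ingested: `mapping` is a named character
#' vector whose names are the package's column names and whose values are
#' the names used in the file.
#'
#' @param path CSV path.
#' @param mapping Optional named character vector, ours = theirs.
#' @return An attack-record data frame.
#' @export
read_records <- function(path, mapping = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    miss_src <- setdiff(unname(mapping), names(df))
    if (length(miss_src)) {
      stop("mapped source columns missing from file: ",
           paste(miss_src, collapse = ", "))
    }
    idx <- match(unname(mapping), names(df))
    names(df)[idx] <- names(mapping)
  }
  miss <- setdiff(RECORD_COLUMNS, names(df))
  if (length(miss)) {
    stop("records file lacks required columns: ",
         paste(miss, collapse = ", "))
  }
  df$attacked <- as.logical(df$attacked)
  df
}

#' Read a study configuration from YAML or JSON
#'
#' Recognized fields mirror the arguments of [study_config()]; archetype
#' entries may carry a `proportion` plus archetype parameters.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  arch <- raw$archetypes
  if (is.null(arch)) arch <- list(human_like = 1)
  arch <- lapply(arch, function(a) {
    if (is.list(a)) {
      prop <- a$proportion %||% 1
      params <- a[setdiff(names(a), "proportion")]
      out <- list(proportion = prop, params = params)
      out
    } else {
      as.numeric(a)
    }
  })
  # archetype entries with parameters become full archetype objects
  arch <- stats::setNames(lapply(names(arch), function(k) {
    a <- arch[[k]]
    if (is.list(a) && length(a$params)) {
      proto <- resolve_archetype(k)
      proto$params[names(a$params)] <- a$params
      proto$proportion <- a$proportion
      proto
    } else if (is.list(a)) {
      a$proportion
    } else {
      a
    }
  }), names(arch))
  study_config(
    n_subjects = raw$n_subjects %||% 45L,
    archetypes = arch,
    master_seed = raw$master_seed %||% 1L,
    game = do.call(game_config, raw$game %||% list()),
    balance_treatments = raw$balance_treatments %||% TRUE,
    total_size = raw$total_size %||% 36L,
    abundances = raw$abundances
  )
}
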