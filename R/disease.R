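# Disease definitions: a code list plus a chronicity class that selects the
# exposure and prevalence rules, and — for anything other than a lifelong
# condition — the expected duration of one episode, which doubles as the
# recurrence lookback window for incidence.

CHRONICITY_LEVELS <- c("lifelong", "non_lifelong", "acute")

#' Define a disease
#'
#' @param name Disease name (used to label outputs).
#' @param chronicity One of `"lifelong"`, `"non_lifelong"`, `"acute"`.
#'   Lifelong conditions keep a patient exposed from presentation to the end
#'   of follow-up; the others expose the patient for `expected_duration_days`
#'   after each qualifying record.
#' @param expected_duration_days Positive integer number of days one episode
#'   is expected to last. Required for non-lifelong and acute diseases and
#'   must be absent for lifelong ones.
#' @param codes Character vector of clinical codes identifying the disease;
#'   matching is exact, duplicates are removed.
#' @return A `disease_definition` object.
#' @export
disease_definition <- function(name, chronicity, expected_duration_days = NULL,
                               codes) {
  chronicity <- match.arg(chronicity, CHRONICITY_LEVELS)
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop("disease name must be a non-empty string", call. = FALSE)
  }
  if (chronicity == "lifelong") {
    if (!is.null(expected_duration_days)) {
      stop("a lifelong disease must not set expected_duration_days",
           call. = FALSE)
    }
  } else {
    if (is.null(expected_duration_days) ||
        length(expected_duration_days) != 1 ||
        is.na(expected_duration_days) ||
        expected_duration_days < 1 ||
        expected_duration_days != as.integer(expected_duration_days)) {
      stop("chronicity '", chronicity,
           "' requires expected_duration_days >= 1", call. = FALSE)
    }
    expected_duration_days <- as.integer(expected_duration_days)
  }
  codes <- unique(as.character(codes))
  codes <- codes[nzchar(codes)]
  if (length(codes) == 0) stop("code list must be non-empty", call. = FALSE)
  structure(
    list(name = name, chronicity = chronicity,
         expected_duration_days = expected_duration_days, codes = codes),
    class = "disease_definition"
  )
}

is_lifelong <- function(d) d$chronicity == "lifelong"

#' @export
print.disease_definition <- function(x, ...) {
  dur <- if (is_lifelong(x)) "until end of follow-up" else
    paste0(x$expected_duration_days, " days per episode")
  cat("<disease_definition> ", x$name, " (", x$chronicity, ", exposure ",
      dur, "; ", length(x$codes), " codes)\n", sep = "")
  invisible(x)
}

#' Load a disease definition from YAML or JSON
#'
#' Reads a one-disease config document with keys `name`, `chronicity`,
#' `expected_duration_days` (required unless lifelong) and either `codes`
#' (inline list) or `codes_file` (one code per line, resolved relative to the
#' config file). Validation and deduplication follow [disease_definition()].
#'
#' @param config_path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `disease_definition`.
#' @export
load_disease_definition <- function(config_path) {
  if (!file.exists(config_path)) {
    stop("file not found: ", config_path, call. = FALSE)
  }
  cfg <- if (grepl("\\.json$", config_path, ignore.case = TRUE)) {
    jsonlite::read_json(config_path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(config_path)
  }
  for (key in c("name", "chronicity")) {
    if (is.null(cfg[[key]])) {
      stop("disease config is missing key '", key, "'", call. = FALSE)
    }
  }
  codes <- cfg[["codes"]]
  if (is.null(codes) && !is.null(cfg[["codes_file"]])) {
    codes_path <- file.path(dirname(config_path), cfg[["codes_file"]])
    if (!file.exists(codes_path)) {
      stop("codes_file not found: ", codes_path, call. = FALSE)
    }
    codes <- readLines(codes_path, warn = FALSE)
    codes <- trimws(codes)
    codes <- codes[nzchar(codes)]
  }
  if (is.null(codes)) {
    stop("disease config needs 'codes' or 'codes_file'", call. = FALSE)
  }
  disease_definition(
    name = cfg[["name"]],
    chronicity = cfg[["chronicity"]],
    expected_duration_days = cfg[["expected_duration_days"]],
    codes = unlist(codes)
  )
}
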