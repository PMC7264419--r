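#' Read a situation specification file
#'
#' Reads the JSON (or equivalent YAML) situation format:
#' \preformatted{
#' {"events": {"A": "breast cancer", "notA": "no breast cancer",
#'             "B": "positive test", "notB": "negative test"},
#'  "given": {"P(A)": 0.02, "P(B|A)": 0.8, "P(B|notA)": 0.1},
#'  "frequencies": {"P(A)": 200},
#'  "N": 10000}
#' }
#' All keys except one of `given`/`frequencies` are optional. Values may be
#' numbers or fraction strings (`"8/57"`).
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return a list with components `given`, `events`, `frequencies`, `N`,
#'   ready to be spliced into [solve_situation()].
#' @seealso [write_situation_spec()]
#' @export
read_situation_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  events <- if (!is.null(raw$events)) {
    e <- raw$events
    event_pair(
      first = e$A %||% "A", second = e$B %||% "B",
      first_negation = e$notA %||% paste("no", e$A %||% "A"),
      second_negation = e$notB %||% paste("no", e$B %||% "B"))
  } else {
    event_pair()
  }
  N <- if (!is.null(raw$N)) {
    n <- raw$N
    if (!is.numeric(n) || n < 1 || n != trunc(n)) stop("N must be a positive integer")
    as.numeric(n)
  } else NULL
  given <- raw$given %||% list()
  freqs <- raw$frequencies %||% NULL
  if (length(given) == 0L && length(freqs) == 0L) {
    stop("spec provides neither 'given' probabilities nor 'frequencies'")
  }
  list(given = given, events = events, frequencies = freqs, N = N)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a completed situation as a specification file
#'
#' Serializes all sixteen quantities (undefined conditionals are omitted)
#' into the same format read by [read_situation_spec()]. Exact-decimal values
#' are written as numbers, all other fractions as strings like `"8/57"`.
#'
#' @param situation a `"completed_situation"`.
#' @param path output path; `.yaml`/`.yml` selects YAML, anything else JSON.
#' @return `path`, invisibly.
#' @export
write_situation_spec <- function(situation, path) {
  ev <- situation$events
  given <- situation_assignment(situation)
  out <- list(
    events = list(A = ev$first, notA = ev$first_negation,
                  B = ev$second, notB = ev$second_negation),
    given = lapply(given, .rat_serialize)
  )
  if (!is.null(situation$N)) out$N <- situation$N
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(out, path)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
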