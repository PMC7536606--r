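`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom rlang abort
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange bind_rows distinct
#' @importFrom purrr map map_chr map_lgl map_int keep discard compact
NULL

# classed error helper: every user-facing failure carries a subclass so the
# dialogue layer / CLI can route it
da_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "dietassist_error"), ...)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

is_num <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

# fill {placeholders} in a template from a named list; missing keys are an
# error so broken templates surface immediately
interpolate <- function(template, payload) {
  keys <- unique(regmatches(template, gregexpr("\\{[a-zA-Z0-9_]+\\}", template))[[1]])
  out <- template
  for (k in keys) {
    name <- substr(k, 2L, nchar(k) - 1L)
    if (is.null(payload[[name]])) {
      da_abort(sprintf("template placeholder '%s' missing from payload", name),
               "dietassist_template_error")
    }
    out <- gsub(k, paste(format(payload[[name]], trim = TRUE), collapse = ", "),
                out, fixed = TRUE)
  }
  out
}

# normalize a surface term for case-insensitive matching
norm_term <- function(x) tolower(trimws(x))

# tokenize an utterance: lowercase, strip punctuation, split on whitespace
tokenize <- function(utterance) {
  x <- tolower(utterance)
  x <- gsub("[^a-z0-9?'{}_ ]", " ", x)
  x <- gsub("'", "", x, fixed = TRUE)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' @export
generics::tidy

#' @export
generics::glance
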