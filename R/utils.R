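#' Signal a classed package error
#'
#' All user-facing failures raise conditions with a machine-readable class
#' (`invalid_argument`, `insufficient_data`, `fit_failure`,
#' `degenerate_input`, `missing_data`, `cv_degenerate`) so callers and the
#' pipeline can branch on them.
#'
#' @param class condition class string
#' @param message human-readable message
#' @param data optional payload attached to the condition
#' @keywords internal
crsf_stop <- function(class, message, data = NULL) {
  stop(errorCondition(message, data = data,
                      class = c(class, "crsf_error"),
                      call = sys.call(-1)))
}

assert_that <- function(ok, class, message) {
  if (!isTRUE(ok)) crsf_stop(class, message)
  invisible(TRUE)
}

#' Derive a reproducible substream seed from a root seed and a stage name
#'
#' Every stage of the pipeline draws its randomness from a named substream
#' of one root seed, so stages can be re-run individually with identical
#' results. The derived seed is kept below 2^31 - 1.
#'
#' @param seed integer root seed
#' @param name substream name (stage label)
#' @return an integer seed
#' @export
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131L) %% 1000003L
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# UTC ISO-8601 helpers used by every CSV interface
format_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
parse_utc <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
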