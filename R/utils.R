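## Internal helpers shared across modules.

#' Signal a classed sexscreen error
#'
#' All user-facing errors in the package carry a subclass of
#' \code{"sexscreen_error"} so callers and tests can react to the error
#' category (format, consistency, metadata, eligibility, ...) rather than
#' matching message text.
#'
#' @param msg character message.
#' @param class character scalar, error category, e.g. \code{"format"};
#'   produces condition classes \code{sexscreen_<class>_error} and
#'   \code{sexscreen_error}.
#' @param call. logical, include the call.
#' @keywords internal
#' @noRd
ssStop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(paste0("sexscreen_", class, "_error"), "sexscreen_error",
              "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

ssWarn <- function(msg, class) {
  warning(structure(
    class = c(paste0("sexscreen_", class, "_warning"), "sexscreen_warning",
              "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

## Collapse internal whitespace and trim a surface form / token.
squishWs <- function(x) {
  gsub("^\\s+|\\s+$", "", gsub("\\s+", " ", x))
}

## Geometric mean (no zeros expected by construction in qBase quantities).
geoMean <- function(x) exp(mean(log(x)))

## Deterministic child seeds below 2^31 derived from a user seed.
childSeed <- function(seed, k) {
  s <- (as.numeric(seed) %% 1000003) * 1009 + 97 * as.numeric(k)
  as.integer(s %% 2147480000)
}

## Normalize free-text sex annotations to "female"/"male"; NA if unknown.
parseSexValue <- function(x) {
  v <- tolower(squishWs(x))
  out <- rep(NA_character_, length(v))
  out[v %in% c("female", "f", "woman", "women", "xx")] <- "female"
  out[v %in% c("male", "m", "man", "men", "xy")] <- "male"
  out
}
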