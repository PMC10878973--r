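#' @keywords internal
"_PACKAGE"

# Shared input checks. All validation errors go through stop() with call. = FALSE
# so messages read as user-facing diagnostics, not tracebacks.

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(NULL)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, allow_na = FALSE) {
  abort_if(!is.numeric(x) || length(x) != 1L,
           sprintf("`%s` must be a single number", name))
  if (is.na(x)) {
    abort_if(!allow_na, sprintf("`%s` must not be NA", name))
    return(invisible(x))
  }
  abort_if(x < lower || x > upper,
           sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  invisible(x)
}

# Format doubles so that write -> read round-trips exactly (17 significant
# digits is lossless for IEEE doubles).
format_double <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- NA_character_
  trimws(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
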