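## Structured error conditions. Every domain failure carries a condition class
## so callers (and the command-line wrapper) can map it to a distinct exit code.

cranio_abort <- function(class, message, ...) {
  stop(structure(
    class = c(class, "cranio_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

## condition class -> process exit code for the CLI
.cranio_exit_codes <- c(
  cranio_input_error          = 10L,
  cranio_degenerate_landmarks = 11L,
  cranio_empty_slice          = 12L,
  cranio_open_contour         = 13L,
  cranio_degenerate_outline   = 14L,
  cranio_start_not_found      = 15L,
  cranio_center_outside       = 16L,
  cranio_invalid_radius       = 17L,
  cranio_flat_curve           = 18L,
  cranio_peak_too_flat        = 19L,
  cranio_undefined_icc        = 20L,
  cranio_singleton_group      = 21L,
  cranio_degenerate_variance  = 22L,
  cranio_spec_error           = 23L,
  cranio_usage_error          = 64L
)

#' Exit code associated with a craniocurve error condition
#'
#' @param cond a condition object (typically caught with `tryCatch`).
#' @return an integer exit code; `1L` for errors outside the package's
#'   known condition classes.
#' @export
cranio_exit_code <- function(cond) {
  hit <- intersect(class(cond), names(.cranio_exit_codes))
  if (length(hit)) .cranio_exit_codes[[hit[1]]] else 1L
}
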