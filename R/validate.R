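# Condition classes.  All package errors inherit from "pcbtox_error";
# the CLI maps validation/config errors to exit 2 and data-quality errors
# to exit 3.

stop_pcbtox <- function(msg, class) {
  cond <- structure(
    class = c(class, "pcbtox_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cond)
}

abort_validation <- function(...) {
  stop_pcbtox(paste0(...), "pcbtox_validation_error")
}

abort_config <- function(...) {
  stop_pcbtox(paste0(...), "pcbtox_config_error")
}

abort_data_quality <- function(...) {
  stop_pcbtox(paste0(...), "pcbtox_data_quality_error")
}

abort_insufficient_data <- function(...) {
  stop_pcbtox(paste0(...),
              c("pcbtox_insufficient_data_error", "pcbtox_validation_error"))
}

# scalar numeric checks --------------------------------------------------

check_number <- function(x, name, min = -Inf, allow_na = FALSE) {
  if (allow_na && (is.null(x) || length(x) == 0 || is.na(x))) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort_validation(name, " must be a single finite number")
  }
  if (x < min) abort_validation(name, " must be >= ", min)
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1 || is.na(x)) {
    abort_validation(name, " must be TRUE or FALSE")
  }
  invisible(x)
}

check_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1 || is.na(x) || !nzchar(x)) {
    abort_validation(name, " must be a non-empty string")
  }
  invisible(x)
}

check_class_label <- function(x) {
  check_string(x, "class")
  if (!x %in% c("parent", "hydroxylated", "sulfated")) {
    abort_validation("class must be one of 'parent', 'hydroxylated', 'sulfated'",
                     " (got '", x, "')")
  }
  invisible(x)
}

# deterministic FNV-1a hash of a config-like object; used to stamp outputs
# so re-runs with identical inputs are byte-identical
config_hash <- function(x) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                          force = TRUE)
  bytes <- utf8ToInt(as.character(txt))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
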