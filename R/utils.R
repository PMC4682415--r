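#' @importFrom rlang abort %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange bind_rows distinct filter mutate select
#' @keywords internal
"_PACKAGE"

stop_io <- function(msg, ...) {
  abort(msg, class = c("seednet_io_error", "seednet_error"), ...)
}

stop_parse <- function(msg, ...) {
  abort(msg, class = c("seednet_parse_error", "seednet_error"), ...)
}

stop_resolution <- function(msg, ...) {
  abort(msg, class = c("seednet_resolution_error", "seednet_error"), ...)
}

stop_schema <- function(msg, ...) {
  abort(msg, class = c("seednet_schema_error", "seednet_error"), ...)
}

stop_domain <- function(msg, ...) {
  abort(msg, class = c("seednet_domain_error", "seednet_error"), ...)
}

check_readable <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_io(sprintf("File not found or unreadable: %s", paste(path, collapse = ", ")))
  }
  invisible(path)
}

# Run code under a fixed Mersenne-Twister seed, restoring the caller's RNG
# state afterwards so library calls never perturb user scripts.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Retrieve the load report attached to a loaded object
#'
#' Loaders ([load_interactome()], [load_catalog()]) attach a per-stage
#' accounting of rows read, kept and dropped (with reasons).  This accessor
#' returns it as a tibble.
#'
#' @param x An object returned by a loader.
#' @return A tibble with columns `stage`, `count`.
#' @export
load_report <- function(x) {
  rep <- attr(x, "load_report", exact = TRUE)
  if (is.null(rep)) {
    stop_domain("Object carries no load report")
  }
  rep
}
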