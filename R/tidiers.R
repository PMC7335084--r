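#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an `mea_synchrony` object
#'
#' `tidy()` returns the per-pair table (one row per unordered channel pair
#' with observed distance, null statistics and synchrony under every
#' convention); `glance()` a one-row device summary.
#'
#' @param x An `mea_synchrony` object from [device_synchrony()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mea_synchrony
#' @export
tidy.mea_synchrony <- function(x, ...) {
  x$pairs
}

#' @rdname tidy.mea_synchrony
#' @method glance mea_synchrony
#' @export
glance.mea_synchrony <- function(x, ...) {
  tibble::tibble(
    device_id = x$device_id,
    n_channels = x$n_channels,
    n_pairs = if (is.null(x$pairs)) 0L else nrow(x$pairs),
    device_synchrony = x$device_synchrony,
    convention = x$params$convention,
    n_random = x$params$n_random,
    timeline_s = x$params$timeline_s
  )
}
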