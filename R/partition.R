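# One-dimensional channel partitions used by the optimizers.

#' Create a one-dimensional channel partition
#'
#' A partition of an interval (time within a laser period, or the detected
#' wavelength band) into contiguous channels, defined by its interior
#' boundaries. The optimizers add, remove and move boundaries subject to a
#' minimal channel width `resolution` (the instrument's timing/spectral
#' resolution).
#'
#' @param domain Length-2 numeric: the closed interval being partitioned.
#' @param boundaries Strictly increasing interior boundary points (possibly
#'   empty for a single channel).
#' @param resolution Minimal allowed channel width (default: domain width /
#'   1024).
#' @return An object of class `partition1d`.
#' @examples
#' partition1d(c(0, 12.5), boundaries = c(3.2))
#' @export
partition1d <- function(domain, boundaries = numeric(),
                        resolution = diff(domain) / 1024) {
  if (!is.numeric(domain) || length(domain) != 2L || diff(domain) <= 0) {
    abort("`domain` must be an increasing length-2 interval.",
          class = "hdim_error_domain")
  }
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) > 0) {
    if (any(diff(boundaries) <= 0) ||
        boundaries[1L] <= domain[1L] ||
        boundaries[length(boundaries)] >= domain[2L]) {
      abort("`boundaries` must be strictly increasing, inside the open domain.",
            class = "hdim_error_invalid_partition")
    }
  }
  check_scalar(resolution, "resolution")
  edges <- c(domain[1L], boundaries, domain[2L])
  if (any(diff(edges) < resolution - 1e-12)) {
    abort("All channel widths must be >= `resolution`.",
          class = "hdim_error_invalid_partition")
  }
  structure(list(domain = as.numeric(domain), boundaries = boundaries,
                 resolution = resolution),
            class = "partition1d")
}

#' Channel edges of a partition
#' @param partition A [partition1d()].
#' @return Numeric vector `c(domain lower, boundaries, domain upper)`.
#' @export
partition_edges <- function(partition) {
  c(partition$domain[1L], partition$boundaries, partition$domain[2L])
}

n_partition_channels <- function(partition) length(partition$boundaries) + 1L

#' Equal-width partition of a domain
#' @param domain Length-2 interval.
#' @param n Number of equal channels.
#' @param resolution Passed to [partition1d()].
#' @return A [partition1d()].
#' @export
even_partition <- function(domain, n, resolution = diff(domain) / 1024) {
  edges <- seq(domain[1L], domain[2L], length.out = n + 1L)
  partition1d(domain, edges[-c(1L, n + 1L)], resolution)
}

#' @export
print.partition1d <- function(x, ...) {
  cat(sprintf("<partition1d: %d channels on [%g, %g]>\n",
              n_partition_channels(x), x$domain[1L], x$domain[2L]))
  cat("  edges:", paste(signif(partition_edges(x), 5), collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy partition1d
#' @export
tidy.partition1d <- function(x, ...) {
  e <- partition_edges(x)
  tibble(channel = seq_len(length(e) - 1L),
         lower = utils::head(e, -1L),
         upper = utils::tail(e, -1L),
         width = diff(e))
}

#' @method autoplot partition1d
#' @export
autoplot.partition1d <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                                    ymin = 0, ymax = 1,
                                    fill = factor(.data$channel)),
                       colour = "grey20", show.legend = FALSE) +
    ggplot2::labs(x = "coordinate", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
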