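#' Tidy a refinement: per-cycle statistics
#'
#' @param x A [run_refinement()] result.
#' @param ... Unused.
#' @return Tibble with one row per cycle (row 0 = starting state):
#'   `cycle`, `r_work`, `r_free`, scale (`k`, `u_overall`), RMS applied
#'   shifts per component and `n_singular`.
#' @export
tidy.shift_refinement <- function(x, ...) {
  x$stats
}

#' Glance at a refinement: one-row summary
#'
#' @inheritParams tidy.shift_refinement
#' @return One-row tibble: mode, kernel, r0, cycles, initial and final
#'   R_work and R_free.
#' @export
glance.shift_refinement <- function(x, ...) {
  s <- x$stats
  tibble(
    mode = x$config$mode,
    kernel = x$config$kernel,
    r0 = x$r0,
    n_cycles = x$config$n_cycles,
    r_work_initial = s$r_work[1],
    r_work_final = s$r_work[nrow(s)],
    r_free_initial = s$r_free[1],
    r_free_final = s$r_free[nrow(s)]
  )
}

#' Plot R-factor trajectories over refinement cycles
#'
#' @param object A [run_refinement()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shift_refinement <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$stats[c("cycle", "r_work", "r_free")],
    c("r_work", "r_free"),
    names_to = "statistic", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$cycle, y = .data$value, colour = .data$statistic
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "cycle", y = "R factor", colour = NULL,
      title = sprintf("shift-field refinement (%s, r0 = %.1f A)",
        object$config$mode, object$r0))
}

#' Plot a radius sweep
#'
#' @param object A [radius_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object of final R and free R against r0.
#' @export
autoplot.radius_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object),
    c("r_work_final", "r_free_final"),
    names_to = "statistic", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$r0, y = .data$value, colour = .data$statistic
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "kernel radius r0 (A)", y = "final R factor", colour = NULL)
}
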