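#' Plot-ready table for CNV frequency tracks
#'
#' Emits the exact coordinates [plot_frequency()] draws, so rendering is
#' testable without pixel comparison. Gains are mirrored upward (positive
#' percent), losses downward (negative percent). In `genome` layout bin
#' positions are offset to a single cumulative axis; in `chromosome` layout
#' positions stay chromosome-local and a panel per chromosome is implied.
#'
#' @param tracks a `cnv_freq_track` or list of them (multiple cohorts).
#' @param layout `"genome"` or `"chromosome"`.
#' @param chromosomes optional chromosome subset (only for `"chromosome"`
#'   layout); unknown labels are an error.
#' @return tibble: group, chromosome, start, end, x_start, x_end, state,
#'   percent, y (signed percent).
#' @export
freq_plot_data <- function(tracks, layout = c("genome", "chromosome"),
                           chromosomes = NULL) {
  layout <- match.arg(layout)
  if (inherits(tracks, "cnv_freq_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    tbl <- as_tibble(tr)
    tbl$group <- attr(tr, "group") %||% "all"
    tbl
  })
  tbl <- bind_rows(rows)
  known <- unique(tbl$chromosome)
  if (!is.null(chromosomes)) {
    bad <- setdiff(as.character(chromosomes), known)
    if (length(bad)) {
      abort(paste0("Unknown chromosome(s) in subset: ",
                   paste(bad, collapse = ", ")))
    }
    tbl <- tbl[tbl$chromosome %in% as.character(chromosomes), , drop = FALSE]
  }
  tbl$chromosome <- as.character(tbl$chromosome)
  chrom_order <- levels(chromosome_factor(tbl$chromosome))
  offsets <- if (layout == "genome") {
    lens <- vapply(chrom_order, function(ch) max(tbl$end[tbl$chromosome == ch]), 0)
    setNames(cumsum(c(0, head(lens, -1))), chrom_order)
  } else {
    setNames(rep(0, length(chrom_order)), chrom_order)
  }
  long <- tidyr::pivot_longer(tbl, c("gain_percent", "loss_percent"),
                              names_to = "state", values_to = "percent")
  long$state <- sub("_percent$", "", long$state)
  long$x_start <- long$start + offsets[long$chromosome]
  long$x_end <- long$end + offsets[long$chromosome]
  long$y <- ifelse(long$state == "gain", long$percent, -long$percent)
  long$chromosome <- factor(long$chromosome, levels = chrom_order)
  long[, c("group", "chromosome", "start", "end", "x_start", "x_end",
           "state", "percent", "y")]
}

#' Plot CNV frequency tracks
#'
#' Mirrored frequency plot in the style of cohort CNV summaries: per-bin
#' gain percentages drawn upward, loss percentages downward, on a fixed
#' -100..100 axis. Several tracks (cohorts) stack as labelled facet rows;
#' `chromosome` layout gives one panel per chromosome with local
#' coordinates.
#'
#' @inheritParams freq_plot_data
#' @return a ggplot object.
#' @export
plot_frequency <- function(tracks, layout = c("genome", "chromosome"),
                           chromosomes = NULL) {
  layout <- match.arg(layout)
  pd <- freq_plot_data(tracks, layout, chromosomes)
  p <- ggplot2::ggplot(pd) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$x_start, xmax = .data$x_end,
      ymin = pmin(.data$y, 0), ymax = pmax(.data$y, 0),
      fill = .data$state)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(gain = "#D6604D", loss = "#4393C3")) +
    ggplot2::scale_y_continuous(limits = c(-100, 100),
                                labels = function(b) abs(b)) +
    ggplot2::labs(x = if (layout == "genome") "genome position (bp)"
                      else "position (bp)",
                  y = "CNV frequency (%)  losses | gains", fill = "state") +
    ggplot2::theme_minimal()
  n_groups <- length(unique(pd$group))
  if (layout == "chromosome") {
    p <- p + if (n_groups > 1) {
      ggplot2::facet_grid(group ~ chromosome, scales = "free_x")
    } else {
      ggplot2::facet_wrap(~chromosome, scales = "free_x")
    }
  } else if (n_groups > 1) {
    p <- p + ggplot2::facet_grid(group ~ .)
  }
  p
}

#' @export
autoplot.cnv_freq_track <- function(object, ...) plot_frequency(object, ...)

#' Plot-ready step coordinates for Kaplan-Meier curves
#'
#' Duplicates curve points into right-continuous step coordinates starting
#' at (0, 1), the exact polyline [survival_plot()] draws.
#'
#' @param curves a `km_curve` or list of them.
#' @return tibble: group, time, survival.
#' @export
km_plot_data <- function(curves) {
  if (inherits(curves, "km_curve")) curves <- list(curves)
  bind_rows(lapply(curves, function(cv) {
    g <- attr(cv, "group") %||% "all"
    t <- c(0, rep(cv$time, each = 2))
    s <- c(1, 1, rep(cv$survival, each = 2))
    s <- s[-length(s)]
    tibble(group = g, time = t, survival = s)
  }))
}

#' Plot Kaplan-Meier survival curves
#'
#' Step-function curves per group, optional censor tick marks, optional
#' at-risk table beneath the plot (rendered with patchwork when available).
#'
#' @param curves a `km_curve` or list of them (e.g. from [km_by_group()]).
#' @param show_censor_marks draw tick marks at censoring times.
#' @param risk_table add a numbers-at-risk panel below.
#' @param conf_int shade Greenwood log-scale confidence bands.
#' @return a ggplot (or patchwork) object.
#' @export
survival_plot <- function(curves, show_censor_marks = TRUE,
                          risk_table = FALSE, conf_int = FALSE) {
  if (inherits(curves, "km_curve")) curves <- list(curves)
  pd <- km_plot_data(curves)
  p <- ggplot2::ggplot(pd, ggplot2::aes(.data$time, .data$survival,
                                        colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability", colour = "group") +
    ggplot2::theme_minimal()
  if (conf_int) {
    band <- bind_rows(lapply(curves, function(cv) {
      tibble(group = attr(cv, "group") %||% "all", time = cv$time,
             low = cv$conf_low, high = cv$conf_high)
    }))
    if (nrow(band)) {
      p <- p + ggplot2::geom_step(data = band,
              ggplot2::aes(.data$time, .data$low, colour = .data$group),
              linetype = "dashed", inherit.aes = FALSE) +
        ggplot2::geom_step(data = band,
              ggplot2::aes(.data$time, .data$high, colour = .data$group),
              linetype = "dashed", inherit.aes = FALSE)
    }
  }
  if (show_censor_marks) {
    cens <- bind_rows(lapply(curves, function(cv) {
      ct <- attr(cv, "censor_times") %||% numeric()
      if (length(ct) == 0) return(NULL)
      s_at <- vapply(ct, function(t) {
        past <- cv$survival[cv$time <= t]
        if (length(past)) past[length(past)] else 1
      }, 0)
      tibble(group = attr(cv, "group") %||% "all", time = ct, survival = s_at)
    }))
    if (!is.null(cens) && nrow(cens) > 0) {
      p <- p + ggplot2::geom_point(data = cens, shape = 3, size = 2)
    }
  }
  if (risk_table) {
    rt <- bind_rows(lapply(curves, function(cv) {
      tibble(group = attr(cv, "group") %||% "all",
             time = cv$time, n_risk = cv$n_risk)
    }))
    tbl_plot <- ggplot2::ggplot(rt, ggplot2::aes(.data$time, .data$group,
                                                 label = .data$n_risk)) +
      ggplot2::geom_text(size = 3) +
      ggplot2::labs(x = NULL, y = NULL, title = "Number at risk") +
      ggplot2::theme_minimal()
    if (requireNamespace("patchwork", quietly = TRUE)) {
      return(patchwork::wrap_plots(p, tbl_plot, ncol = 1, heights = c(3, 1)))
    }
    warn("patchwork not installed; returning the curve plot without the risk table.")
  }
  p
}

#' @export
autoplot.km_curve <- function(object, ...) survival_plot(object, ...)

#' Save a plot to PNG, SVG or PDF by file extension
#'
#' @param plot a ggplot/patchwork object.
#' @param path output file; extension selects the device.
#' @param width,height size in inches.
#' @return `path`, invisibly.
#' @export
save_plot <- function(plot, path, width = 9, height = 5) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "svg", "pdf")) {
    abort(paste0("Unsupported plot format ", sQuote(ext),
                 "; use .png, .svg or .pdf."))
  }
  dev <- if (ext == "svg") grDevices::svg else NULL
  ggplot2::ggsave(path, plot = plot, width = width, height = height,
                  device = if (is.null(dev)) ext else dev, dpi = 150)
  invisible(path)
}
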