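#' Kaplan-Meier product-limit estimate for one group
#'
#' Computes the nonparametric survival estimate
#' \eqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over the distinct event
#' times \eqn{t_i}, with \eqn{d_i} events and \eqn{n_i} subjects at risk.
#' Censored observations reduce later risk sets but contribute no factor;
#' at tied times, subjects censored at \eqn{t} are still at risk for the
#' events at \eqn{t} (the standard convention). Confidence intervals use the
#' Greenwood variance on the log scale:
#' \eqn{\widehat{\mathrm{Var}}[\log S(t)] = \sum_{t_i \le t} d_i / (n_i (n_i - d_i))},
#' giving \eqn{S(t) \exp(\pm z \sqrt{\cdot})} bounds clipped to \[0, 1\].
#'
#' @param records data frame with columns `time` (non-negative follow-up)
#'   and `event` (logical or 0/1; `TRUE` = event observed, `FALSE` =
#'   censored). Extra columns are ignored.
#' @param group label attached to the curve (default `"all"`).
#' @param conf_level confidence level for the Greenwood log-scale interval.
#' @return a `km_curve` tibble with one row per distinct event time:
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`, `std_err`,
#'   `conf_low`, `conf_high`; attributes `group`, `n`, `n_events`.
#' @export
#' @examples
#' rec <- data.frame(time = c(5, 10, 15, 20),
#'                   event = c(FALSE, TRUE, TRUE, FALSE))
#' km_estimate(rec)   # S(10) = 2/3, S(15) = 1/3
km_estimate <- function(records, group = "all", conf_level = 0.95) {
  rec <- as_tibble(records)
  if (nrow(rec) == 0) abort("Need at least one record.")
  if (!all(c("time", "event") %in% names(rec))) {
    abort("`records` needs `time` and `event` columns.")
  }
  time <- as.numeric(rec$time)
  event <- as.logical(rec$event)
  if (any(is.na(time)) || any(time < 0)) abort("`time` must be non-negative.")
  if (any(is.na(event))) abort("`event` must be TRUE/FALSE.")

  times <- sort(unique(time[event]))
  n_total <- length(time)
  if (length(times) == 0) {
    out <- tibble(time = numeric(), n_risk = integer(), n_event = integer(),
                  n_censor = integer(), survival = numeric(),
                  std_err = numeric(), conf_low = numeric(),
                  conf_high = numeric())
    return(structure(out, group = group, n = n_total, n_events = 0L,
                     class = c("km_curve", class(out))))
  }
  n_risk <- vapply(times, function(t) sum(time >= t), 0L)
  n_event <- vapply(times, function(t) sum(time == t & event), 0L)
  n_censor <- vapply(times, function(t) sum(time == t & !event), 0L)
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood variance of log S
  var_log <- cumsum(ifelse(n_risk > n_event,
                           n_event / (n_risk * (n_risk - n_event)), NA))
  z <- qnorm(1 - (1 - conf_level) / 2)
  conf_low <- pmax(0, surv * exp(-z * sqrt(var_log)))
  conf_high <- pmin(1, surv * exp(z * sqrt(var_log)))
  conf_low[surv == 0] <- 0
  conf_high[surv == 0] <- 0

  out <- tibble(time = times, n_risk = as.integer(n_risk),
                n_event = as.integer(n_event), n_censor = as.integer(n_censor),
                survival = surv, std_err = surv * sqrt(var_log),
                conf_low = conf_low, conf_high = conf_high)
  structure(out, group = group, n = n_total, n_events = sum(n_event),
            censor_times = sort(time[!event]),
            class = c("km_curve", class(out)))
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> group:", attr(x, "group"), " n =", attr(x, "n"),
      " events =", attr(x, "n_events"), "\n")
  NextMethod()
}

#' @export
tidy.km_curve <- function(x, ...) {
  mutate(as_tibble(x), group = attr(x, "group"), .before = 1)
}

#' @export
glance.km_curve <- function(x, ...) {
  s <- x$survival
  median_t <- if (any(s <= 0.5)) x$time[which(s <= 0.5)[1]] else NA_real_
  tibble(group = attr(x, "group"), n = attr(x, "n"),
         n_events = attr(x, "n_events"), median_survival = median_t)
}

#' Estimate one Kaplan-Meier curve per group
#'
#' @param records data frame with `time`, `event` and a `group` column.
#' @param conf_level confidence level, see [km_estimate()].
#' @return named list of `km_curve` objects, one per group level.
#' @export
km_by_group <- function(records, conf_level = 0.95) {
  rec <- as_tibble(records)
  if (!"group" %in% names(rec)) rec$group <- "all"
  groups <- unique(as.character(rec$group))
  setNames(lapply(groups, function(g) {
    km_estimate(rec[rec$group == g, , drop = FALSE], group = g,
                conf_level = conf_level)
  }), groups)
}

#' Log-rank test across survival groups
#'
#' The standard (unweighted) log-rank test: at each distinct event time the
#' expected events in group j are \eqn{e_j = d \, n_j / n} and the
#' hypergeometric covariance of the observed counts is
#' \eqn{V_{jl} = d (n - d) / (n - 1) \cdot (n_j / n)(\delta_{jl} - n_l / n)}.
#' Sums over event times give the observed-minus-expected vector and its
#' covariance; the statistic is the quadratic form over any k-1 groups,
#' chi-square distributed with k-1 degrees of freedom under equal hazards.
#'
#' @param records data frame with `time`, `event`, `group`; at least two
#'   groups, each with at least one record.
#' @return a `logrank_test` list: `statistic`, `df`, `p_value`, and a
#'   per-group `summary` tibble (n, observed, expected).
#' @export
logrank_test <- function(records) {
  rec <- as_tibble(records)
  if (!all(c("time", "event", "group") %in% names(rec))) {
    abort("`records` needs `time`, `event` and `group` columns.")
  }
  rec$group <- as.character(rec$group)
  groups <- sort(unique(rec$group))
  k <- length(groups)
  if (k < 2) abort("Log-rank test needs at least two groups.")
  time <- as.numeric(rec$time)
  event <- as.logical(rec$event)
  if (any(time < 0)) abort("`time` must be non-negative.")

  gidx <- match(rec$group, groups)
  times <- sort(unique(time[event]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    if (n < 1) next
    d <- sum(time == t & event)
    nj <- vapply(seq_len(k), function(j) sum(at_risk & gidx == j), 0)
    dj <- vapply(seq_len(k), function(j) sum(time == t & event & gidx == j), 0)
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      frac <- nj / n
      V <- V + d * (n - d) / (n - 1) * (diag(frac, k) - outer(frac, frac))
    }
  }
  u <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  stat <- tryCatch(drop(t(u) %*% solve(Vk, u)), error = function(e) {
    # singular covariance (e.g. no events): statistic 0 by convention
    0
  })
  df <- k - 1L
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  structure(
    list(statistic = as.numeric(stat), df = df, p_value = p,
         summary = tibble(group = groups,
                          n = as.integer(table(factor(rec$group, groups))),
                          observed = O, expected = E)),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Log-rank test: chi-square =", format(x$statistic, digits = 4),
      "on", x$df, "df, p =", format.pval(x$p_value, digits = 4), "\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.logrank_test <- function(x, ...) x$summary

#' @export
glance.logrank_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' Build survival records from a flattened individual table
#'
#' Bridges a flattened table of individuals (e.g. from
#' [fetch_multi_domain()]) to the input of [km_by_group()] /
#' [logrank_test()]: picks the follow-up-time and vital-status columns, maps
#' status text to the event indicator through a configurable vocabulary, and
#' assigns groups either from a metadata column or by thresholding a numeric
#' column. Rows with missing time or status — or a status string absent from
#' the vocabulary — are dropped and counted in a warning.
#'
#' @param table a data frame of individuals.
#' @param time_col,status_col column names for follow-up time and status.
#' @param group group rule: `NULL` (single group `"all"`), the name of a
#'   grouping column, or a two-element list `list(column =, threshold =)`
#'   splitting a numeric column into `"<x"` / `">=x"`.
#' @param status_vocab named logical vector mapping status strings
#'   (lower-cased) to the event indicator.
#' @param id_col column holding the individual identifier, if present.
#' @return tibble: individual_id, time, event, group; attribute `n_dropped`.
#' @export
build_survival_records <- function(table, time_col, status_col,
                                   group = NULL,
                                   status_vocab = c(
                                     "dead" = TRUE, "deceased" = TRUE,
                                     "death" = TRUE, "true" = TRUE, "1" = TRUE,
                                     "alive" = FALSE, "censored" = FALSE,
                                     "false" = FALSE, "0" = FALSE),
                                   id_col = "individual_id") {
  tbl <- as_tibble(table)
  for (col in c(time_col, status_col)) {
    if (!col %in% names(tbl)) {
      abort(paste0("Column ", sQuote(col), " not found in table."))
    }
  }
  id <- if (id_col %in% names(tbl)) as.character(tbl[[id_col]])
        else sprintf("row%d", seq_len(nrow(tbl)))
  time <- suppressWarnings(as.numeric(tbl[[time_col]]))
  status_raw <- tolower(trimws(as.character(tbl[[status_col]])))
  event <- unname(status_vocab[status_raw])

  grp <- if (is.null(group)) {
    rep("all", nrow(tbl))
  } else if (is.character(group) && length(group) == 1) {
    if (!group %in% names(tbl)) abort(paste0("Group column ", sQuote(group), " not found."))
    as.character(tbl[[group]])
  } else if (is.list(group) && !is.null(group$column)) {
    if (!group$column %in% names(tbl)) {
      abort(paste0("Group column ", sQuote(group$column), " not found."))
    }
    v <- suppressWarnings(as.numeric(tbl[[group$column]]))
    ifelse(v >= group$threshold, paste0(">=", group$threshold),
           paste0("<", group$threshold))
  } else {
    abort("`group` must be NULL, a column name, or list(column=, threshold=).")
  }

  keep <- !is.na(time) & !is.na(event) & !is.na(grp)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    unknown <- unique(status_raw[!is.na(time) & is.na(event)])
    msg <- paste0("Dropped ", n_dropped, " record(s) with missing time/status",
                  if (length(unknown))
                    paste0(" (unmapped status: ",
                           paste(unknown[!is.na(unknown)], collapse = ", "), ")"))
    warn(msg)
  }
  if (!any(keep)) abort("No usable records after dropping missing time/status.")
  out <- tibble(individual_id = id[keep], time = time[keep],
                event = as.logical(event[keep]), group = grp[keep])
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Export Kaplan-Meier curves as TSV
#'
#' Columns: group, time, survival, at_risk, n_events.
#'
#' @param curves a `km_curve` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_km_tsv <- function(curves, path) {
  if (inherits(curves, "km_curve")) curves <- list(curves)
  tbl <- bind_rows(lapply(curves, function(c) {
    tibble(group = attr(c, "group"), time = c$time, survival = c$survival,
           at_risk = c$n_risk, n_events = c$n_event)
  }))
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
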