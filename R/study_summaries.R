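# Treatment x period aggregation, fixed-effects RCBD ANOVA, derived statistics.

#' Study design table
#'
#' Randomized complete block design bookkeeping: each paddock maps to one
#' block and one treatment, every treatment appears once per block, and two
#' tester animals carry collars per paddock. Periods map an index to a start
#' date (consecutive 21-day windows by default).
#'
#' @param paddocks data.frame with `paddock_id`, `block`, `treatment` and
#'   optionally `animal_id` rows (one per tester).
#' @param periods data.frame with `period` (integer) and `start_date` (Date).
#' @param period_length_d window length in days.
#' @return object of class `design_table`.
#' @export
design_table <- function(paddocks, periods, period_length_d = 21) {
  stopifnot(all(c("paddock_id", "block", "treatment") %in% names(paddocks)),
            all(c("period", "start_date") %in% names(periods)))
  periods$start_date <- as.Date(periods$start_date)
  pd <- unique(paddocks[, c("paddock_id", "block", "treatment")])
  tab <- table(pd$block, pd$treatment)
  if (any(tab != 1L))
    stop("not an RCBD: every treatment must appear exactly once per block")
  structure(list(paddocks = paddocks, periods = periods,
                 period_length_d = period_length_d),
            class = "design_table")
}

#' Assign dates to evaluation periods
#'
#' @param dates Date vector.
#' @param design `design_table`.
#' @return integer period index (NA outside all windows).
#' @export
assign_period <- function(dates, design) {
  stopifnot(inherits(design, "design_table"))
  p <- design$periods
  out <- rep(NA_integer_, length(dates))
  for (i in seq_len(nrow(p))) {
    in_win <- dates >= p$start_date[i] & dates < p$start_date[i] + design$period_length_d
    out[in_win] <- p$period[i]
  }
  out
}

#' Average animal-day metrics across the two testers of each paddock
#'
#' Arithmetic mean per paddock-day of every numeric metric column. Days where
#' only one tester reported are flagged (`n_animals < 2`), never silently
#' averaged away.
#'
#' @param animal_days data.frame with `paddock_id`, `date`, `animal_id` and
#'   numeric metric columns.
#' @param metrics character vector of metric column names; default all
#'   numeric columns.
#' @return data.frame per paddock-day with metric means, `n_animals`, and
#'   `complete` flag.
#' @export
paddock_daily_means <- function(animal_days, metrics = NULL) {
  stopifnot(all(c("paddock_id", "date", "animal_id") %in% names(animal_days)))
  if (is.null(metrics))
    metrics <- names(animal_days)[vapply(animal_days, is.numeric, TRUE) &
                                    !names(animal_days) %in% c("block", "period")]
  key <- interaction(animal_days$paddock_id, animal_days$date, drop = TRUE)
  rows <- lapply(split(animal_days, key), function(d) {
    out <- data.frame(paddock_id = d$paddock_id[1L], date = d$date[1L],
                      stringsAsFactors = FALSE)
    for (m in metrics) out[[m]] <- mean(d[[m]])
    out$n_animals <- length(unique(d$animal_id))
    out$complete <- out$n_animals >= 2L
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$paddock_id, out$date), , drop = FALSE]
}

#' Fixed-effects RCBD analysis of variance
#'
#' Classical sum-of-squares decomposition for the model
#' `y = mu + treatment + block + period + treatment:period + error` on a
#' balanced design (one observation per paddock x period, i.e. per
#' treatment x block x period cell). F ratios are taken against the residual
#' mean square. Missing cells are an error — no imputation.
#'
#' @param data data.frame with the response and `treatment`, `block`,
#'   `period` columns.
#' @param response name of the response column.
#' @return object of class `rcbd_anova`: the ANOVA `table`, cell and
#'   treatment means, the treatment-mean SEM, and residual statistics.
#' @export
rcbd_anova <- function(data, response) {
  stopifnot(response %in% names(data),
            all(c("treatment", "block", "period") %in% names(data)))
  y <- data[[response]]
  trt <- factor(data$treatment)
  blk <- factor(data$block)
  per <- factor(data$period)
  a <- nlevels(trt); b <- nlevels(blk); p <- nlevels(per)
  if (nrow(data) != a * b * p ||
      any(table(trt, blk, per) != 1L))
    stop("design is unbalanced or has missing cells: need one observation per treatment x block x period")
  grand <- mean(y)
  m_t <- tapply(y, trt, mean)
  m_b <- tapply(y, blk, mean)
  m_p <- tapply(y, per, mean)
  m_tp <- tapply(y, list(trt, per), mean)
  ss_total <- sum((y - grand)^2)
  ss_t <- b * p * sum((m_t - grand)^2)
  ss_b <- a * p * sum((m_b - grand)^2)
  ss_p <- a * b * sum((m_p - grand)^2)
  int_dev <- sweep(sweep(m_tp, 1L, m_t), 2L, m_p) + grand
  ss_tp <- b * sum(int_dev^2)
  ss_res <- ss_total - ss_t - ss_b - ss_p - ss_tp
  df <- c(a - 1L, b - 1L, p - 1L, (a - 1L) * (p - 1L))
  df_res <- (a * b * p - 1L) - sum(df)
  ms <- c(ss_t, ss_b, ss_p, ss_tp) / df
  ms_res <- ss_res / df_res
  fval <- ms / ms_res
  pval <- stats::pf(fval, df, df_res, lower.tail = FALSE)
  tab <- data.frame(
    term = c("treatment", "block", "period", "treatment:period", "residual"),
    df = c(df, df_res), ss = c(ss_t, ss_b, ss_p, ss_tp, ss_res),
    ms = c(ms, ms_res), f = c(fval, NA), p = c(pval, NA),
    stringsAsFactors = FALSE)
  structure(list(table = tab, response = response, grand_mean = grand,
                 treatment_means = m_t, period_means = m_p, cell_means = m_tp,
                 sem_treatment = sqrt(ms_res / (b * p)),
                 ms_residual = ms_res, df_residual = df_res,
                 n_blocks = b, n_periods = p),
            class = "rcbd_anova")
}

#' @export
print.rcbd_anova <- function(x, ...) {
  cat(sprintf("RCBD ANOVA for '%s' (SEM of treatment means: %.3g)\n",
              x$response, x$sem_treatment))
  tab <- x$table
  tab$ss <- signif(tab$ss, 5); tab$ms <- signif(tab$ms, 5)
  tab$f <- signif(tab$f, 4); tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

# compact letter display: maximal runs of mutually non-significant treatments
# along the means sorted in descending order (the "lines" method)
.letter_groups <- function(means, differs) {
  k <- length(means)
  ord <- order(-means)
  runs <- vector("list", k)
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(differs[ord[i:(j + 1L)], ord[i:(j + 1L)]])) j <- j + 1L
    runs[[i]] <- i:j
  }
  keep <- vapply(seq_len(k), function(i)
    !any(vapply(seq_len(k), function(m)
      m != i && all(runs[[i]] %in% runs[[m]]), TRUE)), TRUE)
  runs <- runs[keep]
  lab <- rep("", k)
  for (g in seq_along(runs))
    lab[ord[runs[[g]]]] <- paste0(lab[ord[runs[[g]]]], letters[g])
  lab
}

#' Treatment x period cell means, SEM, and mean-separation letters
#'
#' In a balanced design the least-squares cell means reduce to arithmetic
#' means. Treatment means carry a compact letter display from pairwise t
#' tests on the residual mean square (unadjusted, as in "significant at
#' p < 0.05"; pass `p_adjust` for a multiplicity correction).
#'
#' @param data paddock-period data.frame with the response and `treatment`,
#'   `block`, `period`.
#' @param response response column name.
#' @param alpha significance level for the letters.
#' @param p_adjust method for [stats::p.adjust()] (default `"none"`).
#' @return list: `cells` (treatment x period means), `treatments` (means,
#'   SEM, letters), and the underlying `anova`.
#' @export
treatment_period_table <- function(data, response, alpha = 0.05,
                                   p_adjust = "none") {
  an <- rcbd_anova(data, response)
  m <- an$treatment_means
  k <- length(m)
  se_diff <- sqrt(2 * an$ms_residual / (an$n_blocks * an$n_periods))
  pm <- matrix(1, k, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    tstat <- (m[i] - m[j]) / se_diff
    pm[i, j] <- pm[j, i] <- 2 * stats::pt(-abs(tstat), an$df_residual)
  }
  pv <- stats::p.adjust(pm[upper.tri(pm)], method = p_adjust)
  pm[upper.tri(pm)] <- pv
  pm[lower.tri(pm)] <- t(pm)[lower.tri(pm)]
  differs <- pm < alpha
  diag(differs) <- FALSE
  letters_ <- .letter_groups(m, differs)
  list(cells = an$cell_means,
       treatments = data.frame(treatment = names(m), mean = as.numeric(m),
                               sem = an$sem_treatment, group = letters_,
                               stringsAsFactors = FALSE),
       anova = an)
}

#' Percent change between two values
#'
#' `100 * (a - b) / b`, e.g. how much farther animals walked under one
#' treatment relative to another.
#'
#' @param a,b numeric; `b` is the reference and must be nonzero.
#' @return percent.
#' @export
percent_change <- function(a, b) {
  if (any(b == 0)) stop("reference value must be nonzero")
  100 * (a - b) / b
}

#' Mean across treatments
#'
#' Arithmetic mean of one value per treatment, as used for study-wide
#' activity summaries.
#'
#' @param values numeric vector, one per treatment.
#' @return mean.
#' @export
cross_treatment_mean <- function(values) mean(values)

#' Convert a percent-of-day to hours
#'
#' @param pct_of_day percent (0-100).
#' @return hours (pct/100 x 24).
#' @export
frac_to_hours <- function(pct_of_day) {
  if (any(pct_of_day < 0 | pct_of_day > 100)) stop("pct_of_day must be in [0, 100]")
  pct_of_day / 100 * 24
}

#' Total herbage mass from component masses
#'
#' @param component_masses non-negative kg DM/ha component values.
#' @return total kg DM/ha.
#' @export
total_herbage <- function(component_masses) {
  if (any(component_masses < 0, na.rm = TRUE)) stop("herbage masses must be non-negative")
  sum(component_masses, na.rm = TRUE)
}
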