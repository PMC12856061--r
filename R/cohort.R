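# Synthetic cohorts ------------------------------------------------------

#' Generate a per-subject cohort table
#'
#' Draws per-subject values from group-wise normal distributions,
#' deterministically under the seed.  This is the input shape the
#' statistical battery consumes: one row per subject with a group label
#' and a measurement.
#'
#' @param groups Data frame with columns `label`, `mean`, `sd` (>= 0) and
#'   `n` (>= 2), one row per group.
#' @param seed Integer seed.
#' @param measure Measurement name recorded in the table.
#' @return Data frame `subject, group, value, measure`.
#' @export
generate_cohort <- function(groups, seed = 1L, measure = "value") {
  groups <- as.data.frame(groups)
  need <- c("label", "mean", "sd", "n")
  if (!all(need %in% names(groups)))
    stop("groups must have columns label, mean, sd, n")
  if (any(groups$sd < 0)) stop("sd must be >= 0")
  if (any(groups$n < 2)) stop("each group needs n >= 2")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(groups)), function(i) {
      g <- groups[i, ]
      data.frame(subject = paste0(g$label, seq_len(g$n)),
                 group = g$label,
                 value = rnorm(g$n, g$mean, g$sd),
                 measure = measure)
    })
    do.call(rbind, rows)
  })
}

#' Write / read cohort tables as CSV (`subject,group,value`)
#'
#' @param table A cohort data frame.
#' @param path CSV path.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("subject", "group", "value") %in% names(df)))
    stop("cohort CSV must have columns subject, group, value")
  df
}
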